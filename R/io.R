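#' Read a genome from FASTA
#'
#' Loads a multi-record FASTA into a [Biostrings::DNAStringSet], uppercases
#' the sequences, converts U to T, and rejects characters outside A/C/G/T/N.
#' Record order is preserved.
#'
#' @param path path to a FASTA file.
#' @return a named `DNAStringSet`.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  g <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop(sprintf("malformed FASTA '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  if (length(g) == 0) stop("FASTA file has no records: ", path, call. = FALSE)
  if (any(Biostrings::width(g) == 0)) {
    stop(sprintf("empty sequence for record '%s' in %s",
                 names(g)[which(Biostrings::width(g) == 0)[1]], path),
         call. = FALSE)
  }
  g <- Biostrings::BStringSet(chartr("u", "t", tolower(g)))
  g <- Biostrings::BStringSet(toupper(g))
  bad <- grepl("[^ACGTN]", as.character(g))
  if (any(bad)) {
    seqc <- as.character(g[[which(bad)[1]]])
    off <- regexpr("[^ACGTN]", seqc)
    stop(sprintf(
      "record '%s': invalid character '%s' at base %d (A/C/G/T/N only)",
      names(g)[which(bad)[1]], substr(seqc, off, off), as.integer(off)),
      call. = FALSE)
  }
  # drop any description after the first whitespace, like most aligners do
  names(g) <- sub("\\s.*$", "", names(g))
  assert_genome(Biostrings::DNAStringSet(g))
}

#' Write a genome to FASTA
#'
#' @param genome a named `DNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  assert_genome(genome)
  Biostrings::writeXStringSet(genome, filepath = path, width = 70)
  invisible(path)
}

#' Read reads from FASTQ or FASTA
#'
#' @param path path to a FASTQ (or FASTA) file; format chosen by extension
#'   (`.fq`/`.fastq` vs anything else).
#' @return a `DNAStringSet` of reads.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) "fastq"
         else "fasta"
  Biostrings::readDNAStringSet(path, format = fmt)
}

#' Write reads to FASTQ
#'
#' Writes plain four-line FASTQ records with a constant quality of "I"
#' (the simulator carries no base-quality model).
#'
#' @param reads a `DNAStringSet` or named character vector of reads.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- as.character(reads)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  lines <- as.vector(rbind(paste0("@", ids), seqs, "+",
                           vapply(nchar(seqs), function(n) {
                             strrep("I", n)
                           }, character(1))))
  writeLines(lines, path)
  invisible(path)
}

# ---- gene models ----------------------------------------------------------

new_gene_models <- function(df) {
  stopifnot(all(c("gene_id", "chrom", "strand", "exons", "cds",
                  "utr5", "utr3") %in% names(df)))
  class(df) <- c("wga_gene_models", class(tibble()))
  df
}

empty_intervals <- function() tibble(start = integer(0), end = integer(0))

validate_gene_models <- function(models) {
  for (i in seq_len(nrow(models))) {
    ex <- models$exons[[i]]
    if (nrow(ex) == 0) {
      stop("gene '", models$gene_id[i], "' has no exons", call. = FALSE)
    }
    ex <- ex[order(ex$start), , drop = FALSE]
    if (any(ex$start >= ex$end)) {
      stop("gene '", models$gene_id[i], "': empty or inverted exon interval",
           call. = FALSE)
    }
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop("gene '", models$gene_id[i], "': overlapping exons",
           call. = FALSE)
    }
    cds <- models$cds[[i]]
    if (nrow(cds) > 0) {
      inside <- vapply(seq_len(nrow(cds)), function(j) {
        any(cds$start[j] >= ex$start & cds$end[j] <= ex$end)
      }, logical(1))
      if (!all(inside)) {
        stop("gene '", models$gene_id[i],
             "': CDS extends outside the exon union", call. = FALSE)
      }
    }
  }
  invisible(models)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon/CDS/UTR features linked by `Parent` attributes into
#' one record per gene. GFF3 1-based inclusive coordinates are converted to
#' the package-internal 0-based half-open convention. When a gene carries
#' several mRNAs, the transcript with the longest total CDS is kept.
#'
#' @param path path to a GFF3 file.
#' @return a `wga_gene_models` tibble with columns `gene_id`, `chrom`,
#'   `strand` and interval list-columns `exons`, `cds`, `utr5`, `utr3`
#'   (each a tibble of `start`, `end`).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    parent = vapply(
      if (!is.null(gr$Parent)) as.list(gr$Parent) else
        rep(list(character(0)), length(gr)),
      function(p) if (length(p)) p[[1]] else NA_character_, character(1))
  )
  genes <- df[df$type == "gene", ]
  if (nrow(genes) == 0) {
    return(new_gene_models(tibble(
      gene_id = character(0), chrom = character(0), strand = character(0),
      exons = list(), cds = list(), utr5 = list(), utr3 = list()
    )))
  }
  mrna <- df[df$type == "mRNA", ]
  kids <- df[df$type %in% c("exon", "CDS", "five_prime_UTR",
                            "three_prime_UTR"), ]
  orphan <- kids$type == "CDS" &
    !(kids$parent %in% c(mrna$id, genes$id))
  if (any(orphan)) {
    stop("CDS feature without a parent gene/mRNA: parent '",
         kids$parent[which(orphan)[1]], "'", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$id[i]
    tx <- mrna[mrna$parent %in% gid, ]
    if (nrow(tx) > 0) {
      # one transcript per gene: keep the longest total CDS
      cds_len <- vapply(tx$id, function(tid) {
        k <- kids[kids$parent == tid & kids$type == "CDS", ]
        sum(k$end - k$start)
      }, numeric(1))
      keep_tx <- tx$id[order(-cds_len, tx$id)[1]]
      k <- kids[kids$parent == keep_tx, ]
    } else {
      k <- kids[kids$parent %in% gid, ]
    }
    grab <- function(type) {
      x <- k[k$type %in% type, c("start", "end")]
      x <- x[order(x$start), ]
      as_tibble(x)
    }
    tibble(
      gene_id = gid, chrom = genes$chrom[i], strand = genes$strand[i],
      exons = list(grab("exon")), cds = list(grab("CDS")),
      utr5 = list(grab("five_prime_UTR")), utr3 = list(grab("three_prime_UTR"))
    )
  })
  out <- new_gene_models(bind_rows(rows))
  validate_gene_models(out)
  out
}

#' Write gene models to GFF3
#'
#' Emits gene/mRNA/exon/CDS/UTR rows (1-based inclusive) with `Parent`
#' links, one transcript per gene.
#'
#' @param models a `wga_gene_models` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  lines <- "##gff-version 3"
  fmt_row <- function(chrom, type, s, e, strand, attr) {
    sprintf("%s\twgacompare\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, s + 1L, e, strand, attr)
  }
  for (i in seq_len(nrow(models))) {
    gid <- models$gene_id[i]
    tid <- paste0(gid, ".t1")
    ex <- models$exons[[i]]
    span <- c(min(ex$start), max(ex$end))
    lines <- c(lines,
      fmt_row(models$chrom[i], "gene", span[1], span[2], models$strand[i],
              paste0("ID=", gid)),
      fmt_row(models$chrom[i], "mRNA", span[1], span[2], models$strand[i],
              paste0("ID=", tid, ";Parent=", gid)))
    emit <- function(tbl, type) {
      if (nrow(tbl) == 0) return(character(0))
      vapply(seq_len(nrow(tbl)), function(j) {
        fmt_row(models$chrom[i], type, tbl$start[j], tbl$end[j],
                models$strand[i], paste0("Parent=", tid))
      }, character(1))
    }
    lines <- c(lines, emit(ex, "exon"), emit(models$cds[[i]], "CDS"),
               emit(models$utr5[[i]], "five_prime_UTR"),
               emit(models$utr3[[i]], "three_prime_UTR"))
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- BED ------------------------------------------------------------------

#' Read a BED file of intervals
#'
#' BED is 0-based half-open, matching the internal convention, so no
#' coordinate shift is applied.
#'
#' @param path path to a BED file (3-6 columns).
#' @return a tibble with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  first <- readLines(path, n = 50)
  first <- first[!startsWith(first, "#")]
  ncol_bed <- length(strsplit(first[1], "\t", fixed = TRUE)[[1]])
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         comment.char = "#",
                         colClasses = c("character", "integer", "integer",
                                        "character", "character",
                                        "character")[seq_len(ncol_bed)],
                         stringsAsFactors = FALSE)
  names(x) <- cols[seq_len(ncol(x))]
  as_tibble(x)
}

#' Write intervals to BED
#'
#' @param x tibble with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  utils::write.table(x[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- VCF ------------------------------------------------------------------

#' Write SNPs and indels to a minimal VCF v4.2
#'
#' SNP records carry `POS` = 1-based reference position; indels are written
#' left-anchored with one preceding reference base. `INFO` stores the source
#' alignment block (`BID`) and the query-side coordinate (`QCHR`, `QPOS`,
#' 1-based). Records are sorted by (chrom, pos).
#'
#' @param snps SNP tibble from [call_variants()] (may have zero rows).
#' @param indels indel tibble from [call_variants()] (may have zero rows).
#' @param reference the reference `DNAStringSet` the positions refer to.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(snps, indels, reference, path) {
  assert_genome(reference, "reference")
  chrlen <- setNames(Biostrings::width(reference), names(reference))
  check_pos <- function(chrom, pos, what) {
    if (length(pos) == 0) return(invisible())
    bad <- !(chrom %in% names(chrlen)) | pos < 0 | pos >= chrlen[chrom]
    if (any(bad)) {
      stop(sprintf("%s record at %s:%d outside the reference",
                   what, chrom[which(bad)[1]], pos[which(bad)[1]] + 1L),
           call. = FALSE)
    }
  }
  recs <- list()
  if (!is.null(snps) && nrow(snps) > 0) {
    check_pos(snps$ref_chrom, snps$ref_pos, "SNP")
    recs[[1]] <- tibble(
      chrom = snps$ref_chrom, pos = snps$ref_pos + 1L,
      ref = snps$ref_base, alt = snps$qry_base,
      info = sprintf("TYPE=SNP;BID=%s;QCHR=%s;QPOS=%d",
                     snps$block_id, snps$qry_chrom, snps$qry_pos + 1L)
    )
  }
  if (!is.null(indels) && nrow(indels) > 0) {
    anchor_pos <- pmax(indels$ref_pos, 0L)
    check_pos(indels$ref_chrom, anchor_pos, "indel")
    anchor <- vapply(seq_len(nrow(indels)), function(i) {
      as.character(Biostrings::subseq(reference[[indels$ref_chrom[i]]],
                                      anchor_pos[i] + 1L, anchor_pos[i] + 1L))
    }, character(1))
    is_del <- indels$kind == "deletion"
    recs[[2]] <- tibble(
      chrom = indels$ref_chrom, pos = anchor_pos + 1L,
      ref = ifelse(is_del, paste0(anchor, indels$seq), anchor),
      alt = ifelse(is_del, anchor, paste0(anchor, indels$seq)),
      info = sprintf("TYPE=%s;LEN=%d;BID=%s;QCHR=%s;QPOS=%d",
                     toupper(substr(indels$kind, 1, 3)), indels$length,
                     indels$block_id, indels$qry_chrom, indels$qry_pos + 1L)
    )
  }
  body <- bind_rows(recs)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(reference),
            Biostrings::width(reference)),
    "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"SNP/INS/DEL\">",
    "##INFO=<ID=LEN,Number=1,Type=Integer,Description=\"Indel length\">",
    "##INFO=<ID=BID,Number=1,Type=String,Description=\"Alignment block\">",
    "##INFO=<ID=QCHR,Number=1,Type=String,Description=\"Query chromosome\">",
    "##INFO=<ID=QPOS,Number=1,Type=Integer,Description=\"Query position\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  if (nrow(body) > 0) {
    body <- body[order(match(body$chrom, names(reference)), body$pos), ]
    lines <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                     body$chrom, body$pos, body$ref, body$alt, body$info)
  } else lines <- character(0)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a VCF written by [write_variants()]
#'
#' Round-trip companion of [write_variants()]; supports only the minimal
#' single-sample-free records this package emits.
#'
#' @param path path to the VCF file.
#' @return list with `snps` and `indels` tibbles in internal 0-based
#'   coordinates.
#' @export
read_variants <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  empty_snps <- tibble(ref_chrom = character(0), ref_pos = integer(0),
                       ref_base = character(0), qry_base = character(0),
                       qry_chrom = character(0), qry_pos = integer(0),
                       block_id = character(0))
  empty_ind <- tibble(ref_chrom = character(0), ref_pos = integer(0),
                      kind = character(0), seq = character(0),
                      length = integer(0), qry_chrom = character(0),
                      qry_pos = integer(0), block_id = character(0))
  if (length(lines) == 0) return(list(snps = empty_snps, indels = empty_ind))
  f <- strsplit(lines, "\t", fixed = TRUE)
  get_info <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(?<=", key, "=)[^;]+"), info,
                                  perl = TRUE))
    ifelse(length(m) == 1, m, NA_character_)
  }
  rows <- lapply(f, function(x) {
    info <- x[8]
    tibble(chrom = x[1], pos = as.integer(x[2]), ref = x[4], alt = x[5],
           type = get_info(info, "TYPE"), bid = get_info(info, "BID"),
           qchr = get_info(info, "QCHR"),
           qpos = as.integer(get_info(info, "QPOS")))
  })
  d <- bind_rows(rows)
  snp <- d[d$type == "SNP", ]
  ind <- d[d$type != "SNP", ]
  snps <- if (nrow(snp)) tibble(
    ref_chrom = snp$chrom, ref_pos = snp$pos - 1L, ref_base = snp$ref,
    qry_base = snp$alt, qry_chrom = snp$qchr, qry_pos = snp$qpos - 1L,
    block_id = snp$bid) else empty_snps
  indels <- if (nrow(ind)) {
    sq <- ifelse(ind$type == "DEL", substring(ind$ref, 2),
                 substring(ind$alt, 2))
    tibble(
      ref_chrom = ind$chrom, ref_pos = ind$pos - 1L,
      kind = ifelse(ind$type == "DEL", "deletion", "insertion"),
      seq = sq, length = nchar(sq), qry_chrom = ind$qchr,
      qry_pos = ind$qpos - 1L, block_id = ind$bid)
  } else empty_ind
  list(snps = snps, indels = indels)
}
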