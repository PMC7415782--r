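# Synthetic genome-pair simulator: an ancestral genome with gene models is
# evolved into two descendants carrying SNPs, small indels, inversions,
# translocations, relocations and TE insertions, with every event recorded
# in an exact truth set (coordinates in both descendants).

#' Mutation configuration for one descendant genome
#'
#' @param snp_rate substitutions per base.
#' @param indel_rate indel events per base.
#' @param indel_size_geometric_p geometric size parameter; sizes are
#'   `1 + Geom(p)`, capped at `indel_max_size`.
#' @param indel_max_size largest indel (bases).
#' @param ts_tv_ratio expected transition:transversion count ratio of
#'   simulated SNPs (default 2:1).
#' @param n_inversions,inversion_size_range count and size range (bases) of
#'   in-place reverse-complemented segments.
#' @param n_translocations,translocation_size_range count and size range of
#'   segments excised and reinserted on a different chromosome.
#' @param n_relocations,relocation_size_range count and size range of
#'   segments excised and reinserted on the same chromosome, at least
#'   `reloc_min_shift` away.
#' @param reloc_min_shift minimum displacement of a relocation (bases).
#' @param te_insertions number of TE insertions.
#' @param te_ltr_fraction fraction of TE insertions that are LTR elements
#'   (5'LTR-internal-3'LTR, LTRs identical at insertion).
#' @param te_ltr_length length of each terminal repeat (bases).
#' @param te_internal_size_range internal-domain size range of LTR elements.
#' @param te_other_size_range size range of non-LTR TE insertions.
#' @param ltr_divergence per-site divergence applied independently to each
#'   terminal repeat after insertion (so expected pairwise LTR difference is
#'   about twice this value).
#' @param seed integer seed driving every random draw for this genome.
#' @return a `wga_mutation_config` list.
#' @export
mutation_config <- function(snp_rate = 0, indel_rate = 0,
                            indel_size_geometric_p = 0.5,
                            indel_max_size = 50,
                            ts_tv_ratio = 2,
                            n_inversions = 0,
                            inversion_size_range = c(2000, 20000),
                            n_translocations = 0,
                            translocation_size_range = c(5000, 20000),
                            n_relocations = 0,
                            relocation_size_range = c(5000, 20000),
                            reloc_min_shift = 10000,
                            te_insertions = 0,
                            te_ltr_fraction = 0.5,
                            te_ltr_length = 500,
                            te_internal_size_range = c(1000, 3000),
                            te_other_size_range = c(200, 2000),
                            ltr_divergence = 0,
                            seed = 1) {
  stopifnot(snp_rate >= 0, snp_rate < 1, indel_rate >= 0, indel_rate < 1,
            indel_size_geometric_p > 0, indel_size_geometric_p <= 1,
            ts_tv_ratio > 0,
            n_inversions >= 0, n_translocations >= 0, n_relocations >= 0,
            te_insertions >= 0,
            te_ltr_fraction >= 0, te_ltr_fraction <= 1,
            ltr_divergence >= 0, ltr_divergence < 1)
  rng_ok <- function(r) length(r) == 2 && r[1] > 0 && r[2] >= r[1]
  stopifnot(rng_ok(inversion_size_range), rng_ok(translocation_size_range),
            rng_ok(relocation_size_range), rng_ok(te_internal_size_range),
            rng_ok(te_other_size_range))
  structure(list(
    snp_rate = snp_rate, indel_rate = indel_rate,
    indel_size_geometric_p = indel_size_geometric_p,
    indel_max_size = indel_max_size, ts_tv_ratio = ts_tv_ratio,
    n_inversions = n_inversions,
    inversion_size_range = inversion_size_range,
    n_translocations = n_translocations,
    translocation_size_range = translocation_size_range,
    n_relocations = n_relocations,
    relocation_size_range = relocation_size_range,
    reloc_min_shift = reloc_min_shift,
    te_insertions = te_insertions, te_ltr_fraction = te_ltr_fraction,
    te_ltr_length = te_ltr_length,
    te_internal_size_range = te_internal_size_range,
    te_other_size_range = te_other_size_range,
    ltr_divergence = ltr_divergence, seed = as.integer(seed)
  ), class = "wga_mutation_config")
}

rand_dna <- function(n, gc = 0.39) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# codons without stops, uniform; returns one string of n_codons codons
rand_cds_body <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  ok <- setdiff(all_codons, c("TAA", "TAG", "TGA"))
  paste(sample(ok, n_codons, replace = TRUE), collapse = "")
}

interval_hits <- function(chrom, start, end, reserved) {
  out <- rep(FALSE, length(chrom))
  if (nrow(reserved) == 0) return(out)
  for (ch in unique(chrom)) {
    r_sel <- reserved$chrom == ch
    if (!any(r_sel)) next
    # merge to sorted disjoint intervals
    o <- order(reserved$start[r_sel])
    rs <- reserved$start[r_sel][o]
    re <- cummax(reserved$end[r_sel][o])
    sel <- which(chrom == ch)
    i <- findInterval(start[sel], rs)
    hit <- (i >= 1 & re[pmax(i, 1)] > start[sel]) |
      (i < length(rs) & rs[pmin(i + 1L, length(rs))] < end[sel])
    out[sel] <- hit
  }
  out
}

#' Generate an ancestral genome with gene models
#'
#' Background sequence is i.i.d. at the requested GC; genes (2-5 exons,
#' 5'/3' UTRs, a valid CDS with start codon, no internal stop, length
#' divisible by three) are placed uniformly without overlap on either
#' strand. Deterministic for a fixed seed.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome (bases).
#' @param gene_count total genes to place.
#' @param gc GC fraction of the background.
#' @param seed integer seed.
#' @return list with `genome` (`DNAStringSet`) and `genes`
#'   (`wga_gene_models` tibble).
#' @export
generate_ancestor <- function(n_chroms, chrom_length, gene_count,
                              gc = 0.39, seed = 1) {
  stopifnot(n_chroms >= 1, chrom_length >= 1000, gene_count >= 0)
  if (gene_count * 3000 > n_chroms * chrom_length / 2) {
    stop("gene_count too large for the requested genome size", call. = FALSE)
  }
  with_seed(seed, {
    chroms <- vapply(seq_len(n_chroms), function(i) {
      rand_dna(chrom_length, gc)
    }, character(1))
    names(chroms) <- sprintf("chr%d", seq_len(n_chroms))
    placed <- tibble(chrom = character(0), start = integer(0),
                     end = integer(0))
    gene_rows <- vector("list", gene_count)
    for (g in seq_len(gene_count)) {
      cds_len <- 3L * sample(100:500, 1)
      n_ex <- sample(2:5, 1)
      utr5_len <- sample(50:200, 1)
      utr3_len <- sample(100:300, 1)
      tx_len <- utr5_len + cds_len + utr3_len
      # random exon cut points on the transcript, each exon >= 20 nt
      repeat {
        cuts <- sort(sample(seq(20L, tx_len - 20L), n_ex - 1))
        if (all(diff(c(0L, cuts, tx_len)) >= 20L)) break
      }
      ex_tx <- tibble(start = c(0L, cuts), end = c(cuts, tx_len))
      introns <- sample(60:500, n_ex - 1, replace = TRUE)
      span <- tx_len + sum(introns)
      # genomic offsets of exons within the gene span (transcript orientation)
      off <- cumsum(c(0L, introns))
      ex_gen <- tibble(start = ex_tx$start + off, end = ex_tx$end + off)
      tx2gen <- function(p) { # transcript coord -> gene-span offset
        i <- findInterval(p, ex_tx$start)
        ex_gen$start[i] + (p - ex_tx$start[i])
      }
      cut_tx <- function(s, e) { # transcript interval -> genomic pieces
        pieces <- lapply(seq_len(n_ex), function(i) {
          a <- max(s, ex_tx$start[i]); b <- min(e, ex_tx$end[i])
          if (a >= b) return(NULL)
          tibble(start = tx2gen(a), end = tx2gen(b - 1L) + 1L)
        })
        bind_rows(pieces)
      }
      cds_gen <- cut_tx(utr5_len, utr5_len + cds_len)
      utr5_gen <- cut_tx(0L, utr5_len)
      utr3_gen <- cut_tx(utr5_len + cds_len, tx_len)
      # sequence in transcript orientation, introns included
      cds_seq <- paste0("ATG", rand_cds_body(cds_len / 3L - 2L),
                        sample(c("TAA", "TAG", "TGA"), 1))
      tx_seq <- paste0(rand_dna(utr5_len, gc), cds_seq,
                       rand_dna(utr3_len, gc))
      gene_seq <- character(2 * n_ex - 1)
      gene_seq[seq(1, 2 * n_ex - 1, by = 2)] <-
        substring(tx_seq, ex_tx$start + 1L, ex_tx$end)
      if (n_ex > 1) {
        gene_seq[seq(2, 2 * n_ex - 2, by = 2)] <-
          vapply(introns, rand_dna, character(1), gc = gc)
      }
      gene_seq <- paste(gene_seq, collapse = "")
      strand <- sample(c("+", "-"), 1)
      flip <- function(tbl) {
        if (nrow(tbl) == 0) return(tbl)
        out <- tibble(start = span - tbl$end, end = span - tbl$start)
        out[order(out$start), ]
      }
      if (strand == "-") {
        gene_seq <- revcomp_chr(gene_seq)
        ex_gen <- flip(ex_gen); cds_gen <- flip(cds_gen)
        utr5_gen <- flip(utr5_gen); utr3_gen <- flip(utr3_gen)
      }
      # place without overlap (200 bp clearance), bounded retries
      ok <- FALSE
      for (try in seq_len(200)) {
        chrom <- sample(names(chroms), 1)
        if (chrom_length - span - 2000 < 1000) {
          stop("chromosomes too short for gene placement", call. = FALSE)
        }
        s <- sample(seq(1000L, chrom_length - span - 1000L), 1)
        if (!any(interval_hits(chrom, s - 200L, s + span + 200L, placed))) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place gene ", g,
                    " without overlap (capacity)", call. = FALSE)
      placed <- bind_rows(placed, tibble(chrom = chrom, start = s,
                                         end = s + span))
      substr(chroms[chrom], s + 1L, s + span) <- gene_seq
      shift <- function(tbl) tibble(start = tbl$start + s, end = tbl$end + s)
      gene_rows[[g]] <- tibble(
        gene_id = sprintf("g%04d", g), chrom = chrom, strand = strand,
        exons = list(shift(ex_gen)), cds = list(shift(cds_gen)),
        utr5 = list(shift(utr5_gen)), utr3 = list(shift(utr3_gen))
      )
    }
    genes <- if (gene_count > 0) {
      bind_rows(gene_rows) %>% arrange(.data$chrom, purrr::map_int(
        .data$exons, ~ min(.x$start)))
    } else {
      tibble(gene_id = character(0), chrom = character(0),
             strand = character(0), exons = list(), cds = list(),
             utr5 = list(), utr3 = list())
    }
    genes <- new_gene_models(genes)
    validate_gene_models(genes)
    list(genome = Biostrings::DNAStringSet(chroms), genes = genes)
  })
}

# ---- event sampling -------------------------------------------------------

sample_events <- function(genome, genes, cfg, reserved, label,
                          avoid_genes = TRUE) {
  chrlen <- setNames(Biostrings::width(genome), names(genome))
  gene_spans <- if (nrow(genes) > 0) {
    tibble(chrom = genes$chrom,
           start = purrr::map_int(genes$exons, ~ min(.x$start)) - 100L,
           end = purrr::map_int(genes$exons, ~ max(.x$end)) + 100L)
  } else tibble(chrom = character(0), start = integer(0), end = integer(0))
  sv_avoid <- function() {
    if (avoid_genes) bind_rows(reserved, gene_spans) else reserved
  }
  draw_interval <- function(size_range, avoid) {
    for (try in seq_len(500)) {
      chrom <- sample(names(chrlen), 1,
                      prob = pmax(chrlen - size_range[2], 1))
      size <- sample(size_range[1]:size_range[2], 1)
      if (chrlen[chrom] - size - 200 < 200) next
      s <- sample(seq(100L, chrlen[chrom] - size - 100L), 1)
      if (!any(interval_hits(chrom, s - 2L, s + size + 2L, avoid))) {
        return(tibble(chrom = chrom, start = s, end = s + size))
      }
    }
    stop("could not sample a disjoint SV interval (capacity); ",
         "reduce event counts or sizes", call. = FALSE)
  }
  draw_point <- function(avoid, chrom_choice = NULL, min_dist_from = NULL,
                         min_dist = 0) {
    for (try in seq_len(500)) {
      chrom <- if (is.null(chrom_choice)) sample(names(chrlen), 1,
                                                 prob = chrlen) else
        chrom_choice
      p <- sample(seq(100L, chrlen[chrom] - 100L), 1)
      if (any(interval_hits(chrom, p - 2L, p + 2L, avoid))) next
      if (!is.null(min_dist_from) &&
          abs(p - min_dist_from) < min_dist) next
      return(tibble(chrom = chrom, pos = p))
    }
    stop("could not sample an insertion point (capacity)", call. = FALSE)
  }
  events <- list()
  eid <- 0
  add_reserved <- function(chrom, start, end) {
    reserved <<- bind_rows(reserved, tibble(chrom = chrom, start = start,
                                            end = end))
  }
  new_id <- function(type) {
    eid <<- eid + 1
    sprintf("%s_%s%03d", label, type, eid)
  }
  # inversions: in place
  for (i in seq_len(cfg$n_inversions)) {
    iv <- draw_interval(cfg$inversion_size_range, sv_avoid())
    events[[length(events) + 1]] <- tibble(
      id = new_id("inv"), type = "inversion", chrom = iv$chrom,
      start = iv$start, end = iv$end,
      dest_chrom = NA_character_, dest_pos = NA_integer_,
      seq = NA_character_)
    add_reserved(iv$chrom, iv$start - 2L, iv$end + 2L)
  }
  # translocations: to a different chromosome
  for (i in seq_len(cfg$n_translocations)) {
    if (length(chrlen) < 2) {
      stop("translocations need at least two chromosomes", call. = FALSE)
    }
    iv <- draw_interval(cfg$translocation_size_range, sv_avoid())
    dst <- draw_point(sv_avoid(),
                      chrom_choice = sample(setdiff(names(chrlen),
                                                    iv$chrom), 1))
    events[[length(events) + 1]] <- tibble(
      id = new_id("tra"), type = "translocation", chrom = iv$chrom,
      start = iv$start, end = iv$end,
      dest_chrom = dst$chrom, dest_pos = dst$pos, seq = NA_character_)
    add_reserved(iv$chrom, iv$start - 2L, iv$end + 2L)
    add_reserved(dst$chrom, dst$pos - 2L, dst$pos + 2L)
  }
  # relocations: same chromosome, displaced by at least reloc_min_shift
  for (i in seq_len(cfg$n_relocations)) {
    iv <- draw_interval(cfg$relocation_size_range, sv_avoid())
    dst <- draw_point(sv_avoid(), chrom_choice = iv$chrom,
                      min_dist_from = (iv$start + iv$end) %/% 2L,
                      min_dist = cfg$reloc_min_shift + (iv$end - iv$start))
    events[[length(events) + 1]] <- tibble(
      id = new_id("rel"), type = "relocation", chrom = iv$chrom,
      start = iv$start, end = iv$end,
      dest_chrom = dst$chrom, dest_pos = dst$pos, seq = NA_character_)
    add_reserved(iv$chrom, iv$start - 2L, iv$end + 2L)
    add_reserved(dst$chrom, dst$pos - 2L, dst$pos + 2L)
  }
  # TE insertions
  for (i in seq_len(cfg$te_insertions)) {
    pt <- draw_point(reserved)
    is_ltr <- runif(1) < cfg$te_ltr_fraction
    if (is_ltr) {
      ltr <- rand_dna(cfg$te_ltr_length, 0.42)
      mutate_sites <- function(s, rate) {
        if (rate <= 0) return(s)
        v <- strsplit(s, "")[[1]]
        hit <- which(runif(length(v)) < rate)
        for (h in hit) {
          v[h] <- sample(setdiff(c("A", "C", "G", "T"), v[h]), 1)
        }
        paste(v, collapse = "")
      }
      ltr5 <- mutate_sites(ltr, cfg$ltr_divergence)
      ltr3 <- mutate_sites(ltr, cfg$ltr_divergence)
      internal <- rand_dna(sample(
        cfg$te_internal_size_range[1]:cfg$te_internal_size_range[2], 1), 0.42)
      seq <- paste0(ltr5, internal, ltr3)
      events[[length(events) + 1]] <- tibble(
        id = new_id("te"), type = "te_ltr", chrom = pt$chrom,
        start = pt$pos, end = pt$pos, dest_chrom = NA_character_,
        dest_pos = NA_integer_, seq = seq)
      attr(events[[length(events)]], "ltr_len") <- cfg$te_ltr_length
    } else {
      seq <- rand_dna(sample(
        cfg$te_other_size_range[1]:cfg$te_other_size_range[2], 1), 0.42)
      events[[length(events) + 1]] <- tibble(
        id = new_id("te"), type = "te_other", chrom = pt$chrom,
        start = pt$pos, end = pt$pos, dest_chrom = NA_character_,
        dest_pos = NA_integer_, seq = seq)
    }
    add_reserved(pt$chrom, pt$pos - 2L, pt$pos + 2L)
  }
  # small indels
  n_indel <- rbinom(1, sum(chrlen), cfg$indel_rate)
  for (i in seq_len(n_indel)) {
    size <- 1L + min(rgeom(1, cfg$indel_size_geometric_p),
                     cfg$indel_max_size - 1L)
    if (runif(1) < 0.5) { # insertion
      pt <- draw_point(reserved)
      events[[length(events) + 1]] <- tibble(
        id = new_id("ins"), type = "small_insertion", chrom = pt$chrom,
        start = pt$pos, end = pt$pos, dest_chrom = NA_character_,
        dest_pos = NA_integer_, seq = rand_dna(size, 0.39))
      add_reserved(pt$chrom, pt$pos - 2L, pt$pos + 2L)
    } else { # deletion
      iv <- draw_interval(c(size, size), reserved)
      events[[length(events) + 1]] <- tibble(
        id = new_id("del"), type = "small_deletion", chrom = iv$chrom,
        start = iv$start, end = iv$end, dest_chrom = NA_character_,
        dest_pos = NA_integer_, seq = NA_character_)
      add_reserved(iv$chrom, iv$start - 2L, iv$end + 2L)
    }
  }
  list(events = if (length(events)) bind_rows(events) else
    tibble(id = character(0), type = character(0), chrom = character(0),
           start = integer(0), end = integer(0),
           dest_chrom = character(0), dest_pos = integer(0),
           seq = character(0)),
    reserved = reserved)
}

# ---- descendant assembly --------------------------------------------------

# build the piece table of one descendant from its event table
build_pieces <- function(genome, events) {
  chrlen <- setNames(Biostrings::width(genome), names(genome))
  removal <- events[events$type %in%
                      c("small_deletion", "translocation", "relocation"), ]
  invs <- events[events$type == "inversion", ]
  inserts <- bind_rows(
    events[events$type %in% c("small_insertion", "te_ltr", "te_other"),
           c("id", "chrom", "start", "seq")] %>%
      rename(pos = "start"),
    events[events$type %in% c("translocation", "relocation"), ] %>%
      mutate(pos = .data$dest_pos, seq = NA_character_) %>%
      select(id = "id", chrom = "dest_chrom", pos = "pos", seq = "seq")
  )
  moved <- events[events$type %in% c("translocation", "relocation"), ]
  pieces <- list()
  for (chrom in names(chrlen)) {
    bp <- sort(unique(c(
      0L, chrlen[[chrom]],
      removal$start[removal$chrom == chrom],
      removal$end[removal$chrom == chrom],
      invs$start[invs$chrom == chrom], invs$end[invs$chrom == chrom],
      inserts$pos[inserts$chrom == chrom]
    )))
    segs <- tibble(start = bp[-length(bp)], end = bp[-1])
    for (i in seq_len(nrow(segs))) {
      s <- segs$start[i]; e <- segs$end[i]
      # insertions attached to breakpoint s
      at <- inserts[inserts$chrom == chrom & inserts$pos == s, ]
      for (j in seq_len(nrow(at))) {
        if (is.na(at$seq[j])) { # a moved segment lands here
          mv <- moved[moved$id == at$id[j], ]
          pieces[[length(pieces) + 1]] <- tibble(
            desc_chrom = chrom, src = "anc", src_chrom = mv$chrom,
            src_start = mv$start, src_end = mv$end, strand = "+",
            novel_seq = NA_character_, event_id = mv$id)
        } else {
          pieces[[length(pieces) + 1]] <- tibble(
            desc_chrom = chrom, src = "novel", src_chrom = NA_character_,
            src_start = NA_integer_, src_end = NA_integer_, strand = "+",
            novel_seq = at$seq[j], event_id = at$id[j])
        }
      }
      # the ancestral segment itself (skipped if removed)
      rem <- removal[removal$chrom == chrom & removal$start <= s &
                       removal$end >= e, ]
      if (nrow(rem) > 0) next
      inv <- invs[invs$chrom == chrom & invs$start <= s & invs$end >= e, ]
      pieces[[length(pieces) + 1]] <- tibble(
        desc_chrom = chrom, src = "anc", src_chrom = chrom,
        src_start = s, src_end = e,
        strand = if (nrow(inv) > 0) "-" else "+",
        novel_seq = NA_character_,
        event_id = if (nrow(inv) > 0) inv$id[1] else NA_character_)
    }
  }
  pieces <- bind_rows(pieces)
  pieces$length <- ifelse(pieces$src == "anc",
                          pieces$src_end - pieces$src_start,
                          nchar(pieces$novel_seq))
  pieces <- pieces %>% group_by(.data$desc_chrom) %>%
    mutate(desc_start = cumsum(c(0, head(.data$length, -1)))) %>%
    ungroup()
  pieces
}

assemble_sequence <- function(genome, pieces) {
  chroms <- unique(pieces$desc_chrom)
  seqs <- vapply(chroms, function(ch) {
    p <- pieces[pieces$desc_chrom == ch, ]
    parts <- vapply(seq_len(nrow(p)), function(i) {
      if (p$src[i] == "novel") return(p$novel_seq[i])
      s <- as.character(Biostrings::subseq(genome[[p$src_chrom[i]]],
                                           p$src_start[i] + 1L,
                                           p$src_end[i]))
      if (p$strand[i] == "-") revcomp_chr(s) else s
    }, character(1))
    paste(parts, collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(setNames(seqs, chroms))
}

# lift table: ancestor position -> descendant position
build_lift <- function(pieces) {
  anc <- pieces[pieces$src == "anc", ]
  split(anc[order(anc$src_chrom, anc$src_start), ], anc$src_chrom[
    order(anc$src_chrom, anc$src_start)])
}

lift_pos <- function(lift, chrom, pos) {
  out_chrom <- rep(NA_character_, length(pos))
  out_pos <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    tab <- lift[[ch]]
    sel <- which(chrom == ch)
    if (is.null(tab)) next
    i <- findInterval(pos[sel], tab$src_start)
    ok <- i >= 1 & pos[sel] < ifelse(i >= 1, tab$src_end[pmax(i, 1)], 0L)
    ii <- i[ok]
    p <- pos[sel][ok]
    fwd <- tab$strand[ii] == "+"
    out_pos[sel][ok] <- ifelse(
      fwd, tab$desc_start[ii] + (p - tab$src_start[ii]),
      tab$desc_start[ii] + (tab$src_end[ii] - 1L - p))
    out_chrom[sel][ok] <- tab$desc_chrom[ii]
  }
  tibble(chrom = out_chrom, pos = out_pos)
}

# left-normalize an indel description against the ancestral sequence
normalize_indel <- function(anc_chrom_seq, pos, seq, kind) {
  # pos: for insertion, the gap offset (insert before `pos`);
  #      for deletion, the first deleted base
  s <- strsplit(seq, "")[[1]]
  if (kind == "insertion") {
    while (pos > 0 &&
           substr(anc_chrom_seq, pos, pos) == s[length(s)]) {
      s <- c(s[length(s)], s[-length(s)])
      pos <- pos - 1L
    }
  } else {
    len <- length(s)
    while (pos > 0 &&
           substr(anc_chrom_seq, pos, pos) ==
           substr(anc_chrom_seq, pos + len, pos + len)) {
      pos <- pos - 1L
    }
    s <- strsplit(substr(anc_chrom_seq, pos + 1L, pos + len), "")[[1]]
  }
  list(pos = pos, seq = paste(s, collapse = ""))
}

lift_gene_models <- function(genes, lift, events) {
  dropped <- character(0)
  rows <- vector("list", nrow(genes))
  indel_fp <- events[events$type %in%
                       c("small_deletion", "small_insertion",
                         "te_ltr", "te_other"), ]
  for (i in seq_len(nrow(genes))) {
    map_tbl <- function(tbl) {
      if (nrow(tbl) == 0) return(tbl)
      a <- lift_pos(lift, rep(genes$chrom[i], nrow(tbl)), tbl$start)
      b <- lift_pos(lift, rep(genes$chrom[i], nrow(tbl)), tbl$end - 1L)
      if (anyNA(a$pos) || anyNA(b$pos) ||
          length(unique(c(a$chrom, b$chrom))) != 1) return(NULL)
      out <- tibble(start = pmin(a$pos, b$pos), end = pmax(a$pos, b$pos) + 1L)
      attr(out, "chrom") <- a$chrom[1]
      attr(out, "flipped") <- any(a$pos > b$pos)
      out[order(out$start), ]
    }
    ex <- map_tbl(genes$exons[[i]])
    cds <- map_tbl(genes$cds[[i]])
    u5 <- map_tbl(genes$utr5[[i]])
    u3 <- map_tbl(genes$utr3[[i]])
    if (is.null(ex) || is.null(cds) ||
        (nrow(genes$utr5[[i]]) > 0 && is.null(u5)) ||
        (nrow(genes$utr3[[i]]) > 0 && is.null(u3))) {
      dropped <- c(dropped, genes$gene_id[i])
      next
    }
    strand <- genes$strand[i]
    if (isTRUE(attr(ex, "flipped"))) {
      strand <- if (strand == "+") "-" else "+"
    }
    cds_hit <- any(interval_hits(rep(genes$chrom[i], nrow(genes$cds[[i]])),
                                 genes$cds[[i]]$start, genes$cds[[i]]$end,
                                 indel_fp))
    rows[[i]] <- tibble(
      gene_id = genes$gene_id[i], chrom = attr(ex, "chrom"),
      strand = strand, exons = list(ex), cds = list(cds),
      utr5 = list(if (is.null(u5)) empty_intervals() else u5),
      utr3 = list(if (is.null(u3)) empty_intervals() else u3),
      cds_disrupted = cds_hit
    )
  }
  keep <- !vapply(rows, is.null, logical(1))
  models <- if (any(keep)) bind_rows(rows[keep]) else
    tibble(gene_id = character(0), chrom = character(0),
           strand = character(0), exons = list(), cds = list(),
           utr5 = list(), utr3 = list(), cds_disrupted = logical(0))
  list(models = new_gene_models(models), dropped = dropped)
}

#' Evolve two descendant genomes from an ancestor
#'
#' Applies the two mutation configurations to independent copies of the
#' ancestor and returns both descendants, their lifted gene models, and an
#' exact truth set with every variant's coordinates in both genomes. Event
#' footprints are sampled disjointly across the two configurations, so each
#' variant falls in sequence that is unrescued in the sibling genome. With
#' an all-zero `config_a` (single-sided mode) genome A equals the ancestor
#' and the truth describes exactly the edits that turn A into B.
#'
#' @param ancestor list from [generate_ancestor()] (or `genome` +
#'   `genes` of the same shape).
#' @param config_a,config_b [mutation_config()] objects for the two
#'   descendants.
#' @param avoid_genes if `TRUE` (default), structural-variant intervals and
#'   their destinations keep clear of gene bodies; SNPs, indels and TE
#'   insertions may still hit genes (flagged in the lifted models).
#' @return list with `genome_a`, `genes_a`, `genome_b`, `genes_b`, and
#'   `truth` (class `wga_truth`).
#' @export
evolve_pair <- function(ancestor, config_a = mutation_config(),
                        config_b = mutation_config(seed = 2),
                        avoid_genes = TRUE) {
  genome <- ancestor$genome
  genes <- ancestor$genes
  assert_genome(genome, "ancestor$genome")
  ev_a <- with_seed(derive_seed(config_a$seed, "events_a"), {
    sample_events(genome, genes, config_a, tibble(
      chrom = character(0), start = integer(0), end = integer(0)),
      "A", avoid_genes)
  })
  ev_b <- with_seed(derive_seed(config_b$seed, "events_b"), {
    sample_events(genome, genes, config_b, ev_a$reserved, "B", avoid_genes)
  })
  reserved_all <- ev_b$reserved
  pieces_a <- build_pieces(genome, ev_a$events)
  pieces_b <- build_pieces(genome, ev_b$events)
  genome_a <- assemble_sequence(genome, pieces_a)
  genome_b <- assemble_sequence(genome, pieces_b)
  lift_a <- build_lift(pieces_a)
  lift_b <- build_lift(pieces_b)

  # SNPs: ancestor positions clear of every event footprint in either genome
  sample_snps <- function(cfg, stream) {
    with_seed(derive_seed(cfg$seed, stream), {
      chrlen <- setNames(Biostrings::width(genome), names(genome))
      n <- rbinom(1, sum(chrlen), cfg$snp_rate)
      if (n == 0) {
        return(tibble(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0)))
      }
      got <- tibble(chrom = character(0), pos = integer(0))
      guard <- 0
      while (nrow(got) < n && guard < 50) {
        guard <- guard + 1
        m <- (n - nrow(got)) * 2L
        chrom <- sample(names(chrlen), m, replace = TRUE, prob = chrlen)
        pos <- floor(runif(m) * chrlen[chrom])
        cand <- tibble(chrom = chrom, pos = as.integer(pos))
        cand <- cand[!interval_hits(cand$chrom, cand$pos, cand$pos + 1L,
                                    reserved_all), ]
        got <- dplyr::distinct(bind_rows(got, cand),
                               .data$chrom, .data$pos)
      }
      got <- head(got, n)
      ref <- vapply(seq_len(nrow(got)), function(i) {
        as.character(Biostrings::subseq(genome[[got$chrom[i]]],
                                        got$pos[i] + 1L, got$pos[i] + 1L))
      }, character(1))
      keep <- ref %in% c("A", "C", "G", "T")
      got <- got[keep, ]; ref <- ref[keep]
      transition <- c(A = "G", G = "A", C = "T", T = "C")
      p_ts <- cfg$ts_tv_ratio / (cfg$ts_tv_ratio + 1)
      is_ts <- runif(nrow(got)) < p_ts
      alt <- character(nrow(got))
      alt[is_ts] <- transition[ref[is_ts]]
      if (any(!is_ts)) {
        alt[!is_ts] <- vapply(which(!is_ts), function(i) {
          sample(setdiff(c("A", "C", "G", "T"),
                         c(ref[i], transition[ref[i]])), 1)
        }, character(1))
      }
      tibble(chrom = got$chrom, pos = got$pos, ref = ref, alt = alt)
    })
  }
  snps_a <- sample_snps(config_a, "snps_a")
  snps_b <- sample_snps(config_b, "snps_b")
  # drop collisions between the two genomes' SNP sets
  if (nrow(snps_a) > 0 && nrow(snps_b) > 0) {
    snps_b <- anti_join(snps_b, snps_a, by = c("chrom", "pos"))
  }
  apply_snps <- function(g, lift, snps) {
    if (nrow(snps) == 0) return(g)
    at <- lift_pos(lift, snps$chrom, snps$pos)
    stopifnot(!anyNA(at$pos))
    for (ch in unique(at$chrom)) {
      sel <- at$chrom == ch
      g[[ch]] <- Biostrings::replaceLetterAt(
        g[[ch]], at$pos[sel] + 1L, snps$alt[sel])
    }
    g
  }
  genome_a <- apply_snps(genome_a, lift_a, snps_a)
  genome_b <- apply_snps(genome_b, lift_b, snps_b)

  # ---- truth assembly -----------------------------------------------------
  both_coords <- function(chrom, pos) {
    a <- lift_pos(lift_a, chrom, pos)
    b <- lift_pos(lift_b, chrom, pos)
    tibble(chrom_a = a$chrom, pos_a = a$pos,
           chrom_b = b$chrom, pos_b = b$pos)
  }
  truth_snps <- bind_rows(
    if (nrow(snps_a)) mutate(snps_a, genome = "A"),
    if (nrow(snps_b)) mutate(snps_b, genome = "B")
  )
  if (is.null(truth_snps) || nrow(truth_snps) == 0) {
    truth_snps <- tibble(genome = character(0), chrom_a = character(0),
                         pos_a = integer(0), base_a = character(0),
                         chrom_b = character(0), pos_b = integer(0),
                         base_b = character(0))
  } else {
    cc <- both_coords(truth_snps$chrom, truth_snps$pos)
    truth_snps <- tibble(
      genome = truth_snps$genome,
      chrom_a = cc$chrom_a, pos_a = cc$pos_a,
      base_a = ifelse(truth_snps$genome == "A", truth_snps$alt,
                      truth_snps$ref),
      chrom_b = cc$chrom_b, pos_b = cc$pos_b,
      base_b = ifelse(truth_snps$genome == "B", truth_snps$alt,
                      truth_snps$ref)
    )
  }
  mk_indel_truth <- function(events, which_genome) {
    ind <- events[events$type %in% c("small_insertion", "small_deletion"), ]
    if (nrow(ind) == 0) {
      return(tibble(id = character(0), genome = character(0),
                    kind = character(0), chrom_anc = character(0),
                    pos_anc = integer(0), seq = character(0),
                    length = integer(0), chrom_a = character(0),
                    pos_a = integer(0), chrom_b = character(0),
                    pos_b = integer(0)))
    }
    rows <- lapply(seq_len(nrow(ind)), function(i) {
      kind <- if (ind$type[i] == "small_insertion") "insertion" else
        "deletion"
      sq <- if (kind == "insertion") ind$seq[i] else
        as.character(Biostrings::subseq(genome[[ind$chrom[i]]],
                                        ind$start[i] + 1L, ind$end[i]))
      nm <- normalize_indel(as.character(genome[[ind$chrom[i]]]),
                            ind$start[i], sq, kind)
      # anchor = ancestral base before the event after left-normalization
      anchor <- nm$pos - 1L
      cc <- both_coords(ind$chrom[i], max(anchor, 0L))
      tibble(id = ind$id[i], genome = which_genome, kind = kind,
             chrom_anc = ind$chrom[i], pos_anc = anchor, seq = nm$seq,
             length = nchar(nm$seq),
             chrom_a = cc$chrom_a, pos_a = cc$pos_a,
             chrom_b = cc$chrom_b, pos_b = cc$pos_b)
    })
    bind_rows(rows)
  }
  truth_indels <- bind_rows(mk_indel_truth(ev_a$events, "A"),
                            mk_indel_truth(ev_b$events, "B"))
  mk_sv_truth <- function(events, pieces, which_genome) {
    sv <- events[events$type %in%
                   c("inversion", "translocation", "relocation"), ]
    if (nrow(sv) == 0) {
      return(tibble(id = character(0), genome = character(0),
                    sv_type = character(0), length = integer(0),
                    chrom_a = character(0), start_a = integer(0),
                    end_a = integer(0), chrom_b = character(0),
                    start_b = integer(0), end_b = integer(0)))
    }
    rows <- lapply(seq_len(nrow(sv)), function(i) {
      # carrier-genome interval from the piece bearing this event id
      pc <- pieces[!is.na(pieces$event_id) & pieces$event_id == sv$id[i] &
                     pieces$src == "anc", ]
      carrier <- tibble(chrom = pc$desc_chrom[1],
                        start = min(pc$desc_start),
                        end = max(pc$desc_start + pc$length))
      # sibling-genome interval: the unmoved ancestral location
      other_lift <- if (which_genome == "A") lift_b else lift_a
      s <- lift_pos(other_lift, sv$chrom[i], sv$start[i])
      e <- lift_pos(other_lift, sv$chrom[i], sv$end[i] - 1L)
      sib <- tibble(chrom = s$chrom, start = min(s$pos, e$pos),
                    end = max(s$pos, e$pos) + 1L)
      ga <- if (which_genome == "A") carrier else sib
      gb <- if (which_genome == "A") sib else carrier
      tibble(id = sv$id[i], genome = which_genome, sv_type = sv$type[i],
             length = sv$end[i] - sv$start[i],
             chrom_a = ga$chrom, start_a = ga$start, end_a = ga$end,
             chrom_b = gb$chrom, start_b = gb$start, end_b = gb$end)
    })
    bind_rows(rows)
  }
  truth_svs <- bind_rows(mk_sv_truth(ev_a$events, pieces_a, "A"),
                         mk_sv_truth(ev_b$events, pieces_b, "B"))
  mk_te_truth <- function(events, pieces, cfg, which_genome) {
    te <- events[events$type %in% c("te_ltr", "te_other"), ]
    if (nrow(te) == 0) {
      return(tibble(id = character(0), genome = character(0),
                    chrom = character(0), start = integer(0),
                    end = integer(0), is_ltr = logical(0),
                    ltr_length = integer(0), ltr5_seq = character(0),
                    ltr3_seq = character(0)))
    }
    rows <- lapply(seq_len(nrow(te)), function(i) {
      pc <- pieces[!is.na(pieces$event_id) & pieces$event_id == te$id[i], ]
      is_ltr <- te$type[i] == "te_ltr"
      L <- if (is_ltr) cfg$te_ltr_length else NA_integer_
      tibble(id = te$id[i], genome = which_genome,
             chrom = pc$desc_chrom[1], start = pc$desc_start[1],
             end = pc$desc_start[1] + pc$length[1], is_ltr = is_ltr,
             ltr_length = L,
             ltr5_seq = if (is_ltr) substr(te$seq[i], 1, L) else
               NA_character_,
             ltr3_seq = if (is_ltr) substr(te$seq[i],
                                           nchar(te$seq[i]) - L + 1L,
                                           nchar(te$seq[i])) else
               NA_character_)
    })
    bind_rows(rows)
  }
  truth_te <- bind_rows(mk_te_truth(ev_a$events, pieces_a, config_a, "A"),
                        mk_te_truth(ev_b$events, pieces_b, config_b, "B"))
  lifted_a <- lift_gene_models(genes, lift_a, ev_a$events)
  lifted_b <- lift_gene_models(genes, lift_b, ev_b$events)
  shared <- intersect(lifted_a$models$gene_id, lifted_b$models$gene_id)
  orthologs <- tibble(gene_a = shared, gene_b = shared)
  truth <- structure(list(
    snps = truth_snps, indels = truth_indels, svs = truth_svs,
    te = truth_te, orthologs = orthologs,
    genes_dropped_a = lifted_a$dropped, genes_dropped_b = lifted_b$dropped
  ), class = "wga_truth")
  list(genome_a = genome_a, genes_a = lifted_a$models,
       genome_b = genome_b, genes_b = lifted_b$models, truth = truth)
}

#' Simulate error-prone shotgun reads from a genome
#'
#' Reads are drawn uniformly with replacement from both strands; total bases
#' approximate `coverage` times the genome length. Substitution errors are
#' i.i.d. per base. Deterministic per seed.
#'
#' @param genome a `DNAStringSet`.
#' @param coverage fold coverage.
#' @param read_length read length (bases).
#' @param error_rate per-base substitution error rate.
#' @param seed integer seed.
#' @return a named `DNAStringSet` of reads.
#' @export
simulate_reads <- function(genome, coverage, read_length,
                           error_rate = 0, seed = 1) {
  assert_genome(genome)
  chrlen <- setNames(Biostrings::width(genome), names(genome))
  if (read_length > min(chrlen)) {
    stop("read_length exceeds the shortest chromosome", call. = FALSE)
  }
  if (coverage <= 0) stop("coverage must be positive", call. = FALSE)
  with_seed(seed, {
    n_reads <- as.integer(round(coverage * sum(chrlen) / read_length))
    chrom <- sample(names(chrlen), n_reads, replace = TRUE,
                    prob = chrlen - read_length + 1)
    start <- vapply(chrlen[chrom] - read_length, function(m) {
      as.integer(floor(runif(1) * (m + 1)))
    }, integer(1))
    minus <- runif(n_reads) < 0.5
    seqs <- character(n_reads)
    for (ch in unique(chrom)) {
      sel <- which(chrom == ch)
      v <- Biostrings::Views(genome[[ch]], start = start[sel] + 1L,
                             width = read_length)
      seqs[sel] <- as.character(v)
    }
    seqs[minus] <- revcomp_chr(seqs[minus])
    if (error_rate > 0) {
      n_err <- rbinom(1, n_reads * read_length, error_rate)
      if (n_err > 0) {
        at_read <- sample.int(n_reads, n_err, replace = TRUE)
        at_pos <- sample.int(read_length, n_err, replace = TRUE)
        for (k in seq_len(n_err)) {
          old <- substr(seqs[at_read[k]], at_pos[k], at_pos[k])
          if (!old %in% c("A", "C", "G", "T")) next
          substr(seqs[at_read[k]], at_pos[k], at_pos[k]) <-
            sample(setdiff(c("A", "C", "G", "T"), old), 1)
        }
      }
    }
    Biostrings::DNAStringSet(setNames(
      seqs, sprintf("read%07d", seq_len(n_reads))))
  })
}

#' Write a truth set to disk
#'
#' The JSON file is the authoritative record; per-genome BED files of SV and
#' TE intervals are written alongside for interval tools.
#'
#' @param truth a `wga_truth` object from [evolve_pair()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "wga_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    lapply(unclass(truth), function(x) x),
    file.path(dir, "truth.json"), dataframe = "rows", na = "null")
  if (nrow(truth$svs) > 0) {
    write_bed(tibble(chrom = truth$svs$chrom_a, start = truth$svs$start_a,
                     end = truth$svs$end_a,
                     name = paste0(truth$svs$sv_type, ":", truth$svs$id)),
              file.path(dir, "sv_a.bed"))
    write_bed(tibble(chrom = truth$svs$chrom_b, start = truth$svs$start_b,
                     end = truth$svs$end_b,
                     name = paste0(truth$svs$sv_type, ":", truth$svs$id)),
              file.path(dir, "sv_b.bed"))
  }
  for (g in c("A", "B")) {
    te <- truth$te[truth$te$genome == g, ]
    if (nrow(te) > 0) {
      write_bed(tibble(chrom = te$chrom, start = te$start, end = te$end,
                       name = ifelse(te$is_ltr, "te_ltr", "te_other")),
                file.path(dir, sprintf("te_%s.bed", tolower(g))))
    }
  }
  invisible(dir)
}
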