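# SNP/indel extraction from one-to-one alignment blocks, substitution
# spectrum, per-genome densities, and pairwise promoter comparison.

#' Call SNPs and indels from one-to-one alignment blocks
#'
#' Walks each block's edit path: every mismatch column yields one SNP;
#' every maximal run of insertion (or deletion) columns yields one indel,
#' left-aligned within its repeat context as in VCF convention. Query
#' coordinates are strand-adjusted; for reverse-strand blocks the reported
#' query base is the complement of the genome base at the mapped position
#' (i.e. the base actually aligned to the reference).
#'
#' @param blocks one-to-one `wga_blocks` (checked; see
#'   [assert_one_to_one()]).
#' @param ref,qry the aligned genomes.
#' @return list with `snps` and `indels` tibbles sorted by
#'   (ref_chrom, ref_pos), in 0-based coordinates.
#' @export
call_variants <- function(blocks, ref, qry) {
  assert_genome(ref, "ref")
  assert_genome(qry, "qry")
  assert_one_to_one(blocks)
  snp_rows <- list()
  ind_rows <- list()
  qlen <- setNames(Biostrings::width(qry), names(qry))
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    ops <- parse_edit_path(b$edit_path)
    if (nrow(ops) == 0) next
    ref_consume <- ifelse(ops$op %in% c("=", "X", "D"), ops$len, 0L)
    qry_consume <- ifelse(ops$op %in% c("=", "X", "I"), ops$len, 0L)
    ref_off <- cumsum(c(0L, head(ref_consume, -1)))
    qry_off <- cumsum(c(0L, head(qry_consume, -1)))
    M <- qlen[[b$qry_chrom]]
    ref_chr_str <- as.character(ref[[b$ref_chrom]])
    # query sequence in walk orientation (revcomp space for '-')
    qry_walk_str <- if (b$strand == "-") {
      revcomp_chr(as.character(qry[[b$qry_chrom]]))
    } else as.character(qry[[b$qry_chrom]])
    walk_q0 <- if (b$strand == "-") M - b$qry_end else b$qry_start
    # SNPs from mismatch runs
    xs <- which(ops$op == "X")
    if (length(xs) > 0) {
      rpos <- unlist(lapply(xs, function(j) {
        b$ref_start + ref_off[j] + seq_len(ops$len[j]) - 1L
      }))
      qpos_walk <- unlist(lapply(xs, function(j) {
        walk_q0 + qry_off[j] + seq_len(ops$len[j]) - 1L
      }))
      rbase <- substring(ref_chr_str, rpos + 1L, rpos + 1L)
      qbase_walk <- substring(qry_walk_str, qpos_walk + 1L, qpos_walk + 1L)
      qpos_fwd <- if (b$strand == "-") M - qpos_walk - 1L else qpos_walk
      snp_rows[[length(snp_rows) + 1]] <- tibble(
        ref_chrom = b$ref_chrom, ref_pos = rpos, ref_base = rbase,
        qry_base = qbase_walk, qry_chrom = b$qry_chrom,
        qry_pos = qpos_fwd, block_id = b$block_id
      )
    }
    # indels from I/D runs
    ids <- which(ops$op %in% c("I", "D"))
    if (length(ids) > 0) {
      rows <- lapply(ids, function(j) {
        is_ins <- ops$op[j] == "I"
        len <- ops$len[j]
        rp <- b$ref_start + ref_off[j]      # first ref base of run (D) or gap
        qp <- walk_q0 + qry_off[j]          # first qry base of run (I) or gap
        if (is_ins) {
          sq <- substr(qry_walk_str, qp + 1L, qp + len)
          # left-align against the reference context
          pos <- rp # gap offset in ref coordinates
          s <- strsplit(sq, "")[[1]]
          while (pos > b$ref_start &&
                 substr(ref_chr_str, pos, pos) == s[length(s)]) {
            s <- c(s[length(s)], s[-length(s)])
            pos <- pos - 1L
          }
          qfwd <- if (b$strand == "-") M - qp - len else qp
          tibble(ref_chrom = b$ref_chrom, ref_pos = pos - 1L,
                 kind = "insertion", seq = paste(s, collapse = ""),
                 length = len, qry_chrom = b$qry_chrom, qry_pos = qfwd,
                 block_id = b$block_id)
        } else {
          pos <- rp
          while (pos > b$ref_start &&
                 substr(ref_chr_str, pos, pos) ==
                 substr(ref_chr_str, pos + len, pos + len)) {
            pos <- pos - 1L
          }
          sq <- substr(ref_chr_str, pos + 1L, pos + len)
          qfwd <- if (b$strand == "-") M - qp else qp
          tibble(ref_chrom = b$ref_chrom, ref_pos = pos - 1L,
                 kind = "deletion", seq = sq, length = len,
                 qry_chrom = b$qry_chrom, qry_pos = qfwd,
                 block_id = b$block_id)
        }
      })
      ind_rows[[length(ind_rows) + 1]] <- bind_rows(rows)
    }
  }
  snps <- if (length(snp_rows)) bind_rows(snp_rows) else
    tibble(ref_chrom = character(0), ref_pos = integer(0),
           ref_base = character(0), qry_base = character(0),
           qry_chrom = character(0), qry_pos = integer(0),
           block_id = character(0))
  indels <- if (length(ind_rows)) bind_rows(ind_rows) else
    tibble(ref_chrom = character(0), ref_pos = integer(0),
           kind = character(0), seq = character(0), length = integer(0),
           qry_chrom = character(0), qry_pos = integer(0),
           block_id = character(0))
  list(snps = arrange(snps, .data$ref_chrom, .data$ref_pos),
       indels = arrange(indels, .data$ref_chrom, .data$ref_pos))
}

#' Directed substitution spectrum of a SNP set
#'
#' @param snps SNP tibble from [call_variants()].
#' @return tibble with one row per directed substitution type (12 types),
#'   `count` and `fraction`; attribute `zero_total` flags an empty input
#'   (fractions are then `NA`).
#' @export
snp_spectrum <- function(snps) {
  bases <- c("A", "C", "G", "T")
  types <- expand.grid(from = bases, to = bases,
                       stringsAsFactors = FALSE) %>%
    filter(.data$from != .data$to) %>%
    arrange(.data$from, .data$to)
  counts <- vapply(seq_len(nrow(types)), function(i) {
    sum(snps$ref_base == types$from[i] & snps$qry_base == types$to[i])
  }, numeric(1))
  total <- sum(counts)
  out <- tibble(
    from = types$from, to = types$to, count = counts,
    fraction = if (total > 0) counts / total else rep(NA_real_, 12)
  )
  transition_pairs <- c("A>G", "G>A", "C>T", "T>C")
  out$is_transition <- paste0(out$from, ">", out$to) %in% transition_pairs
  attr(out, "zero_total") <- total == 0
  out
}

#' Variant density per kilobase
#'
#' @param count number of variants.
#' @param genome_size genome size in bases.
#' @return density per kilobase, rounded to one decimal (half away from
#'   zero).
#' @examples
#' variant_density(4561825, 270.3e6) # 16.9
#' @export
variant_density <- function(count, genome_size) {
  if (genome_size <= 0) stop("genome_size must be positive", call. = FALSE)
  round_half_away(count / (genome_size / 1000), 1)
}

#' Compare two promoter (or other short) sequences
#'
#' Globally aligns the two sequences with the package alignment scores and
#' reports maximal insertion, deletion and substitution runs of at least
#' `min_event` bases, with coordinates in both sequences.
#'
#' @param seq_a,seq_b character or `DNAString` sequences (A is the
#'   reference side).
#' @param min_event smallest reported event length (default 5).
#' @return tibble of events: `type` (insertion/deletion/substitution),
#'   `start_a`, `end_a`, `start_b`, `end_b` (0-based half-open; empty
#'   interval on the non-carrying side), `length`, `seq`.
#' @export
promoter_diff <- function(seq_a, seq_b, min_event = 5) {
  a <- toupper(as.character(seq_a))
  b <- toupper(as.character(seq_b))
  if (nchar(a) == 0 || nchar(b) == 0) {
    stop("both sequences must be non-empty", call. = FALSE)
  }
  aln <- nw_align_cpp(a, b)
  ops <- parse_edit_path(aln$path)
  a_consume <- ifelse(ops$op %in% c("=", "X", "D"), ops$len, 0L)
  b_consume <- ifelse(ops$op %in% c("=", "X", "I"), ops$len, 0L)
  a_off <- cumsum(c(0L, head(a_consume, -1)))
  b_off <- cumsum(c(0L, head(b_consume, -1)))
  sel <- which(ops$op %in% c("X", "I", "D") & ops$len >= min_event)
  rows <- lapply(sel, function(j) {
    type <- c(X = "substitution", I = "insertion", D = "deletion")[ops$op[j]]
    la <- a_consume[j]; lb <- b_consume[j]
    tibble(
      type = unname(type),
      start_a = a_off[j], end_a = a_off[j] + la,
      start_b = b_off[j], end_b = b_off[j] + lb,
      length = ops$len[j],
      seq = if (ops$op[j] == "I") substr(b, b_off[j] + 1L, b_off[j] + lb)
            else substr(a, a_off[j] + 1L, a_off[j] + la)
    )
  })
  if (length(rows) == 0) {
    return(tibble(type = character(0), start_a = integer(0),
                  end_a = integer(0), start_b = integer(0),
                  end_b = integer(0), length = integer(0),
                  seq = character(0)))
  }
  bind_rows(rows)
}
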