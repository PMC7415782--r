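# Structural-variant classification from one-to-one alignment blocks:
# inversions via reverse-strand blocks with forward flank support, and
# translocations/relocations as off-backbone single-copy homologous blocks.

empty_svs <- function() {
  tibble(sv_id = character(0), sv_type = character(0),
         ref_chrom = character(0), ref_start = integer(0),
         ref_end = integer(0), qry_chrom = character(0),
         qry_start = integer(0), qry_end = integer(0),
         length = integer(0), identity = numeric(0),
         support_block_ids = character(0))
}

#' Detect inversions from one-to-one alignment blocks
#'
#' A candidate is a reverse-strand block whose nearest neighbours (same
#' reference and query chromosome, by reference coordinate) on both sides
#' are forward-strand; it is kept only when both flanking forward blocks
#' reach `flank_min_identity` percent identity. Retained reverse-strand
#' blocks separated by at most `merge_gap` reference bases are merged into
#' one record. Merged spans whose reference and query lengths disagree by
#' more than 20 percent are dropped (and reported via a message) in place
#' of manual curation.
#'
#' @param blocks one-to-one `wga_blocks`.
#' @param flank_min_identity minimum identity of both flanks (default 90).
#' @param merge_gap merge distance in reference bases (default 50).
#' @return SV tibble (`sv_type` = "inversion") with length-weighted mean
#'   identity and supporting block ids.
#' @export
detect_inversions <- function(blocks, flank_min_identity = 90,
                              merge_gap = 50) {
  assert_one_to_one(blocks)
  out <- list()
  pairs <- dplyr::distinct(blocks, .data$ref_chrom, .data$qry_chrom)
  for (pi in seq_len(nrow(pairs))) {
    bb <- blocks[blocks$ref_chrom == pairs$ref_chrom[pi] &
                   blocks$qry_chrom == pairs$qry_chrom[pi], ]
    bb <- bb[order(bb$ref_start), ]
    if (nrow(bb) == 0) next
    # maximal runs of reverse-strand blocks; a run is a candidate when its
    # nearest forward neighbours on both sides exist and match well enough
    is_rev <- bb$strand == "-"
    run_id <- cumsum(c(1L, as.integer(diff(is_rev) != 0)))
    keep <- logical(nrow(bb))
    for (rid in unique(run_id[is_rev])) {
      idx <- which(run_id == rid)
      left <- if (min(idx) > 1) bb[min(idx) - 1, ] else NULL
      right <- if (max(idx) < nrow(bb)) bb[max(idx) + 1, ] else NULL
      if (is.null(left) || is.null(right)) next
      if (left$strand != "+" || right$strand != "+") next
      if (left$identity < flank_min_identity ||
          right$identity < flank_min_identity) next
      keep[idx] <- TRUE
    }
    cand <- bb[keep, ]
    if (nrow(cand) == 0) next
    # merge candidates within merge_gap on the reference
    cand <- cand[order(cand$ref_start), ]
    grp <- cumsum(c(1L, as.integer(
      cand$ref_start[-1] - cand$ref_end[-nrow(cand)] > merge_gap)))
    for (g in unique(grp)) {
      m <- cand[grp == g, ]
      rlen <- max(m$ref_end) - min(m$ref_start)
      qlen <- max(m$qry_end) - min(m$qry_start)
      if (abs(rlen - qlen) > 0.2 * max(rlen, qlen)) {
        message("dropping inversion candidate with discordant span at ",
                m$ref_chrom[1], ":", min(m$ref_start))
        next
      }
      out[[length(out) + 1]] <- tibble(
        sv_type = "inversion",
        ref_chrom = m$ref_chrom[1], ref_start = min(m$ref_start),
        ref_end = max(m$ref_end),
        qry_chrom = m$qry_chrom[1], qry_start = min(m$qry_start),
        qry_end = max(m$qry_end),
        length = max(m$ref_end) - min(m$ref_start),
        identity = sum(m$identity * (m$ref_end - m$ref_start)) /
          sum(m$ref_end - m$ref_start),
        support_block_ids = paste(m$block_id, collapse = ",")
      )
    }
  }
  res <- if (length(out)) bind_rows(out) else return(empty_svs())
  res <- arrange(res, .data$ref_chrom, .data$ref_start)
  res$sv_id <- sprintf("inv%04d", seq_len(nrow(res)))
  res[, names(empty_svs())]
}

# maximum-weight collinear backbone chain per reference chromosome
backbone_ids <- function(blocks) {
  unlist(lapply(unique(blocks$ref_chrom), function(ch) {
    bb <- blocks[blocks$ref_chrom == ch, ]
    best <- NULL
    best_w <- -Inf
    # consider each candidate query chromosome; the backbone is the
    # heaviest forward-collinear chain over one query partner
    for (qch in unique(bb$qry_chrom)) {
      s <- bb[bb$qry_chrom == qch & bb$strand == "+", ]
      if (nrow(s) == 0) next
      ch_res <- chain_best_cpp(s$ref_start, s$ref_end, s$qry_start,
                               s$qry_end,
                               (s$ref_end - s$ref_start) * s$identity)
      if (ch_res$weight > best_w) {
        best_w <- ch_res$weight
        best <- s$block_id[ch_res$idx]
      }
    }
    best
  }))
}

#' Detect translocations and relocations
#'
#' Builds a collinear backbone per reference chromosome (the
#' maximum-weight forward chain of blocks, weight = span times identity).
#' Every off-backbone block longer than `min_len` with identity above
#' `min_identity` (both strict) becomes a structural variant:
#' a translocation when its query chromosome differs from the backbone's
#' query partner for that reference chromosome (inter-chromosomal), a
#' relocation otherwise (intra-chromosomal, order-breaking). Blocks listed
#' in `exclude_ids` (e.g. inversion support) are ignored.
#'
#' @param blocks one-to-one `wga_blocks`.
#' @param min_len length threshold in bases, strict (default 100).
#' @param min_identity identity threshold in percent, strict (default 90).
#' @param exclude_ids block ids to ignore.
#' @return SV tibble with `sv_type` translocation/relocation.
#' @export
detect_transloc_reloc <- function(blocks, min_len = 100, min_identity = 90,
                                  exclude_ids = character(0)) {
  assert_one_to_one(blocks)
  bb <- blocks[!(blocks$block_id %in% exclude_ids), ]
  if (nrow(bb) == 0) return(empty_svs())
  bbone <- backbone_ids(bb)
  expected_partner <- bb[bb$block_id %in% bbone, ] %>%
    group_by(.data$ref_chrom) %>%
    summarise(partner = .data$qry_chrom[which.max(
      .data$ref_end - .data$ref_start)], .groups = "drop")
  off <- bb[!(bb$block_id %in% bbone) & bb$strand == "+", ]
  off <- off[(off$ref_end - off$ref_start) > min_len &
               off$identity > min_identity, ]
  if (nrow(off) == 0) return(empty_svs())
  off <- left_join(off, expected_partner, by = "ref_chrom")
  res <- tibble(
    sv_type = ifelse(!is.na(off$partner) & off$qry_chrom != off$partner,
                     "translocation", "relocation"),
    ref_chrom = off$ref_chrom, ref_start = off$ref_start,
    ref_end = off$ref_end, qry_chrom = off$qry_chrom,
    qry_start = off$qry_start, qry_end = off$qry_end,
    length = off$ref_end - off$ref_start, identity = off$identity,
    support_block_ids = off$block_id
  ) %>% arrange(.data$ref_chrom, .data$ref_start)
  res$sv_id <- sprintf("%s%04d",
                       ifelse(res$sv_type == "translocation", "tra", "rel"),
                       seq_len(nrow(res)))
  res[, names(empty_svs())]
}

#' Call all structural-variant classes
#'
#' Runs [detect_inversions()] first, then [detect_transloc_reloc()] with
#' inversion support blocks excluded, so no inversion is double-reported.
#'
#' @param blocks one-to-one `wga_blocks`.
#' @param flank_min_identity,merge_gap see [detect_inversions()].
#' @param min_len,min_identity see [detect_transloc_reloc()].
#' @return combined SV tibble.
#' @export
call_svs <- function(blocks, flank_min_identity = 90, merge_gap = 50,
                     min_len = 100, min_identity = 90) {
  inv <- detect_inversions(blocks, flank_min_identity, merge_gap)
  used <- unlist(strsplit(inv$support_block_ids, ","))
  # any reverse-strand block is inversion evidence, never a translocation
  rev_ids <- blocks$block_id[blocks$strand == "-"]
  tr <- detect_transloc_reloc(blocks, min_len, min_identity,
                              exclude_ids = unique(c(used, rev_ids)))
  bind_rows(inv, tr)
}

#' Summarise recovery of simulated SVs
#'
#' Matches reported SVs to a truth set by class and reciprocal overlap of
#' the reference-genome intervals.
#'
#' @param svs SV tibble from [call_svs()].
#' @param truth_svs `truth$svs` tibble from [evolve_pair()] (coordinates in
#'   genome A = the alignment reference).
#' @param min_reciprocal minimum reciprocal overlap (default 0.5).
#' @param classes named list mapping truth types to acceptable reported
#'   types.
#' @return list with per-class `recall`, `precision` and the match table.
#' @export
sv_recovery <- function(svs, truth_svs, min_reciprocal = 0.5,
                        classes = list(
                          inversion = "inversion",
                          translocation = c("translocation", "relocation"),
                          relocation = c("relocation", "translocation"))) {
  reciprocal <- function(s1, e1, s2, e2) {
    ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
    pmin(ov / (e1 - s1), ov / (e2 - s2))
  }
  truth_hit <- vapply(seq_len(nrow(truth_svs)), function(i) {
    ok_types <- classes[[truth_svs$sv_type[i]]]
    cand <- svs[svs$sv_type %in% ok_types &
                  svs$ref_chrom == truth_svs$chrom_a[i], ]
    if (nrow(cand) == 0) return(FALSE)
    any(reciprocal(cand$ref_start, cand$ref_end,
                   truth_svs$start_a[i], truth_svs$end_a[i]) >=
          min_reciprocal)
  }, logical(1))
  pred_hit <- vapply(seq_len(nrow(svs)), function(i) {
    cand <- truth_svs[truth_svs$chrom_a == svs$ref_chrom[i], ]
    if (nrow(cand) == 0) return(FALSE)
    any(reciprocal(cand$start_a, cand$end_a,
                   svs$ref_start[i], svs$ref_end[i]) >= min_reciprocal)
  }, logical(1))
  per_class <- lapply(split(seq_len(nrow(truth_svs)), truth_svs$sv_type),
                      function(ix) mean(truth_hit[ix]))
  list(recall = per_class,
       overall_recall = mean(truth_hit),
       precision = if (nrow(svs)) mean(pred_hit) else NA_real_,
       truth_matched = truth_hit, pred_matched = pred_hit)
}
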