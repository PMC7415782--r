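# Anchor-based pairwise whole-genome alignment: MUM anchors, maximum-weight
# collinear chaining with affine-gap closing, identity/length filtering and
# one-to-one block selection.

empty_blocks <- function() {
  new_blocks(tibble(
    block_id = character(0), ref_chrom = character(0),
    ref_start = integer(0), ref_end = integer(0),
    qry_chrom = character(0), qry_start = integer(0), qry_end = integer(0),
    strand = character(0), identity = numeric(0),
    aligned_columns = numeric(0), n_match = numeric(0),
    edit_path = character(0)
  ))
}

new_blocks <- function(df) {
  class(df) <- unique(c("wga_blocks", class(tibble())))
  df
}

#' Find maximal unique match (MUM) anchors between two genomes
#'
#' Reports every maximal exact match of at least `min_len` bases that
#' occurs exactly once in the reference and once in the query (counting
#' both query strands), on either strand. Matches never contain N.
#'
#' @param ref,qry named `DNAStringSet` genomes.
#' @param min_len minimum anchor length (default 40).
#' @return tibble of anchors: `ref_chrom`, `ref_start`, `ref_end`,
#'   `qry_chrom`, `qry_start`, `qry_end` (query coordinates always on the
#'   forward strand), `length`, `strand`; sorted by (ref_chrom, ref_start).
#' @export
find_anchors <- function(ref, qry, min_len = 40) {
  assert_genome(ref, "ref")
  assert_genome(qry, "qry")
  d <- find_mums_cpp(as.character(ref), as.character(qry),
                     as.integer(min_len))
  tibble(
    ref_chrom = names(ref)[d$ref_seq],
    ref_start = d$ref_start,
    ref_end = d$ref_start + d$length,
    qry_chrom = names(qry)[d$qry_seq],
    qry_start = d$qry_start,
    qry_end = d$qry_start + d$length,
    length = d$length,
    strand = d$strand
  )
}

# total covered length of each interval [s, e) by the union of the used
# intervals
ranges_overlap_len <- function(s, e, used_s, used_e) {
  o <- order(used_s)
  us <- used_s[o]
  ue <- used_e[o]
  grp <- if (length(us) > 1) {
    cumsum(c(1L, as.integer(us[-1] > cummax(ue)[-length(ue)])))
  } else 1L
  ms <- us[!duplicated(grp)]
  me <- as.numeric(tapply(ue, grp, max))
  pre <- c(0, cumsum(me - ms))
  covered_below <- function(x) {
    i <- findInterval(x, ms)
    ifelse(i == 0, 0,
           pre[pmax(i, 1)] +
             pmin(pmax(x - ms[pmax(i, 1)], 0), me[pmax(i, 1)] - ms[pmax(i, 1)]))
  }
  covered_below(e) - covered_below(s)
}

#' Chain anchors and close gaps into alignment blocks
#'
#' Per (ref chromosome, qry chromosome, strand) the maximum-weight collinear
#' chains of anchors are extracted repeatedly (weight = anchor length) until
#' no chain reaches `min_cluster` total anchor bases. Chains are split where
#' the inter-anchor gap exceeds `max_gap` on either genome or where the two
#' gap lengths differ by more than `band`; remaining gaps are closed with
#' affine-gap alignment (match +1, mismatch -1, gap open -4, extend -1),
#' yielding one block with an exact edit path per chain segment.
#'
#' Edit paths are run-length strings over `=` (match), `X` (mismatch),
#' `I` (insertion in query) and `D` (deletion from query), walking the
#' reference left to right; reverse-strand blocks walk the query in
#' reverse-complement space.
#'
#' @param anchors anchor tibble from [find_anchors()].
#' @param ref,qry the genomes the anchors refer to.
#' @param max_gap largest bridgeable gap (default 1000).
#' @param band largest tolerated difference between the ref-side and
#'   qry-side gap lengths (default 200); larger disagreements split the
#'   block rather than force an alignment.
#' @param min_cluster minimum total anchor bases per chain (default 90).
#' @return a `wga_blocks` tibble sorted by (ref_chrom, ref_start), with
#'   identity as percent of matching aligned columns.
#' @export
chain_and_extend <- function(anchors, ref, qry, max_gap = 1000, band = 200,
                             min_cluster = 90) {
  assert_genome(ref, "ref")
  assert_genome(qry, "qry")
  if (nrow(anchors) == 0) return(empty_blocks())
  qlen <- setNames(Biostrings::width(qry), names(qry))
  out <- list()
  groups <- dplyr::distinct(anchors, .data$ref_chrom, .data$qry_chrom,
                            .data$strand)
  for (gi in seq_len(nrow(groups))) {
    g <- groups[gi, ]
    a <- anchors[anchors$ref_chrom == g$ref_chrom &
                   anchors$qry_chrom == g$qry_chrom &
                   anchors$strand == g$strand, ]
    M <- qlen[[g$qry_chrom]]
    # chain in an orientation where both coordinates increase
    if (g$strand == "-") {
      a$cs <- M - a$qry_end
      a$ce <- M - a$qry_start
    } else {
      a$cs <- a$qry_start
      a$ce <- a$qry_end
    }
    ref_chr <- as.character(ref[[g$ref_chrom]])
    qry_chr <- as.character(qry[[g$qry_chrom]])
    if (g$strand == "-") qry_chr <- revcomp_chr(qry_chr)
    repeat {
      if (nrow(a) == 0) break
      ch <- chain_best_cpp(a$ref_start, a$ref_end, a$cs, a$ce,
                           as.numeric(a$length))
      if (length(ch$idx) == 0 || ch$weight < min_cluster) break
      sel <- a[ch$idx, ]
      sel <- sel[order(sel$ref_start), ]
      blocks <- build_blocks_cpp(ref_chr, qry_chr,
                                 sel$ref_start, sel$cs, sel$length,
                                 as.integer(max_gap), as.integer(band))
      for (b in blocks) {
        qs <- if (g$strand == "-") M - b$qry_end else b$qry_start
        qe <- if (g$strand == "-") M - b$qry_start else b$qry_end
        out[[length(out) + 1]] <- tibble(
          ref_chrom = g$ref_chrom, ref_start = b$ref_start,
          ref_end = b$ref_end, qry_chrom = g$qry_chrom,
          qry_start = qs, qry_end = qe, strand = g$strand,
          identity = 100 * b$n_match / b$aligned_columns,
          aligned_columns = b$aligned_columns, n_match = b$n_match,
          edit_path = b$edit_path
        )
      }
      # retire used anchors, plus any anchor mostly covered by them on
      # either genome (a sliver of boundary overlap is fine: the
      # one-to-one pass trims it later)
      ov <- pmax(
        ranges_overlap_len(a$ref_start, a$ref_end,
                           sel$ref_start, sel$ref_end),
        ranges_overlap_len(a$cs, a$ce, sel$cs, sel$ce))
      a <- a[ov <= 0.5 * a$length, ]
    }
  }
  if (length(out) == 0) return(empty_blocks())
  res <- bind_rows(out) %>%
    arrange(.data$ref_chrom, .data$ref_start, .data$qry_chrom,
            .data$qry_start)
  res$block_id <- sprintf("b%05d", seq_len(nrow(res)))
  new_blocks(res[, c("block_id", "ref_chrom", "ref_start", "ref_end",
                     "qry_chrom", "qry_start", "qry_end", "strand",
                     "identity", "aligned_columns", "n_match",
                     "edit_path")])
}

#' Filter alignment blocks by identity and reference span
#'
#' Mirrors delta-filter style `-i`/`-l` filtering: keep blocks with
#' identity at or above `min_identity` percent and an aligned reference
#' span of at least `min_len` bases. Order is preserved.
#'
#' @param blocks a `wga_blocks` tibble.
#' @param min_identity percent identity threshold (default 80).
#' @param min_len minimum reference span in bases (default 20000).
#' @return the filtered `wga_blocks` tibble.
#' @export
filter_blocks <- function(blocks, min_identity = 80, min_len = 20000) {
  new_blocks(blocks[blocks$identity >= min_identity &
                      (blocks$ref_end - blocks$ref_start) >= min_len, ])
}

# weighted interval scheduling; returns logical keep vector.
# `tol` bases of overlap are treated as compatible (resolved later by
# trimming).
wis_keep <- function(start, end, w, tol = 0) {
  n <- length(start)
  if (n <= 1) return(rep(TRUE, n))
  ord <- order(end, start)
  s <- start[ord]; e <- end[ord]; wt <- w[ord]
  p <- findInterval(s + tol, e) # last interval ending at or before s + tol
  dp <- numeric(n + 1)
  take <- logical(n)
  for (i in seq_len(n)) {
    with_i <- wt[i] + dp[p[i] + 1]
    if (with_i > dp[i]) { # strict: ties prefer the earlier-sorted set
      dp[i + 1] <- with_i
      take[i] <- TRUE
    } else {
      dp[i + 1] <- dp[i]
    }
  }
  keep_sorted <- logical(n)
  i <- n
  while (i >= 1) {
    if (take[i]) {
      keep_sorted[i] <- TRUE
      i <- p[i]
    } else i <- i - 1
  }
  keep <- logical(n)
  keep[ord] <- keep_sorted
  keep
}

# remove `n` bases of one axis from one end of an edit path.
# side: which end of the path; axis "ref" counts =/X/D, "qry" counts =/X/I.
# Gap runs that stop consuming the axis at the cut edge are stripped too,
# so a trimmed block never starts or ends in a gap.
trim_path <- function(path, n, axis = c("ref", "qry"),
                      side = c("left", "right")) {
  axis <- match.arg(axis)
  side <- match.arg(side)
  ops <- parse_edit_path(path)
  if (side == "right") ops <- ops[rev(seq_len(nrow(ops))), ]
  consumes_set <- if (axis == "ref") c("=", "X", "D") else c("=", "X", "I")
  ref_removed <- 0L
  qry_removed <- 0L
  remaining <- n
  while (nrow(ops) > 0 && remaining > 0) {
    op <- ops$op[1]
    len <- ops$len[1]
    consumes <- op %in% consumes_set
    k <- if (consumes) min(len, remaining) else len
    if (op %in% c("=", "X")) {
      ref_removed <- ref_removed + k
      qry_removed <- qry_removed + k
    } else if (op == "D") {
      ref_removed <- ref_removed + k
    } else {
      qry_removed <- qry_removed + k
    }
    if (consumes) remaining <- remaining - k
    if (k < len) ops$len[1] <- len - k else ops <- ops[-1, , drop = FALSE]
  }
  # never end a block on a gap run
  while (nrow(ops) > 0 && ops$op[1] %in% c("I", "D")) {
    if (ops$op[1] == "D") ref_removed <- ref_removed + ops$len[1] else
      qry_removed <- qry_removed + ops$len[1]
    ops <- ops[-1, , drop = FALSE]
  }
  if (side == "right") ops <- ops[rev(seq_len(nrow(ops))), ]
  list(path = paste0(ops$len, ops$op, collapse = ""),
       ref_removed = ref_removed, qry_removed = qry_removed,
       empty = nrow(ops) == 0)
}

# trim a one-row block tibble; axis "ref": n ref bases off `side` of the
# reference extent; axis "qry": n query bases off the `low` or `high`
# (forward-coordinate) end of the query extent
trim_block <- function(b, n, axis, side) {
  path_side <- if (axis == "ref") side else {
    # path left end holds the low-qry coordinate on '+', high on '-'
    if (b$strand == "+") {
      if (side == "low") "left" else "right"
    } else {
      if (side == "low") "right" else "left"
    }
  }
  t <- trim_path(b$edit_path, n, axis = axis, side = path_side)
  if (t$empty) return(NULL)
  if (path_side == "left") {
    b$ref_start <- b$ref_start + t$ref_removed
    if (b$strand == "+") b$qry_start <- b$qry_start + t$qry_removed else
      b$qry_end <- b$qry_end - t$qry_removed
  } else {
    b$ref_end <- b$ref_end - t$ref_removed
    if (b$strand == "+") b$qry_end <- b$qry_end - t$qry_removed else
      b$qry_start <- b$qry_start + t$qry_removed
  }
  if (b$ref_end <= b$ref_start || b$qry_end <= b$qry_start) return(NULL)
  ops <- parse_edit_path(t$path)
  b$edit_path <- t$path
  b$n_match <- sum(ops$len[ops$op == "="])
  b$aligned_columns <- sum(ops$len)
  b$identity <- 100 * b$n_match / b$aligned_columns
  b
}

# resolve residual overlaps (at most `tol` bases) between selected blocks
# by trimming the lower-weight block
resolve_overlaps <- function(blocks, axis) {
  cols <- if (axis == "ref") c("ref_chrom", "ref_start", "ref_end") else
    c("qry_chrom", "qry_start", "qry_end")
  repeat {
    w <- (blocks$ref_end - blocks$ref_start) * blocks$identity
    changed <- FALSE
    for (ch in unique(blocks[[cols[1]]])) {
      sel <- which(blocks[[cols[1]]] == ch)
      o <- sel[order(blocks[[cols[2]]][sel])]
      if (length(o) < 2) next
      ov <- blocks[[cols[2]]][o][-1] - blocks[[cols[3]]][o][-length(o)]
      bad <- which(ov < 0)
      if (length(bad) == 0) next
      j <- bad[1]
      n <- -ov[j]
      first <- o[j]; second <- o[j + 1]
      victim <- if (w[first] <= w[second]) first else second
      side <- if (axis == "ref") {
        if (victim == second) "left" else "right"
      } else {
        if (victim == second) "low" else "high"
      }
      trimmed <- trim_block(blocks[victim, ], n, axis, side)
      if (is.null(trimmed)) {
        blocks <- blocks[-victim, ]
      } else {
        blocks[victim, ] <- trimmed
      }
      changed <- TRUE
      break
    }
    if (!changed) return(blocks)
  }
}

#' Select a one-to-one set of alignment blocks
#'
#' Keeps a subset in which no reference base and no query base is covered
#' by more than one block, maximizing the total of reference span times
#' identity via weighted interval scheduling run on the reference and then
#' on the query (fixed two-pass order, as in delta-filter's one-to-one
#' mode). Small boundary overlaps (up to `tol` bases, as arise where two
#' chains share an ambiguous breakpoint base) are tolerated during
#' selection and then removed by trimming the lower-weight block, so the
#' returned set covers every base at most once.
#'
#' @param blocks a `wga_blocks` tibble.
#' @param tol largest boundary overlap resolved by trimming instead of
#'   block rejection (default 100 bases).
#' @return the selected `wga_blocks` tibble, original order preserved.
#' @export
one_to_one <- function(blocks, tol = 100) {
  if (nrow(blocks) <= 1) return(blocks)
  w <- (blocks$ref_end - blocks$ref_start) * blocks$identity
  keep1 <- rep(FALSE, nrow(blocks))
  for (ch in unique(blocks$ref_chrom)) {
    sel <- which(blocks$ref_chrom == ch)
    keep1[sel] <- wis_keep(blocks$ref_start[sel], blocks$ref_end[sel],
                           w[sel], tol = tol)
  }
  b2 <- blocks[keep1, ]
  keep2 <- rep(FALSE, nrow(b2))
  for (ch in unique(b2$qry_chrom)) {
    sel <- which(b2$qry_chrom == ch)
    keep2[sel] <- wis_keep(b2$qry_start[sel], b2$qry_end[sel],
                           w[keep1][sel], tol = tol)
  }
  out <- b2[keep2, ]
  out <- resolve_overlaps(out, "ref")
  out <- resolve_overlaps(out, "qry")
  new_blocks(out)
}

#' Check that blocks are one-to-one
#'
#' @param blocks a `wga_blocks` tibble.
#' @return `TRUE` invisibly; errors listing offending block pairs otherwise.
#' @export
assert_one_to_one <- function(blocks) {
  check_axis <- function(chrom, start, end, label) {
    for (ch in unique(chrom)) {
      sel <- which(chrom == ch)
      o <- sel[order(start[sel])]
      if (length(o) > 1 &&
          any(start[o][-1] < end[o][-length(o)])) {
        i <- which(start[o][-1] < end[o][-length(o)])[1]
        stop(sprintf(
          "blocks are not one-to-one: %s and %s overlap on the %s",
          blocks$block_id[o[i]], blocks$block_id[o[i + 1]], label),
          call. = FALSE)
      }
    }
  }
  check_axis(blocks$ref_chrom, blocks$ref_start, blocks$ref_end,
             "reference")
  check_axis(blocks$qry_chrom, blocks$qry_start, blocks$qry_end, "query")
  invisible(TRUE)
}

#' Recompute block identity from the edit path
#'
#' @param blocks a `wga_blocks` tibble.
#' @return numeric vector of identities (percent).
#' @export
recompute_identity <- function(blocks) {
  vapply(blocks$edit_path, function(p) {
    ops <- parse_edit_path(p)
    100 * sum(ops$len[ops$op == "="]) / sum(ops$len)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Align two genomes end to end
#'
#' Convenience wrapper: [find_anchors()], [chain_and_extend()], optional
#' [filter_blocks()] and [one_to_one()].
#'
#' @param ref,qry named `DNAStringSet` genomes.
#' @param min_anchor minimum MUM length (default 40).
#' @param max_gap,band,min_cluster see [chain_and_extend()].
#' @param min_identity,min_len if non-`NULL`, applied via
#'   [filter_blocks()].
#' @param one_to_one select a one-to-one subset (default `TRUE`).
#' @return a `wga_blocks` tibble.
#' @export
align_genomes <- function(ref, qry, min_anchor = 40, max_gap = 1000,
                          band = 200, min_cluster = 90,
                          min_identity = NULL, min_len = NULL,
                          one_to_one = TRUE) {
  anchors <- find_anchors(ref, qry, min_len = min_anchor)
  blocks <- chain_and_extend(anchors, ref, qry, max_gap = max_gap,
                             band = band, min_cluster = min_cluster)
  if (!is.null(min_identity) || !is.null(min_len)) {
    blocks <- filter_blocks(blocks,
                            min_identity = min_identity %||% 0,
                            min_len = min_len %||% 0)
  }
  if (one_to_one) blocks <- one_to_one(blocks)
  blocks
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write alignment blocks to TSV
#'
#' Emits a show-coords-like table; edit paths go to a sidecar file
#' (`<path>.paths`) keyed by block id.
#'
#' @param blocks a `wga_blocks` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blocks <- function(blocks, path) {
  main <- as.data.frame(blocks[, c("block_id", "ref_chrom", "ref_start",
                                   "ref_end", "qry_chrom", "qry_start",
                                   "qry_end", "strand", "identity",
                                   "aligned_columns")])
  con <- file(path, "w")
  writeLines(paste0("#", paste(names(main), collapse = "\t")), con)
  utils::write.table(main, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  writeLines(paste(blocks$block_id, blocks$edit_path, sep = "\t"),
             paste0(path, ".paths"))
  invisible(path)
}
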