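# Gene-anatomy region index (exon / intron / promoter / downstream) and
# classification of TE or SV intervals over it, with paired ortholog
# comparison.

CATEGORY_LEVELS <- c("exon", "intron", "promoter", "downstream")

#' Build a gene-anatomy region index
#'
#' For every gene: its exons; introns (gaps of the exon union inside the
#' gene body); a promoter of `promoter_len` bases immediately upstream of
#' the 5' UTR start; and a downstream region of `downstream_len` bases
#' immediately past the 3' UTR end — both strand-aware and truncated at
#' chromosome ends. Genes lacking a UTR fall back to the CDS boundary as
#' the anchor (counted and messaged).
#'
#' @param models a `wga_gene_models` tibble.
#' @param chrom_lengths named vector of chromosome lengths (or a
#'   `DNAStringSet`).
#' @param promoter_len promoter length in bases (default 2000).
#' @param downstream_len downstream length in bases (default 1000).
#' @return a `wga_feature_index` tibble: `chrom`, `start`, `end`,
#'   `gene_id`, `category`.
#' @export
build_feature_index <- function(models, chrom_lengths,
                                promoter_len = 2000,
                                downstream_len = 1000) {
  if (methods::is(chrom_lengths, "DNAStringSet")) {
    chrom_lengths <- setNames(Biostrings::width(chrom_lengths),
                              names(chrom_lengths))
  }
  n_proxy <- 0L
  rows <- lapply(seq_len(nrow(models)), function(i) {
    ex <- models$exons[[i]]
    cds <- models$cds[[i]]
    u5 <- models$utr5[[i]]
    u3 <- models$utr3[[i]]
    chrom <- models$chrom[i]
    L <- chrom_lengths[[chrom]]
    strand <- models$strand[i]
    gs <- min(ex$start); ge <- max(ex$end)
    introns <- if (nrow(ex) > 1) {
      tibble(start = ex$end[-nrow(ex)], end = ex$start[-1])
    } else empty_intervals()
    # transcription-sense anchors
    if (strand == "+") {
      p5 <- if (nrow(u5) > 0) min(u5$start) else {
        n_proxy <<- n_proxy + 1L
        if (nrow(cds) > 0) min(cds$start) else gs
      }
      p3 <- if (nrow(u3) > 0) max(u3$end) else {
        if (nrow(cds) > 0) max(cds$end) else ge
      }
      prom <- tibble(start = max(0L, p5 - promoter_len), end = max(0L, p5))
      down <- tibble(start = min(L, p3), end = min(L, p3 + downstream_len))
    } else {
      p5 <- if (nrow(u5) > 0) max(u5$end) else {
        n_proxy <<- n_proxy + 1L
        if (nrow(cds) > 0) max(cds$end) else ge
      }
      p3 <- if (nrow(u3) > 0) min(u3$start) else {
        if (nrow(cds) > 0) min(cds$start) else gs
      }
      prom <- tibble(start = min(L, p5), end = min(L, p5 + promoter_len))
      down <- tibble(start = max(0L, p3 - downstream_len), end = max(0L, p3))
    }
    mk <- function(tbl, cat) {
      tbl <- tbl[tbl$end > tbl$start, , drop = FALSE]
      if (nrow(tbl) == 0) return(NULL)
      tibble(chrom = chrom, start = as.integer(tbl$start),
             end = as.integer(tbl$end), gene_id = models$gene_id[i],
             category = cat)
    }
    bind_rows(mk(ex, "exon"), mk(introns, "intron"),
              mk(prom, "promoter"), mk(down, "downstream"))
  })
  if (n_proxy > 0) {
    message(n_proxy, " gene(s) lack a UTR; CDS boundary used as anchor")
  }
  out <- bind_rows(rows)
  class(out) <- unique(c("wga_feature_index", class(tibble())))
  out
}

#' Classify elements into gene-anatomy regions
#'
#' Membership is any-overlap (at least one base). In `precedence` mode
#' each element is assigned exactly one category by
#' exon > intron > promoter > downstream > intergenic (per-gene counts use
#' the gene owning the winning region; ties resolve to the alphabetically
#' first gene). In `multi` mode every overlapped (gene, category) is
#' tallied.
#'
#' @param elements tibble of intervals: `chrom`, `start`, `end`.
#' @param index a `wga_feature_index` from [build_feature_index()].
#' @param mode `"precedence"` (default) or `"multi"`.
#' @return a `wga_region_counts` list: `per_gene` (gene_id by category
#'   counts), `totals` (named count per category plus `intergenic`),
#'   `n_elements`, `mode`.
#' @export
classify_elements <- function(elements, index,
                              mode = c("precedence", "multi")) {
  mode <- match.arg(mode)
  el <- GenomicRanges::GRanges(
    elements$chrom,
    IRanges::IRanges(start = elements$start + 1L, end = elements$end))
  ix <- GenomicRanges::GRanges(
    index$chrom,
    IRanges::IRanges(start = index$start + 1L, end = index$end))
  ov <- GenomicRanges::findOverlaps(el, ix)
  hits <- tibble(
    element = S4Vectors::queryHits(ov),
    gene_id = index$gene_id[S4Vectors::subjectHits(ov)],
    category = index$category[S4Vectors::subjectHits(ov)]
  )
  n_el <- nrow(elements)
  if (mode == "precedence") {
    hits$rank <- match(hits$category, CATEGORY_LEVELS)
    hits <- hits %>%
      arrange(.data$element, .data$rank, .data$gene_id) %>%
      dplyr::distinct(.data$element, .keep_all = TRUE)
  } else {
    hits <- dplyr::distinct(hits, .data$element, .data$gene_id,
                            .data$category)
  }
  per_gene <- hits %>%
    dplyr::count(.data$gene_id, .data$category) %>%
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L)
  for (cat in CATEGORY_LEVELS) {
    if (!cat %in% names(per_gene)) per_gene[[cat]] <- 0L
  }
  per_gene <- per_gene[, c("gene_id", CATEGORY_LEVELS)]
  totals <- vapply(CATEGORY_LEVELS, function(cat) {
    sum(hits$category == cat)
  }, numeric(1))
  totals <- c(totals,
              intergenic = if (mode == "precedence") {
                n_el - length(unique(hits$element))
              } else {
                n_el - length(unique(hits$element))
              })
  structure(list(per_gene = per_gene, totals = totals,
                 n_elements = n_el, mode = mode),
            class = "wga_region_counts")
}

#' Compare per-gene region counts across ortholog pairs
#'
#' For each category, sums counts in both genomes over the ortholog
#' pairing and runs a two-sided exact sign test on the non-tied pairs.
#'
#' @param counts_a,counts_b `wga_region_counts` for the two genomes.
#' @param ortholog_pairs tibble with `gene_a`, `gene_b` (one-to-one).
#' @return tibble per category: `sum_a`, `sum_b`, `n_gt` (A > B), `n_lt`,
#'   `n_tie`, `p_value`.
#' @export
compare_paired_counts <- function(counts_a, counts_b, ortholog_pairs) {
  if (nrow(ortholog_pairs) == 0) {
    stop("empty ortholog pairing", call. = FALSE)
  }
  if (anyDuplicated(ortholog_pairs$gene_a) ||
      anyDuplicated(ortholog_pairs$gene_b)) {
    stop("ortholog pairing must be one-to-one", call. = FALSE)
  }
  ga <- ortholog_pairs %>%
    left_join(counts_a$per_gene, by = c(gene_a = "gene_id"))
  gb <- ortholog_pairs %>%
    left_join(counts_b$per_gene, by = c(gene_b = "gene_id"))
  rows <- lapply(CATEGORY_LEVELS, function(cat) {
    a <- tidyr::replace_na(ga[[cat]], 0L)
    b <- tidyr::replace_na(gb[[cat]], 0L)
    n_gt <- sum(a > b); n_lt <- sum(a < b); n_tie <- sum(a == b)
    p <- if (n_gt + n_lt == 0) 1 else
      binom.test(n_gt, n_gt + n_lt, 0.5)$p.value
    tibble(category = cat, sum_a = sum(a), sum_b = sum(b),
           n_gt = n_gt, n_lt = n_lt, n_tie = n_tie, p_value = p)
  })
  bind_rows(rows)
}
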