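# ggplot2 visualisations for the main result types

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a k-mer depth histogram
#'
#' @param object a `wga_kmer_histogram`.
#' @param max_depth right edge of the plotted depth range (default three
#'   times the main peak).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot wga_kmer_histogram
#' @export
autoplot.wga_kmer_histogram <- function(object, max_depth = NULL, ...) {
  peak <- tryCatch(find_main_peak(object), error = function(e) NA)
  if (is.null(max_depth)) {
    max_depth <- if (is.na(peak)) max(object$depth) else 3 * peak
  }
  d <- object[object$depth <= max_depth, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$depth,
                                       y = .data$distinct_kmers)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "k-mer depth", y = "distinct k-mers",
                  title = sprintf("k-mer depth distribution (k = %s)",
                                  attr(object, "k")))
  if (!is.na(peak)) {
    p <- p + ggplot2::geom_vline(xintercept = peak, linetype = "dashed")
  }
  p
}

#' Dotplot of alignment blocks
#'
#' @param object a `wga_blocks` tibble.
#' @param ... unused.
#' @return a ggplot with one segment per block, faceted by chromosome
#'   pair; reverse-strand blocks slope downward.
#' @method autoplot wga_blocks
#' @export
autoplot.wga_blocks <- function(object, ...) {
  d <- as_tibble(object) %>%
    mutate(y0 = ifelse(.data$strand == "+", .data$qry_start,
                       .data$qry_end),
           y1 = ifelse(.data$strand == "+", .data$qry_end,
                       .data$qry_start))
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$ref_start, xend = .data$ref_end,
      y = .data$y0, yend = .data$y1, colour = .data$strand)) +
    ggplot2::facet_grid(.data$qry_chrom ~ .data$ref_chrom,
                        scales = "free") +
    ggplot2::labs(x = "reference position", y = "query position")
}

#' Plot a substitution spectrum
#'
#' @param spectrum output of [snp_spectrum()].
#' @return a ggplot of the twelve directed substitution fractions.
#' @export
plot_spectrum <- function(spectrum) {
  d <- mutate(spectrum, type = paste0(.data$from, ">", .data$to))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$type, y = .data$fraction,
                                  fill = .data$is_transition)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "substitution", y = "fraction",
                  fill = "transition")
}

#' Plot a Ks distribution with detected modes
#'
#' @param values numeric vector of Ks values.
#' @param peaks optional result of [ks_peak()] to annotate.
#' @return a ggplot.
#' @export
plot_ks_distribution <- function(values, peaks = NULL) {
  v <- values[is.finite(values) & values >= 0 & values <= 3]
  p <- ggplot2::ggplot(tibble(ks = v), ggplot2::aes(x = .data$ks)) +
    ggplot2::geom_density(bw = "nrd0") +
    ggplot2::labs(x = "Ks (synonymous substitutions per synonymous site)",
                  y = "density")
  if (!is.null(peaks) && peaks$status == "ok") {
    p <- p + ggplot2::geom_vline(xintercept = peaks$modes$location,
                                 linetype = "dashed")
  }
  p
}

#' Plot LTR insertion-age distribution
#'
#' @param ages tibble with an `age_years` column (e.g. row-bound
#'   [ltr_age()] results).
#' @param binwidth_years histogram bin width (default 1e5 years).
#' @return a ggplot.
#' @export
plot_ltr_ages <- function(ages, binwidth_years = 1e5) {
  ggplot2::ggplot(ages, ggplot2::aes(x = .data$age_years / 1e6)) +
    ggplot2::geom_histogram(binwidth = binwidth_years / 1e6,
                            boundary = 0) +
    ggplot2::labs(x = "insertion age (million years)",
                  y = "intact LTR elements")
}
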