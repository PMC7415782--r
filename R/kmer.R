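# k-mer depth profiling: histogram construction from reads and estimation of
# genome size, heterozygosity and repetitive fraction from the histogram.

new_kmer_histogram <- function(df, k, total, n_short) {
  stopifnot(all(c("depth", "distinct_kmers") %in% names(df)))
  structure(df, class = c("wga_kmer_histogram", class(tibble())),
            k = k, total_kmers = total, n_short_reads = n_short)
}

#' Build a k-mer depth histogram from reads
#'
#' Counts canonical k-mers (the lexicographic minimum of a k-mer and its
#' reverse complement) exactly, in memory. k-mers containing N are excluded;
#' reads shorter than `k` are skipped and counted.
#'
#' @param reads a `DNAStringSet`, character vector of reads, or path to a
#'   FASTQ/FASTA file.
#' @param k odd k-mer length, 11-31 (default 19).
#' @return a `wga_kmer_histogram` tibble of (`depth`, `distinct_kmers`),
#'   with attributes `k`, `total_kmers` (counted k-mer instances) and
#'   `n_short_reads`.
#' @export
kmer_histogram <- function(reads, k = 19) {
  if (k %% 2 == 0 || k < 11 || k > 31) {
    stop("k must be odd and within [11, 31]", call. = FALSE)
  }
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    reads <- read_reads(reads)
  }
  reads <- as.character(reads)
  if (length(reads) == 0) stop("no reads supplied", call. = FALSE)
  res <- kmer_count_cpp(reads, as.integer(k))
  if (res$n_short_reads > 0) {
    message(sprintf("skipped %d reads shorter than k = %d",
                    as.integer(res$n_short_reads), k))
  }
  if (length(res$depth) == 0) stop("no countable k-mers in input",
                                   call. = FALSE)
  new_kmer_histogram(tibble(depth = res$depth,
                            distinct_kmers = res$distinct_kmers),
                     k = k, total = res$n_instances,
                     n_short = res$n_short_reads)
}

#' Locate the main peak of a k-mer histogram
#'
#' Returns the depth with the largest distinct-k-mer count among depths at
#' or above `min_depth` (which excludes the sequencing-error spike at depth
#' 1-3). Ties break to the larger depth.
#'
#' @param hist a `wga_kmer_histogram` (or tibble with `depth`,
#'   `distinct_kmers`).
#' @param min_depth smallest depth eligible as the peak (default 4).
#' @return integer peak depth.
#' @export
find_main_peak <- function(hist, min_depth = 4) {
  h <- hist[hist$depth >= min_depth, ]
  if (nrow(h) == 0) {
    stop("no histogram mass at or above min_depth; no peak", call. = FALSE)
  }
  best <- max(h$distinct_kmers)
  max(h$depth[h$distinct_kmers == best])
}

#' Estimate a genome profile from a k-mer histogram
#'
#' Genome size is total counted k-mer instances divided by the main peak
#' depth (rounded to the nearest base). The repeat depth threshold is
#' `2 * peak + 1`; the repetitive fraction is the share of k-mer instances
#' above that threshold. Heterozygosity is estimated as `d / (2k)` where
#' `d` is the fraction of k-mer instances in the half-depth window
#' `[0.4 * peak, 0.6 * peak]` (the heterozygous peak of a diploid sits at
#' half the homozygous depth).
#'
#' @param hist a `wga_kmer_histogram`.
#' @param min_depth passed to [find_main_peak()].
#' @return a `wga_genome_profile` list with `k`, `peak_depth`,
#'   `total_kmers`, `genome_size_estimate`, `repeat_depth_threshold`,
#'   `repetitive_fraction`, `heterozygosity_estimate`.
#' @export
estimate_profile <- function(hist, min_depth = 4) {
  k <- attr(hist, "k", exact = TRUE)
  total <- attr(hist, "total_kmers", exact = TRUE)
  if (is.null(total)) total <- sum(hist$depth * hist$distinct_kmers)
  peak <- find_main_peak(hist, min_depth)
  if (peak <= 0) stop("peak depth is zero; no peak", call. = FALSE)
  gs <- round(total / peak)
  thr <- 2L * as.integer(peak) + 1L
  inst <- hist$depth * hist$distinct_kmers
  rep_frac <- sum(inst[hist$depth > thr]) / total
  lo <- 0.4 * peak
  hi <- 0.6 * peak
  d_het <- sum(inst[hist$depth >= lo & hist$depth <= hi]) / total
  het <- if (is.null(k)) NA_real_ else d_het / (2 * k)
  structure(list(
    k = k, peak_depth = as.integer(peak), total_kmers = total,
    genome_size_estimate = gs, repeat_depth_threshold = thr,
    repetitive_fraction = rep_frac, heterozygosity_estimate = het,
    peak_definition = "main histogram peak at depth >= min_depth"
  ), class = "wga_genome_profile")
}

#' @export
print.wga_genome_profile <- function(x, ...) {
  cat("k-mer genome profile (k =", x$k, ")\n")
  cat(sprintf("  peak depth:            %d\n", x$peak_depth))
  cat(sprintf("  total k-mer instances: %.0f\n", x$total_kmers))
  cat(sprintf("  genome size estimate:  %.0f bp\n", x$genome_size_estimate))
  cat(sprintf("  repeat depth cutoff:   > %d\n", x$repeat_depth_threshold))
  cat(sprintf("  repetitive fraction:   %.4f\n", x$repetitive_fraction))
  cat(sprintf("  heterozygosity:        %.5f\n",
              x$heterozygosity_estimate))
  invisible(x)
}

#' Write a k-mer histogram to TSV
#'
#' @param hist a `wga_kmer_histogram`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kmer_histogram <- function(hist, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# k=%d total_kmers=%.0f", attr(hist, "k"),
                     attr(hist, "total_kmers")), con)
  utils::write.table(as.data.frame(hist)[, c("depth", "distinct_kmers")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
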