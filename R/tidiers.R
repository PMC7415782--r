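# broom-style tidiers for result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a k-mer genome profile
#'
#' @param x a `wga_genome_profile`.
#' @param ... unused.
#' @return one-row tibble of the profile estimates.
#' @method tidy wga_genome_profile
#' @export
tidy.wga_genome_profile <- function(x, ...) {
  tibble(k = x$k, peak_depth = x$peak_depth, total_kmers = x$total_kmers,
         genome_size_estimate = x$genome_size_estimate,
         repeat_depth_threshold = x$repeat_depth_threshold,
         repetitive_fraction = x$repetitive_fraction,
         heterozygosity_estimate = x$heterozygosity_estimate)
}

#' @rdname tidy.wga_genome_profile
#' @method glance wga_genome_profile
#' @export
glance.wga_genome_profile <- tidy.wga_genome_profile

#' Tidy per-gene region counts
#'
#' @param x a `wga_region_counts`.
#' @param ... unused.
#' @return the per-gene count tibble.
#' @method tidy wga_region_counts
#' @export
tidy.wga_region_counts <- function(x, ...) {
  x$per_gene
}

#' Summarise region counts
#'
#' @param x a `wga_region_counts`.
#' @param ... unused.
#' @return one-row tibble of category totals.
#' @method glance wga_region_counts
#' @export
glance.wga_region_counts <- function(x, ...) {
  as_tibble(as.list(c(x$totals, n_elements = x$n_elements)))
}

#' Tidy a printed-arithmetic check table
#'
#' @param x a `wga_paper_check`.
#' @param ... unused.
#' @return the claim tibble itself (already tidy).
#' @method tidy wga_paper_check
#' @export
tidy.wga_paper_check <- function(x, ...) {
  as_tibble(x)
}

#' Summarise a printed-arithmetic check
#'
#' @param x a `wga_paper_check`.
#' @param ... unused.
#' @return one-row tibble with `n_claims`, `n_pass`, `all_pass`.
#' @method glance wga_paper_check
#' @export
glance.wga_paper_check <- function(x, ...) {
  tibble(n_claims = nrow(x), n_pass = sum(x$pass),
         all_pass = all(x$pass))
}
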