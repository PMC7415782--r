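# Derived summary arithmetic: percentage/density recomputation from printed
# report inputs, size-difference attribution, the printed-arithmetic check
# suite, and run-report aggregation.

PRINTED_INPUTS_MD5 <- "da2b9877744ede2a3b3efda7f06febce"

#' Percentage of a whole, at printed precision
#'
#' @param part,whole non-negative quantities, `whole > 0`.
#' @return `100 * part / whole`, rounded to two decimals half away from
#'   zero (the rounding that reproduces published repeat-content
#'   percentages from their printed inputs).
#' @examples
#' fraction_pct(57063567, 117216089) # 48.68
#' @export
fraction_pct <- function(part, whole) {
  if (any(whole <= 0)) stop("whole must be positive", call. = FALSE)
  if (any(part < 0)) stop("part must be non-negative", call. = FALSE)
  round_half_away(100 * part / whole, 2)
}

#' Share of a genome-size difference explained by repeat content
#'
#' @param repeats_a,repeats_b total repeat lengths of the larger and
#'   smaller genome (bases).
#' @param size_a,size_b assembly sizes (bases), `size_a > size_b`.
#' @return percent of the size difference attributable to repeats, two
#'   decimals.
#' @examples
#' size_difference_attribution(117216089, 76805372, 270.3e6, 220.4e6)
#' @export
size_difference_attribution <- function(repeats_a, repeats_b,
                                        size_a, size_b) {
  if (size_a <= size_b) {
    stop("size_a must exceed size_b", call. = FALSE)
  }
  round_half_away(100 * (repeats_a - repeats_b) / (size_a - size_b), 2)
}

#' Load the bundled printed-input constants
#'
#' @param path optional override of the bundled file (for testing the
#'   integrity check).
#' @return named numeric vector of printed inputs.
#' @export
printed_inputs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "printed_inputs.tsv",
                        package = "wgacompare")
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, PRINTED_INPUTS_MD5)) {
      stop("printed-inputs constants file failed its checksum",
           call. = FALSE)
    }
  }
  if (!file.exists(path) || file.size(path) == 0) {
    stop("printed-inputs constants missing or empty", call. = FALSE)
  }
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(d) == 0) stop("printed-inputs constants empty", call. = FALSE)
  setNames(as.numeric(d$value), d$key)
}

#' Recompute every derived printed number from printed inputs
#'
#' Each claim recomputes one derived quantity (a percentage, density,
#' genome-size estimate or threshold) purely from the bundled printed
#' inputs and compares it with the published printed value at its printed
#' precision.
#'
#' @param inputs named vector from [printed_inputs()].
#' @return tibble: `claim`, `computed`, `expected`, `pass`.
#' @export
paper_check <- function(inputs = printed_inputs()) {
  need <- function(k) {
    if (!k %in% names(inputs)) {
      stop("printed input missing: ", k, call. = FALSE)
    }
    inputs[[k]]
  }
  gs <- round(need("kmer_number") / need("kmer_peak_depth"))
  claims <- list(
    list("genome size = k-mer number / peak depth",
         gs, 298529694),
    list("repeat depth threshold = 2 * peak + 1",
         2 * need("kmer_peak_depth") + 1, 115),
    list("SNP density per kb",
         variant_density(need("snp_total"), need("assembly_size_fn")),
         16.9),
    list("indel density per kb",
         variant_density(need("indel_total"), need("assembly_size_fn")),
         3.1),
    list("retrotransposons as % of TE content",
         fraction_pct(need("classI_len_fn"), need("te_total_len_fn")),
         48.68),
    list("retrotransposons as % of genome",
         fraction_pct(need("classI_len_fn"), need("assembly_size_fn")),
         21.11),
    list("retrotransposons as % of sibling genome",
         fraction_pct(need("classI_len_fv"), need("assembly_size_fv")),
         22.32),
    list("LTR retrotransposons as % of genome",
         fraction_pct(need("classI_ltr_len_fn") +
                        need("classI_copia_len_fn") +
                        need("classI_gypsy_len_fn"),
                      need("assembly_size_fn")), 16.55),
    list("LINE+SINE as % of genome",
         fraction_pct(need("classI_line_len_fn") +
                        need("classI_sine_len_fn"),
                      need("assembly_size_fn")), 3.15),
    list("DNA transposons as % of TE content",
         fraction_pct(need("classII_len_fn"), need("te_total_len_fn")),
         39.49),
    list("DNA transposons as % of genome",
         fraction_pct(need("classII_len_fn"), need("assembly_size_fn")),
         17.12),
    list("TIR as % of genome",
         fraction_pct(need("tir_len_fn"), need("assembly_size_fn")),
         13.67),
    list("TIR as % of sibling genome",
         fraction_pct(need("tir_len_fv"), need("assembly_size_fv")),
         7.65),
    list("sibling TE content as % of its genome",
         fraction_pct(need("te_total_len_fv"), need("assembly_size_fv")),
         34.85),
    list("repeat difference as % of genome-size difference",
         size_difference_attribution(need("te_total_len_fn"),
                                     need("te_total_len_fv"),
                                     need("assembly_size_fn"),
                                     need("assembly_size_fv")), 80.98),
    list("GO biological process as % of genes",
         fraction_pct(need("go_bp"), need("gene_total")), 34.36),
    list("GO molecular function as % of genes",
         fraction_pct(need("go_mf"), need("gene_total")), 33.13),
    list("GO cellular component as % of genes",
         fraction_pct(need("go_cc"), need("gene_total")), 22.22)
  )
  out <- bind_rows(lapply(claims, function(cl) {
    tibble(claim = cl[[1]], computed = cl[[2]], expected = cl[[3]],
           pass = isTRUE(all.equal(cl[[2]], cl[[3]], tolerance = 1e-12)))
  }))
  class(out) <- unique(c("wga_paper_check", class(out)))
  out
}

#' Aggregate module outputs into one run report
#'
#' @param kmer_profile a `wga_genome_profile`, or `NULL`.
#' @param blocks a `wga_blocks` tibble, or `NULL`.
#' @param variants list with `snps`/`indels` from [call_variants()], or
#'   `NULL`.
#' @param spectrum output of [snp_spectrum()], or `NULL`.
#' @param svs SV tibble from [call_svs()], or `NULL`.
#' @param region_counts a `wga_region_counts`, or `NULL`.
#' @param molevo tibble of per-pair molecular-evolution statistics, or
#'   `NULL`.
#' @param params named list of run parameters/seeds echoed as provenance.
#' @param path if non-`NULL`, write the report JSON here.
#' @return the report as a named list, invisibly when written.
#' @export
build_report <- function(kmer_profile = NULL, blocks = NULL,
                         variants = NULL, spectrum = NULL, svs = NULL,
                         region_counts = NULL, molevo = NULL,
                         params = list(), path = NULL) {
  sections <- list()
  if (!is.null(kmer_profile)) {
    sections$kmer_profile <- unclass(kmer_profile)
  }
  if (!is.null(blocks)) {
    sections$alignment <- list(
      n_blocks = nrow(blocks),
      ref_span = sum(blocks$ref_end - blocks$ref_start),
      qry_span = sum(blocks$qry_end - blocks$qry_start),
      mean_identity = if (nrow(blocks)) {
        sum(blocks$identity * (blocks$ref_end - blocks$ref_start)) /
          sum(blocks$ref_end - blocks$ref_start)
      } else NA_real_,
      n_reverse = sum(blocks$strand == "-")
    )
  }
  if (!is.null(variants)) {
    sections$variants <- list(
      n_snps = nrow(variants$snps),
      n_indels = nrow(variants$indels),
      n_insertions = sum(variants$indels$kind == "insertion"),
      n_deletions = sum(variants$indels$kind == "deletion")
    )
  }
  if (!is.null(spectrum)) {
    sections$spectrum <- as.list(setNames(
      spectrum$fraction, paste0(spectrum$from, ">", spectrum$to)))
  }
  if (!is.null(svs)) {
    sections$svs <- as.list(table(svs$sv_type))
  }
  if (!is.null(region_counts)) {
    sections$regions <- as.list(region_counts$totals)
  }
  if (!is.null(molevo)) {
    sections$molevo <- list(
      n_pairs = nrow(molevo),
      median_ks = stats::median(molevo$ks[is.finite(molevo$ks)]),
      median_4dtv = stats::median(molevo$fourdtv_raw, na.rm = TRUE)
    )
  }
  if (length(sections) == 0) {
    stop("no module outputs supplied", call. = FALSE)
  }
  report <- c(sections, list(provenance = c(
    params, list(package = "wgacompare",
                 version = as.character(utils::packageVersion("wgacompare"))))))
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    return(invisible(report))
  }
  report
}
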