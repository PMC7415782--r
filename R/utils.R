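#' Round half away from zero
#'
#' Base [round()] rounds half to even; printed genome-report percentages and
#' densities use the conventional half-away-from-zero rule, so summary
#' arithmetic reproduces published values digit for digit.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_away(0.125, 2) # 0.13, where round() gives 0.12
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# reverse complement of a plain character vector of sequences
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

# validate a DNAStringSet as a genome: named, non-empty, A/C/G/T/N only
assert_genome <- function(genome, arg = "genome") {
  if (!methods::is(genome, "DNAStringSet")) {
    stop(sprintf("`%s` must be a DNAStringSet (see read_genome())", arg),
         call. = FALSE)
  }
  if (length(genome) == 0) stop(sprintf("`%s` is empty", arg), call. = FALSE)
  if (is.null(names(genome)) || anyNA(names(genome)) ||
      any(names(genome) == "")) {
    stop(sprintf("`%s` must have non-empty sequence names", arg),
         call. = FALSE)
  }
  freq <- Biostrings::alphabetFrequency(genome)
  extra <- rowSums(freq) - rowSums(freq[, c("A", "C", "G", "T", "N"),
                                       drop = FALSE])
  if (any(extra > 0)) {
    bad <- names(genome)[which(extra > 0)[1]]
    stop(sprintf("`%s`: sequence '%s' contains characters outside A/C/G/T/N",
                 arg, bad), call. = FALSE)
  }
  invisible(genome)
}

# run-length edit path "12=1X3D" -> tibble(len, op)
parse_edit_path <- function(path) {
  m <- gregexpr("(\\d+)([=XID])", path, perl = TRUE)[[1]]
  if (m[1] == -1) return(tibble(len = integer(0), op = character(0)))
  toks <- regmatches(path, gregexpr("\\d+[=XID]", path))[[1]]
  tibble(
    len = as.integer(sub("[=XID]$", "", toks)),
    op = sub("^\\d+", "", toks)
  )
}

# derive a child seed from a base seed and a stream label, kept below 2^31
derive_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(stream)) * 1009L
  as.integer((as.double(seed) * 7919 + offs) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
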