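# Molecular-evolution statistics: synteny-based ortholog pairing, codon
# alignment, 4DTv, NG86 synonymous substitution rates with Jukes-Cantor
# correction, Ks-distribution peak detection, and LTR insertion-age dating.

# fourfold-degenerate codon prefixes under the standard genetic code
FOURFOLD_PREFIXES <- c("TC", "CT", "CC", "CG", "AC", "GT", "GC", "GG")

.molevo_env <- new.env(parent = emptyenv())

genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

codon_neighbors <- function(codon) {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (p in 1:3) {
    for (b in setdiff(bases, substr(codon, p, p))) {
      x <- codon
      substr(x, p, p) <- b
      out <- c(out, x)
    }
  }
  out
}

# NG86 synonymous site count of one codon: per position, the fraction of
# the three possible changes that are synonymous (changes to stop codons
# count as nonsynonymous); stop codons carry zero sites
ng86_tables <- function() {
  if (!is.null(.molevo_env$syn_sites)) {
    return(list(syn_sites = .molevo_env$syn_sites,
                code = .molevo_env$code))
  }
  code <- genetic_code()
  codons <- names(code)
  syn_sites <- vapply(codons, function(cd) {
    if (code[[cd]] == "*") return(0)
    s <- 0
    for (p in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"), substr(cd, p, p))) {
        x <- cd
        substr(x, p, p) <- b
        if (code[[x]] != "*" && code[[x]] == code[[cd]]) s <- s + 1 / 3
      }
    }
    s
  }, numeric(1))
  .molevo_env$syn_sites <- syn_sites
  .molevo_env$code <- code
  list(syn_sites = syn_sites, code = code)
}

# pathway-averaged (synonymous, total) difference counts between two codons
ng86_pair_diff <- function(c1, c2) {
  key <- paste0(c1, c2)
  cached <- .molevo_env$pair_cache[[key]]
  if (!is.null(cached)) return(cached)
  tb <- ng86_tables()
  code <- tb$code
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0) {
    res <- c(sd = 0, nd = 0)
  } else {
    perms <- if (nd == 1) list(pos) else {
      if (nd == 2) list(pos, rev(pos)) else {
        idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                    c(3, 1, 2), c(3, 2, 1))
        lapply(idx, function(o) pos[o])
      }
    }
    sd_tot <- 0
    nd_tot <- 0
    for (pw in perms) {
      cur <- c1
      for (p in pw) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        syn <- code[[cur]] != "*" && code[[nxt]] != "*" &&
          code[[cur]] == code[[nxt]]
        if (syn) sd_tot <- sd_tot + 1 else nd_tot <- nd_tot + 1
        cur <- nxt
      }
    }
    res <- c(sd = sd_tot / length(perms), nd = nd_tot / length(perms))
  }
  if (is.null(.molevo_env$pair_cache)) {
    .molevo_env$pair_cache <- new.env(parent = emptyenv())
  }
  assign(key, res, envir = .molevo_env$pair_cache)
  res
}

#' Extract the spliced CDS of a gene
#'
#' @param genome a `DNAStringSet`.
#' @param model one row of a `wga_gene_models` tibble.
#' @return the CDS as a character string in translation orientation.
#' @export
gene_cds <- function(genome, model) {
  cds <- model$cds[[1]]
  parts <- vapply(seq_len(nrow(cds)), function(i) {
    as.character(Biostrings::subseq(genome[[model$chrom]],
                                    cds$start[i] + 1L, cds$end[i]))
  }, character(1))
  s <- paste(parts, collapse = "")
  if (model$strand == "-") revcomp_chr(s) else s
}

#' Pair orthologous genes through one-to-one alignment blocks
#'
#' A gene of the reference genome is mapped by pushing its midpoint
#' through the block covering it (linear interpolation along the block,
#' strand-aware); it pairs with the query gene whose midpoint lies within
#' `max_dist` of the mapped point. Reciprocal-best filtering enforces a
#' one-to-one pairing.
#'
#' @param blocks one-to-one `wga_blocks`.
#' @param genes_a,genes_b gene models of reference and query genomes.
#' @param max_dist maximum midpoint distance in bases (default 10000).
#' @return list with `pairs` (gene_a, gene_b, dist) and `unpaired_a`,
#'   `unpaired_b` character vectors.
#' @export
pair_orthologs <- function(blocks, genes_a, genes_b, max_dist = 10000) {
  assert_one_to_one(blocks)
  mid <- function(models) {
    vapply(models$exons, function(ex) {
      as.integer((min(ex$start) + max(ex$end)) %/% 2)
    }, integer(1))
  }
  mid_a <- mid(genes_a)
  mid_b <- mid(genes_b)
  # map reference midpoints through the covering block
  bl <- blocks[order(blocks$ref_chrom, blocks$ref_start), ]
  map_one <- function(chrom, pos) {
    cand <- bl[bl$ref_chrom == chrom & bl$ref_start <= pos &
                 bl$ref_end > pos, ]
    if (nrow(cand) == 0) return(NULL)
    b <- cand[1, ]
    f <- (pos - b$ref_start) / (b$ref_end - b$ref_start)
    qpos <- if (b$strand == "+") {
      b$qry_start + f * (b$qry_end - b$qry_start)
    } else {
      b$qry_end - f * (b$qry_end - b$qry_start)
    }
    list(chrom = b$qry_chrom, pos = qpos)
  }
  cand_rows <- list()
  for (i in seq_len(nrow(genes_a))) {
    mp <- map_one(genes_a$chrom[i], mid_a[i])
    if (is.null(mp)) next
    sel <- which(genes_b$chrom == mp$chrom &
                   abs(mid_b - mp$pos) <= max_dist)
    if (length(sel) == 0) next
    d <- abs(mid_b[sel] - mp$pos)
    cand_rows[[length(cand_rows) + 1]] <- tibble(
      gene_a = genes_a$gene_id[i], gene_b = genes_b$gene_id[sel], dist = d)
  }
  if (length(cand_rows) == 0) {
    return(list(pairs = tibble(gene_a = character(0),
                               gene_b = character(0), dist = numeric(0)),
                unpaired_a = genes_a$gene_id,
                unpaired_b = genes_b$gene_id))
  }
  cand <- bind_rows(cand_rows)
  best_a <- cand %>% group_by(.data$gene_a) %>%
    filter(.data$dist == min(.data$dist)) %>%
    dplyr::slice(1) %>% ungroup()
  best_b <- cand %>% group_by(.data$gene_b) %>%
    filter(.data$dist == min(.data$dist)) %>%
    dplyr::slice(1) %>% ungroup()
  pairs <- inner_join(best_a, best_b,
                      by = c("gene_a", "gene_b", "dist"))
  list(pairs = pairs,
       unpaired_a = setdiff(genes_a$gene_id, pairs$gene_a),
       unpaired_b = setdiff(genes_b$gene_id, pairs$gene_b))
}

#' Codon-aware alignment of two CDS sequences
#'
#' Translates both CDS (trailing stop removed), aligns the proteins
#' globally with BLOSUM62, and threads the codons back through the protein
#' alignment, so gaps occur only in whole-codon units.
#'
#' @param cds_a,cds_b CDS strings (length divisible by 3).
#' @return a `wga_codon_alignment` list: `aln_a`, `aln_b` (equal-length,
#'   gapped), `n_codon_pairs` (gap- and stop-free codon pairs).
#' @export
codon_align <- function(cds_a, cds_b) {
  cds_a <- toupper(as.character(cds_a))
  cds_b <- toupper(as.character(cds_b))
  if (nchar(cds_a) %% 3 != 0 || nchar(cds_b) %% 3 != 0) {
    stop("CDS lengths must be divisible by 3", call. = FALSE)
  }
  code <- genetic_code()
  strip_stop <- function(s) {
    last <- substr(s, nchar(s) - 2, nchar(s))
    if (!is.na(code[last]) && code[last] == "*") {
      substr(s, 1, nchar(s) - 3)
    } else s
  }
  cds_a <- strip_stop(cds_a)
  cds_b <- strip_stop(cds_b)
  pa <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds_a), if.fuzzy.codon = "X"))
  pb <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds_b), if.fuzzy.codon = "X"))
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = 10, gapExtension = 0.5, type = "global")
  ap <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ca <- substring(cds_a, seq(1, nchar(cds_a), 3), seq(3, nchar(cds_a), 3))
  cb <- substring(cds_b, seq(1, nchar(cds_b), 3), seq(3, nchar(cds_b), 3))
  oa <- ob <- character(length(ap))
  ia <- ib <- 0L
  for (i in seq_along(ap)) {
    if (ap[i] != "-") { ia <- ia + 1L; oa[i] <- ca[ia] } else oa[i] <- "---"
    if (as_[i] != "-") { ib <- ib + 1L; ob[i] <- cb[ib] } else ob[i] <- "---"
  }
  keep_ok <- oa != "---" & ob != "---" &
    !is.na(code[oa]) & !is.na(code[ob]) &
    code[oa] != "*" & code[ob] != "*"
  structure(list(aln_a = paste(oa, collapse = ""),
                 aln_b = paste(ob, collapse = ""),
                 n_codon_pairs = sum(keep_ok)),
            class = "wga_codon_alignment")
}

codon_pairs_of <- function(aln) {
  a <- aln$aln_a
  b <- aln$aln_b
  stopifnot(nchar(a) == nchar(b), nchar(a) %% 3 == 0)
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  code <- genetic_code()
  ok <- !grepl("-", ca) & !grepl("-", cb) &
    !is.na(code[ca]) & !is.na(code[cb]) &
    code[ca] != "*" & code[cb] != "*"
  tibble(codon_a = ca[ok], codon_b = cb[ok])
}

#' 4DTv: fourfold-degenerate third-codon transversion fraction
#'
#' A fourfold-degenerate (4D) site is a codon pair whose first two bases
#' are identical in both codons and form a fourfold-degenerate prefix
#' (TC, CT, CC, CG, AC, GT, GC, GG). The raw statistic is the fraction of
#' 4D sites whose third bases differ by a transversion. The optional
#' correction applies the Kimura-style transversion-distance formula
#' `-log(1 - 2Q) / 2` for multiple hits.
#'
#' @param aln a `wga_codon_alignment`.
#' @param correct also report the corrected value (default `TRUE`).
#' @return tibble: `n_4d_sites`, `n_4d_transversions`, `fourdtv_raw`,
#'   `fourdtv_corrected`, `defined` (FALSE when no 4D sites exist; the
#'   statistics are then `NA`, not zero).
#' @export
compute_4dtv <- function(aln, correct = TRUE) {
  cp <- codon_pairs_of(aln)
  pre_a <- substr(cp$codon_a, 1, 2)
  pre_b <- substr(cp$codon_b, 1, 2)
  is4d <- pre_a == pre_b & pre_a %in% FOURFOLD_PREFIXES
  t3a <- substr(cp$codon_a[is4d], 3, 3)
  t3b <- substr(cp$codon_b[is4d], 3, 3)
  n4 <- sum(is4d)
  if (n4 == 0) {
    return(tibble(n_4d_sites = 0L, n_4d_transversions = 0L,
                  fourdtv_raw = NA_real_, fourdtv_corrected = NA_real_,
                  defined = FALSE))
  }
  purine <- c("A", "G")
  tv <- t3a != t3b & ((t3a %in% purine) != (t3b %in% purine))
  q <- sum(tv) / n4
  corr <- if (correct && q < 0.5) -0.5 * log(1 - 2 * q) else NA_real_
  tibble(n_4d_sites = as.integer(n4), n_4d_transversions = sum(tv),
         fourdtv_raw = q, fourdtv_corrected = corr, defined = TRUE)
}

#' Synonymous substitution rate (Ks) by NG86 with Jukes-Cantor correction
#'
#' Nei-Gojobori counting: synonymous site counts per codon (averaged over
#' the two sequences), pathway-averaged synonymous differences for codons
#' differing at 1-3 positions (all substitution orders weighted equally;
#' steps through stop codons count as nonsynonymous), then
#' `ks = -3/4 log(1 - 4/3 ps)` with `ps = Sd / S`.
#'
#' @param aln a `wga_codon_alignment`.
#' @param min_codons minimum codon pairs for a confident estimate
#'   (default 30; fewer sets `low_confidence`).
#' @return tibble: `ks`, `ps`, `syn_sites` (S), `syn_diffs` (Sd),
#'   `n_codon_pairs`, `ks_method`, `low_confidence`, `saturated`.
#' @export
compute_ks <- function(aln, min_codons = 30) {
  cp <- codon_pairs_of(aln)
  tb <- ng86_tables()
  if (nrow(cp) == 0) {
    return(tibble(ks = NA_real_, ps = NA_real_, syn_sites = 0,
                  syn_diffs = 0, n_codon_pairs = 0L,
                  ks_method = "NG86-JC", low_confidence = TRUE,
                  saturated = FALSE))
  }
  S <- (sum(tb$syn_sites[cp$codon_a]) + sum(tb$syn_sites[cp$codon_b])) / 2
  diff_rows <- cp[cp$codon_a != cp$codon_b, ]
  Sd <- 0
  if (nrow(diff_rows) > 0) {
    for (i in seq_len(nrow(diff_rows))) {
      Sd <- Sd + ng86_pair_diff(diff_rows$codon_a[i],
                                diff_rows$codon_b[i])[["sd"]]
    }
  }
  ps <- if (S > 0) Sd / S else NA_real_
  saturated <- !is.na(ps) && ps >= 0.75
  ks <- if (is.na(ps)) NA_real_ else if (saturated) Inf else
    -3 / 4 * log(1 - 4 / 3 * ps)
  tibble(ks = ks, ps = ps, syn_sites = S, syn_diffs = Sd,
         n_codon_pairs = nrow(cp), ks_method = "NG86-JC",
         low_confidence = nrow(cp) < min_codons, saturated = saturated)
}

#' Modes of a Ks distribution
#'
#' Gaussian kernel density (Silverman's rule) over finite values in
#' `[0, 3]`; modes are local maxima with prominence at least 5 percent of
#' the global maximum, returned sorted by height.
#'
#' @param values numeric vector of Ks values.
#' @param min_n minimum number of usable values (default 50).
#' @return list with `status` ("ok", "insufficient" or "no peak") and
#'   `modes` (tibble of `location`, `height`, `prominence`).
#' @export
ks_peak <- function(values, min_n = 50) {
  v <- values[is.finite(values) & values >= 0 & values <= 3]
  if (length(v) < min_n) {
    return(list(status = "insufficient",
                modes = tibble(location = numeric(0), height = numeric(0),
                               prominence = numeric(0))))
  }
  d <- density(v, bw = "nrd0", from = 0, to = 3, n = 512)
  y <- d$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                y[2:(n - 1)] >= y[3:n], FALSE)
  peaks <- which(is_max)
  if (length(peaks) == 0) {
    return(list(status = "no peak",
                modes = tibble(location = numeric(0), height = numeric(0),
                               prominence = numeric(0))))
  }
  prom <- vapply(peaks, function(p) {
    higher <- peaks[y[peaks] > y[p]]
    left_bound <- max(c(1, higher[higher < p]))
    right_bound <- min(c(n, higher[higher > p]))
    saddle <- max(min(y[left_bound:p]), min(y[p:right_bound]))
    y[p] - saddle
  }, numeric(1))
  keep <- prom >= 0.05 * max(y)
  if (!any(keep)) {
    return(list(status = "no peak",
                modes = tibble(location = numeric(0), height = numeric(0),
                               prominence = numeric(0))))
  }
  modes <- tibble(location = d$x[peaks[keep]], height = y[peaks[keep]],
                  prominence = prom[keep]) %>%
    arrange(desc(.data$height))
  list(status = "ok", modes = modes)
}

#' LTR insertion age from terminal-repeat divergence
#'
#' The two terminal repeats of an LTR retrotransposon are identical at
#' insertion; their Jukes-Cantor distance K dates the insertion as
#' `K / (2 mu)`.
#'
#' @param ltr5,ltr3 the two terminal-repeat sequences (at least 100 bases
#'   each).
#' @param mu substitution rate per site per year (default 1.3e-8; no
#'   universally agreed plant value exists, so it is always echoed in the
#'   result).
#' @param min_identity minimum alignment identity in percent (default 60);
#'   lower pairs raise an error as unreliable.
#' @return tibble: `K`, `age_years`, `identity`, `aligned_columns`, `mu`.
#' @export
ltr_age <- function(ltr5, ltr3, mu = 1.3e-8, min_identity = 60) {
  a <- toupper(as.character(ltr5))
  b <- toupper(as.character(ltr3))
  if (nchar(a) < 100 || nchar(b) < 100) {
    stop("both LTR sequences must be at least 100 bases", call. = FALSE)
  }
  aln <- nw_align_cpp(a, b)
  ops <- parse_edit_path(aln$path)
  n_eq <- sum(ops$len[ops$op == "="])
  n_x <- sum(ops$len[ops$op == "X"])
  identity <- 100 * n_eq / sum(ops$len)
  if (identity < min_identity) {
    stop(sprintf("LTR pair identity %.1f%% below %.0f%%: unreliable",
                 identity, min_identity), call. = FALSE)
  }
  p <- n_x / (n_eq + n_x)
  K <- if (p > 0) -3 / 4 * log(1 - 4 / 3 * p) else 0
  tibble(K = K, age_years = ltr_age_from_k(K, mu), identity = identity,
         aligned_columns = sum(ops$len), mu = mu)
}

#' Closed-form LTR age from a known divergence
#'
#' @param k substitutions per site between the two LTRs.
#' @param mu substitution rate per site per year.
#' @return age in years, `k / (2 mu)`.
#' @examples
#' ltr_age_from_k(0.026, 1.3e-8) # 1e6
#' @export
ltr_age_from_k <- function(k, mu = 1.3e-8) {
  k / (2 * mu)
}

#' Simulate a codon pair under synonymous-only divergence
#'
#' Starting from random sense codons, applies a Poisson number of
#' synonymous single-base substitutions (expected `ks` per NG86
#' synonymous site); each event picks a codon with probability
#' proportional to its current synonymous site count and moves to a
#' uniformly chosen synonymous neighbour. Multiple hits at a site are
#' possible, which is what the Jukes-Cantor correction of [compute_ks()]
#' must absorb.
#'
#' @param n_codons number of codons.
#' @param ks target synonymous substitutions per synonymous site.
#' @param seed integer seed.
#' @return a `wga_codon_alignment` of the ancestral and derived sequences.
#' @export
sim_codon_pair <- function(n_codons, ks, seed = 1) {
  tb <- ng86_tables()
  code <- tb$code
  sense <- names(code)[code != "*"]
  with_seed(seed, {
    cod <- sample(sense, n_codons, replace = TRUE)
    derived <- cod
    syn_nb <- lapply(setNames(names(code), names(code)), function(cd) {
      nb <- codon_neighbors(cd)
      nb[code[nb] != "*" & code[nb] == code[cd]]
    })
    S0 <- sum(tb$syn_sites[derived])
    n_events <- rpois(1, ks * S0)
    for (e in seq_len(n_events)) {
      wts <- tb$syn_sites[derived]
      i <- sample.int(n_codons, 1, prob = wts)
      nb <- syn_nb[[derived[i]]]
      if (length(nb) == 0) next
      derived[i] <- nb[sample.int(length(nb), 1)]
    }
    structure(list(aln_a = paste(cod, collapse = ""),
                   aln_b = paste(derived, collapse = ""),
                   n_codon_pairs = n_codons),
              class = "wga_codon_alignment")
  })
}
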