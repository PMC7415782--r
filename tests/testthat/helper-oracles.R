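# Independent oracles used by unit and acceptance tests. These deliberately
# reimplement the checked operations by brute force (quadratic scans,
# exhaustive enumeration, explicit recursion) and share no code with the
# package internals they verify.

rnd_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_str <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# all maximal exact matches of length >= min_len unique in both sequences
# (query counted over both strands), by quadratic substring scan
brute_force_mums <- function(ref, qry, min_len) {
  qrc <- revcomp_str(qry)
  count_occ <- function(pat, s) {
    n <- 0L
    start <- 1L
    repeat {
      i <- regexpr(pat, substr(s, start, nchar(s)), fixed = TRUE)
      if (i == -1) break
      n <- n + 1L
      start <- start + i
    }
    n
  }
  out <- list()
  for (i in seq_len(nchar(ref) - min_len + 1)) {
    for (target in list(c("+", qry), c("-", qrc))) {
      strand <- target[1]
      q <- target[2]
      for (j in seq_len(nchar(q) - min_len + 1)) {
        # extend the match at (i, j) maximally
        L <- 0L
        while (i + L <= nchar(ref) && j + L <= nchar(q) &&
               substr(ref, i + L, i + L) == substr(q, j + L, j + L)) {
          L <- L + 1L
        }
        if (L < min_len) next
        # left-maximal?
        if (i > 1 && j > 1 &&
            substr(ref, i - 1, i - 1) == substr(q, j - 1, j - 1)) next
        pat <- substr(ref, i, i + L - 1)
        occ_ref <- count_occ(pat, ref)
        occ_qry <- count_occ(pat, qry) + count_occ(pat, qrc)
        if (occ_ref != 1 || occ_qry != 1) next
        qs <- if (strand == "+") j - 1L else nchar(qry) - (j - 1L) - L
        out[[length(out) + 1]] <- data.frame(
          ref_start = i - 1L, qry_start = qs, length = L, strand = strand)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(ref_start = integer(0), qry_start = integer(0),
                      length = integer(0), strand = character(0)))
  }
  u <- unique(do.call(rbind, out))
  u[order(u$ref_start, u$qry_start), , drop = FALSE]
}

# exhaustive maximum-weight collinear chain over all anchor subsets,
# mirroring the chain precedence (all four coordinates strictly advance)
# and tie-break (smaller off-diagonal drift)
exhaustive_chain <- function(rs, re, qs, qe, w) {
  n <- length(rs)
  best_w <- -Inf
  best_d <- Inf
  for (mask in seq_len(2^n) - 1) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) == 0) next
    idx <- idx[order(rs[idx], qs[idx])]
    ok <- TRUE
    drift <- 0
    if (length(idx) > 1) {
      for (k in 2:length(idx)) {
        i <- idx[k - 1]; j <- idx[k]
        if (!(rs[i] < rs[j] && qs[i] < qs[j] && re[i] < re[j] &&
              qe[i] < qe[j])) { ok <- FALSE; break }
        drift <- drift + abs((rs[j] - re[i]) - (qs[j] - qe[i]))
      }
    }
    if (!ok) next
    tw <- sum(w[idx])
    if (tw > best_w + 1e-9 ||
        (tw > best_w - 1e-9 && drift < best_d - 1e-9)) {
      best_w <- tw
      best_d <- drift
    }
  }
  list(weight = best_w, drift = best_d)
}

# exhaustive two-pass one-to-one selection: the maximum-weight subset
# non-overlapping on the reference, then the maximum-weight subset of that
# non-overlapping on the query
exhaustive_one_to_one_weight <- function(blocks, w) {
  n <- nrow(blocks)
  ok_subset <- function(idx, chrom, s, e) {
    for (ch in unique(chrom[idx])) {
      k <- idx[chrom[idx] == ch]
      o <- k[order(s[k])]
      if (length(o) > 1 && any(s[o][-1] < e[o][-length(o)])) return(FALSE)
    }
    TRUE
  }
  best1 <- -Inf
  sets1 <- list()
  for (mask in seq_len(2^n) - 1) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) == 0) next
    if (!ok_subset(idx, blocks$ref_chrom, blocks$ref_start,
                   blocks$ref_end)) next
    tw <- sum(w[idx])
    if (tw > best1 + 1e-9) {
      best1 <- tw
      sets1 <- list(idx)
    } else if (tw > best1 - 1e-9) {
      sets1 <- c(sets1, list(idx))
    }
  }
  best2 <- -Inf
  for (s1 in sets1) {
    m <- length(s1)
    for (mask in seq_len(2^m) - 1) {
      idx <- s1[which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)]
      if (length(idx) == 0) next
      if (!ok_subset(idx, blocks$qry_chrom, blocks$qry_start,
                     blocks$qry_end)) next
      tw <- sum(w[idx])
      if (tw > best2) best2 <- tw
    }
  }
  best2
}

# quadratic per-element scan over all index regions (any-overlap,
# precedence exon > intron > promoter > downstream)
brute_force_classify <- function(elements, index) {
  cats <- c("exon", "intron", "promoter", "downstream")
  assign_cat <- character(nrow(elements))
  for (i in seq_len(nrow(elements))) {
    hit <- rep(FALSE, 4)
    for (j in seq_len(nrow(index))) {
      if (index$chrom[j] == elements$chrom[i] &&
          index$start[j] < elements$end[i] &&
          index$end[j] > elements$start[i]) {
        hit[match(index$category[j], cats)] <- TRUE
      }
    }
    assign_cat[i] <- if (any(hit)) cats[which(hit)[1]] else "intergenic"
  }
  table(factor(assign_cat, levels = c(cats, "intergenic")))
}

# independent NG86 counting: explicit recursion over substitution orders
# using the standard genetic code from Biostrings
ng86_oracle <- function(codons_a, codons_b) {
  code <- as.character(Biostrings::GENETIC_CODE)
  names(code) <- names(Biostrings::GENETIC_CODE)
  syn_sites_one <- function(cd) {
    if (code[cd] == "*") return(0)
    s <- 0
    for (p in 1:3) {
      for (b in c("A", "C", "G", "T")) {
        if (b == substr(cd, p, p)) next
        x <- paste0(substr(cd, 1, p - 1), b, substr(cd, p + 1, 3))
        if (code[x] != "*" && code[x] == code[cd]) s <- s + 1 / 3
      }
    }
    s
  }
  all_orders <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in all_orders(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  Sd <- 0
  S <- 0
  for (k in seq_along(codons_a)) {
    ca <- codons_a[k]; cb <- codons_b[k]
    S <- S + (syn_sites_one(ca) + syn_sites_one(cb)) / 2
    pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
    if (length(pos) == 0) next
    orders <- all_orders(pos)
    sd_k <- 0
    for (ord in orders) {
      cur <- ca
      for (p in ord) {
        nxt <- paste0(substr(cur, 1, p - 1), substr(cb, p, p),
                      substr(cur, p + 1, 3))
        if (code[cur] != "*" && code[nxt] != "*" &&
            code[cur] == code[nxt]) sd_k <- sd_k + 1
        cur <- nxt
      }
    }
    Sd <- Sd + sd_k / length(orders)
  }
  ps <- Sd / S
  list(S = S, Sd = Sd, ps = ps,
       ks = if (ps >= 0.75) Inf else -3 / 4 * log(1 - 4 / 3 * ps))
}

# apply called SNPs and indels (reference coordinates) to a reference
# chromosome string, producing the implied query sequence
apply_edits <- function(ref_str, snps, indels) {
  ed <- rbind(
    if (nrow(snps)) data.frame(pos = snps$ref_pos, kind = "snp",
                               seq = snps$qry_base, len = 1L),
    if (nrow(indels)) data.frame(pos = indels$ref_pos, kind = indels$kind,
                                 seq = indels$seq, len = indels$length)
  )
  if (is.null(ed) || nrow(ed) == 0) return(ref_str)
  ed <- ed[order(-ed$pos), ]
  s <- ref_str
  for (i in seq_len(nrow(ed))) {
    p <- ed$pos[i]
    if (ed$kind[i] == "snp") {
      substr(s, p + 1, p + 1) <- ed$seq[i]
    } else if (ed$kind[i] == "insertion") {
      s <- paste0(substr(s, 1, p + 1), ed$seq[i],
                  substr(s, p + 2, nchar(s)))
    } else {
      s <- paste0(substr(s, 1, p + 1),
                  substr(s, p + 2 + ed$len[i], nchar(s)))
    }
  }
  s
}
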