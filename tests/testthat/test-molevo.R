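test_that("4DTv counts fourfold sites and transversions correctly", {
  # GGT/GGA: transversion at a 4D site; GGT/GGC: transition at a 4D site
  r <- compute_4dtv(codon_aln("GGTGGT", "GGAGGC"))
  expect_equal(r$n_4d_sites, 2)
  expect_equal(r$n_4d_transversions, 1)
  expect_equal(r$fourdtv_raw, 0.5)
  # identical sequences: zero transversions
  expect_equal(compute_4dtv(codon_aln("GGTCTA", "GGTCTA"))$fourdtv_raw, 0)
  # ATG prefix is not fourfold degenerate: undefined, not zero
  r2 <- compute_4dtv(codon_aln("ATGATG", "ATGATG"))
  expect_false(r2$defined)
  expect_true(is.na(r2$fourdtv_raw))
  # prefix-mismatched codons are excluded even if third bases align
  r3 <- compute_4dtv(codon_aln("GGT", "GCT"))
  expect_equal(r3$n_4d_sites, 0)
})

test_that("4DTv and Ks are symmetric in their sequences", {
  sim <- sim_codon_pair(300, 0.05, seed = 14)
  fwd <- codon_aln(sim$aln_a, sim$aln_b)
  rev <- codon_aln(sim$aln_b, sim$aln_a)
  expect_equal(compute_4dtv(fwd)$fourdtv_raw,
               compute_4dtv(rev)$fourdtv_raw)
  expect_equal(compute_ks(fwd)$ks, compute_ks(rev)$ks)
})

test_that("Ks is zero iff there are no synonymous differences", {
  set.seed(15)
  base <- paste(sample(c("GGT", "CCA", "TTA", "GAT", "AAA"), 60,
                       replace = TRUE), collapse = "")
  expect_equal(compute_ks(codon_aln(base, base))$ks, 0)
  # purely nonsynonymous divergence (ATG -> AAG is Met -> Lys)
  r <- compute_ks(codon_aln(strrep("ATG", 40), strrep("AAG", 40)))
  expect_equal(r$ks, 0)
  expect_equal(r$syn_diffs, 0)
  # one synonymous change gives ks > 0
  r2 <- compute_ks(codon_aln(paste0(base, "GGT"), paste0(base, "GGA")))
  expect_gt(r2$ks, 0)
})

test_that("NG86 counting equals the pathway-enumeration oracle", {
  tb <- wgacompare:::ng86_tables()
  sense <- names(tb$code)[tb$code != "*"]
  set.seed(16)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    ca <- sample(sense, n, replace = TRUE)
    cb <- vapply(ca, function(cd) {
      # mutate 0-3 positions, avoiding stops
      repeat {
        x <- cd
        for (p in sample(1:3, sample(0:3, 1))) {
          substr(x, p, p) <- sample(c("A", "C", "G", "T"), 1)
        }
        if (tb$code[[x]] != "*") return(x)
      }
    }, character(1))
    mine <- compute_ks(codon_aln(paste(ca, collapse = ""),
                                 paste(cb, collapse = "")))
    oracle <- ng86_oracle(ca, unname(cb))
    expect_equal(mine$syn_sites, oracle$S, tolerance = 1e-9)
    expect_equal(mine$syn_diffs, oracle$Sd, tolerance = 1e-9)
    if (is.finite(oracle$ks) && is.finite(mine$ks)) {
      expect_equal(mine$ks, oracle$ks, tolerance = 1e-9)
    }
  }
})

test_that("codon alignment back-threads gaps in whole codons", {
  a <- "ATGGCTGCTAAAGGTTGA"          # M A A K G *
  b <- "ATGGCTAAAGGTTGA"             # M A K G * (one codon deleted)
  al <- codon_align(a, b)
  expect_equal(nchar(al$aln_a) %% 3, 0)
  expect_equal(nchar(al$aln_a), nchar(al$aln_b))
  expect_equal(nchar(al$aln_b) - nchar(gsub("-", "", al$aln_b)), 3)
  expect_equal(al$n_codon_pairs, 4) # stop stripped, one gap codon
  expect_error(codon_align("ATGA", "ATG"), "divisible")
})

test_that("Ks distribution modes are found where the mass is", {
  set.seed(17)
  v <- abs(rnorm(500, 0.05, 0.01))
  pk <- ks_peak(v)
  expect_equal(pk$status, "ok")
  expect_gt(pk$modes$location[1], 0.02)
  expect_lt(pk$modes$location[1], 0.08)
  expect_equal(ks_peak(runif(10))$status, "insufficient")
})

test_that("orthologs pair by synteny and drop deleted genes", {
  pair <- fixture_gene_pair()
  po <- pair_orthologs(pair$blocks, pair$genes_a, pair$genes_b)
  truth <- pair$truth$orthologs
  expect_setequal(paste(po$pairs$gene_a, po$pairs$gene_b),
                  paste(truth$gene_a, truth$gene_b))
  # remove one gene from B: it must move to the unpaired list
  drop <- pair$genes_b$gene_id[1]
  po2 <- pair_orthologs(pair$blocks, pair$genes_a,
                        pair$genes_b[pair$genes_b$gene_id != drop, ])
  expect_true(drop %in% po2$unpaired_a)
  expect_false(drop %in% po2$pairs$gene_a)
})

test_that("ortholog CDS pairs have near-zero Ks at low divergence", {
  pair <- fixture_gene_pair()
  po <- pair_orthologs(pair$blocks, pair$genes_a, pair$genes_b)
  g <- po$pairs$gene_a[1:5]
  ks <- vapply(g, function(id) {
    al <- codon_align(
      gene_cds(pair$genome_a, pair$genes_a[pair$genes_a$gene_id == id, ]),
      gene_cds(pair$genome_b, pair$genes_b[pair$genes_b$gene_id == id, ]))
    compute_ks(al)$ks
  }, numeric(1))
  expect_true(all(is.finite(ks)))
  expect_true(all(ks < 0.05))
})

test_that("LTR ages follow the closed form and recover divergence", {
  expect_equal(ltr_age_from_k(0.026, 1.3e-8), 1.0e6)
  expect_equal(ltr_age_from_k(0, 1.3e-8), 0)
  set.seed(18)
  l <- rnd_dna(3000)
  la <- ltr_age(l, l)
  expect_equal(la$K, 0)
  expect_equal(la$age_years, 0)
  mut <- function(s, r) {
    v <- strsplit(s, "")[[1]]
    for (i in which(runif(length(v)) < r)) {
      v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
    }
    paste(v, collapse = "")
  }
  est <- ltr_age(mut(l, 0.02), mut(l, 0.02), mu = 1.3e-8)
  expected <- 0.04 / (2 * 1.3e-8)
  expect_lt(abs(est$age_years - expected) / expected, 0.25)
  expect_error(ltr_age(substr(l, 1, 50), l), "100 bases")
  expect_error(ltr_age(rnd_dna(300), rnd_dna(300)), "unreliable")
})

test_that("simulator LTR pairs date back to their divergence setting", {
  anc <- generate_ancestor(1, 60000, 0, seed = 71)
  pair <- evolve_pair(anc, mutation_config(seed = 1),
                      mutation_config(te_insertions = 5,
                                      te_ltr_fraction = 1,
                                      te_ltr_length = 1000,
                                      ltr_divergence = 0.02, seed = 71))
  te <- pair$truth$te
  ages <- vapply(seq_len(nrow(te)), function(i) {
    ltr_age(te$ltr5_seq[i], te$ltr3_seq[i], mu = 1.3e-8)$age_years
  }, numeric(1))
  expected <- 0.04 / (2 * 1.3e-8)
  expect_lt(abs(mean(ages) - expected) / expected, 0.25)
})
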