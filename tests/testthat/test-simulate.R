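test_that("ancestor generation is deterministic and respects GC", {
  a1 <- generate_ancestor(1, 100000, 10, gc = 0.39, seed = 7)
  a2 <- generate_ancestor(1, 100000, 10, gc = 0.39, seed = 7)
  expect_identical(as.character(a1$genome), as.character(a2$genome))
  expect_identical(a1$genes$gene_id, a2$genes$gene_id)
  a3 <- generate_ancestor(1, 100000, 10, gc = 0.39, seed = 8)
  expect_false(identical(as.character(a1$genome), as.character(a3$genome)))
  # GC concentration at 0.5 on gene-free sequence
  g <- generate_ancestor(1, 500000, 0, gc = 0.5, seed = 3)
  freq <- Biostrings::alphabetFrequency(g$genome)[1, c("C", "G")]
  expect_lt(abs(sum(freq) / 500000 - 0.5), 0.01)
  expect_equal(nrow(g$genes), 0)
})

test_that("generated genes carry valid CDS on both strands", {
  anc <- generate_ancestor(2, 150000, 15, seed = 12)
  expect_setequal(unique(anc$genes$strand) %in% c("+", "-"), TRUE)
  code <- Biostrings::GENETIC_CODE
  for (i in seq_len(nrow(anc$genes))) {
    cds <- gene_cds(anc$genome, anc$genes[i, ])
    expect_equal(nchar(cds) %% 3, 0)
    expect_equal(substr(cds, 1, 3), "ATG")
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    aas <- unname(code[codons])
    expect_false(any(aas[-length(aas)] == "*"))
    expect_equal(aas[length(aas)], "*")
  }
})

test_that("all-zero configurations reproduce the ancestor exactly", {
  anc <- generate_ancestor(1, 50000, 3, seed = 5)
  pair <- evolve_pair(anc, mutation_config(seed = 1),
                      mutation_config(seed = 2))
  expect_identical(as.character(pair$genome_a), as.character(anc$genome))
  expect_identical(as.character(pair$genome_b), as.character(anc$genome))
  expect_equal(nrow(pair$truth$snps), 0)
  expect_equal(nrow(pair$truth$indels), 0)
  expect_equal(nrow(pair$truth$svs), 0)
  expect_equal(nrow(pair$truth$orthologs), 3)
})

test_that("SNP counts concentrate around the binomial mean", {
  anc <- generate_ancestor(1, 1e6, 0, seed = 9)
  pair <- evolve_pair(anc, mutation_config(seed = 1),
                      mutation_config(snp_rate = 0.005, seed = 9))
  n <- nrow(pair$truth$snps)
  mu <- 1e6 * 0.005
  sd <- sqrt(1e6 * 0.005 * 0.995)
  expect_lt(abs(n - mu), 4 * sd)
  # substituted bases really differ and land where truth says
  idx <- sample(n, 50)
  for (i in idx) {
    tr <- pair$truth$snps[i, ]
    expect_equal(as.character(Biostrings::subseq(
      pair$genome_b[[tr$chrom_b]], tr$pos_b + 1, tr$pos_b + 1)), tr$base_b)
    expect_false(tr$base_a == tr$base_b)
  }
})

test_that("an implanted inversion is the reverse complement in place", {
  anc <- generate_ancestor(1, 100000, 0, seed = 31)
  pair <- evolve_pair(anc, mutation_config(seed = 1),
                      mutation_config(n_inversions = 1,
                                      inversion_size_range = c(5000, 5000),
                                      seed = 31))
  tr <- pair$truth$svs
  expect_equal(nrow(tr), 1)
  expect_equal(tr$sv_type, "inversion")
  a <- as.character(pair$genome_a[[tr$chrom_a]])
  b <- as.character(pair$genome_b[[tr$chrom_b]])
  seg_a <- substr(a, tr$start_a + 1, tr$end_a)
  seg_b <- substr(b, tr$start_b + 1, tr$end_b)
  expect_identical(seg_b, revcomp_str(seg_a))
  # outside the inversion the genomes agree
  expect_identical(substr(a, 1, tr$start_a), substr(b, 1, tr$start_b))
  expect_identical(substr(a, tr$end_a + 1, nchar(a)),
                   substr(b, tr$end_b + 1, nchar(b)))
})

test_that("length conservation holds in single-sided mode", {
  anc <- generate_ancestor(2, 120000, 0, seed = 44)
  pair <- evolve_pair(anc, mutation_config(seed = 1),
                      mutation_config(indel_rate = 2e-4, te_insertions = 4,
                                      n_inversions = 1, n_translocations = 1,
                                      n_relocations = 1, seed = 44))
  ind <- pair$truth$indels
  te <- pair$truth$te
  expected <- sum(ind$length[ind$kind == "insertion"]) -
    sum(ind$length[ind$kind == "deletion"]) + sum(te$end - te$start)
  expect_equal(sum(Biostrings::width(pair$genome_b)) -
                 sum(Biostrings::width(pair$genome_a)), expected)
})

test_that("lifted gene models stay valid and orthologs cover survivors", {
  pair <- fixture_gene_pair()
  expect_silent(wgacompare:::validate_gene_models(pair$genes_b))
  expect_setequal(pair$truth$orthologs$gene_a,
                  intersect(pair$genes_a$gene_id, pair$genes_b$gene_id))
  # CDS length divisible by 3 unless flagged as disrupted
  for (i in seq_len(nrow(pair$genes_b))) {
    len <- sum(pair$genes_b$cds[[i]]$end - pair$genes_b$cds[[i]]$start)
    if (!isTRUE(pair$genes_b$cds_disrupted[i])) {
      expect_equal(len %% 3, 0)
    }
  }
})

test_that("LTR insertions carry diverged terminal repeats", {
  anc <- generate_ancestor(1, 80000, 0, seed = 77)
  pair <- evolve_pair(anc, mutation_config(seed = 1),
                      mutation_config(te_insertions = 6,
                                      te_ltr_fraction = 1,
                                      te_ltr_length = 400,
                                      ltr_divergence = 0.03, seed = 77))
  te <- pair$truth$te
  expect_equal(nrow(te), 6)
  expect_true(all(te$is_ltr))
  b <- as.character(pair$genome_b[[1]])
  for (i in seq_len(nrow(te))) {
    el <- substr(b, te$start[i] + 1, te$end[i])
    expect_identical(substr(el, 1, 400), te$ltr5_seq[i])
    expect_identical(substr(el, nchar(el) - 399, nchar(el)), te$ltr3_seq[i])
    d <- mean(strsplit(te$ltr5_seq[i], "")[[1]] !=
                strsplit(te$ltr3_seq[i], "")[[1]])
    expect_gt(d, 0)
    expect_lt(d, 0.2)
  }
})

test_that("simulated reads match coverage arithmetic and determinism", {
  anc <- generate_ancestor(1, 100000, 0, seed = 15)
  reads <- simulate_reads(anc$genome, coverage = 10, read_length = 150,
                          seed = 2)
  expect_equal(length(reads), round(10 * 100000 / 150))
  reads2 <- simulate_reads(anc$genome, coverage = 10, read_length = 150,
                           seed = 2)
  expect_identical(as.character(reads), as.character(reads2))
  # error-free reads are exact substrings of the genome or its revcomp
  g <- as.character(anc$genome[[1]])
  grc <- revcomp_str(g)
  for (r in as.character(reads[sample(length(reads), 25)])) {
    expect_true(grepl(r, g, fixed = TRUE) || grepl(r, grc, fixed = TRUE))
  }
  expect_error(simulate_reads(anc$genome, 10, 2e5, seed = 1),
               "read_length")
})

test_that("truth sets serialize to JSON and BED", {
  pair <- fixture_gene_pair()
  dir <- withr::local_tempdir()
  write_truth(pair$truth, dir)
  expect_true(file.exists(file.path(dir, "truth.json")))
  js <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(length(js$snps), nrow(pair$truth$snps))
  expect_true(file.exists(file.path(dir, "te_b.bed")))
})
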