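test_that("fully collinear forward blocks give no SVs", {
  blocks <- dplyr::bind_rows(
    make_block("b1", "c1", 0, 1000, "c1", 0, 1000),
    make_block("b2", "c1", 1200, 2200, "c1", 1200, 2200),
    make_block("b3", "c1", 2400, 3400, "c1", 2400, 3400)
  )
  expect_equal(nrow(detect_inversions(blocks)), 0)
  expect_equal(nrow(detect_transloc_reloc(blocks)), 0)
})

test_that("reverse blocks within 50 bp merge into one inversion", {
  scaffold <- function(gap) dplyr::bind_rows(
    make_block("bL", "c1", 0, 900, "c1", 0, 900, identity = 99),
    make_block("r1", "c1", 1000, 1400, "c1", 1000, 1400, strand = "-",
               identity = 98),
    make_block("r2", "c1", 1400 + gap, 1800 + gap, "c1", 1400 + gap,
               1800 + gap, strand = "-", identity = 98),
    make_block("bR", "c1", 1900 + gap, 2900 + gap, "c1", 1900 + gap,
               2900 + gap, identity = 99)
  )
  merged <- detect_inversions(scaffold(30), merge_gap = 50)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$ref_start, 1000)
  expect_equal(merged$ref_end, 1830)
  split <- detect_inversions(scaffold(60), merge_gap = 50)
  expect_equal(nrow(split), 2)
})

test_that("inversions need high-identity forward flanks on both sides", {
  mk <- function(flank_id) dplyr::bind_rows(
    make_block("bL", "c1", 0, 900, "c1", 0, 900, identity = flank_id),
    make_block("inv", "c1", 1000, 1500, "c1", 1000, 1500, strand = "-",
               identity = 99),
    make_block("bR", "c1", 1600, 2600, "c1", 1600, 2600, identity = 99)
  )
  expect_equal(nrow(detect_inversions(mk(95))), 1)
  expect_equal(nrow(detect_inversions(mk(85))), 0)
  # a reverse block at the chromosome edge has no left flank
  edge <- dplyr::bind_rows(
    make_block("inv", "c1", 0, 500, "c1", 0, 500, strand = "-",
               identity = 99),
    make_block("bR", "c1", 600, 1600, "c1", 600, 1600, identity = 99)
  )
  expect_equal(nrow(detect_inversions(edge)), 0)
})

test_that("off-backbone blocks obey the strict length/identity cutoffs", {
  mk <- function(len, ident) dplyr::bind_rows(
    make_block("bb1", "c1", 0, 50000, "c1", 0, 50000, identity = 99),
    make_block("bb2", "c1", 60000, 120000, "c1", 60000, 120000,
               identity = 99),
    # order-breaking block (crosses the backbone on the query side)
    make_block("off", "c1", 52000, 52000 + len, "c1", 150000,
               150000 + len, identity = ident)
  )
  expect_equal(nrow(detect_transloc_reloc(mk(100, 99))), 0)  # not > 100
  expect_equal(nrow(detect_transloc_reloc(mk(101, 90))), 0)  # not > 90
  got <- detect_transloc_reloc(mk(5000, 95))
  expect_equal(nrow(got), 1)
  expect_equal(got$sv_type, "relocation") # same chromosome pair
})

test_that("inter-chromosomal off-backbone blocks are translocations", {
  blocks <- dplyr::bind_rows(
    make_block("bb1", "c1", 0, 50000, "c1", 0, 50000, identity = 99),
    make_block("bb2", "c1", 60000, 120000, "c1", 60000, 120000,
               identity = 99),
    make_block("bbB", "c2", 0, 80000, "c2", 0, 80000, identity = 99),
    make_block("off", "c1", 52000, 58000, "c2", 90000, 96000,
               identity = 97)
  )
  got <- detect_transloc_reloc(blocks)
  expect_equal(nrow(got), 1)
  expect_equal(got$sv_type, "translocation")
})

test_that("implanted SVs are recovered with correct classes", {
  anc <- generate_ancestor(2, 600000, 0, seed = 61)
  pair <- evolve_pair(anc, mutation_config(seed = 1),
                      mutation_config(snp_rate = 0.002, n_inversions = 3,
                                      inversion_size_range = c(2000, 8000),
                                      n_translocations = 2,
                                      n_relocations = 2,
                                      translocation_size_range =
                                        c(5000, 10000),
                                      relocation_size_range =
                                        c(5000, 10000),
                                      seed = 61))
  blocks <- align_genomes(pair$genome_a, pair$genome_b)
  svs <- call_svs(blocks)
  rec <- sv_recovery(svs, pair$truth$svs)
  expect_gte(rec$recall$inversion, 0.9)
  expect_gte(mean(c(rec$recall$translocation, rec$recall$relocation)),
             0.75)
  expect_equal(rec$precision, 1)
  # no inversion doubles as a translocation and intervals are disjoint
  # within each class
  for (tp in unique(svs$sv_type)) {
    s <- svs[svs$sv_type == tp, ]
    s <- s[order(s$ref_chrom, s$ref_start), ]
    same <- s$ref_chrom[-1] == s$ref_chrom[-nrow(s)]
    if (nrow(s) > 1) {
      expect_true(all(s$ref_start[-1][same] >= s$ref_end[-nrow(s)][same]))
    }
  }
  inv_truth <- pair$truth$svs[pair$truth$svs$sv_type == "inversion", ]
  tra <- svs[svs$sv_type != "inversion", ]
  if (nrow(tra) > 0) {
    for (i in seq_len(nrow(inv_truth))) {
      ov <- pmin(tra$ref_end, inv_truth$end_a[i]) -
        pmax(tra$ref_start, inv_truth$start_a[i])
      frac <- ov / (inv_truth$end_a[i] - inv_truth$start_a[i])
      expect_true(all(frac < 0.5))
    }
  }
})
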