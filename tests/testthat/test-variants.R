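test_that("a single mismatch becomes one SNP with correct alleles", {
  ref <- Biostrings::DNAStringSet(c(c1 = "ACGTACGT"))
  qry <- Biostrings::DNAStringSet(c(c1 = "ACGAACGT"))
  blocks <- wgacompare:::new_blocks(
    make_block("b1", "c1", 0, 8, "c1", 0, 8, path = "3=1X4="))
  v <- call_variants(blocks, ref, qry)
  expect_equal(nrow(v$snps), 1)
  expect_equal(v$snps$ref_pos, 3)
  expect_equal(v$snps$ref_base, "T")
  expect_equal(v$snps$qry_base, "A")
  expect_equal(nrow(v$indels), 0)
})

test_that("a deletion run is one left-aligned record", {
  # ref ACGTTTGG vs qry ACGGG, path 3= 3D 2=
  ref <- Biostrings::DNAStringSet(c(c1 = "ACGTTTGG"))
  qry <- Biostrings::DNAStringSet(c(c1 = "ACGGG"))
  blocks <- wgacompare:::new_blocks(
    make_block("b1", "c1", 0, 8, "c1", 0, 5, path = "3=3D2="))
  v <- call_variants(blocks, ref, qry)
  expect_equal(nrow(v$snps), 0)
  expect_equal(nrow(v$indels), 1)
  expect_equal(v$indels$kind, "deletion")
  expect_equal(v$indels$ref_pos, 2)
  expect_equal(v$indels$seq, "TTT")
  expect_equal(v$indels$length, 3)
})

test_that("identical genomes give zero variants", {
  set.seed(21)
  g <- Biostrings::DNAStringSet(c(c1 = rnd_dna(3000)))
  v <- call_variants(align_genomes(g, g), g, g)
  expect_equal(nrow(v$snps), 0)
  expect_equal(nrow(v$indels), 0)
})

test_that("variant calling requires one-to-one blocks", {
  overlapping <- dplyr::bind_rows(
    make_block("b1", "c1", 0, 100, "c1", 0, 100),
    make_block("b2", "c1", 50, 150, "c1", 200, 300)
  )
  g <- Biostrings::DNAStringSet(c(c1 = strrep("A", 400)))
  expect_error(call_variants(overlapping, g, g), "one-to-one")
})

test_that("reverse-strand blocks report complemented query bases", {
  # ref aligns to the revcomp of qry; one mismatch in the middle
  set.seed(22)
  s <- rnd_dna(4000)
  q <- s
  old <- substr(q, 2000, 2000)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  substr(q, 2000, 2000) <- new
  ref <- Biostrings::DNAStringSet(c(c1 = s))
  qry <- Biostrings::DNAStringSet(c(c1 = revcomp_str(q)))
  blocks <- align_genomes(ref, qry)
  expect_equal(blocks$strand, "-")
  v <- call_variants(blocks, ref, qry)
  expect_equal(nrow(v$snps), 1)
  expect_equal(v$snps$ref_pos, 1999)
  expect_equal(v$snps$ref_base, old)
  expect_equal(v$snps$qry_base, new) # complement of the genome base
  expect_equal(v$snps$qry_pos, 4000 - 2000) # mapped forward coordinate
})

test_that("called edits reconstruct the query genome", {
  pair <- fixture_small_pair()
  v <- call_variants(pair$blocks, pair$genome_a, pair$genome_b)
  b <- pair$blocks[1, ]
  rebuilt <- apply_edits(as.character(pair$genome_a[[1]]), v$snps,
                         v$indels)
  # compare over the aligned query span of the (single) block
  expect_equal(nrow(pair$blocks), 1)
  shift <- b$qry_start - b$ref_start
  expect_identical(
    substr(rebuilt, b$ref_start + 1 + shift, b$qry_end),
    substr(as.character(pair$genome_b[[1]]), b$qry_start + 1, b$qry_end))
})

test_that("spectrum counts directed substitution types", {
  snps <- tibble::tibble(
    ref_base = c("A", "A", "C"), qry_base = c("G", "G", "T"))
  sp <- snp_spectrum(snps)
  expect_equal(sum(sp$count), 3)
  expect_equal(sp$fraction[sp$from == "A" & sp$to == "G"], 2 / 3)
  expect_equal(sp$fraction[sp$from == "C" & sp$to == "T"], 1 / 3)
  expect_equal(sum(sp$fraction), 1)
  empty <- snp_spectrum(tibble::tibble(ref_base = character(0),
                                       qry_base = character(0)))
  expect_true(attr(empty, "zero_total"))
  expect_true(all(is.na(empty$fraction)))
})

test_that("variant density reproduces the printed per-kb values", {
  expect_equal(variant_density(4561825, 270.3e6), 16.9)
  expect_equal(variant_density(846301, 270.3e6), 3.1)
  expect_equal(variant_density(0, 1e6), 0)
  expect_error(variant_density(10, 0), "positive")
})

test_that("promoter comparison reports only events at min_event scale", {
  set.seed(23)
  a <- rnd_dna(2000)
  expect_equal(nrow(promoter_diff(a, a)), 0)
  # 10-base deletion at position 500
  b <- paste0(substr(a, 1, 500), substr(a, 511, 2000))
  ev <- promoter_diff(a, b)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "deletion")
  expect_equal(ev$length, 10)
  expect_lte(abs(ev$start_a - 500), 10) # left-shift ambiguity only
  # a single substitution stays below the default threshold
  c2 <- a
  substr(c2, 1000, 1000) <- setdiff(c("A", "C", "G", "T"),
                                    substr(a, 1000, 1000))[1]
  expect_equal(nrow(promoter_diff(a, c2)), 0)
  expect_error(promoter_diff("", a), "non-empty")
})
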