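test_that("identity and strand cases produce single full-length anchors", {
  set.seed(2)
  s <- rnd_dna(2000)
  g <- Biostrings::DNAStringSet(c(c1 = s))
  a <- find_anchors(g, g, 20)
  expect_equal(nrow(a), 1)
  expect_equal(a$length, 2000)
  expect_equal(a$strand, "+")
  grc <- Biostrings::DNAStringSet(c(c1 = revcomp_str(s)))
  arc <- find_anchors(g, grc, 20)
  expect_equal(nrow(arc), 1)
  expect_equal(arc$strand, "-")
  expect_equal(arc$qry_start, 0)
})

test_that("repeated sequence breaks uniqueness, matching brute force", {
  set.seed(3)
  core <- rnd_dna(15)
  ref <- paste0(rnd_dna(40), core, rnd_dna(40), core, rnd_dna(40))
  qry <- paste0(rnd_dna(30), core, rnd_dna(60))
  mums <- find_anchors(Biostrings::DNAStringSet(c(c1 = ref)),
                       Biostrings::DNAStringSet(c(c1 = qry)), 10)
  bf <- brute_force_mums(ref, qry, 10)
  expect_equal(nrow(mums), nrow(bf))
  if (nrow(bf) > 0) {
    expect_equal(mums$ref_start, bf$ref_start)
    expect_equal(mums$qry_start, bf$qry_start)
    expect_equal(mums$length, bf$length)
  }
  # no reported anchor sits inside the repeated 15-mer on the query
  rep_q <- regexpr(core, qry, fixed = TRUE)[1] - 1
  inside <- mums$qry_start >= rep_q & mums$qry_start + mums$length <=
    rep_q + 15
  expect_false(any(inside))
})

test_that("anchor discovery equals the brute-force scan on fuzz cases", {
  for (seed in 1:10) {
    set.seed(seed)
    ref <- rnd_dna(180)
    # query: mutated copy with an occasional reverse-complemented piece
    qry <- ref
    pos <- sample(30:150, 4)
    for (p in pos) substr(qry, p, p) <- sample(c("A", "C", "G", "T"), 1)
    if (seed %% 2 == 0) {
      qry <- paste0(substr(qry, 1, 59), revcomp_str(substr(qry, 60, 119)),
                    substr(qry, 120, 180))
    }
    mums <- find_anchors(Biostrings::DNAStringSet(c(c1 = ref)),
                         Biostrings::DNAStringSet(c(c1 = qry)), 8)
    bf <- brute_force_mums(ref, qry, 8)
    expect_equal(nrow(mums), nrow(bf), info = paste("seed", seed))
    expect_equal(mums$ref_start, bf$ref_start, info = paste("seed", seed))
    expect_equal(mums$qry_start, bf$qry_start, info = paste("seed", seed))
    expect_equal(mums$length, bf$length, info = paste("seed", seed))
    expect_equal(mums$strand, bf$strand, info = paste("seed", seed))
  }
})

test_that("anchors are symmetric under swapping the genomes", {
  set.seed(6)
  ref <- rnd_dna(500)
  qry <- ref
  for (p in sample(50:450, 6)) {
    substr(qry, p, p) <- sample(c("A", "C", "G", "T"), 1)
  }
  g1 <- Biostrings::DNAStringSet(c(c1 = ref))
  g2 <- Biostrings::DNAStringSet(c(c1 = qry))
  a12 <- find_anchors(g1, g2, 12)
  a21 <- find_anchors(g2, g1, 12)
  swapped <- a21[order(a21$qry_start), ]
  orig <- a12[order(a12$ref_start), ]
  expect_equal(orig$ref_start, swapped$qry_start)
  expect_equal(orig$qry_start, swapped$ref_start)
  expect_equal(orig$length, swapped$length)
})

test_that("collinear chaining picks the documented example chain", {
  # anchors (ref,qry,len): (0,0,5), (10,10,5), (6,20,5); best chain keeps
  # the two on-diagonal anchors
  res <- wgacompare:::chain_best_cpp(c(0L, 10L, 6L), c(5L, 15L, 11L),
                                     c(0L, 10L, 20L), c(5L, 15L, 25L),
                                     c(5, 5, 5))
  expect_equal(res$weight, 10)
  expect_equal(sort(res$idx), c(1, 2))
})

test_that("chaining matches exhaustive search on fuzz instances", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:10, 1)
    rs <- sort(sample(0:200, n))
    len <- sample(5:20, n, replace = TRUE)
    qs <- sample(0:200, n)
    res <- wgacompare:::chain_best_cpp(rs, rs + len, qs, qs + len,
                                       as.numeric(len))
    oracle <- exhaustive_chain(rs, rs + len, qs, qs + len, as.numeric(len))
    expect_equal(res$weight, oracle$weight, info = paste("seed", seed))
  }
})

test_that("identical genomes chain into one perfect block", {
  set.seed(10)
  g <- Biostrings::DNAStringSet(c(c1 = rnd_dna(10000)))
  b <- chain_and_extend(find_anchors(g, g, 20), g, g)
  expect_equal(nrow(b), 1)
  expect_equal(b$identity, 100)
  expect_equal(b$edit_path, "10000=")
  expect_equal(b$aligned_columns, 10000)
})

test_that("a single SNP yields one mismatch column", {
  set.seed(11)
  s <- rnd_dna(5000)
  g <- Biostrings::DNAStringSet(c(c1 = s))
  q <- s
  old <- substr(q, 2500, 2500)
  substr(q, 2500, 2500) <- setdiff(c("A", "C", "G", "T"), old)[1]
  gq <- Biostrings::DNAStringSet(c(c1 = q))
  b <- chain_and_extend(find_anchors(g, gq, 20), g, gq)
  expect_equal(nrow(b), 1)
  expect_equal(b$identity, (5000 - 1) / 5000 * 100, tolerance = 1e-9)
  ops <- wgacompare:::parse_edit_path(b$edit_path)
  expect_equal(sum(ops$len[ops$op == "X"]), 1)
})

test_that("block filtering applies strict thresholds and preserves order", {
  blocks <- dplyr::bind_rows(
    make_block("b1", "c1", 0, 30000, "c1", 0, 30000, identity = 79.9),
    make_block("b2", "c1", 40000, 70000, "c1", 40000, 70000,
               identity = 95),
    make_block("b3", "c1", 80000, 90000, "c1", 80000, 90000,
               identity = 99)
  )
  f <- filter_blocks(blocks, 80, 20000)
  expect_equal(f$block_id, "b2") # b1 fails identity, b3 fails length
  expect_equal(filter_blocks(blocks, 0, 0)$block_id, blocks$block_id)
  # predicate oracle on a random mixed set
  set.seed(12)
  mixed <- dplyr::bind_rows(lapply(1:20, function(i) {
    s <- sample(0:1e6, 1)
    make_block(paste0("m", i), "c1", s, s + sample(1000:40000, 1), "c1",
               s, s + 1000, identity = runif(1, 60, 100))
  }))
  kept <- filter_blocks(mixed, 85, 15000)
  expect_equal(nrow(kept), sum(mixed$identity >= 85 &
                                 (mixed$ref_end - mixed$ref_start) >=
                                 15000))
})

test_that("one-to-one selection keeps the dominant block", {
  blocks <- dplyr::bind_rows(
    make_block("b1", "c1", 0, 100000, "c1", 0, 100000, identity = 99),
    make_block("b2", "c1", 0, 50000, "c2", 0, 50000, identity = 80)
  )
  sel <- one_to_one(blocks, tol = 0)
  expect_equal(sel$block_id, "b1")
  # non-overlapping input returned unchanged
  clean <- dplyr::bind_rows(
    make_block("b1", "c1", 0, 1000, "c1", 0, 1000),
    make_block("b2", "c1", 2000, 3000, "c1", 2000, 3000)
  )
  expect_equal(one_to_one(clean)$block_id, c("b1", "b2"))
})

test_that("one-to-one matches exhaustive two-pass search on fuzz sets", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:8, 1)
    blocks <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      rs <- sample(0:500, 1) * 100
      qs <- sample(0:500, 1) * 100
      len <- sample(2:40, 1) * 100
      make_block(paste0("f", i), "c1", rs, rs + len, "c1", qs, qs + len,
                 identity = runif(1, 70, 100))
    }))
    sel <- one_to_one(blocks, tol = 0)
    w_sel <- sum((sel$ref_end - sel$ref_start) * sel$identity)
    w_opt <- exhaustive_one_to_one_weight(
      blocks, (blocks$ref_end - blocks$ref_start) * blocks$identity)
    expect_equal(w_sel, w_opt, tolerance = 1e-9,
                 info = paste("seed", seed))
    expect_silent(assert_one_to_one(sel))
  }
})

test_that("stored identity is recomputable from the edit path", {
  pair <- fixture_small_pair()
  expect_lt(max(abs(recompute_identity(pair$blocks) -
                      pair$blocks$identity)), 0.011)
})

test_that("self-alignment covers nearly everything at identity 100", {
  anc <- generate_ancestor(1, 150000, 5, seed = 55)
  b <- align_genomes(anc$genome, anc$genome)
  expect_gte(sum(b$ref_end - b$ref_start) / 150000, 0.999)
  expect_true(all(b$identity == 100))
})
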