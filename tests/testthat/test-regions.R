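chrom_lens <- c(c1 = 100000L)

test_that("promoter and downstream regions follow the strand", {
  gplus <- make_gene("g1", "c1", "+",
                     exons = rbind(c(10000, 10500), c(11000, 12000)),
                     cds = rbind(c(10200, 10500), c(11000, 11800)),
                     utr5 = rbind(c(10000, 10200)),
                     utr3 = rbind(c(11800, 12000)))
  ix <- build_feature_index(gplus, chrom_lens)
  prom <- ix[ix$category == "promoter", ]
  expect_equal(prom$start, 8000)
  expect_equal(prom$end, 10000)
  down <- ix[ix$category == "downstream", ]
  expect_equal(down$start, 12000)
  expect_equal(down$end, 13000)
  intr <- ix[ix$category == "intron", ]
  expect_equal(intr$start, 10500)
  expect_equal(intr$end, 11000)

  gminus <- make_gene("g2", "c1", "-",
                      exons = rbind(c(3000, 3200), c(3600, 5000)),
                      cds = rbind(c(3200 - 60, 3200), c(3600, 4800)),
                      utr5 = rbind(c(4800, 5000)),
                      utr3 = rbind(c(3000, 3140)))
  ixm <- build_feature_index(gminus, chrom_lens)
  promm <- ixm[ixm$category == "promoter", ]
  expect_equal(promm$start, 5000) # upstream of the 5' UTR end on '-'
  expect_equal(promm$end, 7000)
  downm <- ixm[ixm$category == "downstream", ]
  expect_equal(downm$start, 2000) # 1 kb past the 3' UTR start on '-'
  expect_equal(downm$end, 3000)
})

test_that("regions truncate at chromosome boundaries", {
  g <- make_gene("g1", "c1", "+",
                 exons = rbind(c(500, 1500)),
                 cds = rbind(c(700, 1300)),
                 utr5 = rbind(c(500, 700)), utr3 = rbind(c(1300, 1500)))
  ix <- build_feature_index(g, chrom_lens)
  prom <- ix[ix$category == "promoter", ]
  expect_equal(prom$start, 0)
  expect_equal(prom$end, 500)
})

test_that("precedence assigns one category per element", {
  g <- make_gene("g1", "c1", "+",
                 exons = rbind(c(10000, 11000)),
                 cds = rbind(c(10200, 10800)),
                 utr5 = rbind(c(10000, 10200)),
                 utr3 = rbind(c(10800, 11000)))
  ix <- build_feature_index(g, chrom_lens)
  elements <- tibble::tibble(
    chrom = "c1",
    start = c(9900, 50000, 8100),   # exon+promoter, intergenic, promoter
    end = c(10100, 50100, 8200))
  rc <- classify_elements(elements, ix, mode = "precedence")
  expect_equal(unname(rc$totals["exon"]), 1)
  expect_equal(unname(rc$totals["promoter"]), 1)
  expect_equal(unname(rc$totals["intergenic"]), 1)
  expect_equal(sum(rc$totals), nrow(elements)) # conservation
  multi <- classify_elements(elements, ix, mode = "multi")
  expect_equal(unname(multi$totals["exon"]), 1)
  expect_equal(unname(multi$totals["promoter"]), 2) # spanning counts twice
})

test_that("classification agrees with the brute-force scan on fuzz sets", {
  for (seed in 1:10) {
    set.seed(seed)
    genes <- dplyr::bind_rows(lapply(1:4, function(i) {
      s <- 5000 + (i - 1) * 20000 + sample(0:2000, 1)
      make_gene(paste0("g", i), "c1", sample(c("+", "-"), 1),
                exons = rbind(c(s, s + 800), c(s + 1400, s + 3000)),
                cds = rbind(c(s + 200, s + 800), c(s + 1400, s + 2600)),
                utr5 = rbind(c(s, s + 200)),
                utr3 = rbind(c(s + 2600, s + 3000)))
    }))
    ix <- build_feature_index(genes, chrom_lens)
    n <- 150
    start <- sample(0:99000, n)
    elements <- tibble::tibble(chrom = "c1", start = start,
                               end = start + sample(10:800, n, TRUE))
    rc <- classify_elements(elements, ix, mode = "precedence")
    bf <- brute_force_classify(elements, ix)
    got <- c(rc$totals[c("exon", "intron", "promoter", "downstream")],
             intergenic = unname(rc$totals["intergenic"]))
    expect_equal(unname(got), as.numeric(bf), info = paste("seed", seed))
  }
})

test_that("classification is invariant under reverse-complementation", {
  L <- chrom_lens[["c1"]]
  flip_iv <- function(tbl) {
    out <- tibble::tibble(start = L - tbl$end, end = L - tbl$start)
    out[order(out$start), ]
  }
  set.seed(5)
  s <- 20000
  gene <- make_gene("g1", "c1", "+",
                    exons = rbind(c(s, s + 1000), c(s + 1500, s + 4000)),
                    cds = rbind(c(s + 300, s + 1000), c(s + 1500, s + 3500)),
                    utr5 = rbind(c(s, s + 300)),
                    utr3 = rbind(c(s + 3500, s + 4000)))
  gene_rc <- gene
  gene_rc$strand <- "-"
  for (col in c("exons", "cds", "utr5", "utr3")) {
    gene_rc[[col]] <- list(flip_iv(gene[[col]][[1]]))
  }
  n <- 100
  start <- sample(0:(L - 1000), n)
  el <- tibble::tibble(chrom = "c1", start = start,
                       end = start + sample(20:600, n, TRUE))
  el_rc <- tibble::tibble(chrom = "c1", start = L - el$end,
                          end = L - el$start)
  rc1 <- classify_elements(el, build_feature_index(gene, chrom_lens))
  rc2 <- classify_elements(el_rc, build_feature_index(gene_rc, chrom_lens))
  expect_equal(rc1$totals, rc2$totals)
})

test_that("paired sign test behaves at the null and extremes", {
  per_gene <- function(ids, exon) tibble::tibble(
    gene_id = ids, exon = exon, intron = 0L, promoter = 0L,
    downstream = 0L)
  mk <- function(pg) structure(list(per_gene = pg,
                                    totals = c(exon = sum(pg$exon),
                                               intron = 0, promoter = 0,
                                               downstream = 0,
                                               intergenic = 0),
                                    n_elements = sum(pg$exon),
                                    mode = "precedence"),
                               class = "wga_region_counts")
  ids <- paste0("g", 1:10)
  pairs <- tibble::tibble(gene_a = ids, gene_b = ids)
  same <- compare_paired_counts(mk(per_gene(ids, rep(2L, 10))),
                                mk(per_gene(ids, rep(2L, 10))), pairs)
  expect_equal(same$p_value[same$category == "exon"], 1)
  expect_equal(same$n_tie[same$category == "exon"], 10)
  skew <- compare_paired_counts(mk(per_gene(ids, rep(3L, 10))),
                                mk(per_gene(ids, rep(2L, 10))), pairs)
  expect_equal(skew$p_value[skew$category == "exon"], 2 * 0.5^10,
               tolerance = 1e-12)
  expect_error(compare_paired_counts(mk(per_gene(ids, rep(1L, 10))),
                                     mk(per_gene(ids, rep(1L, 10))),
                                     pairs[0, ]), "empty")
})

test_that("TE insertions skewed into one genome flag significance", {
  # genome A carries TEs in introns of 12 genes, genome B none
  genes <- dplyr::bind_rows(lapply(1:12, function(i) {
    s <- 2000 + (i - 1) * 8000
    make_gene(paste0("g", i), "c1", "+",
              exons = rbind(c(s, s + 500), c(s + 2000, s + 3000)),
              cds = rbind(c(s + 100, s + 500), c(s + 2000, s + 2800)),
              utr5 = rbind(c(s, s + 100)), utr3 = rbind(c(s + 2800, s + 3000)))
  }))
  ix <- build_feature_index(genes, chrom_lens)
  te_a <- tibble::tibble(chrom = "c1",
                         start = 2000 + (0:11) * 8000 + 700,
                         end = 2000 + (0:11) * 8000 + 900)
  rc_a <- classify_elements(te_a, ix)
  rc_b <- classify_elements(te_a[0, ], ix)
  pairs <- tibble::tibble(gene_a = genes$gene_id, gene_b = genes$gene_id)
  cmp <- compare_paired_counts(rc_a, rc_b, pairs)
  expect_lt(cmp$p_value[cmp$category == "intron"], 0.05)
  expect_equal(cmp$sum_a[cmp$category == "intron"], 12)
})
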