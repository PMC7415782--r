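# Shared fixtures, built once per test session.

.fixture_env <- new.env(parent = emptyenv())

fixture_memo <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# small single-sided pair with SNPs and indels, aligned end to end
fixture_small_pair <- function() {
  fixture_memo("small_pair", function() {
    anc <- generate_ancestor(n_chroms = 1, chrom_length = 200000,
                             gene_count = 0, seed = 101)
    pair <- evolve_pair(anc, mutation_config(seed = 1),
                        mutation_config(snp_rate = 0.004,
                                        indel_rate = 3e-4, seed = 101))
    pair$blocks <- align_genomes(pair$genome_a, pair$genome_b)
    pair
  })
}

# gene-bearing pair for ortholog/region tests
fixture_gene_pair <- function() {
  fixture_memo("gene_pair", function() {
    anc <- generate_ancestor(n_chroms = 1, chrom_length = 300000,
                             gene_count = 25, seed = 202)
    pair <- evolve_pair(anc, mutation_config(seed = 1),
                        mutation_config(snp_rate = 0.003,
                                        te_insertions = 8,
                                        ltr_divergence = 0.01, seed = 202))
    pair$ancestor <- anc
    pair$blocks <- align_genomes(pair$genome_a, pair$genome_b)
    pair
  })
}

# a codon alignment object from two gapless in-frame strings
codon_aln <- function(a, b) {
  structure(list(aln_a = a, aln_b = b, n_codon_pairs = nchar(a) / 3),
            class = "wga_codon_alignment")
}

# hand-built gene model row in internal coordinates
make_gene <- function(gene_id, chrom, strand, exons, cds,
                      utr5 = NULL, utr3 = NULL) {
  iv <- function(x) {
    if (is.null(x)) {
      tibble::tibble(start = integer(0), end = integer(0))
    } else {
      tibble::tibble(start = as.integer(x[, 1]), end = as.integer(x[, 2]))
    }
  }
  tibble::tibble(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = list(iv(exons)), cds = list(iv(cds)),
                 utr5 = list(iv(utr5)), utr3 = list(iv(utr3)))
}

# hand-built alignment block row (edit path of pure matches by default)
make_block <- function(id, ref_chrom, ref_start, ref_end, qry_chrom,
                       qry_start, qry_end, strand = "+", identity = 100,
                       path = NULL) {
  n <- ref_end - ref_start
  tibble::tibble(
    block_id = id, ref_chrom = ref_chrom, ref_start = ref_start,
    ref_end = ref_end, qry_chrom = qry_chrom, qry_start = qry_start,
    qry_end = qry_end, strand = strand, identity = identity,
    aligned_columns = n, n_match = round(n * identity / 100),
    edit_path = if (is.null(path)) paste0(n, "=") else path
  )
}
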