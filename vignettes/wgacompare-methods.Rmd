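---
title: "Methods: pairwise whole-genome comparison with synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pairwise whole-genome comparison with synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its methods: the models each
stage implements, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical decisions taken
where the underlying procedures are conventionally left vague.

## Coordinate conventions

Every internal coordinate is 0-based half-open. GFF3 and VCF are 1-based
at the file boundary; BED is 0-based half-open and passes through
unchanged. The conversions live only in the readers and writers
(`read_gene_models()`, `write_variants()`, …), so no analysis code ever
shifts a coordinate. All stochastic operations take an explicit integer
seed and restore the caller's RNG state; there is no hidden global state.

## The synthetic genome pair

`generate_ancestor()` draws i.i.d. bases at a configurable GC fraction
(default 0.39, a typical rosaceous value) and places non-overlapping genes
uniformly: 2–5 exons, 5′/3′ UTRs of 50–200 and 100–300 bases, CDS of
300–1500 nt beginning with ATG, free of internal stops and ending in a
stop codon, on either strand. `evolve_pair()` applies two
`mutation_config()`s to independent copies of the ancestor:

* SNPs at `snp_rate` per base, with a transition:transversion weighting
  (default 2:1 in expected counts, so the expected transition fraction is
  2/3 — recoverable by the spectrum module).
* Indels at `indel_rate` per base; sizes `1 + Geometric(p = 0.5)` capped
  at 50 bases. No published size distribution exists for the target
  system, so the geometric family was chosen for its monotone decay and a
  single interpretable parameter.
* Inversions (in-place reverse complement), translocations (segment
  excised and reinserted on another chromosome) and relocations (excised
  and reinserted at least 10 kb away on the same chromosome). The
  inter- versus intra-chromosomal split is this package's operational
  disambiguation of "a fragment occurring in different locations"; every
  record carries the raw evidence so users can re-bin.
* TE insertions; a configurable fraction are LTR elements built as
  5′LTR–internal–3′LTR with the two terminal repeats identical at
  insertion and then mutated independently at `ltr_divergence` per site,
  which is exactly the signal the insertion-age estimator inverts.

Event footprints are sampled disjointly across both descendants (bounded
rejection sampling; a capacity error is raised rather than degrading into
overlapping events, since the treatment of nested rearrangements in real
comparisons is unknowable). SNPs and indels are also sampled clear of SV
footprints: a variant inside a relocated or inverted segment would be
recoverable in principle, but its truth description would depend on the
orientation convention of the carrying segment, and keeping truth
unambiguous was judged more valuable than the marginal realism. The truth
set records each event's coordinates in both descendants; indel truth is
left-normalized with the same rotate-left rule VCF uses, so caller and
truth agree on representation up to the one-base tolerance used in
matching.

What the simulator does not emulate: recombination, gene duplication and
loss, diploid heterozygosity, read base-quality error models, and nested
or overlapping SVs. Passing recovery tests therefore demonstrates
correctness of the algorithms under clean, independently placed events —
not robustness to the full messiness of real assemblies (collapsed
repeats, assembly gaps, segmental duplications).

## k-mer genome profiling

`kmer_histogram()` counts canonical k-mers (lexicographic minimum of the
k-mer and its reverse complement) exactly in memory; windows containing N
are skipped. The profile estimates are deliberately the simple desk
formulas rather than a mixture-model fit:

* genome size `GS = total instances / peak depth`, rounded to the nearest
  base;
* repeat threshold `2 * peak + 1` (reproducing the published 115 at peak
  57), with the repetitive fraction the instance mass above it;
* heterozygosity `d / (2k)`, where `d` is the instance fraction in the
  half-depth window `[0.4, 0.6] * peak` — the heterozygous peak of a
  diploid sits at half the homozygous depth, and each heterozygous site
  touches 2k k-mers across the two haplotypes.

"Average k-mer depth" in the genome-size formula is read as the main peak
depth: that is the only reading computable from the published inputs
(peak 57, 17,016,192,556 k-mer instances), and it reproduces the printed
298.5 Mb estimate exactly. `find_main_peak()` takes the argmax over
depths at or above `min_depth` (default 4, excluding the sequencing-error
spike), ties broken to the larger depth. Note that read depths are
correlated along a read length, so histogram-argmax stability requires
many independent read placements; validation uses a 1 Mb genome, where
the estimate is stable to about 1–2 %, dominated by peak-depth
quantization.

## Whole-genome alignment

Anchors are MUMs: maximal exact matches of at least 40 bases (the
published seed length) occurring exactly once in the reference and once
in the query, counting both query strands. They are found on a
generalized suffix array over reference + query + reverse-complemented
query, built by prefix doubling with counting sort — chosen over
comparison sorting because near-identical genome pairs have pathological
shared-prefix lengths. Uniqueness is the adjacent-suffix LCP criterion; a
consequence of including the reverse-complement copy is that a perfect
palindromic region matches both strands and is excluded as non-unique,
which is the conservative behaviour for SV evidence.

Chains maximize total anchor length per (reference chromosome, query
chromosome, strand), with anchors allowed to advance strictly in all four
coordinates; ties in weight break to the chain with the smaller total
off-diagonal drift, then to the earlier anchor, making the output
deterministic. Chains are extracted repeatedly until none reaches 90
anchor bases (the published cluster size); anchors mostly (> 50 %)
covered by an extracted chain are retired, so small boundary overlaps
cannot spawn duplicate blocks but displaced segments — the raw material
of SV calling — survive to form their own chains.

Gap closing uses exact affine-gap DP (match +1, mismatch −1, gap open −4,
extend −1; no published scores exist, these are conventional
MUMmer-style values). A chain is split rather than force-aligned when an
inter-anchor gap exceeds `max_gap` (1000) on either genome or when the
two gap lengths disagree by more than `band` (200): at these gap sizes
the full DP is exact, and the band acts purely as the split rule,
mirroring how alignment around an SV is emitted as separate blocks.

`one_to_one()` selects blocks by weighted interval scheduling (weight =
reference span × identity) on the reference, then on the query.
Boundary overlaps up to `tol` (100 bases; arising where two chains share
an ambiguous breakpoint base) are tolerated during selection and then
removed by trimming the lower-weight block's edit path, so the final set
covers every base of either genome at most once — the property the
variant caller asserts before running.

## Variant extraction

Edit paths are run-length strings over `=`, `X`, `I` (insertion in
query), `D` (deletion from query). Each mismatch column is one SNP; for
reverse-strand blocks the reported query base is the complement of the
genome base at the mapped position, i.e. the base actually aligned
against the reference. Maximal gap runs become single indel records,
left-aligned by the VCF rotate-left rule within the block. SNPs adjacent
to gap columns are kept, matching show-snp-style extraction. Densities
are reported per kilobase at one decimal, rounded half away from zero —
the rounding that reproduces the published 16.9 and 3.1.

## Structural variants

Inversion candidates are maximal runs of reverse-strand blocks whose
nearest forward neighbours on both sides reach the flank identity
threshold (default 90 %; the published procedure filters "low similarity
in the two flanks" without a number). Retained reverse blocks within 50
bases on the reference merge into one record. The published "manual
check" is replaced by a deterministic rule: merged spans whose reference
and query lengths disagree by more than 20 % are dropped with a message.
Translocation/relocation calling builds a backbone — the maximum-weight
forward collinear chain per reference chromosome, reusing the chaining
kernel so one oracle covers both — and reports every off-backbone block
longer than 100 bases with identity above 90 % (both strict, as
published): a translocation when its query chromosome differs from the
backbone partner, a relocation otherwise. `call_svs()` runs inversions
first and excludes their support blocks (and all reverse-strand blocks)
from the translocation pass, so no event is double-reported.

## Gene-anatomy regions

Promoter = 2000 bases upstream of the 5′ UTR start; downstream = 1000
bases past the 3′ UTR end; both strand-aware, truncated at chromosome
ends, with the CDS boundary as a logged fallback for UTR-less genes.
Membership is any-overlap (≥ 1 base) — matching the phrase "distributed
in promoters" better than midpoint assignment — with precedence
exon > intron > promoter > downstream > intergenic so gene-body evidence
wins and every element is counted exactly once; a multi-count mode is
available. Ortholog pairs are compared per category with a two-sided
exact sign test on non-tied pairs: the published comparison says only
"significantly larger", so the test choice is this package's and is
recorded in the output rather than asserted against any published
p-value.

## Molecular evolution

Orthologs are paired by pushing reference gene midpoints through the
covering one-to-one block (linear interpolation, strand-aware) and
keeping reciprocal-best partners within 10 kb. Codon alignments come from
global protein alignment (BLOSUM62, Biostrings) back-threaded to
nucleotides, so gaps are whole codons.

Ks uses Nei–Gojobori (1986) counting — per-position synonymous-site
fractions averaged over the two sequences, pathway-averaged synonymous
differences over all substitution orders with steps through stop codons
counted as nonsynonymous — followed by the Jukes–Cantor correction
`ks = -3/4 log(1 - 4/3 ps)`. NG86 was fixed over ML estimators because it
is deterministic and checkable against an independent pathway-enumeration
oracle; the published report never names its estimator. `ps >= 3/4` is
reported as saturated (infinite), zero fourfold sites as undefined rather
than zero, and fewer than 30 codon pairs as low-confidence.

4DTv counts only codon pairs with identical, fourfold-degenerate first
two bases (prefixes TC, CT, CC, CG, AC, GT, GC, GG) and reports the
transversion fraction at the third position; the optional multiple-hit
correction is the Kimura transversion-distance form `-log(1 - 2Q)/2`,
undefined at `Q >= 1/2`.

LTR insertion age is `K / (2 mu)` with K the Jukes–Cantor distance over
aligned non-gap columns of the element's two terminal repeats. No
defensible published substitution rate exists for the target genus, so
`mu` defaults to 1.3e-8 per site per year (a widely used plant value) and
is echoed in every result row. Pairs under 100 bases or below 60 %
alignment identity are rejected as unreliable.

Ks-distribution modes use a Gaussian KDE with Silverman's bandwidth on
values in [0, 3]; a mode must have prominence at least 5 % of the global
maximum, and fewer than 50 usable values returns "insufficient" instead
of a location.

## Printed-arithmetic checks

`paper_check()` recomputes 18 derived quantities (percentages, densities,
the genome-size estimate, the repeat threshold, the size-difference
attribution) purely from a bundled, checksummed table of printed inputs,
at the printed precisions (two decimals for percentages, one for per-kb
densities, half-away-from-zero). The published total-TE rate is the one
derived figure excluded: the printed numerator and denominator round to a
value one hundredth off the printed percentage, consistent with the
published table's internal row-sum discrepancy, and the check suite only
asserts what the printed inputs actually reproduce.

## Validation scale

The recovery analyses run at sizes where exhaustive ground truth is
practical while alignment behaviour is genuinely genomic: 5 Mb pairs for
variant and SV recovery (about 25,000 SNPs and 2,500 indels at the
simulated rates; 10 inversions of 2–20 kb plus 5 translocations and 5
relocations), 1 Mb at 50-fold coverage for genome-size recovery, and
10,000 codons for Ks parameter recovery. Combinatorial kernels (chaining,
one-to-one selection, region classification, NG86 counting) are checked
against exhaustive or brute-force oracles at small n over many seeds.

## Known limitations

* Exact in-memory k-mer counting and suffix arrays target desk-scale
  genomes (tens of Mb), not 100 Mb+ chromosomes.
* One transcript per gene (the longest CDS when a GFF3 offers several);
  regions are not multi-transcript-aware.
* The simulator's independence assumptions (no nested SVs, variants clear
  of SV footprints) mean recovery rates here are upper bounds for real
  data.
* Ks saturates near 0.75 synonymous difference; deep divergences need ML
  methods outside this package's scope.
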