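---
title: "Methods: pooled enrichment resequencing population genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled enrichment resequencing population genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolrens)
```

## Scope and data model

`poolrens` analyses pooled target-enrichment resequencing of a gene family
within one population. The pipeline consumes per-site nucleotide counts
(a plain TSV dialect `contig pos ref A C G T indel_count`, or a
PoPoolation2-style sync table), CDS annotations (GFF3) over a reference
(FASTA), and — for the consensus layer — externally produced call sets
(VCF subset with `MC`/`DP`/`AF` INFO keys). Individual genotypes are never
available: every statistic is built from pooled allele frequencies
`p̂ = minor count / depth` over a pool of `n` chromosomes (default 20 —
ten diploid plants contributing equal amounts of DNA).

One convention applies everywhere: all on-disk coordinates are 1-based
inclusive (pileup, GFF3, VCF). Ambiguous bases (`N`) contribute to depth but
are never candidate alleles; in the native 8-column dialect they simply do
not occur, while the sync importer routes them to a depth-only `other`
column.

## Pooled SNP detection

A site is called polymorphic when

1. depth ≥ `min_cov` (default 30),
2. the **second-most-frequent** base is seen at least `min_count` times
   (default 6), and
3. the site is not masked.

The count threshold applies to the single second-ranked base, not the sum of
non-reference bases: this matches pooled-caller practice and makes the
worked example exact — at depth 30 a minor allele at frequency 4/20 has
expected count 6 and is still detectable, while singletons (1/20) need depth
near 120 (`detectability_threshold()` returns
`ceil(min_count · n / depth)`). A third base reaching `min_count` marks the
site `multiallelic`; such sites are not called (one-alternate-allele
biology is overwhelmingly the norm at these depths) but are preserved in the
reason log for inspection. When the top two counts tie, the reference base
is kept as the major allele so the minor allele is the non-reference one.

Two masks are computed per contig before thresholding:

- **indel proximity**: ± `indel_window` bp (default 5) around any site with
  indel evidence. No radius is canonical; 5 bp is a deliberately tight
  default that still removes the alignment-slippage shoulder around indels.
- **excess coverage**: depth above the per-contig empirical quantile
  `max_cov_quantile` (default 0.98). Enrichment capture plus PCR gives a
  long right tail of pile-up artifacts; an empirical quantile adapts to each
  contig's coverage level where a fixed cutoff would not.

Copy classes are estimated as `k = clamp(round(p̂·n), 1, n−1)` with half-up
rounding (base R's round-half-even would make class boundaries asymmetric
between odd and even classes). The clamp to ≥ 1 encodes that a called SNP is
segregating by definition.

`filter_fixed_differences()` handles a caller-vs-reference artifact: a
variant reported only because the pool differs fixedly from the reference
(second allele count < `min_count`) is not a within-population SNP and is
dropped. `intersect_callsets()` implements the multi-caller consensus,
keyed on (contig, position, minor allele) by default — position-only
matching is available — with the first argument's frequency estimates kept
in the shared set (one canonical frequency is needed downstream; the choice
is configurable by swapping arguments). `validate_against_truth()` reports
`fp_rate = fp/(tp+fp)` and `fn_rate = fn/(tp+fn)`; these denominators are a
documented convention, flagged undefined when zero.

## Diversity statistics

Per-site pooled diversity is `π = 2 p̂ (1−p̂) · n/(n−1)`; the `n/(n−1)`
factor corrects the finite-pool sampling bias and can be disabled. Per-gene
π divides the summed site diversities by the full CDS length (all sites,
not just polymorphic ones — the per-site convention of diversity
estimators).

π~N~/π~S~ uses Nei–Gojobori fractional site counting: each codon position
contributes `(number of synonymous single-base changes)/3` synonymous sites,
so every codon contributes exactly 3 sites in total. Mutations creating stop
codons are nonsynonymous; reference stop codons are excluded from the gene
totals. `π_N = Σ site π (nonsynonymous) / N_sites` and likewise for π~S~;
the ratio is reported as 0 when π~N~ = 0 with π~S~ > 0 and as undefined
(`NA`) when π~S~ = 0 — a gene with only nonsynonymous polymorphism has no
finite ratio, which is itself informative.

Effect classification evaluates the single substituted base against the
reference codon (minus-strand genes on the reverse complement). If two SNPs
fall in one codon, each is classified against the reference codon background
with a warning — pooled data cannot phase them, and at the SNP densities
this pipeline targets (tens of SNPs over kb-scale genes) codon co-occupancy
is rare.

## Folded site-frequency spectrum

Pooled frequencies are discretized to `k₀ = clamp(round(p̂·n), 1, n−1)` and
folded onto the minor side `k = min(k₀, n−k₀)`, giving classes `1..n/2`
(class `n/2` = frequency 0.5). The folding is idempotent and conserves the
SNP count. Spectra are compared as **relative** spectra (classes normalized
to sum 1) by Pearson correlation — absolute counts differ between estimation
routes for uninteresting reasons (filtering stringency), while the shape is
the comparable object.

## The heterozygosity-decay model

A germplasm accession founded from a partially selfing population and
regenerated serially as a small population loses heterozygosity (here
operationalized as the expected proportion of polymorphic loci) in two ways:

- **founding**: a single founder plant propagated by selfing halves
  heterozygosity (`f = 0.5`); two or more crossed founders lose the fraction
  `0.5·s` through the selfing rate `s` (`f = 1 − 0.5·s`).
- **regeneration**: each of the subsequent rounds of random mating among
  `2N` chromosomes retains `1 − 1/2N`.

With `t_total` total rounds (the founding step being the first), the
forward model is `H_sample = H₀ · f · (1 − 1/2N)^(t_total−1)` and
`invert_H0()` solves it for `H₀`. The exponent convention matters: with the
observed `H_sample = 13/220` and ten rounds, founder + 9 matings gives the
2-dp estimates 0.17/0.21 (s = 1, 2N = 24/16) and 0.12/0.14 (s = 0.5);
a literal exponent of 10 would give 0.18/0.23 and 0.12/0.15 instead. The
founder-plus-`t−1` reading is the one consistent with those reference
values, and is what the package implements. Estimates are kept at full
precision internally and rounded to two decimals only for reporting; an
inverted `H₀ > 1` flags the scenario infeasible.

`simulate_propagation()` validates the recursion stochastically. Each locus
is founded polymorphic at frequency `p = 0.5` (a heterozygous founder) with
probability `2·H₀` — chosen so that the founding expectation of the
pairwise-difference heterozygosity `2p(1−p)` equals `H₀` exactly, which
requires `H₀ ≤ 0.5`. The founder factor is applied as a deterministic
expectation step (the analytic model is itself an expectation recursion, so
simulating founder matings would only add variance), and each subsequent
round resamples `Binomial(2N, p)/2N`, losing exactly `1/2N` of expected
heterozygosity per round. The two operationalizations of "heterozygosity" —
expected `2p(1−p)` versus the proportion of polymorphic loci — coincide in
expectation at founding but drift apart under Wright–Fisher sampling (the
frequency distribution of surviving loci spreads); the analytic model tracks
the former, and the pool generator's gene-level polymorphism rate (the
latter) therefore sits slightly above the analytic decay, well within
Monte-Carlo error at 220 loci. This conflation is inherited from the model
being validated, and is deliberate.

## The synthetic-data generator

The generator emulates the study design, not read-level sequencing:

- **Reference**: 220 genes of 1200 bp CDS (kb-scale NLR exomes), each an
  ATG-initiated ORF free of internal stops; every tenth gene carries a
  120-bp intron to exercise multi-segment CDS assembly. Annotated CDS covers
  coding positions only, so N + S site totals equal the CDS length exactly.
- **Pool truth**: with a propagation scenario, each gene is a locus of the
  drift model — founded polymorphic with probability `H₀`, surviving the
  founding step with probability `f`, drifting through `t−1` Wright–Fisher
  rounds, then sampled as `k ~ Binomial(20, p)` chromosomes. All SNPs within
  a polymorphic gene share the gene's `k`: after serial bottlenecks of a
  selfer the pool segregates two haplotypes per gene, which also reproduces
  the observed per-gene clustering of intermediate-frequency classes.
  A polymorphic gene carries `max(1, Poisson(18))` sites at uniform CDS
  positions with uniform non-reference bases.
- **Counts**: per-site depth `NegBin(mean 346, size 6)` — the size was
  fixed once so the first-quartile/median ratio (≈ 0.74) matches deep
  enrichment data (≈ 251/346); at a segregating site reads carry the
  alternative allele with probability `k/20`; every read base is miscalled
  uniformly to another base with probability `ε = 0.002`. The post-trimming
  error rate of real Q30-trimmed data is not a published quantity; 0.002 is
  a placeholder default, configurable. No indel errors are simulated, but
  indel evidence can be injected at chosen positions to exercise the
  caller's mask.

What the generator does **not** model — and what passing tests therefore do
not certify about real data: linkage beyond the shared per-gene `k` (no
downstream statistic here uses LD), mapping and duplicate-read artifacts,
probe-affinity bias between paralogs (the reason copy-number variation is
out of scope), transition/transversion mutational bias (alternative bases
are uniform, so the generator's expected Ts/Tv is 0.5, not the ≈ 1–2 of
real mutation spectra), and multiallelic truth sites (the caller still
handles multiallelic counts arising from error).

## Numerical conventions and problem sizes

Half-up rounding for copy classes; machine-precision round trips for
`invert_H0()` → forward decay; degenerate inputs (no transversions,
zero-variance correlate vectors, empty spectra, zero denominators in
validation rates) return `NA` with explicit flags rather than errors. The
test suite validates the caller against exhaustive enumeration of all
two-allele count vectors to depth 60, the site counting against the 9-mutant
enumeration for all 61 sense codons, effect labels against whole-sequence
translation, and the full pipeline at the study design point (220 genes,
~230 truth SNPs, depth 346): recall ≥ 95% for detectable classes with
false-positive rate ≤ 5%. Monte-Carlo checks use 220 loci × 2000 replicates
with fixed seeds and 3-standard-error envelopes; these sizes make the checks
sharp at the scale the model is actually used while keeping every run
deterministic.

## Known limitations

- The caller assumes equal DNA contribution per plant; unequal pooling
  biases `p̂` and everything downstream.
- `π` uses hard frequency estimates; no sampling-variance correction beyond
  `n/(n−1)` is applied (model-based pooled estimators are out of scope).
- Per-gene π~N~/π~S~ ratios from few SNPs are noisy; the per-gene table is
  descriptive, not a test statistic.
- The decay model has no mutation (none is expected over ~10 generations)
  and treats `N` as constant per round.
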