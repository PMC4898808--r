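# poolrens

Population-genetic analysis of pooled target-enrichment resequencing of a
plant immune-receptor (NLR) gene family within a single population.

## The problem

Hybridization capture of a few hundred resistance genes, sequenced as a
single pool of ten diploid plants, is a cheap way to scan an entire NLR
complement for maintained polymorphism. But pooled data give only per-site
read counts — individual genotypes are not recoverable — so every downstream
statistic has to be built from pooled allele frequencies, and the SNP calls
themselves need explicit count/coverage rules plus consensus between
independent callers to be trustworthy. `poolrens` implements that pipeline
for a pool of `n` chromosomes (default `n = 20`):

- **Pooled SNP detection** from per-site counts: a site is called when depth
  ≥ 30 and the second-most-frequent base is seen ≥ 6 times, after masking
  sites near indel evidence and sites above the per-contig 98% depth
  quantile (PCR-bias guard). With these thresholds a minor allele at
  frequency 4/20 is still detectable at depth 30, and singletons (1/20)
  at depth ≥ 120: `ceil(min_count · n / depth)`.
- **Consensus and validation**: set algebra over call sets keyed by
  (contig, position, minor allele), and scoring against a truth set with
  `fp_rate = fp/(tp+fp)`, `fn_rate = fn/(tp+fn)` inside validated regions.
- **Diversity**: per-site pooled diversity `π = 2p̂(1−p̂)·n/(n−1)`, per-gene
  π, and π_N/π_S with Nei–Gojobori fractional site counting (each codon
  position contributes the fraction of its 9 single-base changes that are
  synonymous; mutations to stop codons count as nonsynonymous).
- **Folded site-frequency spectrum**: pooled frequencies discretized to
  copy classes `k = clamp(round(p̂·n), 1, n−1)` and folded to
  `min(k, n−k)`, classes `1..n/2`; spectra compared by Pearson correlation
  of relative class frequencies.
- **Heterozygosity decay in a germplasm accession**: for a partially selfing
  population founded once and regenerated `t` times as `N` plants, the
  expected proportion of polymorphic loci decays as

  H_sample = H₀ · f · (1 − 1/2N)^(t−1),   f = 1 − 0.5·s  (or 0.5 for a single founder),

  where `s` is the selfing rate. `invert_H0()` solves this for the initial
  heterozygosity of the source population; `simulate_propagation()` is a
  forward Wright–Fisher simulator that validates the recursion.
- **Synthetic data**: `generate_reference()` / `generate_pool()` /
  `generate_pileup()` emulate the whole design — 220 genes, a pool of 20
  chromosomes, negative-binomial enrichment coverage (mean 346×), residual
  post-trimming miscalls at rate 0.002 — so the entire pipeline is testable
  without raw reads.

## Worked example

Call SNPs from the small bundled pileup (one 60-bp gene, two segregating
sites) and build its folded spectrum:

```r
library(poolrens)

pu  <- read_pileup(system.file("extdata", "example_pileup.tsv", package = "poolrens"))
res <- call_pileup(pu, caller_params())
res$calls
#>    contig pos ref minor alt minor_count depth        af  k
#> 1 gene001  21   C     T   T          19    68 0.2794118  6
#> 2 gene001  45   C     C   G          50   104 0.4807692 10
```

Two SNPs are called. At position 21 the minor allele T is seen in 19 of 68
reads (pooled frequency 0.28, estimated copy class 6 of 20 chromosomes); at
position 45 the pool is near 50/50, so the *minor* allele is the reference
base C and the variant allele G sits at copy class 10 — frequency 0.5 in the
pool. The folded spectrum puts one SNP in class 6 and one in class 10:

```r
build_folded_sfs(res$calls, pool_n = 20)$counts
#>  1  2  3  4  5  6  7  8  9 10
#>  0  0  0  0  0  1  0  0  0  1
```

Inverting the decay model for an accession where 13 of 220 genes remained
polymorphic after ten rounds (founding step + nine regenerations):

```r
round(as.numeric(invert_H0(13/220, s = 1, two_N = 24, t_total = 10)), 2)
#> [1] 0.17
```

## The full analysis

The numbered drivers under `analysis/` run the complete study on synthetic
data and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # reference, pool truth, pileup; coverage CDF
Rscript analysis/02_call_snps.R     # calling, consensus, truth validation
Rscript analysis/03_diversity.R     # per-gene pi, piN/piS, Ts/Tv, correlates
Rscript analysis/04_sfs.R           # global and per-gene folded SFS
Rscript analysis/05_drift_model.R   # H0 inversion grid + Monte-Carlo check
```

On the default design point this simulates 233 segregating sites in 13 of
220 genes, calls 231 SNPs (false-positive rate 0.000, false-negative rate
0.009 against the truth), and recovers the true folded spectrum with
Pearson correlation 0.92.

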