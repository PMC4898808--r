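#' Nei-Gojobori synonymous and nonsynonymous site counts for a codon
#'
#' Each codon position contributes fractional "synonymous sites" equal to the
#' fraction of its three possible single-base changes that preserve the amino
#' acid; the remainder are nonsynonymous sites, so the two always sum to 3.
#' Changes creating a stop codon count as nonsynonymous (the standard
#' convention of the estimator).
#'
#' @param codon a 3-letter string over `A`, `C`, `G`, `T`.
#' @param genetic_code named translation table (codon -> amino acid, `*` for
#'   stop); defaults to the standard code.
#' @return A list with `n_sites`, `s_sites` and `is_stop`. For a stop codon
#'   the site counts are `NA` and `is_stop` is `TRUE`: stop codons are
#'   excluded from gene totals.
#' @examples
#' ng_site_counts("ATG")  # 3 nonsynonymous, 0 synonymous
#' ng_site_counts("TTT")  # 8/3 and 1/3
#' @export
ng_site_counts <- function(codon, genetic_code = Biostrings::GENETIC_CODE) {
  codon <- toupper(codon)
  b <- strsplit(codon, "")[[1L]]
  if (length(b) != 3L || !all(b %in% c("A", "C", "G", "T"))) {
    stop(sprintf("ng_site_counts: '%s' is not an unambiguous codon", codon))
  }
  aa <- unname(genetic_code[codon])
  if (aa == "*") {
    return(list(n_sites = NA_real_, s_sites = NA_real_, is_stop = TRUE))
  }
  s <- 0
  for (p in 1:3) {
    for (nb in setdiff(c("A", "C", "G", "T"), b[p])) {
      mut <- b
      mut[p] <- nb
      maa <- unname(genetic_code[paste(mut, collapse = "")])
      if (maa == aa) s <- s + 1 / 3  # stop mutants (maa == "*") stay nonsynonymous
    }
  }
  list(n_sites = 3 - s, s_sites = s, is_stop = FALSE)
}

# effect of substituting `alt` at genomic position `pos` of `gene`
# (shared by the generator's truth labels and classify_snp_effect)
classify_substitution_effect <- function(pos, alt, gene, ref_seqs,
                                         genetic_code = Biostrings::GENETIC_CODE) {
  idx <- cds_index(gene, pos)
  if (is.na(idx) || idx < 1L) return("non-coding")
  if (!gene$codon_ok) {
    stop(sprintf("classify_snp_effect: CDS frame broken for gene '%s'", gene$gene_id))
  }
  cds <- as.character(cds_sequence(gene, ref_seqs))
  codon_start <- 3L * ((idx - 1L) %/% 3L) + 1L
  if (codon_start + 2L > nchar(cds)) return("non-coding")  # trailing partial codon
  codon <- substr(cds, codon_start, codon_start + 2L)
  within <- idx - codon_start + 1L
  sub_base <- if (gene$strand == "-") chartr("ACGT", "TGCA", alt) else alt
  mut <- codon
  substr(mut, within, within) <- sub_base
  if (!all(strsplit(codon, "")[[1L]] %in% c("A", "C", "G", "T"))) {
    stop(sprintf("classify_snp_effect: ambiguous reference codon in gene '%s'",
                 gene$gene_id))
  }
  if (genetic_code[mut] == genetic_code[codon]) "synonymous" else "nonsynonymous"
}

#' Classify the coding effect of a pooled SNP call
#'
#' Places the call on the gene's coding sequence and compares the reference
#' codon with the codon carrying the substituted base. Minus-strand genes are
#' evaluated on the reverse complement. Positions outside the CDS are
#' non-coding. When two SNPs fall in one codon each is classified against the
#' reference codon background independently.
#'
#' @param call a one-row [call_set] (the variant allele `alt` is used).
#' @param gene a [gene_model] with `codon_ok = TRUE`.
#' @param ref_seqs a [Biostrings::DNAStringSet].
#' @return `"synonymous"`, `"nonsynonymous"` or `"non-coding"`.
#' @export
classify_snp_effect <- function(call, gene, ref_seqs) {
  stopifnot(nrow(call) == 1L)
  classify_substitution_effect(call$pos, call$alt, gene, ref_seqs)
}

#' Per-site pooled nucleotide diversity
#'
#' Heterozygosity contribution of one biallelic site estimated from the
#' pooled minor-allele frequency, with the finite-pool unbiasedness factor
#' `n/(n-1)`: `2 * p * (1 - p) * pool_n / (pool_n - 1)`.
#'
#' @param p_hat pooled minor-allele frequency in `[0, 1]`.
#' @param pool_n chromosomes in the pool (`>= 2`).
#' @param unbiased apply the `n/(n-1)` factor (default) or not.
#' @return Per-site diversity.
#' @examples
#' site_pi(0.5, 20)  # 0.5263...
#' @export
site_pi <- function(p_hat, pool_n = 20L, unbiased = TRUE) {
  if (any(p_hat < 0 | p_hat > 1)) stop("site_pi: p_hat must be in [0, 1]")
  if (pool_n < 2L) stop("site_pi: pool_n must be >= 2")
  f <- if (unbiased) pool_n / (pool_n - 1) else 1
  2 * p_hat * (1 - p_hat) * f
}

#' Per-gene diversity statistics
#'
#' Computes, for one gene, the SNP count, per-gene nucleotide diversity
#' (summed [site_pi()] over CDS SNPs divided by CDS length), and the
#' Nei-Gojobori normalized `piN` and `piS` (summed site diversity over
#' nonsynonymous / synonymous SNPs divided by the gene's fractional
#' nonsynonymous / synonymous site totals). The ratio `piN/piS` is 0 when
#' `piN = 0` with `piS > 0` and undefined (`NA`) when `piS = 0`. Reference
#' stop codons are excluded from the site totals.
#'
#' @param gene a [gene_model] with `codon_ok = TRUE`.
#' @param calls a [call_set] (calls outside this gene's CDS are ignored for
#'   `piN`/`piS` and counted as non-coding).
#' @param ref_seqs a [Biostrings::DNAStringSet].
#' @param pool_n chromosomes in the pool.
#' @param unbiased apply the pooled `n/(n-1)` factor in [site_pi()].
#' @return One-row `data.frame` with `gene_id`, `n_snps`, `pi_per_gene`,
#'   `piN`, `piS`, `piN_piS`, `N_sites`, `S_sites`, `ts`, `tv`.
#' @export
gene_diversity <- function(gene, calls, ref_seqs, pool_n = 20L, unbiased = TRUE) {
  if (gene$cds_length == 0L) stop("gene_diversity: zero-length CDS")
  if (!gene$codon_ok) stop(sprintf("gene_diversity: CDS frame broken for '%s'", gene$gene_id))
  cds <- as.character(cds_sequence(gene, ref_seqs))
  n_codons <- nchar(cds) %/% 3L
  N_sites <- 0; S_sites <- 0
  for (ci in seq_len(n_codons)) {
    ng <- ng_site_counts(substr(cds, 3L * ci - 2L, 3L * ci))
    if (!ng$is_stop) {
      N_sites <- N_sites + ng$n_sites
      S_sites <- S_sites + ng$s_sites
    }
  }
  here <- calls[calls$contig == gene$contig, , drop = FALSE]
  if (nrow(here)) {
    idx <- cds_index(gene, here$pos)
    here <- here[!is.na(idx) & idx >= 1L, , drop = FALSE]
  }
  pi_sum_n <- 0; pi_sum_s <- 0; pi_sum <- 0
  effects <- character(nrow(here))
  if (nrow(here)) {
    codon_of <- (cds_index(gene, here$pos) - 1L) %/% 3L
    if (anyDuplicated(codon_of)) {
      warning(sprintf("gene_diversity: multiple SNPs in one codon of '%s'; each classified against the reference codon", gene$gene_id))
    }
    for (j in seq_len(nrow(here))) {
      eff <- classify_substitution_effect(here$pos[j], here$alt[j], gene, ref_seqs)
      effects[j] <- eff
      sp <- site_pi(here$af[j], pool_n, unbiased)
      pi_sum <- pi_sum + sp
      if (eff == "nonsynonymous") pi_sum_n <- pi_sum_n + sp
      if (eff == "synonymous") pi_sum_s <- pi_sum_s + sp
    }
  }
  piN <- pi_sum_n / N_sites
  piS <- if (S_sites > 0) pi_sum_s / S_sites else NA_real_
  ratio <- if (!is.na(piS) && piS > 0) piN / piS else NA_real_
  tt <- ts_tv(here)
  data.frame(gene_id = gene$gene_id, n_snps = nrow(here),
             pi_per_gene = pi_sum / gene$cds_length,
             piN = piN, piS = piS, piN_piS = ratio,
             N_sites = N_sites, S_sites = S_sites,
             ts = attr(tt, "ts"), tv = attr(tt, "tv"),
             stringsAsFactors = FALSE)
}

#' Transition/transversion ratio of a call set
#'
#' Transitions are `A<->G` and `C<->T` among reference-to-variant pairs;
#' everything else is a transversion.
#'
#' @param calls a [call_set].
#' @return The ratio `ts/tv` (numeric), `NA` when there are no transversions
#'   or no calls; attributes `ts` and `tv` carry the counts.
#' @export
ts_tv <- function(calls) {
  if (nrow(calls) == 0L) {
    return(structure(NA_real_, ts = 0L, tv = 0L))
  }
  pair <- paste0(calls$ref, calls$alt)
  is_ts <- pair %in% c("AG", "GA", "CT", "TC")
  ts <- sum(is_ts); tv <- sum(!is_ts)
  structure(if (tv > 0L) ts / tv else NA_real_, ts = ts, tv = tv)
}

#' Correlation of per-gene SNP counts with length and coverage
#'
#' Pearson correlations of the number of SNPs per gene with gene length and
#' with mean coverage depth — a check that detected polymorphism is not an
#' artifact of target size or enrichment efficiency.
#'
#' @param n_snps,lengths,mean_depths numeric vectors, one entry per gene
#'   (at least 3 genes).
#' @return Named numeric vector `c(r_length = , r_depth = )`; an entry is
#'   `NA` when its input has zero variance.
#' @export
snp_count_correlates <- function(n_snps, lengths, mean_depths) {
  if (length(n_snps) < 3L) stop("snp_count_correlates: need at least 3 genes")
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  c(r_length = safe_cor(n_snps, lengths),
    r_depth = safe_cor(n_snps, mean_depths))
}

#' Per-gene diversity table for a set of genes
#'
#' Convenience wrapper applying [gene_diversity()] across gene models,
#' mirroring a per-gene report table (gene, SNPs, pi, piN, piS, piN/piS,
#' Ts/Tv).
#'
#' @param genes named list of [gene_model]s.
#' @param calls a [call_set].
#' @param ref_seqs a [Biostrings::DNAStringSet].
#' @param pool_n chromosomes in the pool.
#' @param polymorphic_only keep only genes with at least one SNP.
#' @return `data.frame`, one row per gene.
#' @export
diversity_table <- function(genes, calls, ref_seqs, pool_n = 20L,
                            polymorphic_only = FALSE) {
  rows <- lapply(genes, gene_diversity, calls = calls, ref_seqs = ref_seqs,
                 pool_n = pool_n)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (polymorphic_only) out <- out[out$n_snps > 0L, , drop = FALSE]
  out
}
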