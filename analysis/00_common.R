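# Shared setup for the analysis drivers: the study design point and the
# propagation scenario. Sourced by the numbered scripts; every script can be
# run on its own from the repository root.

library(poolrens)

RESULTS_DIR <- "results"
SCRATCH_DIR <- "scratch/simdata"
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)
dir.create(SCRATCH_DIR, showWarnings = FALSE, recursive = TRUE)

STUDY_SEED <- 42L

# the design the generator emulates: 10 diploid plants pooled (20
# chromosomes), 220 target genes, deep overdispersed enrichment coverage,
# residual post-trimming error
study_params <- sim_params(n_genes = 220L, gene_length_bp = 1200L,
                           n_plants = 10L,
                           polymorphic_fraction = 13 / 220,
                           snp_intensity = 18,
                           mean_coverage = 346, coverage_dispersion = 6,
                           error_rate = 0.002, seed = STUDY_SEED)

# germplasm propagation history: accession founded from a fully selfing
# population, regenerated about 10 times as 8-12 plants; we use N = 12
# (2N = 24) with the initial heterozygosity inverted from the observed
# 13/220 polymorphic genes
study_scenario <- propagation_scenario(
  H0 = as.numeric(invert_H0(13 / 220, s = 1, two_N = 24, t_total = 10L)),
  s = 1, N = 12L, t_total = 10L, H_sample = 13 / 220)

simulate_study <- function(params = study_params, scenario = study_scenario) {
  ref <- generate_reference(params)
  truth <- generate_pool(ref, params, scenario = scenario)
  pileup <- generate_pileup(ref, truth, params)
  list(ref = ref, truth = truth, pileup = pileup)
}
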