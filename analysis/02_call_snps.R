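#!/usr/bin/env Rscript
# Step 2 — pooled SNP calling, consensus and truth-set validation.
#
# Calls SNPs from the simulated pileup with the pooled thresholds (depth >=
# 30, minor count >= 6, indel and excess-coverage masks), emulates a second
# caller by an independent resimulation of the same pool, intersects the two
# call sets, and scores calls against the known truth.

source("analysis/00_common.R")

sim <- simulate_study()
params <- caller_params()

res <- call_pileup(sim$pileup, params)
cat(sprintf("primary caller: %d SNP calls from %d sites\n",
            nrow(res$calls), nrow(sim$pileup)))
print(table(res$log$reason))

write_callset_vcf(res$calls, file.path(SCRATCH_DIR, "calls_primary.vcf"))

# second, independent route to the same pool: new sequencing noise over the
# same truth (a stand-in for an external caller's VCF)
pileup2 <- generate_pileup(sim$ref, sim$truth, study_params,
                           seed = study_params$seed + 100L)
res2 <- call_pileup(pileup2, params)
both <- intersect_callsets(res$calls, res2$calls)
cat(sprintf("consensus: %d shared, %d only primary, %d only replicate\n",
            nrow(both$both), nrow(both$only_a), nrow(both$only_b)))

# validation against the generator's truth over the whole target region
region <- data.frame(contig = names(sim$ref$sequences), start = 1L,
                     end = Biostrings::width(sim$ref$sequences))
rep_primary <- validate_against_truth(res$calls, sim$truth, region)
rep_both <- validate_against_truth(both$both, sim$truth, region)
cat("primary: "); print(rep_primary)
cat("consensus: "); print(rep_both)

summary <- data.frame(
  set = c("primary", "replicate", "consensus"),
  n_calls = c(nrow(res$calls), nrow(res2$calls), nrow(both$both)),
  tp = c(rep_primary$tp, NA, rep_both$tp),
  fp = c(rep_primary$fp, NA, rep_both$fp),
  fn = c(rep_primary$fn, NA, rep_both$fn),
  fp_rate = c(rep_primary$fp_rate, NA, rep_both$fp_rate),
  fn_rate = c(rep_primary$fn_rate, NA, rep_both$fn_rate))
write.table(summary, file.path(RESULTS_DIR, "calling_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# detectability across the observed depth range
depths <- c(20L, 30L, 120L, 346L)
det <- data.frame(depth = depths,
                  min_detectable_class = vapply(depths, function(d)
                    as.integer(detectability_threshold(d, params)), integer(1)))
write.table(det, file.path(RESULTS_DIR, "detectability.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("smallest detectable class at depth 30:",
    det$min_detectable_class[det$depth == 30L], "of 20\n")
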