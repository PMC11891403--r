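#!/usr/bin/env Rscript
# End-to-end check of the measurement-analysis pipeline on synthetic LCMS
# data: counts with an internal-normalizer channel, two replicates, three
# pre-feeding baseline samples and multiplicative lognormal noise are
# generated from the palmitate trajectory, then pushed through baseline
# normalization and fold-change estimation, and compared with the generating
# trajectory. A phenomenological FabB induction curve and a Welch t-test on
# replicate-level estimates illustrate the protein-side analysis.

suppressMessages(library(acylsim))
dir.create("results", showWarnings = FALSE)
seed <- 20240917

model <- build_model()
ss <- find_steady_state(model)
tr <- run_feeding_experiment(model, "palmitate", steady_state = ss)

analytes <- c("malonyl_ACP", "C16:0_ACP", "C18:0_ACP", "C18:1_ACP")
meas <- simulate_lcms_counts(tr, analytes,
                             sample_times = c(-9, -6, -3, 1, 2, 3, 4, 5, 10,
                                              20, 30, 45, 60),
                             n_replicates = 2, cv = 0.15, seed = seed)
write_measurements(meas, "results/synthetic_lcms_palmitate.tsv")
norm <- normalize_measurements(meas)
write.table(norm, "results/synthetic_lcms_normalized.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("fold-change recovery from noisy counts (window 1-5 min):")
rec <- lapply(analytes, function(sp) {
  truth <- fold_change_at(tr, sp, window = c(60, 300))
  est <- measured_fold_change(meas, sp, window = c(1, 5))
  message(sprintf("  %-12s true %.2f  recovered %.2f", sp, truth, est))
  data.frame(analyte = sp, true_fold = truth, recovered_fold = est)
})
write.table(do.call(rbind, rec), "results/fold_recovery.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# protein response: FabB induces ~2x over ~2 h after palmitate, FabA stays
# flat; counts are normalized to a constant reference protein (TufA-like)
t_s <- seq(-1800, 14400, by = 600)
set.seed(seed)
noise <- function(n, cv = 0.05) rlnorm(n, -log(1 + cv^2) / 2,
                                       sqrt(log(1 + cv^2)))
fabb <- simulate_protein_response(t_s, baseline = 100, fold = 2) * noise(length(t_s))
faba <- 100 * noise(length(t_s))
tufa <- 500 * noise(length(t_s))
prot <- data.frame(time_s = t_s,
                   fabb_over_tufa = normalize_to_reference(fabb, tufa),
                   faba_over_tufa = normalize_to_reference(faba, tufa))
prot$fabb_norm <- normalize_to_baseline(prot$fabb_over_tufa)
prot$faba_norm <- normalize_to_baseline(prot$faba_over_tufa)
write.table(prot, "results/protein_response.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

late <- t_s > 10800
wt <- welch_t_test(prot$fabb_norm[late], prot$faba_norm[late])
message(sprintf(
  "late-phase FabB vs FabA (baseline-normalized, TufA-referenced): t = %.2f, df = %.1f, p = %.2g",
  wt$t, wt$df, wt$p))
message("wrote results/synthetic_lcms_*.tsv, fold_recovery.tsv, protein_response.tsv")
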