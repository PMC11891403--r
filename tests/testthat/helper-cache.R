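# Shared fixtures: the calibrated model, its pre-feeding steady state and the
# feeding trajectories are expensive (stiff integration), so they are computed
# once per test run and shared across test files.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

baseline_model <- function() memo("model", build_model())

baseline_ss <- function() {
  memo("ss", find_steady_state(baseline_model()))
}

feeding_traj <- function(fatty_acid) {
  memo(paste0("traj_", fatty_acid),
       run_feeding_experiment(baseline_model(), fatty_acid,
                              steady_state = baseline_ss()))
}

knockout_traj <- function(fatty_acid) {
  mk <- memo("ko_model",
             remove_acc_feedback(baseline_model(), baseline_ss()))
  memo(paste0("ko_traj_", fatty_acid),
       run_feeding_experiment(mk, fatty_acid, steady_state = baseline_ss()))
}

# toy acyltransferase-only configuration: fatty acid synthesis silenced,
# clamped acyl-CoA substrates, slow catalysis (kcat << koff), no
# phospholipid feedback, saturating acceptors
toy_at_config <- function(coa_clamps) {
  w0 <- as.list(stats::setNames(
    rep(0, 11),
    c("C6:0", "C8:0", "C10:0", "C12:0", "C14:0", "C16:0", "C18:0",
      "C12:1", "C14:1", "C16:1", "C18:1")))
  list(acc = list(vmax = 1e-9),
       elongation = list(weights = w0),
       clamps = c(list(acetyl_CoA = 500, G3P = 200), coa_clamps),
       plsb = list(kcat = 0.02, km_g3p = 1e-6, k_pl_feedback = 1e12,
                   kon = list("C16:0_CoA" = 2, "C16:1_CoA" = 0.3,
                              "C18:1_CoA" = 1.1)),
       plsc = list(kcat = 0.02, km_lpa = 1e-6))
}

# independent closed-form flux partition for competing substrates binding a
# shared enzyme in rapid equilibrium: v_i = kcat_i E_T (S_i/K_i)/(1 + sum S/K)
rapid_eq_prediction <- function(model, coa_clamps) {
  kon <- unlist(model$params$plsb$kon)
  koff <- unlist(model$params$plsb$koff)
  S <- stats::setNames(numeric(length(kon)), names(kon))
  for (n in names(coa_clamps)) S[n] <- coa_clamps[[n]]
  SK <- S * kon / koff
  model$params$plsb$kcat * model$totals$PlsB * SK / (1 + sum(SK))
}
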