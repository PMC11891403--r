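# Observables: baseline normalization, fold changes, pool fractions,
# PA sn-1/sn-2 composition, reference-protein normalization.

#' Normalize a series to its pre-treatment baseline
#'
#' Divides every value by the mean of the first `n_baseline` (pre-treatment)
#' values, the convention used for the measurement time series ("normalized
#' to average of three measurements before treatments").
#'
#' @param values numeric series in time order, pre-treatment points first
#' @param n_baseline number of leading pre-treatment points (default 3)
#' @return normalized series; the baseline window has mean exactly 1
#' @examples
#' normalize_to_baseline(c(2, 2, 2, 3))   # 1 1 1 1.5
#' @export
normalize_to_baseline <- function(values, n_baseline = 3L) {
  if (length(values) < n_baseline) {
    stop_acylsim("baseline", "need at least ", n_baseline,
                 " pre-treatment points")
  }
  b <- mean(values[seq_len(n_baseline)])
  if (!is.finite(b) || b <= 0) {
    stop_acylsim("baseline", "baseline mean must be positive")
  }
  values / b
}

#' Post-step fold change of a species
#'
#' Mean concentration of `species` in a window after the feeding step,
#' divided by its pre-step steady-state concentration. The default window
#' 60-300 s captures the immediate (~1 min) response.
#'
#' @param traj an `fa_trajectory` produced with a feeding protocol
#' @param species model species id
#' @param window numeric length-2, window in seconds relative to the step
#' @return dimensionless fold change
#' @export
fold_change_at <- function(traj, species, window = c(60, 300)) {
  if (is.null(traj$protocol)) {
    stop_acylsim("fold_change", "trajectory has no feeding protocol")
  }
  if (!species %in% colnames(traj$states)) {
    stop_acylsim("fold_change", "unknown species '", species, "'")
  }
  base <- traj$baseline[[species]]
  if (!is.finite(base) || base <= 0) {
    stop_acylsim("fold_change", "pre-step concentration of '", species,
                 "' is zero; fold change undefined")
  }
  rel <- traj$times - traj$protocol$t_step
  sel <- rel >= window[1] & rel <= window[2]
  if (!any(sel)) {
    stop_acylsim("fold_change", "no trajectory points in the window")
  }
  mean(traj$states[sel, species]) / base
}

#' C16:0 fraction of the PlsB acyl-ACP substrate pool
#'
#' Fraction of C16:0-ACP within the PlsB acyl-ACP substrate pool,
#' \eqn{[C16:0\,ACP] / ([C16:0\,ACP] + [C18:1\,ACP])}. The experimentally
#' reported pool fraction counts acyl-ACP substrates only; setting
#' `include_coa = TRUE` adds the corresponding acyl-CoA species to both
#' numerator and denominator.
#'
#' @param state named state vector
#' @param include_coa include C16:0-CoA and C18:1-CoA in the pool
#' @return fraction in [0, 1]
#' @export
plsb_substrate_fraction <- function(state, include_coa = FALSE) {
  num <- state[["C16:0_ACP"]]
  den <- state[["C16:0_ACP"]] + state[["C18:1_ACP"]]
  if (include_coa) {
    num <- num + state[["C16:0_CoA"]]
    den <- den + state[["C16:0_CoA"]] + state[["C18:1_CoA"]]
  }
  if (!is.finite(den) || den <= 0) {
    stop_acylsim("fraction", "PlsB substrate pool is empty")
  }
  num / den
}

#' Acyl-chain composition of the PA pool at sn-1 and sn-2
#'
#' For each reported time, the fraction of phosphatidic acid bearing each
#' chain at the sn-1 position (marginalized over sn-2) and at the sn-2
#' position (marginalized over sn-1). Fractions at each position sum to 1.
#'
#' @param traj an `fa_trajectory`
#' @param times times (s, absolute) at which to report; default all
#'   trajectory times with a nonzero PA pool
#' @return data.frame with columns `time_s`, `position` (`"sn1"`/`"sn2"`),
#'   `chain`, `fraction`
#' @export
pa_composition <- function(traj, times = NULL) {
  pp <- traj$model$pa_pairs
  pa_cols <- paste0("PA_", pp$sn1, "_", pp$sn2)
  if (is.null(times)) {
    tot <- rowSums(traj$states[, pa_cols, drop = FALSE])
    times <- traj$times[tot > 0]
  }
  it <- match(times, traj$times)
  if (anyNA(it)) {
    stop_acylsim("composition", "requested times not in trajectory")
  }
  out <- list()
  for (k in seq_along(it)) {
    x <- traj$states[it[k], pa_cols]
    tot <- sum(x)
    if (tot <= 0) {
      stop_acylsim("composition", "PA pool empty at t = ", times[k], " s")
    }
    sn1 <- tapply(x, pp$sn1, sum) / tot
    sn2 <- tapply(x, pp$sn2, sum) / tot
    out[[k]] <- data.frame(
      time_s = times[k],
      position = rep(c("sn1", "sn2"), each = length(AT_CHAINS)),
      chain = rep(AT_CHAINS, 2),
      fraction = c(sn1[AT_CHAINS], sn2[AT_CHAINS]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Normalize protein counts to a reference protein
#'
#' Element-wise ratio of a protein's counts to the counts of a constant
#' reference protein (e.g. elongation factor TufA) measured in the same
#' samples.
#'
#' @param protein_counts,reference_counts aligned numeric series
#' @return numeric series of ratios
#' @export
normalize_to_reference <- function(protein_counts, reference_counts) {
  if (length(protein_counts) != length(reference_counts)) {
    stop_acylsim("reference", "series lengths differ (",
                 length(protein_counts), " vs ", length(reference_counts), ")")
  }
  if (any(!is.finite(reference_counts)) || any(reference_counts <= 0)) {
    stop_acylsim("reference", "reference counts must be positive")
  }
  protein_counts / reference_counts
}
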