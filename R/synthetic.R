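# Synthetic LCMS-like measurement generator.
#
# Emulates the structure of the targeted LCMS experiments: per-analyte count
# time series with an internal-normalizer channel (a nonacylated ACP peptide,
# whose abundance tracks the conserved total ACP and is therefore constant),
# two biological replicates, three pre-treatment baseline samples, and
# multiplicative lognormal noise.

#' Generate an LCMS-like measurement series from a trajectory
#'
#' Counts are `scale * concentration * lognormal(cv)` per draw, with the
#' lognormal mean-corrected to 1 (meanlog = -sdlog^2/2), so expected counts
#' are proportional to the true concentration. The normalizer channel is
#' drawn once per (time, replicate) sample with the same cv around
#' `scale * 1` and shared by all analytes of that sample, mirroring a single
#' internal-standard channel per injection.
#'
#' @param truth an `fa_trajectory`
#' @param analytes species ids to measure
#' @param sample_times sample times in minutes relative to the feeding step
#'   (negative = pre-feeding); must include at least 3 pre-feeding times and
#'   lie within the trajectory span
#' @param n_replicates biological replicates (default 2, as in the study
#'   design)
#' @param cv coefficient of variation of the multiplicative noise
#' @param seed integer seed; fixed seed gives a reproducible dataset
#' @param scale counts per µM (arbitrary; analysis is ratio-based)
#' @return data.frame with columns `analyte`, `time_min`, `replicate`,
#'   `counts`, `normalizer_counts`
#' @export
simulate_lcms_counts <- function(truth, analytes,
                                 sample_times = c(-9, -6, -3, 1, 2, 5, 10,
                                                  20, 30, 45, 60),
                                 n_replicates = 2L, cv = 0.15, seed = 1L,
                                 scale = 1e4) {
  if (length(analytes) == 0L) {
    stop_acylsim("synth", "analyte list is empty")
  }
  if (!all(analytes %in% colnames(truth$states))) {
    stop_acylsim("synth", "unknown analytes: ",
                 paste(setdiff(analytes, colnames(truth$states)),
                       collapse = ", "))
  }
  if (sum(sample_times < 0) < 3L) {
    stop_acylsim("synth", "need at least 3 pre-feeding sample times")
  }
  if (n_replicates < 1L) {
    stop_acylsim("synth", "n_replicates must be >= 1")
  }
  if (cv < 0) stop_acylsim("synth", "cv must be >= 0")
  t0 <- if (!is.null(truth$protocol)) truth$protocol$t_step else 0
  t_abs <- t0 + sample_times * 60
  if (min(t_abs) < min(truth$times) || max(t_abs) > max(truth$times)) {
    stop_acylsim("synth", "sample times outside the trajectory span")
  }
  # truth at sample times by linear interpolation on the trajectory grid
  conc <- vapply(analytes, function(a) {
    stats::approx(truth$times, truth$states[, a], xout = t_abs)$y
  }, numeric(length(t_abs)))
  conc <- matrix(conc, nrow = length(t_abs),
                 dimnames = list(NULL, analytes))

  sdlog <- sqrt(log(1 + cv^2))
  mulog <- -sdlog^2 / 2
  draw <- function(n) {
    if (cv == 0) rep(1, n) else stats::rlnorm(n, mulog, sdlog)
  }
  set.seed(as.integer(seed))
  out <- list()
  for (r in seq_len(n_replicates)) {
    norm_r <- scale * draw(length(t_abs))
    for (a in analytes) {
      out[[length(out) + 1L]] <- data.frame(
        analyte = a, time_min = sample_times, replicate = r,
        counts = scale * conc[, a] * draw(length(t_abs)),
        normalizer_counts = norm_r,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Baseline-normalized analyte series from measurements
#'
#' Reduces a measurement table to baseline-normalized response curves: counts
#' are divided by the normalizer channel, then by the mean of the
#' pre-feeding (time < 0) values. With `pooled = TRUE` (default) the
#' baseline is the pooled mean over replicates; otherwise each replicate is
#' normalized to its own baseline.
#'
#' @param meas measurement data.frame as produced by
#'   [simulate_lcms_counts()]
#' @param pooled pool replicates when forming the baseline
#' @return data.frame with columns `analyte`, `time_min`, `replicate`,
#'   `value` (dimensionless)
#' @export
normalize_measurements <- function(meas, pooled = TRUE) {
  need <- c("analyte", "time_min", "replicate", "counts",
            "normalizer_counts")
  if (!all(need %in% names(meas))) {
    stop_acylsim("synth", "measurement table must have columns ",
                 paste(need, collapse = ", "))
  }
  meas$ratio <- normalize_to_reference(meas$counts, meas$normalizer_counts)
  out <- lapply(split(meas, meas$analyte), function(d) {
    if (pooled) {
      b <- mean(d$ratio[d$time_min < 0])
      if (!is.finite(b) || b <= 0) {
        stop_acylsim("baseline", "baseline mean must be positive")
      }
      d$value <- d$ratio / b
    } else {
      d <- do.call(rbind, lapply(split(d, d$replicate), function(dr) {
        b <- mean(dr$ratio[dr$time_min < 0])
        if (!is.finite(b) || b <= 0) {
          stop_acylsim("baseline", "baseline mean must be positive")
        }
        dr$value <- dr$ratio / b
        dr
      }))
    }
    d
  })
  res <- do.call(rbind, out)[, c("analyte", "time_min", "replicate", "value")]
  rownames(res) <- NULL
  res
}

#' Fold change estimated from measurements
#'
#' Mean baseline-normalized value over a post-feeding window — the
#' measurement-side analogue of [fold_change_at()].
#'
#' @param meas measurement table
#' @param analyte analyte id
#' @param window window in minutes relative to feeding
#' @param pooled see [normalize_measurements()]
#' @return estimated fold change
#' @export
measured_fold_change <- function(meas, analyte, window = c(1, 5),
                                 pooled = TRUE) {
  nm <- normalize_measurements(meas[meas$analyte == analyte, , drop = FALSE],
                               pooled = pooled)
  sel <- nm$time_min >= window[1] & nm$time_min <= window[2]
  if (!any(sel)) stop_acylsim("synth", "no samples in the window")
  mean(nm$value[sel])
}

#' Phenomenological protein induction curve
#'
#' Saturating-exponential stand-in for the slow transcriptional response of a
#' protein after feeding: `baseline * (1 + (fold - 1) * (1 - exp(-t/tau)))`
#' for `t >= 0`, `baseline` before. The default `tau` puts 95% of the rise
#' at about 2 h, matching the observed FabB induction timescale.
#'
#' @param times times (s, relative to feeding; negative allowed)
#' @param baseline pre-feeding level
#' @param fold plateau/baseline ratio, > 0
#' @param tau time constant (s), > 0
#' @return numeric series
#' @export
simulate_protein_response <- function(times, baseline, fold,
                                      tau = 7200 / log(20)) {
  if (!is.numeric(tau) || tau <= 0) {
    stop_acylsim("synth", "tau must be positive")
  }
  if (fold <= 0) stop_acylsim("synth", "fold must be positive")
  ifelse(times < 0, baseline,
         baseline * (1 + (fold - 1) * (1 - exp(-times / tau))))
}
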