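#' Michaelis-Menten rate laws
#'
#' Elementary irreversible rate laws used by every non-acyltransferase
#' reaction in the model. `mm_rate()` is the single-substrate form
#' \eqn{v = V_{max} s / (K_m + s)}; `mm_rate_two_substrate()` multiplies two
#' saturation terms and an optional noncompetitive inhibition factor
#' \eqn{1 / (1 + (I/K_i)^n)}, the form used for the lumped ACC-FabD
#' initiation reaction under long-chain acyl-ACP feedback (set
#' `ki = Inf` for an uninhibited two-substrate reaction such as FabH).
#'
#' @param vmax maximal rate (concentration / time), > 0
#' @param s,s1,s2 substrate concentrations, >= 0
#' @param km,km1,km2 Michaelis constants (concentration), > 0
#' @param inhibitor inhibitor concentration, >= 0
#' @param ki inhibition constant; `Inf` disables inhibition
#' @param n Hill coefficient of the inhibition term
#' @return reaction rate (same units as `vmax`); vectorized over substrates.
#' @examples
#' mm_rate(1, 2, 2)                       # half saturation: 0.5
#' mm_rate_two_substrate(1, 1, 1, 1, 1)   # 0.25
#' @export
mm_rate <- function(vmax, s, km) {
  if (any(!is.finite(vmax)) || any(vmax <= 0) || any(km <= 0)) {
    stop_acylsim("invalid_parameter", "vmax and km must be positive")
  }
  if (any(s < 0)) {
    stop_acylsim("invalid_parameter", "substrate concentration must be >= 0")
  }
  vmax * s / (km + s)
}

#' @rdname mm_rate
#' @export
mm_rate_two_substrate <- function(vmax, s1, km1, s2, km2,
                                  inhibitor = 0, ki = Inf, n = 1) {
  if (any(vmax <= 0) || any(km1 <= 0) || any(km2 <= 0) || any(ki <= 0) ||
      any(n <= 0)) {
    stop_acylsim("invalid_parameter",
                 "vmax, km1, km2, ki and n must be positive")
  }
  if (any(s1 < 0) || any(s2 < 0) || any(inhibitor < 0)) {
    stop_acylsim("invalid_parameter", "concentrations must be >= 0")
  }
  inh <- if (all(is.infinite(ki))) 1 else 1 / (1 + (inhibitor / ki)^n)
  vmax * (s1 / (km1 + s1)) * (s2 / (km2 + s2)) * inh
}

#' Welch two-sample t-test (unequal variances)
#'
#' Two-tailed t-test with the Welch statistic and Welch-Satterthwaite degrees
#' of freedom, the "2-tailed unequal distribution" test used for comparing
#' replicate measurements between feeding conditions. Implemented from the
#' defining formulas (so it can be cross-checked against an independent
#' implementation).
#'
#' @param a,b numeric samples, each of length >= 2 with finite variance
#' @return list with elements `t`, `df`, `p`
#' @examples
#' welch_t_test(c(1, 2, 3), c(2, 3, 4))
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop_acylsim("invalid_sample", "each sample needs n >= 2")
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop_acylsim("invalid_sample", "samples must be finite")
  }
  na <- length(a); nb <- length(b)
  va <- stats::var(a) / na
  vb <- stats::var(b) / nb
  se2 <- va + vb
  if (se2 <= 0) {
    stop_acylsim("invalid_sample", "samples must have nonzero variance")
  }
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
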