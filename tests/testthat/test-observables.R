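test_that("baseline normalization divides by the pre-treatment mean", {
  expect_equal(normalize_to_baseline(c(2, 2, 2, 3)), c(1, 1, 1, 1.5))
  expect_equal(normalize_to_baseline(rep(4.2, 10)), rep(1, 10))
  set.seed(11)
  x <- runif(20, 0.5, 5)
  expect_equal(normalize_to_baseline(x), x / mean(x[1:3]))
  # invariant: baseline window mean of normalized values is exactly 1
  expect_equal(mean(normalize_to_baseline(x)[1:3]), 1, tolerance = 1e-12)
  expect_error(normalize_to_baseline(c(0, 0, 0, 1)),
               class = "acylsim_baseline")
  expect_error(normalize_to_baseline(c(1, 2)), class = "acylsim_baseline")
})

test_that("fold change equals the trajectory's own concentration ratio", {
  tr <- feeding_traj("palmitate")
  w <- c(60, 300)
  rel <- tr$times - tr$protocol$t_step
  sel <- rel >= w[1] & rel <= w[2]
  direct <- mean(tr$states[sel, "C16:0_ACP"]) / tr$baseline[["C16:0_ACP"]]
  expect_equal(fold_change_at(tr, "C16:0_ACP", w), direct)
  expect_error(fold_change_at(tr, "no_such_species"),
               class = "acylsim_fold_change")
  # zero pre-step concentration is undefined
  tr0 <- tr; tr0$baseline[["C16:0_ACP"]] <- 0
  expect_error(fold_change_at(tr0, "C16:0_ACP"),
               class = "acylsim_fold_change")
})

test_that("PlsB substrate-pool fraction is the C16:0 share", {
  st <- c("C16:0_ACP" = 4, "C18:1_ACP" = 1, "C16:0_CoA" = 0,
          "C18:1_CoA" = 0)
  expect_equal(plsb_substrate_fraction(st), 0.8)
  st["C18:1_ACP"] <- 4
  expect_equal(plsb_substrate_fraction(st), 0.5)
  # optional acyl-CoA inclusion shifts the pool
  st <- c("C16:0_ACP" = 4, "C18:1_ACP" = 1, "C16:0_CoA" = 5,
          "C18:1_CoA" = 0)
  expect_equal(plsb_substrate_fraction(st, include_coa = TRUE), 0.9)
  expect_error(plsb_substrate_fraction(c("C16:0_ACP" = 0, "C18:1_ACP" = 0)),
               class = "acylsim_fraction")
})

test_that("PA composition marginalizes correctly and sums to one", {
  m <- baseline_model()
  fake <- structure(list(
    times = c(0, 1),
    states = matrix(0, 2, length(m$species),
                    dimnames = list(NULL, m$species)),
    protocol = NULL, model = m), class = "fa_trajectory")
  fake$states[, "PA_C16:0_C16:1"] <- 2
  pc <- pa_composition(fake, times = 0)
  expect_equal(pc$fraction[pc$position == "sn1" & pc$chain == "C16:0"], 1)
  expect_equal(pc$fraction[pc$position == "sn2" & pc$chain == "C16:1"], 1)
  # mixed pool: fractions per position sum to 1
  fake$states[, "PA_C18:1_C18:1"] <- 3
  fake$states[, "PA_C16:0_C18:1"] <- 0.5
  pc <- pa_composition(fake, times = 1)
  sums <- tapply(pc$fraction, pc$position, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-9)
  expect_true(all(pc$fraction >= 0 & pc$fraction <= 1))
})

test_that("cis-vaccenate feeding raises the 18:1 share at both PA positions", {
  tr <- feeding_traj("cis-vaccenate")
  ts <- tr$protocol$t_step
  before <- max(tr$times[tr$times < ts])
  after <- max(tr$times[tr$times <= ts + 300])
  pc0 <- pa_composition(tr, times = before)
  pc1 <- pa_composition(tr, times = after)
  for (pos in c("sn1", "sn2")) {
    f0 <- pc0$fraction[pc0$position == pos & pc0$chain == "C18:1"]
    f1 <- pc1$fraction[pc1$position == pos & pc1$chain == "C18:1"]
    expect_gt(f1, f0)
  }
})

test_that("reference-protein normalization is an element-wise ratio", {
  x <- c(1, 2, 3); ref <- c(2, 2, 2)
  expect_equal(normalize_to_reference(x, ref), x / 2)
  expect_equal(normalize_to_reference(ref, ref), c(1, 1, 1))
  # algebraic identity: normalize-then-ratio equals the direct ratio
  faba <- c(10, 11, 12); fabb <- c(20, 25, 31); tufa <- c(5, 6, 5.5)
  r1 <- normalize_to_reference(faba, tufa) / normalize_to_reference(fabb, tufa)
  expect_equal(r1, faba / fabb)
  expect_error(normalize_to_reference(1:3, 1:2), class = "acylsim_reference")
  expect_error(normalize_to_reference(1:3, c(1, 0, 2)),
               class = "acylsim_reference")
})
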