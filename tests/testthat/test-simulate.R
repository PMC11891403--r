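test_that("steady-state search satisfies its residual contract", {
  m <- baseline_model()
  ss <- baseline_ss()
  expect_lt(attr(ss, "residual"), 1e-8)
  # direct recomputation of the residual from the returned state
  d <- rhs(ss, m)
  keep <- setdiff(m$species, m$clamped)
  expect_lt(max(abs(d[keep]) / (abs(ss[keep]) + 1e-6)), 1e-8)
  # deterministic: a second search from the same inputs is identical
  ss2 <- find_steady_state(m)
  expect_identical(unclass(ss)[m$species], unclass(ss2)[m$species])
})

test_that("baseline (no acyl-CoA) steady state is a viable synthesis state", {
  m <- baseline_model()
  expect_true(all(unlist(m$params$clamps[paste0(c("C16:0", "C16:1", "C18:1"),
                                                "_CoA")]) == 0))
  ss <- baseline_ss()
  expect_gt(ss[["malonyl_ACP"]], 0)
  pa_flux <- m$params$lipid$k_pa_pl * sum(ss[grep("^PA_", names(ss))])
  expect_gt(pa_flux, 0)
  # nonnegativity at the converged state
  expect_true(all(ss > -1e-9))
})

test_that("perturbed admissible initializations converge to the same state", {
  m <- baseline_model()
  ss <- baseline_ss()
  # second initialization: shift 10% of holo-ACP into malonyl-ACP and seed
  # the lipid pools; conserved totals are untouched
  y2 <- initial_state(m)
  y2["malonyl_ACP"] <- 0.1 * y2[["ACP"]]
  y2["ACP"] <- 0.9 * y2[["ACP"]]
  y2["PA_C16:0_C16:1"] <- 30
  y2["PL_C16:0_C18:1"] <- 500
  ss2 <- find_steady_state(m, state0 = y2)
  big <- names(ss)[ss > 1e-6]
  expect_lt(max(abs(ss2[big] - ss[big]) / ss[big]), 1e-4)
})

test_that("time-course integration honours grid, conservation and tolerances", {
  m <- baseline_model()
  ss <- baseline_ss()
  grid <- c(0, 10, 100, 1000, 5000, 10000)
  tr <- simulate_timecourse(m, ss, grid)
  expect_equal(unname(tr$states[1, ]), unname(ss[m$species]))
  # ACP conservation drift < 1e-6 relative over 1e4 s
  ct <- apply(tr$states, 1, function(x)
    conserved_totals(stats::setNames(x, m$species), m)$acp_total)
  expect_lt(max(abs(ct - m$totals$ACP)) / m$totals$ACP, 1e-6)
  expect_true(all(tr$states > -1e-9))
  expect_error(simulate_timecourse(m, ss, c(5, 1)), class = "acylsim_grid")
})

test_that("halving solver tolerances leaves the trajectory unchanged to 1e-6", {
  m1 <- baseline_model()
  m2 <- build_model(list(solver = list(rtol = 5e-10, atol = 5e-14)))
  ss <- baseline_ss()
  grid <- sort(unique(c(seq(0, 8000, 1000), 8000 + seq(20, 1800, 60))))
  prot <- feeding_protocol("C16:0_CoA", 20)
  t1 <- simulate_timecourse(m1, ss, grid, prot)
  t2 <- simulate_timecourse(m2, ss, grid, prot)
  expect_lt(max(abs(t1$states - t2$states) / (abs(t1$states) + 1e-6)), 1e-6)
})

test_that("feeding step clamps the fed species and keeps the rest continuous", {
  m <- baseline_model()
  ss <- baseline_ss()
  prot <- feeding_protocol("C16:0_CoA", 20)
  stepped <- apply_feeding_step(m, ss, prot)
  expect_equal(stepped$state[["C16:0_CoA"]], 20)
  others <- setdiff(m$species, "C16:0_CoA")
  expect_equal(stepped$state[others], ss[others])
  expect_error(feeding_protocol("acetyl_CoA", 5), class = "acylsim_protocol")
  expect_error(feeding_protocol("C16:0_CoA", -1), class = "acylsim_protocol")
})

test_that("null feeding (clamp at baseline) leaves every pool flat", {
  tr <- feeding_traj("none")
  m <- baseline_model()
  sp <- setdiff(colnames(tr$states), m$clamped)
  fc <- vapply(sp[tr$baseline[sp] > 1e-9],
               function(s) fold_change_at(tr, s), numeric(1))
  expect_true(all(abs(fc - 1) < 1e-4))
})

test_that("pre-step window is genuinely stationary", {
  tr <- feeding_traj("palmitate")
  m <- baseline_model()
  pre <- tr$times >= 7200 & tr$times <= 8000   # last 10% of pre-step window
  sp <- setdiff(colnames(tr$states), m$clamped)
  rel_var <- apply(tr$states[pre, sp, drop = FALSE], 2, function(x) {
    mu <- mean(x)
    if (mu < 1e-9) 0 else diff(range(x)) / mu
  })
  expect_lt(max(rel_var), 1e-3)
})

test_that("feeding responses carry the observed signs for all three fatty acids", {
  # palmitate: saturated acyl-ACP up, malonyl-ACP down
  tr <- feeding_traj("palmitate")
  expect_gt(fold_change_at(tr, "C16:0_ACP"), 1)
  expect_gt(fold_change_at(tr, "C18:0_ACP"), 1)
  expect_lt(fold_change_at(tr, "malonyl_ACP"), 1)
  # palmitoleate: long-chain unsaturated acyl-ACP up, malonyl-ACP down
  tr <- feeding_traj("palmitoleate")
  expect_gt(fold_change_at(tr, "C18:1_ACP"), 1)
  expect_lt(fold_change_at(tr, "malonyl_ACP"), 1)
  # cis-vaccenate: both saturated and unsaturated up, malonyl-ACP down
  tr <- feeding_traj("cis-vaccenate")
  expect_gt(fold_change_at(tr, "C16:0_ACP"), 1)
  expect_gt(fold_change_at(tr, "C18:1_ACP"), 1)
  expect_lt(fold_change_at(tr, "malonyl_ACP"), 1)
})

test_that("simulated feeding is deterministic", {
  m <- baseline_model()
  ss <- baseline_ss()
  grid <- c(seq(0, 8000, 2000), 8000 + seq(30, 600, 30))
  prot <- feeding_protocol("C16:1_CoA", 8)
  t1 <- simulate_timecourse(m, ss, grid, prot)
  t2 <- simulate_timecourse(m, ss, grid, prot)
  expect_identical(t1$states, t2$states)
})

test_that("post-step C16:0-ACP response is monotone in the clamped C16:0-CoA", {
  m <- baseline_model()
  ss <- baseline_ss()
  grid <- c(seq(0, 8000, 2000), 8000 + seq(30, 300, 30))
  folds <- vapply(c(6.3, 20, 63), function(cl) {
    tr <- simulate_timecourse(m, ss, grid, feeding_protocol("C16:0_CoA", cl))
    fold_change_at(tr, "C16:0_ACP", window = c(30, 300))
  }, numeric(1))
  expect_false(is.unsorted(folds))
})
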