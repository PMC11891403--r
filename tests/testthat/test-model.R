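test_that("stoichiometry conserves ACP, PlsB and PlsC moieties by construction", {
  m <- baseline_model()
  # conservation vectors lie in the left null space of the stoichiometry
  expect_equal(max(abs(m$w_acp %*% m$stoich)), 0)
  expect_equal(max(abs(m$w_plsb %*% m$stoich)), 0)
  expect_equal(max(abs(m$w_plsc %*% m$stoich)), 0)
  expect_false(anyDuplicated(m$species) > 0)
  expect_true(all(c("acetyl_CoA", "G3P", "C16:0_CoA", "C16:1_CoA",
                    "C18:1_CoA") %in% m$clamped))
})

test_that("acyltransferase substrate sets carry the expected preferences", {
  m <- baseline_model()
  subs <- c("C16:0_ACP", "C16:1_ACP", "C18:1_ACP",
            "C16:0_CoA", "C16:1_CoA", "C18:1_CoA")
  expect_setequal(m$at$id, subs)
  kon_b <- unlist(m$params$plsb$kon)
  kon_c <- unlist(m$params$plsc$kon)
  # PlsB disfavors C16:1 substrates, PlsC disfavors C16:0 substrates
  expect_lt(kon_b[["C16:1_ACP"]], kon_b[["C16:0_ACP"]])
  expect_lt(kon_b[["C16:1_CoA"]], kon_b[["C18:1_CoA"]])
  expect_lt(kon_c[["C16:0_ACP"]], kon_c[["C16:1_ACP"]])
  expect_lt(kon_c[["C16:0_CoA"]], kon_c[["C18:1_CoA"]])
  # and a model violating the ordering is rejected
  expect_error(build_model(list(plsb = list(kon = list("C16:1_ACP" = 100)))),
               class = "acylsim_config")
})

test_that("configuration validation names the offending key", {
  expect_error(build_model(list(nonsense = list(a = 1))),
               "nonsense", class = "acylsim_config")
  expect_error(build_model(list(acc = list(vmax = -1))),
               "acc", class = "acylsim_config")
  expect_error(build_model(list(acc = list(km_typo = 1))),
               "km_typo", class = "acylsim_config")
  expect_error(build_model(list(acc = list(vmax = "fast"))),
               "acc\\$vmax", class = "acylsim_config")
})

test_that("zeroed elongation weight cuts reachability of all longer chains", {
  m <- build_model(list(elongation = list(weights = list("C12:0" = 0))))
  # independent oracle: breadth-first closure over the reaction graph,
  # firing a reaction when all its substrates are available
  reachable <- c("ACP", "acetyl_CoA", "G3P", "PlsB", "PlsC")
  repeat {
    grew <- FALSE
    for (r in m$rx) {
      if (r$zero) next
      if (all(r$substrates %in% reachable) &&
          !all(r$products %in% reachable)) {
        reachable <- union(reachable, r$products)
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  expect_true("C10:0_ACP" %in% reachable)
  expect_true("C10:1_ACP" %in% reachable)   # branch precedes the cut
  expect_false(any(c("C12:0_ACP", "C14:0_ACP", "C16:0_ACP", "C18:0_ACP")
                   %in% reachable))
  # unsaturated chains pass C12:1 onwards and reach the lipids
  expect_true("C18:1_ACP" %in% reachable)
  expect_true(any(grepl("^PA_", reachable)))
})

test_that("rhs zeroes clamped species and conserves weighted sums", {
  m <- baseline_model()
  set.seed(7)
  for (i in 1:5) {
    y <- initial_state(m)
    y[] <- runif(length(y), 0, 5)
    for (s in names(m$params$clamps)) y[s] <- m$params$clamps[[s]]
    d <- rhs(y, m)
    expect_equal(unname(d[m$clamped]), rep(0, length(m$clamped)))
    expect_lt(abs(sum(d * m$w_acp)), 1e-10)
    expect_lt(abs(sum(d * m$w_plsb)), 1e-10)
    expect_lt(abs(sum(d * m$w_plsc)), 1e-10)
  }
  expect_error(rhs(c(ACP = 1), m), class = "acylsim_state")
})

test_that("rhs reproduces a hand-computed initiation rate", {
  m <- baseline_model()
  y <- initial_state(m)  # only holo-ACP, enzymes, clamps are nonzero
  p <- m$params$acc
  v_hand <- mm_rate_two_substrate(p$vmax, y[["ACP"]], p$km_acp,
                                  y[["acetyl_CoA"]], p$km_accoa,
                                  inhibitor = 0, ki = p$ki, n = p$hill)
  d <- rhs(y, m)
  # with no malonyl-ACP yet, its derivative is exactly the ACC-FabD rate
  expect_equal(d[["malonyl_ACP"]], v_hand, tolerance = 1e-12)
})

test_that("conserved totals do the bookkeeping over free and bound forms", {
  m <- baseline_model()
  y <- stats::setNames(numeric(length(m$species)), m$species)
  y["ACP"] <- 10
  expect_equal(conserved_totals(y, m)$acp_total, 10)
  y["PlsB.C16:0_ACP"] <- 1
  y["ACP"] <- 2
  ct <- conserved_totals(y, m)
  expect_equal(ct$acp_total, 3)       # complex carries one ACP moiety
  expect_equal(ct$plsb_total, 1)      # and one PlsB moiety
  y["PlsC.C18:1_CoA"] <- 0.5          # CoA complex: enzyme but no ACP
  ct <- conserved_totals(y, m)
  expect_equal(ct$acp_total, 3)
  expect_equal(ct$plsc_total, 0.5)
  st <- initial_state(m)
  ct <- conserved_totals(st, m)
  expect_equal(ct$acp_total, m$totals$ACP)
  expect_equal(ct$plsb_total, m$totals$PlsB)
})

test_that("acyltransferase fluxes follow the cycle rate laws", {
  m <- baseline_model()
  y <- initial_state(m)
  y["PlsB"] <- 0; y["C16:0_ACP"] <- 5
  fl <- acyltransferase_fluxes(m, y, "PlsB")
  expect_equal(fl$bind, rep(0, 6))     # no free enzyme, no binding
  # phospholipid feedback half-point: PL_total = k_pl_feedback, hill = 1
  m2 <- build_model(list(plsb = list(pl_hill = 1)))
  y <- initial_state(m2)
  y["PlsB.C16:0_ACP"] <- 0.5; y["PlsB"] <- 0.5
  f0 <- acyltransferase_fluxes(m2, y, "PlsB")
  y["PL_C16:0_C16:1"] <- m2$params$plsb$k_pl_feedback
  f1 <- acyltransferase_fluxes(m2, y, "PlsB")
  i <- match("C16:0_ACP", f1$substrate)
  expect_equal(f1$catalyze[i], f0$catalyze[i] / 2, tolerance = 1e-12)
})
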