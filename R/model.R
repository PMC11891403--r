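# Model assembly: species inventory, reaction network, stoichiometry, RHS.
#
# The network follows the simplified pathway used for the feeding simulations:
# a single lumped ACC-FabD initiation reaction (holo-ACP + acetyl-CoA ->
# malonyl-ACP) under noncompetitive feedback inhibition by free long-chain
# acyl-ACP; FabH condensation starting the chain at C4:0-ACP; a generic
# elongation reaction per C2 step with chain-length preference weights; a
# branch point at C10:0-ACP with two parallel consuming reactions (continued
# saturated elongation vs. isomerization into the unsaturated precursor
# C10:1-ACP); explicit bind/unbind/catalysis cycles for every PlsB and PlsC
# substrate (acyl-ACP and acyl-CoA compete for the free enzyme); a lumped
# PA -> PL conversion; and first-order growth dilution of the lipid pools so
# that a genuine pre-feeding steady state exists.

#' Default model parameters
#'
#' Complete parameter set of the pathway model, in µM and seconds. These are
#' the package's documented defaults, calibrated so that the pre-feeding
#' steady state has a PlsB acyl-ACP substrate-pool C16:0 fraction of about
#' 0.8 with minor C18:0, and so that the simulated feeding responses land in
#' the experimentally reported fold-change ranges.
#'
#' Sections:
#' \describe{
#' \item{totals}{conserved moiety totals (µM) for ACP, PlsB, PlsC}
#' \item{clamps}{boundary species held constant: acetyl-CoA, G3P, and the
#'   three acyl-CoA species (0 before feeding)}
#' \item{acc}{lumped ACC-FabD reaction: `vmax` (µM/s), `km_acp`, `km_accoa`
#'   (µM), feedback `ki` (µM total free long-chain acyl-ACP at
#'   half-inhibition) and Hill coefficient `hill`}
#' \item{fabh}{FabH condensation (malonyl-ACP + acetyl-CoA -> C4:0-ACP)}
#' \item{elongation}{generic condensation step Cn -> Cn+2 consuming
#'   malonyl-ACP and releasing holo-ACP; `weights` scale vmax per product
#'   chain and encode the combined FabB/FabF chain-length preference (small
#'   weights stop elongation past C16)}
#' \item{branch}{isomerization C10:0-ACP -> C10:1-ACP committing flux to the
#'   unsaturated pathway}
#' \item{plsb, plsc}{acyltransferase cycles: per-substrate `kon`
#'   (µM^-1 s^-1) and `koff` (s^-1), catalytic `kcat` (s^-1), acceptor Km;
#'   PlsB additionally carries the phospholipid feedback (`k_pl_feedback`
#'   µM, `pl_hill`). Disfavored substrates (C16:1 for PlsB, C16:0 for PlsC)
#'   have kon reduced `kon_disfavor_factor`-fold}
#' \item{lipid}{first-order PA -> PL conversion `k_pa_pl` (s^-1) and growth
#'   dilution `mu` (s^-1) of LPA/PA/PL}
#' \item{feeding}{named fatty acid -> clamped acyl-CoA species map, default
#'   post-step clamp values (µM), and step time `t_step` (s)}
#' \item{solver}{integrator tolerances}
#' }
#'
#' @return nested named list of parameters
#' @export
fa_default_params <- function() {
  kon_b <- c("C16:0_ACP" = 7, "C16:1_ACP" = 0.4, "C18:1_ACP" = 1.5,
             "C16:0_CoA" = 6, "C16:1_CoA" = 0.4, "C18:1_CoA" = 14)
  kon_c <- c("C16:0_ACP" = 0.27, "C16:1_ACP" = 4, "C18:1_ACP" = 7,
             "C16:0_CoA" = 0.27, "C16:1_CoA" = 6, "C18:1_CoA" = 7.5)
  koff  <- c("C16:0_ACP" = 20, "C16:1_ACP" = 20, "C18:1_ACP" = 20,
             "C16:0_CoA" = 20, "C16:1_CoA" = 20, "C18:1_CoA" = 20)
  w_sat   <- c("C6:0" = 1, "C8:0" = 1, "C10:0" = 1, "C12:0" = 1,
               "C14:0" = 1, "C16:0" = 1, "C18:0" = 0.0008)
  w_unsat <- c("C12:1" = 1, "C14:1" = 1, "C16:1" = 1, "C18:1" = 0.054)
  list(
    totals = list(ACP = 200, PlsB = 1, PlsC = 1),
    clamps = list(acetyl_CoA = 500, G3P = 200,
                  "C16:0_CoA" = 0, "C16:1_CoA" = 0, "C18:1_CoA" = 0),
    acc   = list(vmax = 45, km_acp = 10, km_accoa = 100, ki = 1.1, hill = 2),
    fabh  = list(vmax = 30, km_malonyl = 20, km_accoa = 100),
    elongation = list(vmax = 12, km_acyl = 5, km_malonyl = 0.5,
                      weights = as.list(c(w_sat, w_unsat)),
                      # per-substrate-chain Km overrides; the C16:1 step runs
                      # near substrate saturation so malonyl-ACP demand is
                      # buffered against swings of the C16:1 pool
                      km_by_chain = list("C16:1" = 0.15)),
    branch = list(vmax = 8, km = 5),
    plsb  = list(kcat = 7, km_g3p = 10, kon = as.list(kon_b),
                 koff = as.list(koff), k_pl_feedback = 2000, pl_hill = 4),
    plsc  = list(kcat = 7, km_lpa = 5, kon = as.list(kon_c),
                 koff = as.list(koff)),
    lipid = list(k_pa_pl = 0.01, mu = log(2) / 2500),
    turnover = list(k_c18 = 0.01),
    feeding = list(t_step = 8000,
                   map = list(palmitate = "C16:0_CoA",
                              palmitoleate = "C16:1_CoA",
                              "cis-vaccenate" = "C18:1_CoA"),
                   clamp_values = list("C16:0_CoA" = 20,
                                       "C16:1_CoA" = 8,
                                       "C18:1_CoA" = 12)),
    solver = list(rtol = 1e-9, atol = 1e-13)
  )
}

# recursive override of defaults; unknown keys are rejected by full path
merge_params <- function(defaults, config, path = character()) {
  if (is.null(config)) return(defaults)
  if (!is.list(config)) {
    stop_acylsim("config", "configuration section '",
                 paste(path, collapse = "$"), "' must be a named list")
  }
  nm <- names(config)
  if (length(config) && (is.null(nm) || any(nm == ""))) {
    stop_acylsim("config", "unnamed entry in configuration section '",
                 paste(path, collapse = "$"), "'")
  }
  for (k in nm) {
    here <- paste(c(path, k), collapse = "$")
    if (!k %in% names(defaults)) {
      stop_acylsim("config", "unknown configuration key '", here, "'")
    }
    if (is.list(defaults[[k]])) {
      defaults[[k]] <- merge_params(defaults[[k]], config[[k]], c(path, k))
    } else {
      v <- config[[k]]
      want_chr <- is.character(defaults[[k]])
      ok <- length(v) == 1L && !is.null(v) && !is.na(v) &&
        (if (want_chr) is.character(v) else is.numeric(v))
      if (!ok) {
        stop_acylsim("config", "configuration parameter '", here,
                     "' must be a single ",
                     if (want_chr) "string" else "number")
      }
      defaults[[k]] <- v
    }
  }
  defaults
}

at_substrates <- function() {
  subs <- c(paste0(AT_CHAINS, "_ACP"), paste0(AT_CHAINS, "_CoA"))
  data.frame(id = subs,
             chain = rep(AT_CHAINS, 2),
             is_acp = rep(c(TRUE, FALSE), each = length(AT_CHAINS)),
             stringsAsFactors = FALSE)
}

pa_pairs <- function() {
  g <- expand.grid(sn2 = AT_CHAINS, sn1 = AT_CHAINS,
                   stringsAsFactors = FALSE)[, c("sn1", "sn2")]
  g[order(g$sn1, g$sn2), , drop = FALSE]
}

#' Assemble the pathway model
#'
#' Builds the full reaction network (species, stoichiometry matrix, rate-law
#' bindings, clamped set, conserved totals) from the default parameters,
#' optionally overridden by a configuration. Unknown configuration keys and
#' non-numeric parameter values are rejected with an error naming the key.
#'
#' @param config partial parameter override (nested list with the structure
#'   of [fa_default_params()]), a path to a YAML file with a `model:` section
#'   or such a section itself, or `NULL` for the defaults
#' @return an object of class `fa_model`: list with elements `species`,
#'   `stoich` (species x reaction matrix), `rx` (reaction metadata for
#'   introspection), `clamped`, `totals`, `params`, plus internal index
#'   caches used by [rhs()]
#' @examples
#' m <- build_model()
#' length(m$species)
#' m$clamped
#' @export
build_model <- function(config = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- load_config(config)$model
  }
  p <- merge_params(fa_default_params(), config)
  validate_params(p)

  sat_acp   <- paste0(SAT_CHAINS, "_ACP")
  unsat_acp <- paste0(UNSAT_CHAINS, "_ACP")
  at <- at_substrates()
  cplx_b <- paste0("PlsB.", at$id)
  cplx_c <- paste0("PlsC.", at$id)
  lpa <- paste0("LPA_", AT_CHAINS)
  pp  <- pa_pairs()
  pa  <- paste0("PA_", pp$sn1, "_", pp$sn2)
  pl  <- paste0("PL_", pp$sn1, "_", pp$sn2)

  species <- c("ACP", "malonyl_ACP", sat_acp, unsat_acp,
               "acetyl_CoA", "G3P", paste0(COA_CHAINS, "_CoA"),
               "PlsB", "PlsC", cplx_b, cplx_c, lpa, pa, pl)
  stopifnot(!anyDuplicated(species))
  ns <- length(species)
  si <- stats::setNames(seq_len(ns), species)

  rx <- list()
  cols <- list()
  add <- function(name, kind, stoich, substrates, products, zero = FALSE) {
    col <- numeric(ns)
    col[si[names(stoich)]] <- stoich
    rx[[length(rx) + 1L]] <<- list(name = name, kind = kind,
                                   substrates = substrates,
                                   products = products, zero = zero)
    cols[[length(cols) + 1L]] <<- col
  }

  add("acc_fabd", "acc",
      c("ACP" = -1, "acetyl_CoA" = -1, "malonyl_ACP" = 1),
      c("ACP", "acetyl_CoA"), "malonyl_ACP")
  add("fabh", "fabh",
      c("malonyl_ACP" = -1, "acetyl_CoA" = -1, "C4:0_ACP" = 1),
      c("malonyl_ACP", "acetyl_CoA"), "C4:0_ACP")

  w <- p$elongation$weights
  sat_steps <- data.frame(sub = paste0(SAT_CHAINS[-8], "_ACP"),
                          prod = paste0(SAT_CHAINS[-1], "_ACP"),
                          w = unlist(w[SAT_CHAINS[-1]]),
                          stringsAsFactors = FALSE)
  for (i in seq_len(nrow(sat_steps))) {
    add(paste0("elong_", SAT_CHAINS[-1][i]), "elong",
        stats::setNames(c(-1, -1, 1, 1),
                        c(sat_steps$sub[i], "malonyl_ACP",
                          sat_steps$prod[i], "ACP")),
        c(sat_steps$sub[i], "malonyl_ACP"),
        c(sat_steps$prod[i], "ACP"),
        zero = sat_steps$w[i] == 0)
  }
  add("branch_unsat", "branch",
      c("C10:0_ACP" = -1, "C10:1_ACP" = 1),
      "C10:0_ACP", "C10:1_ACP")
  unsat_steps <- data.frame(sub = paste0(UNSAT_CHAINS[-5], "_ACP"),
                            prod = paste0(UNSAT_CHAINS[-1], "_ACP"),
                            w = unlist(w[UNSAT_CHAINS[-1]]),
                            stringsAsFactors = FALSE)
  for (i in seq_len(nrow(unsat_steps))) {
    add(paste0("elong_", UNSAT_CHAINS[-1][i]), "elong",
        stats::setNames(c(-1, -1, 1, 1),
                        c(unsat_steps$sub[i], "malonyl_ACP",
                          unsat_steps$prod[i], "ACP")),
        c(unsat_steps$sub[i], "malonyl_ACP"),
        c(unsat_steps$prod[i], "ACP"),
        zero = unsat_steps$w[i] == 0)
  }

  for (i in seq_len(nrow(at))) {  # PlsB cycle
    s <- at$id[i]; cx <- cplx_b[i]
    add(paste0("bind_PlsB_", s), "bind",
        stats::setNames(c(-1, -1, 1), c("PlsB", s, cx)),
        c("PlsB", s), cx)
    add(paste0("unbind_PlsB_", s), "unbind",
        stats::setNames(c(1, 1, -1), c("PlsB", s, cx)),
        cx, c("PlsB", s))
    prod <- c(paste0("LPA_", at$chain[i]), "PlsB", if (at$is_acp[i]) "ACP")
    st <- stats::setNames(c(-1, -1, rep(1, length(prod))),
                          c(cx, "G3P", prod))
    add(paste0("cat_PlsB_", s), "cat_b", st, c(cx, "G3P"), prod)
  }
  for (i in seq_len(nrow(at))) {  # PlsC cycle
    s <- at$id[i]; cx <- cplx_c[i]
    add(paste0("bind_PlsC_", s), "bind",
        stats::setNames(c(-1, -1, 1), c("PlsC", s, cx)),
        c("PlsC", s), cx)
    add(paste0("unbind_PlsC_", s), "unbind",
        stats::setNames(c(1, 1, -1), c("PlsC", s, cx)),
        cx, c("PlsC", s))
    for (l in AT_CHAINS) {
      pa_sp <- paste0("PA_", l, "_", at$chain[i])
      prod <- c(pa_sp, "PlsC", if (at$is_acp[i]) "ACP")
      st <- stats::setNames(c(-1, -1, rep(1, length(prod))),
                            c(cx, paste0("LPA_", l), prod))
      add(paste0("cat_PlsC_", s, "_", l), "cat_c", st,
          c(cx, paste0("LPA_", l)), prod)
    }
  }
  for (i in seq_along(pa)) {
    add(paste0("pa_to_pl_", substr(pa[i], 4, 100)), "pa_pl",
        stats::setNames(c(-1, 1), c(pa[i], pl[i])), pa[i], pl[i])
  }
  for (s in c(lpa, pa, pl)) {
    add(paste0("dil_", s), "dil", stats::setNames(-1, s), s, character())
  }
  # C18:0-ACP is not an acyltransferase substrate; a slow thioesterase-like
  # hydrolysis returns its ACP so the terminal saturated pool has a sink and
  # a genuine pre-feeding steady state exists
  add("turnover_C18:0", "turnover",
      c("C18:0_ACP" = -1, "ACP" = 1), "C18:0_ACP", "ACP")

  stoich <- do.call(cbind, cols)
  dimnames(stoich) <- list(species, vapply(rx, `[[`, "", "name"))

  clamped <- c("acetyl_CoA", "G3P", paste0(COA_CHAINS, "_CoA"))

  is_acp_weight <- function(sp) {
    sp == "ACP" | sp == "malonyl_ACP" | grepl("_ACP$", sp) |
      grepl("^Pls[BC]\\.C[0-9]+:[01]_ACP$", sp)
  }
  w_acp  <- as.numeric(is_acp_weight(species))
  w_plsb <- as.numeric(species == "PlsB" | startsWith(species, "PlsB."))
  w_plsc <- as.numeric(species == "PlsC" | startsWith(species, "PlsC."))

  kinds <- vapply(rx, `[[`, "", "kind")
  idx <- list(
    acp = si[["ACP"]], mal = si[["malonyl_ACP"]],
    accoa = si[["acetyl_CoA"]], g3p = si[["G3P"]],
    plsb = si[["PlsB"]], plsc = si[["PlsC"]],
    lc = unname(si[paste0(LONG_CHAINS, "_ACP")]),
    sat_sub = unname(si[sat_steps$sub]),
    unsat_sub = unname(si[unsat_steps$sub]),
    c10 = si[["C10:0_ACP"]],
    b_sub = unname(si[at$id]), b_cplx = unname(si[cplx_b]),
    c_cplx = unname(si[cplx_c]),
    lpa = unname(si[lpa]), pa = unname(si[pa]), pl = unname(si[pl]),
    r_acc = which(kinds == "acc"), r_fabh = which(kinds == "fabh"),
    r_sat = which(names(rx) %in% character()) # placeholder replaced below
  )
  rn <- vapply(rx, `[[`, "", "name")
  idx$r_sat    <- match(paste0("elong_", SAT_CHAINS[-1]), rn)
  idx$r_branch <- match("branch_unsat", rn)
  idx$r_unsat  <- match(paste0("elong_", UNSAT_CHAINS[-1]), rn)
  idx$r_bind_b   <- match(paste0("bind_PlsB_", at$id), rn)
  idx$r_unbind_b <- match(paste0("unbind_PlsB_", at$id), rn)
  idx$r_cat_b    <- match(paste0("cat_PlsB_", at$id), rn)
  idx$r_bind_c   <- match(paste0("bind_PlsC_", at$id), rn)
  idx$r_unbind_c <- match(paste0("unbind_PlsC_", at$id), rn)
  cat_c_names <- as.vector(t(outer(at$id, AT_CHAINS,
                                   function(s, l) paste0("cat_PlsC_", s, "_", l))))
  idx$r_cat_c <- match(cat_c_names, rn)   # sub-major, sn1-minor
  idx$r_pa_pl <- which(kinds == "pa_pl")
  idx$r_dil   <- which(kinds == "dil")
  idx$dil_sp  <- unname(si[c(lpa, pa, pl)])
  idx$r_turn  <- which(kinds == "turnover")
  idx$c18     <- si[["C18:0_ACP"]]

  m <- structure(list(
    species = species, stoich = stoich, rx = rx,
    clamped = clamped, iclamp = unname(si[clamped]),
    totals = p$totals, params = p,
    w_acp = w_acp, w_plsb = w_plsb, w_plsc = w_plsc,
    w_sat = unname(sat_steps$w), w_unsat = unname(unsat_steps$w),
    km_sat = step_km(p, SAT_CHAINS[-8]), km_unsat = step_km(p, UNSAT_CHAINS[-5]),
    at = at, pa_pairs = pp, idx = idx, si = si, nr = length(rx)
  ), class = "fa_model")
  m
}

# elongation Km per substrate chain (scalar km_acyl with per-chain overrides)
step_km <- function(p, sub_chains) {
  km <- rep(p$elongation$km_acyl, length(sub_chains))
  ov <- p$elongation$km_by_chain
  hit <- match(names(ov), sub_chains)
  km[hit[!is.na(hit)]] <- unlist(ov)[!is.na(hit)]
  km
}

validate_params <- function(p) {
  pos <- function(x, name) {
    if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
      stop_acylsim("config", "parameter '", name, "' must be positive")
    }
  }
  pos(unlist(p$totals), "totals")
  pos(unlist(p$acc), "acc"); pos(unlist(p$fabh), "fabh")
  pos(p$elongation$vmax, "elongation$vmax")
  pos(p$elongation$km_acyl, "elongation$km_acyl")
  pos(p$elongation$km_malonyl, "elongation$km_malonyl")
  pos(unlist(p$elongation$km_by_chain), "elongation$km_by_chain")
  wts <- unlist(p$elongation$weights)
  if (any(wts < 0) || any(wts > 1)) {
    stop_acylsim("config", "elongation weights must lie in [0, 1]")
  }
  pos(unlist(p$branch), "branch")
  pos(unlist(p$plsb), "plsb"); pos(unlist(p$plsc), "plsc")
  pos(unlist(p$lipid), "lipid")
  pos(unlist(p$turnover), "turnover")
  if (any(unlist(p$clamps) < 0)) {
    stop_acylsim("config", "clamp concentrations must be >= 0")
  }
  kon_b <- unlist(p$plsb$kon); kon_c <- unlist(p$plsc$kon)
  if (!(kon_b[["C16:1_ACP"]] < kon_b[["C16:0_ACP"]] &&
        kon_b[["C16:1_CoA"]] < kon_b[["C18:1_CoA"]])) {
    stop_acylsim("config",
                 "PlsB kon for disfavored C16:1 substrates must be below the favored substrates")
  }
  if (!(kon_c[["C16:0_ACP"]] < kon_c[["C16:1_ACP"]] &&
        kon_c[["C16:0_CoA"]] < kon_c[["C18:1_CoA"]])) {
    stop_acylsim("config",
                 "PlsC kon for disfavored C16:0 substrates must be below the favored substrates")
  }
  invisible(p)
}

# rate vector for the full network; y is the unnamed state in model species
# order. Negative excursions from the solver are clipped for rate evaluation
# only (stoichiometric conservation is unaffected).
reaction_rates <- function(y, m) {
  p <- m$params; ix <- m$idx
  yc <- pmax(y, 0)
  v <- numeric(m$nr)

  lc <- sum(yc[ix$lc])
  accoa_fac <- yc[ix$accoa]
  v[ix$r_acc] <- p$acc$vmax *
    (yc[ix$acp] / (p$acc$km_acp + yc[ix$acp])) *
    (accoa_fac / (p$acc$km_accoa + accoa_fac)) /
    (1 + (lc / p$acc$ki)^p$acc$hill)
  mal <- yc[ix$mal]
  v[ix$r_fabh] <- p$fabh$vmax *
    (mal / (p$fabh$km_malonyl + mal)) *
    (accoa_fac / (p$fabh$km_accoa + accoa_fac))

  malfac <- mal / (p$elongation$km_malonyl + mal)
  e <- p$elongation
  v[ix$r_sat] <- m$w_sat * e$vmax * malfac *
    yc[ix$sat_sub] / (m$km_sat + yc[ix$sat_sub])
  v[ix$r_branch] <- p$branch$vmax * yc[ix$c10] / (p$branch$km + yc[ix$c10])
  v[ix$r_unsat] <- m$w_unsat * e$vmax * malfac *
    yc[ix$unsat_sub] / (m$km_unsat + yc[ix$unsat_sub])

  kon_b <- unlist(p$plsb$kon); koff_b <- unlist(p$plsb$koff)
  kon_c <- unlist(p$plsc$kon); koff_c <- unlist(p$plsc$koff)
  v[ix$r_bind_b]   <- kon_b * yc[ix$plsb] * yc[ix$b_sub]
  v[ix$r_unbind_b] <- koff_b * yc[ix$b_cplx]
  pl_tot <- sum(yc[ix$pl])
  fpl <- 1 / (1 + (pl_tot / p$plsb$k_pl_feedback)^p$plsb$pl_hill)
  g3p <- yc[ix$g3p]
  v[ix$r_cat_b] <- p$plsb$kcat * yc[ix$b_cplx] *
    (g3p / (p$plsb$km_g3p + g3p)) * fpl

  v[ix$r_bind_c]   <- kon_c * yc[ix$plsc] * yc[ix$b_sub]
  v[ix$r_unbind_c] <- koff_c * yc[ix$c_cplx]
  lpa <- yc[ix$lpa]
  lpa_tot <- sum(lpa)
  # competitive acceptor partition over LPA species (sub-major order)
  v[ix$r_cat_c] <- p$plsc$kcat *
    rep(yc[ix$c_cplx], each = length(lpa)) *
    rep(lpa, times = length(ix$c_cplx)) / (p$plsc$km_lpa + lpa_tot)

  v[ix$r_pa_pl] <- p$lipid$k_pa_pl * yc[ix$pa]
  v[ix$r_dil]   <- p$lipid$mu * yc[ix$dil_sp]
  v[ix$r_turn]  <- p$turnover$k_c18 * yc[ix$c18]
  v
}

rhs_raw <- function(y, m) {
  dy <- as.vector(m$stoich %*% reaction_rates(y, m))
  dy[m$iclamp] <- 0
  dy
}

#' Time derivative of the state
#'
#' Evaluates the full network right-hand side for a complete named state.
#' Clamped species (acetyl-CoA, G3P, acyl-CoA) have derivative exactly zero;
#' ACP-, PlsB- and PlsC-weighted derivative sums vanish by construction of
#' the stoichiometry.
#'
#' @param state named numeric vector over all model species (µM)
#' @param model an `fa_model`
#' @return named derivative vector (µM/s)
#' @export
rhs <- function(state, model) {
  y <- check_state(state, model)
  stats::setNames(rhs_raw(y, model), model$species)
}

check_state <- function(state, model) {
  if (is.null(names(state)) || !setequal(names(state), model$species)) {
    missing <- setdiff(model$species, names(state))
    extra <- setdiff(names(state), model$species)
    stop_acylsim("state",
                 "state must be named over all model species",
                 if (length(missing)) paste0("; missing: ",
                                             paste(utils::head(missing, 5), collapse = ", ")),
                 if (length(extra)) paste0("; unknown: ",
                                           paste(utils::head(extra, 5), collapse = ", ")))
  }
  unname(state[model$species])
}

#' Conserved moiety totals
#'
#' Sums the ACP moiety (holo-ACP, malonyl-ACP, free acyl-ACP, and
#' enzyme-bound acyl-ACP in PlsB/PlsC complexes) and the PlsB and PlsC
#' moieties (free enzyme plus all complexes). These totals are invariant
#' along any trajectory.
#'
#' @inheritParams rhs
#' @return list with `acp_total`, `plsb_total`, `plsc_total` (µM)
#' @export
conserved_totals <- function(state, model) {
  y <- check_state(state, model)
  list(acp_total = sum(y * model$w_acp),
       plsb_total = sum(y * model$w_plsb),
       plsc_total = sum(y * model$w_plsc))
}

#' Initial state of the model
#'
#' All ACP starts as holo-ACP, both acyltransferases start free, lipid pools
#' start empty, and clamped species sit at their clamp values.
#'
#' @param model an `fa_model`
#' @return named state vector (µM)
#' @export
initial_state <- function(model) {
  y <- stats::setNames(numeric(length(model$species)), model$species)
  y["ACP"] <- model$totals$ACP
  y["PlsB"] <- model$totals$PlsB
  y["PlsC"] <- model$totals$PlsC
  for (s in names(model$params$clamps)) y[s] <- model$params$clamps[[s]]
  y
}

#' Acyltransferase cycle fluxes
#'
#' Per-substrate bind, unbind and catalysis fluxes of one acyltransferase at
#' a given state: bind = kon [E][S], unbind = koff [ES], catalysis =
#' kcat [ES] x acceptor saturation (x phospholipid feedback for PlsB).
#'
#' @param model an `fa_model`
#' @param state named state vector
#' @param enzyme `"PlsB"` or `"PlsC"`
#' @return data.frame with columns `substrate`, `bind`, `unbind`, `catalyze`
#'   (µM/s); for PlsC, `catalyze` is summed over LPA acceptors
#' @export
acyltransferase_fluxes <- function(model, state, enzyme = c("PlsB", "PlsC")) {
  enzyme <- match.arg(enzyme)
  y <- check_state(state, model)
  v <- reaction_rates(y, model)
  ix <- model$idx
  if (enzyme == "PlsB") {
    data.frame(substrate = model$at$id,
               bind = v[ix$r_bind_b], unbind = v[ix$r_unbind_b],
               catalyze = v[ix$r_cat_b], stringsAsFactors = FALSE)
  } else {
    cat_tot <- rowSums(matrix(v[ix$r_cat_c], nrow = nrow(model$at),
                              byrow = TRUE))
    data.frame(substrate = model$at$id,
               bind = v[ix$r_bind_c], unbind = v[ix$r_unbind_c],
               catalyze = cat_tot, stringsAsFactors = FALSE)
  }
}

#' Remove the ACC feedback at a fixed operating point
#'
#' Returns a model with the long-chain acyl-ACP feedback on ACC-FabD removed
#' (`ki = Inf`) and the ACC vmax rescaled by the inhibition factor prevailing
#' at `state`, so the given steady state is preserved. This isolates the
#' feedback mechanism: any malonyl-ACP response to an acyl-CoA step that
#' survives in the knockout model flows through routes other than ACC
#' inhibition (holo-ACP sequestration, elongation demand shifts).
#'
#' @param model an `fa_model`
#' @param state operating state (normally the pre-feeding steady state)
#' @return an `fa_model` with feedback removed
#' @export
remove_acc_feedback <- function(model, state) {
  y <- check_state(state, model)
  lc <- sum(y[model$idx$lc])
  pars <- model$params
  factor <- 1 / (1 + (lc / pars$acc$ki)^pars$acc$hill)
  pars$acc$vmax <- pars$acc$vmax * factor
  pars$acc$ki <- 1e30
  build_model(pars)
}

#' @export
print.fa_model <- function(x, ...) {
  cat("<fa_model>", length(x$species), "species,", x$nr, "reactions\n")
  cat("  clamped:", paste(x$clamped, collapse = ", "), "\n")
  cat("  totals (uM): ACP", x$totals$ACP, "| PlsB", x$totals$PlsB,
      "| PlsC", x$totals$PlsC, "\n")
  invisible(x)
}
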