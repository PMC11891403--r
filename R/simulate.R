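# Steady state, feeding step, and time-course integration (deSolve/lsoda).

desolve_func <- function(model) {
  force(model)
  function(t, y, parms) list(rhs_raw(y, model))
}

integrate_grid <- function(model, y0, times, rtol, atol) {
  out <- deSolve::lsoda(y = stats::setNames(unname(y0), model$species),
                        times = times, func = desolve_func(model),
                        parms = NULL, rtol = rtol, atol = atol,
                        maxsteps = 200000)
  if (attr(out, "istate")[1] < 0) {
    stop_acylsim("solver", "integration failed over [",
                 times[1], ", ", times[length(times)], "] s (istate ",
                 attr(out, "istate")[1], ")")
  }
  out
}

steady_residual <- function(state, model, atol = 1e-6) {
  y <- check_state(state, model)
  dy <- rhs_raw(y, model)
  keep <- setdiff(seq_along(y), model$iclamp)
  max(abs(dy[keep]) / (abs(y[keep]) + atol))
}

#' Integrate to steady state
#'
#' Runs the model forward in growing time chunks until the maximum relative
#' rate of change of every non-clamped species falls below `tol`
#' (residual \eqn{\max_i |dx_i/dt| / (|x_i| + 10^{-6})}). Deterministic for
#' fixed inputs.
#'
#' @param model an `fa_model`
#' @param state0 starting state; defaults to [initial_state()]
#' @param t_max maximum total integration time (s) before giving up
#' @param tol steady-state residual tolerance (relative rate, 1/s)
#' @return named steady state vector with attributes `residual` and
#'   `t_elapsed`
#' @export
find_steady_state <- function(model, state0 = initial_state(model),
                              t_max = 4e5, tol = 1e-8) {
  y <- check_state(state0, model)
  rtol <- model$params$solver$rtol
  atol <- model$params$solver$atol
  t <- 0; dt <- 4000
  repeat {
    res <- steady_residual(stats::setNames(y, model$species), model)
    if (res < tol) break
    if (t >= t_max) {
      stop_acylsim("no_convergence",
                   sprintf("steady state not reached by t = %g s (residual %.3g, tol %.3g)",
                           t_max, res, tol))
    }
    dt <- min(dt * 2, t_max - t)
    out <- integrate_grid(model, y, c(0, dt), rtol, atol)
    y <- as.numeric(out[nrow(out), -1])
    t <- t + dt
  }
  structure(stats::setNames(y, model$species),
            residual = res, t_elapsed = t)
}

#' Feeding protocol
#'
#' Describes an exogenous fatty-acid feeding experiment as a stepwise clamp:
#' at `t_step` the fed acyl-CoA species jumps to `clamp_value` and is held
#' there (the extracellular fatty-acid reservoir is large relative to
#' consumption).
#'
#' @param fed_species one of `"C16:0_CoA"`, `"C16:1_CoA"`, `"C18:1_CoA"`
#' @param clamp_value post-step concentration (µM), >= 0
#' @param t_step step time (s)
#' @return object of class `feeding_protocol`
#' @export
feeding_protocol <- function(fed_species, clamp_value,
                             t_step = fa_default_params()$feeding$t_step) {
  if (!fed_species %in% paste0(COA_CHAINS, "_CoA")) {
    stop_acylsim("protocol", "fed_species must be one of ",
                 paste(paste0(COA_CHAINS, "_CoA"), collapse = ", "))
  }
  if (!is.numeric(clamp_value) || length(clamp_value) != 1L ||
      clamp_value < 0) {
    stop_acylsim("protocol", "clamp_value must be a single number >= 0")
  }
  structure(list(fed_species = fed_species, clamp_value = clamp_value,
                 t_step = t_step), class = "feeding_protocol")
}

#' Apply the feeding step
#'
#' Sets the fed species' clamp to its post-step value. All other species are
#' left untouched, so the state is continuous at the step.
#'
#' @param model an `fa_model`
#' @param state pre-step state (normally the pre-step steady state)
#' @param protocol a [feeding_protocol()]
#' @return list with updated `model` (clamp bookkeeping) and `state`
#' @export
apply_feeding_step <- function(model, state, protocol) {
  if (!protocol$fed_species %in% model$clamped) {
    stop_acylsim("protocol", "species '", protocol$fed_species,
                 "' is not clampable in this model")
  }
  y <- stats::setNames(check_state(state, model), model$species)
  y[protocol$fed_species] <- protocol$clamp_value
  model$params$clamps[[protocol$fed_species]] <- protocol$clamp_value
  list(model = model, state = y)
}

#' Integrate a time course
#'
#' Integrates the model over an ascending time grid, optionally applying a
#' feeding step: the integration is split at `protocol$t_step`, the clamp is
#' applied, and integration restarts exactly at the step time.
#'
#' @param model an `fa_model`
#' @param state0 state at `t_grid[1]`
#' @param t_grid strictly increasing times (s)
#' @param protocol optional [feeding_protocol()] with
#'   `t_grid[1] <= t_step <= max(t_grid)`
#' @return object of class `fa_trajectory`: list with `times`, `states`
#'   (time x species matrix), `protocol`, `baseline` (state at the last
#'   pre-step time, or `state0` without a protocol)
#' @export
simulate_timecourse <- function(model, state0, t_grid, protocol = NULL) {
  if (is.unsorted(t_grid, strictly = TRUE)) {
    stop_acylsim("grid", "t_grid must be strictly increasing")
  }
  y0 <- check_state(state0, model)
  rtol <- model$params$solver$rtol
  atol <- model$params$solver$atol
  if (is.null(protocol)) {
    out <- integrate_grid(model, y0, t_grid, rtol, atol)
    states <- out[, -1, drop = FALSE]
    baseline <- stats::setNames(y0, model$species)
  } else {
    ts <- protocol$t_step
    if (t_grid[1] > ts || max(t_grid) < ts) {
      stop_acylsim("protocol",
                   "t_step must lie within the time grid")
    }
    pre_t <- c(t_grid[t_grid <= ts], if (!ts %in% t_grid) ts)
    pre_t <- sort(unique(pre_t))
    if (length(pre_t) == 1L) {
      pre <- matrix(y0, nrow = 1, dimnames = list(NULL, model$species))
    } else {
      out <- integrate_grid(model, y0, pre_t, rtol, atol)
      pre <- out[, -1, drop = FALSE]
    }
    y_step <- stats::setNames(as.numeric(pre[nrow(pre), ]), model$species)
    baseline <- y_step
    stepped <- apply_feeding_step(model, y_step, protocol)
    post_t <- c(ts, t_grid[t_grid > ts])
    out2 <- integrate_grid(stepped$model, stepped$state, post_t, rtol, atol)
    post <- out2[, -1, drop = FALSE]
    keep_pre <- pre_t %in% t_grid & pre_t < ts
    keep_post <- post_t %in% t_grid
    states <- rbind(pre[keep_pre, , drop = FALSE],
                    post[keep_post, , drop = FALSE])
  }
  colnames(states) <- model$species
  structure(list(times = t_grid, states = states, protocol = protocol,
                 baseline = baseline, model = model),
            class = "fa_trajectory")
}

#' Run a named feeding experiment
#'
#' Full pipeline for one simulated experiment: integrate to the pre-feeding
#' steady state, hold it over a pre-step window, apply the stepwise acyl-CoA
#' clamp matching the named fatty acid (palmitate -> C16:0-CoA,
#' palmitoleate -> C16:1-CoA, cis-vaccenate -> C18:1-CoA), and follow the
#' response. The post-step grid resolves the fast (~1 min) response: 10 s
#' spacing for the first 10 min, then 60 s.
#'
#' @param model an `fa_model`
#' @param fatty_acid `"palmitate"`, `"palmitoleate"` or `"cis-vaccenate"`;
#'   `"none"` runs a null feeding (clamp held at its baseline value)
#' @param clamp_value post-step acyl-CoA concentration (µM); default from the
#'   model's feeding configuration
#' @param post_window length of the post-step window (s), >= 3600
#' @param steady_state optional precomputed pre-step steady state (skips the
#'   steady-state search; must come from the same model)
#' @return `fa_trajectory` with attribute `t_step`; times in the trajectory
#'   are absolute, [trajectory_df()] reports them relative to the step
#' @export
run_feeding_experiment <- function(model,
                                   fatty_acid = c("palmitate", "palmitoleate",
                                                  "cis-vaccenate", "none"),
                                   clamp_value = NULL,
                                   post_window = 3600,
                                   steady_state = NULL) {
  fatty_acid <- match.arg(fatty_acid)
  feeding <- model$params$feeding
  if (fatty_acid == "none") {
    fed <- "C16:0_CoA"
    clamp_value <- model$params$clamps[[fed]]
  } else {
    fed <- feeding$map[[fatty_acid]]
    if (is.null(clamp_value)) clamp_value <- feeding$clamp_values[[fed]]
  }
  ts <- feeding$t_step
  ss <- if (is.null(steady_state)) find_steady_state(model) else steady_state
  prot <- feeding_protocol(fed, clamp_value, t_step = ts)
  t_grid <- sort(unique(c(seq(0, ts, by = 200),
                          ts + seq(10, min(600, post_window), by = 10),
                          if (post_window > 600)
                            ts + seq(660, post_window, by = 60))))
  traj <- simulate_timecourse(model, ss, t_grid, prot)
  attr(traj, "t_step") <- ts
  attr(traj, "fatty_acid") <- fatty_acid
  traj
}

#' Tidy view of a trajectory
#'
#' @param traj an `fa_trajectory`
#' @param relative report times relative to the feeding step (if any)
#' @return data.frame with columns `time_s`, `species`, `concentration_uM`
#' @export
trajectory_df <- function(traj, relative = FALSE) {
  t0 <- if (relative && !is.null(traj$protocol)) traj$protocol$t_step else 0
  data.frame(
    time_s = rep(traj$times - t0, times = ncol(traj$states)),
    species = rep(colnames(traj$states), each = length(traj$times)),
    concentration_uM = as.vector(traj$states),
    stringsAsFactors = FALSE)
}

#' @export
print.fa_trajectory <- function(x, ...) {
  cat("<fa_trajectory>", length(x$times), "time points, ",
      ncol(x$states), "species")
  if (!is.null(x$protocol)) {
    cat("; step:", x$protocol$fed_species, "->",
        x$protocol$clamp_value, "uM at", x$protocol$t_step, "s")
  }
  cat("\n")
  invisible(x)
}
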