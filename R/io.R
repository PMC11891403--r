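# Configuration loading and tabular serialization (TSV, '.' decimal).

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON, which is a YAML subset) configuration with optional
#' sections `model` (parameter overrides, structure of
#' [fa_default_params()]), `protocol` (`fatty_acid`, `clamp_value`,
#' `t_step`), `solver` (`rtol`, `atol`), `seed` and `output`. Unknown keys
#' anywhere are rejected with an error naming the key; all defaults are
#' resolved so the returned object is a complete effective configuration.
#'
#' @param path path to the configuration file
#' @return list of class `fa_config` with fully resolved fields `model`
#'   (complete parameter list), `protocol`, `seed`, `output`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop_acylsim("config", "configuration file not found: ", path)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("model", "protocol", "solver", "seed", "output")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop_acylsim("config", "unknown configuration key '", unknown[1], "'")
  }
  model <- merge_params(fa_default_params(), raw$model)
  if (!is.null(raw$solver)) {
    model$solver <- merge_params(model$solver, raw$solver, "solver")
  }
  prot_def <- list(fatty_acid = "palmitate", clamp_value = NA,
                   t_step = model$feeding$t_step)
  prot <- prot_def
  if (!is.null(raw$protocol)) {
    unknown <- setdiff(names(raw$protocol), names(prot_def))
    if (length(unknown)) {
      stop_acylsim("config", "unknown configuration key 'protocol$",
                   unknown[1], "'")
    }
    prot[names(raw$protocol)] <- raw$protocol
  }
  valid_fa <- c(names(model$feeding$map), "none")
  if (!prot$fatty_acid %in% valid_fa) {
    stop_acylsim("config", "protocol$fatty_acid must be one of ",
                 paste(valid_fa, collapse = ", "))
  }
  if (is.na(prot$clamp_value) && prot$fatty_acid != "none") {
    prot$clamp_value <-
      model$feeding$clamp_values[[model$feeding$map[[prot$fatty_acid]]]]
  }
  cfg <- structure(list(model = model, protocol = prot,
                        seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
                        output = if (is.null(raw$output)) list() else raw$output),
                   class = "fa_config")
  message("effective configuration: fatty_acid=", cfg$protocol$fatty_acid,
          " clamp_value=", format(cfg$protocol$clamp_value),
          " t_step=", cfg$protocol$t_step, " seed=", cfg$seed)
  cfg
}

#' Serialize a configuration
#'
#' Writes the fully resolved effective configuration back to YAML;
#' `load_config()` on the result reproduces the same configuration
#' (round-trip).
#'
#' @param config an `fa_config`
#' @param path output path
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(list(model = config$model, protocol = config$protocol,
                        seed = config$seed, output = config$output),
                   path, precision = 17)
  invisible(path)
}

#' Trajectory TSV serialization
#'
#' Long-format tab-separated tables with header
#' `time_s  species  concentration_uM`, written at full double precision so
#' write/read round-trips are lossless.
#'
#' @param traj an `fa_trajectory`
#' @param path file path
#' @return `read_trajectory()` returns a data.frame with the three columns
#'   (times absolute); a warning is raised if any concentration is negative.
#' @export
write_trajectory <- function(traj, path) {
  df <- trajectory_df(traj)
  df$concentration_uM <- sprintf("%.17g", df$concentration_uM)
  df$time_s <- sprintf("%.17g", df$time_s)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE,
                      colClasses = c("numeric", "character", "numeric"),
                      stringsAsFactors = FALSE),
    error = function(e) {
      stop_acylsim("parse", "malformed trajectory file '", path, "': ",
                   conditionMessage(e))
    })
  if (!identical(names(df), c("time_s", "species", "concentration_uM"))) {
    stop_acylsim("parse",
                 "expected columns time_s, species, concentration_uM in ",
                 path)
  }
  if (nrow(df) && any(df$concentration_uM < -1e-9)) {
    bad <- which(df$concentration_uM < -1e-9)[1]
    warning("negative concentration at data row ", bad, " of ", path,
            call. = FALSE)
  }
  df
}

#' Measurement TSV serialization
#'
#' @param meas measurement data.frame ([simulate_lcms_counts()] schema)
#' @param path file path
#' @export
write_measurements <- function(meas, path) {
  utils::write.table(meas, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
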