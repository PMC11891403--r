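#' Acyl-chain nomenclature
#'
#' Acyl chains are identified by the usual `"C{carbons}:{double_bonds}"`
#' labels, e.g. `"C16:0"` (palmitoyl) or `"C18:1"` (cis-vaccenoyl). The model
#' grid holds even-numbered chains from C4 to C18; monounsaturated chains only
#' exist from C10 upwards, where the saturated/unsaturated branch point sits.
#'
#' @param carbons even integer chain length, between 4 and 18
#' @param double_bonds 0 (saturated) or 1 (monounsaturated)
#' @return `acyl_chain()` returns a list with fields `carbons`, `double_bonds`
#'   and `label`; `parse_chain()` the same from a label string;
#'   `chain_label()` the canonical label.
#' @examples
#' acyl_chain(16, 0)$label     # "C16:0"
#' parse_chain("C18:1")$carbons
#' @export
acyl_chain <- function(carbons, double_bonds = 0L) {
  carbons <- as.integer(carbons)
  double_bonds <- as.integer(double_bonds)
  if (length(carbons) != 1L || is.na(carbons) || carbons %% 2L != 0L ||
      carbons < 4L || carbons > 18L) {
    stop_acylsim("invalid_chain",
                 "carbons must be an even integer in 4..18, got ", carbons)
  }
  if (!double_bonds %in% c(0L, 1L)) {
    stop_acylsim("invalid_chain", "double_bonds must be 0 or 1")
  }
  if (double_bonds == 1L && carbons < 10L) {
    stop_acylsim("invalid_chain",
                 "unsaturated chains only exist for carbons >= 10, got C",
                 carbons, ":1")
  }
  structure(list(carbons = carbons, double_bonds = double_bonds,
                 label = sprintf("C%d:%d", carbons, double_bonds)),
            class = "acyl_chain")
}

#' @rdname acyl_chain
#' @param label chain label such as `"C16:0"`
#' @export
parse_chain <- function(label) {
  m <- regmatches(label, regexec("^C([0-9]+):([01])$", label))[[1]]
  if (length(m) != 3L) {
    stop_acylsim("invalid_chain", "cannot parse chain label '", label, "'")
  }
  acyl_chain(as.integer(m[2]), as.integer(m[3]))
}

#' @rdname acyl_chain
#' @export
chain_label <- function(carbons, double_bonds = 0L) {
  acyl_chain(carbons, double_bonds)$label
}

#' Thioester species identifiers
#'
#' A thioester is an acyl chain on one of two carriers: acyl carrier protein
#' (ACP) or coenzyme A (CoA). Free thioester species are named
#' `"C16:0_ACP"`, `"C18:1_CoA"` and so on; CoA carriers are restricted to the
#' exogenously fed / competing set C16:0, C16:1 and C18:1 (acetyl-CoA is a
#' separate, clamped precursor species).
#'
#' @param chain chain label or an `acyl_chain`
#' @param carrier `"ACP"` or `"CoA"`
#' @return species id string
#' @export
thioester_id <- function(chain, carrier = c("ACP", "CoA")) {
  carrier <- match.arg(carrier)
  if (is.character(chain)) chain <- parse_chain(chain)
  if (carrier == "CoA" && !chain$label %in% COA_CHAINS) {
    stop_acylsim("invalid_species",
                 "CoA thioesters are restricted to ",
                 paste(COA_CHAINS, collapse = ", "), "; got ", chain$label)
  }
  paste0(chain$label, "_", carrier)
}

# chain grids used throughout the model
SAT_CHAINS   <- sprintf("C%d:0", seq(4L, 18L, by = 2L))
UNSAT_CHAINS <- sprintf("C%d:1", seq(10L, 18L, by = 2L))
COA_CHAINS   <- c("C16:0", "C16:1", "C18:1")
# chains whose free acyl-ACP forms feed back on ACC-FabD
LONG_CHAINS  <- c("C16:0", "C16:1", "C18:0", "C18:1")
# acyltransferase substrate chains (PlsB and PlsC share the set; preferences
# differ through kon)
AT_CHAINS    <- c("C16:0", "C16:1", "C18:1")

stop_acylsim <- function(class, ...) {
  stop(structure(class = c(paste0("acylsim_", class), "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}
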