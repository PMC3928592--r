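#' @useDynLib lnblood, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor coef lm pt rnorm runif setNames quantile median sd
#' @importFrom utils write.csv read.csv modifyList
NULL

# Parameter registry -----------------------------------------------------
#
# One row per tunable quantity: default value, unit, group, hard bounds used
# by validation, and (where the parameter takes part in the uncertainty /
# sensitivity analysis) the sampled range and the set it belongs to
# ("ln" or "blood").
.param_defs <- function() {
  d <- function(name, default, unit, group, lo = 0, hi = Inf,
                usa_set = NA_character_, usa_lo = NA_real_, usa_hi = NA_real_)
    data.frame(name = name, default = default, unit = unit, group = group,
               lo = lo, hi = hi, usa_set = usa_set, usa_lo = usa_lo,
               usa_hi = usa_hi, stringsAsFactors = FALSE)
  rbind(
    # -- thymic output and initial blood state
    d("s_n4_0",        0.27,    "cells/mm3/day", "thymic"),
    d("s_n8_0",        0.1216,  "cells/mm3/day", "thymic"),
    d("thymic_decline", 0.05,   "fraction/year", "thymic", 0, 1),
    d("n4_0",          450,     "cells/mm3",     "thymic"),
    d("n8_0",          320,     "cells/mm3",     "thymic"),
    # -- blood turnover rates (per day)
    d("delta_n4",  6.0e-4, "1/day", "blood"),
    d("delta_n8",  3.8e-4, "1/day", "blood"),
    d("delta_e4",  0.3,    "1/day", "blood"),
    d("delta_e8",  0.3,    "1/day", "blood"),
    d("delta_cm4", 1.6e-3, "1/day", "blood"),
    d("delta_cm8", log(2) / (20 * 365), "1/day", "blood"),
    d("delta_em4", 0.06,   "1/day", "blood"),
    d("delta_em8", 0.06,   "1/day", "blood"),
    d("xi_e4",     0.7,    "1/day", "blood", 0, Inf, "blood", 0.2,  1.2),
    d("xi_e8",     0.7,    "1/day", "blood", 0, Inf, "blood", 0.2,  1.2),
    d("xi_em4",    0.07,   "1/day", "blood", 0, Inf, "blood", 0.01, 0.12),
    d("xi_em8",    0.05,   "1/day", "blood", 0, Inf, "blood", 0.01, 0.1),
    d("alpha_em4", 0.03,   "1/day", "blood", 0, Inf, "blood", 0.002, 0.06),
    d("alpha_em8", 0.013,  "1/day", "blood", 0, Inf, "blood", 0.005, 0.08),
    # -- LN rules
    d("bind_time",           480, "min", "ln", 0, Inf, "ln", 240,  720),
    d("cm_bind_time",        240, "min", "ln", 0, Inf, "ln", 120,  480),
    d("priming_threshold", 4.5e4, "pMHC.min", "ln", 0, Inf, "ln", 2.5e4, 6.5e4),
    d("effector_threshold", 7.5e4, "pMHC.min", "ln", 0, Inf, "ln", 5.0e4, 1.1e5),
    d("em_threshold",       1.6e5, "pMHC.min", "ln"),
    d("aicd_threshold",     3.2e5, "pMHC.min", "ln"),
    d("aicd_enabled",       1,     "boolean",  "ln", 0, 1),
    d("cd8_threshold_scale", 1.0,  "multiplier", "ln"),
    d("cd8_effector_scale",  1.6,  "multiplier", "ln"),
    d("cd8_aicd_scale",      1.4,  "multiplier", "ln"),
    d("prob_em",             0.25, "probability", "ln", 0, 1, "ln", 0.1, 0.4),
    d("prob_cm",             0.35, "probability", "ln", 0, 1),
    d("cm_signal_efficiency", 2,   "multiplier", "ln", 1, Inf, "ln", 1, 3),
    d("dc_licensing_prob",   0.3,  "probability/min", "ln", 0, 1, "ln", 0.1, 0.6),
    d("licensing_boost",     1.5,  "multiplier", "ln", 1, Inf),
    d("extra_recruitment",   2,    "multiplier", "ln", 1, Inf, "ln", 1, 3),
    d("divisions_activated_cd4", 0, "rounds", "ln", 0, 20),
    d("divisions_activated_cd8", 2, "rounds", "ln", 0, 20),
    d("divisions_activated_cm",  2, "rounds", "ln", 0, 20),
    d("cm_refractory_days",      7, "days", "ln", 0, Inf),
    d("div_signal_slope",      3.4, "rounds per log2 signal excess", "ln", 0, 10),
    d("div_max_extra",           9, "rounds", "ln", 0, 20),
    d("divisions_effector",      2, "rounds", "ln", 0, 20),
    d("divisions_effector_cd8",  2, "rounds", "ln", 0, 20),
    d("cell_cycle_h",            5, "hours",  "ln", 0.5, Inf),
    d("cognate_frequency",    1e-4, "probability", "ln", 0, 1),
    d("cd8_requires_ldc",        1, "boolean", "ln", 0, 1),
    d("k_bind",               100,  "pMHC", "ln", 1e-9, Inf),
    d("dc_pmhc_sdlog",        0.55, "lognormal sd", "ln", 0, 2),
    d("dc_max_bound",          10,  "slots", "ln", 1, Inf),
    d("dc_lifespan_days",       5,  "days", "ln", 0.1, Inf),
    d("t_speed",               10,  "um/min", "ln", 0, Inf),
    d("site_capacity",          8,  "cells/site", "ln", 1, Inf),
    d("ln_transit_h",          16,  "hours", "ln", 0.5, Inf),
    d("ln_target_cells",    170000, "cells (full scale)", "ln", 10, Inf),
    d("ln_density",          4.0e6, "cells/mm3", "ln", 1, Inf),
    # -- scenario defaults (full-scale values; the scale factor is applied
    #    internally)
    d("dc_recruit_count",    200, "DCs (full scale)", "scenario", 0, Inf),
    d("dc_pmhc_level",       200, "pMHC", "scenario", 0, Inf),
    d("dc_window_days",        2, "days", "scenario", 0, Inf),
    d("replicates",            5, "count", "scenario", 1, Inf),
    d("presim_days",           3, "days", "scenario", 0, Inf),
    # -- compartment coupling
    d("compartment_scale",  0.005, "fraction", "coupling", 1e-9, 1),
    d("cells_to_concentration", 4.6e-7, "mm^-3 per cell", "coupling", 0, Inf),
    # -- numerics
    d("abm_dt",          25,   "s", "numerics", 1e-3, 3600),
    d("ode_substeps",   100,   "count", "numerics", 1, Inf),
    d("blood_only_dt",  0.01,  "day", "numerics", 1e-6, 1),
    d("scale",          1,     "fraction of full LN", "numerics", 1e-6, 1),
    d("seed",           1,     "integer", "numerics", 0, 2^31 - 1)
  )
}

#' Baseline parameter set
#'
#' Returns the baseline [parameter_set] used by all experiment drivers.
#' Blood turnover rates are calibrated so that the naive compartments decline
#' from 450 to ~210 (CD4) and 320 to ~170 (CD8) cells/mm3 over 20 years under
#' a thymic output that falls 5% per year; LN rule constants are calibrated so
#' that the uninfected lymph node holds ~170,000 T cells at 4e6 cells/mm3
#' with a mean transit time of ~16 h, and an acute antigen challenge
#' (200 Ag-DCs over 2 days, pMHC level 200, cognate frequency 1e-4)
#' reproduces blood peaks of ~0.91 (CD4) and ~2.49 (CD8) cells/mm3.
#'
#' @return An object of class `parameter_set`: a named list of parameter
#'   values with the registry (units, groups, sampling ranges) attached.
#' @export
default_parameters <- function() {
  defs <- .param_defs()
  p <- as.list(setNames(defs$default, defs$name))
  structure(p, class = "parameter_set", registry = defs)
}

#' Load and validate a parameter set
#'
#' Reads a flat key/value YAML file (or takes a named list) of parameter
#' overrides, merges it over the baseline defaults and validates every
#' invariant (probabilities in `[0,1]`, non-negative rates, effector
#' threshold above priming threshold, ...). Unknown keys are rejected so
#' typos never silently fall back to defaults.
#'
#' @param config Path to a YAML file, a named list of overrides, or `NULL`
#'   for the baseline.
#' @return A validated `parameter_set`.
#' @export
load_parameters <- function(config = NULL) {
  p <- default_parameters()
  if (is.null(config)) return(validate_parameters(p))
  ov <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else if (is.list(config)) config
  else stop("config must be a file path or a named list")
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("parameter overrides must be named")
    unknown <- setdiff(names(ov), names(p))
    if (length(unknown))
      stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
    for (k in names(ov)) p[[k]] <- as.numeric(ov[[k]])
  }
  validate_parameters(p)
}

#' Validate a parameter set
#'
#' @param p A `parameter_set`.
#' @return `p`, invisibly classed, if valid; otherwise an error naming the
#'   offending key.
#' @export
validate_parameters <- function(p) {
  defs <- attr(p, "registry")
  if (is.null(defs)) defs <- .param_defs()
  for (i in seq_len(nrow(defs))) {
    k <- defs$name[i]
    v <- p[[k]]
    if (is.null(v) || length(v) != 1 || !is.finite(v))
      stop("parameter '", k, "' is missing or not a finite scalar")
    if (v < defs$lo[i] || v > defs$hi[i])
      stop("parameter '", k, "' = ", v, " outside [", defs$lo[i], ", ",
           defs$hi[i], "] (", defs$unit[i], ")")
  }
  if (p$effector_threshold <= p$priming_threshold)
    stop("effector_threshold must exceed priming_threshold")
  if (p$seed != round(p$seed)) stop("seed must be an integer")
  structure(p, class = "parameter_set", registry = defs)
}

#' Serialize a parameter set to YAML
#'
#' Inverse of [load_parameters()]: `load_parameters(serialize_parameters(p))`
#' reproduces `p` exactly.
#'
#' @param p A `parameter_set`.
#' @param path Optional file to write; if `NULL` the YAML text is returned.
#' @export
serialize_parameters <- function(p, path = NULL) {
  stopifnot(inherits(p, "parameter_set"))
  txt <- yaml::as.yaml(lapply(unclass(p), as.numeric))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Declared uncertainty/sensitivity ranges
#'
#' @param p A `parameter_set`.
#' @param set `"ln"` for lymph-node mechanism parameters, `"blood"` for blood
#'   mechanism parameters.
#' @return Named list of `c(min, max)` ranges.
#' @export
usa_ranges <- function(p, set = c("ln", "blood")) {
  set <- match.arg(set)
  defs <- attr(p, "registry")
  defs <- defs[!is.na(defs$usa_set) & defs$usa_set == set, ]
  setNames(lapply(seq_len(nrow(defs)),
                  function(i) c(defs$usa_lo[i], defs$usa_hi[i])),
           defs$name)
}

#' @export
print.parameter_set <- function(x, ...) {
  defs <- attr(x, "registry")
  cat("<parameter_set> ", nrow(defs), " parameters\n", sep = "")
  for (g in unique(defs$group)) {
    cat("  [", g, "]\n", sep = "")
    sub <- defs[defs$group == g, ]
    for (i in seq_len(nrow(sub)))
      cat(sprintf("    %-24s %-12g %s\n", sub$name[i],
                  x[[sub$name[i]]], sub$unit[i]))
  }
  invisible(x)
}
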