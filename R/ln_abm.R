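# Lymph-node agent compartment: R surface over the compiled stepper, plus
# single-agent reference implementations of each rule. The compiled core
# applies exactly these rules to the whole lattice; the R versions document
# the semantics and are what the rule-level unit tests exercise.

.phase_bits <- c(recruit = 1L, move = 2L, bind = 4L, proliferate = 8L,
                 license = 16L, egress = 32L)

#' Create a lymph-node state
#'
#' Builds the truncated-cone lattice, places the efferent-lymphatic (EL)
#' exit sites on the cone base and the HEV entry sites in the mid-cone band,
#' and derives the motility, recruitment and egress constants from the
#' parameter set. The per-step EL exit probability is auto-calibrated as
#' `dt / (transit * f_EL)` so the mean naive transit time matches
#' `ln_transit_h` at any scale.
#'
#' @param p A `parameter_set`.
#' @param scale Fraction of the full-size lymph node to simulate (shrinks the
#'   lattice and the target population; blood coupling is rescaled inversely
#'   so concentrations are scale-invariant in expectation).
#' @return Object of class `ln_state` (an environment; stepping functions
#'   update it in place).
#' @export
ln_state <- function(p, scale = p$scale) {
  stopifnot(inherits(p, "parameter_set"))
  e <- new.env(parent = emptyenv())
  p$scale <- scale
  e$xp <- .ln_create_cpp(unclass(p), scale)
  e$p <- p
  e$active <- TRUE
  e$t <- 0
  class(e) <- "ln_state"
  e
}

#' @export
print.ln_state <- function(x, ...) {
  info <- ln_info(x)
  cnt <- ln_counts(x)
  cat("<ln_state> ", info$n_sites, " lattice sites (",
      paste(info$dims, collapse = "x"), "), ",
      cnt$total, " T cells, ", cnt$agdc, " Ag-DC, ", cnt$ldc, " LDC",
      if (!x$active) ", SUSPENDED", "\n", sep = "")
  print(cnt$counts)
  invisible(x)
}

#' Lattice geometry and derived constants
#' @param ln An `ln_state`.
#' @export
ln_info <- function(ln) .ln_info_cpp(ln$xp)

#' Current agent counts by lineage and state
#' @param ln An `ln_state`.
#' @return List with `counts` (2x5 matrix), `n_bound`, `agdc`, `ldc`, `total`.
#' @export
ln_counts <- function(ln) .ln_counts_cpp(ln$xp)

#' Cumulative recruitment/exit tallies since creation
#' @param ln An `ln_state`.
#' @export
ln_cumulative <- function(ln) .ln_cumulative_cpp(ln$xp)

#' T cell registry as a data frame
#' @param ln An `ln_state`.
#' @export
ln_tcells <- function(ln) .ln_tcells_cpp(ln$xp)

#' DC registry as a data frame
#' @param ln An `ln_state`.
#' @export
ln_dcs <- function(ln) .ln_dcs_cpp(ln$xp)

#' Traced exits (clone serial, lineage, exit state)
#' @param ln An `ln_state`.
#' @param clear Whether to clear the log after reading.
#' @export
ln_exit_log <- function(ln, clear = FALSE) .ln_exit_log_cpp(ln$xp, clear)

#' Enable or disable lineage tracing (and optionally the signal event log)
#' @param ln An `ln_state`.
#' @param on Assign clone serials to cognate naive recruits and log exits.
#' @param signal_log Also log every signal accumulation/reset event
#'   (small runs only; used by the replay oracle in the tests).
#' @export
ln_set_tracing <- function(ln, on = TRUE, signal_log = FALSE) {
  .ln_set_tracing_cpp(ln$xp, on, signal_log)
  invisible(ln)
}

#' Signal event log for the replay oracle
#' @param ln An `ln_state`.
#' @param clear Whether to clear the log after reading.
#' @export
ln_signal_log <- function(ln, clear = FALSE) .ln_signal_log_cpp(ln$xp, clear)

#' Seed the lymph node at its uninfected steady state
#'
#' Fills the lattice to the scaled target population, split across
#' naive/CM CD4/CD8 in proportion to the supplied blood concentrations.
#'
#' @param ln An `ln_state`.
#' @param blood A `blood_state` providing the concentrations.
#' @export
ln_seed_steady <- function(ln, blood) {
  n_target <- round(ln$p$ln_target_cells * ln$p$scale)
  x <- blood$conc
  .ln_seed_cpp(ln$xp, n_target, x[["n4"]], x[["cm4"]], x[["n8"]], x[["cm8"]])
  invisible(ln)
}

#' Introduce antigen-bearing DCs
#'
#' Places `n` Ag-DCs at random lattice sites. Each DC draws its pMHC display
#' once from a lognormal around the scenario level (`dc_pmhc_sdlog`) and
#' keeps it for life (licensing multiplies it). `n` is in already-scaled
#' units (the scenario drivers apply the scale factor).
#'
#' @param ln An `ln_state`.
#' @param n Number of DCs to place.
#' @param pmhc1,pmhc2 pMHC-I and pMHC-II display levels (molecules).
#' @return Number actually placed (lattice may saturate), invisibly.
#' @export
ln_add_dcs <- function(ln, n, pmhc1 = ln$p$dc_pmhc_level,
                       pmhc2 = ln$p$dc_pmhc_level) {
  invisible(.ln_add_dcs_cpp(ln$xp, as.integer(n), pmhc1, pmhc2))
}

#' Remove every DC instantly (diphtheria-toxin style ablation)
#'
#' Bound T cells unbind and face the usual post-binding checkpoint with
#' whatever signal they accumulated.
#'
#' @param ln An `ln_state`.
#' @return Number of DCs removed, invisibly.
#' @export
ln_ablate_dcs <- function(ln) invisible(.ln_ablate_dcs_cpp(ln$xp))

.empty_report <- function() {
  m <- matrix(0L, 2, 5, dimnames = list(c("CD4", "CD8"),
                                        c("N", "A", "E", "CM", "EM")))
  list(recruited = c(n4 = 0, cm4 = 0, n8 = 0, cm8 = 0),
       exited = m, births = 0L, deaths = 0L, dc_deaths = 0L,
       agdc = 0L, ldc = 0L, counts = m, n_bound = 0L, total = 0L,
       naive_exit_age_s = 0, naive_exit_n = 0L)
}

.blood4 <- function(blood)
  c(blood$conc[["n4"]], blood$conc[["cm4"]],
    blood$conc[["n8"]], blood$conc[["cm8"]])

#' Advance the lymph node by one ABM step
#'
#' Applies, in order: recruitment from blood, motility, DC binding with
#' signal accumulation and the unbinding checkpoint, proliferation with the
#' differentiation and EM checkpoints, DC licensing by CD4 effectors, and
#' egress/death. Returns the consolidated step report; the `ln_state` is
#' updated in place. A suspended LN is a no-op returning an empty report.
#'
#' @param ln An `ln_state`.
#' @param blood A `blood_state` (recruitment probabilities are proportional
#'   to the matching concentrations).
#' @param phases Character vector of phases to run (default all); subsets
#'   give the individual operations, e.g. `"move"` for a motility-only step.
#' @export
step_ln <- function(ln, blood, phases = names(.phase_bits)) {
  if (!ln$active) return(.empty_report())
  bits <- sum(.phase_bits[match.arg(phases, names(.phase_bits),
                                    several.ok = TRUE)])
  rep <- .ln_step_cpp(ln$xp, .blood4(blood), as.integer(bits))
  ln$t <- ln$t + ln$p$abm_dt
  rep
}

#' Recruit T cells from blood (single phase)
#'
#' Naive and CM cells enter at HEV sites at rates proportional to their
#' blood concentrations; naive recruits are cognate with probability
#' `cognate_frequency`, CM recruits are all antigen-experienced. The rate is
#' multiplied by `extra_recruitment` while DCs are present.
#'
#' @param ln An `ln_state`.
#' @param blood A `blood_state`.
#' @export
recruit_t_cells <- function(ln, blood) {
  if (!ln$active) {
    warning("recruit_t_cells: LN is suspended; no-op")
    return(.empty_report())
  }
  step_ln(ln, blood, phases = "recruit")
}

#' Move every unbound T cell one step (single phase)
#' @param ln An `ln_state`.
#' @export
move_cells <- function(ln) {
  if (!ln$active) stop("move_cells: LN is suspended")
  step_ln(ln, blood_state(0, 0, 0, 0, 0, 0, 0, 0), phases = "move")
}

#' Egress at EL sites and DC death (single phase)
#' @param ln An `ln_state`.
#' @export
egress_and_death <- function(ln) {
  if (!ln$active) {
    warning("egress_and_death: LN is suspended; no-op")
    return(.empty_report())
  }
  step_ln(ln, blood_state(0, 0, 0, 0, 0, 0, 0, 0), phases = "egress")
}

# Single-agent reference rules -------------------------------------------

#' Construct a single T cell agent (reference rule interface)
#'
#' @param lineage `"CD4"` or `"CD8"`.
#' @param state One of `"N"`, `"A"`, `"E"`, `"CM"`, `"EM"`.
#' @param cognate Whether the TCR recognises the simulated antigen.
#' @param signal Accumulated stimulation (pMHC x minutes).
#' @param divisions_done Divisions completed in the current program.
#' @param clone_serial Lineage-tracing serial (`NA` when untraced).
#' @param mem_allowed Whether the memory branch is open (for CD8 under the
#'   licensed-DC rule this is set at binding).
#' @export
tcell <- function(lineage = "CD4", state = "N", cognate = TRUE, signal = 0,
                  divisions_done = 0, clone_serial = NA_integer_,
                  mem_allowed = TRUE) {
  stopifnot(lineage %in% c("CD4", "CD8"),
            state %in% c("N", "A", "E", "CM", "EM"))
  structure(list(lineage = lineage, state = state, cognate = cognate,
                 bound_to = NA_integer_, bind_elapsed = 0, signal = signal,
                 divisions_done = divisions_done, clone_serial = clone_serial,
                 mem_allowed = mem_allowed), class = "tcell")
}

#' Construct a single DC agent (reference rule interface)
#'
#' @param kind `"AgDC"` or `"LDC"`.
#' @param pmhc1,pmhc2 Surface pMHC-I / pMHC-II counts.
#' @param id Integer id.
#' @param n_bound Currently bound T cells.
#' @export
dcell <- function(kind = "AgDC", pmhc1 = 200, pmhc2 = 200, id = 1L,
                  n_bound = 0L) {
  stopifnot(kind %in% c("AgDC", "LDC"))
  structure(list(id = id, kind = kind, pmhc1 = pmhc1, pmhc2 = pmhc2,
                 n_bound = n_bound), class = "dcell")
}

#' Attempt a cognate T cell-DC binding
#'
#' The binding probability is `pMHC / (pMHC + k_bind)` in the class-matched
#' pMHC (pMHC-II for CD4, pMHC-I for CD8), hence zero without ligand and
#' non-decreasing in display level. Under the licensed-DC rule a CD8 cell
#' may still bind an unlicensed Ag-DC (it can be primed to effector) but its
#' memory branch is closed for that program.
#'
#' @param t A [tcell()]; must be cognate, unbound, in state `N` or `CM`.
#' @param dc A [dcell()] with a free binding slot.
#' @param p A `parameter_set`.
#' @return List with `bound` (logical) and the updated `tcell`/`dcell`.
#' @export
attempt_binding <- function(t, dc, p) {
  if (!t$cognate) stop("attempt_binding: non-cognate T cell (contract violation)")
  if (!is.na(t$bound_to)) stop("attempt_binding: T cell already bound")
  if (!t$state %in% c("N", "CM")) stop("attempt_binding: state must be N or CM")
  if (dc$n_bound >= p$dc_max_bound) return(list(bound = FALSE, tcell = t, dc = dc))
  pm <- if (t$lineage == "CD4") dc$pmhc2 else dc$pmhc1
  pb <- pm / (pm + p$k_bind)
  if (runif(1) < pb) {
    t$bound_to <- dc$id
    t$bind_elapsed <- 0
    t$mem_allowed <- t$lineage == "CD4" || !p$cd8_requires_ldc ||
      dc$kind == "LDC"
    dc$n_bound <- dc$n_bound + 1L
    list(bound = TRUE, tcell = t, dc = dc)
  } else list(bound = FALSE, tcell = t, dc = dc)
}

#' Accumulate stimulation signal from a bound DC
#'
#' Signal grows by `pMHC x dt` (in pMHC x minutes), multiplied by
#' `cm_signal_efficiency` for CM cells, and only before the first division
#' of the current program.
#'
#' @param t A bound [tcell()].
#' @param dc The [dcell()] it is bound to.
#' @param dt Step, seconds.
#' @param p A `parameter_set`.
#' @export
accumulate_signal <- function(t, dc, dt, p) {
  if (is.na(t$bound_to)) stop("accumulate_signal: unbound T cell (contract violation)")
  if (t$divisions_done == 0) {
    pm <- if (t$lineage == "CD4") dc$pmhc2 else dc$pmhc1
    eff <- if (t$state == "CM") p$cm_signal_efficiency else 1
    t$signal <- t$signal + pm * (dt / 60) * eff
  }
  t$bind_elapsed <- t$bind_elapsed + dt
  t
}

#' Unbinding checkpoint: prime or revert
#'
#' At the end of the bind (or when the DC dies), the accumulated signal is
#' compared with the priming threshold (inclusive): at or above it the cell
#' becomes Activated with its division program armed; below it the cell
#' reverts to its resting state with the signal forgotten. With
#' activation-induced cell death enabled, signal at or above the upper
#' cutoff kills the cell instead.
#'
#' @param t A bound [tcell()].
#' @param p A `parameter_set`.
#' @return The updated `tcell`; `state == "dead"` marks AICD.
#' @export
unbind_and_checkpoint <- function(t, p) {
  if (is.na(t$bound_to)) stop("unbind_and_checkpoint: unbound T cell")
  t$bound_to <- NA_integer_
  t$bind_elapsed <- 0
  sc <- if (t$lineage == "CD8") p$cd8_threshold_scale else 1
  sca <- if (t$lineage == "CD8") p$cd8_aicd_scale else 1
  if (p$aicd_enabled != 0 && t$signal >= p$aicd_threshold * sca) {
    t$state <- "dead"
    return(t)
  }
  if (t$signal >= p$priming_threshold * sc) {
    t$state <- "A"
    t$divisions_done <- 0
  } else {
    t$signal <- 0 # reverts to N or CM: state unchanged
  }
  t
}

#' One division of an Activated or Effector cell
#'
#' Two daughters replace the parent, inheriting lineage, clone serial,
#' accumulated signal and memory eligibility; both carry the incremented
#' division count.
#'
#' @param t A [tcell()] in state `A` or `E`.
#' @param p A `parameter_set`.
#' @return List of two `tcell` daughters.
#' @export
proliferate <- function(t, p) {
  if (!t$state %in% c("A", "E")) stop("proliferate: state must be A or E")
  t$divisions_done <- t$divisions_done + 1
  list(t, t)
}

#' Differentiation checkpoint after the activation division rounds
#'
#' Signal at or above the effector threshold commits the cell to the
#' effector state; below it the cell becomes CM with probability `prob_cm`
#' (memory branch permitting) and otherwise stays on the effector track.
#'
#' @param t A [tcell()] in state `A` with the activation rounds complete.
#' @param p A `parameter_set`.
#' @export
differentiation_checkpoint <- function(t, p) {
  sc <- if (t$lineage == "CD8") p$cd8_effector_scale else 1
  if (t$signal >= p$effector_threshold * sc) {
    t$state <- "E"
  } else if (t$mem_allowed && runif(1) < p$prob_cm) {
    t$state <- "CM"
    t$signal <- 0
    t$divisions_done <- 0
  } else {
    t$state <- "E"
  }
  t
}

#' Effector-memory checkpoint after the effector division rounds
#'
#' Effectors with sufficient signal (at or above `em_threshold`) and an open
#' memory branch become EM with probability `prob_em`.
#'
#' @param t A [tcell()] in state `E`, expansion complete.
#' @param p A `parameter_set`.
#' @export
em_checkpoint <- function(t, p) {
  sc <- if (t$lineage == "CD8") p$cd8_threshold_scale else 1
  if (t$mem_allowed && t$signal >= p$em_threshold * sc &&
      runif(1) < p$prob_em)
    t$state <- "EM"
  t
}

#' License an Ag-DC through CD4 effector contact
#'
#' Per minute of contact with a CD4 effector, an Ag-DC is licensed with
#' probability `dc_licensing_prob`; licensing is one-way and multiplies both
#' pMHC displays by `licensing_boost`.
#'
#' @param dc A [dcell()] of kind `"AgDC"` in contact with a CD4 effector.
#' @param p A `parameter_set`.
#' @param dt Contact duration to evaluate, seconds.
#' @export
license_dc <- function(dc, p, dt = 60) {
  if (dc$kind != "AgDC") return(dc)
  if (runif(1) < min(1, p$dc_licensing_prob * dt / 60)) {
    dc$kind <- "LDC"
    dc$pmhc1 <- dc$pmhc1 * p$licensing_boost
    dc$pmhc2 <- dc$pmhc2 * p$licensing_boost
  }
  dc
}
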