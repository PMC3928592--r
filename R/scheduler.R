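# Hybrid orchestration: sequential LN -> blood stepping, tunable-resolution
# suspension of quiescent compartments, pre-simulation, and the scenario
# event clock (DC recruitment windows, ablations, recall challenges).

#' Describe an infection scenario
#'
#' @param name Label.
#' @param dc_windows Data frame with columns `start_day`, `end_day`,
#'   `count` (full-scale Ag-DC number recruited over the window), `pmhc1`,
#'   `pmhc2`. Windows must be ordered and non-overlapping, and lie at or
#'   after day 0 (the pre-simulation precedes day 0).
#' @param duration_days Experiment length after the pre-simulation.
#' @param ablation_day Optional day at which every DC is removed instantly.
#' @param overrides Named list of parameter overrides (e.g.
#'   `cd8_requires_ldc = 0` for the LPS/Listeria rule set).
#' @param tracing Enable lineage tracing.
#' @return Object of class `infection_scenario`.
#' @export
make_scenario <- function(name, dc_windows, duration_days,
                          ablation_day = NA_real_, overrides = list(),
                          tracing = FALSE) {
  w <- dc_windows
  if (nrow(w)) {
    need <- c("start_day", "end_day", "count", "pmhc1", "pmhc2")
    stopifnot(all(need %in% names(w)))
    if (any(w$start_day < 0))
      stop("scenario event scheduled before the pre-simulation end (day 0)")
    if (any(w$end_day <= w$start_day)) stop("empty DC window")
    o <- order(w$start_day)
    w <- w[o, ]
    if (nrow(w) > 1 && any(w$start_day[-1] < w$end_day[-nrow(w)]))
      stop("DC windows overlap")
  }
  structure(list(name = name, dc_windows = w, duration_days = duration_days,
                 ablation_day = ablation_day, overrides = overrides,
                 tracing = tracing),
            class = "infection_scenario")
}

#' The null (uninfected) scenario
#' @param duration_days Length in days.
#' @export
scenario_baseline <- function(duration_days = 30)
  make_scenario("baseline",
                data.frame(start_day = numeric(), end_day = numeric(),
                           count = numeric(), pmhc1 = numeric(),
                           pmhc2 = numeric()),
                duration_days)

#' Acute primary infection scenario (Ag-DC influx days 0-2)
#' @param p A `parameter_set` supplying the DC count and pMHC level.
#' @param duration_days Length in days.
#' @param tracing Enable lineage tracing.
#' @export
scenario_acute <- function(p, duration_days = 30, tracing = FALSE)
  make_scenario("acute",
                data.frame(start_day = 0, end_day = p$dc_window_days,
                           count = p$dc_recruit_count,
                           pmhc1 = p$dc_pmhc_level, pmhc2 = p$dc_pmhc_level),
                duration_days, tracing = tracing)

#' Primary plus recall scenario (second Ag-DC influx days 600-602)
#' @param p A `parameter_set`.
#' @param recall_day Day the secondary DC influx starts.
#' @param duration_days Length in days.
#' @export
scenario_recall <- function(p, recall_day = 600,
                            duration_days = recall_day + 30)
  make_scenario("recall",
                data.frame(start_day = c(0, recall_day),
                           end_day = c(p$dc_window_days,
                                       recall_day + p$dc_window_days),
                           count = p$dc_recruit_count,
                           pmhc1 = p$dc_pmhc_level, pmhc2 = p$dc_pmhc_level),
                duration_days)

#' Tunable-resolution quiescence test
#'
#' The LN can be suspended when it holds no Ag-DCs, no LDCs, no bound cells,
#' and no Activated, Effector or EM cells — i.e. nothing but freely
#' recirculating naive and CM cells.
#'
#' @param counts A counts list as returned by [ln_counts()] or the matching
#'   fields of a step report.
#' @export
ln_quiescent <- function(counts) {
  cnt <- counts$counts
  counts$agdc == 0 && counts$ldc == 0 && counts$n_bound == 0 &&
    sum(cnt[, c("A", "E", "EM")]) == 0
}

#' Phase transitions of the tunable-resolution clock
#'
#' presim -> ln_active once the pre-simulation window has elapsed;
#' ln_active -> blood_only when the LN quiescence criterion holds and no DC
#' recruitment event is imminent; blood_only -> ln_active one day before the
#' next scheduled DC recruitment (the LN is re-equilibrated to current blood
#' concentrations before antigen arrives).
#'
#' @param clock List with `t_days`, `phase`, and `events` (sorted vector of
#'   DC-window start days).
#' @param counts Current LN counts (see [ln_quiescent()]).
#' @param lead_days Re-equilibration lead time before a DC event.
#' @export
update_resolution_switches <- function(clock, counts, lead_days = 1) {
  # a window starting exactly now is still upcoming: never suspend past it
  nxt <- clock$events[clock$events >= clock$t_days - 1e-6]
  nxt <- if (length(nxt)) nxt[1] else Inf
  if (clock$phase == "presim") {
    if (clock$t_days >= 0) clock$phase <- "ln_active"
  } else if (clock$phase == "ln_active") {
    started <- length(clock$events) == 0 || clock$t_days > clock$events[1]
    if (started && ln_quiescent(counts) && nxt - clock$t_days > lead_days)
      clock$phase <- "blood_only"
  } else if (clock$phase == "blood_only") {
    if (nxt - clock$t_days <= lead_days) clock$phase <- "ln_active"
  }
  clock
}

#' One hybrid step: LN, then its flux into blood, then the blood ODEs
#'
#' @param ln An `ln_state`.
#' @param blood A `blood_state`.
#' @param p The scale-adjusted `parameter_set`.
#' @return List with `report` and the updated `blood` (the LN updates in
#'   place).
#' @export
run_step <- function(ln, blood, p) {
  if (ln$active) {
    rep <- step_ln(ln, blood)
    blood <- apply_ln_flux(blood, rep, p)
    blood <- euler_advance(blood, p$abm_dt, p$ode_substeps, p)
  } else {
    rep <- .empty_report()
    blood <- euler_advance(blood, p$abm_dt, 1L, p)
  }
  list(report = rep, blood = blood)
}

.ln_series_row <- function(t_days, cnt, cum) {
  c(t_days = t_days,
    ln_n4 = cnt$counts["CD4", "N"], ln_a4 = cnt$counts["CD4", "A"],
    ln_e4 = cnt$counts["CD4", "E"], ln_cm4 = cnt$counts["CD4", "CM"],
    ln_em4 = cnt$counts["CD4", "EM"],
    ln_n8 = cnt$counts["CD8", "N"], ln_a8 = cnt$counts["CD8", "A"],
    ln_e8 = cnt$counts["CD8", "E"], ln_cm8 = cnt$counts["CD8", "CM"],
    ln_em8 = cnt$counts["CD8", "EM"],
    agdc = cnt$agdc, ldc = cnt$ldc, total = cnt$total,
    cum_e4 = cum["CD4", "E"], cum_cm4 = cum["CD4", "CM"],
    cum_em4 = cum["CD4", "EM"],
    cum_e8 = cum["CD8", "E"], cum_cm8 = cum["CD8", "CM"],
    cum_em8 = cum["CD8", "EM"])
}

#' Run a scenario through the hybrid two-compartment model
#'
#' Executes the 3-day LN pre-simulation (blood suspended, naive
#' concentrations held fixed), then the scenario's event schedule under
#' sequential LN -> blood stepping with tunable-resolution suspension, and
#' returns the recorded time series.
#'
#' @param scenario An `infection_scenario`.
#' @param p A `parameter_set`.
#' @param seed Integer seed for this run.
#' @param scale LN scale factor (defaults to `p$scale`).
#' @param record Blood/LN recording cadence in days while the LN is active
#'   (1 day while suspended).
#' @return Object of class `scenario_result`: list with `blood` and `ln`
#'   time-series data frames, cumulative LN production `production`,
#'   `lineage_exits` (when tracing), `seed`, and the scaled parameter set.
#' @export
run_scenario <- function(scenario, p, seed = p$seed, scale = p$scale,
                         record = 0.1) {
  stopifnot(inherits(scenario, "infection_scenario"))
  if (length(scenario$overrides))
    p <- load_parameters(modifyList(as.list(unclass(p)), scenario$overrides))
  p$scale <- scale
  set.seed(seed)
  dt <- p$abm_dt
  steps_per_day <- round(86400 / dt)

  ln <- ln_state(p, scale)
  if (scenario$tracing) ln_set_tracing(ln, TRUE)
  blood <- blood_state(n4 = p$n4_0, n8 = p$n8_0)
  ln_seed_steady(ln, blood)

  # --- pre-simulation: LN alone, blood frozen -------------------------
  for (i in seq_len(p$presim_days * steps_per_day)) step_ln(ln, blood)
  cum0 <- ln_cumulative(ln)$exited
  ln_exit_log(ln, clear = TRUE)

  w <- scenario$dc_windows
  events <- if (nrow(w)) w$start_day else numeric()
  clock <- list(t_days = 0, phase = "ln_active", events = events)
  rec_rows <- list()
  ln_rows <- list()
  push <- function() {
    rec_rows[[length(rec_rows) + 1L]] <<- c(t_days = clock$t_days, blood$conc)
    cnt <- ln_counts(ln)
    cum <- ln_cumulative(ln)$exited - cum0
    ln_rows[[length(ln_rows) + 1L]] <<- .ln_series_row(clock$t_days, cnt, cum)
  }
  push()

  step_i <- 0L
  rec_every <- max(1L, round(record * steps_per_day))
  ablated <- FALSE
  # hot-loop constants (inlined hybrid step: LN, flux, blood Euler)
  rates <- .blood_rates(p)
  h_day <- (dt / 86400) / p$ode_substeps
  substeps <- as.integer(p$ode_substeps)
  mult <- p$cells_to_concentration / (p$compartment_scale * p$scale)
  while (clock$t_days < scenario$duration_days - 1e-9) {
    if (clock$phase == "ln_active") {
      t0 <- clock$t_days
      if (!ablated && !is.na(scenario$ablation_day) &&
          t0 >= scenario$ablation_day) {
        ln_ablate_dcs(ln)
        ablated <- TRUE
      }
      # DC influx for any open window, spread uniformly over the window;
      # an ablation terminates presentation from windows already underway,
      # but later challenges (e.g. a day-30 re-challenge) deliver fresh DCs
      if (nrow(w)) {
        open <- which(w$start_day - 1e-9 <= t0 & t0 < w$end_day)
        if (ablated)
          open <- open[w$start_day[open] > scenario$ablation_day]
        for (j in open) {
          lam <- w$count[j] * scale * dt / ((w$end_day[j] - w$start_day[j]) * 86400)
          n <- stats::rpois(1, lam)
          if (n > 0) ln_add_dcs(ln, n, w$pmhc1[j], w$pmhc2[j])
        }
      }
      if (!ablated && !is.na(scenario$ablation_day) &&
          t0 >= scenario$ablation_day) {
        ln_ablate_dcs(ln)
        ablated <- TRUE
      }
      x <- blood$conc
      rep <- .ln_step_cpp(ln$xp, c(x[[1L]], x[[3L]], x[[5L]], x[[7L]]), 63L)
      ex <- rep$exited
      rec <- rep$recruited
      x <- x + c(ex[[1L]] - rec[[1L]], ex[[5L]], ex[[7L]] - rec[[2L]],
                 ex[[9L]], ex[[2L]] - rec[[3L]], ex[[6L]],
                 ex[[8L]] - rec[[4L]], ex[[10L]]) * mult
      if (x[[3L]] < 0) x[[3L]] <- 0  # transient CM undershoot at trace levels
      if (x[[7L]] < 0) x[[7L]] <- 0
      out <- .euler_cpp(unname(x), blood$t, h_day, substeps, rates)
      blood$conc <- setNames(out$conc, .blood_pools)
      blood$t <- out$t
      step_i <- step_i + 1L
      clock$t_days <- step_i * dt / 86400
      if (step_i %% rec_every == 0L) push()
      if (step_i %% steps_per_day == 0L)
        clock <- update_resolution_switches(
          clock, list(counts = rep$counts, agdc = rep$agdc, ldc = rep$ldc,
                      n_bound = rep$n_bound))
    } else { # blood_only
      nxt <- clock$events[clock$events > clock$t_days + 1e-9]
      stop_at <- min(scenario$duration_days,
                     if (length(nxt)) nxt[1] - 1 else Inf)
      span <- stop_at - clock$t_days
      nchunk <- max(1L, ceiling(span))
      for (k in seq_len(nchunk)) {
        d <- min(1, stop_at - clock$t_days)
        if (d <= 0) break
        blood <- run_blood_only(blood, d, p)
        clock$t_days <- clock$t_days + d
        push()
      }
      step_i <- as.integer(round(clock$t_days * steps_per_day))
      clock <- update_resolution_switches(clock, ln_counts(ln))
      if (clock$phase == "blood_only" && clock$t_days >= scenario$duration_days - 1e-9)
        break
    }
  }

  bl <- as.data.frame(do.call(rbind, rec_rows))
  lnno <- as.data.frame(do.call(rbind, ln_rows))
  res <- list(blood = bl, ln = lnno,
              production = ln_cumulative(ln)$exited - cum0,
              lineage_exits = if (scenario$tracing)
                ln_exit_log(ln, clear = FALSE) else NULL,
              scenario = scenario, seed = seed, params = p)
  class(res) <- "scenario_result"
  res
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> '", x$scenario$name, "', ",
      x$scenario$duration_days, " days, seed ", x$seed,
      ", scale ", x$params$scale, "\n", sep = "")
  cat("final blood concentrations (cells/mm3):\n")
  print(round(x$blood[nrow(x$blood), -1], 5))
  cat("cumulative LN production (exits):\n")
  print(x$production)
  invisible(x)
}
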