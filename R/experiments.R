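# In-silico protocols: acute primary infection, recall, DC-ablation
# calibration, DC-number/pMHC sweeps, and single-precursor lineage tracing.
# Every driver runs a configured number of replicates with derived seeds
# and reports replicate-level results plus pooled summaries.

.rep_seeds <- function(seed, n) as.integer(seed) + seq_len(n) - 1L

.total_ag <- function(bl, lineage) {
  if (lineage == "CD4") bl$e4 + bl$cm4 + bl$em4 else bl$e8 + bl$cm8 + bl$em8
}

.peak <- function(t, y) {
  i <- which.max(y)
  c(value = y[i], day = t[i])
}

#' Simulate an acute primary infection
#'
#' Ag-DCs are recruited over days 0-2 (full-scale count `dc_recruit_count`,
#' display level `dc_pmhc_level`) and live ~5 days; cognate naive T cells
#' (frequency `cognate_frequency`) are primed, expand, differentiate, and
#' their progeny exit to blood.
#'
#' @param p A `parameter_set`.
#' @param seed Base seed; replicate `i` runs with `seed + i - 1`.
#' @param scale LN scale factor.
#' @param replicates Number of replicate simulations.
#' @param duration_days Simulated span.
#' @param tracing Enable lineage tracing.
#' @return Object of class `acute_result`: per-replicate `runs`, and a
#'   `summary` data frame with per-replicate peak concentration/timing of
#'   total antigen-specific (E+CM+EM) CD4 and CD8 cells, the late memory
#'   plateau as a fraction of peak, and memory-appearance days.
#' @export
run_acute <- function(p, seed = p$seed, scale = p$scale,
                      replicates = p$replicates, duration_days = 30,
                      tracing = FALSE) {
  sc <- scenario_acute(p, duration_days, tracing = tracing)
  seeds <- .rep_seeds(seed, replicates)
  runs <- lapply(seeds, function(s) run_scenario(sc, p, seed = s, scale = scale))
  summary <- do.call(rbind, lapply(seq_along(runs), function(i) {
    bl <- runs[[i]]$blood
    p4 <- .peak(bl$t_days, .total_ag(bl, "CD4"))
    p8 <- .peak(bl$t_days, .total_ag(bl, "CD8"))
    late <- bl$t_days >= duration_days - 2
    mem4 <- mean(bl$cm4[late] + bl$em4[late])
    mem8 <- mean(bl$cm8[late] + bl$em8[late])
    thr <- 1e-4
    app4 <- bl$t_days[which(bl$cm4 + bl$em4 > thr)[1]]
    app8 <- bl$t_days[which(bl$cm8 + bl$em8 > thr)[1]]
    data.frame(replicate = i, seed = seeds[i],
               peak4 = p4[["value"]], peak4_day = p4[["day"]],
               peak8 = p8[["value"]], peak8_day = p8[["day"]],
               plateau4 = mem4 / p4[["value"]],
               plateau8 = mem8 / p8[["value"]],
               mem4_day = if (is.na(app4)) NA_real_ else app4,
               mem8_day = if (is.na(app8)) NA_real_ else app8)
  }))
  structure(list(runs = runs, summary = summary, seeds = seeds),
            class = "acute_result")
}

#' @export
print.acute_result <- function(x, ...) {
  s <- x$summary
  cat("<acute_result> ", nrow(s), " replicates\n", sep = "")
  cat(sprintf("  CD4 peak %.3g /mm3 at day %.1f; CD8 peak %.3g /mm3 at day %.1f\n",
              mean(s$peak4), mean(s$peak4_day),
              mean(s$peak8), mean(s$peak8_day)))
  cat(sprintf("  late memory plateau: %.1f%% (CD4), %.1f%% (CD8) of peak\n",
              100 * mean(s$plateau4), 100 * mean(s$plateau8)))
  invisible(x)
}

#' Simulate a primary plus recall response
#'
#' The primary challenge runs at day 0 and an identical Ag-DC influx is
#' repeated at `recall_day` (default 600); between the responses the LN is
#' suspended under tunable resolution and only the blood ODEs advance.
#'
#' @inheritParams run_acute
#' @param recall_day Day the secondary influx starts.
#' @param duration_days Total span.
#' @return Object of class `recall_result` with per-replicate primary and
#'   recall peaks, their ratios, CM concentrations just before recall and at
#'   the end of the run.
#' @export
run_recall <- function(p, seed = p$seed, scale = p$scale,
                       replicates = p$replicates, recall_day = 600,
                       duration_days = recall_day + 30) {
  sc <- scenario_recall(p, recall_day, duration_days)
  seeds <- .rep_seeds(seed, replicates)
  runs <- lapply(seeds, function(s) run_scenario(sc, p, seed = s, scale = scale))
  summary <- do.call(rbind, lapply(seq_along(runs), function(i) {
    bl <- runs[[i]]$blood
    pri <- bl$t_days < recall_day / 2
    rec <- bl$t_days >= recall_day
    pre <- bl$t_days <= recall_day - 1
    p4p <- .peak(bl$t_days[pri], .total_ag(bl[pri, ], "CD4"))
    p8p <- .peak(bl$t_days[pri], .total_ag(bl[pri, ], "CD8"))
    p4r <- .peak(bl$t_days[rec], .total_ag(bl[rec, ], "CD4"))
    p8r <- .peak(bl$t_days[rec], .total_ag(bl[rec, ], "CD8"))
    i600 <- max(which(pre))
    last <- bl$t_days >= duration_days - 2
    data.frame(replicate = i, seed = seeds[i],
               peak4_primary = p4p[["value"]], peak8_primary = p8p[["value"]],
               peak4_recall = p4r[["value"]], peak8_recall = p8r[["value"]],
               ratio4 = p4r[["value"]] / p4p[["value"]],
               ratio8 = p8r[["value"]] / p8p[["value"]],
               cm4_at_recall = bl$cm4[i600], cm8_at_recall = bl$cm8[i600],
               cm4_post = mean(bl$cm4[last]), cm8_post = mean(bl$cm8[last]))
  }))
  structure(list(runs = runs, summary = summary, seeds = seeds,
                 recall_day = recall_day),
            class = "recall_result")
}

#' @export
print.recall_result <- function(x, ...) {
  s <- x$summary
  cat("<recall_result> ", nrow(s), " replicates, recall at day ",
      x$recall_day, "\n", sep = "")
  cat(sprintf("  recall peaks %.3g (CD4) / %.3g (CD8) /mm3; recall:primary %.2f / %.2f\n",
              mean(s$peak4_recall), mean(s$peak8_recall),
              mean(s$ratio4), mean(s$ratio8)))
  cat(sprintf("  CM before recall %.3g / %.3g; after %.3g / %.3g /mm3\n",
              mean(s$cm4_at_recall), mean(s$cm8_at_recall),
              mean(s$cm4_post), mean(s$cm8_post)))
  invisible(x)
}

.expanded_cd8 <- function(run, day) {
  # expanded (non-naive) CD8 population, LN agents plus blood converted back
  # to cell counts at the simulated-cone scale
  ln <- run$ln
  bl <- run$blood
  i <- which.min(abs(ln$t_days - day))
  j <- which.min(abs(bl$t_days - day))
  per_cell <- run$params$cells_to_concentration /
    (run$params$compartment_scale * run$params$scale)
  ln$ln_a8[i] + ln$ln_e8[i] + ln$ln_cm8[i] + ln$ln_em8[i] +
    (bl$e8[j] + bl$cm8[j] + bl$em8[j]) / per_cell
}

#' DC-ablation calibration experiment
#'
#' Reproduces the ablation protocol used to calibrate clonal expansion:
#' Ag-DCs recruited days 0-2 are removed at each indicated time point
#' (diphtheria-toxin style; `Inf` = control, DCs live out their lifespan), a
#' recall challenge is given from day 30, and the expanded CD8 population is
#' measured on day 5 (primary) and day 33 (recall). CD8 cells may form
#' memory from unlicensed Ag-DCs under this rule set
#' (`cd8_requires_ldc = 0`).
#'
#' @inheritParams run_acute
#' @param ablation_days Ablation time points in days; `Inf` for the control.
#' @return Object of class `ablation_result`; `$table` holds replicate-mean
#'   day-5 primary and day-33 recall expanded CD8 counts per ablation time.
#' @export
run_dc_ablation <- function(p, ablation_days = c(1, 2, 3, 4, Inf),
                            seed = p$seed, scale = p$scale,
                            replicates = p$replicates) {
  seeds <- .rep_seeds(seed, replicates)
  rows <- list()
  runs <- list()
  for (a in ablation_days) {
    w <- data.frame(start_day = c(0, 30), end_day = c(p$dc_window_days, 32),
                    count = p$dc_recruit_count,
                    pmhc1 = p$dc_pmhc_level, pmhc2 = p$dc_pmhc_level)
    sc <- make_scenario(paste0("ablation_d", a), w, duration_days = 33.5,
                        ablation_day = if (is.finite(a)) a else NA_real_,
                        overrides = list(cd8_requires_ldc = 0))
    res <- lapply(seeds, function(s) run_scenario(sc, p, seed = s, scale = scale))
    runs[[as.character(a)]] <- res
    rows[[length(rows) + 1L]] <- data.frame(
      ablation_day = a,
      primary_day5 = mean(vapply(res, .expanded_cd8, 0, day = 5)),
      recall_day33 = mean(vapply(res, .expanded_cd8, 0, day = 33)))
  }
  structure(list(table = do.call(rbind, rows), runs = runs, seeds = seeds),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("<ablation_result> expanded CD8 cells (LN + blood, cone scale)\n")
  print(transform(x$table,
                  primary_day5 = round(primary_day5),
                  recall_day33 = round(recall_day33)), row.names = FALSE)
  invisible(x)
}

#' DC-number / pMHC sweep
#'
#' Varies the number of recruited Ag-DCs and their pMHC display level over
#' the stated experimental ranges and reports replicate-mean LN production
#' (cumulative exits) of effector and CM cells per lineage, plus the CM
#' fraction of the expanded output.
#'
#' @inheritParams run_acute
#' @param dc_counts Full-scale Ag-DC numbers (range 50-300 in the
#'   experiments this reproduces; values outside warn).
#' @param pmhc_levels pMHC display levels (stated range 100-300).
#' @param duration_days Span of each primary-response run.
#' @return Object of class `sweep_result`; `$grid` has one row per
#'   (dc_count, pmhc) cell with columns `mean_e4`, `mean_cm4`, `mean_e8`,
#'   `mean_cm8`, `cm_frac4`, `cm_frac8` and replicate SDs.
#' @export
run_dc_sweep <- function(p, dc_counts = c(50, 150, 300),
                         pmhc_levels = c(100, 200, 300),
                         seed = p$seed, scale = p$scale,
                         replicates = p$replicates, duration_days = 18) {
  if (any(dc_counts < 50 | dc_counts > 300))
    warning("dc_counts outside the calibrated 50-300 range; extrapolating")
  if (any(pmhc_levels < 100 | pmhc_levels > 300))
    warning("pmhc_levels outside the calibrated 100-300 range; extrapolating")
  seeds <- .rep_seeds(seed, replicates)
  rows <- list()
  for (nd in dc_counts)
    for (pm in pmhc_levels) {
      w <- data.frame(start_day = 0, end_day = p$dc_window_days,
                      count = nd, pmhc1 = pm, pmhc2 = pm)
      sc <- make_scenario(sprintf("sweep_dc%d_pmhc%d", nd, pm), w,
                          duration_days)
      prod <- lapply(seeds, function(s)
        run_scenario(sc, p, seed = s, scale = scale)$production)
      g <- function(l, st) vapply(prod, function(m) m[l, st], 0)
      e4 <- g("CD4", "E"); cm4 <- g("CD4", "CM")
      e8 <- g("CD8", "E"); cm8 <- g("CD8", "CM")
      rows[[length(rows) + 1L]] <- data.frame(
        dc_count = nd, pmhc = pm,
        mean_e4 = mean(e4), mean_cm4 = mean(cm4),
        mean_e8 = mean(e8), mean_cm8 = mean(cm8),
        sd_e4 = sd(e4), sd_cm4 = sd(cm4), sd_e8 = sd(e8), sd_cm8 = sd(cm8),
        cm_frac4 = mean(cm4) / max(1e-12, mean(cm4) + mean(e4)),
        cm_frac8 = mean(cm8) / max(1e-12, mean(cm8) + mean(e8)))
    }
  structure(list(grid = do.call(rbind, rows), seeds = seeds),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> replicate-mean LN production\n")
  print(x$grid[, c("dc_count", "pmhc", "mean_e4", "mean_cm4",
                   "mean_e8", "mean_cm8")], row.names = FALSE, digits = 3)
  invisible(x)
}

#' Lineage tracing of single cognate precursors
#'
#' Runs the acute primary scenario with every cognate naive recruit tagged
#' with a unique clone serial that is inherited through division; the exit
#' state of every differentiated descendant leaving the LN is recorded. One
#' record is produced per precursor with at least one differentiated exiting
#' descendant; records are pooled over replicates and ranked by progeny size.
#'
#' @inheritParams run_acute
#' @return Object of class `lineage_result`: `$records` (clone, lineage,
#'   n_effector, n_cm, n_em, total, replicate; ranked by total, largest
#'   first) and the underlying `runs`.
#' @export
trace_lineages <- function(p, seed = p$seed, scale = p$scale,
                           replicates = p$replicates, duration_days = 30) {
  ac <- run_acute(p, seed = seed, scale = scale, replicates = replicates,
                  duration_days = duration_days, tracing = TRUE)
  recs <- list()
  for (i in seq_along(ac$runs)) {
    log <- ac$runs[[i]]$lineage_exits
    log <- log[log$state %in% c("E", "CM", "EM"), , drop = FALSE]
    if (!nrow(log)) next
    key <- interaction(log$clone, log$lineage, drop = TRUE)
    tab <- do.call(rbind, lapply(split(log, key), function(d) {
      data.frame(clone = d$clone[1], lineage = d$lineage[1],
                 n_effector = sum(d$state == "E"),
                 n_cm = sum(d$state == "CM"),
                 n_em = sum(d$state == "EM"))
    }))
    tab$total <- tab$n_effector + tab$n_cm + tab$n_em
    tab$replicate <- i
    recs[[length(recs) + 1L]] <- tab
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(clone = integer(), lineage = character(),
               n_effector = integer(), n_cm = integer(), n_em = integer(),
               total = integer(), replicate = integer())
  records <- records[order(-records$total), ]
  rownames(records) <- NULL
  structure(list(records = records, runs = ac$runs, seeds = ac$seeds),
            class = "lineage_result")
}

#' @export
print.lineage_result <- function(x, ...) {
  r <- x$records
  cat("<lineage_result> ", nrow(r), " traced progenies\n", sep = "")
  for (l in c("CD4", "CD8")) {
    tot <- r$total[r$lineage == l]
    if (!length(tot)) next
    cat(sprintf("  %s: n=%d, largest %d, median %.0f, disparity %.3f\n",
                l, length(tot), max(tot), median(tot),
                index_of_disparity(tot / sum(tot))))
  }
  invisible(x)
}
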