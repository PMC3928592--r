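# Blood compartment: well-mixed ODE model of the eight T cell pools
# (naive / effector / central memory / effector memory, CD4 and CD8),
# integrated with forward Euler. Lymph-node net output enters as a
# state increment before each blood step, not as an ODE term.

.blood_pools <- c("n4", "e4", "cm4", "em4", "n8", "e8", "cm8", "em8")

#' Construct a blood state
#'
#' @param n4,e4,cm4,em4,n8,e8,cm8,em8 Concentrations in cells/mm3.
#' @param t Time in days since simulation start.
#' @param active Whether the compartment is being advanced (tunable
#'   resolution switch).
#' @return Object of class `blood_state`.
#' @export
blood_state <- function(n4 = 450, e4 = 0, cm4 = 0, em4 = 0,
                        n8 = 320, e8 = 0, cm8 = 0, em8 = 0,
                        t = 0, active = TRUE) {
  conc <- c(n4 = n4, e4 = e4, cm4 = cm4, em4 = em4,
            n8 = n8, e8 = e8, cm8 = cm8, em8 = em8)
  if (any(conc < 0)) stop("blood concentrations must be non-negative")
  structure(list(conc = conc, t = t, active = active), class = "blood_state")
}

#' @export
print.blood_state <- function(x, ...) {
  cat("<blood_state> t =", format(x$t, digits = 6), "days",
      if (!x$active) "(suspended)", "\n")
  print(round(x$conc, 6))
  invisible(x)
}

#' Thymic output of naive T cells
#'
#' The thymus exports naive cells at an initial rate `S(0)` that declines by
#' a fixed fraction per year, compounded continuously per day:
#' `S(t) = S(0) * (1 - decline)^(t/365)`.
#'
#' @param t_days Time in days (>= 0).
#' @param lineage `"CD4"` or `"CD8"`.
#' @param p A `parameter_set`.
#' @return Output rate in cells/mm3/day.
#' @export
thymic_output <- function(t_days, lineage = c("CD4", "CD8"), p) {
  if (any(t_days < 0)) stop("thymic_output: t must be non-negative")
  lineage <- match.arg(lineage)
  s0 <- if (lineage == "CD4") p$s_n4_0 else p$s_n8_0
  s0 * (1 - p$thymic_decline)^(t_days / 365)
}

#' Blood ODE right-hand side
#'
#' Returns the eight derivatives (cells/mm3/day). LN exchange terms are not
#' part of the vector field; they are applied to the state before each blood
#' step by [apply_ln_flux()].
#'
#' @param s A `blood_state`.
#' @param p A `parameter_set`.
#' @return Named numeric vector of derivatives.
#' @export
blood_derivatives <- function(s, p) {
  x <- s$conc
  c(n4  = thymic_output(s$t, "CD4", p) - p$delta_n4 * x[["n4"]],
    e4  = -(p$delta_e4 + p$xi_e4) * x[["e4"]],
    cm4 = -p$delta_cm4 * x[["cm4"]] + p$alpha_em4 * x[["em4"]],
    em4 = -(p$delta_em4 + p$xi_em4 + p$alpha_em4) * x[["em4"]],
    n8  = thymic_output(s$t, "CD8", p) - p$delta_n8 * x[["n8"]],
    e8  = -(p$delta_e8 + p$xi_e8) * x[["e8"]],
    cm8 = -p$delta_cm8 * x[["cm8"]] + p$alpha_em8 * x[["em8"]],
    em8 = -(p$delta_em8 + p$xi_em8 + p$alpha_em8) * x[["em8"]])
}

# packed rate constants for the compiled Euler kernel
.blood_rates <- function(p)
  c(p$s_n4_0, p$s_n8_0, log(1 - p$thymic_decline) / 365,
    p$delta_n4, p$delta_e4 + p$xi_e4, p$delta_cm4, p$alpha_em4,
    p$delta_em4 + p$xi_em4 + p$alpha_em4,
    p$delta_n8, p$delta_e8 + p$xi_e8, p$delta_cm8, p$alpha_em8,
    p$delta_em8 + p$xi_em8 + p$alpha_em8)

#' Advance the blood state with forward Euler
#'
#' @param s A `blood_state`.
#' @param dt_total Total advance, in seconds.
#' @param substeps Number of Euler substeps (>= 1).
#' @param p A `parameter_set`.
#' @return Updated `blood_state`.
#' @export
euler_advance <- function(s, dt_total, substeps = NULL, p) {
  if (is.null(substeps)) substeps <- p$ode_substeps
  if (substeps < 1) stop("substeps must be >= 1")
  if (dt_total == 0) return(s)
  h <- (dt_total / 86400) / substeps     # days
  out <- .euler_cpp(unname(s$conc), s$t, h, as.integer(substeps),
                    .blood_rates(p))
  x <- setNames(out$conc, .blood_pools)
  t <- out$t
  if (any(!is.finite(x)))
    stop("euler_advance: non-finite value in component ",
         paste(.blood_pools[!is.finite(x)], collapse = ", "))
  if (any(x < 0)) {
    neg <- x < -1e-9
    if (any(neg))
      stop("euler_advance: negative overshoot in component ",
           paste(.blood_pools[neg], collapse = ", "))
    x[x < 0] <- 0
  }
  s$conc <- x
  s$t <- t
  s
}

#' Inject lymph-node net output into the blood
#'
#' Converts one step's LN tallies to concentration increments: for naive and
#' CM pools the net flux is (exited - recruited); for effector and EM pools
#' it is the exit count. Counts are multiplied by
#' `cells_to_concentration / (compartment_scale * scale)`, i.e. scaled from
#' the simulated cone back to the whole paracortex and converted from cell
#' number to blood concentration. Transient negatives (possible for naive/CM
#' when recruitment momentarily exceeds return flow beyond the standing
#' concentration) are clipped at zero with a warning.
#'
#' @param s A `blood_state`.
#' @param report A step report, as returned by [step_ln()].
#' @param p A `parameter_set` (the `scale`-adjusted set used by the LN).
#' @return Updated `blood_state`.
#' @export
apply_ln_flux <- function(s, report, p) {
  mult <- p$cells_to_concentration / (p$compartment_scale * p$scale)
  ex <- report$exited      # 2 x 5 matrix, rows CD4/CD8, cols N A E CM EM
  rec <- report$recruited  # named: n4, cm4, n8, cm8
  # N/CM pools take the net flux (exited - recruited); E/EM take exits only
  dx <- c(ex[[1L]]  - rec[[1L]],  # n4  (row CD4, col N)
          ex[[5L]],               # e4
          ex[[7L]]  - rec[[2L]],  # cm4
          ex[[9L]],               # em4
          ex[[2L]]  - rec[[3L]],  # n8
          ex[[6L]],               # e8
          ex[[8L]]  - rec[[4L]],  # cm8
          ex[[10L]]) * mult       # em8
  x <- s$conc + dx
  if (any(x < 0)) {
    warning("apply_ln_flux: clipped transient negative concentration in ",
            paste(names(x)[x < 0], collapse = ", "))
    x[x < 0] <- 0
  }
  s$conc <- x
  s
}

#' Advance the blood compartment alone over a long span
#'
#' Used while the LN compartment is suspended: integrates with a coarse step
#' (default `p$blood_only_dt` days) which first-order convergence checks show
#' is ample for the slow blood rates.
#'
#' @param s A `blood_state`.
#' @param days Number of days to advance.
#' @param p A `parameter_set`.
#' @param record Optional cadence in days at which to record the trajectory.
#' @return If `record` is `NULL`, the final `blood_state`; otherwise a list
#'   with elements `state` and `series` (data frame `t_days` + pools).
#' @export
run_blood_only <- function(s, days, p, record = NULL) {
  dt_day <- p$blood_only_dt
  n <- ceiling(days / dt_day)
  keep <- !is.null(record)
  if (keep) {
    every <- max(1L, round(record / dt_day))
    out <- matrix(NA_real_, nrow = floor(n / every) + 1L, ncol = 9L)
    out[1L, ] <- c(s$t, s$conc)
    k <- 1L
  }
  for (i in seq_len(n)) {
    step <- min(dt_day, days - (i - 1) * dt_day)
    s <- euler_advance(s, step * 86400, substeps = 1L, p = p)
    if (keep && i %% every == 0L) {
      k <- k + 1L
      out[k, ] <- c(s$t, s$conc)
    }
  }
  if (!keep) return(s)
  series <- as.data.frame(out[seq_len(k), , drop = FALSE])
  names(series) <- c("t_days", .blood_pools)
  list(state = s, series = series)
}
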