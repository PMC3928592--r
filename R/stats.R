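# Statistics: clonal disparity index, lineage-composition rank
# correlations, Latin hypercube sampling, and partial rank correlation
# coefficients with significance tiers.

#' Index of disparity between single-cell derived progenies
#'
#' The inverse Simpson diversity index mapped to the unit interval:
#' `D = (N - 1/sum(f_i^2)) / (N - 1)` for `N >= 2` progenies with
#' frequencies `f_i`. `D = 0` for uniform progeny sizes; `D -> 1` as one
#' progeny dominates. The degenerate single-progeny case (0/0 in the
#' formula) is defined as 1 — a lone clone is maximal dominance — with a
#' warning.
#'
#' @param frequencies Non-negative progeny frequencies summing to 1 (within
#'   `tol`).
#' @param n_progenies Number of progenies; must equal
#'   `length(frequencies)`.
#' @param tol Normalisation tolerance.
#' @return Disparity `D` in `[0, 1]`.
#' @export
index_of_disparity <- function(frequencies, n_progenies = length(frequencies),
                               tol = 1e-8) {
  f <- frequencies
  if (n_progenies != length(f))
    stop("n_progenies must equal length(frequencies)")
  if (any(f < 0)) stop("frequencies must be non-negative")
  if (abs(sum(f) - 1) > tol)
    stop("frequencies must sum to 1 (got ", format(sum(f)), ")")
  n <- n_progenies
  if (n == 1) {
    warning("single progeny: index of disparity defined as 1")
    return(1)
  }
  (n - 1 / sum(f^2)) / (n - 1)
}

#' Spearman correlations of subset composition with progeny size
#'
#' Rank correlation (ties mid-ranked) of each exit subset count (effector,
#' CM, EM) against the total expanded progeny size, across lineage records.
#'
#' @param records Data frame with columns `n_effector`, `n_cm`, `n_em`,
#'   `total` (one row per progeny), e.g. from [trace_lineages()].
#' @return Named vector of Spearman coefficients (`effector`, `cm`, `em`);
#'   a constant column yields `NA` for that subset.
#' @export
composition_correlations <- function(records) {
  if (nrow(records) < 3) stop("need at least 3 progeny records")
  one <- function(x) {
    if (length(unique(x)) < 2 || length(unique(records$total)) < 2)
      return(NA_real_)
    cor(x, records$total, method = "spearman")
  }
  c(effector = one(records$n_effector),
    cm = one(records$n_cm),
    em = one(records$n_em))
}

#' Latin hypercube sample of a parameter space
#'
#' Stratified-uniform design: for each parameter the range is cut into
#' `n_samples` equal-probability strata and exactly one sample falls in each
#' stratum, with stratum assignment permuted independently per parameter.
#'
#' @param ranges Named list of `c(min, max)` ranges.
#' @param n_samples Number of design rows (>= 2).
#' @return Object of class `lhs_design`: list with `names`, `ranges`,
#'   `n_samples` and the `n_samples x n_params` `matrix`.
#' @export
lhs_sample <- function(ranges, n_samples) {
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (!length(ranges) || is.null(names(ranges)))
    stop("ranges must be a named list of c(min, max)")
  lo <- vapply(ranges, `[`, 0, 1)
  hi <- vapply(ranges, `[`, 0, 2)
  if (any(hi <= lo)) stop("invalid range (max <= min) in: ",
                          paste(names(ranges)[hi <= lo], collapse = ", "))
  u <- lhs::randomLHS(n_samples, length(ranges))
  m <- sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
  colnames(m) <- names(ranges)
  structure(list(names = names(ranges), ranges = ranges,
                 n_samples = n_samples, matrix = m),
            class = "lhs_design")
}

#' @export
print.lhs_design <- function(x, ...) {
  cat("<lhs_design> ", x$n_samples, " samples x ", length(x$names),
      " parameters\n", sep = "")
  print(vapply(x$ranges, identity, c(min = 0, max = 0)))
  invisible(x)
}

.tier <- function(prcc, p) {
  s <- if (prcc >= 0) "+" else "-"
  if (p < 0.001) paste(rep(s, 3), collapse = "")
  else if (p < 0.01) paste(rep(s, 2), collapse = "")
  else if (p < 0.05) s
  else ""
}

#' Partial rank correlation coefficients
#'
#' Rank-transforms the design matrix and the output, then for each
#' parameter correlates the residuals of its ranks and the output's ranks
#' after linear regression on the ranks of every other parameter.
#' Significance is the t test on the partial correlation with
#' `n - 2 - (k - 1)` degrees of freedom; tiers map p < 0.05 / 0.01 / 0.001
#' to one / two / three `+` or `-` signs by the coefficient's sign.
#'
#' @param design An `lhs_design` or a numeric design matrix with column
#'   names.
#' @param outputs Numeric vector, one model readout per design row
#'   (replicate-averaged upstream).
#' @return Object of class `prcc_result`: data frame with `parameter`,
#'   `prcc`, `p_value`, `tier`.
#' @export
prcc <- function(design, outputs) {
  m <- if (inherits(design, "lhs_design")) design$matrix else as.matrix(design)
  n <- nrow(m)
  k <- ncol(m)
  if (length(outputs) != n)
    stop("outputs length (", length(outputs), ") != design rows (", n, ")")
  if (qr(scale(m, scale = FALSE))$rank < k) {
    stop("collinear design columns: ", paste(colnames(m), collapse = ", "))
  }
  rm_ <- apply(m, 2, rank)
  ry <- rank(outputs)
  out <- data.frame(parameter = colnames(m), prcc = NA_real_,
                    p_value = NA_real_, tier = "",
                    stringsAsFactors = FALSE)
  df <- n - 2 - (k - 1)
  for (j in seq_len(k)) {
    others <- rm_[, -j, drop = FALSE]
    rx <- stats::lm.fit(cbind(1, others), rm_[, j])$residuals
    ryres <- stats::lm.fit(cbind(1, others), ry)$residuals
    r <- suppressWarnings(cor(rx, ryres))
    if (!is.finite(r)) r <- 0
    r <- max(-1, min(1, r))
    tval <- r * sqrt(df / max(1e-12, 1 - r^2))
    pval <- 2 * pt(-abs(tval), df)
    out$prcc[j] <- r
    out$p_value[j] <- pval
    out$tier[j] <- .tier(r, pval)
  }
  class(out) <- c("prcc_result", "data.frame")
  out
}

#' @export
print.prcc_result <- function(x, ...) {
  y <- x[order(-abs(x$prcc)), ]
  y$prcc <- round(y$prcc, 2)
  y$p_value <- signif(y$p_value, 2)
  NextMethod(object = y)
  invisible(x)
}

#' Global uncertainty and sensitivity analysis
#'
#' Latin hypercube sampling over the declared parameter ranges of one
#' mechanism set (lymph node or blood), replicate-averaged scenario runs
#' per sample, and PRCCs of each readout against each parameter. Readouts:
#' cumulative LN production of effector and CM cells and blood peak
#' effector / end-of-run CM concentrations, per lineage.
#'
#' @param p A `parameter_set` (supplies baseline values and ranges).
#' @param set `"ln"` or `"blood"` mechanism parameters.
#' @param n_samples LHS design size (the full analyses use 408 for LN and
#'   100 for blood; desk-scale smoke runs use far fewer).
#' @param seed Base seed.
#' @param scale LN scale factor.
#' @param replicates Replicates per sample.
#' @param duration_days Span of each run.
#' @return Object of class `sensitivity_result`: `design`, `readouts`
#'   (matrix sample x readout), and `prcc` (named list of `prcc_result`).
#' @export
run_sensitivity <- function(p, set = c("ln", "blood"), n_samples = 50,
                            seed = p$seed, scale = p$scale,
                            replicates = p$replicates, duration_days = 18) {
  set <- match.arg(set)
  ranges <- usa_ranges(p, set)
  set.seed(seed)
  design <- lhs_sample(ranges, n_samples)
  readout_names <- c("ln_e4", "ln_cm4", "ln_e8", "ln_cm8",
                     "bl_e4_peak", "bl_cm4_end", "bl_e8_peak", "bl_cm8_end")
  ro <- matrix(NA_real_, n_samples, length(readout_names),
               dimnames = list(NULL, readout_names))
  sc0 <- scenario_acute(p, duration_days)
  for (i in seq_len(n_samples)) {
    ov <- as.list(design$matrix[i, ])
    pi_ <- load_parameters(modifyList(as.list(unclass(p)), ov))
    reps <- lapply(.rep_seeds(seed * 1000L + i, replicates), function(s)
      run_scenario(sc0, pi_, seed = s %% .Machine$integer.max, scale = scale))
    prod <- Reduce(`+`, lapply(reps, `[[`, "production")) / replicates
    bl <- lapply(reps, `[[`, "blood")
    ro[i, ] <- c(prod["CD4", "E"], prod["CD4", "CM"],
                 prod["CD8", "E"], prod["CD8", "CM"],
                 mean(vapply(bl, function(b) max(b$e4), 0)),
                 mean(vapply(bl, function(b) b$cm4[nrow(b)], 0)),
                 mean(vapply(bl, function(b) max(b$e8), 0)),
                 mean(vapply(bl, function(b) b$cm8[nrow(b)], 0)))
  }
  pr <- lapply(readout_names, function(nm) prcc(design, ro[, nm]))
  names(pr) <- readout_names
  structure(list(design = design, readouts = ro, prcc = pr, set = set),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result> set '", x$set, "', ",
      x$design$n_samples, " samples\n", sep = "")
  for (nm in names(x$prcc)) {
    cat("--", nm, "--\n")
    print(x$prcc[[nm]])
  }
  invisible(x)
}
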