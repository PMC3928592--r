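# Shared fixtures. Heavy simulations are memoised so several test files can
# reuse one run; everything is rebuilt from code under fixed seeds.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# Desk-scale numerics used throughout the tests: a 60 s ABM step (binding,
# cycling and egress time scales are minutes-hours, so this is still finely
# resolved) over the baseline parameter set.
fast_params <- function(...) {
  ov <- list(...)
  load_parameters(modifyList(list(abm_dt = 60), ov))
}

# Acute primary infection with lineage tracing: five replicates at one tenth
# of the full lymph node. Feeds both the blood-dynamics checks and the
# clonal-heterogeneity checks.
acute_tracing_fixture <- function() {
  fixture("acute_tracing", function() {
    trace_lineages(fast_params(), seed = 101, scale = 0.1, replicates = 5)
  })
}

# Primary plus day-600 recall, three replicates at ~1/17 scale.
recall_fixture <- function() {
  fixture("recall", function() {
    run_recall(fast_params(), seed = 101, scale = 0.06, replicates = 3)
  })
}

# Replicate summary for heavy-tailed outputs: single runs are dominated by
# their largest clones, so the median across replicates is the robust
# location estimate the scaled acceptance checks compare against.
rep_med <- function(x) median(x)

# Band check for a set of named quantities: one expectation per group,
# failing with the full list of out-of-band values.
expect_bands <- function(checks) {
  msgs <- vapply(names(checks), function(nm) {
    x <- checks[[nm]]          # c(value, lo, hi)
    if (x[1] >= x[2] && x[1] <= x[3]) "" else
      sprintf("%s = %.4g outside [%.4g, %.4g]", nm, x[1], x[2], x[3])
  }, "")
  bad <- msgs[nzchar(msgs)]
  testthat::expect(length(bad) == 0,
                   paste("out-of-band:", paste(bad, collapse = "; ")))
}

acute_summary <- function(tr) {
  do.call(rbind, lapply(tr$runs, function(run) {
    bl <- run$blood
    tot4 <- bl$e4 + bl$cm4 + bl$em4
    tot8 <- bl$e8 + bl$cm8 + bl$em8
    last <- bl$t_days >= max(bl$t_days) - 2
    thr <- 1e-4
    data.frame(peak4 = max(tot4), peak4_day = bl$t_days[which.max(tot4)],
               peak8 = max(tot8), peak8_day = bl$t_days[which.max(tot8)],
               plateau4 = mean(bl$cm4[last] + bl$em4[last]) / max(tot4),
               plateau8 = mean(bl$cm8[last] + bl$em8[last]) / max(tot8),
               mem4_day = bl$t_days[which(bl$cm4 + bl$em4 > thr)[1]],
               mem8_day = bl$t_days[which(bl$cm8 + bl$em8 > thr)[1]])
  }))
}
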