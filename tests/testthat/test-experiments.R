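# Experiment drivers: smoke-scale runs checking structure and strong
# directional effects; the quantitative surfaces live in test-acceptance.R.

test_that("DC ablation empties the grid and curtails expansion", {
  p <- fast_params(cognate_frequency = 1e-3)  # denser precursors: clean contrast
  w <- data.frame(start_day = 0, end_day = 2, count = 200,
                  pmhc1 = 200, pmhc2 = 200)
  sc_cut <- make_scenario("cut", w, 10, ablation_day = 0.5,
                          overrides = list(cd8_requires_ldc = 0))
  sc_ctl <- make_scenario("ctl", w, 10,
                          overrides = list(cd8_requires_ldc = 0))
  cut <- run_scenario(sc_cut, p, seed = 31, scale = 0.03)
  ctl <- run_scenario(sc_ctl, p, seed = 31, scale = 0.03)
  # ablation terminates antigen presentation for good
  post <- cut$ln[cut$ln$t_days > 0.6, ]
  expect_true(all(post$agdc + post$ldc == 0))
  expect_lt(sum(cut$production[, c("E", "CM", "EM")]),
            sum(ctl$production[, c("E", "CM", "EM")]))
})

test_that("lineage records partition the traced differentiated exits", {
  tr <- acute_tracing_fixture()
  pooled_exits <- sum(vapply(tr$runs, function(run) {
    log <- run$lineage_exits
    sum(log$state %in% c("E", "CM", "EM"))
  }, 0))
  expect_equal(sum(tr$records$total), pooled_exits)
  expect_true(all(tr$records$total ==
                    tr$records$n_effector + tr$records$n_cm + tr$records$n_em))
  # ranked by abundance, largest first
  expect_true(all(diff(tr$records$total) <= 0))
  # serials never collide within a replicate
  for (i in unique(tr$records$replicate)) {
    sub <- tr$records[tr$records$replicate == i, ]
    expect_false(any(duplicated(paste(sub$clone, sub$lineage))))
  }
})

test_that("more antigen-bearing DCs produce more expanded output", {
  # denser precursors make the DC-number effect resolvable in a smoke run
  p <- fast_params(cognate_frequency = 1e-3)
  sw <- run_dc_sweep(p, dc_counts = c(50, 300), pmhc_levels = 200, seed = 51,
                     scale = 0.03, replicates = 2, duration_days = 10)
  g <- sw$grid
  expect_equal(nrow(g), 2)
  tot <- function(dc) sum(g[g$dc_count == dc,
                            c("mean_e4", "mean_cm4", "mean_e8", "mean_cm8")])
  expect_lt(tot(50), tot(300))
})

test_that("sweep inputs outside the calibrated ranges warn", {
  p <- fast_params()
  expect_warning(
    try(run_dc_sweep(p, dc_counts = 10, pmhc_levels = 200, replicates = 1,
                     scale = 0.01, duration_days = 0.1), silent = TRUE),
    "50-300")
})

test_that("acute summaries expose per-replicate peaks and seeds", {
  tr <- acute_tracing_fixture()
  s <- acute_summary(tr)
  expect_equal(nrow(s), 5)
  expect_true(all(is.finite(s$peak4) & s$peak4 > 0))
  expect_true(all(is.finite(s$peak8) & s$peak8 > 0))
  expect_identical(tr$seeds, 101L + 0:4)
})
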