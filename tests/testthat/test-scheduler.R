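# Tunable-resolution scheduling and scenario orchestration.

test_that("the LN quiescence test admits only naive/CM residents", {
  cnt <- function(a = 0, e = 0, em = 0, agdc = 0, ldc = 0, bound = 0) {
    m <- matrix(0, 2, 5, dimnames = list(c("CD4", "CD8"),
                                         c("N", "A", "E", "CM", "EM")))
    m[1, "N"] <- 100; m[1, "CM"] <- 5
    m[1, "A"] <- a; m[1, "E"] <- e; m[1, "EM"] <- em
    list(counts = m, agdc = agdc, ldc = ldc, n_bound = bound)
  }
  expect_true(ln_quiescent(cnt()))                 # naive + CM only
  expect_false(ln_quiescent(cnt(ldc = 1)))         # a single LDC blocks it
  expect_false(ln_quiescent(cnt(agdc = 1)))
  expect_false(ln_quiescent(cnt(a = 1)))
  expect_false(ln_quiescent(cnt(em = 1)))
  expect_false(ln_quiescent(cnt(bound = 1)))
})

test_that("phase transitions follow presim -> active -> suspended -> active", {
  quiet <- list(counts = matrix(0, 2, 5,
                                dimnames = list(c("CD4", "CD8"),
                                                c("N", "A", "E", "CM", "EM"))),
                agdc = 0, ldc = 0, n_bound = 0)
  clock <- list(t_days = -1, phase = "presim", events = c(0, 600))
  clock$t_days <- 0
  clock <- update_resolution_switches(clock, quiet)
  expect_equal(clock$phase, "ln_active")
  # quiescent mid-run, next event far away -> suspend
  clock$t_days <- 20
  clock <- update_resolution_switches(clock, quiet)
  expect_equal(clock$phase, "blood_only")
  # reactivates one day ahead of the scheduled recall
  clock$t_days <- 599.5
  clock <- update_resolution_switches(clock, quiet)
  expect_equal(clock$phase, "ln_active")
  # an active LN does not suspend while cells are engaged
  busy <- quiet
  busy$agdc <- 3
  clock2 <- list(t_days = 5, phase = "ln_active", events = c(0, 600))
  expect_equal(update_resolution_switches(clock2, busy)$phase, "ln_active")
})

test_that("scenario validation rejects malformed schedules", {
  w <- function(s, e) data.frame(start_day = s, end_day = e, count = 100,
                                 pmhc1 = 200, pmhc2 = 200)
  expect_error(make_scenario("x", w(-1, 2), 10), "pre-simulation")
  expect_error(make_scenario("x", w(2, 2), 10), "empty")
  expect_error(make_scenario("x", w(c(0, 1), c(2, 3)), 10), "overlap")
  expect_s3_class(make_scenario("x", w(c(0, 5), c(2, 7)), 10),
                  "infection_scenario")
})

test_that("a null scenario keeps naive-only dynamics and suspends the LN", {
  p <- fast_params()
  res <- run_scenario(scenario_baseline(10), p, seed = 5, scale = 0.02)
  bl <- res$blood
  expect_true(all(bl[, c("e4", "cm4", "em4", "e8", "cm8", "em8")] == 0))
  # naive blood levels stay within a percent of the uninfected baseline
  expect_lt(max(abs(bl$n4 - 450)) / 450, 0.01)
  expect_lt(max(abs(bl$n8 - 320)) / 320, 0.01)
  expect_equal(sum(res$production[, c("A", "E", "CM", "EM")]), 0)
  # tunable resolution kicks in: far fewer records than full cadence
  expect_lt(nrow(bl), 10 / 0.1)
  # no agent changes state while suspended
  lnr <- res$ln
  frozen <- lnr[lnr$t_days >= 2, ]
  expect_true(all(frozen$total == frozen$total[1]))
})

test_that("run_step advances blood only when the LN is suspended", {
  p <- fast_params()
  set.seed(3)
  ln <- ln_state(p, scale = 0.01)
  b <- blood_state(e4 = 10)
  ln_seed_steady(ln, b)
  ln$active <- FALSE
  out <- run_step(ln, b, p)
  expect_equal(sum(out$report$recruited), 0)
  expect_equal(out$blood$t, p$abm_dt / 86400)
  expect_lt(out$blood$conc[["e4"]], 10)  # decayed, no LN input
})

test_that("identical (scenario, parameters, seed) reproduce byte-identical output", {
  p <- fast_params()
  sc <- scenario_acute(p, 6)
  r1 <- run_scenario(sc, p, seed = 17, scale = 0.02)
  r2 <- run_scenario(sc, p, seed = 17, scale = 0.02)
  expect_identical(r1$blood, r2$blood)
  expect_identical(r1$ln, r2$ln)
  expect_identical(r1$production, r2$production)
})
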