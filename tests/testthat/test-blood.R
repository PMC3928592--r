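test_that("thymic output declines 5% per year, compounded continuously", {
  p <- load_parameters()
  expect_equal(thymic_output(0, "CD4", p), p$s_n4_0)
  expect_equal(thymic_output(365, "CD4", p), 0.95 * p$s_n4_0)
  expect_equal(thymic_output(20 * 365, "CD8", p), 0.95^20 * p$s_n8_0)
  expect_error(thymic_output(-1, "CD4", p), "non-negative")
})

test_that("blood derivatives match the compartmental equations", {
  p <- load_parameters()
  # empty system with no thymic source is a fixed point
  p0 <- load_parameters(list(s_n4_0 = 0, s_n8_0 = 0))
  s0 <- blood_state(0, 0, 0, 0, 0, 0, 0, 0)
  expect_equal(unname(blood_derivatives(s0, p0)), rep(0, 8))
  # quasi-equilibrium closure: naive pools are stationary at t = 0
  s <- blood_state()
  d <- blood_derivatives(s, p)
  expect_equal(d[["n4"]], 0, tolerance = 1e-10)
  expect_equal(d[["n8"]], 0, tolerance = 1e-10)
  # single-term arithmetic on the CM equation
  p1 <- load_parameters(list(alpha_em4 = 0.02, delta_cm4 = 0))
  s1 <- blood_state(0, 0, 0, em4 = 10, 0, 0, 0, 0)
  expect_equal(blood_derivatives(s1, p1)[["cm4"]], 0.2)
})

test_that("forward Euler reproduces exponential decay to 0.1%", {
  # pure decay at 0.1/day over 10 days, 0.25 s substeps
  p <- load_parameters(list(s_n4_0 = 0, s_n8_0 = 0, delta_e4 = 0.1,
                            xi_e4 = 0))
  s <- blood_state(0, e4 = 100, 0, 0, 0, 0, 0, 0)
  out <- euler_advance(s, 10 * 86400, substeps = 10 * 86400 * 4, p = p)
  expect_equal(out$conc[["e4"]], 100 * exp(-1), tolerance = 1e-3)
  expect_equal(out$t, 10)
})

test_that("zero-length advance is the identity", {
  p <- load_parameters()
  s <- blood_state(e4 = 5)
  expect_equal(euler_advance(s, 0, 100, p), s)
})

test_that("halving the Euler step shows first-order convergence", {
  p <- load_parameters(list(s_n4_0 = 0, s_n8_0 = 0, delta_e4 = 0.2,
                            xi_e4 = 0))
  s <- blood_state(0, e4 = 100, 0, 0, 0, 0, 0, 0)
  exact <- 100 * exp(-2)
  err <- function(m) {
    abs(euler_advance(s, 10 * 86400, substeps = m, p = p)$conc[["e4"]] - exact)
  }
  r <- err(40) / err(80)
  expect_gt(r, 1.7)
  expect_lt(r, 2.3)
})

test_that("LN flux enters blood with net naive/CM and exit-only E/EM terms", {
  p <- load_parameters(list(cells_to_concentration = 1, scale = 1))
  s <- blood_state(n4 = 450, e4 = 1)
  # empty report leaves the state untouched
  expect_equal(apply_ln_flux(s, lnblood:::.empty_report(), p), s)
  # one effector exit at 0.5% compartment scale adds 200 x conversion
  rep1 <- lnblood:::.empty_report()
  rep1$exited["CD4", "E"] <- 1L
  out <- apply_ln_flux(s, rep1, p)
  expect_equal(out$conc[["e4"]] - s$conc[["e4"]], 1 / 0.005)
  # naive flux is net: recruiting more than exit drains the pool
  rep2 <- lnblood:::.empty_report()
  rep2$recruited[["n4"]] <- 3
  rep2$exited["CD4", "N"] <- 1L
  out2 <- apply_ln_flux(s, rep2, p)
  expect_equal(out2$conc[["n4"]] - 450, -2 / 0.005)
  # transient negatives clip at zero with a warning
  rep3 <- lnblood:::.empty_report()
  rep3$recruited[["cm4"]] <- 10
  expect_warning(out3 <- apply_ln_flux(s, rep3, p), "clipped")
  expect_equal(out3$conc[["cm4"]], 0)
})

test_that("non-negativity is preserved over a long baseline integration", {
  p <- load_parameters()
  s <- blood_state(e4 = 1, cm4 = 1, em4 = 1, e8 = 1, cm8 = 1, em8 = 1)
  out <- run_blood_only(s, 365, p)
  expect_true(all(out$conc >= 0))
  # with no sources, the antigen-experienced CD4 mass cannot grow
  tot0 <- sum(s$conc[c("e4", "cm4", "em4")])
  expect_lte(sum(out$conc[c("e4", "cm4", "em4")]), tot0)
})
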