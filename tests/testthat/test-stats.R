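# Disparity index, composition correlations, Latin hypercube sampling, PRCC.

test_that("index of disparity matches hand-computed values", {
  expect_equal(index_of_disparity(rep(0.25, 4)), 0)
  expect_equal(index_of_disparity(c(0.5, 0.25, 0.25)), 1 / 6)
  expect_warning(d1 <- index_of_disparity(1), "single progeny")
  expect_equal(d1, 1)
  expect_error(index_of_disparity(c(0.5, 0.4)), "sum to 1")
  expect_error(index_of_disparity(c(1.2, -0.2)), "non-negative")
  expect_error(index_of_disparity(c(0.5, 0.5), n_progenies = 3), "length")
})

test_that("disparity is bounded, zero iff uniform, and near 1 under dominance", {
  set.seed(1)
  for (i in 1:50) {
    n <- sample(2:30, 1)
    x <- rgamma(n, shape = runif(1, 0.2, 5))
    d <- index_of_disparity(x / sum(x))
    expect_gte(d, -1e-12)
    expect_lte(d, 1 + 1e-12)
  }
  dom <- c(0.999, rep(0.001 / 9, 9))
  expect_gt(index_of_disparity(dom / sum(dom)), 0.95)
})

test_that("composition correlations recover known rank structure", {
  set.seed(2)
  n <- 30
  eff <- sort(rpois(n, 50) + 1)
  rec <- data.frame(n_effector = eff, n_cm = 0L, n_em = 0L, total = eff)
  cc <- composition_correlations(rec)
  expect_equal(cc[["effector"]], 1)
  expect_true(is.na(cc[["cm"]]))     # constant column undefined
  # permutation null: shuffled CM counts decorrelate from the total
  rec2 <- data.frame(n_effector = eff, n_cm = rpois(n, 10), n_em = 0L,
                     total = eff)
  nulls <- replicate(300, {
    rec2$n_cm <- sample(rec2$n_cm)
    composition_correlations(rec2)[["cm"]]
  })
  expect_lt(abs(mean(nulls)), 0.1)
  expect_error(composition_correlations(rec[1:2, ]), "3")
})

test_that("LHS places exactly one sample in each stratum", {
  set.seed(3)
  d <- lhs_sample(list(a = c(0, 1), b = c(10, 30)), 4)
  expect_equal(dim(d$matrix), c(4, 2))
  bins_a <- findInterval(d$matrix[, "a"], c(0, 0.25, 0.5, 0.75),
                         rightmost.closed = TRUE)
  expect_setequal(bins_a, 1:4)
  bins_b <- findInterval(d$matrix[, "b"], 10 + 20 * c(0, 0.25, 0.5, 0.75))
  expect_setequal(bins_b, 1:4)
  # stratification bounds the column mean deterministically
  for (n in c(10, 100, 408)) {
    dn <- lhs_sample(list(a = c(0, 1)), n)
    expect_lt(abs(mean(dn$matrix[, "a"]) - 0.5), 1 / (2 * n) + 1e-12)
    expect_equal(nrow(dn$matrix), n)
  }
  expect_error(lhs_sample(list(a = c(1, 0)), 10), "invalid range")
  expect_error(lhs_sample(list(a = c(0, 1)), 1), "n_samples")
})

test_that("PRCC identifies exact monotone dependence and is rank-invariant", {
  set.seed(4)
  d <- lhs_sample(list(a = c(0, 1), b = c(0, 1), c = c(0, 1)), 60)
  y <- d$matrix[, "b"]
  r <- prcc(d, y)
  expect_equal(r$prcc[r$parameter == "b"], 1, tolerance = 1e-6)
  expect_lt(max(abs(r$prcc[r$parameter != "b"])), 0.35)
  expect_lt(r$p_value[r$parameter == "b"], 1e-6)
  expect_match(r$tier[r$parameter == "b"], "\\+\\+\\+")
  # strictly monotone transforms leave every coefficient unchanged
  r2 <- prcc(d, exp(3 * y))
  expect_equal(r2$prcc, r$prcc, tolerance = 1e-12)
  # collinear designs are refused
  m <- cbind(a = d$matrix[, "a"], b = 2 * d$matrix[, "a"] + 1)
  expect_error(prcc(m, y), "collinear")
  expect_error(prcc(d, y[-1]), "length")
})

test_that("PRCC significance is calibrated on independent noise", {
  set.seed(5)
  hits <- 0; tests <- 0
  for (i in 1:150) {
    d <- lhs_sample(list(a = c(0, 1), b = c(0, 1), c = c(0, 1)), 30)
    r <- prcc(d, runif(30))
    hits <- hits + sum(r$p_value < 0.05)
    tests <- tests + nrow(r)
  }
  expect_gt(hits / tests, 0.02)
  expect_lt(hits / tests, 0.09)
})
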