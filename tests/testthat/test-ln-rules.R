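# Single-agent reference rules: binding, signal accumulation, checkpoints,
# licensing. These are the documented semantics the compiled stepper applies
# at scale.

p0 <- load_parameters()

test_that("binding probability is zero without ligand and rises with pMHC", {
  set.seed(1)
  t4 <- tcell("CD4")
  none <- dcell(pmhc1 = 0, pmhc2 = 0)
  expect_false(any(replicate(50, attempt_binding(t4, none, p0)$bound)))
  freq <- vapply(c(100, 200, 300), function(pm) {
    mean(replicate(400, attempt_binding(t4, dcell(pmhc2 = pm), p0)$bound))
  }, 0)
  expect_true(all(diff(freq) > 0))
  expect_equal(freq[1], 100 / (100 + p0$k_bind), tolerance = 0.15)
})

test_that("binding contracts: cognate gate, state gate, slot limit", {
  expect_error(attempt_binding(tcell(cognate = FALSE), dcell(), p0),
               "non-cognate")
  expect_error(attempt_binding(tcell(state = "E"), dcell(), p0), "state")
  full <- dcell(n_bound = p0$dc_max_bound)
  expect_false(attempt_binding(tcell(), full, p0)$bound)
})

test_that("CD8 binding an unlicensed Ag-DC closes the memory branch", {
  set.seed(2)
  bind_until <- function(t, dc) {
    for (i in 1:200) {
      out <- attempt_binding(t, dc, p0)
      if (out$bound) return(out$tcell)
    }
    stop("never bound")
  }
  expect_false(bind_until(tcell("CD8"), dcell("AgDC"))$mem_allowed)
  expect_true(bind_until(tcell("CD8"), dcell("LDC"))$mem_allowed)
  expect_true(bind_until(tcell("CD4"), dcell("AgDC"))$mem_allowed)
  # without the licensed-DC rule the branch stays open for CD8
  p_off <- load_parameters(list(cd8_requires_ldc = 0))
  out <- attempt_binding(tcell("CD8"), dcell("AgDC", pmhc1 = 1e9), p_off)
  expect_true(out$bound && out$tcell$mem_allowed)
})

test_that("signal accumulates as pMHC x time, only before first division", {
  t <- tcell("CD4")
  t$bound_to <- 1L
  dc <- dcell(pmhc2 = 100)
  t2 <- accumulate_signal(t, dc, dt = 300, p = p0)
  expect_equal(t2$signal, 100 * 5)    # pMHC x minutes
  expect_equal(t2$bind_elapsed, 300)
  # CM cells accumulate more efficiently
  cm <- tcell("CD4", "CM")
  cm$bound_to <- 1L
  expect_equal(accumulate_signal(cm, dc, 300, p0)$signal,
               p0$cm_signal_efficiency * 500)
  # post-first-division cells gain nothing
  t$divisions_done <- 1
  expect_equal(accumulate_signal(t, dc, 300, p0)$signal, 0)
  expect_error(accumulate_signal(tcell(), dc, 300, p0), "unbound")
})

test_that("priming checkpoint is inclusive at the threshold", {
  mk <- function(sig, lineage = "CD4", state = "N") {
    t <- tcell(lineage, state, signal = sig)
    t$bound_to <- 1L
    t
  }
  thr <- p0$priming_threshold
  below <- unbind_and_checkpoint(mk(thr - 1e-9), p0)
  expect_equal(below$state, "N")
  expect_equal(below$signal, 0)       # stimulation forgotten on reversion
  at <- unbind_and_checkpoint(mk(thr), p0)
  expect_equal(at$state, "A")
  expect_equal(at$signal, thr)        # retained through the program
  # CM cells revert to CM, not naive
  expect_equal(unbind_and_checkpoint(mk(thr - 1, state = "CM"), p0)$state, "CM")
})

test_that("excessive stimulation causes activation-induced death", {
  t <- tcell("CD4", signal = p0$aicd_threshold)
  t$bound_to <- 1L
  expect_equal(unbind_and_checkpoint(t, p0)$state, "dead")
  p_off <- load_parameters(list(aicd_enabled = 0))
  t$bound_to <- 1L
  expect_equal(unbind_and_checkpoint(t, p_off)$state, "A")
})

test_that("differentiation checkpoint routes by signal and memory branch", {
  hi <- tcell("CD4", "A", signal = p0$effector_threshold)
  expect_equal(differentiation_checkpoint(hi, p0)$state, "E")
  lo <- tcell("CD4", "A", signal = p0$effector_threshold - 1)
  p_cm <- load_parameters(list(prob_cm = 1))
  got <- differentiation_checkpoint(lo, p_cm)
  expect_equal(got$state, "CM")
  expect_equal(got$signal, 0)
  p_no <- load_parameters(list(prob_cm = 0))
  expect_equal(differentiation_checkpoint(lo, p_no)$state, "E")
  # closed memory branch forces the effector track
  lo$mem_allowed <- FALSE
  expect_equal(differentiation_checkpoint(lo, p_cm)$state, "E")
})

test_that("EM conversion needs signal, probability and an open branch", {
  e <- tcell("CD4", "E", signal = p0$em_threshold)
  p_em1 <- load_parameters(list(prob_em = 1))
  expect_equal(em_checkpoint(e, p_em1)$state, "EM")
  p_em0 <- load_parameters(list(prob_em = 0))
  expect_equal(em_checkpoint(e, p_em0)$state, "E")
  weak <- tcell("CD4", "E", signal = p0$em_threshold - 1)
  expect_equal(em_checkpoint(weak, p_em1)$state, "E")
  e$mem_allowed <- FALSE
  expect_equal(em_checkpoint(e, p_em1)$state, "E")
})

test_that("division copies lineage markers into both daughters", {
  t <- tcell("CD8", "A", signal = 123, clone_serial = 7L)
  t$divisions_done <- 2
  kids <- proliferate(t, p0)
  expect_length(kids, 2)
  for (k in kids) {
    expect_equal(k$clone_serial, 7L)
    expect_equal(k$signal, 123)
    expect_equal(k$divisions_done, 3)
    expect_equal(k$lineage, "CD8")
  }
  expect_error(proliferate(tcell(state = "N"), p0), "state")
})

test_that("licensing is one-way and strictly increases both pMHC displays", {
  set.seed(3)
  p_sure <- load_parameters(list(dc_licensing_prob = 1))
  dc <- dcell("AgDC", pmhc1 = 100, pmhc2 = 150)
  ldc <- license_dc(dc, p_sure, dt = 60)
  expect_equal(ldc$kind, "LDC")
  expect_gt(ldc$pmhc1, dc$pmhc1)
  expect_gt(ldc$pmhc2, dc$pmhc2)
  # already-licensed DCs are unchanged
  expect_equal(license_dc(ldc, p_sure), ldc)
  p_never <- load_parameters(list(dc_licensing_prob = 0))
  expect_equal(license_dc(dc, p_never)$kind, "AgDC")
})
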