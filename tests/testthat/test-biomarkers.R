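test_that("APD90 matches closed-form values on analytic AP shapes", {
  rect <- gen_ap_train(rest = -80, peak = 20, apd = 120, shape = "rectangular",
                       n_beats = 1)
  expect_equal(apd(rect$V, rect$t), 120, tolerance = 0.005 * 120)
  tri <- gen_ap_train(rest = -80, peak = 20, apd = 100, shape = "triangular",
                      n_beats = 1)
  expect_equal(apd(tri$V, tri$t), 90, tolerance = 0.005 * 90)
})

test_that("APD90 is invariant to time shift and voltage offset", {
  tri <- gen_ap_train(rest = -80, peak = 20, apd = 100, shape = "triangular",
                      n_beats = 1)
  a0 <- apd(tri$V, tri$t)
  expect_equal(apd(tri$V, tri$t + 137.5), a0)
  expect_equal(apd(tri$V + 13, tri$t), a0)
})

test_that("apd rejects traces without an upstroke", {
  t <- 0:500
  expect_error(apd(rep(-78, length(t)), t), "no action potential")
})

test_that("rmp reports the diastolic level before each stimulus", {
  t <- seq(0, 2000, by = 1)
  expect_equal(rmp(rep(-78, length(t)), t, stimulus_times = c(1000, 2000)),
               -78)
  train <- gen_ap_train(rest = -74, peak = 20, apd = 100,
                        shape = "triangular", n_beats = 3)
  expect_equal(rmp(train$V, train$t, stimulus_times = c(1000, 2000, 3000)),
               -74)
  expect_error(rmp(numeric(0), numeric(0), 1000), "empty")
})

test_that("cat_metrics recovers amplitude and CD50 of a triangular transient", {
  # rise 0.1 -> 0.4 uM over 20 ms, linear return over 180 ms
  t <- seq(0, 999, by = 0.5)
  ca <- ifelse(t <= 20, 0.1 + 0.3 * t / 20,
               ifelse(t <= 200, 0.4 - 0.3 * (t - 20) / 180, 0.1))
  m <- cat_metrics(ca, t, cbind(0, 1000))
  expect_equal(m$amplitude, 0.3, tolerance = 1e-6)
  expect_equal(m$cd50, 100, tolerance = 0.005 * 100)
  expect_equal(m$diastolic, 0.1)

  flat <- cat_metrics(rep(0.2, length(t)), t, cbind(0, 1000))
  expect_equal(flat$amplitude, 0)
  expect_equal(flat$cd50, 0)

  # offset invariance and linear scaling of the amplitude
  m_off <- cat_metrics(ca + 0.25, t, cbind(0, 1000))
  expect_equal(m_off$amplitude, m$amplitude, tolerance = 1e-9)
  m_scaled <- cat_metrics(ca * 3, t, cbind(0, 1000))
  expect_equal(m_scaled$amplitude, 3 * m$amplitude, tolerance = 1e-9)
  # CD50 never exceeds the window
  expect_lte(m$cd50, 1000)
})

test_that("cat_ratio divides central by membrane amplitude", {
  expect_equal(as.numeric(cat_ratio(0.3, 0.3)), 1)
  expect_equal(as.numeric(cat_ratio(0.0001, 0.033)), 0.0001 / 0.033)
  r0 <- cat_ratio(0.1, 0)
  expect_equal(as.numeric(r0), 0)
  expect_true(attr(r0, "degenerate"))
  expect_error(cat_ratio(-0.1, 0.2), ">= 0")
})

test_that("beat biomarkers of a paced run are physiologically coherent", {
  res <- baseline_run()
  bm <- beat_biomarkers(res)
  expect_equal(nrow(bm), res$protocol$record_last_n_beats)
  expect_true(all(bm$APD90 > 0))
  expect_true(all(bm$CaTm_amplitude >= 0))
  expect_true(all(bm$CaT_ratio >= 0))
  expect_true(all(bm$CD50m <= res$protocol$cycle_length))
})

test_that("population comparison uses a Welch two-sample test", {
  expect_error(compare_populations(1, c(1, 2)), "at least 2")
  same <- compare_populations(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_false(same$significant)
  set.seed(11)
  a <- rnorm(16, 22, 4); b <- rnorm(16, 9.5, 2)
  cmp <- compare_populations(a, b)
  expect_true(cmp$significant)
  expect_gt(cmp$mean_a, cmp$mean_b)
  # hand-computable case with tiny jitter
  x <- c(0, 0, 0) + c(-1, 0, 1) * 1e-9
  y <- c(1, 1, 1) + c(-1, 0, 1) * 1e-9
  expect_true(compare_populations(x, y)$significant)
})

test_that("per-domain amplitudes are available and consistent", {
  res <- gen_linescan(trace_spec(n_beats = 3,
                                 attenuation = c(1, rep(0.5, 16), 1)))
  bm <- beat_biomarkers(res, per_domain = TRUE)
  amp <- attr(bm, "domain_amplitudes")
  expect_equal(dim(amp), c(3, 18))
  # interior domains carry half the membrane amplitude by construction
  expect_equal(mean(amp[, 2:17]) / mean(amp[, c(1, 18)]), 0.5,
               tolerance = 0.01)
  expect_equal(dim(attr(bm, "domain_diastolic")), c(3, 18))
})
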