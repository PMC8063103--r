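test_that("without a stimulus the cell stays quiescent", {
  p <- baseline_parameters()
  prot <- pacing_protocol(n_beats = 2, record_last_n_beats = 2,
                          stimulus_amplitude = 0)
  res <- run_paced(p, prot)
  expect_lt(max(abs(res$V - res$V[1])), 2)
  expect_lt(max(membrane_trace(res)) - min(membrane_trace(res)), 0.02)
})

test_that("a suprathreshold stimulus evokes one CaT upstroke per beat", {
  res <- memo("five_beats", {
    run_paced(baseline_parameters(),
              pacing_protocol(n_beats = 5, record_last_n_beats = 5))
  })
  catm <- membrane_trace(res)
  # count threshold crossings of the membrane-domain transient
  th <- min(catm) + 0.5 * (max(catm) - min(catm))
  up <- sum(diff(catm > th) == 1)
  expect_equal(up, 5)
  # and a voltage upstroke per beat
  vup <- sum(diff(res$V > 0) == 1)
  expect_equal(vup, 5)
})

test_that("identical inputs give bitwise-identical results", {
  p <- baseline_parameters()
  prot <- short_protocol(n_beats = 3, rec = 1)
  r1 <- run_paced(p, prot)
  r2 <- run_paced(p, prot)
  expect_identical(r1$V, r2$V)
  expect_identical(r1$Ca_cyto, r2$Ca_cyto)
  expect_identical(r1$Na_i, r2$Na_i)
})

test_that("halving the integrator step barely changes APD90 and CaT amplitude", {
  p <- baseline_parameters()
  run_dt <- function(dt) {
    res <- run_paced(p, pacing_protocol(n_beats = 8, record_last_n_beats = 1,
                                        dt = dt))
    bm <- beat_biomarkers(res)
    c(apd = bm$APD90[1], amp = bm$CaTm_amplitude[1])
  }
  a <- run_dt(0.02); b <- run_dt(0.01)
  expect_lt(abs(a["apd"] - b["apd"]), 1)
  expect_lt(abs(a["amp"] - b["amp"]) / b["amp"], 0.02)
})

test_that("the adaptive stiff solver agrees with the operator-split scheme", {
  p <- baseline_parameters()
  split <- run_paced(p, pacing_protocol(n_beats = 2, record_last_n_beats = 1))
  lsoda <- run_paced(p, pacing_protocol(n_beats = 2, record_last_n_beats = 1,
                                        method = "lsoda"))
  bs <- beat_biomarkers(split); bl <- beat_biomarkers(lsoda)
  expect_lt(abs(bs$APD90[1] - bl$APD90[1]), 1.5)
  expect_lt(abs(bs$CaTm_amplitude[1] - bl$CaTm_amplitude[1]) /
              bl$CaTm_amplitude[1], 0.05)
})

test_that("calcium upstroke times are centripetally ordered", {
  res <- baseline_run()
  cl <- res$protocol$cycle_length
  w <- res$t >= cl & res$t < 2 * cl
  ups <- apply(res$Ca_cyto[, w], 1, function(x) {
    a <- max(x) - x[1]
    th <- x[1] + 0.5 * a
    which(x >= th)[1]
  })
  n <- length(ups)
  expect_true(all(diff(ups[1:(n / 2)]) >= 0))
  expect_true(all(diff(ups[(n / 2 + 1):n]) <= 0))
})

test_that("pace_to_steady honours its stopping rules", {
  p <- baseline_parameters()
  prot <- short_protocol()
  s1 <- pace_to_steady(p, prot, tolerance = Inf, beat_cap = 50)
  expect_equal(attr(s1, "beats"), 1L)
  expect_true(attr(s1, "converged"))
  s2 <- pace_to_steady(p, prot, tolerance = 1e-9, beat_cap = 3)
  expect_equal(attr(s2, "stopping_rule"), "beat_cap")
  # a state already at quasi-steady state re-converges within a beat or two
  s3 <- pace_to_steady(p, prot, tolerance = 5e-3, beat_cap = 100)
  s4 <- pace_to_steady(p, prot, tolerance = 5e-3, beat_cap = 100,
                       initial_state = s3)
  expect_lte(attr(s4, "beats"), attr(s3, "beats"))
})

test_that("a diverging simulation raises a simulation-failed condition", {
  p <- baseline_parameters()
  prot <- pacing_protocol(n_beats = 1, record_last_n_beats = 1,
                          stimulus_amplitude = 1e7, stimulus_duration = 900)
  err <- tryCatch(run_paced(p, prot), simulation_failed = function(e) e)
  expect_s3_class(err, "simulation_failed")
  expect_true(is.finite(err$t_fail))
})

test_that("simulation results round-trip through delimited text", {
  res <- baseline_run()
  dir <- tempfile()
  write_simulation_result(res, dir, prefix = "chk")
  mat <- read_linescan(file.path(dir, "chk_linescan.tsv"))
  expect_equal(unname(mat), unname(res$Ca_cyto), tolerance = 1e-12)
  meta <- jsonlite::read_json(file.path(dir, "chk_meta.json"))
  expect_equal(meta$n_domains, 18)
  unlink(dir, recursive = TRUE)
})

test_that("no stored concentration ever goes negative", {
  res <- baseline_run()
  expect_true(all(res$Ca_cyto >= 0))
  expect_true(all(res$Na_i >= 0))
  expect_true(all(res$Ca_SR_mean >= 0))
  fs <- attr(res, "final_state")
  expect_true(all(fs[15:length(fs)] >= 0))
})
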