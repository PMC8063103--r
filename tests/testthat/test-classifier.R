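test_that("alternans detector applies the 5% consecutive-beat rule", {
  expect_false(detect_alternans(c(0.30, 0.30, 0.30)))
  expect_true(detect_alternans(c(0.30, 0.40)))          # 25% of the larger
  expect_false(detect_alternans(c(0.300, 0.312)))       # ~3.8%
  expect_error(detect_alternans(0.3), "at least 2")
  # zero-amplitude pairs are excluded rather than dividing by zero
  expect_false(detect_alternans(c(0, 0, 0)))
  expect_true(detect_alternans(c(0, 0.3)))
})

test_that("silencing detector uses an inclusive 0.10 threshold on all beats", {
  expect_true(detect_silencing(c(0.05, 0.08, 0.09)))
  expect_true(detect_silencing(c(0.10, 0.10)))
  expect_false(detect_silencing(c(0.05, 0.50)))
  expect_error(detect_silencing(numeric(0)), "at least 1")
})

test_that("validity flags catch repolarization failure and irregular dynamics", {
  # clean periodic train (recording starts in diastole): no flags
  spec <- trace_spec(n_beats = 6)
  res <- gen_linescan(spec)
  train <- gen_ap_train(n_beats = 6, apd = 100, shape = "triangular")
  res$V <- approx(train$t, train$V, xout = (res$t + 900) %% 6000,
                  rule = 2)$y
  flags <- check_validity(res)
  expect_false(any(flags))

  # diastolic potential stuck 30 mV above the starting resting level
  v_fail <- res$V
  v_fail[res$t >= 300 & res$V <= -70] <- -80 + 30
  res_fail <- res; res_fail$V <- v_fail
  expect_true(check_validity(res_fail)["repolarization_failure"])

  # amplitude sequence that is neither period-1 nor period-2
  bm <- beat_biomarkers(res)
  bm$CaTm_amplitude <- c(0.3, 0.1, 0.4, 0.05, 0.3, 0.1)
  expect_true(check_validity(res, bm)["irregular_dynamics"])
})

test_that("classification follows the category precedence", {
  normal <- gen_linescan(trace_spec(n_beats = 6))
  expect_equal(as.character(classify(normal)$category), "normal")

  att <- rep(1, 18); att[3:16] <- 0.05
  silenced <- gen_linescan(trace_spec(n_beats = 6, attenuation = att))
  expect_equal(as.character(classify(silenced)$category), "silencing")

  alt <- gen_linescan(trace_spec(n_beats = 6, alternans_ratio = 0.8))
  expect_equal(as.character(classify(alt)$category), "alternans")

  both <- gen_linescan(trace_spec(n_beats = 6, attenuation = att,
                                  alternans_ratio = 0.7))
  expect_equal(as.character(classify(both)$category),
               "alternans_and_silencing")
})

test_that("population summaries are percentages over the five categories", {
  s <- summarize_population(rep("silencing", 16))
  expect_equal(unname(s["silencing"]), 100)
  expect_equal(sum(s), 100)
  s2 <- summarize_population(c(rep("normal", 6), rep("silencing", 10)))
  expect_equal(unname(s2["normal"]), 37.5)
  expect_equal(unname(s2["silencing"]), 62.5)
  s3 <- summarize_population("normal")
  expect_equal(unname(s3["normal"]), 100)
  expect_error(summarize_population(character(0)), "empty")
})

test_that("classifier matches a straight-line oracle on random sequences", {
  # independently coded rules: 5% alternans on consecutive pairs, 0.10
  # silencing on all beats, alternans+silencing combination
  oracle <- function(amps, ratios) {
    alt <- FALSE
    for (i in seq_len(length(amps) - 1)) {
      m <- max(amps[i], amps[i + 1])
      if (m > 0 && abs(amps[i + 1] - amps[i]) / m > 0.05) alt <- TRUE
    }
    sil <- TRUE
    for (r in ratios) if (r > 0.10) sil <- FALSE
    if (sil && alt) "alternans_and_silencing"
    else if (sil) "silencing"
    else if (alt) "alternans"
    else "normal"
  }
  set.seed(123)
  for (k in 1:1000) {
    nb <- sample(2:12, 1)
    amps <- runif(nb, 0, 0.5)
    if (runif(1) < 0.3) amps <- rep(runif(1, 0.1, 0.4), nb) *
        rep_len(c(1, runif(1, 0.9, 1)), nb)
    ratios <- runif(nb, 0, 0.3)
    if (runif(1) < 0.3) ratios <- pmin(ratios, 0.1)
    got <- if (detect_silencing(ratios) && detect_alternans(amps))
      "alternans_and_silencing"
    else if (detect_silencing(ratios)) "silencing"
    else if (detect_alternans(amps)) "alternans"
    else "normal"
    expect_identical(got, oracle(amps, ratios))
  }
})

test_that("raising the silencing threshold only moves models into silencing", {
  set.seed(99)
  for (k in 1:200) {
    ratios <- runif(sample(2:10, 1), 0, 0.4)
    lo <- detect_silencing(ratios, threshold = 0.10)
    hi <- detect_silencing(ratios, threshold = 0.25)
    expect_true(!lo || hi)   # silencing at 0.10 implies silencing at 0.25
  }
})

test_that("failed simulations are classified as other", {
  p <- baseline_parameters()
  prot <- pacing_protocol(n_beats = 1, record_last_n_beats = 1,
                          stimulus_amplitude = 1e7, stimulus_duration = 900)
  err <- tryCatch(run_paced(p, prot), simulation_failed = function(e) e)
  cls <- classify(err)
  expect_equal(as.character(cls$category), "other")
  expect_true(cls$evidence$flags["simulation_failure"])
})

test_that("external line-scan matrices classify without the simulator", {
  spec <- trace_spec(n_beats = 5, alternans_ratio = 0.75)
  res <- gen_linescan(spec)
  dir <- tempfile()
  write_simulation_result(res, dir, prefix = "ext")
  mat <- read_linescan(file.path(dir, "ext_linescan.tsv"))
  cls <- classify_linescan(mat, cycle_length = 1000)
  expect_equal(as.character(cls$category), "alternans")
  unlink(dir, recursive = TRUE)
})

test_that("a single-beat recording classifies without an alternans verdict", {
  res <- gen_linescan(trace_spec(n_beats = 1))
  expect_equal(as.character(classify(res)$category), "normal")
})
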