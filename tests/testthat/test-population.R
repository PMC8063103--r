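test_that("candidate sampling is seeded, bounded, and conductance-only", {
  expect_equal(sample_candidates(0), list())
  a <- sample_candidates(5, seed = 3)
  b <- sample_candidates(5, seed = 3)
  expect_equal(a, b)
  expect_false(identical(sample_candidates(5, seed = 4), a))

  cand <- sample_candidates(100, seed = 1)
  mult <- t(vapply(cand, attr, numeric(8), "multipliers"))
  expect_true(all(mult >= 0.5 & mult <= 2.0))
  base <- baseline_parameters()
  for (p in cand[1:10]) {
    expect_identical(p$Jmaxup, base$Jmaxup)
    expect_identical(p$RyR_P, base$RyR_P)
    expect_identical(p$NRyRs, base$NRyRs)
    expect_identical(p$Buff_factor, base$Buff_factor)
  }
  expect_error(sample_candidates(3, ranges = list(GCaL = c(2, 1))),
               "interval")
})

test_that("afterdepolarization detector flags secondary upstrokes", {
  tr <- gen_ap_train(n_beats = 2, apd = 100, shape = "triangular")
  expect_false(atriawave:::detect_afterdepolarization(tr$V, tr$t, 1000, 2))
  v2 <- tr$V
  bump <- tr$t %% 1000 >= 400 & tr$t %% 1000 < 450
  v2[bump] <- v2[bump] + 12
  expect_true(atriawave:::detect_afterdepolarization(v2, tr$t, 1000, 2))
})

test_that("calibration filters candidates with per-criterion diagnostics", {
  prot <- pacing_protocol(n_beats = 12, record_last_n_beats = 4)
  base <- baseline_parameters()
  # a low-GCaL candidate fails the full-propagation criterion
  weak <- base; weak$GCaL <- 0.5
  attr(weak, "model_id") <- 99L
  pop <- calibrate(list(base, weak), protocol = prot)
  expect_equal(length(pop$models), 1L)
  expect_true(pop$diagnostics$pass[1])
  expect_false(pop$diagnostics$pass[2])
  expect_match(pop$diagnostics$reason[2], "propagation")

  # pure filter: the accepted model re-passes on re-simulation
  again <- calibrate(pop$models, protocol = prot)
  expect_equal(length(again$models), 1L)

  # monotone screening: tightening a window can only shrink the accepted set
  tight <- calibration_criteria(apd90_window = c(70, 90))
  pop_tight <- calibrate(list(base, weak), criteria = tight, protocol = prot)
  expect_lte(length(pop_tight$models), length(pop$models))

  # empty candidate list -> empty population
  empty <- calibrate(list(), protocol = prot)
  expect_equal(length(empty$models), 0L)
})

test_that("populations serialize to JSON and CSV", {
  prot <- pacing_protocol(n_beats = 8, record_last_n_beats = 2)
  pop <- calibrate(list(baseline_parameters()), protocol = prot)
  dir <- tempfile()
  write_population(pop, dir)
  models <- read_parameters(file.path(dir, "population.json"))
  expect_equal(length(models), 1L)
  expect_equal(models[[1]]$Jmaxup, 0.0053)
  rep <- read.csv(file.path(dir, "calibration_report.csv"))
  expect_true(all(c("model_id", "pass", "reason") %in% names(rep)))
  unlink(dir, recursive = TRUE)
})

test_that("parameter sets round-trip through JSON", {
  p <- baseline_parameters()
  p$GCaL <- 1.2345
  p$RyR_P[6] <- 1.6e-4
  f <- tempfile(fileext = ".json")
  write_parameters(p, f)
  q <- read_parameters(f)
  expect_equal(q$GCaL, p$GCaL)
  expect_equal(q$RyR_P, p$RyR_P)
  expect_equal(q$geometry$n_domains, p$geometry$n_domains)
  expect_equal(q$geometry$diffusion_coupling, p$geometry$diffusion_coupling)
  unlink(f)
})

test_that("the shipped baseline parameter file matches the in-code baseline", {
  f <- system.file("extdata", "baseline_parameters.json",
                   package = "atriawave")
  p <- read_parameters(f)
  expect_equal(p, baseline_parameters())
  expect_equal(p$Jmaxup, 0.0053)
  expect_equal(p$RyR_P[c(1, 2, 6, 12)], c(0.2, 0.22, 8e-5, 0.007))
  expect_equal(p$NRyRs, 198000)
  expect_equal(p$Buff_factor, 1.0)
})

test_that("the population build is reproducible end-to-end under a seed", {
  prot <- pacing_protocol(n_beats = 10, record_last_n_beats = 3)
  b1 <- build_population(n_accept = 1L, n_candidates = 4L, seed = 9L,
                         protocol = prot)
  b2 <- build_population(n_accept = 1L, n_candidates = 4L, seed = 9L,
                         protocol = prot)
  expect_identical(b1$diagnostics, b2$diagnostics)
  expect_identical(lapply(b1$models, attr, "multipliers"),
                   lapply(b2$models, attr, "multipliers"))
})
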