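test_that("currents vanish at their reversal potentials and scale linearly", {
  params <- baseline_parameters()
  y <- default_state(params)
  # clamp V to the K reversal potential: all K currents must vanish
  ek <- 26.712 * log(5.4 / y["K_i"])
  y_ek <- y; y_ek["V"] <- ek
  cur <- compute_membrane_currents(y_ek, params)
  expect_equal(unname(cur[c("Ito1", "IKr", "IKs", "IK1")]), rep(0, 4))
  # likewise the Na reversal for INa / INab
  ena <- 26.712 * log(140 / y["Na_i"])
  y_ena <- y; y_ena["V"] <- ena
  cur <- compute_membrane_currents(y_ena, params)
  expect_equal(unname(cur[c("INa", "INab")]), rep(0, 2))

  # linear conductance scaling at frozen state
  y2 <- y; y2["V"] <- 0; y2["d"] <- 0.5; y2["f"] <- 0.8
  base <- compute_membrane_currents(y2, params)
  for (fld in c("GCaL", "ImaxNCX", "ImaxNaK")) {
    p2 <- params; p2[[fld]] <- p2[[fld]] * 2.5
    cur2 <- compute_membrane_currents(y2, p2)
    key <- c(GCaL = "ICaL", ImaxNCX = "INCX", ImaxNaK = "INaK")[[fld]]
    expect_equal(cur2[[key]], 2.5 * base[[key]], tolerance = 1e-12)
  }
  p3 <- params; p3$GCaL <- p3$GCaL / 2
  expect_equal(compute_membrane_currents(y2, p3)[["ICaL"]],
               base[["ICaL"]] / 2, tolerance = 1e-12)

  y_bad <- y; y_bad["V"] <- NaN
  expect_error(compute_membrane_currents(y_bad, params), "non-finite")
})

test_that("SERCA flux has no forward component at zero calcium and saturates", {
  p <- baseline_parameters()
  comp <- compute_serca_flux(0, 0.5, params = p, components = TRUE)
  expect_equal(comp$forward, 0)
  expect_lte(comp$net, 0)

  # saturation: far above half-activation the flux approaches Jmaxup and
  # scales with it
  sat <- compute_serca_flux(10, 1e-9, Jmaxup = 0.0053, params = p)
  expect_equal(sat, 0.0053, tolerance = 1e-3)
  expect_equal(compute_serca_flux(10, 1e-9, Jmaxup = 0.7 * 0.0053, params = p),
               0.7 * sat, tolerance = 1e-6)

  # monotone in cytosolic calcium at fixed SR calcium
  ca <- seq(0, 0.002, length.out = 40)
  flux <- compute_serca_flux(ca, 0.5, params = p)
  expect_true(all(diff(flux) >= 0))

  expect_error(compute_serca_flux(-1e-4, 0.5, params = p), "negative")
  expect_error(compute_serca_flux(1e-4, -0.5, params = p), "negative")
})

test_that("RyR release flux follows gradient, density, and open fraction", {
  expect_equal(compute_ryr_release(0, 0.001, 0.5), 0)
  expect_equal(compute_ryr_release(0.7, 0.5, 0.5), 0)
  f1 <- compute_ryr_release(0.3, 0.001, 0.5)
  expect_gt(f1, 0)
  # monotone in NRyRs at fixed state
  expect_equal(compute_ryr_release(0.3, 0.001, 0.5, NRyRs = 99000), f1 / 2)
  rp_bad <- atriawave:::.baseline_ryr_p(); rp_bad[6] <- -1
  expect_error(compute_ryr_release(0.3, 0.001, 0.5, RyR_P = rp_bad),
               "positive")
  expect_error(compute_ryr_release(1.4, 0.001, 0.5), "open fraction")
})

test_that("steady-state open probability is linear in RyR_P[5] at low calcium", {
  rp <- atriawave:::.baseline_ryr_p()
  rp2 <- rp; rp2[6] <- 2 * rp[6]
  # low-calcium linear regime: far below the activation half-point
  o1 <- ryr_open_steady(1e-4, 0.5, RyR_P = rp)
  o2 <- ryr_open_steady(1e-4, 0.5, RyR_P = rp2)
  expect_equal(o2 / o1, 2, tolerance = 1e-3)
})

test_that("buffering attenuation strengthens as Buff_factor decreases", {
  att1 <- apply_buffering(1, 1e-4, Buff_factor = 1, compartment = "cytosol",
                          attenuation_only = TRUE)
  att015 <- apply_buffering(1, 1e-4, Buff_factor = 0.15,
                            compartment = "cytosol", attenuation_only = TRUE)
  expect_gt(att1, 0); expect_lte(att1, 1)
  expect_lt(att015, att1)
  # strictly decreasing along a grid of Buff_factor below 1, at several Ca
  for (ca in c(5e-5, 1e-4, 5e-4)) {
    att <- vapply(c(1, 0.7, 0.4, 0.15), function(b)
      apply_buffering(1, ca, b, "cytosol", attenuation_only = TRUE),
      numeric(1))
    expect_true(all(diff(att) < 0))
  }
  # with the buffer capacity set to zero the rate passes through unchanged
  op <- options(atriawave.model_refs = list(bj = 0))
  on.exit(options(op))
  expect_equal(apply_buffering(0.37, 2e-4, compartment = "junctional"), 0.37)
  options(op)
  expect_error(apply_buffering(1, 1e-4, Buff_factor = 0), "positive")
})

test_that("diffusion operator is linear, conservative, and down-gradient", {
  g <- cell_geometry()
  expect_equal(compute_diffusion(rep(0.3, 18), g), rep(0, 18))

  g2 <- cell_geometry(n_domains = 3)
  r <- compute_diffusion(c(1, 0, 0), g2)
  expect_equal(r[1], -g2$diffusion_coupling * 1)
  # conservation against an independently coded dense operator
  set.seed(7)
  n <- g$n_domains
  lap <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    lap[i, i] <- lap[i, i] - g$diffusion_coupling
    lap[i, i + 1] <- lap[i, i + 1] + g$diffusion_coupling
    lap[i + 1, i + 1] <- lap[i + 1, i + 1] - g$diffusion_coupling
    lap[i + 1, i] <- lap[i + 1, i] + g$diffusion_coupling
  }
  for (k in 1:25) {
    ca <- runif(n, 0, 1e-3)
    r <- compute_diffusion(ca, g)
    expect_equal(r, as.numeric(lap %*% ca), tolerance = 1e-12)
    expect_lt(abs(sum(r * g$v_cyto)) / max(abs(r * g$v_cyto)), 1e-12)
    # per-interface flux is directed down-gradient
    iface <- g$diffusion_coupling * diff(ca)  # flux received by domain i
    expect_true(all(sign(iface) == sign(diff(ca)) | diff(ca) == 0))
  }
  expect_error(compute_diffusion(rep(1e-4, 5), g), "expected 18")
})

test_that("rhs detects invalid states and yields finite derivatives", {
  p <- baseline_parameters()
  y <- default_state(p)
  r <- cell_rhs(0, y, p, stimulus = 0)
  expect_true(all(is.finite(r$dy)))
  y_bad <- y; y_bad[20] <- NaN
  expect_error(cell_rhs(0, y_bad, p), "non-finite")
})

test_that("the production integrator matches explicit Euler to first order", {
  p <- baseline_parameters()
  y0 <- as.numeric(default_state(p))
  # reference: fine explicit-Euler advance of 2 ms under the stimulus
  y_ref <- y0
  for (s in 1:2000) y_ref <- y_ref + 0.001 * cell_rhs(0, y_ref, p, 40)$dy
  v_at_2ms <- function(dt) {
    prot <- pacing_protocol(n_beats = 1, record_last_n_beats = 1, dt = dt,
                            output_dt = 2)
    run_paced(p, prot)$V[2]
  }
  err <- abs(c(v_at_2ms(0.02), v_at_2ms(0.005)) - y_ref[1])
  expect_lt(err[1], 2)            # close through the upstroke
  expect_lt(err[2], err[1])       # and converging as the step shrinks
})

test_that("closed-cell configuration conserves total calcium over one second", {
  p <- baseline_parameters()
  prot <- pacing_protocol(n_beats = 1, record_last_n_beats = 1,
                          stimulus_amplitude = 0, dt = 0.02)
  y0 <- default_state(p)
  tot0 <- total_calcium(as.numeric(y0), p)
  res <- run_paced(p, prot, initial_state = y0, closed_cell = TRUE)
  tot1 <- total_calcium(attr(res, "final_state"), p)
  expect_lt(abs(tot1 - tot0) / tot0, 1e-6)
})
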