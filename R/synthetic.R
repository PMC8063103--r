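#' Specification of a synthetic line scan
#'
#' Describes a line-scan-like matrix of per-domain calcium transients with
#' prescribed phenotype structure: centripetal activation delay, toward-
#' center amplitude attenuation, even/odd beat amplitude alternation, and
#' additive Gaussian noise. Used to exercise the biomarker and classifier
#' layers independently of the differential-equation model.
#'
#' @param n_domains number of domains.
#' @param cycle_length stimulus period, ms.
#' @param n_beats number of beats.
#' @param membrane_amplitude calcium transient amplitude at the membrane
#'   domains, uM.
#' @param diastolic diastolic level, uM.
#' @param delay_per_domain centripetal activation delay per domain step, ms.
#' @param attenuation per-domain amplitude multiplier in `[0, 1]`; must be 1
#'   at the membrane domains. Default: no attenuation.
#' @param alternans_ratio even/odd beat amplitude ratio in (0, 1].
#' @param noise_sd additive Gaussian noise SD, uM.
#' @param seed noise seed.
#' @param output_dt sampling interval, ms.
#' @export
trace_spec <- function(n_domains = 18L, cycle_length = 1000, n_beats = 10L,
                       membrane_amplitude = 0.35, diastolic = 0.1,
                       delay_per_domain = 1.5,
                       attenuation = rep(1, n_domains),
                       alternans_ratio = 1, noise_sd = 0, seed = 1L,
                       output_dt = 1) {
  stopifnot(n_domains >= 3, cycle_length > 0, n_beats >= 1,
            membrane_amplitude > 0, diastolic >= 0, delay_per_domain >= 0,
            length(attenuation) == n_domains,
            all(attenuation >= 0), all(attenuation <= 1),
            alternans_ratio > 0, alternans_ratio <= 1, noise_sd >= 0)
  if (attenuation[1] != 1 || attenuation[n_domains] != 1)
    stop("attenuation must equal 1 at the membrane domains")
  structure(as.list(environment()), class = "trace_spec")
}

# difference-of-exponentials beat waveform, normalized to unit peak
beat_waveform <- function(t, tau_rise = 5, tau_decay = 60) {
  w <- ifelse(t < 0, 0, exp(-t / tau_decay) - exp(-t / tau_rise))
  tpk <- log(tau_decay / tau_rise) * tau_rise * tau_decay /
    (tau_decay - tau_rise)
  w / (exp(-tpk / tau_decay) - exp(-tpk / tau_rise))
}

#' Generate a synthetic line scan
#'
#' Each domain's trace is diastolic level plus amplitude x attenuation x a
#' difference-of-exponentials beat waveform (rise 5 ms, decay 60 ms),
#' delayed by the domain's centripetal delay; even-numbered beats are
#' scaled by `alternans_ratio`; Gaussian noise is added under the spec's
#' seed. The result has the same shape as a `simulation_result` (calcium in
#' mM), so synthetic and simulated data are interchangeable in the
#' biomarker and classifier layers.
#'
#' @param spec a [trace_spec()].
#' @return a `simulation_result`-shaped object (no voltage or sodium
#'   traces).
#' @export
gen_linescan <- function(spec) {
  if (!inherits(spec, "trace_spec")) stop("spec must be a trace_spec")
  n <- spec$n_domains
  t <- seq(0, spec$n_beats * spec$cycle_length - spec$output_dt,
           by = spec$output_dt)
  # centripetal delay: distance in domain steps from the nearest membrane end
  dist <- pmin(seq_len(n) - 1L, n - seq_len(n))
  delay <- spec$delay_per_domain * dist
  set.seed(spec$seed)
  ca <- matrix(0, n, length(t))
  for (b in seq_len(spec$n_beats)) {
    bf <- if (b %% 2 == 0) spec$alternans_ratio else 1
    t0 <- (b - 1) * spec$cycle_length
    for (d in seq_len(n)) {
      amp <- spec$membrane_amplitude * spec$attenuation[d] * bf
      ca[d, ] <- ca[d, ] + amp * beat_waveform(t - t0 - delay[d])
    }
  }
  ca <- ca + spec$diastolic
  if (spec$noise_sd > 0)
    ca <- ca + matrix(stats::rnorm(length(ca), 0, spec$noise_sd), nrow = n)
  ca <- pmax(ca, 0) * 1e-3  # uM -> mM, clipped at zero
  structure(list(t = t, V = NULL, Ca_cyto = ca, Na_i = NULL,
                 Ca_SR_mean = NULL,
                 protocol = list(cycle_length = spec$cycle_length,
                                 record_last_n_beats = spec$n_beats,
                                 output_dt = spec$output_dt),
                 params = list(geometry = list(
                   n_domains = n, membrane_domain_indices = c(1L, n))),
                 meta = list(synthetic = TRUE, spec = unclass(spec))),
            class = "simulation_result")
}

#' Generate an analytic action-potential train
#'
#' Produces a voltage trace whose true APD90 is known in closed form:
#' `"rectangular"` jumps to `peak` for `apd` ms then returns to `rest`
#' (APD90 = `apd`); `"triangular"` jumps to `peak` and decays linearly back
#' to `rest` over `apd` ms (APD90 = 0.9 x `apd`). An optional diastolic
#' offset per beat emulates repolarization failure.
#'
#' @param rest,peak resting and peak potential, mV (`peak > rest`).
#' @param apd shape duration parameter, ms (< `cycle_length`).
#' @param cycle_length,n_beats pacing layout.
#' @param shape `"rectangular"` or `"triangular"`.
#' @param diastolic_offset added to the diastolic segments, mV (default 0).
#' @param output_dt sampling interval, ms.
#' @return list with `t`, `V`, and `true_apd90`.
#' @export
gen_ap_train <- function(rest = -80, peak = 20, apd = 120,
                         cycle_length = 1000, n_beats = 10L,
                         shape = c("rectangular", "triangular"),
                         diastolic_offset = 0, output_dt = 0.5) {
  shape <- match.arg(shape)
  if (peak <= rest) stop("peak must exceed rest")
  if (apd >= cycle_length) stop("apd must be shorter than the cycle length")
  t <- seq(0, n_beats * cycle_length - output_dt, by = output_dt)
  tb <- t %% cycle_length
  V <- rep(rest + diastolic_offset, length(t))
  act <- tb < apd
  V[act] <- if (shape == "rectangular") peak
            else peak - (peak - rest) * tb[act] / apd
  true_apd90 <- if (shape == "rectangular") apd else 0.9 * apd
  list(t = t, V = V, true_apd90 = true_apd90)
}
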