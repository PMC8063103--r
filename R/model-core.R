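#' Sarcolemmal membrane currents
#'
#' Evaluates every membrane current at a frozen state: the L-type and
#' T-type calcium currents, fast sodium current, transient outward and
#' delayed/inward rectifier potassium currents, background currents, the
#' sodium-calcium exchanger (forward and reverse mode), the sodium-potassium
#' pump and the plasmalemmal calcium pump. Currents are whole-cell densities
#' in pA/pF and are carried by the two membrane domains.
#'
#' @param state a state vector from [default_state()] or a simulation.
#' @param params a [cell_parameters()] object.
#' @return named numeric vector of currents (pA/pF): `ICaL`, `ICaT`, `INa`,
#'   `Ito1`, `IKr`, `IKs`, `IK1`, `ICab`, `INab`, `IClb`, `INCX`, `INaK`,
#'   `ICaP`.
#' @export
compute_membrane_currents <- function(state, params) {
  if (any(!is.finite(state))) stop("invalid state: non-finite values")
  .cw_currents(as.numeric(state), pack_params(params))
}

#' SERCA uptake flux
#'
#' Reversible Hill pump (cytosol to SR positive, cytosolic frame, mM/ms).
#' The flux magnitude is bounded by `Jmaxup` and is non-decreasing in
#' cytosolic calcium at fixed SR calcium.
#'
#' @param ca_cyto,ca_sr free calcium concentrations, mM.
#' @param Jmaxup maximal pump flux, mM/ms (defaults to the value carried by
#'   `params`).
#' @param params a [cell_parameters()] object (supplies the half-activation
#'   constants).
#' @param components if `TRUE`, return the forward and reverse components
#'   alongside the net flux.
#' @export
compute_serca_flux <- function(ca_cyto, ca_sr, Jmaxup = params$Jmaxup,
                               params = baseline_parameters(),
                               components = FALSE) {
  if (any(ca_cyto < 0) || any(ca_sr < 0)) stop("negative concentration")
  r <- .model_refs()
  fwd <- (ca_cyto / r$kmf_up)^r$h_up
  rev <- (ca_sr / r$kmr_up)^r$h_up
  den <- 1 + fwd + rev
  net <- Jmaxup * (fwd - rev) / den
  if (components)
    list(net = net, forward = Jmaxup * fwd / den, reverse = Jmaxup * rev / den)
  else net
}

#' Ryanodine-receptor release flux
#'
#' Deterministic mean-field release through one effective calcium release
#' unit: flux (SR to sub-SR space positive, sub-SR frame, mM/ms) is the open
#' fraction times the SR/sub-SR concentration gradient, scaled by the
#' release-unit density (`NRyRs`, `RyR_P[11]`, both as ratios to baseline).
#'
#' @param open_fraction CRU open fraction in `[0, 1]`.
#' @param ca_srs,ca_sr free calcium in the sub-SR space and SR, mM.
#' @param RyR_P RyR property vector (zero-based indexing convention).
#' @param NRyRs receptors per release unit.
#' @export
compute_ryr_release <- function(open_fraction, ca_srs, ca_sr,
                                RyR_P = .baseline_ryr_p(), NRyRs = 198000) {
  if (any(RyR_P <= 0)) stop("RyR_P entries must be strictly positive")
  if (any(open_fraction < 0 | open_fraction > 1))
    stop("open fraction must lie in [0, 1]")
  r <- .model_refs()
  rp0 <- .baseline_ryr_p()
  krel <- r$krel * (NRyRs / 198000) * (RyR_P[12] / rp0[12])
  krel * open_fraction * (ca_sr - ca_srs)
}

#' Steady-state CRU open fraction
#'
#' Closed-form steady state of the mean-field closed/open/refractory gating
#' scheme at clamped sub-SR and SR calcium. In the low-calcium linear regime
#' the open fraction is proportional to the single-channel open-probability
#' scale `RyR_P[5]`.
#'
#' @inheritParams compute_ryr_release
#' @export
ryr_open_steady <- function(ca_srs, ca_sr, RyR_P = .baseline_ryr_p()) {
  if (any(RyR_P <= 0)) stop("RyR_P entries must be strictly positive")
  r <- .model_refs()
  rp0 <- .baseline_ryr_p()
  kopen <- r$kopen * (RyR_P[6] / rp0[6]) *
    ca_srs^r$hact / (ca_srs^r$hact + r$ksrs^r$hact) *
    ca_sr^r$hsr / (ca_sr^r$hsr + r$ksrload^r$hsr)
  kclose <- r$kclose / (RyR_P[2] / rp0[2])
  ki <- r$ki0 * ca_srs / (ca_srs + r$kihalf)
  cin <- r$kci * ca_srs^2 / (ca_srs^2 + r$kcihalf^2)
  # O = kopen C / (kclose + ki); R = (ki O + cin C) / kr; C + O + R = 1
  o_over_c <- kopen / (kclose + ki)
  r_over_c <- (ki * o_over_c + cin) / r$kr
  o_over_c / (1 + o_over_c + r_over_c)
}

#' Instantaneous-buffering attenuation
#'
#' Applies the rapid-buffering approximation: the net free-calcium rate of a
#' compartment is the unbuffered rate times an attenuation factor in (0, 1].
#' The cytosolic and sub-sarcolemmal compartments carry a fixed high-affinity
#' buffer plus a scalable low-affinity buffer whose dissociation constant is
#' multiplied by `Buff_factor`; because the working calcium range lies below
#' that buffer's Kd, decreasing `Buff_factor` below 1 strictly strengthens
#' buffering (smaller attenuation). The SR (calsequestrin), sub-SR and
#' junctional buffers are fixed.
#'
#' @param free_ca_rate unbuffered net rate, mM/ms.
#' @param ca free calcium in the compartment, mM.
#' @param Buff_factor buffering factor (> 0; < 1 strengthens buffering).
#' @param compartment one of `"cytosol"`, `"SL"`, `"SR"`, `"SRS"`,
#'   `"junctional"`.
#' @param attenuation_only if `TRUE`, return the attenuation factor itself.
#' @export
apply_buffering <- function(free_ca_rate, ca, Buff_factor = 1.0,
                            compartment = c("cytosol", "SL", "SR", "SRS",
                                            "junctional"),
                            attenuation_only = FALSE) {
  if (Buff_factor <= 0) stop("Buff_factor must be strictly positive")
  if (any(ca < 0)) stop("negative concentration")
  compartment <- match.arg(compartment)
  r <- .model_refs()
  bpow <- switch(compartment,
    cytosol = ,
    SL = r$bfc * r$kdfc / (r$kdfc + ca)^2 +
         r$bsc * (r$kdsc * Buff_factor) / (r$kdsc * Buff_factor + ca)^2,
    SR = r$bcsq * r$kdcsq / (r$kdcsq + ca)^2,
    SRS = r$bsrs * r$kdsrs / (r$kdsrs + ca)^2,
    junctional = r$bj * r$kdj / (r$kdj + ca)^2)
  att <- 1 / (1 + bpow)
  if (attenuation_only) att else free_ca_rate * att
}

#' Inter-domain calcium diffusion
#'
#' Linear nearest-neighbour diffusion between the cytosolic spaces of the
#' serially coupled domains, with reflecting ends. Each interface flux is
#' proportional to the concentration difference and directed down-gradient;
#' because domain cytosolic volumes are equal, the volume-weighted sum of
#' all rates vanishes (internal diffusion conserves calcium).
#'
#' @param ca_by_domain free cytosolic calcium per domain, mM.
#' @param geometry a [cell_geometry()].
#' @return per-domain net diffusive rate, mM/ms.
#' @export
compute_diffusion <- function(ca_by_domain, geometry = cell_geometry()) {
  n <- geometry$n_domains
  if (length(ca_by_domain) != n)
    stop(sprintf("expected %d domain concentrations, got %d", n,
                 length(ca_by_domain)))
  g <- geometry$diffusion_coupling
  rate <- numeric(n)
  d <- diff(ca_by_domain)          # interface fluxes, domain i -> i+1
  rate[-n] <- rate[-n] + g * d
  rate[-1] <- rate[-1] - g * d
  rate
}

#' Full right-hand side of the cell model
#'
#' Time derivative of the complete state under an applied stimulus, plus the
#' membrane currents and per-domain fluxes used to assemble it. Voltage
#' follows `dV/dt = -(total ionic current - stimulus)`; every internal
#' calcium flux appears with opposite sign in its source and sink
#' compartments, weighted by the volume ratio.
#'
#' @param t time, ms (the system is autonomous; kept for solver interfaces).
#' @param state state vector.
#' @param params a [cell_parameters()] object.
#' @param stimulus applied stimulus, pA/pF (positive = depolarizing).
#' @param closed_cell if `TRUE`, evaluate with all sarcolemmal calcium
#'   fluxes disabled (conservation test configuration).
#' @return list with `dy`, `currents`, and per-domain `Jrel`, `Jup`,
#'   `Jleak`, `Jdiff`.
#' @export
cell_rhs <- function(t, state, params, stimulus = 0, closed_cell = FALSE) {
  p <- pack_params(params)
  if (closed_cell) p[c("GCAL", "GCAT", "GCAB", "VCAP", "VNCX")] <- 0
  .cw_rhs(as.numeric(state), p, stimulus)
}

#' Total cell calcium
#'
#' Volume-weighted free plus buffer-bound calcium summed over every
#' compartment of every domain (mol equivalents, reported in mM x litre).
#' Conserved in the closed-cell configuration.
#'
#' @inheritParams cell_rhs
#' @export
total_calcium <- function(state, params) {
  r <- .model_refs()
  g <- params$geometry
  n <- g$n_domains
  idx <- state_idx(n)
  bound <- function(ca, b, kd) b * ca / (kd + ca)
  tot_c <- function(ca) ca + bound(ca, r$bfc, r$kdfc) +
    bound(ca, r$bsc, r$kdsc * params$Buff_factor)
  ca <- state[idx$ca_cyto]; casr <- state[idx$ca_sr]; cass <- state[idx$ca_srs]
  casl <- state[idx$ca_sl]; caj <- state[idx$ca_junct]
  sum(g$v_cyto * tot_c(ca)) +
    sum(g$v_sr * (casr + bound(casr, r$bcsq, r$kdcsq))) +
    sum(g$v_srs * (cass + bound(cass, r$bsrs, r$kdsrs))) +
    sum(g$v_sl * tot_c(casl)) +
    sum(g$v_junct * (caj + bound(caj, r$bj, r$kdj)))
}
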