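#' Default quiescent state
#'
#' Packaged initial condition: resting potential -78 mV, diastolic cytosolic
#' calcium 0.1 uM, SR calcium 0.5 mM, intracellular sodium 9.5 mM and
#' potassium 140 mM; gates at their voltage steady state, release units
#' closed. Runs normally refine this state by pre-pacing.
#'
#' @param params a [cell_parameters()] object.
#' @return a named numeric state vector of class `cell_state`.
#' @export
default_state <- function(params = baseline_parameters()) {
  n <- params$geometry$n_domains
  V <- -78
  gates <- .cw_gating_inf(V)
  dom <- rep(c(1e-4, 0.5, 1e-4, 0, 0), n)
  y <- c(V, gates, 9.5, 140, dom, rep(1e-4, 4))
  names(y) <- state_names(n)
  structure(y, class = "cell_state")
}

state_names <- function(n) {
  gnames <- c("m", "h", "j", "d", "f", "b", "g", "oa", "oi", "xr", "xs")
  dom <- as.vector(vapply(seq_len(n), function(i)
    paste0(c("Ca_cyto", "Ca_SR", "Ca_SRS", "O", "R"), "_", i),
    character(5)))
  c("V", gnames, "Na_i", "K_i", dom, "Ca_SL_1", paste0("Ca_SL_", n),
    "Ca_junct_1", paste0("Ca_junct_", n))
}

# index helpers into the packed state vector (1-based)
state_idx <- function(n) {
  list(V = 1L, gates = 2L:12L, Na = 13L, K = 14L,
       ca_cyto = 15L + 5L * (seq_len(n) - 1L),
       ca_sr = 16L + 5L * (seq_len(n) - 1L),
       ca_srs = 17L + 5L * (seq_len(n) - 1L),
       o = 18L + 5L * (seq_len(n) - 1L),
       r = 19L + 5L * (seq_len(n) - 1L),
       ca_sl = 14L + 5L * n + 1:2,
       ca_junct = 14L + 5L * n + 3:4)
}

validate_state <- function(y, params) {
  n <- params$geometry$n_domains
  if (length(y) != 14L + 5L * n + 4L) stop("state vector has wrong length")
  if (any(!is.finite(y))) stop("invalid state: non-finite values")
  idx <- state_idx(n)
  conc <- c(idx$ca_cyto, idx$ca_sr, idx$ca_srs, idx$ca_sl, idx$ca_junct,
            idx$Na, idx$K)
  if (any(y[conc] < 0)) stop("invalid state: negative concentration")
  frac <- c(idx$gates, idx$o, idx$r)
  if (any(y[frac] < 0 | y[frac] > 1)) stop("invalid state: fraction outside [0, 1]")
  invisible(y)
}
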