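#' Pacing protocol
#'
#' Square-pulse field stimulation at a fixed cycle length. The default
#' solver is the fixed-step operator-split integrator (Rush-Larsen
#' exponential updates for the gates, forward Euler elsewhere) at
#' `dt = 0.02` ms; `method = "lsoda"` selects the adaptive stiff solver
#' (relative tolerance 1e-6, absolute 1e-9 by default) as a cross-check.
#'
#' @param cycle_length pacing cycle length, ms.
#' @param n_beats total number of beats to integrate.
#' @param stimulus_amplitude stimulus amplitude, pA/pF (depolarizing).
#' @param stimulus_duration stimulus duration, ms.
#' @param record_last_n_beats how many trailing beats to record.
#' @param output_dt recording interval, ms.
#' @param method `"split"` or `"lsoda"`.
#' @param dt fixed step for the split method, ms.
#' @param rtol,atol tolerances for the lsoda method.
#' @export
pacing_protocol <- function(cycle_length = 1000, n_beats = 10,
                            stimulus_amplitude = 40, stimulus_duration = 2,
                            record_last_n_beats = min(n_beats, 10L),
                            output_dt = 1,
                            method = c("split", "lsoda"),
                            dt = 0.02, rtol = 1e-6, atol = 1e-9) {
  method <- match.arg(method)
  stopifnot(cycle_length > stimulus_duration, stimulus_duration > 0,
            n_beats >= record_last_n_beats, record_last_n_beats >= 1,
            output_dt > 0, dt > 0)
  structure(list(cycle_length = cycle_length, n_beats = as.integer(n_beats),
                 stimulus_amplitude = stimulus_amplitude,
                 stimulus_duration = stimulus_duration,
                 record_last_n_beats = as.integer(record_last_n_beats),
                 output_dt = output_dt, method = method, dt = dt,
                 rtol = rtol, atol = atol),
            class = "pacing_protocol")
}

new_simulation_result <- function(t, V, ca_cyto, na_i, ca_sr_mean, protocol,
                                  params, meta = list()) {
  stopifnot(ncol(ca_cyto) == length(t), !is.unsorted(t, strictly = TRUE))
  structure(list(t = t, V = V, Ca_cyto = ca_cyto, Na_i = na_i,
                 Ca_SR_mean = ca_sr_mean, protocol = protocol,
                 params = params, meta = meta),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d domains x %d samples, %d beat(s) at CL %g ms\n",
              nrow(x$Ca_cyto), length(x$t), x$protocol$record_last_n_beats,
              x$protocol$cycle_length))
  invisible(x)
}

simulation_failed <- function(t_fail, model_id = NA) {
  structure(class = c("simulation_failed", "error", "condition"),
            list(message = sprintf("simulation failed (diverged) at t = %.1f ms",
                                   t_fail),
                 call = NULL, t_fail = t_fail, model_id = model_id))
}

#' Run a paced simulation
#'
#' Integrates the cell under the pacing protocol and records voltage,
#' sodium and the per-domain cytosolic calcium traces (the in-silico line
#' scan) for the trailing `record_last_n_beats` cycles. Identical inputs
#' yield identical outputs.
#'
#' @param params a [cell_parameters()] object.
#' @param protocol a [pacing_protocol()].
#' @param initial_state a state vector or `"default"`.
#' @param closed_cell disable sarcolemmal calcium fluxes (test
#'   configuration).
#' @param meta provenance list stored on the result (model id, scenario id,
#'   seed).
#' @return a `simulation_result`.
#' @export
run_paced <- function(params, protocol = pacing_protocol(),
                      initial_state = "default", closed_cell = FALSE,
                      meta = list()) {
  y0 <- if (identical(initial_state, "default")) default_state(params)
        else initial_state
  validate_state(as.numeric(y0), params)
  p <- pack_params(params)
  if (closed_cell) p[c("GCAL", "GCAT", "GCAB", "VCAP", "VNCX")] <- 0

  rec_from <- protocol$n_beats - protocol$record_last_n_beats
  if (protocol$method == "split") {
    out <- .cw_integrate(as.numeric(y0), p, protocol$n_beats,
                         protocol$cycle_length, protocol$stimulus_amplitude,
                         protocol$stimulus_duration, protocol$dt,
                         protocol$output_dt, rec_from)
    if (isTRUE(out$failed)) stop(simulation_failed(out$t_fail, meta$model_id))
    nrec <- out$n_recorded
    res <- new_simulation_result(
      t = out$t[seq_len(nrec)] - rec_from * protocol$cycle_length,
      V = out$V[seq_len(nrec)],
      ca_cyto = out$Ca_cyto[, seq_len(nrec), drop = FALSE],
      na_i = out$Na_i[seq_len(nrec)],
      ca_sr_mean = out$Ca_SR_mean[seq_len(nrec)],
      protocol = protocol, params = params, meta = meta)
    attr(res, "final_state") <- out$state
    return(res)
  }

  # adaptive stiff solver, integrated beat by beat so the stimulus edges
  # fall on segment boundaries
  n <- params$geometry$n_domains
  idx <- state_idx(n)
  y <- as.numeric(y0)
  keep_t <- c(); keep_y <- NULL
  deriv <- function(t, y, parms, stim) list(.cw_rhs_dy(y, p, stim))
  for (beat in seq_len(protocol$n_beats) - 1L) {
    record <- beat >= rec_from
    for (seg in 1:2) {
      t0 <- if (seg == 1) 0 else protocol$stimulus_duration
      t1 <- if (seg == 1) protocol$stimulus_duration else protocol$cycle_length
      stim <- if (seg == 1) protocol$stimulus_amplitude else 0
      times <- if (record)
        unique(c(seq(t0, t1, by = protocol$output_dt), t1)) else c(t0, t1)
      sol <- deSolve::lsoda(y, times, deriv, parms = NULL, stim = stim,
                            rtol = protocol$rtol, atol = protocol$atol,
                            maxsteps = 50000)
      if (attr(sol, "istate")[1] < 0 || any(!is.finite(sol[nrow(sol), -1])))
        stop(simulation_failed(beat * protocol$cycle_length +
                               sol[nrow(sol), 1], meta$model_id))
      y <- as.numeric(sol[nrow(sol), -1])
      if (record) {
        seg_keep <- sol[-nrow(sol), , drop = FALSE]
        keep_t <- c(keep_t, (beat - rec_from) * protocol$cycle_length +
                      seg_keep[, 1])
        keep_y <- rbind(keep_y, seg_keep[, -1, drop = FALSE])
      }
    }
  }
  keep_t <- c(keep_t, protocol$record_last_n_beats * protocol$cycle_length)
  keep_y <- rbind(keep_y, y)
  res <- new_simulation_result(
    t = keep_t, V = keep_y[, idx$V],
    ca_cyto = t(keep_y[, idx$ca_cyto, drop = FALSE]),
    na_i = keep_y[, idx$Na],
    ca_sr_mean = rowMeans(keep_y[, idx$ca_sr, drop = FALSE]),
    protocol = protocol, params = params, meta = meta)
  attr(res, "final_state") <- y
  res
}

#' Pace to a quasi-steady state
#'
#' Paces beat by beat until the relative beat-to-beat change in diastolic
#' cytosolic calcium, SR calcium and intracellular sodium all fall below
#' `tolerance`, or `beat_cap` beats have been run. The returned state
#' carries attributes `converged`, `beats` and `stopping_rule`.
#'
#' @inheritParams run_paced
#' @param tolerance relative convergence tolerance (> 0).
#' @param beat_cap maximum number of beats.
#' @export
pace_to_steady <- function(params, protocol = pacing_protocol(),
                           tolerance = 1e-3, beat_cap = 200L,
                           initial_state = "default") {
  stopifnot(tolerance > 0)
  y <- if (identical(initial_state, "default")) as.numeric(default_state(params))
       else as.numeric(initial_state)
  p <- pack_params(params)
  n <- params$geometry$n_domains
  idx <- state_idx(n)
  snap <- function(y) c(mean(y[idx$ca_cyto]), mean(y[idx$ca_sr]), y[idx$Na])
  prev <- snap(y)
  converged <- FALSE; beats <- 0L
  while (beats < beat_cap) {
    out <- .cw_integrate(y, p, 1L, protocol$cycle_length,
                         protocol$stimulus_amplitude,
                         protocol$stimulus_duration, protocol$dt,
                         protocol$cycle_length, 1L)
    if (isTRUE(out$failed)) stop(simulation_failed(out$t_fail))
    y <- out$state
    beats <- beats + 1L
    cur <- snap(y)
    if (all(abs(cur - prev) / pmax(abs(prev), 1e-12) < tolerance)) {
      converged <- TRUE
      break
    }
    prev <- cur
  }
  y <- stats::setNames(y, state_names(n))
  structure(y, class = "cell_state", converged = converged, beats = beats,
            stopping_rule = if (converged) "tolerance" else "beat_cap")
}
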