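#' Action potential duration
#'
#' Duration from the upstroke (maximum dV/dt) to the time at which the
#' membrane potential has recovered `level_pct` percent of the action
#' potential amplitude (peak minus resting potential), with linear
#' interpolation between samples.
#'
#' @param v voltage trace, mV.
#' @param t time grid, ms (same length as `v`).
#' @param level_pct repolarization level, percent (default 90 for APD90).
#' @return duration in ms.
#' @export
apd <- function(v, t, level_pct = 90) {
  stopifnot(length(v) == length(t), length(v) >= 3)
  rmp <- min(v)
  peak <- max(v)
  if (peak - rmp < 20) stop("no action potential upstroke found")
  # upstroke = first point of near-maximal dV/dt; a trace that starts at or
  # inside the upstroke (no rising edge) is taken to begin at the upstroke
  dvdt <- diff(v) / diff(t)
  i_up <- if (max(dvdt) > 1) which(dvdt >= 0.5 * max(dvdt))[1] else 1L
  t_up <- t[i_up]
  i_peak <- i_up - 1L + which.max(v[i_up:length(v)])
  level <- peak - level_pct / 100 * (peak - rmp)
  below <- which(seq_along(v) > i_peak & v < level)
  if (!length(below)) stop("trace does not repolarize to the requested level")
  i2 <- below[1]; i1 <- i2 - 1L
  # linear interpolation of the crossing
  t_cross <- if (v[i1] == v[i2]) t[i2] else
    t[i1] + (level - v[i1]) / (v[i2] - v[i1]) * (t[i2] - t[i1])
  t_cross - t_up
}

#' Resting membrane potential
#'
#' Diastolic potential over the final 50 ms before each stimulus, averaged
#' over beats. `method = "min"` (default) takes the window minimum,
#' `"mean"` the window mean.
#'
#' @param v voltage trace, mV.
#' @param t time grid, ms.
#' @param stimulus_times stimulus onset times, ms.
#' @param window diastolic window length before each stimulus, ms.
#' @param method `"min"` or `"mean"`.
#' @export
rmp <- function(v, t, stimulus_times, window = 50,
                method = c("min", "mean")) {
  if (!length(v) || !length(t)) stop("empty trace")
  stopifnot(length(v) == length(t))
  method <- match.arg(method)
  vals <- vapply(stimulus_times, function(s) {
    w <- t >= s - window & t < s
    if (!any(w)) return(NA_real_)
    if (method == "min") min(v[w]) else mean(v[w])
  }, numeric(1))
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("no diastolic interval before any stimulus")
  mean(vals)
}

# time spent above a threshold, with linear interpolation at the crossings
time_above <- function(x, t, threshold) {
  above <- x > threshold
  if (!any(above)) return(0)
  total <- 0
  n <- length(x)
  for (i in seq_len(n - 1L)) {
    a <- above[i]; b <- above[i + 1L]
    dt <- t[i + 1L] - t[i]
    if (a && b) total <- total + dt
    else if (a != b) {
      frac <- (threshold - x[i]) / (x[i + 1L] - x[i])
      total <- total + if (b) (1 - frac) * dt else frac * dt
    }
  }
  total
}

#' Per-beat calcium transient metrics
#'
#' For each beat window: amplitude (peak minus the pre-stimulus diastolic
#' level at the window start), CD50 (time spent above diastolic + 50% of
#' amplitude, interpolated), and the diastolic level itself. A flat trace
#' yields amplitude 0 and CD50 0.
#'
#' @param ca calcium trace (any concentration unit; outputs match it).
#' @param t time grid, ms.
#' @param beat_windows two-column matrix of window start/end times, ms.
#' @return data.frame with one row per beat: `amplitude`, `cd50`,
#'   `diastolic`.
#' @export
cat_metrics <- function(ca, t, beat_windows) {
  beat_windows <- matrix(beat_windows, ncol = 2)
  if (!nrow(beat_windows)) stop("at least one beat window is required")
  out <- apply(beat_windows, 1, function(bw) {
    w <- t >= bw[1] & t < bw[2]
    x <- unname(ca[w]); tt <- t[w]
    dia <- x[1]
    amp <- max(x) - dia
    cd50 <- if (amp <= 0) 0 else time_above(x, tt, dia + 0.5 * amp)
    c(amplitude = max(amp, 0), cd50 = cd50, diastolic = dia)
  })
  as.data.frame(t(out))
}

#' Central-to-membrane calcium transient amplitude ratio
#'
#' @param catc_amp,catm_amp central and membrane amplitudes (same units,
#'   non-negative). A zero membrane amplitude yields ratio 0 flagged as
#'   degenerate.
#' @export
cat_ratio <- function(catc_amp, catm_amp) {
  if (any(catc_amp < 0) || any(catm_amp < 0)) stop("amplitudes must be >= 0")
  r <- ifelse(catm_amp == 0, 0, catc_amp / catm_amp)
  attr(r, "degenerate") <- catm_amp == 0
  r
}

central_domain_indices <- function(n) {
  unique(c(floor((n + 1) / 2), floor(n / 2) + 1L))
}

#' Per-beat biomarkers of a simulation result
#'
#' Membrane calcium (CaTm) is the mean of the two membrane domains'
#' cytosolic traces; central calcium (CaTc) the mean of the two centermost
#' domains. Amplitudes are reported in uM. Each beat's resting potential is
#' taken over the final 50 ms of its own cycle.
#'
#' @param result a `simulation_result` (or the shaped list produced by
#'   [gen_linescan()]).
#' @param rmp_method passed to [rmp()].
#' @param per_domain if `TRUE`, attach beats x domains matrices of per-domain
#'   amplitudes and diastolic levels (uM) as attributes
#'   `domain_amplitudes` and `domain_diastolic`.
#' @return data.frame with one row per recorded beat.
#' @export
beat_biomarkers <- function(result, rmp_method = "min", per_domain = FALSE) {
  t <- result$t
  cl <- result$protocol$cycle_length
  nb <- result$protocol$record_last_n_beats
  n <- nrow(result$Ca_cyto)
  mem <- result$params$geometry$membrane_domain_indices
  if (is.null(mem)) mem <- c(1L, n)
  cen <- central_domain_indices(n)
  catm_tr <- colMeans(result$Ca_cyto[mem, , drop = FALSE]) * 1e3
  catc_tr <- colMeans(result$Ca_cyto[cen, , drop = FALSE]) * 1e3
  windows <- cbind(seq_len(nb) - 1, seq_len(nb)) * cl
  m_m <- cat_metrics(catm_tr, t, windows)
  m_c <- cat_metrics(catc_tr, t, windows)

  has_v <- !is.null(result$V)
  apd90 <- rmp_b <- rep(NA_real_, nb)
  if (has_v) {
    for (b in seq_len(nb)) {
      w <- t >= windows[b, 1] & t < windows[b, 2]
      apd90[b] <- tryCatch(apd(result$V[w], t[w]), error = function(e) NA_real_)
      rmp_b[b] <- rmp(result$V, t, windows[b, 2], method = rmp_method)
    }
  }
  dia_na <- if (!is.null(result$Na_i))
    vapply(seq_len(nb), function(b) {
      w <- t >= windows[b, 2] - 50 & t < windows[b, 2]
      mean(result$Na_i[w])
    }, numeric(1)) else rep(NA_real_, nb)

  out <- data.frame(beat = seq_len(nb), APD90 = apd90, RMP = rmp_b,
             CaTm_amplitude = m_m$amplitude, CaTc_amplitude = m_c$amplitude,
             CaT_ratio = as.numeric(cat_ratio(m_c$amplitude, m_m$amplitude)),
             CD50m = m_m$cd50, CD50c = m_c$cd50,
             diastolic_CaTm = m_m$diastolic, diastolic_CaTc = m_c$diastolic,
             diastolic_Na = dia_na)
  if (per_domain) {
    amp <- dia <- matrix(NA_real_, nb, n)
    for (d in seq_len(n)) {
      md <- cat_metrics(result$Ca_cyto[d, ] * 1e3, t, windows)
      amp[, d] <- md$amplitude
      dia[, d] <- md$diastolic
    }
    attr(out, "domain_amplitudes") <- amp
    attr(out, "domain_diastolic") <- dia
  }
  out
}

#' Mean and SD of per-model biomarkers across a population
#'
#' One row per population, mirroring the standard AP/CaT property table:
#' APD90, RMP, membrane and central CaT amplitudes, their ratio, and the
#' CD50 durations, as mean +/- SD of per-model beat-averaged values.
#'
#' @param biomarker_list list of per-model data.frames from
#'   [beat_biomarkers()].
#' @param population label for the row.
#' @export
summarize_biomarkers <- function(biomarker_list, population = "population") {
  cols <- c("APD90", "RMP", "CaTm_amplitude", "CaTc_amplitude", "CaT_ratio",
            "CD50m", "CD50c", "diastolic_Na")
  per_model <- t(vapply(biomarker_list, function(df)
    colMeans(df[cols], na.rm = TRUE), numeric(length(cols))))
  out <- data.frame(population = population)
  for (cn in cols) {
    out[[paste0(cn, "_mean")]] <- mean(per_model[, cn], na.rm = TRUE)
    out[[paste0(cn, "_sd")]] <- stats::sd(per_model[, cn], na.rm = TRUE)
  }
  out
}

#' Welch two-sample comparison of a biomarker between populations
#'
#' @param values_a,values_b numeric vectors (>= 2 values each).
#' @param alpha significance level.
#' @return list with per-group mean and SD, the Welch t statistic, p value
#'   and a significance flag at `alpha`.
#' @export
compare_populations <- function(values_a, values_b, alpha = 0.05) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 values")
  tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  list(mean_a = mean(values_a), sd_a = stats::sd(values_a),
       mean_b = mean(values_b), sd_b = stats::sd(values_b),
       statistic = unname(tt$statistic), p_value = tt$p.value,
       significant = tt$p.value < alpha, alpha = alpha)
}
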