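wave_categories <- c("normal", "alternans", "silencing",
                     "alternans_and_silencing", "other")

#' Detect calcium transient alternans
#'
#' True if any pair of consecutive beats differs in amplitude by more than
#' `threshold` (default 5%), normalized by the larger of the pair
#' (`normalize = "max"`, symmetric and bounded) or by the pair mean.
#' Pairs in which both amplitudes are zero are excluded.
#'
#' @param beat_amplitudes per-beat amplitudes (>= 2 beats).
#' @param threshold relative difference threshold.
#' @param normalize `"max"` or `"mean"`.
#' @export
detect_alternans <- function(beat_amplitudes, threshold = 0.05,
                             normalize = c("max", "mean")) {
  if (length(beat_amplitudes) < 2) stop("need at least 2 beats")
  normalize <- match.arg(normalize)
  a <- beat_amplitudes[-length(beat_amplitudes)]
  b <- beat_amplitudes[-1]
  denom <- if (normalize == "max") pmax(a, b) else (a + b) / 2
  keep <- denom > 0
  any(abs(b - a)[keep] / denom[keep] > threshold)
}

#' Detect calcium silencing
#'
#' True if the central-to-membrane amplitude ratio is at or below
#' `threshold` (default 0.10, boundary inclusive) on every beat.
#'
#' @param beat_ratios per-beat CaT ratios (>= 1 beat).
#' @param threshold silencing threshold.
#' @export
detect_silencing <- function(beat_ratios, threshold = 0.10) {
  if (!length(beat_ratios)) stop("need at least 1 beat")
  all(beat_ratios <= threshold)
}

# period-1: consecutive beats agree within tol; period-2: beats two cycles
# apart agree within tol. Lag-based comparisons tolerate slow monotone trends
# that are not beat-period patterns.
period_pattern_ok <- function(amps, tol = 0.05, floor_um = 0.02) {
  lag_ok <- function(lag) {
    a <- amps[seq_len(length(amps) - lag)]
    b <- amps[seq_len(length(amps) - lag) + lag]
    all(abs(b - a) / pmax(a, b, floor_um) <= tol)
  }
  lag_ok(1L) || (length(amps) > 2L && lag_ok(2L))
}

#' Validity checks for a simulated cell
#'
#' Flags that route a model to the "other" (unphysiological) category:
#' repolarization failure (diastolic potential fails to return within
#' 15 mV of the starting resting potential before a stimulus), irregular
#' dynamics (membrane amplitude sequence neither period-1 nor period-2
#' within 5%), and outright simulation failure. Irregularity is assessed
#' relative to at least 0.02 uM so numerically tiny transients are not
#' flagged.
#'
#' @param result a `simulation_result` (a trace-only line scan yields
#'   voltage flags of `FALSE`).
#' @param biomarkers optional precomputed [beat_biomarkers()] table.
#' @return named logical vector: `repolarization_failure`,
#'   `irregular_dynamics`, `simulation_failure`.
#' @export
check_validity <- function(result, biomarkers = NULL) {
  if (inherits(result, "simulation_failed") || isTRUE(result$meta$failed))
    return(c(repolarization_failure = FALSE, irregular_dynamics = FALSE,
             simulation_failure = TRUE))
  if (is.null(biomarkers)) biomarkers <- beat_biomarkers(result)
  repol <- FALSE
  if (!is.null(result$V)) {
    cl <- result$protocol$cycle_length
    nb <- result$protocol$record_last_n_beats
    ref <- result$V[1]
    dia <- vapply(seq_len(nb), function(b) {
      w <- result$t >= b * cl - 50 & result$t < b * cl
      min(result$V[w])
    }, numeric(1))
    repol <- any(dia > ref + 15)
  }
  irregular <- !period_pattern_ok(biomarkers$CaTm_amplitude)
  c(repolarization_failure = repol, irregular_dynamics = irregular,
    simulation_failure = FALSE)
}

#' Classify a cell into one of five calcium-wave categories
#'
#' Categories: normal propagation, calcium alternans, calcium silencing,
#' alternans with silencing, and "other" (unphysiological). Precedence:
#' validity flags force "other"; otherwise silencing and alternans are
#' combined from their detectors. Alternans is evaluated on the
#' membrane-domain amplitude sequence.
#'
#' @param result a `simulation_result`, or a `simulation_failed` condition
#'   (classified as "other").
#' @param alternans_threshold,silencing_threshold detector thresholds.
#' @return list with `category` (factor over the five categories) and
#'   `evidence` (per-beat amplitudes and ratios, validity flags).
#' @export
classify <- function(result, alternans_threshold = 0.05,
                     silencing_threshold = 0.10) {
  if (inherits(result, "simulation_failed")) {
    return(list(category = factor("other", levels = wave_categories),
                evidence = list(flags = c(repolarization_failure = FALSE,
                                          irregular_dynamics = FALSE,
                                          simulation_failure = TRUE),
                                t_fail = result$t_fail)))
  }
  bm <- beat_biomarkers(result)
  flags <- check_validity(result, bm)
  sil <- detect_silencing(bm$CaT_ratio, silencing_threshold)
  # alternans needs at least two beats; a single-beat recording cannot show it
  alt <- nrow(bm) >= 2 &&
    detect_alternans(bm$CaTm_amplitude, alternans_threshold)
  category <- if (any(flags)) "other"
    else if (sil && alt) "alternans_and_silencing"
    else if (sil) "silencing"
    else if (alt) "alternans"
    else "normal"
  list(category = factor(category, levels = wave_categories),
       evidence = list(amplitudes = bm$CaTm_amplitude,
                       ratios = bm$CaT_ratio, flags = flags))
}

#' Category percentages for a population
#'
#' @param categories vector (or factor) of per-model categories.
#' @return named numeric vector of percentages over the five categories,
#'   summing to 100.
#' @export
summarize_population <- function(categories) {
  if (!length(categories)) stop("empty category list")
  categories <- factor(as.character(unlist(categories)),
                       levels = wave_categories)
  if (anyNA(categories)) stop("unknown category label")
  100 * table(categories) / length(categories)
}

#' Classify an externally supplied line-scan matrix
#'
#' Runs the wave classifier on a domains x time calcium matrix without the
#' simulator (voltage-based validity checks are skipped unless a voltage
#' trace is supplied).
#'
#' @param ca_matrix numeric matrix, rows = domains, columns = time points.
#' @param t time grid, ms; defaults to 0, 1, ... columns-1.
#' @param cycle_length pacing period of the recording, ms.
#' @param v optional voltage trace.
#' @param ... passed to [classify()].
#' @export
classify_linescan <- function(ca_matrix, cycle_length, t = NULL, v = NULL,
                              ...) {
  ca_matrix <- as.matrix(ca_matrix)
  if (is.null(t)) t <- seq_len(ncol(ca_matrix)) - 1
  nb <- floor((max(t) + (t[2] - t[1])) / cycle_length)
  if (nb < 1) stop("recording shorter than one cycle")
  res <- list(t = t, V = v, Ca_cyto = ca_matrix, Na_i = NULL,
              protocol = list(cycle_length = cycle_length,
                              record_last_n_beats = nb),
              params = list(geometry = list(
                membrane_domain_indices = c(1L, nrow(ca_matrix)))),
              meta = list())
  classify(res, ...)
}
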