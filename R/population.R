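#' Calibration criteria for the control population
#'
#' A candidate model is accepted if, under the calibration protocol, it
#' shows (1) fully regenerative centripetal calcium wave propagation
#' (beat-averaged CaT ratio at or above `min_cat_ratio`), (2) no alternans
#' and no afterdepolarizations, and (3) AP and calcium transient biomarkers
#' within the physiological windows. Default windows are the control-
#' population mean +/- 2 SD: APD90 70-122 ms, resting potential -82 to
#' -74 mV, membrane CaT amplitude 0.19-0.47 uM.
#'
#' @param apd90_window APD90 window, ms.
#' @param rmp_window resting membrane potential window, mV.
#' @param catm_window membrane CaT amplitude window, uM.
#' @param min_cat_ratio full-propagation minimum CaT ratio, in (0, 1].
#' @param forbid_alternans,forbid_afterdepolarizations prohibition flags.
#' @export
calibration_criteria <- function(apd90_window = c(70, 122),
                                 rmp_window = c(-82, -74),
                                 catm_window = c(0.19, 0.47),
                                 min_cat_ratio = 0.5,
                                 forbid_alternans = TRUE,
                                 forbid_afterdepolarizations = TRUE) {
  stopifnot(length(apd90_window) == 2, diff(apd90_window) > 0,
            length(rmp_window) == 2, diff(rmp_window) > 0,
            length(catm_window) == 2, diff(catm_window) > 0,
            min_cat_ratio > 0, min_cat_ratio <= 1)
  structure(list(apd90_window = apd90_window, rmp_window = rmp_window,
                 catm_window = catm_window, min_cat_ratio = min_cat_ratio,
                 forbid_alternans = isTRUE(forbid_alternans),
                 forbid_afterdepolarizations =
                   isTRUE(forbid_afterdepolarizations)),
            class = "calibration_criteria")
}

default_sampling_ranges <- function() {
  nm <- c("GCaL", "GNa", "Gto1", "GKr", "GKs", "GK1", "ImaxNCX", "ImaxNaK")
  stats::setNames(rep(list(c(0.5, 2.0)), length(nm)), nm)
}

#' Sample candidate models
#'
#' Draws `n` parameter sets whose maximum conductances/fluxes are the
#' baseline values times log-uniform multipliers within the given ranges.
#' All calcium-handling parameters (`Jmaxup`, `RyR_P`, `NRyRs`,
#' `Buff_factor`) stay at baseline. Reproducible under a fixed seed.
#'
#' @param n number of candidates (>= 0).
#' @param ranges named list of multiplicative `c(lo, hi)` intervals per
#'   conductance; defaults to `[0.5, 2]` on GCaL, GNa, Gto1, GKr, GKs, GK1,
#'   ImaxNCX, ImaxNaK.
#' @param seed integer seed.
#' @param base baseline parameter set the multipliers act on.
#' @param method `"random"` (independent log-uniform draws) or `"lhs"`
#'   (Latin-hypercube stratification of the same log-uniform ranges).
#' @return list of `cell_params`, each carrying a `model_id` and its
#'   `multipliers` as attributes.
#' @export
sample_candidates <- function(n, ranges = default_sampling_ranges(),
                              seed = 1L, base = baseline_parameters(),
                              method = c("random", "lhs")) {
  stopifnot(n >= 0)
  method <- match.arg(method)
  if (!length(ranges) || is.null(names(ranges)))
    stop("ranges must be a named list of intervals")
  for (r in ranges)
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2])
      stop("each range must be a positive interval c(lo, hi)")
  if (n == 0) return(list())
  set.seed(seed)
  u <- if (method == "lhs") {
    if (!requireNamespace("lhs", quietly = TRUE))
      stop("the 'lhs' package is required for method = \"lhs\"")
    lhs::randomLHS(n, length(ranges))
  } else {
    matrix(stats::runif(n * length(ranges)), nrow = n, byrow = TRUE)
  }
  lo <- log(vapply(ranges, `[`, numeric(1), 1))
  hi <- log(vapply(ranges, `[`, numeric(1), 2))
  lapply(seq_len(n), function(i) {
    p <- base
    mult <- stats::setNames(exp(lo + u[i, ] * (hi - lo)), names(ranges))
    for (nm in names(mult)) p[[nm]] <- p[[nm]] * mult[[nm]]
    p <- validate_cell_parameters(p)
    attr(p, "model_id") <- i
    attr(p, "multipliers") <- mult
    p
  })
}

# afterdepolarization: any rebound of V more than 5 mV above the running
# repolarization envelope between the end of the AP and the next stimulus
detect_afterdepolarization <- function(v, t, cycle_length, n_beats,
                                       threshold = 5) {
  for (b in seq_len(n_beats)) {
    w <- which(t >= (b - 1) * cycle_length & t < b * cycle_length)
    vb <- v[w]
    ip <- which.max(vb)
    post <- vb[seq(min(ip + 1, length(vb)), length(vb))]
    # skip the repolarization ramp: start checking once V < peak - 60% amp
    start <- which(post < max(vb) - 0.6 * (max(vb) - min(vb)))[1]
    if (is.na(start)) next
    seg <- post[start:length(post)]
    if (any(seg - cummin(seg) > threshold)) return(TRUE)
  }
  FALSE
}

evaluate_candidate <- function(params, criteria, protocol) {
  res <- tryCatch(run_paced(params, protocol),
                  simulation_failed = function(e) e)
  if (inherits(res, "simulation_failed")) {
    checks <- c(simulation = FALSE, apd90 = NA, rmp = NA, catm = NA,
                propagation = NA, alternans = NA, afterdepolarization = NA)
    return(list(pass = FALSE, checks = checks, reason = "simulation_failed",
                biomarkers = NULL, result = NULL))
  }
  bm <- beat_biomarkers(res)
  apd_m <- mean(bm$APD90, na.rm = TRUE)
  rmp_m <- mean(bm$RMP, na.rm = TRUE)
  catm_m <- mean(bm$CaTm_amplitude)
  ratio_m <- mean(bm$CaT_ratio)
  checks <- c(
    simulation = TRUE,
    apd90 = is.finite(apd_m) && apd_m >= criteria$apd90_window[1] &&
      apd_m <= criteria$apd90_window[2],
    rmp = is.finite(rmp_m) && rmp_m >= criteria$rmp_window[1] &&
      rmp_m <= criteria$rmp_window[2],
    catm = catm_m >= criteria$catm_window[1] &&
      catm_m <= criteria$catm_window[2],
    propagation = ratio_m >= criteria$min_cat_ratio,
    alternans = !criteria$forbid_alternans ||
      !detect_alternans(bm$CaTm_amplitude),
    afterdepolarization = !criteria$forbid_afterdepolarizations ||
      !detect_afterdepolarization(res$V, res$t, protocol$cycle_length,
                                  protocol$record_last_n_beats))
  failed <- names(checks)[!checks %in% TRUE]
  list(pass = all(checks %in% TRUE), checks = checks,
       reason = if (length(failed)) paste(failed, collapse = ";") else "",
       biomarkers = bm, result = res)
}

#' Calibrate candidate models against rabbit-like criteria
#'
#' Simulates every candidate under the calibration protocol and keeps
#' exactly those passing all criteria. Candidates whose simulation diverges
#' are rejected with reason `"simulation_failed"` rather than aborting.
#'
#' @param candidates list of `cell_params` (e.g. from
#'   [sample_candidates()]).
#' @param criteria a [calibration_criteria()].
#' @param protocol the calibration [pacing_protocol()].
#' @param n_accept stop after this many acceptances (default: screen all).
#' @return a `model_population`: accepted models, the criteria, and a
#'   per-candidate diagnostics data.frame (one column per criterion).
#' @export
calibrate <- function(candidates, criteria = calibration_criteria(),
                      protocol = pacing_protocol(n_beats = 40,
                                                 record_last_n_beats = 10),
                      n_accept = Inf) {
  models <- list()
  diag_rows <- list()
  bms <- list()
  for (i in seq_along(candidates)) {
    p <- candidates[[i]]
    id <- attr(p, "model_id")
    if (is.null(id)) id <- i
    ev <- evaluate_candidate(p, criteria, protocol)
    diag_rows[[i]] <- data.frame(model_id = id, pass = ev$pass,
                                 reason = ev$reason,
                                 t(as.data.frame(ev$checks)))
    if (ev$pass) {
      models[[length(models) + 1L]] <- p
      bms[[length(bms) + 1L]] <- ev$biomarkers
      if (length(models) >= n_accept) break
    }
  }
  diagnostics <- do.call(rbind, diag_rows)
  rownames(diagnostics) <- NULL
  structure(list(models = models, criteria = criteria, protocol = protocol,
                 diagnostics = diagnostics, biomarkers = bms),
            class = "model_population")
}

#' @export
print.model_population <- function(x, ...) {
  cat(sprintf("<model_population> %d accepted of %d screened\n",
              length(x$models), nrow(x$diagnostics)))
  invisible(x)
}

#' Build a calibrated control population
#'
#' Samples candidate conductance sets and accepts the first `n_accept`
#' passers of the calibration criteria, mirroring the published control
#' population of 16 models drawn from a larger screened pool.
#'
#' @param n_accept population size to accept.
#' @param n_candidates candidate pool size.
#' @param seed sampling seed (also recorded in the result).
#' @param ranges sampling ranges, see [sample_candidates()].
#' @param criteria,protocol calibration settings.
#' @export
build_population <- function(n_accept = 16L, n_candidates = 300L, seed = 1L,
                             ranges = default_sampling_ranges(),
                             criteria = calibration_criteria(),
                             protocol = pacing_protocol(n_beats = 40,
                                                        record_last_n_beats = 10)) {
  cand <- sample_candidates(n_candidates, ranges = ranges, seed = seed)
  pop <- calibrate(cand, criteria, protocol, n_accept = n_accept)
  pop$seed <- seed
  pop$ranges <- ranges
  pop
}

#' Save / load a population's parameter sets
#'
#' @param population a `model_population`.
#' @param dir output directory (created if needed).
#' @export
write_population <- function(population, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_parameters(population$models, file.path(dir, "population.json"))
  utils::write.csv(population$diagnostics,
                   file.path(dir, "calibration_report.csv"),
                   row.names = FALSE)
  invisible(dir)
}
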