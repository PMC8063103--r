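#' Cell geometry for the spatially discretized myocyte
#'
#' The cell cross-section is segmented into `n_domains` serially coupled
#' transversal domains. The first and last domains face the sarcolemma and
#' carry the membrane currents plus two additional sub-volumes (the
#' sub-sarcolemmal space and the junctional space under the L-type channel
#' clusters); interior domains contain only cytosol, sarcoplasmic reticulum
#' (SR) and a sub-SR space (SRS) hosting the calcium release units.
#' Ends are reflecting: no calcium flux beyond the outer domains.
#'
#' @param n_domains number of transversal domains (>= 3).
#' @param v_cyto_total total cytosolic volume of the slice, litres.
#' @param sr_frac,srs_frac SR and sub-SR volumes as fractions of the
#'   cytosolic volume of each domain.
#' @param sl_frac,junct_frac sub-sarcolemmal and junctional volumes of the
#'   two membrane domains, as fractions of one domain's cytosolic volume.
#' @param diffusion_coupling calcium transfer rate between adjacent domains,
#'   1/ms (symmetric per interface).
#'
#' @return an object of class `cell_geometry`.
#' @export
cell_geometry <- function(n_domains = 18L,
                          v_cyto_total = 7.0e-12,
                          sr_frac = 0.06,
                          srs_frac = 0.02,
                          sl_frac = 0.02,
                          junct_frac = 0.001,
                          diffusion_coupling = 0.8,
                          srs_coupling = 0.4) {
  n_domains <- as.integer(n_domains)
  if (n_domains < 3L) stop("n_domains must be at least 3")
  stopifnot(v_cyto_total > 0, sr_frac > 0, srs_frac > 0, sl_frac > 0,
            junct_frac > 0, diffusion_coupling > 0, srs_coupling > 0)
  v_cyto <- v_cyto_total / n_domains
  structure(list(
    n_domains = n_domains,
    membrane_domain_indices = c(1L, n_domains),
    v_cyto = v_cyto,
    v_sr = sr_frac * v_cyto,
    v_srs = srs_frac * v_cyto,
    v_sl = sl_frac * v_cyto,
    v_junct = junct_frac * v_cyto,
    diffusion_coupling = diffusion_coupling,
    srs_coupling = srs_coupling
  ), class = "cell_geometry")
}

# Baseline values of the tachypacing-remodeling target parameters.
.baseline_ryr_p <- function() {
  rp <- rep(1.0, 12)
  rp[c(1L, 2L, 6L, 12L)] <- c(0.2, 0.22, 8e-5, 0.007)  # indices 0,1,5,11
  rp
}

#' Parameters of one cell model instance
#'
#' Maximum conductances and pump/exchanger fluxes are dimensionless scales
#' relative to the baseline cell (1.0 = baseline); reference magnitudes are
#' internal to the model core. `Jmaxup` is the maximal SERCA uptake rate in
#' mM/ms. `RyR_P` is the ryanodine-receptor property vector; entries at
#' zero-based indices 0, 1, 5 and 11 are used by the model (transition-rate
#' scales, single-channel open-probability scale, and SR-fraction density)
#' and only their ratio to baseline matters. `NRyRs` is the release-unit
#' channel count (baseline 198000), likewise used as a ratio. `Buff_factor`
#' multiplies the dissociation constant of the scalable cytosolic buffer,
#' so values below 1 mean *stronger* buffering (0.15 is markedly stronger
#' than baseline 1.0).
#'
#' @param GCaL,GCaT,GNa,Gto1,GKr,GKs,GK1,GCab,GNab,GClb conductance scales.
#' @param ImaxNCX,ImaxNaK,ICaP_max exchanger/pump flux scales.
#' @param Jmaxup maximal SERCA flux, mM/ms.
#' @param RyR_P numeric vector of 12 RyR properties (zero-based indices
#'   0..11; see Details).
#' @param NRyRs ryanodine receptors per release unit.
#' @param Buff_factor calcium buffering factor (affinity multiplier of the
#'   scalable cytosolic buffer; < 1 strengthens buffering).
#' @param geometry a [cell_geometry()].
#'
#' @return an object of class `cell_params`.
#' @export
cell_parameters <- function(GCaL = 1, GCaT = 1, GNa = 1, Gto1 = 1, GKr = 1,
                            GKs = 1, GK1 = 1, GCab = 1, GNab = 1, GClb = 1,
                            ImaxNCX = 1, ImaxNaK = 1, ICaP_max = 1,
                            Jmaxup = 0.0053,
                            RyR_P = .baseline_ryr_p(),
                            NRyRs = 198000,
                            Buff_factor = 1.0,
                            geometry = cell_geometry()) {
  p <- list(GCaL = GCaL, GCaT = GCaT, GNa = GNa, Gto1 = Gto1, GKr = GKr,
            GKs = GKs, GK1 = GK1, GCab = GCab, GNab = GNab, GClb = GClb,
            ImaxNCX = ImaxNCX, ImaxNaK = ImaxNaK, ICaP_max = ICaP_max,
            Jmaxup = Jmaxup, RyR_P = RyR_P, NRyRs = NRyRs,
            Buff_factor = Buff_factor, geometry = geometry)
  validate_cell_parameters(structure(p, class = "cell_params"))
}

#' @rdname cell_parameters
#' @export
baseline_parameters <- function() cell_parameters()

validate_cell_parameters <- function(p) {
  scales <- c("GCaL", "GCaT", "GNa", "Gto1", "GKr", "GKs", "GK1", "GCab",
              "GNab", "GClb", "ImaxNCX", "ImaxNaK", "ICaP_max", "Jmaxup",
              "NRyRs", "Buff_factor")
  for (s in scales) {
    v <- p[[s]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("parameter '%s' must be a single positive number", s))
  }
  if (!is.numeric(p$RyR_P) || length(p$RyR_P) != 12L || any(p$RyR_P <= 0))
    stop("RyR_P must be a vector of 12 strictly positive values")
  if (!inherits(p$geometry, "cell_geometry")) stop("geometry must be a cell_geometry")
  p
}

# zero-based accessor matching the conventional RyR_P index labels
ryr_p <- function(params, index0) params$RyR_P[index0 + 1L]

# Reference magnitudes of the baseline cell. Conductances in nS/pF-equivalent
# units so that currents come out in pA/pF; rates in 1/ms; concentrations in
# mM. These were fixed once while parameterizing the baseline model against
# the rabbit atrial action potential and calcium-transient targets and are
# not user-facing.
.model_refs <- function() {
  refs <- list(
    gCaL = 0.03, gCaT = 0.01, gNa = 7.8, gto = 0.25, gKr = 0.20,
    gKs = 0.06, gK1 = 0.08, gCab = 0.00013, gNab = 0.0024, gClb = 0.0018,
    vNCX = 350, vNaK = 0.90, vCaP = 0.15,
    kmf_up = 0.000246, kmr_up = 1.2, h_up = 1.787,
    krel = 8.0, gleak = 4e-5,
    kopen = 1.6, kclose = 1.0, ki0 = 2.0, kihalf = 0.02,
    kr = 0.005, kci = 0.01, kcihalf = 5e-4,
    ksrs = 0.032, hact = 4, ksrload = 0.32, hsr = 4,
    tau_xfer = 0.5, tau_sl = 0.1, tau_j = 0.6, tau_ssl = 500,
    # cytosolic buffering: fixed high-affinity (troponin-like) buffer plus a
    # smaller low-affinity buffer whose Kd is multiplied by Buff_factor
    bfc = 0.05, kdfc = 0.0006, bsc = 0.05, kdsc = 0.025,
    bcsq = 14.0, kdcsq = 0.65, bsrs = 0.06, kdsrs = 0.01,
    bj = 0.012, kdj = 0.02,
    cm = 50, cao = 1.8, nao = 140, ko = 5.4,
    # effective fractional volume of the sodium pool: sodium equilibrates
    # over minutes in a full cytosolic volume; a restricted effective pool
    # brings it to quasi-steady state within a practical pre-pacing window
    f_na_vol = 0.08,
    ecl = -40, kd_fca = 0.3
  )
  override <- getOption("atriawave.model_refs")
  if (!is.null(override)) refs[names(override)] <- override
  refs
}

# names/order must match the ParIdx enum in src/cellmodel.cpp
.param_order <- c(
  "NDOM",
  "GCAL", "GCAT", "GNA", "GTO", "GKR", "GKS", "GK1", "GCAB", "GNAB", "GCLB",
  "VNCX", "VNAK", "VCAP",
  "VUP", "KMF", "KMR", "HUP",
  "KREL", "GLEAK",
  "KOPEN", "KCLOSE", "KI0", "KIHALF", "KR", "KCI", "KCIHALF",
  "KSRS", "HACT", "KSRLOAD", "HSR",
  "TAUXFER", "TAUSL", "TAUJ",
  "GDIFF",
  "BFC", "KDFC", "BSC", "KDSC",
  "BCSQ", "KDCSQ", "BSRS", "KDSRS", "BJ", "KDJ",
  "VCYTO", "VSR", "VSRS", "VSL", "VJ",
  "CM", "CAO", "NAO", "KO", "FNAVOL",
  "ECL", "KDFCA", "GSRS", "TAUSSL")

# Pack user-facing parameters (scales) times reference magnitudes into the
# flat numeric vector consumed by the compiled core.
pack_params <- function(params) {
  validate_cell_parameters(params)
  r <- .model_refs()
  g <- params$geometry
  rp0 <- .baseline_ryr_p()
  p5r <- ryr_p(params, 5) / rp0[6]
  p1r <- ryr_p(params, 1) / rp0[2]
  p0r <- ryr_p(params, 0) / rp0[1]
  p11r <- ryr_p(params, 11) / rp0[12]
  nryr <- params$NRyRs / 198000

  v <- c(
    NDOM = g$n_domains,
    GCAL = params$GCaL * r$gCaL, GCAT = params$GCaT * r$gCaT,
    GNA = params$GNa * r$gNa, GTO = params$Gto1 * r$gto,
    GKR = params$GKr * r$gKr, GKS = params$GKs * r$gKs,
    GK1 = params$GK1 * r$gK1, GCAB = params$GCab * r$gCab,
    GNAB = params$GNab * r$gNab, GCLB = params$GClb * r$gClb,
    VNCX = params$ImaxNCX * r$vNCX, VNAK = params$ImaxNaK * r$vNaK,
    VCAP = params$ICaP_max * r$vCaP,
    VUP = params$Jmaxup, KMF = r$kmf_up, KMR = r$kmr_up, HUP = r$h_up,
    KREL = r$krel * nryr * p11r, GLEAK = r$gleak * p0r,
    KOPEN = r$kopen * p5r, KCLOSE = r$kclose / p1r,
    KI0 = r$ki0, KIHALF = r$kihalf, KR = r$kr, KCI = r$kci,
    KCIHALF = r$kcihalf,
    KSRS = r$ksrs, HACT = r$hact, KSRLOAD = r$ksrload, HSR = r$hsr,
    TAUXFER = r$tau_xfer, TAUSL = r$tau_sl, TAUJ = r$tau_j,
    GDIFF = g$diffusion_coupling,
    BFC = r$bfc, KDFC = r$kdfc, BSC = r$bsc,
    KDSC = r$kdsc * params$Buff_factor,
    BCSQ = r$bcsq, KDCSQ = r$kdcsq, BSRS = r$bsrs, KDSRS = r$kdsrs,
    BJ = r$bj, KDJ = r$kdj,
    VCYTO = g$v_cyto, VSR = g$v_sr, VSRS = g$v_srs, VSL = g$v_sl,
    VJ = g$v_junct,
    CM = r$cm * 1e-12, CAO = r$cao, NAO = r$nao, KO = r$ko,
    FNAVOL = r$f_na_vol,
    ECL = r$ecl, KDFCA = r$kd_fca,
    GSRS = g$srs_coupling, TAUSSL = r$tau_ssl)
  stopifnot(identical(names(v), .param_order))
  v
}

#' Serialize / restore parameter sets as JSON
#'
#' Field names follow the conventional parameter naming of the model
#' (`GCaL`, `ImaxNCX`, `Jmaxup`, `RyR_P`, `NRyRs`, `Buff_factor`, ...).
#'
#' @param params a `cell_params` object (or a list of them).
#' @param path file path.
#' @export
write_parameters <- function(params, path) {
  ser <- function(p) {
    p <- unclass(p)
    p$geometry <- unclass(p$geometry)
    p
  }
  x <- if (inherits(params, "cell_params")) ser(params) else lapply(params, ser)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  de <- function(p) {
    geom <- p$geometry
    g <- cell_geometry(n_domains = geom$n_domains,
                       v_cyto_total = geom$v_cyto * geom$n_domains,
                       sr_frac = geom$v_sr / geom$v_cyto,
                       srs_frac = geom$v_srs / geom$v_cyto,
                       sl_frac = geom$v_sl / geom$v_cyto,
                       junct_frac = geom$v_junct / geom$v_cyto,
                       diffusion_coupling = geom$diffusion_coupling,
                       srs_coupling = geom$srs_coupling)
    cell_parameters(GCaL = p$GCaL, GCaT = p$GCaT, GNa = p$GNa, Gto1 = p$Gto1,
                    GKr = p$GKr, GKs = p$GKs, GK1 = p$GK1, GCab = p$GCab,
                    GNab = p$GNab, GClb = p$GClb, ImaxNCX = p$ImaxNCX,
                    ImaxNaK = p$ImaxNaK, ICaP_max = p$ICaP_max,
                    Jmaxup = p$Jmaxup, RyR_P = as.numeric(p$RyR_P),
                    NRyRs = p$NRyRs, Buff_factor = p$Buff_factor,
                    geometry = g)
  }
  if (!is.null(x$GCaL)) de(x) else lapply(x, de)
}
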