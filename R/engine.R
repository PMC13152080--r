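## Engine configuration and pacing driver.

.pkgCache <- new.env(parent = emptyenv())

#' Engine configuration
#'
#' Returns the full constant set of the reduced ventricular myocyte engine,
#' with any named overrides applied. Conductances are in mS/uF (or pore
#' scaling units for the GHK-style L-type current), concentrations in mM,
#' time in ms. Integration uses a fixed fine step \code{dtFine} inside
#' \code{fineWindowMs} after each stimulus (upstroke window) and
#' \code{dtCoarse} elsewhere; output is recorded on a uniform
#' \code{recordDt} grid.
#'
#' @param ... Named overrides, e.g. \code{engineConfig(gKr = 0.2)}.
#' @return Named list of engine constants.
#' @export
engineConfig <- function(...) {
  cfg <- list(
    ## maximal conductances / rates
    gNa = 11, gNaL = 0.0075, gto = 0.08, kCaL = 4, gKr = 0.30,
    gKs = 0.02, gK1 = 5.405, kNaCa = 1000, PNaK = 1.362,
    GpCa = 0.825, KpCa = 5e-4, gbCa = 5.92e-4, gbNa = 2.9e-4,
    ## SR calcium handling
    Vmaxup = 4.5e-3, Kup = 2.5e-4,
    Vrel = 1, arel = 0.8, brel = 3.2, brelH = 4, crel = 2e-3,
    tauGrelInact = 60, tauGrelRec = 250, KgrelCa = 1.5e-4, Krefill = 2.5,
    k2c = 10, k4 = 3.3e-3, powRbar = 2, Vleak = 1.5e-4, vratio = 15,
    Bufc = 0.15, Kbufc = 1e-3, Bufsr = 10, Kbufsr = 0.3,
    ## membrane-flux to concentration conversion (mM/ms per uA/uF)
    kCa = 3e-5, kNa = 6e-5,
    ## milieu
    Nao = 140, Cao = 1.8, Ko = 5.4, Ki = 140,
    ## kinetics
    tauhL = 200, taufca = 30, fcaFloor = 0.4, KfCa = 6e-4,
    ## active tension
    Ca50 = 5e-4, hillT = 4, tauF = 18,
    ## ICaL voltage-gating shape (window current controls EAD propensity)
    dMid = -5, dSlope = 10, fMid = -18, fSlope = 6.5, fFloor = 0.03,
    fSlowAmp = 100, fPlateau = 45, fDepolAmp = 80, fRestAmp = 150,
    ## Nav1.8 gating (right-shifted Boltzmann midpoints vs Nav1.5)
    nav18ActMid = -24, nav18ActSlope = 8,
    nav18InactMid = -30, nav18InactSlope = 4,
    nav18Power = 3, nav18TauM = 6, nav18TauH = 30,
    ## CaMKII composite hook: per unit activity above 1, SERCA uptake is
    ## scaled by camkiiJupFactor (<= 1) and I_CaL by camkiiCaLFactor (>= 1)
    camkiiJupFactor = 0.85, camkiiCaLFactor = 1.2,
    ## stimulus and integration
    stimAmplitude = -52, stimDuration = 1,
    dtFine = 0.02, dtCoarse = 0.05, fineWindowMs = 10, recordDt = 0.1,
    rtf = 8314 * 310 / 96485)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad))
      stop("unknown engine constant(s): ", paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  cfg
}

#' Default engine initial state
#'
#' Resting state used when no restart state is supplied; pre-beats bring the
#' model to its paced quasi-steady state.
#' @return Numeric vector of the 20 state variables.
#' @export
defaultState <- function() {
  c(V = -86.2, m = 0.0017, h = 0.93, j = 0.93, hL = 0.7,
    d = 2e-5, f = 1, fca = 1, r = 0, s = 1, xr1 = 0, xr2 = 0.45,
    xs = 0.003, Cai = 1e-4, CaSR = 3, Nai = 9, Rbar = 1, Ften = 0.001,
    m18 = 0, h18 = 0.95, grel = 1)
}

.engineMultipliers <- function(params, cfg) {
  m <- multipliers(params)
  ck <- m[["camkii"]]
  c(m[["g_Na"]], m[["g_NaL"]], m[["g_to"]],
    m[["g_CaL"]] * cfg$camkiiCaLFactor^(ck - 1),
    m[["g_Kr"]], m[["g_Ks"]], m[["g_K1"]], m[["g_NaCa"]], m[["g_NaK"]],
    m[["j_up"]] * cfg$camkiiJupFactor^(ck - 1),
    m[["j_rel"]], m[["j_leak"]], m[["g_Nav18"]])
}

.checkGrid <- function(protocol, cfg) {
  cl <- protocol@cycleLength
  near <- function(x) abs(x - round(x)) < 1e-9
  if (!near(cl / cfg$recordDt))
    stop("cycleLength must be a multiple of recordDt (", cfg$recordDt, " ms)")
  if (!near(cfg$fineWindowMs / cfg$recordDt) ||
      !near(cfg$recordDt / cfg$dtFine) || !near(cfg$recordDt / cfg$dtCoarse))
    stop("recordDt must be a multiple of dtFine and dtCoarse, and ",
         "fineWindowMs a multiple of recordDt")
  if (protocol@stimDuration > cfg$fineWindowMs)
    stop("stimDuration must lie within the fine integration window")
  if (cl < cfg$fineWindowMs)
    stop("cycleLength must be >= fineWindowMs")
  invisible(TRUE)
}

#' Peak baseline tension at reference parameters
#'
#' Runs the engine once at the all-default multiplier set (1 Hz, to
#' quasi-steady state) and returns the peak raw tension, which defines the
#' tension normalization (baseline peak = 1). Cached per configuration.
#'
#' @param cfg Engine configuration.
#' @return Positive scalar, raw engine tension units.
#' @export
referencePeakTension <- function(cfg = engineConfig()) {
  key <- paste0("tens:", paste(unlist(cfg), collapse = ","))
  hit <- .pkgCache[[key]]
  if (!is.null(hit)) return(hit)
  tr <- runPacing(ionicParams(), pacingProtocol(1000, nBeats = 100L,
                                                recordLastN = 2L),
                  cfg, normalizeTension = FALSE)
  val <- max(tr@tension)
  if (val <= 0) stop("reference tension peak is not positive")
  assign(key, val, envir = .pkgCache)
  val
}

#' Run a pacing protocol on the myocyte engine
#'
#' Paces the reduced ventricular model for \code{nBeats} beats at fixed
#' cycle length and records the last \code{recordLastN} beats on a uniform
#' grid. Deterministic: identical inputs give identical traces. The final
#' state is attached so a run can be continued seamlessly
#' (\code{initState = finalState(trace)}).
#'
#' @param params An \linkS4class{IonicParams} multiplier set.
#' @param protocol A \linkS4class{PacingProtocol}.
#' @param cfg Engine configuration from \code{\link{engineConfig}}.
#' @param initState Optional 20-element state vector to restart from
#'   (default: \code{\link{defaultState}}).
#' @param recordCurrents Record ICaL, IKr, INa, INaL and INav18 series.
#' @param normalizeTension Normalize tension by the reference baseline peak.
#' @return A \linkS4class{CardiacTrace}.
#' @examples
#' \donttest{
#' tr <- runPacing(ionicParams(), pacingProtocol(1000, 50L, 2L))
#' computeBiomarkers(tr)
#' }
#' @export
runPacing <- function(params, protocol, cfg = engineConfig(),
                      initState = NULL, recordCurrents = FALSE,
                      normalizeTension = TRUE) {
  stopifnot(is(params, "IonicParams"), is(protocol, "PacingProtocol"))
  validObject(params); validObject(protocol)
  .checkGrid(protocol, cfg)
  if (is.null(initState)) initState <- defaultState()
  if (length(initState) != 21)
    stop("initState must have 21 elements")
  cfg$stimAmplitude <- protocol@stimAmplitude
  cfg$stimDuration <- protocol@stimDuration
  res <- .engine_run(as.numeric(initState), .engineMultipliers(params, cfg),
                     cfg, protocol@cycleLength, protocol@nBeats,
                     protocol@recordLastN, recordCurrents)
  if (res$errorBeat > 0)
    stop("integration failure (non-finite or out-of-range V) at beat ",
         res$errorBeat, " of ", protocol@nBeats)
  scale <- if (normalizeTension) referencePeakTension(cfg) else 1
  cur <- if (recordCurrents) {
    colnames(res$currents) <- c("ICaL", "IKr", "INa", "INaL", "INav18")
    res$currents
  } else matrix(numeric(), 0, 0)
  st <- res$finalState
  names(st) <- names(defaultState())
  new("CardiacTrace",
      time = res$time, V = res$V, Cai = res$Cai * 1000,
      tension = res$tension / scale,
      beatStarts = as.integer(res$beatStarts), stimTimes = res$stimTimes,
      cycleLength = protocol@cycleLength, currents = cur,
      extra = list(CaSR = res$CaSR, Nai = res$Nai,
                   maxAbsINa = res$maxAbsINa,
                   maxAbsINav18 = res$maxAbsINav18,
                   finalState = st,
                   normalized = normalizeTension,
                   tensionScale = scale))
}

#' Final engine state of a trace
#' @param trace A CardiacTrace produced by \code{\link{runPacing}}.
#' @return Named numeric state vector usable as \code{initState}.
#' @export
finalState <- function(trace) {
  stopifnot(is(trace, "CardiacTrace"))
  trace@extra$finalState
}

#' Nav1.8 current density
#'
#' Hodgkin-Huxley form \code{g * m^p * h * (V - ENa)} with Boltzmann
#' steady-state activation/inactivation whose midpoints default to values
#' right-shifted (depolarized) relative to the engine's Nav1.5 gating. Pure
#' function of voltage and gate state; zero when \code{g_Nav18 = 0}.
#'
#' @param V Membrane potential, mV.
#' @param state Either a named engine state vector (gates \code{m18},
#'   \code{h18}, \code{Nai} are used) or NULL to use steady-state gates at
#'   \code{V}.
#' @param params An IonicParams (only \code{g_Nav18} is used).
#' @param cfg Engine configuration.
#' @return Current density in uA/uF.
#' @export
nav18Current <- function(V, state = NULL, params = ionicParams(),
                         cfg = engineConfig()) {
  g <- multipliers(params)[["g_Nav18"]]
  if (g < 0) stop("g_Nav18 must be >= 0")
  ss <- nav18SteadyState(V, cfg)
  if (is.null(state)) {
    m18 <- ss$m; h18 <- ss$h; Nai <- 9
  } else {
    m18 <- state[["m18"]]; h18 <- state[["h18"]]; Nai <- state[["Nai"]]
  }
  ENa <- cfg$rtf * log(cfg$Nao / Nai)
  g * m18^cfg$nav18Power * h18 * (V - ENa)
}

#' Steady-state Nav1.8 gating
#' @param V Membrane potential, mV (vectorized).
#' @param cfg Engine configuration.
#' @return List with activation \code{m}, inactivation \code{h} and the
#'   open-probability window factor \code{window} = m^p * h.
#' @export
nav18SteadyState <- function(V, cfg = engineConfig()) {
  m <- 1 / (1 + exp(-(V - cfg$nav18ActMid) / cfg$nav18ActSlope))
  h <- 1 / (1 + exp((V - cfg$nav18InactMid) / cfg$nav18InactSlope))
  list(m = m, h = h, window = m^cfg$nav18Power * h)
}

#' Steady-state Nav1.5 window factor of the engine
#' @param V Membrane potential, mV (vectorized).
#' @return Open-probability factor m^3 * h at steady state.
#' @export
nav15SteadyState <- function(V) {
  m <- 1 / (1 + exp(-(V + 40) / 6.5))
  h <- 1 / (1 + exp((V + 70) / 6.5))
  list(m = m, h = h, window = m^3 * h)
}

#' Calibrate the Nav1.8 conductance to a fraction of peak I_Na
#'
#' Finds \code{g_Nav18} such that the peak absolute Nav1.8 current over a
#' steady paced beat equals \code{f} times the peak absolute (Nav1.8-free)
#' fast sodium current of the baseline beat, by bisection to a relative
#' tolerance of 1e-3.
#'
#' @param f Target fraction, 0 <= f < 0.1.
#' @param params Baseline parameters (g_Nav18 ignored).
#' @param protocol Pacing protocol (default 1 Hz to quasi-steady state).
#' @param cfg Engine configuration.
#' @param nAdaptBeats Beats run per candidate conductance (from the cached
#'   baseline steady state).
#' @return The calibrated conductance, mS/uF.
#' @export
calibrateNav18Fraction <- function(f, params = ionicParams(),
                                   protocol = pacingProtocol(1000, 100L, 2L),
                                   cfg = engineConfig(),
                                   nAdaptBeats = 20L) {
  if (!is.finite(f) || f < 0 || f >= 0.1)
    stop("f must satisfy 0 <= f < 0.1")
  if (f == 0) return(0)
  base <- runPacing(params, protocol, cfg, normalizeTension = FALSE)
  target <- f * base@extra$maxAbsINa
  st <- finalState(base)
  probe <- function(g) {
    p <- ionicParams(.values = c(multipliers(params)[.PARAM_NAMES[1:13]],
                                 g_Nav18 = g))
    tr <- runPacing(p, pacingProtocol(protocol@cycleLength, nAdaptBeats,
                                      2L, protocol@stimAmplitude,
                                      protocol@stimDuration),
                    cfg, initState = st, normalizeTension = FALSE)
    tr@extra$maxAbsINav18
  }
  ## peak INav18 is monotone in g; bracket then bisect
  hi <- 1e-3
  while (probe(hi) < target && hi < 10) hi <- hi * 4
  lo <- 0
  while ((hi - lo) / hi > 1e-3) {
    mid <- (lo + hi) / 2
    if (probe(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
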