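## Analytic synthetic traces with implanted abnormalities, certified
## synthetic drug compendia, and the bundled reference fixtures.

#' TraceSpec: specification of an analytic synthetic trace
#'
#' Beats are sums of logistic rise/fall segments (analytically smooth), so
#' every implanted abnormality has exact recorded ground truth.
#'
#' @slot restV,peakV Resting and peak potential, mV.
#' @slot apd90 Target APD90, ms.
#' @slot cycleLength,beats Pacing cycle length (ms) and number of beats.
#' @slot gridDt Grid step, ms.
#' @slot eads data.frame (beat, takeoff mV, amplitude mV, width ms): bumps
#'   implanted on the repolarization limb where the template crosses the
#'   requested takeoff.
#' @slot repolFailBeats Beats whose repolarization is suppressed.
#' @slot alternansRatio CaT amplitude ratio of even/odd beats (1 = none).
#' @slot catAmplitude,catTau CaT amplitude (uM) and decay constant (ms).
#' @slot tensionPeak,tensionTau Tension beat peak and monoexponential
#'   decay constant (ms).
#' @slot jitterAmp Amplitude of smooth seeded jitter, mV.
#' @slot seed Jitter seed.
#' @export
setClass("TraceSpec",
         representation(restV = "numeric", peakV = "numeric",
                        apd90 = "numeric", cycleLength = "numeric",
                        beats = "integer", gridDt = "numeric",
                        eads = "data.frame", repolFailBeats = "integer",
                        alternansRatio = "numeric",
                        catAmplitude = "numeric", catTau = "numeric",
                        tensionPeak = "numeric", tensionTau = "numeric",
                        jitterAmp = "numeric", seed = "integer"))

#' Construct a synthetic trace specification
#' @param restV,peakV Resting / peak potential, mV.
#' @param apd90 Target APD90, ms (must fit inside the cycle length).
#' @param cycleLength,beats Cycle length (ms) and beat count.
#' @param gridDt Grid step, ms.
#' @param eads data.frame(beat, takeoff, amplitude, width).
#' @param repolFailBeats Integer beats with suppressed repolarization.
#' @param alternansRatio Even/odd CaT amplitude ratio.
#' @param catAmplitude,catTau CaT shape parameters (uM, ms).
#' @param tensionPeak,tensionTau Tension shape parameters.
#' @param jitterAmp,seed Smooth jitter amplitude (mV) and seed.
#' @return A \linkS4class{TraceSpec}.
#' @export
traceSpec <- function(restV = -85, peakV = 35, apd90 = 300,
                      cycleLength = 1000, beats = 4L, gridDt = 0.1,
                      eads = data.frame(), repolFailBeats = integer(),
                      alternansRatio = 1, catAmplitude = 0.6, catTau = 120,
                      tensionPeak = 1, tensionTau = 120,
                      jitterAmp = 0.15, seed = 1L) {
  if (apd90 >= cycleLength - 50)
    stop("apd90 must leave a diastolic interval within the cycle length")
  new("TraceSpec", restV = restV, peakV = peakV, apd90 = apd90,
      cycleLength = cycleLength, beats = as.integer(beats),
      gridDt = gridDt, eads = eads,
      repolFailBeats = as.integer(repolFailBeats),
      alternansRatio = alternansRatio, catAmplitude = catAmplitude,
      catTau = catTau, tensionPeak = tensionPeak, tensionTau = tensionTau,
      jitterAmp = jitterAmp, seed = as.integer(seed))
}

## analytic AP template over one beat (t in ms from beat start)
.apTemplate <- function(spec, tFall) {
  tUp <- 2; wUp <- 0.25; pl <- 0.85; tauEarly <- 60; wFall <- 6
  force(tFall)
  function(t) {
    rise <- 1 / (1 + exp(-(t - tUp) / wUp))
    shape <- (pl + (1 - pl) * exp(-pmax(t - tUp, 0) / tauEarly)) /
      (1 + exp((t - tFall) / wFall))
    spec@restV + (spec@peakV - spec@restV) * rise * shape
  }
}

.solveTFall <- function(spec) {
  level <- spec@peakV - 0.9 * (spec@peakV - spec@restV)
  crossAt <- function(tFall) {
    f <- .apTemplate(spec, tFall)
    g <- function(t) f(t) - level
    ## crossing after the fall midpoint
    stats::uniroot(g, c(5, spec@cycleLength - 1), tol = 1e-6)$root - 2
  }
  stats::uniroot(function(tf) crossAt(tf) - spec@apd90,
                 c(10, spec@cycleLength - 20), tol = 1e-4)$root
}

#' Build a synthetic trace with exact ground truth
#'
#' Constructs voltage / calcium / tension series from smooth analytic
#' segments, implants the requested abnormalities, and returns the trace
#' together with an annotation of every implanted event, computed exactly
#' from the jitter-free construction.
#'
#' @param spec A \linkS4class{TraceSpec}.
#' @return A \linkS4class{CardiacTrace}; the ground-truth annotation is in
#'   \code{trace@extra$annotation} (fields \code{eads},
#'   \code{repolFailBeats}, \code{alternans}).
#' @examples
#' tr <- makeSyntheticTrace(traceSpec(beats = 2))
#' detectEADs(tr)   # empty: clean template
#' @export
makeSyntheticTrace <- function(spec) {
  stopifnot(is(spec, "TraceSpec"))
  if (nrow(spec@eads) &&
      !all(c("beat", "takeoff", "amplitude", "width") %in%
           names(spec@eads)))
    stop("eads needs columns beat, takeoff, amplitude, width")
  cl <- spec@cycleLength; dt <- spec@gridDt
  nPer <- round(cl / dt)
  tBeat <- (seq_len(nPer) - 1) * dt
  tFall <- .solveTFall(spec)
  apFun <- .apTemplate(spec, tFall)
  apFail <- .apTemplate(spec, cl + 500) # fall pushed beyond the beat
  ## CaT / tension templates
  tUp <- 2
  catShape <- (1 - exp(-pmax(tBeat - tUp, 0) / 15)) *
    exp(-pmax(tBeat - tUp, 0) / spec@catTau)
  catShape[tBeat <= tUp] <- 0
  catShape <- catShape / max(catShape)
  tpkF <- 80
  fShape <- ifelse(tBeat < tUp, 0,
            ifelse(tBeat < tpkF,
                   0.5 * (1 - cos(pi * (tBeat - tUp) / (tpkF - tUp))),
                   exp(-(tBeat - tpkF) / spec@tensionTau)))
  V <- Cai <- Ften <- numeric(nPer * spec@beats)
  annEads <- list()
  for (b in seq_len(spec@beats)) {
    fail <- b %in% spec@repolFailBeats
    ## implant EAD bumps as exact piecewise segments: the template pauses
    ## at the requested takeoff, a raised-cosine bump of exactly the
    ## requested amplitude is inserted, and the fall resumes time-shifted,
    ## so takeoff and amplitude are exact by construction
    ev <- spec@eads[spec@eads$beat == b, , drop = FALSE]
    if (nrow(ev) && fail)
      stop("cannot implant an EAD on a repolarization-failure beat")
    if (nrow(ev)) {
      tks <- numeric(nrow(ev))
      for (k in seq_len(nrow(ev))) {
        if (ev$takeoff[k] >= apFun(10) || ev$takeoff[k] <= spec@restV + 1)
          stop("takeoff must lie on the repolarization limb")
        g <- function(t) apFun(t) - ev$takeoff[k]
        tks[k] <- stats::uniroot(g, c(10, cl - 5), tol = 1e-8)$root
      }
      o <- order(tks)
      ev <- ev[o, , drop = FALSE]; tks <- tks[o]
      dur <- 3 * ev$width
      starts <- tks + c(0, cumsum(dur))[seq_len(nrow(ev))]
      ends <- starts + dur
      if (nrow(ev) > 1 && any(diff(tks) < dur[-length(dur)] / 2))
        stop("overlapping EAD implants")
      shiftTot <- c(0, cumsum(dur))
      v <- numeric(nPer)
      for (ii in seq_len(nPer)) {
        t <- tBeat[ii]
        seg <- findInterval(t, c(rbind(starts, ends)))
        if (seg %% 2 == 1) { # inside bump number (seg+1)/2
          k <- (seg + 1) %/% 2
          v[ii] <- ev$takeoff[k] + ev$amplitude[k] * 0.5 *
            (1 - cos(2 * pi * (t - starts[k]) / dur[k]))
        } else {
          v[ii] <- apFun(t - shiftTot[seg %/% 2 + 1])
        }
      }
      for (k in seq_len(nrow(ev)))
        annEads[[length(annEads) + 1L]] <- data.frame(
          beat = b, time = (b - 1) * cl + starts[k],
          takeoff = ev$takeoff[k], amplitude = ev$amplitude[k])
    } else {
      v <- (if (fail) apFail else apFun)(tBeat)
    }
    amp <- spec@catAmplitude *
      (if (b %% 2 == 0) spec@alternansRatio else 1)
    idx <- seq.int((b - 1) * nPer + 1, b * nPer)
    V[idx] <- v
    Cai[idx] <- 0.07 + amp * catShape
    Ften[idx] <- spec@tensionPeak *
      (if (b %% 2 == 0) spec@alternansRatio else 1) * fShape
  }
  ## smooth seeded jitter: low-frequency, too gentle to create spurious
  ## minima with a detectable rise
  if (spec@jitterAmp > 0) {
    set.seed(spec@seed)
    ph <- runif(2, 0, 2 * pi)
    tt <- (seq_along(V) - 1) * dt
    V <- V + spec@jitterAmp * (sin(2 * pi * tt / 53 + ph[1]) +
                               0.5 * sin(2 * pi * tt / 17 + ph[2]))
  }
  r <- spec@alternansRatio
  ann <- list(
    eads = if (length(annEads)) do.call(rbind, annEads) else
      data.frame(beat = integer(), time = numeric(), takeoff = numeric(),
                 amplitude = numeric()),
    repolFailBeats = spec@repolFailBeats,
    alternans = list(ratio = r, magnitude = 2 * abs(1 - r) / (1 + r)))
  new("CardiacTrace",
      time = (seq_along(V) - 1) * dt, V = V, Cai = Cai, tension = Ften,
      beatStarts = as.integer((seq_len(spec@beats) - 1) * nPer + 1),
      stimTimes = (seq_len(spec@beats) - 1) * cl,
      cycleLength = cl, currents = matrix(numeric(), 0, 0),
      extra = list(annotation = ann, synthetic = TRUE))
}

#' Generate a synthetic drug compendium with certified risk labels
#'
#' Draws channel-block profiles spanning risky (strong hERG block near the
#' therapeutic range, optionally with an L-type enhancement schedule) and
#' benign (weak or non-repolarization-channel) designs, then certifies
#' every label by running the full trial on the reference population: the
#' label is the brute-force trial outcome, not an assumption.
#'
#' @param nDrugs Number of drugs (>= 0).
#' @param seed RNG seed.
#' @param population Calibrated reference \linkS4class{PopulationTable}.
#' @param multiples Concentration schedule.
#' @param protocol,cfg,detector Trial settings.
#' @return List: \code{drugs} (DrugDescription list), \code{labels} (named
#'   character, "high"/"no"), \code{scores} (named numeric),
#'   \code{trials} (list of TrialResults).
#' @export
makeSyntheticCompendium <- function(nDrugs, seed, population,
                                    multiples = c(1, 10, 30, 100),
                                    protocol = pacingProtocol(2000, 15L, 4L),
                                    cfg = engineConfig(),
                                    detector = detectorConfig()) {
  nDrugs <- as.integer(nDrugs)
  if (nDrugs == 0)
    return(list(drugs = list(), labels = character(),
                scores = numeric(), trials = list()))
  set.seed(seed)
  drugs <- vector("list", nDrugs)
  for (i in seq_len(nDrugs)) {
    eftpc <- 10^runif(1, -1.5, 0.5)
    risky <- i %% 2 == 1
    effects <- list()
    if (risky) {
      ## strong hERG block within 10x of the therapeutic concentration
      effects[[1]] <- channelEffect("g_Kr", "block",
                                    ic50 = eftpc * runif(1, 1, 10),
                                    hill = runif(1, 0.8, 1.5))
      if (runif(1) < 0.3)
        effects[[2]] <- channelEffect("g_CaL", "scale",
          schedule = data.frame(multiple = c(10, 30, 100),
                                change = round(runif(3, 0.05, 0.15) *
                                               c(1, 2, 4), 3)))
    } else {
      ## benign: weak hERG and/or moderate depolarizing-current block
      if (runif(1) < 0.7)
        effects[[length(effects) + 1]] <-
          channelEffect("g_Kr", "block", ic50 = eftpc * runif(1, 500, 5000),
                        hill = 1)
      effects[[length(effects) + 1]] <-
        channelEffect(sample(c("g_Na", "g_NaL", "g_to", "g_CaL"), 1),
                      "block", ic50 = eftpc * runif(1, 30, 300), hill = 1)
    }
    drugs[[i]] <- drugDescription(sprintf("synth%02d", i), effects, eftpc,
                                  note = "synthetic")
  }
  trials <- lapply(drugs, function(d)
    runDrugTrial(population, d, multiples, protocol, cfg, detector))
  scores <- vapply(trials, function(tr) trialRiskScore(tr)@score, numeric(1))
  names(scores) <- vapply(drugs, function(d) d@name, character(1))
  labels <- setNames(ifelse(scores > 0, "high", "no"), names(scores))
  list(drugs = drugs, labels = labels, scores = scores, trials = trials)
}

#' Reference drug and disease fixtures
#'
#' Channel-level descriptions used throughout the examples and tests:
#' cilostazol with and without its PDE3-mediated L-type enhancement
#' schedule, lidocaine with and without its late-sodium block, two
#' mexiletine formulations (one with an I_Ks component), and the LQTS2
#' disease variant, together with phenotype expectation tables. Each value
#' carries a provenance tag; placeholder values are plausible inventions,
#' not measurements, and are never used as quantitative targets.
#'
#' @return List with \code{drugs}, \code{variants}, \code{expectations}
#'   and a \code{provenance} data.frame.
#' @export
makeReferenceFixtures <- function() {
  cilo_block <- drugDescription("cilostazol_block",
    list(channelEffect("g_Kr", "block", ic50 = 13.8, hill = 1),
         channelEffect("g_CaL", "block", ic50 = 91.2, hill = 1)),
    eftpc = 0.128, note = "hERG/L-type block only")
  cilo_enh <- drugDescription("cilostazol_enh",
    c(cilo_block@effects,
      list(channelEffect("g_CaL", "scale",
        schedule = data.frame(multiple = c(10, 30, 100),
                              change = c(0.10, 0.22, 0.40))))),
    eftpc = 0.128, note = "with PDE3-mediated I_CaL enhancement")
  lido_inal <- drugDescription("lidocaine_inal",
    list(channelEffect("g_Na", "block", ic50 = 400),
         channelEffect("g_NaL", "block", ic50 = 15),
         channelEffect("g_Kr", "block", ic50 = 900)),
    eftpc = 2.2, note = "description including late-Na block")
  lido_noinal <- drugDescription("lidocaine_noinal",
    list(channelEffect("g_Na", "block", ic50 = 400),
         channelEffect("g_Kr", "block", ic50 = 900)),
    eftpc = 2.2, note = "description lacking late-Na block")
  mex_crumb <- drugDescription("mexiletine_crumb",
    list(channelEffect("g_NaL", "block", ic50 = 9),
         channelEffect("g_CaL", "block", ic50 = 38),
         channelEffect("g_Kr", "block", ic50 = 28),
         channelEffect("g_Ks", "block", ic50 = 80)),
    eftpc = 2.5, note = "formulation with I_Ks component")
  mex_joh <- drugDescription("mexiletine_johannesen",
    list(channelEffect("g_NaL", "block", ic50 = 8),
         channelEffect("g_CaL", "block", ic50 = 42),
         channelEffect("g_Kr", "block", ic50 = 60)),
    eftpc = 2.5, note = "formulation without I_Ks component")
  expectations <- list(
    lidocaine = data.frame(biomarker = "APD90", direction = "decrease",
                           multiple = 10, tolerance = 0.01),
    ## "marked" inotropy: the engine's steep force-Ca relation inflates
    ## relative tension changes, so the bar for a marked increase is 100%
    cilostazol = data.frame(biomarker = "peak_tension",
                            direction = "increase", multiple = 100,
                            tolerance = 1.0))
  provenance <- data.frame(
    field = c("cilostazol eftpc_uM", "cilostazol IKr ic50_uM",
              "cilostazol ICaL ic50_uM", "cilostazol enhancement schedule",
              "LQTS2 multipliers", "lidocaine ic50s", "lidocaine eftpc",
              "mexiletine ic50s", "mexiletine eftpc", "hill coefficients"),
    value = c("0.128", "13.8", "91.2", "+10%@10x +22%@30x +40%@100x",
              "g_Kr 0.30, g_NaL 1.82", "400/15/900", "2.2",
              "crumb 9/38/28/80; johannesen 8/42/60", "2.5", "1"),
    source = c("paper", "paper", "paper", "paper", "paper",
               "placeholder", "placeholder", "placeholder", "placeholder",
               "placeholder"))
  list(drugs = list(cilostazol_block = cilo_block,
                    cilostazol_enh = cilo_enh,
                    lidocaine_inal = lido_inal,
                    lidocaine_noinal = lido_noinal,
                    mexiletine_crumb = mex_crumb,
                    mexiletine_johannesen = mex_joh),
       variants = list(LQTS2 = diseaseVariants()$LQTS2),
       expectations = expectations,
       provenance = provenance)
}
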