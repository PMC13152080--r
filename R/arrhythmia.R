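## Repolarization-abnormality and alternans detectors, and the
## arrhythmia-threshold search protocols.

#' AbnormalityReport: EAD / repolarization-failure summary of a trace
#'
#' @slot hasEAD At least one early afterdepolarization detected.
#' @slot hasRepolFailure At least one beat never repolarized (APD90
#'   undefined).
#' @slot events data.frame of EAD events (beat, time ms, takeoff mV,
#'   amplitude mV).
#' @slot apd90Undefined Per-beat logical flags.
#' @export
setClass("AbnormalityReport",
         representation(hasEAD = "logical", hasRepolFailure = "logical",
                        events = "data.frame", apd90Undefined = "logical"))

setMethod("show", "AbnormalityReport", function(object) {
  cat(sprintf("AbnormalityReport: EAD=%s (%d events), repolFailure=%s\n",
              object@hasEAD, nrow(object@events), object@hasRepolFailure))
})

#' AlternansResult: calcium-transient alternans assessment
#'
#' @slot present Alternans called (magnitude above threshold with strictly
#'   alternating sign).
#' @slot magnitude Relative beat-to-beat amplitude alternation,
#'   mean|A_n - A_(n-1)| / mean(A).
#' @slot nBeats Number of beats assessed.
#' @export
setClass("AlternansResult",
         representation(present = "logical", magnitude = "numeric",
                        nBeats = "integer"))

setMethod("show", "AlternansResult", function(object) {
  cat(sprintf("AlternansResult: present=%s, magnitude=%.3f over %d beats\n",
              object@present, object@magnitude, object@nBeats))
})

#' Default detector configuration
#'
#' The engine trace grid is fine (0.1 ms); the detector smooths with a short
#' moving average and requires a minimum secondary rise so that numerical
#' ripple is never called an EAD. Minima at or below the takeoff floor are
#' diastolic events (DAD territory) and are excluded.
#'
#' @param amplitudeThreshold Minimum secondary voltage rise, mV.
#' @param smoothWindowMs Moving-average window, ms.
#' @param takeoffFloor Minimum takeoff potential, mV.
#' @param stimExcludeMs Window around stimuli excluded as artifact, ms.
#' @return Named list.
#' @export
detectorConfig <- function(amplitudeThreshold = 2, smoothWindowMs = 1,
                           takeoffFloor = -60, stimExcludeMs = 2) {
  list(amplitudeThreshold = amplitudeThreshold,
       smoothWindowMs = smoothWindowMs,
       takeoffFloor = takeoffFloor, stimExcludeMs = stimExcludeMs)
}

.smooth <- function(x, k) {
  if (k <= 1) return(x)
  s <- stats::filter(x, rep(1 / k, k), sides = 2)
  s <- as.numeric(s)
  s[is.na(s)] <- x[is.na(s)]
  s
}

#' Detect early afterdepolarizations
#'
#' Per beat, within the window from the action-potential peak to the
#' earlier of the 90\% repolarization crossing and the next stimulus, the
#' smoothed voltage is scanned for local minima above the takeoff floor
#' that are followed by a secondary rise of at least the amplitude
#' threshold. Samples within \code{stimExcludeMs} of a stimulus are
#' excluded as stimulus artifact.
#'
#' @param trace A \linkS4class{CardiacTrace} on a uniform grid.
#' @param config Detector configuration from \code{\link{detectorConfig}}.
#' @return data.frame with columns beat, time (ms), takeoff (mV),
#'   amplitude (mV); zero rows when no EAD is present.
#' @export
detectEADs <- function(trace, config = detectorConfig()) {
  stopifnot(is(trace, "CardiacTrace"))
  dt <- if (length(trace@time) > 1) trace@time[2] - trace@time[1] else NA
  if (!is.finite(dt)) stop("trace grid is not uniform")
  idx <- beatIndices(trace)
  k <- max(1L, round(config$smoothWindowMs / dt))
  if (k %% 2 == 0) k <- k + 1L
  nex <- round(config$stimExcludeMs / dt)
  out <- list()
  for (b in seq_along(idx)) {
    ii <- idx[[b]]
    t <- trace@time[ii]
    v <- .smooth(trace@V[ii], k)
    n <- length(v)
    ipk <- which.max(v)
    ## end of assessment window: 90% crossing if reached, else beat end;
    ## always clipped clear of the next stimulus artifact window
    dias <- trace@V[ii][1]
    iend <- n - nex
    if (dias <= -60) {
      level <- v[ipk] - 0.9 * (v[ipk] - dias)
      seg <- seq.int(ipk, n)
      below <- which(v[seg] <= level)
      if (length(below)) iend <- min(iend, seg[below[1]])
    }
    i <- ipk + max(1L, nex)
    while (i < iend) {
      if (v[i] < v[i - 1] && v[i] <= v[i + 1] &&
          v[i] > config$takeoffFloor) {
        ## local minimum: measure the subsequent rise until the voltage
        ## drops back below the takeoff
        jmax <- v[i]; kk <- i + 1L; hit <- FALSE
        while (kk <= iend) {
          if (v[kk] > jmax) jmax <- v[kk]
          if (jmax - v[i] >= config$amplitudeThreshold) { hit <- TRUE; break }
          if (v[kk] < v[i]) break
          kk <- kk + 1L
        }
        if (hit) {
          ## extend to the full local maximum for the reported amplitude
          while (kk < iend && v[kk + 1] >= v[kk]) { kk <- kk + 1L }
          amp <- max(v[i:kk]) - v[i]
          out[[length(out) + 1L]] <-
            data.frame(beat = b, time = t[i], takeoff = v[i],
                       amplitude = amp)
          i <- kk
        }
      }
      i <- i + 1L
    }
  }
  if (!length(out))
    return(data.frame(beat = integer(), time = numeric(),
                      takeoff = numeric(), amplitude = numeric()))
  do.call(rbind, out)
}

#' Detect repolarization failure
#'
#' TRUE iff in any assessed beat the membrane never reaches the 90\%
#' repolarization level before the next stimulus (equivalently, the beat's
#' APD90 is undefined; a beat whose pre-stimulus diastolic potential is
#' above -60 mV has no valid diastole and counts as failed).
#'
#' @param trace A \linkS4class{CardiacTrace}.
#' @return Logical flag with attribute \code{failingBeats} (integer vector).
#' @export
detectRepolarizationFailure <- function(trace) {
  stopifnot(is(trace, "CardiacTrace"))
  idx <- beatIndices(trace)
  und <- vapply(idx, function(ii)
    is.na(.apdOne(trace@time[ii], trace@V[ii], 90)), logical(1))
  structure(any(und), failingBeats = which(und))
}

#' Full abnormality report for a trace
#' @param trace A \linkS4class{CardiacTrace}.
#' @param config Detector configuration.
#' @return An \linkS4class{AbnormalityReport}.
#' @export
abnormalityReport <- function(trace, config = detectorConfig()) {
  ev <- detectEADs(trace, config)
  rf <- detectRepolarizationFailure(trace)
  new("AbnormalityReport", hasEAD = nrow(ev) > 0,
      hasRepolFailure = as.logical(rf), events = ev,
      apd90Undefined = seq_along(trace@beatStarts) %in%
        attr(rf, "failingBeats"))
}

#' Detect calcium-transient alternans from per-beat amplitudes
#'
#' Magnitude is mean|A_n - A_(n-1)| / mean(A); alternans is called when the
#' magnitude reaches the threshold and the sign of the beat-to-beat
#' difference strictly alternates over the assessed beats.
#'
#' @param amplitudes Numeric vector of per-beat CaT amplitudes (>= minBeats).
#' @param threshold Relative magnitude threshold (default 0.05).
#' @param minBeats Minimum number of beats required (default 6).
#' @return An \linkS4class{AlternansResult}.
#' @examples
#' detectAlternans(rep(c(1, 0.8), 5))   # magnitude 2/9, present
#' @export
detectAlternans <- function(amplitudes, threshold = 0.05, minBeats = 6L) {
  if (length(amplitudes) < minBeats)
    stop("need at least ", minBeats, " beats, got ", length(amplitudes))
  if (any(!is.finite(amplitudes)) || mean(amplitudes) <= 0)
    return(new("AlternansResult", present = FALSE, magnitude = NA_real_,
               nBeats = length(amplitudes)))
  d <- diff(amplitudes)
  mag <- mean(abs(d)) / mean(amplitudes)
  strict <- length(d) >= 2 && all(sign(d[-1]) * sign(d[-length(d)]) < 0)
  new("AlternansResult", present = mag >= threshold && strict,
      magnitude = mag, nBeats = length(amplitudes))
}

## shared helper: one assessment run from a warm state
.assessRun <- function(params, cl, nBeats, recordLastN, cfg, initState) {
  runPacing(params, pacingProtocol(cl, as.integer(nBeats),
                                   as.integer(recordLastN)),
            cfg, initState = initState, normalizeTension = FALSE)
}

#' Search configuration for threshold protocols
#'
#' @param resolution Multiplier search resolution.
#' @param range Multiplier search range.
#' @param nBeats Beats simulated per candidate (from the warm state).
#' @param recordLastN Beats assessed per candidate.
#' @param warmBeats Beats used to reach quasi-steady state before the search.
#' @param coarsePoints Points of the monotonicity pre-check grid.
#' @param initState Optional warm state (skips the warm-up run).
#' @return Named list.
#' @export
searchConfig <- function(resolution = 0.01, range = c(0, 1), nBeats = 12L,
                         recordLastN = 3L, warmBeats = 20L,
                         coarsePoints = 5L, initState = NULL) {
  stopifnot(resolution > 0, length(range) == 2, range[1] < range[2])
  list(resolution = resolution, range = range, nBeats = nBeats,
       recordLastN = recordLastN, warmBeats = warmBeats,
       coarsePoints = coarsePoints, initState = initState)
}

#' EAD threshold: largest I_Kr multiplier that still triggers EADs
#'
#' Scales the model's \code{g_Kr} by a multiplier in \code{range} and
#' returns the largest multiplier (to \code{resolution}) at which the EAD
#' detector fires on the assessed beats at slow pacing. EAD presence is
#' first checked for monotonicity on a coarse grid; if monotone, the value
#' is located by bisection over the resolution grid, otherwise by an
#' exhaustive descending grid scan.
#'
#' @param params Model parameters (the multiplier applies on top of the
#'   model's own \code{g_Kr}).
#' @param protocol Pacing protocol; default 0.25 Hz (CL 4000 ms).
#' @param cfg Engine configuration.
#' @param search Search configuration from \code{\link{searchConfig}}.
#' @param detector Detector configuration.
#' @return A \linkS4class{ThresholdResult} (value = multiplier).
#' @export
eadThreshold <- function(params, protocol = pacingProtocol(4000, 20L, 3L),
                         cfg = engineConfig(), search = searchConfig(),
                         detector = detectorConfig()) {
  stopifnot(is(params, "IonicParams"))
  cl <- protocol@cycleLength
  warm <- search$initState
  if (is.null(warm)) {
    tr <- tryCatch(
      .assessRun(params, cl, search$warmBeats, 1L, cfg, NULL),
      error = function(e) stop("engine failure during warm-up: ",
                               conditionMessage(e)))
    warm <- finalState(tr)
  }
  base <- multipliers(params)
  presence <- function(m) {
    p2 <- ionicParams(.values = replace(base, "g_Kr", base[["g_Kr"]] * m))
    tr <- tryCatch(
      .assessRun(p2, cl, search$nBeats, search$recordLastN, cfg, warm),
      error = function(e) stop("engine failure at multiplier ", m, ": ",
                               conditionMessage(e)))
    nrow(detectEADs(tr, detector)) > 0
  }
  lo <- search$range[1]; hi <- search$range[2]
  grid <- seq(lo, hi, by = search$resolution)
  proto <- list(cycleLength = cl, range = search$range,
                resolution = search$resolution, nBeats = search$nBeats)
  ## coarse monotonicity pre-check: presence should be TRUE up to the
  ## threshold and FALSE beyond
  cg <- seq(lo, hi, length.out = search$coarsePoints)
  cp <- vapply(cg, presence, logical(1))
  if (!any(cp))
    ## coarse grid saw nothing; fall back to checking the lower bound
    return(new("ThresholdResult",
               value = if (presence(lo)) lo else NA_real_,
               found = presence(lo), resolution = search$resolution,
               protocol = proto))
  monotone <- !is.unsorted(rev(cp)) # TRUEs first, then FALSEs
  if (monotone) {
    ## discrete bisection over the resolution grid for the largest TRUE
    loi <- max(which(cp)) # index into cg
    lo_i <- which.min(abs(grid - cg[loi]))
    hi_i <- length(grid)
    if (cp[length(cp)]) {
      val <- grid[hi_i]
    } else {
      hi_i <- which.min(abs(grid - cg[min(which(!cp[loi:length(cp)])) +
                                        loi - 1]))
      while (hi_i - lo_i > 1L) {
        mid <- (lo_i + hi_i) %/% 2L
        if (presence(grid[mid])) lo_i <- mid else hi_i <- mid
      }
      val <- grid[lo_i]
    }
    return(new("ThresholdResult", value = val, found = TRUE,
               resolution = search$resolution, protocol = proto))
  }
  ## non-monotone: exhaustive descending scan (largest grid member wins)
  for (m in rev(grid)) {
    if (presence(m))
      return(new("ThresholdResult", value = m, found = TRUE,
                 resolution = search$resolution, protocol = proto))
  }
  new("ThresholdResult", value = NA_real_, found = FALSE,
      resolution = search$resolution, protocol = proto)
}

#' Alternans threshold: longest cycle length with CaT alternans
#'
#' Scans a descending cycle-length grid (grid semantics, no interpolation;
#' alternans windows can be non-contiguous) and returns the longest CL at
#' which calcium-transient alternans is present at quasi-steady state.
#'
#' @param params Model parameters.
#' @param clGrid Cycle-length grid, ms (default 600 down to 250, step 10).
#' @param cfg Engine configuration.
#' @param nBeats Beats per cycle length (last \code{assessBeats} assessed).
#' @param assessBeats Beats assessed for alternans (>= 6).
#' @param initState Optional warm state shared across cycle lengths.
#' @param threshold Alternans magnitude threshold.
#' @return A \linkS4class{ThresholdResult} (value = cycle length, ms).
#' @export
alternansThreshold <- function(params, clGrid = seq(600, 250, by = -10),
                               cfg = engineConfig(), nBeats = 40L,
                               assessBeats = 10L, initState = NULL,
                               threshold = 0.05) {
  stopifnot(is(params, "IonicParams"), assessBeats >= 6L)
  clGrid <- sort(clGrid, decreasing = TRUE)
  proto <- list(clGrid = range(clGrid), step = if (length(clGrid) > 1)
    abs(diff(clGrid[1:2])) else NA, nBeats = nBeats)
  for (cl in clGrid) {
    tr <- .assessRun(params, cl, nBeats, assessBeats, cfg, initState)
    amps <- computeBiomarkers(tr)@perBeat$CaT_amplitude
    res <- detectAlternans(amps, threshold = threshold)
    if (res@present)
      return(new("ThresholdResult", value = cl, found = TRUE,
                 resolution = proto$step, protocol = proto))
  }
  new("ThresholdResult", value = NA_real_, found = FALSE,
      resolution = proto$step, protocol = proto)
}

#' Single-factor knockout analysis of a multichannel drug
#'
#' Computes the EAD threshold for the untreated disease model, the model
#' under the full drug effect, and one variant per channel effect in which
#' that single effect is removed (all other effects applied). A knockout
#' row above the full-drug row means the omitted block was protective.
#'
#' @param diseaseParams Disease-model parameters (e.g. LQTS2).
#' @param drug A \linkS4class{DrugDescription} with at least two effects.
#' @param concMultiple Concentration as a multiple of the drug's EFTPC.
#' @param protocol,cfg,search,detector Passed to \code{\link{eadThreshold}}.
#' @return data.frame with columns condition, value, found.
#' @export
knockoutAnalysis <- function(diseaseParams, drug, concMultiple,
                             protocol = pacingProtocol(4000, 20L, 3L),
                             cfg = engineConfig(), search = searchConfig(),
                             detector = detectorConfig()) {
  stopifnot(is(drug, "DrugDescription"))
  if (length(drug@effects) < 2)
    stop("knockout analysis needs a drug with >= 2 channel effects")
  th <- function(p) eadThreshold(p, protocol, cfg, search, detector)
  rows <- list()
  r <- th(diseaseParams)
  rows[["untreated"]] <- c(r@value, r@found)
  r <- th(applyDrug(diseaseParams, drug, concMultiple))
  rows[["full_drug"]] <- c(r@value, r@found)
  for (i in seq_along(drug@effects)) {
    ko <- drug
    ko@effects <- drug@effects[-i]
    lab <- sprintf("minus_%s_%s", drug@effects[[i]]@channel,
                   drug@effects[[i]]@mode)
    r <- th(applyDrug(diseaseParams, ko, concMultiple))
    rows[[lab]] <- c(r@value, r@found)
  }
  data.frame(condition = names(rows),
             value = vapply(rows, `[`, numeric(1), 1),
             found = as.logical(vapply(rows, `[`, numeric(1), 2)),
             row.names = NULL)
}
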