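#' @useDynLib cardiotrial, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot show setValidity
#' @importFrom stats setNames median cor approx rnorm runif quantile coef
#' @importFrom utils read.csv write.csv head tail
NULL

## Canonical multiplier names, in engine order. `camkii` is a composite
## remodeling hook (scales SERCA uptake down and I_CaL up per unit above 1);
## `g_Nav18` is an absolute conductance (mS/uF), not a multiplier.
.PARAM_NAMES <- c("g_Na", "g_NaL", "g_to", "g_CaL", "g_Kr", "g_Ks", "g_K1",
                  "g_NaCa", "g_NaK", "j_up", "j_rel", "j_leak",
                  "camkii", "g_Nav18")

.BIOMARKER_NAMES <- c("APD40", "APD50", "APD90", "CaT_amplitude",
                      "CaT_diastolic", "CaTD50", "CaTD90",
                      "peak_tension", "relaxation_tau")

#' IonicParams: per-current multiplier set
#'
#' The single hook through which populations, drugs and disease variants act
#' on the myocyte engine. Holds one nonnegative multiplier per conductance or
#' flux (default 1), a composite CaMKII activity multiplier, and the absolute
#' Nav1.8 conductance \code{g_Nav18} in mS/uF (default 0, i.e. channel
#' absent). Applying the all-default set leaves engine output identical to
#' baseline.
#'
#' @slot multipliers Named numeric vector over the canonical parameter names.
#' @export
setClass("IonicParams", representation(multipliers = "numeric"))

setValidity("IonicParams", function(object) {
  m <- object@multipliers
  if (!identical(names(m), .PARAM_NAMES))
    return(sprintf("multipliers must be named exactly: %s",
                   paste(.PARAM_NAMES, collapse = ", ")))
  if (any(!is.finite(m))) return("all multipliers must be finite")
  if (any(m < 0)) return("all multipliers must be >= 0")
  TRUE
})

#' Construct an IonicParams multiplier set
#'
#' @param ... Named multipliers to override (e.g. \code{g_Kr = 0.3}). Any
#'   parameter not named keeps its default (1, or 0 for \code{g_Nav18}).
#' @param .values Optional named numeric vector/list used the same way.
#' @return An \linkS4class{IonicParams} object.
#' @examples
#' ionicParams()                 # baseline
#' ionicParams(g_Kr = 0.3, g_NaL = 1.82)  # LQTS2-like remodeling
#' @export
ionicParams <- function(..., .values = NULL) {
  m <- setNames(rep(1, length(.PARAM_NAMES)), .PARAM_NAMES)
  m["g_Nav18"] <- 0
  ov <- c(list(...), as.list(.values))
  if (length(ov)) {
    bad <- setdiff(names(ov), .PARAM_NAMES)
    if (length(bad))
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
           "; allowed: ", paste(.PARAM_NAMES, collapse = ", "))
    m[names(ov)] <- unlist(ov)
  }
  new("IonicParams", multipliers = m)
}

#' Multiplier accessor
#' @param object An IonicParams object.
#' @return Named numeric vector of multipliers.
#' @export
multipliers <- function(object) {
  stopifnot(is(object, "IonicParams"))
  object@multipliers
}

setMethod("show", "IonicParams", function(object) {
  m <- object@multipliers
  changed <- m != c(setNames(rep(1, 13), .PARAM_NAMES[1:13]), g_Nav18 = 0)
  cat("IonicParams (", sum(changed), " non-default)\n", sep = "")
  if (any(changed))
    print(round(m[changed], 4))
})

#' PacingProtocol: periodic stimulation protocol
#'
#' @slot cycleLength Pacing cycle length, ms.
#' @slot nBeats Total number of beats simulated.
#' @slot stimAmplitude Stimulus amplitude, uA/uF (negative = depolarizing).
#' @slot stimDuration Stimulus duration, ms.
#' @slot recordLastN Number of final beats recorded on the output grid.
#' @export
setClass("PacingProtocol",
         representation(cycleLength = "numeric", nBeats = "integer",
                        stimAmplitude = "numeric", stimDuration = "numeric",
                        recordLastN = "integer"))

setValidity("PacingProtocol", function(object) {
  if (object@cycleLength <= 0) return("cycleLength must be > 0")
  if (object@nBeats < 1L) return("nBeats must be >= 1")
  if (object@stimDuration >= object@cycleLength)
    return("stimDuration must be < cycleLength")
  if (object@recordLastN < 0L || object@recordLastN > object@nBeats)
    return("recordLastN must be in [0, nBeats]")
  TRUE
})

#' Construct a pacing protocol
#'
#' @param cycleLength Cycle length in ms (> 0); must be a multiple of the
#'   engine recording step (0.1 ms by default).
#' @param nBeats Number of beats to pace (>= 1).
#' @param recordLastN How many of the final beats to record (<= nBeats).
#' @param stimAmplitude Stimulus amplitude in uA/uF.
#' @param stimDuration Stimulus duration in ms.
#' @return A \linkS4class{PacingProtocol}.
#' @examples
#' pacingProtocol(1000, nBeats = 200, recordLastN = 10)
#' @export
pacingProtocol <- function(cycleLength = 1000, nBeats = 200L,
                           recordLastN = min(10L, nBeats),
                           stimAmplitude = -52, stimDuration = 1) {
  new("PacingProtocol", cycleLength = as.numeric(cycleLength),
      nBeats = as.integer(nBeats), stimAmplitude = as.numeric(stimAmplitude),
      stimDuration = as.numeric(stimDuration),
      recordLastN = as.integer(recordLastN))
}

setMethod("show", "PacingProtocol", function(object) {
  cat(sprintf(
    "PacingProtocol: CL %g ms x %d beats (recording last %d), stim %g uA/uF x %g ms\n",
    object@cycleLength, object@nBeats, object@recordLastN,
    object@stimAmplitude, object@stimDuration))
})

#' CardiacTrace: recorded voltage / calcium / tension time series
#'
#' Uniform 0.1 ms (configurable) grid over the recorded beats. Tension is
#' normalized so that the baseline peak at reference parameters equals 1
#' (raw engine units if \code{normalized} is FALSE). \code{beatStarts} are
#' 1-based indices of each recorded beat's first sample, aligned with the
#' stimulus times.
#'
#' @slot time Time, ms (strictly increasing, uniform).
#' @slot V Membrane potential, mV.
#' @slot Cai Cytosolic free calcium, uM.
#' @slot tension Normalized active tension.
#' @slot beatStarts Integer indices of beat starts.
#' @slot stimTimes Stimulus onset times, ms.
#' @slot cycleLength Pacing cycle length, ms.
#' @slot currents Optional matrix of current densities (uA/uF), columns
#'   ICaL, IKr, INa, INaL, INav18; zero rows when not recorded.
#' @slot extra List with additional series (CaSR, Nai) and engine metadata
#'   (maxAbsINa, maxAbsINav18, normalized flag).
#' @export
setClass("CardiacTrace",
         representation(time = "numeric", V = "numeric", Cai = "numeric",
                        tension = "numeric", beatStarts = "integer",
                        stimTimes = "numeric", cycleLength = "numeric",
                        currents = "matrix", extra = "list"))

setValidity("CardiacTrace", function(object) {
  n <- length(object@time)
  if (length(object@V) != n || length(object@Cai) != n ||
      length(object@tension) != n)
    return("time, V, Cai and tension must have equal length")
  if (n > 1) {
    dt <- diff(object@time)
    if (any(dt <= 0)) return("time must be strictly increasing")
    if (max(dt) - min(dt) > 1e-6) return("time grid must be uniform")
  }
  if (length(object@beatStarts) &&
      (min(object@beatStarts) < 1L || max(object@beatStarts) > n))
    return("beatStarts out of range")
  TRUE
})

setMethod("show", "CardiacTrace", function(object) {
  cat(sprintf(
    "CardiacTrace: %d samples, %d beat(s) at CL %g ms; V in [%.1f, %.1f] mV\n",
    length(object@time), length(object@beatStarts), object@cycleLength,
    min(object@V), max(object@V)))
})

#' Number of recorded beats in a trace
#' @param trace A CardiacTrace.
#' @return Integer beat count.
#' @export
nBeatsRecorded <- function(trace) length(trace@beatStarts)

#' BiomarkerSet: scalar biomarkers of a recorded trace
#'
#' Values are averaged over the recorded beats; a biomarker that is not
#' computable (e.g. APD90 when repolarization fails) is NA and flagged in
#' \code{undefined}.
#'
#' @slot values Named numeric vector (APD40/50/90 ms, CaT_amplitude and
#'   CaT_diastolic uM, CaTD50/CaTD90 ms, peak_tension normalized,
#'   relaxation_tau ms).
#' @slot undefined Named logical vector marking non-computable biomarkers.
#' @slot perBeat List of per-beat values (APD90, CaT amplitude) used by the
#'   abnormality detectors.
#' @export
setClass("BiomarkerSet",
         representation(values = "numeric", undefined = "logical",
                        perBeat = "list"))

setValidity("BiomarkerSet", function(object) {
  if (!identical(names(object@values), .BIOMARKER_NAMES))
    return("values must be named with the canonical biomarker names")
  v <- object@values
  if (!is.na(v["APD40"]) && !is.na(v["APD50"]) && v["APD40"] > v["APD50"] + 1e-9)
    return("APD40 must be <= APD50")
  if (!is.na(v["APD50"]) && !is.na(v["APD90"]) && v["APD50"] > v["APD90"] + 1e-9)
    return("APD50 must be <= APD90")
  if (!is.na(v["CaT_amplitude"]) && v["CaT_amplitude"] < 0)
    return("CaT_amplitude must be >= 0")
  if (!is.na(v["relaxation_tau"]) && v["relaxation_tau"] <= 0)
    return("relaxation_tau must be > 0 when defined")
  TRUE
})

setMethod("show", "BiomarkerSet", function(object) {
  cat("BiomarkerSet:\n")
  print(round(object@values, 3))
  if (any(object@undefined))
    cat("undefined:", paste(names(object@undefined)[object@undefined],
                            collapse = ", "), "\n")
})

#' Biomarker value accessor
#' @param object A BiomarkerSet.
#' @param name Biomarker name (one of the canonical names); NULL for all.
#' @return Numeric value(s); NA when undefined.
#' @export
biomarker <- function(object, name = NULL) {
  stopifnot(is(object, "BiomarkerSet"))
  if (is.null(name)) return(object@values)
  if (!name %in% .BIOMARKER_NAMES)
    stop("unknown biomarker '", name, "'; allowed: ",
         paste(.BIOMARKER_NAMES, collapse = ", "))
  unname(object@values[name])
}

#' ChannelEffect: one channel-level drug effect
#'
#' Either a Hill pore block (\code{mode = "block"}: multiplier
#' \code{1/(1 + (C/IC50)^h)}) or a dose-to-fractional-enhancement schedule
#' (\code{mode = "scale"}: multiplier \code{1 + interpolated change}, with
#' log-linear interpolation between listed dose multiples).
#'
#' @slot channel Target parameter name (an IonicParams field).
#' @slot mode "block" or "scale".
#' @slot ic50 IC50 in uM (block mode).
#' @slot hill Hill coefficient (block mode).
#' @slot schedule data.frame with columns \code{multiple} (of the therapeutic
#'   concentration, strictly increasing) and \code{change} (fractional, e.g.
#'   0.10 for +10\%) for scale mode; zero rows otherwise.
#' @export
setClass("ChannelEffect",
         representation(channel = "character", mode = "character",
                        ic50 = "numeric", hill = "numeric",
                        schedule = "data.frame"))

setValidity("ChannelEffect", function(object) {
  if (!object@channel %in% .PARAM_NAMES)
    return(sprintf("unknown channel '%s'; allowed: %s", object@channel,
                   paste(.PARAM_NAMES, collapse = ", ")))
  if (!object@mode %in% c("block", "scale"))
    return("mode must be 'block' or 'scale'")
  if (object@mode == "block") {
    if (!is.finite(object@ic50) || object@ic50 <= 0)
      return("block effect requires ic50 > 0")
    if (!is.finite(object@hill) || object@hill <= 0)
      return("block effect requires hill > 0")
  } else {
    s <- object@schedule
    if (nrow(s) < 1) return("scale effect requires a nonempty schedule")
    if (!all(c("multiple", "change") %in% names(s)))
      return("schedule needs columns 'multiple' and 'change'")
    if (any(diff(s$multiple) <= 0))
      return("schedule multiples must be strictly increasing")
    if (any(s$multiple <= 0)) return("schedule multiples must be > 0")
    if (any(1 + s$change <= 0)) return("scale factors must stay > 0")
  }
  TRUE
})

#' Construct a channel effect
#' @param channel Target parameter name, e.g. "g_Kr".
#' @param mode "block" (Hill) or "scale" (enhancement schedule).
#' @param ic50,hill Hill block parameters (uM; dimensionless). Default hill 1.
#' @param schedule data.frame(multiple, change) for scale mode.
#' @return A \linkS4class{ChannelEffect}.
#' @export
channelEffect <- function(channel, mode = c("block", "scale"),
                          ic50 = NA_real_, hill = 1,
                          schedule = data.frame(multiple = numeric(),
                                                change = numeric())) {
  mode <- match.arg(mode)
  new("ChannelEffect", channel = channel, mode = mode,
      ic50 = as.numeric(ic50), hill = as.numeric(hill),
      schedule = schedule)
}

#' DrugDescription: channel-level description of a compound
#'
#' @slot name Drug name.
#' @slot effects List of \linkS4class{ChannelEffect}s (at most one block per
#'   channel).
#' @slot eftpc Effective free therapeutic plasma concentration, uM (> 0).
#' @slot note Free-text provenance note.
#' @export
setClass("DrugDescription",
         representation(name = "character", effects = "list",
                        eftpc = "numeric", note = "character"))

setValidity("DrugDescription", function(object) {
  if (!is.finite(object@eftpc) || object@eftpc <= 0)
    return("eftpc must be > 0")
  if (!all(vapply(object@effects, is, logical(1), class2 = "ChannelEffect")))
    return("effects must all be ChannelEffect objects")
  blk <- vapply(object@effects, function(e)
    if (e@mode == "block") e@channel else NA_character_, character(1))
  blk <- blk[!is.na(blk)]
  if (anyDuplicated(blk))
    return("at most one block effect per channel")
  TRUE
})

#' Construct a drug description
#' @param name Drug name.
#' @param effects List of \code{\link{channelEffect}}s.
#' @param eftpc Effective free therapeutic plasma concentration, uM.
#' @param note Provenance note.
#' @return A \linkS4class{DrugDescription}.
#' @examples
#' drugDescription("ikrblocker",
#'   effects = list(channelEffect("g_Kr", "block", ic50 = 1)), eftpc = 0.5)
#' @export
drugDescription <- function(name, effects = list(), eftpc, note = "") {
  new("DrugDescription", name = name, effects = effects,
      eftpc = as.numeric(eftpc), note = note)
}

setMethod("show", "DrugDescription", function(object) {
  cat(sprintf("DrugDescription '%s' (EFTPC %g uM), %d effect(s)\n",
              object@name, object@eftpc, length(object@effects)))
  for (e in object@effects) {
    if (e@mode == "block")
      cat(sprintf("  %s block: IC50 %g uM, hill %g\n", e@channel, e@ic50,
                  e@hill))
    else
      cat(sprintf("  %s scale: %s\n", e@channel,
                  paste(sprintf("%+.0f%% @%gx", 100 * e@schedule$change,
                                e@schedule$multiple), collapse = ", ")))
  }
})

#' DiseaseVariant: named partial multiplier set
#'
#' @slot name Variant name (e.g. "LQTS2", "D1", "CONTROL").
#' @slot multipliers Named numeric vector over a subset of IonicParams
#'   fields; unspecified fields act as 1.
#' @slot description Free-text description / provenance.
#' @export
setClass("DiseaseVariant",
         representation(name = "character", multipliers = "numeric",
                        description = "character"))

setValidity("DiseaseVariant", function(object) {
  m <- object@multipliers
  if (length(m) && (is.null(names(m)) || any(!names(m) %in% .PARAM_NAMES)))
    return("multiplier names must be IonicParams fields")
  if (any(m < 0)) return("multipliers must be >= 0")
  TRUE
})

#' Construct a disease variant
#' @param name Variant name.
#' @param multipliers Named numeric vector of the remodeled fields.
#' @param description Free-text note.
#' @return A \linkS4class{DiseaseVariant}.
#' @export
diseaseVariant <- function(name, multipliers = numeric(), description = "") {
  m <- unlist(multipliers)
  if (is.null(m)) m <- numeric()
  new("DiseaseVariant", name = name, multipliers = m,
      description = description)
}

setMethod("show", "DiseaseVariant", function(object) {
  cat(sprintf("DiseaseVariant '%s'", object@name))
  if (length(object@multipliers)) {
    cat(": ")
    cat(paste(sprintf("%s=%g", names(object@multipliers),
                      object@multipliers), collapse = ", "))
  }
  cat("\n")
})

#' ThresholdResult: outcome of an arrhythmia-threshold search
#'
#' @slot value Threshold value (I_Kr multiplier, dimensionless, or pacing
#'   cycle length, ms); NA when \code{found} is FALSE.
#' @slot found Whether a qualifying value exists in the search range.
#' @slot resolution Search resolution (multiplier step or CL grid step).
#' @slot protocol List of protocol metadata (search range, CL, beats).
#' @export
setClass("ThresholdResult",
         representation(value = "numeric", found = "logical",
                        resolution = "numeric", protocol = "list"))

setMethod("show", "ThresholdResult", function(object) {
  if (object@found)
    cat(sprintf("ThresholdResult: %g (resolution %g)\n", object@value,
                object@resolution))
  else
    cat("ThresholdResult: not found in search range\n")
})
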