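## Population-of-models sampling and biomarker calibration.

#' SamplingSpec: multiplier-sampling specification
#'
#' Latin-hypercube sampling on a log scale, one stratum per sample, fully
#' reproducible from the seed.
#'
#' @slot parameters Names of the varied IonicParams fields.
#' @slot lower,upper Named range bounds per parameter (0 < lower <= upper).
#' @slot seed Integer RNG seed.
#' @export
setClass("SamplingSpec",
         representation(parameters = "character", lower = "numeric",
                        upper = "numeric", seed = "integer"))

setValidity("SamplingSpec", function(object) {
  p <- object@parameters
  if (!all(p %in% .PARAM_NAMES))
    return("parameters must be IonicParams fields")
  if (!identical(names(object@lower), p) || !identical(names(object@upper), p))
    return("lower/upper must be named like parameters")
  if (any(object@lower <= 0)) return("lower bounds must be > 0")
  if (any(object@lower > object@upper)) return("need lower <= upper")
  TRUE
})

#' Construct a sampling specification
#'
#' Default: the twelve conductance/flux multipliers varied log-uniformly in
#' [0.5, 2], the conventional range for population-of-models studies of
#' inter-subject variability in ionic densities.
#'
#' @param parameters Character vector of varied parameters.
#' @param range Length-2 range applied to every parameter, or NULL when
#'   lower/upper given explicitly.
#' @param lower,upper Optional named bounds.
#' @param seed Integer seed.
#' @return A \linkS4class{SamplingSpec}.
#' @export
samplingSpec <- function(parameters = .PARAM_NAMES[1:12], range = c(0.5, 2),
                         lower = NULL, upper = NULL, seed = 1L) {
  if (is.null(lower)) lower <- setNames(rep(range[1], length(parameters)),
                                        parameters)
  if (is.null(upper)) upper <- setNames(rep(range[2], length(parameters)),
                                        parameters)
  new("SamplingSpec", parameters = parameters,
      lower = lower[parameters], upper = upper[parameters],
      seed = as.integer(seed))
}

setMethod("show", "SamplingSpec", function(object) {
  cat(sprintf("SamplingSpec: %d parameters, seed %d\n",
              length(object@parameters), object@seed))
})

#' Sample a population of multiplier sets
#'
#' Latin-hypercube sample: for each parameter the N samples occupy all N
#' equal log-space strata exactly once.
#'
#' @param spec A \linkS4class{SamplingSpec}.
#' @param N Population size (>= 0).
#' @return data.frame with column \code{model_id} and one column per
#'   sampled parameter.
#' @examples
#' pop <- samplePopulation(samplingSpec(seed = 7), 10)
#' @export
samplePopulation <- function(spec, N) {
  validObject(spec)
  N <- as.integer(N)
  if (N < 0) stop("N must be >= 0")
  p <- spec@parameters
  if (N == 0)
    return(setNames(data.frame(matrix(nrow = 0, ncol = length(p) + 1)),
                    c("model_id", p)))
  set.seed(spec@seed)
  u <- lhs::randomLHS(N, length(p))
  out <- data.frame(model_id = seq_len(N))
  for (j in seq_along(p)) {
    lo <- log(spec@lower[[p[j]]]); hi <- log(spec@upper[[p[j]]])
    out[[p[j]]] <- exp(lo + u[, j] * (hi - lo))
  }
  out
}

#' Default biomarker calibration ranges
#'
#' Human-plausible ranges for 1 Hz pacing, standing in for experimentally
#' observed reference ranges; every range is user-overridable. Units match
#' \linkS4class{BiomarkerSet} (ms, uM, normalized tension).
#'
#' @param ... Named length-2 numeric overrides, e.g.
#'   \code{APD90 = c(200, 400)}. Biomarkers set to NULL are unconstrained.
#' @return Named list of c(min, max) ranges.
#' @export
calibrationRanges <- function(...) {
  rg <- list(APD90 = c(180, 440),
             CaT_amplitude = c(0.1, 1.2),
             CaT_diastolic = c(0.02, 0.2),
             peak_tension = c(0.2, 5),
             relaxation_tau = c(10, 250))
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), .BIOMARKER_NAMES)
    if (length(bad)) stop("unknown biomarker(s): ", paste(bad, collapse = ", "))
    for (nm in names(ov)) rg[[nm]] <- ov[[nm]]
    rg <- rg[!vapply(rg, is.null, logical(1))]
  }
  for (nm in names(rg))
    if (length(rg[[nm]]) != 2 || rg[[nm]][1] > rg[[nm]][2])
      stop("range for ", nm, " must be c(min, max) with min <= max")
  rg
}

#' PopulationTable: sampled models with biomarkers and acceptance flags
#'
#' @slot table data.frame: model_id, sampled multipliers, biomarkers,
#'   \code{accepted} flag and rejection \code{reason}.
#' @slot states Named list of engine states (one per solver-successful
#'   model) at the screening pacing rate, reusable as trial initial states.
#' @slot provenance List: sampling spec summary, seed, ranges, protocol.
#' @export
setClass("PopulationTable",
         representation(table = "data.frame", states = "list",
                        provenance = "list"))

setMethod("show", "PopulationTable", function(object) {
  cat(sprintf("PopulationTable: %d models, %d accepted (%.0f%%)\n",
              nrow(object@table), sum(object@table$accepted),
              100 * mean(object@table$accepted)))
})

#' Accepted subset of a population table
#' @param pop A \linkS4class{PopulationTable}.
#' @return data.frame of accepted rows.
#' @export
acceptedModels <- function(pop) {
  stopifnot(is(pop, "PopulationTable"))
  pop@table[pop@table$accepted, , drop = FALSE]
}

.paramsFromRow <- function(row, parameters) {
  v <- as.numeric(row[parameters])
  names(v) <- parameters
  ionicParams(.values = v)
}

#' Calibrate a sampled population against biomarker ranges
#'
#' Runs every model to quasi-steady state, computes biomarkers and accepts
#' models whose constrained biomarkers all lie inside their ranges. Models
#' with undefined APD90 or an integration failure are rejected with a
#' recorded reason, as are models whose drug-free trace already triggers
#' the EAD detector at the screening (trial) pacing rate - an in silico
#' trial population must be arrhythmia-free at baseline.
#'
#' @param pop data.frame from \code{\link{samplePopulation}}.
#' @param ranges Ranges from \code{\link{calibrationRanges}}.
#' @param protocol Calibration pacing protocol (default 1 Hz, 150 beats).
#' @param cfg Engine configuration.
#' @param screenProtocol Protocol of the baseline abnormality screen at the
#'   trial pacing rate; its final states are cached for trials. NULL skips
#'   the screen.
#' @param detector Detector configuration for the screen.
#' @return A \linkS4class{PopulationTable}.
#' @export
calibratePopulation <- function(pop, ranges = calibrationRanges(),
                                protocol = pacingProtocol(1000, 150L, 3L),
                                cfg = engineConfig(),
                                screenProtocol = pacingProtocol(2000, 12L, 3L),
                                detector = detectorConfig()) {
  parameters <- setdiff(names(pop), "model_id")
  n <- nrow(pop)
  bm <- matrix(NA_real_, n, length(.BIOMARKER_NAMES),
               dimnames = list(NULL, .BIOMARKER_NAMES))
  accepted <- logical(n)
  reason <- character(n)
  states <- list()
  for (i in seq_len(n)) {
    params <- .paramsFromRow(pop[i, ], parameters)
    tr <- tryCatch(runPacing(params, protocol, cfg, normalizeTension = FALSE),
                   error = function(e) NULL)
    if (is.null(tr)) { reason[i] <- "integration_failure"; next }
    b <- computeBiomarkers(tr)
    vals <- b@values
    vals["peak_tension"] <- vals["peak_tension"] / referencePeakTension(cfg)
    bm[i, ] <- vals
    if (is.na(vals["APD90"])) { reason[i] <- "apd90_undefined"; next }
    bad <- NULL
    for (nm in names(ranges)) {
      v <- vals[nm]
      if (is.na(v) || v < ranges[[nm]][1] || v > ranges[[nm]][2]) {
        bad <- nm; break
      }
    }
    if (!is.null(bad)) { reason[i] <- paste0("out_of_range:", bad); next }
    if (!is.null(screenProtocol)) {
      sc <- tryCatch(runPacing(params, screenProtocol, cfg,
                               initState = finalState(tr),
                               normalizeTension = FALSE),
                     error = function(e) NULL)
      if (is.null(sc)) { reason[i] <- "integration_failure"; next }
      rep0 <- abnormalityReport(sc, detector)
      if (rep0@hasEAD || rep0@hasRepolFailure) {
        reason[i] <- "baseline_abnormality"; next
      }
      states[[as.character(pop$model_id[i])]] <- finalState(sc)
    } else {
      states[[as.character(pop$model_id[i])]] <- finalState(tr)
    }
    accepted[i] <- TRUE
    reason[i] <- ""
  }
  tab <- cbind(pop, as.data.frame(bm), accepted = accepted, reason = reason)
  new("PopulationTable", table = tab, states = states,
      provenance = list(parameters = parameters, ranges = ranges,
                        cycleLength = protocol@cycleLength,
                        nBeats = protocol@nBeats,
                        screenCycleLength = if (!is.null(screenProtocol))
                          screenProtocol@cycleLength else NA))
}
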