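## In silico drug trials, torsadogenic risk scoring, classification and
## phenotype-consistency checking.

#' TrialResult: outcome of one drug trial on a population
#'
#' @slot drug Drug name.
#' @slot counts data.frame per concentration multiple: nAbnormal,
#'   nUndetermined, nModels, fraction (abnormal / determined).
#' @slot perModel Logical matrix (models x multiples) of abnormality flags
#'   (NA = undetermined).
#' @export
setClass("TrialResult",
         representation(drug = "character", counts = "data.frame",
                        perModel = "matrix"))

setMethod("show", "TrialResult", function(object) {
  cat(sprintf("TrialResult '%s':\n", object@drug))
  print(object@counts, row.names = FALSE)
})

#' RiskScore: concentration-weighted torsadogenic risk score
#'
#' @slot score Score in [0, 1].
#' @slot fractions Abnormal fractions per concentration multiple.
#' @slot multiples Concentration multiples.
#' @slot weights Weights used.
#' @export
setClass("RiskScore",
         representation(score = "numeric", fractions = "numeric",
                        multiples = "numeric", weights = "numeric"))

setMethod("show", "RiskScore", function(object) {
  cat(sprintf("RiskScore: %.4g\n", object@score))
})

#' Run an in silico drug trial
#'
#' Exposes every accepted model of a calibrated population to the drug at
#' each concentration multiple, re-runs to quasi-steady state at the trial
#' pacing rate (from the cached per-model state), and evaluates the EAD and
#' repolarization-failure detectors. Models whose integration fails under
#' drug are counted as undetermined and excluded from the denominator.
#'
#' @param population A calibrated \linkS4class{PopulationTable}.
#' @param drug A \linkS4class{DrugDescription}.
#' @param multiples Concentration schedule, multiples of EFTPC.
#' @param protocol Trial pacing protocol (default CL 2000 ms; slow pacing
#'   favors EADs).
#' @param cfg Engine configuration.
#' @param detector Detector configuration.
#' @return A \linkS4class{TrialResult}.
#' @export
runDrugTrial <- function(population, drug, multiples = c(1, 10, 30, 100),
                         protocol = pacingProtocol(2000, 15L, 4L),
                         cfg = engineConfig(),
                         detector = detectorConfig()) {
  stopifnot(is(population, "PopulationTable"), is(drug, "DrugDescription"))
  if (!length(multiples) || any(multiples <= 0) || anyDuplicated(multiples))
    stop("multiples must be distinct and positive")
  acc <- acceptedModels(population)
  parameters <- population@provenance$parameters
  nm <- nrow(acc)
  per <- matrix(NA, nm, length(multiples),
                dimnames = list(acc$model_id, as.character(multiples)))
  for (i in seq_len(nm)) {
    params <- .paramsFromRow(acc[i, ], parameters)
    st <- population@states[[as.character(acc$model_id[i])]]
    for (j in seq_along(multiples)) {
      pd <- applyDrug(params, drug, multiples[j])
      tr <- tryCatch(runPacing(pd, protocol, cfg, initState = st,
                               normalizeTension = FALSE),
                     error = function(e) NULL)
      if (is.null(tr)) next # stays NA (undetermined)
      rep1 <- abnormalityReport(tr, detector)
      per[i, j] <- rep1@hasEAD || rep1@hasRepolFailure
    }
  }
  counts <- data.frame(
    multiple = multiples,
    nAbnormal = as.integer(colSums(per, na.rm = TRUE)),
    nUndetermined = as.integer(colSums(is.na(per))),
    nModels = nm)
  counts$fraction <- ifelse(counts$nModels - counts$nUndetermined > 0,
                            counts$nAbnormal /
                              (counts$nModels - counts$nUndetermined), 0)
  new("TrialResult", drug = drug@name, counts = counts, perModel = per)
}

#' Torsadogenic risk score
#'
#' Aggregates per-concentration abnormal fractions into a score weighted
#' inversely by concentration, so strongly supraphysiological doses
#' contribute less: \code{score = sum(f * w) / sum(w)} with
#' \code{w = 1/multiple} (default) or \code{w = 1/log10(10 * multiple)}.
#'
#' @param fractions Abnormal fractions in [0, 1], one per multiple.
#' @param multiples Distinct positive concentration multiples.
#' @param weighting "inverse" (1/c, default) or "log" (1/log10(10c)).
#' @return A \linkS4class{RiskScore}.
#' @examples
#' tdpRiskScore(c(0, 0, 0, 0.5), c(1, 10, 30, 100))  # 0.004373...
#' @export
tdpRiskScore <- function(fractions, multiples, weighting = c("inverse", "log")) {
  weighting <- match.arg(weighting)
  if (!length(multiples)) stop("empty concentration schedule")
  if (length(fractions) != length(multiples))
    stop("fractions and multiples must have equal length")
  if (any(multiples <= 0) || anyDuplicated(multiples))
    stop("multiples must be distinct and positive")
  if (any(fractions < 0 | fractions > 1)) stop("fractions must be in [0, 1]")
  w <- switch(weighting, inverse = 1 / multiples,
              log = 1 / log10(10 * multiples))
  new("RiskScore", score = sum(fractions * w) / sum(w),
      fractions = fractions, multiples = multiples, weights = w)
}

#' @describeIn tdpRiskScore Risk score of a \linkS4class{TrialResult}.
#' @param trial A TrialResult.
#' @export
trialRiskScore <- function(trial, weighting = c("inverse", "log")) {
  tdpRiskScore(trial@counts$fraction, trial@counts$multiple, weighting)
}

#' Classify drugs and compute prediction metrics
#'
#' Maps risk classes to the two-category scheme (no -> safe; high,
#' possible, conditional -> unsafe), predicts unsafe when the risk score
#' exceeds the threshold, and returns the confusion counts with accuracy,
#' sensitivity and specificity (unsafe = positive class).
#'
#' @param scores Named numeric vector of risk scores per drug.
#' @param labels Named character vector of risk classes per drug.
#' @param threshold Score threshold (default 0: any abnormality is unsafe).
#' @return List with accuracy, sensitivity, specificity, counts (TP, FP,
#'   TN, FN) and \code{excluded} (drugs with a score but no label).
#' @export
classifyAndScore <- function(scores, labels, threshold = 0) {
  if (is.null(names(scores))) stop("scores must be named by drug")
  excluded <- setdiff(names(scores), names(labels))
  keep <- intersect(names(scores), names(labels))
  lab <- labels[keep]
  bad <- !lab %in% c("high", "possible", "conditional", "no")
  if (any(bad)) stop("invalid risk class: ", lab[which(bad)[1]])
  truthUnsafe <- lab != "no"
  predUnsafe <- scores[keep] > threshold
  tp <- sum(predUnsafe & truthUnsafe)
  fp <- sum(predUnsafe & !truthUnsafe)
  tn <- sum(!predUnsafe & !truthUnsafe)
  fn <- sum(!predUnsafe & truthUnsafe)
  list(accuracy = if (length(keep)) (tp + tn) / length(keep) else NA_real_,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
       excluded = excluded)
}

#' Check a drug description against known phenotypic effects
#'
#' Simulates the drug on the baseline model and compares the signed
#' relative change of each named biomarker (vs drug-free) with the
#' expected direction. A discrepancy indicates that an important effect of
#' the drug is missing from its channel-level description. The change in
#' EAD/repolarization-failure status is reported alongside as an
#' arrhythmic-risk phenotype.
#'
#' @param drug A \linkS4class{DrugDescription}.
#' @param expectations data.frame with columns \code{biomarker},
#'   \code{direction} (increase / decrease / no-change), \code{multiple}
#'   and \code{tolerance} (relative band for no-change, and minimum
#'   relative change for increase/decrease; default 0.02).
#' @param params Baseline parameters.
#' @param protocol Pacing protocol (default 1 Hz to quasi-steady state).
#' @param cfg Engine configuration.
#' @param detector Detector configuration.
#' @return data.frame expectations plus \code{observed} (relative change)
#'   and \code{consistent}; attribute \code{abnormality} holds the
#'   drug-free and on-drug abnormality flags per multiple.
#' @export
phenotypeDiscrepancyCheck <- function(drug, expectations,
                                      params = ionicParams(),
                                      protocol = pacingProtocol(1000, 100L, 3L),
                                      cfg = engineConfig(),
                                      detector = detectorConfig()) {
  stopifnot(is(drug, "DrugDescription"))
  if (!nrow(expectations)) {
    out <- cbind(expectations, observed = numeric(0),
                 consistent = logical(0))
    return(out)
  }
  if (!all(c("biomarker", "direction", "multiple") %in% names(expectations)))
    stop("expectations need columns biomarker, direction, multiple")
  if (is.null(expectations$tolerance)) expectations$tolerance <- 0.02
  bad <- !expectations$biomarker %in% .BIOMARKER_NAMES
  if (any(bad))
    stop("unknown biomarker '", expectations$biomarker[which(bad)[1]], "'")
  tr0 <- runPacing(params, protocol, cfg, normalizeTension = FALSE)
  b0 <- computeBiomarkers(tr0)@values
  rep0 <- abnormalityReport(tr0, detector)
  cacheTr <- list()
  getTr <- function(mult) {
    key <- as.character(mult)
    if (is.null(cacheTr[[key]])) {
      pd <- applyDrug(params, drug, mult)
      cacheTr[[key]] <<- runPacing(pd, protocol, cfg,
                                   initState = finalState(tr0),
                                   normalizeTension = FALSE)
    }
    cacheTr[[key]]
  }
  observed <- consistent <- rep(NA_real_, nrow(expectations))
  for (i in seq_len(nrow(expectations))) {
    e <- expectations[i, ]
    bd <- computeBiomarkers(getTr(e$multiple))@values
    rel <- (bd[e$biomarker] - b0[e$biomarker]) / abs(b0[e$biomarker])
    observed[i] <- rel
    consistent[i] <- switch(e$direction,
      increase = isTRUE(rel > e$tolerance),
      decrease = isTRUE(rel < -e$tolerance),
      "no-change" = isTRUE(abs(rel) <= e$tolerance),
      stop("direction must be increase, decrease or no-change"))
  }
  abn <- lapply(unique(expectations$multiple), function(m) {
    r <- abnormalityReport(getTr(m), detector)
    c(multiple = m, baselineAbnormal = rep0@hasEAD || rep0@hasRepolFailure,
      drugAbnormal = r@hasEAD || r@hasRepolFailure)
  })
  out <- cbind(expectations, observed = observed,
               consistent = as.logical(consistent))
  attr(out, "abnormality") <- do.call(rbind, abn)
  out
}
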