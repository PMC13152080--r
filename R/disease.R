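## Disease-variant library (LQTS2, T2D D1-D6) and the population-level
## T2D analyses.

#' Built-in disease-variant library
#'
#' CONTROL is the identity. LQTS2 combines a 70\% I_Kr reduction with an
#' 82\% I_NaL increase. D1-D6 are alternative parameterizations of type 2
#' diabetes ionic remodeling: D1 is the best-estimate combination (I_Kr
#' down, NCX up, I_CaL up, SERCA down), D2 adds CaMKII hyperactivity (with
#' its coupled I_NaL increase), and D3-D6 replace the I_CaL increase by a
#' 20\% reduction, with or without CaMKII and direct I_NaL remodeling.
#' Magnitudes other than the LQTS2 pair are package defaults; every value
#' is user-overridable by constructing variants directly.
#'
#' @return Named list of \linkS4class{DiseaseVariant}s.
#' @export
diseaseVariants <- function() {
  list(
    CONTROL = diseaseVariant("CONTROL", description = "identity"),
    LQTS2 = diseaseVariant("LQTS2", c(g_Kr = 0.30, g_NaL = 1.82),
      "loss-of-function IKr remodeling with late-Na increase"),
    D1 = diseaseVariant("D1",
      c(g_Kr = 0.55, g_NaCa = 1.6, g_CaL = 1.2, j_up = 0.5),
      "best-estimate T2D remodeling"),
    D2 = diseaseVariant("D2",
      c(g_Kr = 0.55, g_NaCa = 1.6, g_CaL = 1.2, j_up = 0.5,
        camkii = 1.5, g_NaL = 1.3),
      "D1 plus CaMKII hyperactivity (coupled I_NaL increase)"),
    D3 = diseaseVariant("D3",
      c(g_Kr = 0.55, g_NaCa = 1.6, g_CaL = 0.8, j_up = 0.5),
      "reduced-I_CaL variant"),
    D4 = diseaseVariant("D4",
      c(g_Kr = 0.55, g_NaCa = 1.6, g_CaL = 0.8, j_up = 0.5,
        camkii = 1.5, g_NaL = 1.3),
      "reduced-I_CaL variant plus CaMKII (coupled I_NaL increase)"),
    D5 = diseaseVariant("D5",
      c(g_Kr = 0.55, g_NaCa = 1.6, g_CaL = 0.8, j_up = 0.5, g_NaL = 1.3),
      "reduced-I_CaL variant plus direct I_NaL remodeling"),
    D6 = diseaseVariant("D6",
      c(g_Kr = 0.55, g_NaCa = 1.6, g_CaL = 0.8, j_up = 0.5, camkii = 1.5),
      "reduced-I_CaL variant plus CaMKII without direct I_NaL"))
}

#' Single remodeling components of the T2D variants
#'
#' Each element isolates one remodeling factor for addition to the control
#' model; the CaMKII component carries its coupled I_NaL increase.
#'
#' @return Named list of \linkS4class{DiseaseVariant}s.
#' @export
t2dComponents <- function() {
  list(
    "IKr_down" = diseaseVariant("IKr_down", c(g_Kr = 0.55)),
    "NCX_up" = diseaseVariant("NCX_up", c(g_NaCa = 1.6)),
    "ICaL_up" = diseaseVariant("ICaL_up", c(g_CaL = 1.2)),
    "ICaL_down" = diseaseVariant("ICaL_down", c(g_CaL = 0.8)),
    "Jup_down" = diseaseVariant("Jup_down", c(j_up = 0.5)),
    "CaMKII" = diseaseVariant("CaMKII", c(camkii = 1.5, g_NaL = 1.3)),
    "INaL_up" = diseaseVariant("INaL_up", c(g_NaL = 1.3)))
}

#' Apply a disease variant to a multiplier set
#'
#' Element-wise multiplication; composable with drugs in either order.
#'
#' @param params An \linkS4class{IonicParams}.
#' @param variant A \linkS4class{DiseaseVariant}.
#' @return A new \linkS4class{IonicParams}.
#' @export
applyVariant <- function(params, variant) {
  stopifnot(is(params, "IonicParams"), is(variant, "DiseaseVariant"))
  validObject(variant)
  m <- multipliers(params)
  for (nm in names(variant@multipliers))
    m[nm] <- m[nm] * variant@multipliers[[nm]]
  ionicParams(.values = m)
}

#' Spearman rank correlation, computed from first principles
#'
#' Rank transform (average ranks for ties) followed by the product-moment
#' correlation of the ranks.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation in [-1, 1]; NA when either vector has no variance.
#' @export
spearmanRho <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) return(NA_real_)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

#' Rank-biserial correlation between two groups
#'
#' \code{2 * P(upper > lower) - 1} with ties counted half, computed by
#' pairwise enumeration; positive when \code{upper} tends to exceed
#' \code{lower}.
#'
#' @param lower,upper Numeric vectors.
#' @return Statistic in [-1, 1].
#' @export
rankBiserial <- function(lower, upper) {
  n1 <- length(lower); n2 <- length(upper)
  if (n1 == 0 || n2 == 0) return(NA_real_)
  wins <- 0
  for (v in upper) wins <- wins + sum(v > lower) + 0.5 * sum(v == lower)
  2 * wins / (n1 * n2) - 1
}

#' T2D population analysis: alternans threshold vs relaxation
#'
#' Applies a disease variant to every accepted model of a calibrated
#' population, computes each model's calcium-transient alternans threshold
#' (longest alternans-positive cycle length) and its tension relaxation
#' time constant at 1 Hz, and returns the per-model table with the
#' Spearman correlation between the two. Models without a threshold in the
#' scanned grid are assigned a sentinel one grid step below the smallest
#' scanned cycle length (ties preserve rank order without inventing
#' magnitudes).
#'
#' @param population A calibrated \linkS4class{PopulationTable}.
#' @param variant Disease variant (default D1).
#' @param clGrid Cycle-length grid for the threshold scan.
#' @param cfg Engine configuration.
#' @param nBeats,assessBeats Per-CL beats and assessed beats.
#' @param tauBeats Beats of the 1 Hz run used for relaxation tau.
#' @return List: \code{table} (model_id, alternans_threshold, found,
#'   relaxation_tau), \code{rho} (Spearman), \code{sentinel}.
#' @export
t2dPopulationAnalysis <- function(population, variant = diseaseVariants()$D1,
                                  clGrid = seq(600, 250, by = -10),
                                  cfg = engineConfig(), nBeats = 30L,
                                  assessBeats = 10L, tauBeats = 30L) {
  acc <- acceptedModels(population)
  parameters <- population@provenance$parameters
  step <- if (length(clGrid) > 1) abs(diff(sort(clGrid)[1:2])) else 10
  sentinel <- min(clGrid) - step
  out <- data.frame(model_id = acc$model_id,
                    alternans_threshold = NA_real_, found = FALSE,
                    relaxation_tau = NA_real_)
  for (i in seq_len(nrow(acc))) {
    params <- applyVariant(.paramsFromRow(acc[i, ], parameters), variant)
    st <- population@states[[as.character(acc$model_id[i])]]
    th <- tryCatch(
      alternansThreshold(params, clGrid, cfg, nBeats, assessBeats,
                         initState = st),
      error = function(e) NULL)
    if (!is.null(th) && th@found) {
      out$alternans_threshold[i] <- th@value
      out$found[i] <- TRUE
    } else {
      out$alternans_threshold[i] <- sentinel
    }
    tb <- tryCatch({
      tr <- runPacing(params, pacingProtocol(1000, tauBeats, 3L), cfg,
                      initState = st, normalizeTension = FALSE)
      computeBiomarkers(tr)@values[["relaxation_tau"]]
    }, error = function(e) NA_real_)
    out$relaxation_tau[i] <- tb
  }
  list(table = out,
       rho = spearmanRho(out$relaxation_tau, out$alternans_threshold),
       sentinel = sentinel)
}

#' Quartile discrimination of parameter scalings by an outcome
#'
#' Splits the models into lower and upper outcome quartiles (group size
#' floor(N/4)) and computes, per sampled parameter, the rank-biserial
#' correlation between the two groups. The ranking is by absolute
#' statistic, descending; ties break by parameter name (stable order).
#'
#' @param table data.frame holding the parameter scaling columns and the
#'   outcome column.
#' @param outcome Name of the numeric outcome column.
#' @param parameters Character vector of parameter column names (default:
#'   all canonical multiplier names present in the table).
#' @return data.frame (parameter, statistic) sorted by |statistic|
#'   descending.
#' @export
quartileDiscrimination <- function(table, outcome,
                                   parameters = intersect(.PARAM_NAMES,
                                                          names(table))) {
  if (!outcome %in% names(table)) stop("no outcome column '", outcome, "'")
  y <- table[[outcome]]
  n <- length(y)
  if (n < 8) stop("need at least 8 models, got ", n)
  if (mean(duplicated(y)) >= 0.5)
    stop("outcome has too many ties (>= 50%)")
  k <- floor(n / 4)
  ord <- order(y)
  loIdx <- ord[seq_len(k)]
  hiIdx <- ord[seq.int(n - k + 1, n)]
  stat <- vapply(parameters, function(p)
    rankBiserial(table[[p]][loIdx], table[[p]][hiIdx]), numeric(1))
  out <- data.frame(parameter = parameters, statistic = unname(stat))
  out <- out[order(-abs(out$statistic), out$parameter), ]
  rownames(out) <- NULL
  out
}

#' EAD vulnerability panel across disease variants and components
#'
#' EAD threshold (largest I_Kr multiplier supporting EAD formation at slow
#' pacing) for the control model, each disease variant, and each single
#' remodeling component added alone to the control model.
#'
#' @param variants Named list of \linkS4class{DiseaseVariant}s.
#' @param components Named list of single-factor variants.
#' @param params Base parameters (default all-ones).
#' @param protocol,cfg,search,detector Passed to \code{\link{eadThreshold}}.
#' @return data.frame: condition, kind (control / variant / component),
#'   value, found.
#' @export
eadVulnerabilityPanel <- function(variants = diseaseVariants()[c("D1", "D2",
                                    "D3", "D4", "D5", "D6")],
                                  components = t2dComponents(),
                                  params = ionicParams(),
                                  protocol = pacingProtocol(4000, 20L, 3L),
                                  cfg = engineConfig(),
                                  search = searchConfig(),
                                  detector = detectorConfig()) {
  th <- function(p) eadThreshold(p, protocol, cfg, search, detector)
  rows <- list()
  r <- th(params)
  rows[[1]] <- data.frame(condition = "CONTROL", kind = "control",
                          value = r@value, found = r@found)
  for (nm in names(variants)) {
    r <- th(applyVariant(params, variants[[nm]]))
    rows[[length(rows) + 1]] <- data.frame(condition = nm, kind = "variant",
                                           value = r@value, found = r@found)
  }
  for (nm in names(components)) {
    r <- th(applyVariant(params, components[[nm]]))
    rows[[length(rows) + 1]] <- data.frame(condition = nm,
                                           kind = "component",
                                           value = r@value, found = r@found)
  }
  do.call(rbind, rows)
}
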