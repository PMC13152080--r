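## Hill channel block, dose-dependent enhancement schedules, and the
## drug-table readers/writers.

#' Hill pore-block multiplier
#'
#' Fraction of conductance remaining under a simple pore block,
#' \code{1 / (1 + (C/IC50)^h)}.
#'
#' @param conc Free drug concentration, uM (>= 0, vectorized).
#' @param ic50 Half-maximal inhibitory concentration, uM (> 0).
#' @param hill Hill coefficient (> 0, default 1).
#' @return Multiplier in (0, 1]; strictly decreasing in \code{conc}.
#' @examples
#' hillMultiplier(0, 13.8)          # 1
#' hillMultiplier(13.8, 13.8)       # 0.5
#' hillMultiplier(12.8, 13.8, 1)    # cilostazol I_Kr at 100x dose
#' @export
hillMultiplier <- function(conc, ic50, hill = 1) {
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("conc must be >= 0")
  if (!is.finite(ic50) || ic50 <= 0) stop("ic50 must be > 0")
  if (!is.finite(hill) || hill <= 0) stop("hill must be > 0")
  1 / (1 + (conc / ic50)^hill)
}

#' Dose-dependent enhancement multiplier
#'
#' Interpolates a schedule of fractional changes (e.g. +0.10 at 10x the
#' therapeutic concentration) log-linearly in the dose multiple. Below the
#' smallest listed multiple the change is interpolated toward 0 at multiple
#' 1 (no drug effect at the anchor); above the largest it is held constant.
#'
#' @param concMultiple Dose as a multiple of the therapeutic concentration
#'   (> 0, vectorized).
#' @param schedule data.frame with strictly increasing \code{multiple} and
#'   fractional \code{change} columns.
#' @return Multiplier \code{1 + change} (> 0).
#' @examples
#' sched <- data.frame(multiple = c(10, 30, 100),
#'                     change = c(0.10, 0.22, 0.40))
#' scaleMultiplier(10, sched)    # 1.10
#' scaleMultiplier(100, sched)   # 1.40
#' @export
scaleMultiplier <- function(concMultiple, schedule) {
  if (!nrow(schedule)) stop("schedule must be nonempty")
  if (any(!is.finite(concMultiple)) || any(concMultiple <= 0))
    stop("concMultiple must be > 0")
  m <- schedule$multiple; ch <- schedule$change
  if (any(diff(m) <= 0)) stop("schedule multiples must be strictly increasing")
  ## anchor the interpolation at (multiple 1, change 0) when the schedule
  ## starts above 1
  if (m[1] > 1) { m <- c(1, m); ch <- c(0, ch) }
  vapply(concMultiple, function(x) {
    if (x <= m[1]) return(1 + ch[1] * if (m[1] > 1) 0 else 1)
    if (x >= m[length(m)]) return(1 + ch[length(ch)])
    1 + approx(log(m), ch, xout = log(x))$y
  }, numeric(1))
}

.effectMultiplier <- function(effect, concMultiple, eftpc) {
  if (effect@mode == "block")
    hillMultiplier(concMultiple * eftpc, effect@ic50, effect@hill)
  else
    scaleMultiplier(concMultiple, effect@schedule)
}

#' Apply a drug to a multiplier set
#'
#' Each affected conductance/flux multiplier is multiplied by its block
#' and/or scale factor at the given concentration; unaffected fields are
#' unchanged. Multiplicative, hence composable with disease variants in
#' either order.
#'
#' @param params An \linkS4class{IonicParams}.
#' @param drug A \linkS4class{DrugDescription}.
#' @param concMultiple Concentration as a multiple of the drug's EFTPC
#'   (0 returns \code{params} unchanged).
#' @return A new \linkS4class{IonicParams}.
#' @export
applyDrug <- function(params, drug, concMultiple) {
  stopifnot(is(params, "IonicParams"), is(drug, "DrugDescription"))
  validObject(drug)
  if (concMultiple == 0) return(params)
  m <- multipliers(params)
  for (e in drug@effects) {
    if (!e@channel %in% names(m))
      stop("unknown channel '", e@channel, "'; allowed: ",
           paste(names(m), collapse = ", "))
    m[e@channel] <- m[e@channel] *
      .effectMultiplier(e, concMultiple, drug@eftpc)
  }
  ionicParams(.values = m)
}

## CSV schema: drug,channel,mode,ic50_uM,hill,schedule_json,eftpc_uM
.DRUG_COLS <- c("drug", "channel", "mode", "ic50_uM", "hill",
                "schedule_json", "eftpc_uM")

#' Write a drug compendium to CSV
#' @param drugs List of \linkS4class{DrugDescription}s.
#' @param file Output path.
#' @export
writeDrugTable <- function(drugs, file) {
  rows <- list()
  for (d in drugs) {
    for (e in d@effects) {
      rows[[length(rows) + 1L]] <- data.frame(
        drug = d@name, channel = e@channel, mode = e@mode,
        ic50_uM = if (e@mode == "block") e@ic50 else NA_real_,
        hill = if (e@mode == "block") e@hill else NA_real_,
        schedule_json = if (e@mode == "scale")
          as.character(jsonlite::toJSON(e@schedule, digits = NA)) else "",
        eftpc_uM = d@eftpc, stringsAsFactors = FALSE)
    }
    if (!length(d@effects))
      rows[[length(rows) + 1L]] <- data.frame(
        drug = d@name, channel = "", mode = "none", ic50_uM = NA_real_,
        hill = NA_real_, schedule_json = "", eftpc_uM = d@eftpc,
        stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    setNames(data.frame(matrix(nrow = 0, ncol = length(.DRUG_COLS))),
             .DRUG_COLS)
  write.csv(tab, file, row.names = FALSE)
  invisible(file)
}

#' Read a drug compendium
#'
#' Accepts the documented CSV schema (columns drug, channel, mode, ic50_uM,
#' hill, schedule_json, eftpc_uM; '#' comment lines tolerated) or a JSON
#' file with the same fields. Validation errors name the offending row and
#' field.
#'
#' @param file Path to a CSV or JSON compendium.
#' @return List of \linkS4class{DrugDescription}s.
#' @export
readDrugTable <- function(file) {
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    tab <- jsonlite::fromJSON(file)
    if (!is.data.frame(tab)) tab <- as.data.frame(tab)
  } else {
    tab <- read.csv(file, comment.char = "#", stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
  }
  if (nrow(tab) == 0) return(list())
  missing <- setdiff(c("drug", "channel", "mode", "eftpc_uM"), names(tab))
  if (length(missing))
    stop("drug table is missing column(s): ", paste(missing, collapse = ", "))
  key <- paste(tab$drug, tab$channel, tab$mode)
  dup <- which(duplicated(key) & tab$mode != "none")
  if (length(dup))
    stop("duplicate (drug, channel, mode) at row ", dup[1], ": ", key[dup[1]])
  out <- list()
  for (nm in unique(tab$drug)) {
    sub <- tab[tab$drug == nm, , drop = FALSE]
    eftpc <- unique(sub$eftpc_uM)
    if (length(eftpc) != 1 || is.na(eftpc) || eftpc <= 0)
      stop("drug '", nm, "': eftpc_uM must be a single positive value")
    effects <- list()
    for (r in seq_len(nrow(sub))) {
      mode <- sub$mode[r]
      if (mode == "none") next
      if (mode == "block") {
        if (is.na(sub$ic50_uM[r]) || sub$ic50_uM[r] <= 0)
          stop("drug '", nm, "' row ", r, ": block requires ic50_uM > 0")
        h <- if ("hill" %in% names(sub) && !is.na(sub$hill[r]))
          sub$hill[r] else 1
        effects[[length(effects) + 1L]] <-
          channelEffect(sub$channel[r], "block", ic50 = sub$ic50_uM[r],
                        hill = h)
      } else if (mode == "scale") {
        sj <- sub$schedule_json[r]
        if (is.na(sj) || !nzchar(sj))
          stop("drug '", nm, "' row ", r, ": scale requires schedule_json")
        sched <- as.data.frame(jsonlite::fromJSON(sj))
        effects[[length(effects) + 1L]] <-
          channelEffect(sub$channel[r], "scale", schedule = sched)
      } else {
        stop("drug '", nm, "' row ", r, ": unknown mode '", mode, "'")
      }
    }
    out[[nm]] <- drugDescription(nm, effects, eftpc)
  }
  unname(out)
}

#' Read / write risk-label tables
#'
#' CSV with columns \code{drug} and \code{risk_class}; classes are the
#' CredibleMeds-style categories high, possible, conditional, no.
#'
#' @param file Path to the label CSV.
#' @return Named character vector of risk classes (names = drugs).
#' @export
readRiskLabels <- function(file) {
  tab <- read.csv(file, comment.char = "#", stringsAsFactors = FALSE,
                  fileEncoding = "UTF-8")
  if (!all(c("drug", "risk_class") %in% names(tab)))
    stop("label file needs columns drug, risk_class")
  bad <- !tab$risk_class %in% c("high", "possible", "conditional", "no")
  if (any(bad))
    stop("invalid risk_class at row ", which(bad)[1], ": ",
         tab$risk_class[which(bad)[1]])
  setNames(tab$risk_class, tab$drug)
}

#' @rdname readRiskLabels
#' @param labels Named character vector of risk classes.
#' @export
writeRiskLabels <- function(labels, file) {
  write.csv(data.frame(drug = names(labels), risk_class = unname(labels)),
            file, row.names = FALSE)
  invisible(file)
}
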