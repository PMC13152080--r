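## Plain-text I/O: traces, populations, configs, run manifests.
## Units are embedded in column headers to prevent silent unit drift.

#' Write a trace to CSV
#'
#' Columns time_ms, V_mV, Cai_uM, tension (plus any recorded currents in
#' uA/uF); cycle length and stimulus times are kept in '#' header comments
#' so the file round-trips.
#'
#' @param trace A \linkS4class{CardiacTrace}.
#' @param file Output path.
#' @export
writeTrace <- function(trace, file) {
  stopifnot(is(trace, "CardiacTrace"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# cycleLength_ms=%g", trace@cycleLength),
               sprintf("# stimTimes_ms=%s",
                       paste(trace@stimTimes, collapse = ";"))), con)
  tab <- data.frame(time_ms = trace@time, V_mV = trace@V,
                    Cai_uM = trace@Cai, tension = trace@tension)
  if (ncol(trace@currents) > 0) {
    cur <- as.data.frame(trace@currents)
    names(cur) <- paste0(names(cur), "_uA_uF")
    tab <- cbind(tab, cur)
  }
  write.csv(tab, con, row.names = FALSE)
  invisible(file)
}

#' Read a trace written by \code{\link{writeTrace}}
#' @param file Path to the CSV.
#' @return A \linkS4class{CardiacTrace}.
#' @export
readTrace <- function(file) {
  hdr <- readLines(file, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  getval <- function(key) {
    line <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(line)) stop("trace file lacks header '", key, "'")
    sub(paste0("^# ", key, "="), "", line[1])
  }
  cl <- as.numeric(getval("cycleLength_ms"))
  stims <- as.numeric(strsplit(getval("stimTimes_ms"), ";")[[1]])
  tab <- read.csv(file, comment.char = "#")
  dt <- tab$time_ms[2] - tab$time_ms[1]
  starts <- as.integer(round((stims - tab$time_ms[1]) / dt)) + 1L
  curcols <- grep("_uA_uF$", names(tab), value = TRUE)
  cur <- if (length(curcols)) {
    m <- as.matrix(tab[curcols])
    colnames(m) <- sub("_uA_uF$", "", curcols)
    m
  } else matrix(numeric(), 0, 0)
  new("CardiacTrace", time = tab$time_ms, V = tab$V_mV, Cai = tab$Cai_uM,
      tension = tab$tension, beatStarts = starts, stimTimes = stims,
      cycleLength = cl, currents = cur, extra = list())
}

#' Write a calibrated population (CSV + JSON sidecar)
#'
#' The CSV holds one row per model (multipliers, biomarkers, acceptance);
#' the sidecar \code{<file>.json} holds the provenance and the cached
#' per-model engine states, so the population round-trips completely in
#' plain text.
#'
#' @param pop A \linkS4class{PopulationTable}.
#' @param file CSV path (sidecar written next to it).
#' @export
writePopulation <- function(pop, file) {
  stopifnot(is(pop, "PopulationTable"))
  write.csv(pop@table, file, row.names = FALSE)
  side <- list(provenance = pop@provenance, states = pop@states)
  jsonlite::write_json(side, paste0(file, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(file)
}

#' Read a population written by \code{\link{writePopulation}}
#' @param file CSV path.
#' @return A \linkS4class{PopulationTable}.
#' @export
readPopulation <- function(file) {
  tab <- read.csv(file, stringsAsFactors = FALSE)
  tab$reason[is.na(tab$reason)] <- ""
  side <- jsonlite::fromJSON(paste0(file, ".json"), simplifyVector = TRUE)
  states <- lapply(side$states, function(s) {
    v <- as.numeric(s); names(v) <- names(defaultState()); v
  })
  prov <- side$provenance
  prov$ranges <- lapply(prov$ranges, as.numeric)
  new("PopulationTable", table = tab, states = states, provenance = prov)
}

#' Write / read an engine configuration as JSON
#' @param cfg Engine configuration list.
#' @param file Path.
#' @export
writeEngineConfig <- function(cfg, file) {
  jsonlite::write_json(cfg, file, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname writeEngineConfig
#' @export
readEngineConfig <- function(file) {
  raw <- jsonlite::fromJSON(file)
  do.call(engineConfig, raw)
}

#' Write / read a disease-variant library as JSON
#' @param variants Named list of \linkS4class{DiseaseVariant}s.
#' @param file Path.
#' @export
writeVariantLibrary <- function(variants, file) {
  out <- lapply(variants, function(v)
    list(multipliers = as.list(v@multipliers), description = v@description))
  jsonlite::write_json(out, file, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname writeVariantLibrary
#' @export
readVariantLibrary <- function(file) {
  raw <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  out <- lapply(names(raw), function(nm)
    diseaseVariant(nm, unlist(raw[[nm]]$multipliers),
                   description = if (is.null(raw[[nm]]$description)) ""
                   else raw[[nm]]$description))
  setNames(out, names(raw))
}

#' Run manifest
#'
#' Records what produced a set of artifacts: the command label, the full
#' configuration snapshot, every seed, and md5 digests of input and output
#' files, so deterministic stages can be reproduced bit-identically.
#'
#' @param command Free-text command label.
#' @param config List of configuration values (engine config, protocol,
#'   schedule, ...).
#' @param seeds Named list/vector of seeds used.
#' @param inputs,outputs Character vectors of file paths (digested).
#' @return Manifest list.
#' @export
runManifest <- function(command, config = list(), seeds = list(),
                        inputs = character(), outputs = character()) {
  digest <- function(files) {
    files <- files[file.exists(files)]
    if (!length(files)) return(list())
    as.list(tools::md5sum(files))
  }
  list(command = command, timestamp = format(Sys.time(), tz = "UTC"),
       config = config, seeds = seeds,
       inputs = digest(inputs), outputs = digest(outputs))
}

#' @rdname runManifest
#' @param manifest Manifest list.
#' @param file Path.
#' @export
writeManifest <- function(manifest, file) {
  jsonlite::write_json(manifest, file, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname runManifest
#' @export
readManifest <- function(file) jsonlite::fromJSON(file)
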