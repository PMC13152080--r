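## Scalar biomarkers from recorded traces.

#' Split a trace into per-beat index ranges
#' @param trace A CardiacTrace.
#' @return List of integer index vectors, one per recorded beat.
#' @export
beatIndices <- function(trace) {
  n <- length(trace@time)
  st <- trace@beatStarts
  if (!length(st)) stop("trace contains no recorded beats")
  en <- c(st[-1] - 1L, n)
  Map(function(a, b) seq.int(a, b), st, en)
}

## APDx for one beat; level = peak - x/100 * (peak - diastolic),
## measured from the time of maximum upstroke velocity.
## Returns NA when the level is never crossed before the beat ends.
.apdOne <- function(t, V, x) {
  dias <- V[1]
  ## no true diastole: the beat started from a non-repolarized membrane,
  ## so the repolarization level is not computable (repolarization failure)
  if (dias > -60) return(NA_real_)
  ipk <- which.max(V)
  dv <- diff(V)
  iup <- which.max(dv[seq_len(max(ipk - 1L, 1L))])
  tup <- t[iup]
  level <- V[ipk] - x / 100 * (V[ipk] - dias)
  seg <- seq.int(ipk, length(V))
  below <- which(V[seg] <= level)
  if (!length(below)) return(NA_real_)
  i2 <- seg[below[1]]
  if (i2 == ipk) return(t[i2] - tup)
  i1 <- i2 - 1L
  ## linear interpolation of the crossing time
  tc <- t[i1] + (t[i2] - t[i1]) * (V[i1] - level) / (V[i1] - V[i2])
  tc - tup
}

.catdOne <- function(t, ca, x) {
  dias <- min(ca[seq_len(max(3L, length(ca) %/% 20))])
  ipk <- which.max(ca)
  amp <- ca[ipk] - dias
  if (amp <= 0) return(NA_real_)
  dca <- diff(ca)
  iup <- which.max(dca[seq_len(max(ipk - 1L, 1L))])
  level <- ca[ipk] - x / 100 * amp
  seg <- seq.int(ipk, length(ca))
  below <- which(ca[seg] <= level)
  if (!length(below)) return(NA_real_)
  t[seg[below[1]]] - t[iup]
}

## Monoexponential-plus-offset fit of the tension decay between 90% and 10%
## of the beat peak. Returns NA when tension is flat or the fit fails.
.tauOne <- function(t, f) {
  ipk <- which.max(f)
  pk <- f[ipk]
  base <- min(f)
  if (pk - base < 1e-6 || pk <= 0) return(NA_real_)
  seg <- seq.int(ipk, length(f))
  y <- f[seg]; tt <- t[seg] - t[ipk]
  lo <- base + 0.1 * (pk - base)
  hi <- base + 0.9 * (pk - base)
  keep <- which(y <= hi & y >= lo)
  if (length(keep) < 8) return(NA_real_)
  keep <- seq.int(keep[1], keep[length(keep)])
  y <- y[keep]; tt <- tt[keep] - tt[keep[1]]
  ## profiled least squares: for fixed tau the model A*exp(-t/tau) + C is
  ## linear in (A, C); optimize the residual sum of squares over log(tau)
  rss <- function(ltau) {
    x <- exp(-tt / exp(ltau))
    fit <- stats::lm.fit(cbind(1, x), y)
    sum(fit$residuals^2)
  }
  opt <- stats::optimize(rss, interval = log(c(0.5, 5000)))
  tau <- exp(opt$minimum)
  ## reject boundary solutions (flat or non-exponential decay)
  if (tau > 4500 || tau < 0.6) return(NA_real_)
  tau
}

#' Compute biomarkers of a recorded trace
#'
#' Action-potential durations (APD40/50/90, from maximum upstroke velocity
#' to the given repolarization fraction of the peak-to-diastolic range),
#' calcium-transient amplitude/diastolic level and durations, peak tension,
#' and the monoexponential time constant of tension relaxation (fit with an
#' offset between 90\% and 10\% of the beat peak). All values are averaged
#' over the recorded beats; per-beat APD90 and CaT amplitudes are kept in
#' the \code{perBeat} slot for the abnormality detectors.
#'
#' @param trace A \linkS4class{CardiacTrace} with at least one complete beat.
#' @return A \linkS4class{BiomarkerSet}.
#' @export
computeBiomarkers <- function(trace) {
  stopifnot(is(trace, "CardiacTrace"))
  idx <- beatIndices(trace)
  nb <- length(idx)
  perApd90 <- perApd50 <- perApd40 <- numeric(nb)
  perAmp <- perDias <- perCatd50 <- perCatd90 <- numeric(nb)
  perPk <- perTau <- numeric(nb)
  for (b in seq_len(nb)) {
    ii <- idx[[b]]
    t <- trace@time[ii]; V <- trace@V[ii]; ca <- trace@Cai[ii]
    f <- trace@tension[ii]
    perApd40[b] <- .apdOne(t, V, 40)
    perApd50[b] <- .apdOne(t, V, 50)
    perApd90[b] <- .apdOne(t, V, 90)
    dias <- min(ca[seq_len(max(3L, length(ca) %/% 20))])
    perDias[b] <- dias
    perAmp[b] <- max(ca) - dias
    perCatd50[b] <- .catdOne(t, ca, 50)
    perCatd90[b] <- .catdOne(t, ca, 90)
    perPk[b] <- max(f)
    perTau[b] <- .tauOne(t, f)
  }
  avg <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  vals <- c(APD40 = avg(perApd40), APD50 = avg(perApd50),
            APD90 = avg(perApd90), CaT_amplitude = avg(perAmp),
            CaT_diastolic = avg(perDias), CaTD50 = avg(perCatd50),
            CaTD90 = avg(perCatd90), peak_tension = avg(perPk),
            relaxation_tau = avg(perTau))
  ## enforce the APD ordering against averaging/interpolation jitter
  if (!is.na(vals["APD50"]) && !is.na(vals["APD40"]))
    vals["APD50"] <- max(vals["APD50"], vals["APD40"])
  if (!is.na(vals["APD90"]) && !is.na(vals["APD50"]))
    vals["APD90"] <- max(vals["APD90"], vals["APD50"])
  und <- is.na(vals)
  names(und) <- names(vals)
  new("BiomarkerSet", values = vals, undefined = und,
      perBeat = list(APD90 = perApd90, CaT_amplitude = perAmp,
                     peak_tension = perPk, relaxation_tau = perTau))
}
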