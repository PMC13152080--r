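## Shared, lazily built fixtures (engine runs are deterministic, so these
## are safe to reuse across test files).

.testCache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.testCache[[key]])) assign(key, force(expr), envir = .testCache)
  .testCache[[key]]
}

## reference calibrated population: 50 sampled models, shortened
## quasi-steady-state runs (the vignette documents the problem sizes)
sharedPopulation <- function() memo("pop50", {
  pop <- samplePopulation(samplingSpec(seed = 42L), 50)
  calibratePopulation(pop, protocol = pacingProtocol(1000, 80L, 3L))
})

trialProtocol <- function() pacingProtocol(2000, 12L, 4L)

cheapSearch <- function(resolution = 0.02)
  searchConfig(resolution = resolution, nBeats = 10L, warmBeats = 15L)

## manual square-wave trace: diastole at rest, instant rise/fall plateau
squareTrace <- function(width = 300, cl = 1000, rest = -85, top = 20,
                        beats = 2L, dt = 0.1) {
  n <- round(cl / dt)
  tb <- (seq_len(n) - 1) * dt
  v <- ifelse(tb >= 2 & tb < 2 + width, top, rest)
  ca <- ifelse(tb >= 2 & tb < 2 + width, 0.5, 0.07)
  V <- rep(v, beats); Cai <- rep(ca, beats)
  new("CardiacTrace", time = (seq_len(n * beats) - 1) * dt, V = V,
      Cai = Cai, tension = rep(0, n * beats),
      beatStarts = as.integer((seq_len(beats) - 1) * n + 1),
      stimTimes = (seq_len(beats) - 1) * cl, cycleLength = cl,
      currents = matrix(numeric(), 0, 0), extra = list())
}
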