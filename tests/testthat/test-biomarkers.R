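test_that("a square action potential gives APD40 = APD50 = APD90 = width", {
  tr <- squareTrace(width = 300)
  b <- computeBiomarkers(tr)
  expect_equal(biomarker(b, "APD40"), 300, tolerance = 0.3)
  expect_equal(biomarker(b, "APD50"), 300, tolerance = 0.3)
  expect_equal(biomarker(b, "APD90"), 300, tolerance = 0.3)
})

test_that("relaxation tau recovers the constructed exponential constant", {
  ## tension built from the closed form being fit (A*exp(-(t-tpk)/120))
  tr <- makeSyntheticTrace(traceSpec(beats = 3L, tensionTau = 120,
                                     jitterAmp = 0))
  b <- computeBiomarkers(tr)
  expect_equal(biomarker(b, "relaxation_tau"), 120, tolerance = 1)
})

test_that("APD90 is flagged undefined when repolarization never completes", {
  tr <- makeSyntheticTrace(traceSpec(beats = 2L, repolFailBeats = 2L,
                                     jitterAmp = 0))
  b <- computeBiomarkers(tr)
  expect_true(is.na(b@perBeat$APD90[2]))
  expect_false(is.na(b@perBeat$APD90[1]))
})

test_that("CaT metrics are internally consistent on engine output", {
  tr <- runPacing(ionicParams(), pacingProtocol(1000, 60L, 3L),
                  normalizeTension = FALSE)
  b <- computeBiomarkers(tr)
  v <- biomarker(b)
  expect_true(v["APD40"] <= v["APD50"] && v["APD50"] <= v["APD90"])
  expect_gt(v["CaT_amplitude"], 0)
  expect_lt(v["CaTD50"], v["CaTD90"])
  expect_gt(v["relaxation_tau"], 0)
})

test_that("computeBiomarkers refuses traces without beats", {
  tr <- squareTrace(beats = 1L)
  tr@beatStarts <- integer(0)
  expect_error(computeBiomarkers(tr), "no recorded beats")
})
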