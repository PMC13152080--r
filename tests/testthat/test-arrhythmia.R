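test_that("a monotonically repolarizing synthetic AP yields no events", {
  tr <- makeSyntheticTrace(traceSpec(beats = 3L))
  expect_identical(nrow(detectEADs(tr)), 0L)
  expect_false(as.logical(detectRepolarizationFailure(tr)))
})

test_that("implanted EADs are recovered with their construction takeoff", {
  sp <- traceSpec(beats = 3L,
                  eads = data.frame(beat = 2, takeoff = -25, amplitude = 8,
                                    width = 10))
  tr <- makeSyntheticTrace(sp)
  ev <- detectEADs(tr)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$beat, 2L)
  ann <- tr@extra$annotation$eads
  expect_equal(ev$takeoff, ann$takeoff, tolerance = 1)
  expect_equal(ev$takeoff, -25, tolerance = 1)
  expect_gte(ev$amplitude, 2)
})

test_that("a sub-threshold bump is not reported", {
  sp <- traceSpec(beats = 2L,
                  eads = data.frame(beat = 2, takeoff = -25, amplitude = 1,
                                    width = 10))
  tr <- makeSyntheticTrace(sp)
  expect_identical(nrow(detectEADs(tr)), 0L)
})

test_that("diastolic events below the takeoff floor are excluded", {
  sp <- traceSpec(beats = 2L,
                  eads = data.frame(beat = 2, takeoff = -70, amplitude = 8,
                                    width = 10))
  tr <- makeSyntheticTrace(sp)
  expect_identical(nrow(detectEADs(tr)), 0L)
})

test_that("repolarization failure is flagged with the failing beat", {
  tr <- makeSyntheticTrace(traceSpec(beats = 3L, repolFailBeats = 3L,
                                     jitterAmp = 0))
  rf <- detectRepolarizationFailure(tr)
  expect_true(as.logical(rf))
  expect_identical(attr(rf, "failingBeats"), 3L)
  rep <- abnormalityReport(tr)
  expect_true(rep@hasRepolFailure)
  ## invariant: failure implies at least one APD90-undefined beat
  expect_true(any(rep@apd90Undefined))
})

test_that("a fully failed paced steady state is still recognized", {
  tr <- runPacing(ionicParams(g_Kr = 0, g_Ks = 0),
                  pacingProtocol(1000, 30L, 3L), normalizeTension = FALSE)
  expect_true(as.logical(detectRepolarizationFailure(tr)))
})

test_that("alternans magnitude arithmetic matches direct computation", {
  r <- detectAlternans(rep(c(1, 0.8), 5))
  expect_true(r@present)
  expect_equal(r@magnitude, 0.2 / 0.9, tolerance = 1e-12)
  r2 <- detectAlternans(rep(c(1, 0.99), 5))
  expect_false(r2@present)
  expect_equal(r2@magnitude, 0.01 / 0.995, tolerance = 1e-12)
  expect_false(detectAlternans(rep(1, 8))@present)
  expect_identical(detectAlternans(rep(1, 8))@magnitude, 0)
  ## monotone drift is not alternans even when large
  expect_false(detectAlternans(seq(1, 2, length.out = 8))@present)
  expect_error(detectAlternans(c(1, 0.8, 1)), "at least 6")
})

test_that("EAD threshold saturates and reports not-found correctly", {
  ## LQTS2-like remodeling shows EADs at the upper bound of a narrow range
  lq <- applyVariant(ionicParams(), diseaseVariants()$LQTS2)
  sat <- eadThreshold(lq, search = searchConfig(range = c(0, 0.2),
                                                resolution = 0.05,
                                                nBeats = 8L, warmBeats = 10L))
  expect_true(sat@found)
  expect_equal(sat@value, 0.2)
  ## baseline never fires in a high multiplier range
  nf <- eadThreshold(ionicParams(),
                     search = searchConfig(range = c(0.8, 1),
                                           resolution = 0.05,
                                           nBeats = 8L, warmBeats = 10L))
  expect_false(nf@found)
})

test_that("alternans threshold value is always a grid member", {
  grid <- seq(400, 150, by = -10)
  th <- alternansThreshold(ionicParams(), grid, nBeats = 25L)
  expect_true(th@found)
  expect_true(th@value %in% grid)
})

test_that("knockout analysis refuses single-effect drugs", {
  d <- drugDescription("x", list(channelEffect("g_Kr", "block", ic50 = 1)),
                       eftpc = 1)
  expect_error(knockoutAnalysis(ionicParams(), d, 10), ">= 2 channel effects")
})
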