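test_that("parameter sets validate and default to the identity", {
  p <- ionicParams()
  expect_equal(unname(multipliers(p)[["g_Kr"]]), 1)
  expect_equal(unname(multipliers(p)[["g_Nav18"]]), 0)
  expect_error(ionicParams(g_Kx = 2), "unknown parameter")
  expect_error(ionicParams(g_Kr = -1), "must be >= 0")
})

test_that("pacing protocols validate their invariants", {
  expect_error(pacingProtocol(-1), "cycleLength")
  expect_error(pacingProtocol(1000, 10L, 20L), "recordLastN")
  expect_error(pacingProtocol(100, 5L, 1L, stimDuration = 200),
               "stimDuration")
})

test_that("two identical runs produce identical traces", {
  pr <- pacingProtocol(1000, 20L, 2L)
  t1 <- runPacing(ionicParams(), pr, normalizeTension = FALSE)
  t2 <- runPacing(ionicParams(), pr, normalizeTension = FALSE)
  expect_identical(t1@V, t2@V)
  expect_identical(t1@Cai, t2@Cai)
})

test_that("the explicit all-default multiplier set reproduces baseline", {
  pr <- pacingProtocol(1000, 15L, 2L)
  m <- setNames(rep(1, 14), names(multipliers(ionicParams())))
  m["g_Nav18"] <- 0
  t1 <- runPacing(ionicParams(), pr, normalizeTension = FALSE)
  t2 <- runPacing(ionicParams(.values = m), pr, normalizeTension = FALSE)
  expect_identical(t1@V, t2@V)
})

test_that("a run restarted from its final state continues seamlessly", {
  pr1 <- pacingProtocol(1000, 60L, 1L)
  pr2 <- pacingProtocol(1000, 120L, 1L)
  a <- runPacing(ionicParams(), pr1, normalizeTension = FALSE)
  b <- runPacing(ionicParams(), pr1, initState = finalState(a),
                 normalizeTension = FALSE)
  cont <- runPacing(ionicParams(), pr2, normalizeTension = FALSE)
  expect_equal(b@V, cont@V, tolerance = 1e-12)
})

test_that("gates stay bounded and concentrations positive in the output", {
  tr <- runPacing(ionicParams(g_Kr = 0.3, g_NaL = 1.82),
                  pacingProtocol(1000, 20L, 3L), normalizeTension = FALSE)
  st <- finalState(tr)
  gates <- st[c("m", "h", "j", "hL", "d", "f", "fca", "r", "s",
                "xr1", "xr2", "xs", "Rbar", "m18", "h18", "grel")]
  expect_true(all(gates >= 0 & gates <= 1))
  expect_true(all(tr@Cai > 0))
  expect_true(all(tr@extra$CaSR > 0))
})

test_that("Nav1.8 current obeys its closed-form limits", {
  expect_equal(nav18Current(-30, params = ionicParams()), 0)
  cfg <- engineConfig()
  ena <- cfg$rtf * log(cfg$Nao / 9)
  p <- ionicParams(g_Nav18 = 0.05)
  expect_equal(nav18Current(ena, params = p, cfg = cfg), 0, tolerance = 1e-9)
  ## right-shifted gating: larger steady-state window than Nav1.5 at -30 mV
  expect_gt(nav18SteadyState(-30, cfg)$window, nav15SteadyState(-30)$window)
})

test_that("Nav1.8 fraction calibration hits its target peak ratio", {
  cfg <- engineConfig()
  expect_equal(calibrateNav18Fraction(0, cfg = cfg), 0)
  expect_error(calibrateNav18Fraction(0.5, cfg = cfg), "0 <= f < 0.1")
  pr <- pacingProtocol(1000, 40L, 2L)
  g <- calibrateNav18Fraction(0.003, protocol = pr, cfg = cfg)
  expect_gt(g, 0)
  base <- runPacing(ionicParams(), pr, cfg, normalizeTension = FALSE)
  withg <- runPacing(ionicParams(g_Nav18 = g),
                     pacingProtocol(1000, 20L, 2L), cfg,
                     initState = finalState(base), normalizeTension = FALSE)
  achieved <- withg@extra$maxAbsINav18 / base@extra$maxAbsINa
  expect_equal(achieved, 0.003, tolerance = 0.05)
  ## a small Nav1.8 current prolongs the action potential
  b0 <- biomarker(computeBiomarkers(base), "APD90")
  b1 <- biomarker(computeBiomarkers(
    runPacing(ionicParams(g_Nav18 = g), pacingProtocol(1000, 40L, 2L), cfg,
              normalizeTension = FALSE)), "APD90")
  expect_gt(b1, b0)
})

test_that("tension is normalized to the reference baseline peak", {
  cfg <- engineConfig()
  tr <- runPacing(ionicParams(), pacingProtocol(1000, 100L, 2L), cfg,
                  normalizeTension = TRUE)
  expect_equal(max(tr@tension), 1, tolerance = 0.02)
})
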