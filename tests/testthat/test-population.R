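test_that("sampling handles the degenerate cases", {
  spec <- samplingSpec(seed = 3L)
  expect_identical(nrow(samplePopulation(spec, 0)), 0L)
  d <- samplePopulation(samplingSpec(range = c(1, 1), seed = 5L), 7)
  expect_true(all(abs(as.matrix(d[-1]) - 1) < 1e-12))
  expect_error(samplingSpec(range = c(0, 2)), "> 0")
})

test_that("each parameter occupies every Latin-hypercube stratum once", {
  N <- 64
  spec <- samplingSpec(seed = 9L)
  d <- samplePopulation(spec, N)
  for (p in spec@parameters) {
    u <- (log(d[[p]]) - log(spec@lower[[p]])) /
      (log(spec@upper[[p]]) - log(spec@lower[[p]]))
    strata <- floor(u * N)
    expect_identical(as.integer(sort(strata)), 0:(N - 1))
  }
})

test_that("sampling is reproducible from the seed", {
  a <- samplePopulation(samplingSpec(seed = 11L), 20)
  b <- samplePopulation(samplingSpec(seed = 11L), 20)
  expect_identical(a, b)
  c2 <- samplePopulation(samplingSpec(seed = 12L), 20)
  expect_false(identical(a, c2))
})

test_that("acceptance equals exact set arithmetic on known biomarkers", {
  ## set-membership oracle on the shared calibrated population
  cal <- sharedPopulation()
  tab <- cal@table
  rg <- cal@provenance$ranges
  solverOK <- !tab$reason %in% c("integration_failure", "apd90_undefined",
                                 "baseline_abnormality")
  manual <- solverOK
  for (nm in names(rg))
    manual <- manual & !is.na(tab[[nm]]) &
      tab[[nm]] >= rg[[nm]][1] & tab[[nm]] <= rg[[nm]][2]
  expect_identical(unname(tab$accepted), unname(manual))
})

test_that("widening any range never removes an accepted model", {
  cal <- sharedPopulation()
  tab <- cal@table
  rgWide <- calibrationRanges(APD90 = c(100, 600),
                              CaT_amplitude = c(0.01, 10),
                              CaT_diastolic = c(0.001, 1),
                              peak_tension = c(0.01, 50),
                              relaxation_tau = c(1, 2000))
  inWide <- !tab$reason %in% c("integration_failure", "apd90_undefined",
                               "baseline_abnormality")
  for (nm in names(rgWide))
    inWide <- inWide & !is.na(tab[[nm]]) &
      tab[[nm]] >= rgWide[[nm]][1] & tab[[nm]] <= rgWide[[nm]][2]
  expect_true(all(tab$accepted <= inWide))
})

test_that("an impossible range accepts nothing", {
  pop <- samplePopulation(samplingSpec(seed = 2L), 3)
  cal <- calibratePopulation(pop, calibrationRanges(APD90 = c(0, 1)),
                             protocol = pacingProtocol(1000, 20L, 3L),
                             screenProtocol = NULL)
  expect_identical(sum(cal@table$accepted), 0L)
  expect_true(all(grepl("out_of_range|integration|apd90",
                        cal@table$reason)))
})

test_that("the default calibration is informative on the reference engine", {
  cal <- sharedPopulation()
  frac <- mean(cal@table$accepted)
  expect_gt(frac, 0)
  expect_lt(frac, 1)
})
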