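test_that("Hill multiplier closed forms and properties hold", {
  expect_identical(hillMultiplier(0, 13.8, 2), 1)
  expect_identical(hillMultiplier(5, 5, 3.7), 0.5)
  ## cilostazol I_Kr at the 100x dose
  expect_equal(hillMultiplier(12.8, 13.8, 1), 1 / (1 + 12.8 / 13.8),
               tolerance = 1e-12)
  expect_equal(round(hillMultiplier(12.8, 13.8, 1), 4), 0.5188)
  expect_error(hillMultiplier(-1, 1), ">= 0")
  expect_error(hillMultiplier(1, 0), "> 0")
  ## monotone decreasing and scale invariant
  cc <- seq(0, 50, by = 0.5)
  expect_true(all(diff(hillMultiplier(cc, 7, 1.3)) < 0))
  expect_equal(hillMultiplier(3, 7, 2), hillMultiplier(30, 70, 2),
               tolerance = 1e-14)
  expect_lt(hillMultiplier(1e6, 1, 1), 1e-5)
})

test_that("enhancement schedules interpolate log-linearly with the declared
          extrapolation rules", {
  sched <- data.frame(multiple = c(10, 30, 100), change = c(0.10, 0.22, 0.40))
  expect_equal(scaleMultiplier(10, sched), 1.10)
  expect_equal(scaleMultiplier(30, sched), 1.22)
  expect_equal(scaleMultiplier(100, sched), 1.40)
  expect_equal(scaleMultiplier(1000, sched), 1.40) # constant above range
  expect_equal(scaleMultiplier(1, sched), 1)       # anchored at 1x
  ## between 1x and 10x: log-linear toward no effect
  expect_equal(scaleMultiplier(sqrt(10), sched), 1.05, tolerance = 1e-9)
  expect_error(scaleMultiplier(0, sched), "> 0")
  expect_error(scaleMultiplier(10, sched[0, ]), "nonempty")
})

test_that("applyDrug composes block and scale effects multiplicatively", {
  fx <- makeReferenceFixtures()
  p <- ionicParams()
  expect_identical(multipliers(applyDrug(p, fx$drugs$cilostazol_enh, 0)),
                   multipliers(p))
  ## a pure I_Kr blocker at its IC50 halves g_Kr and touches nothing else
  d <- drugDescription("x", list(channelEffect("g_Kr", "block", ic50 = 4)),
                       eftpc = 4)
  m <- multipliers(applyDrug(p, d, 1))
  expect_equal(unname(m[["g_Kr"]]), 0.5)
  expect_identical(m[setdiff(names(m), "g_Kr")],
                   multipliers(p)[setdiff(names(m), "g_Kr")])
  ## cilostazol at 100x: block-only vs block + enhancement on g_CaL
  mb <- multipliers(applyDrug(p, fx$drugs$cilostazol_block, 100))
  me <- multipliers(applyDrug(p, fx$drugs$cilostazol_enh, 100))
  blockFactor <- 1 / (1 + 12.8 / 91.2)
  expect_equal(unname(mb[["g_CaL"]]), blockFactor, tolerance = 1e-12)
  expect_equal(unname(me[["g_CaL"]]), blockFactor * 1.40, tolerance = 1e-12)
  ## element-wise block multipliers shrink with concentration
  m1 <- multipliers(applyDrug(p, fx$drugs$mexiletine_crumb, 1))
  m2 <- multipliers(applyDrug(p, fx$drugs$mexiletine_crumb, 30))
  expect_true(all(m2 <= m1 + 1e-12))
})

test_that("drug and variant application commute", {
  fx <- makeReferenceFixtures()
  lq <- diseaseVariants()$LQTS2
  a <- applyVariant(applyDrug(ionicParams(), fx$drugs$mexiletine_crumb, 10),
                    lq)
  b <- applyDrug(applyVariant(ionicParams(), lq),
                 fx$drugs$mexiletine_crumb, 10)
  expect_equal(multipliers(a), multipliers(b), tolerance = 1e-14)
})

test_that("drug tables round-trip through CSV field by field", {
  fx <- makeReferenceFixtures()
  f <- withr::local_tempfile(fileext = ".csv")
  writeDrugTable(fx$drugs, f)
  back <- readDrugTable(f)
  expect_length(back, length(fx$drugs))
  orig <- unname(fx$drugs)
  for (i in seq_along(orig)) {
    expect_identical(back[[i]]@name, orig[[i]]@name)
    expect_equal(back[[i]]@eftpc, orig[[i]]@eftpc)
    expect_length(back[[i]]@effects, length(orig[[i]]@effects))
    for (j in seq_along(orig[[i]]@effects)) {
      eo <- orig[[i]]@effects[[j]]; eb <- back[[i]]@effects[[j]]
      expect_identical(eb@channel, eo@channel)
      expect_identical(eb@mode, eo@mode)
      if (eo@mode == "block") {
        expect_equal(eb@ic50, eo@ic50)
        expect_equal(eb@hill, eo@hill)
      } else {
        expect_equal(eb@schedule$multiple, eo@schedule$multiple)
        expect_equal(eb@schedule$change, eo@schedule$change)
      }
    }
  }
})

test_that("reader errors name the offending row and field", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("drug,channel,mode,ic50_uM,hill,schedule_json,eftpc_uM",
               "a,g_Kr,block,10,1,,1",
               "a,g_Kr,block,20,1,,1"), f)
  expect_error(readDrugTable(f), "duplicate")
  writeLines(c("drug,channel,mode,ic50_uM,hill,schedule_json,eftpc_uM",
               "a,g_Kr,block,10,1,,NA"), f)
  expect_error(readDrugTable(f), "eftpc")
  ## empty table reads as an empty list
  writeLines("drug,channel,mode,ic50_uM,hill,schedule_json,eftpc_uM", f)
  expect_length(readDrugTable(f), 0)
})

test_that("risk labels validate their categories", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeRiskLabels(c(a = "high", b = "no"), f)
  expect_identical(readRiskLabels(f), c(a = "high", b = "no"))
  writeLines(c("drug,risk_class", "a,terrible"), f)
  expect_error(readRiskLabels(f), "invalid risk_class")
})
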