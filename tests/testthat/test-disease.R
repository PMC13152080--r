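test_that("variant application is element-wise and CONTROL is the identity", {
  v <- diseaseVariants()
  p <- ionicParams()
  expect_identical(multipliers(applyVariant(p, v$CONTROL)), multipliers(p))
  lq <- multipliers(applyVariant(p, v$LQTS2))
  expect_equal(unname(lq[["g_Kr"]]), 0.30)
  expect_equal(unname(lq[["g_NaL"]]), 1.82)
  expect_identical(lq[setdiff(names(lq), c("g_Kr", "g_NaL"))],
                   multipliers(p)[setdiff(names(lq), c("g_Kr", "g_NaL"))])
  d3 <- multipliers(applyVariant(p, v$D3))
  expect_equal(unname(d3[["g_CaL"]]), 0.8)
})

test_that("the CaMKII component carries its coupled late-Na increase", {
  comp <- t2dComponents()$CaMKII
  m <- multipliers(applyVariant(ionicParams(), comp))
  expect_gt(m[["camkii"]], 1)
  expect_gt(m[["g_NaL"]], 1)
})

test_that("Spearman rho from first principles matches known cases", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  ## strictly increasing function: perfect rank correlation
  expect_equal(spearmanRho(x, exp(x)), 1)
  expect_equal(spearmanRho(x, -x^3), -1)
  ## cross-check against the reference implementation, with ties
  set.seed(5)
  a <- sample(1:8, 40, replace = TRUE)
  b <- a + rnorm(40)
  expect_equal(spearmanRho(a, b),
               unname(cor(a, b, method = "spearman")), tolerance = 1e-12)
  ## zero variance is undefined
  expect_true(is.na(spearmanRho(rep(1, 10), 1:10)))
})

test_that("rank-biserial matches the Mann-Whitney U statistic", {
  set.seed(8)
  lo <- rnorm(15); hi <- rnorm(20, 0.5)
  w <- suppressWarnings(wilcox.test(hi, lo))
  u <- unname(w$statistic)
  expect_equal(rankBiserial(lo, hi), 2 * u / (15 * 20) - 1,
               tolerance = 1e-12)
})

test_that("quartile discrimination recovers a constructed j_up dependence", {
  pop <- samplePopulation(samplingSpec(seed = 21L), 200)
  set.seed(22)
  pop$outcome <- -pop$j_up + rnorm(200, 0, 0.05)
  qd <- quartileDiscrimination(pop, "outcome")
  expect_identical(qd$parameter[1], "j_up")
  expect_gt(abs(qd$statistic[1]), 0.8)
})

test_that("two parameters with equal constructed effect land on top, ties
          ordered by name", {
  pop <- samplePopulation(samplingSpec(seed = 23L), 200)
  pop$outcome <- log(pop$g_Kr) + log(pop$j_up)
  qd <- quartileDiscrimination(pop, "outcome")
  expect_setequal(qd$parameter[1:2], c("g_Kr", "j_up"))
  ## deterministic tie order: exact ties sort alphabetically
  same <- abs(qd$statistic[1]) == abs(qd$statistic[2])
  if (same) expect_identical(qd$parameter[1:2], c("g_Kr", "j_up"))
})

test_that("quartile discrimination validates its inputs", {
  pop <- samplePopulation(samplingSpec(seed = 1L), 6)
  pop$outcome <- rnorm(6)
  expect_error(quartileDiscrimination(pop, "outcome"), "at least 8")
  pop2 <- samplePopulation(samplingSpec(seed = 1L), 20)
  pop2$outcome <- rep(1, 20)
  expect_error(quartileDiscrimination(pop2, "outcome"), "ties")
  expect_error(quartileDiscrimination(pop2, "missing"), "no outcome column")
})

test_that("null outcomes rarely produce large discrimination statistics", {
  ## frozen from a direct Monte-Carlo of the null at N=200 (group size 50,
  ## sd of the rank-biserial ~ 0.116, 12 parameters)
  n30 <- 0; n35 <- 0
  for (s in 1:60) {
    pop <- samplePopulation(samplingSpec(seed = 3000L + s), 200)
    set.seed(4000L + s)
    pop$outcome <- rnorm(200)
    mx <- max(abs(quartileDiscrimination(pop, "outcome")$statistic))
    if (mx < 0.30) n30 <- n30 + 1
    if (mx < 0.35) n35 <- n35 + 1
  }
  expect_gte(n30 / 60, 0.80)
  expect_gte(n35 / 60, 0.95)
})
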