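test_that("risk-score arithmetic matches direct computation", {
  expect_identical(tdpRiskScore(rep(0, 4), c(1, 10, 30, 100))@score, 0)
  expect_equal(tdpRiskScore(rep(1, 4), c(1, 10, 30, 100))@score, 1,
               tolerance = 1e-12)
  worked <- (0.5 / 100) / (1 + 1 / 10 + 1 / 30 + 1 / 100)
  expect_equal(tdpRiskScore(c(0, 0, 0, 0.5), c(1, 10, 30, 100))@score,
               worked, tolerance = 1e-12)
  expect_equal(round(worked, 6), 0.004373)
  expect_error(tdpRiskScore(numeric(), numeric()), "empty")
  expect_error(tdpRiskScore(c(0.5), c(-1)), "positive")
  expect_error(tdpRiskScore(c(2), c(1)), "\\[0, 1\\]")
})

test_that("the score is monotone in every fraction", {
  set.seed(77)
  for (i in 1:200) {
    k <- sample(2:6, 1)
    mult <- sort(10^runif(k, 0, 2.5))
    f <- runif(k)
    s0 <- tdpRiskScore(f, mult)@score
    j <- sample(k, 1)
    f2 <- f; f2[j] <- min(1, f[j] + runif(1, 0, 1 - f[j]))
    expect_gte(tdpRiskScore(f2, mult)@score, s0)
    ## adding a higher concentration with zero abnormality never raises it
    s1 <- tdpRiskScore(c(f, 0), c(mult, max(mult) * 10))@score
    expect_lte(s1, s0 + 1e-12)
  }
})

test_that("classification metrics agree with planted confusion counts", {
  ## 60 synthetic drugs with TP=31, FN=8, TN=21, FP=0
  labels <- c(rep("high", 20), rep("possible", 10), rep("conditional", 9),
              rep("no", 21))
  names(labels) <- sprintf("d%02d", 1:60)
  scores <- c(rep(0.5, 31), rep(0, 8), rep(0, 21))
  names(scores) <- names(labels)
  m <- classifyAndScore(scores, labels)
  expect_identical(unname(m$counts), c(31L, 0L, 21L, 8L))
  expect_equal(m$accuracy, 52 / 60, tolerance = 1e-12)
  expect_equal(round(m$accuracy, 3), 0.867)
  expect_equal(m$sensitivity, 31 / 39, tolerance = 1e-12)
  expect_equal(round(m$sensitivity, 3), 0.795)
  expect_identical(m$specificity, 1)
  ## perfect predictions
  p <- classifyAndScore(setNames(c(1, 0), c("a", "b")),
                        c(a = "high", b = "no"))
  expect_identical(c(p$accuracy, p$sensitivity, p$specificity), c(1, 1, 1))
  ## saturating threshold classifies everything safe
  s <- classifyAndScore(scores, labels, threshold = 1)
  expect_identical(s$sensitivity, 0)
  expect_identical(s$specificity, 1)
  ## unlabeled drugs are excluded and reported
  e <- classifyAndScore(setNames(c(1, 0), c("a", "zzz")), c(a = "high"))
  expect_identical(e$excluded, "zzz")
})

test_that("a null drug produces zero abnormal models on the population", {
  cal <- sharedPopulation()
  nd <- drugDescription("null", list(), eftpc = 1)
  tr <- runDrugTrial(cal, nd, protocol = trialProtocol())
  expect_identical(sum(tr@counts$nAbnormal), 0L)
  expect_identical(sum(tr@counts$nUndetermined), 0L)
  expect_true(all(tr@counts$nModels == nrow(acceptedModels(cal))))
})

test_that("trial output is deterministic across reruns", {
  cal <- sharedPopulation()
  fx <- makeReferenceFixtures()
  a <- runDrugTrial(cal, fx$drugs$cilostazol_block,
                    protocol = trialProtocol())
  b <- runDrugTrial(cal, fx$drugs$cilostazol_block,
                    protocol = trialProtocol())
  expect_identical(a@counts, b@counts)
  expect_identical(a@perModel, b@perModel)
})

test_that("an overwhelming hERG blocker reproduces per-model outcomes", {
  ## ic50 = eftpc/100: at 100x the remaining g_Kr is ~1e-4 of baseline
  cal <- sharedPopulation()
  d <- drugDescription("sledgehammer",
                       list(channelEffect("g_Kr", "block", ic50 = 0.01)),
                       eftpc = 1)
  tr <- runDrugTrial(cal, d, multiples = c(1, 100),
                     protocol = trialProtocol())
  ## per-model oracle at the top concentration
  acc <- acceptedModels(cal)
  oracle <- logical(nrow(acc))
  pars <- cal@provenance$parameters
  for (i in seq_len(nrow(acc))) {
    v <- as.numeric(acc[i, pars]); names(v) <- pars
    pd <- applyDrug(ionicParams(.values = v), d, 100)
    t2 <- tryCatch(runPacing(pd, trialProtocol(),
                             initState = cal@states[[as.character(
                               acc$model_id[i])]],
                             normalizeTension = FALSE),
                   error = function(e) NULL)
    oracle[i] <- if (is.null(t2)) NA else {
      r <- abnormalityReport(t2)
      r@hasEAD || r@hasRepolFailure
    }
  }
  expect_identical(unname(tr@perModel[, "100"]), oracle)
  expect_gt(tr@counts$fraction[tr@counts$multiple == 100], 0)
})

test_that("phenotype discrepancy check separates the lidocaine descriptions", {
  fx <- makeReferenceFixtures()
  pr <- pacingProtocol(1000, 50L, 3L)
  good <- phenotypeDiscrepancyCheck(fx$drugs$lidocaine_inal,
                                    fx$expectations$lidocaine,
                                    protocol = pr)
  bad <- phenotypeDiscrepancyCheck(fx$drugs$lidocaine_noinal,
                                   fx$expectations$lidocaine,
                                   protocol = pr)
  expect_true(good$consistent)
  expect_false(bad$consistent)
  ## a pure hERG blocker cannot satisfy an APD-shortening expectation
  d <- drugDescription("herg", list(channelEffect("g_Kr", "block",
                                                  ic50 = 1)), eftpc = 1)
  chk <- phenotypeDiscrepancyCheck(
    d, data.frame(biomarker = "APD90", direction = "decrease",
                  multiple = 1, tolerance = 0.01), protocol = pr)
  expect_false(chk$consistent)
  ## empty expectations produce an empty report
  e <- phenotypeDiscrepancyCheck(d, data.frame(), protocol = pr)
  expect_identical(nrow(e), 0L)
  expect_error(phenotypeDiscrepancyCheck(
    d, data.frame(biomarker = "bogus", direction = "increase",
                  multiple = 1), protocol = pr), "unknown biomarker")
})
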