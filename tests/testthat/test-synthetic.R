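test_that("a spec without implants yields clean detector output", {
  tr <- makeSyntheticTrace(traceSpec(beats = 2L))
  expect_identical(nrow(detectEADs(tr)), 0L)
  expect_false(as.logical(detectRepolarizationFailure(tr)))
  expect_identical(nrow(tr@extra$annotation$eads), 0L)
})

test_that("annotations list exactly the implanted events", {
  sp <- traceSpec(beats = 3L,
                  eads = data.frame(beat = c(2, 3), takeoff = c(-25, -15),
                                    amplitude = c(8, 6), width = c(10, 8)))
  tr <- makeSyntheticTrace(sp)
  ann <- tr@extra$annotation$eads
  expect_identical(nrow(ann), 2L)
  expect_equal(ann$beat, c(2, 3))
  expect_equal(ann$takeoff, c(-25, -15), tolerance = 1e-9)
})

test_that("overlapping implants are rejected", {
  sp <- traceSpec(beats = 2L,
                  eads = data.frame(beat = c(2, 2), takeoff = c(-20, -22),
                                    amplitude = c(8, 8), width = c(15, 15)))
  expect_error(makeSyntheticTrace(sp), "overlapping")
})

test_that("alternans patterns carry their exact ground truth", {
  tr <- makeSyntheticTrace(traceSpec(beats = 8L, alternansRatio = 0.8,
                                     jitterAmp = 0))
  amps <- computeBiomarkers(tr)@perBeat$CaT_amplitude
  res <- detectAlternans(amps)
  expect_true(res@present)
  expect_equal(res@magnitude, tr@extra$annotation$alternans$magnitude,
               tolerance = 0.01)
})

test_that("synthetic generation is deterministic in the seed", {
  a <- makeSyntheticTrace(traceSpec(beats = 2L, seed = 4L))
  b <- makeSyntheticTrace(traceSpec(beats = 2L, seed = 4L))
  expect_identical(a@V, b@V)
  c2 <- makeSyntheticTrace(traceSpec(beats = 2L, seed = 5L))
  expect_false(identical(a@V, c2@V))
})

test_that("reference fixtures carry the documented printed values", {
  fx <- makeReferenceFixtures()
  cb <- fx$drugs$cilostazol_block
  expect_equal(cb@eftpc, 0.128)
  ic <- vapply(cb@effects, function(e) e@ic50, numeric(1))
  names(ic) <- vapply(cb@effects, function(e) e@channel, character(1))
  expect_equal(unname(ic["g_Kr"]), 13.8)
  expect_equal(unname(ic["g_CaL"]), 91.2)
  sched <- fx$drugs$cilostazol_enh@effects[[3]]@schedule
  expect_identical(sched$multiple, c(10, 30, 100))
  expect_identical(sched$change, c(0.10, 0.22, 0.40))
  lq <- fx$variants$LQTS2@multipliers
  expect_identical(unname(lq[c("g_Kr", "g_NaL")]), c(0.30, 1.82))
  ## provenance flags exist, and placeholder values are marked as such
  expect_true(all(c("paper", "placeholder") %in% fx$provenance$source))
  expect_true(any(grepl("mexiletine",
                        fx$provenance$field[fx$provenance$source ==
                                            "placeholder"])))
})

test_that("an empty compendium request returns empty structures", {
  out <- makeSyntheticCompendium(0, seed = 1, population = NULL)
  expect_length(out$drugs, 0)
  expect_length(out$labels, 0)
})

test_that("compendium generation is reproducible and certified", {
  cal <- sharedPopulation()
  a <- makeSyntheticCompendium(4, seed = 31, population = cal,
                               protocol = trialProtocol())
  b <- makeSyntheticCompendium(4, seed = 31, population = cal,
                               protocol = trialProtocol())
  expect_identical(a$labels, b$labels)
  expect_identical(a$scores, b$scores)
  expect_identical(lapply(a$drugs, function(d) d@effects),
                   lapply(b$drugs, function(d) d@effects))
  ## labels are the brute-force trial outcomes
  expect_identical(unname(a$labels == "high"), unname(a$scores > 0))
  ## certified labels survive re-certification on a finer concentration
  ## grid containing the original multiples
  fine <- runDrugTrial(cal, a$drugs[[1]], multiples = c(1, 3, 10, 30, 100),
                       protocol = trialProtocol())
  sc <- trialRiskScore(fine)@score
  expect_identical(sc > 0, unname(a$labels[1] == "high"))
})
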