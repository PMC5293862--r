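test_that("design generation respects its configuration and is deterministic", {
  spec <- designSpec(preset = "full", seed = 5)
  d <- generateDesign(spec)
  geno <- unique(d$genotype[!d$is_control])
  expect_identical(length(geno), 233L)
  expect_true(all(table(d$genotype[!d$is_control]) == 5))
  expect_identical(length(unique(d$batch)), 36L)
  # every batch has controls; replicates span batches for some genotype
  expect_true(all(table(d$batch[d$is_control]) >= 1))
  spread <- tapply(d$batch[!d$is_control], d$genotype[!d$is_control],
                   function(b) length(unique(b)))
  expect_gt(max(spread), 1)
  # genotype totals bounded by the drawn range
  cnt <- table(sub("_g.*", "", geno))
  expect_true(all(cnt >= 3 & cnt <= 25))
  expect_identical(generateDesign(spec), d)

  # minimal design: one sample
  d1 <- generateDesign(designSpec(preset = "custom", nPopulations = 1,
                                  genotypesPerPopulation = c(1, 1),
                                  nReplicates = 1, nBatches = 1,
                                  controlsPerBatch = 0, seed = 1))
  expect_identical(nrow(d1), 1L)
  expect_error(designSpec(preset = "custom", nPopulations = 0),
               "nPopulations")
  expect_error(designSpec(preset = "custom",
                          genotypesPerPopulation = c(5, 3)),
               "genotypesPerPopulation")
})

test_that("simulated truth covers the required presence patterns", {
  spec <- designSpec(seed = 8)
  truth <- simulateTruth(spec)
  met <- truthMetabolites(truth)
  pres <- truthPresence(truth)
  # at least one metabolite absent in a designated population
  expect_true(any(pres[, 1] == 0 & rowSums(pres > 0) > 0))
  # at least one metabolite present in exactly one population
  expect_true(any(rowSums(pres > 0) == 1))
  # an isomer pair at close retention time
  expect_true(any(met$n_isomer_splits >= 2 & met$isomer_delta_rt <= 0.25))
  # thesinine rhamnoside appears as two isomers at its theoretical m/z
  tr <- met[met$name == "The-Rha", ]
  expect_equal(round(tr$true_mz, 4), 434.2173)
  expect_identical(tr$n_isomer_splits, 2L)
  # uniform metabolites are labelled invariant
  expect_true(all(!met$is_differential[met$pattern == "uniform"]))
  # expected isotope ratio for a 30-carbon compound exceeds the
  # de-isotoping threshold
  r <- grassmet:::.isotopeRatios(30)
  expect_equal(1 / r$m1, 3.1, tolerance = 0.02)
  expect_gt(1 / r$m1, 2)
  expect_error(simulateTruth(spec, config = list(named = list(),
                                                 nUnknownNull = 0,
                                                 nUnknownDifferential = 0,
                                                 nControlMarkers = 0)),
               "empty")
})

test_that("rendering honours noise, floors, drift splitting and determinism", {
  r <- fastFixture()
  pe <- r$experiment
  met <- truthMetabolites(r$truth)
  pres <- truthPresence(r$truth)
  map <- truthPeakMap(r$truth)

  # determinism: same truth + design + seed reproduces bit-identical data
  spec <- designSpec(seed = 42)
  r2 <- renderIntensityMatrix(simulateTruth(spec), generateDesign(spec),
                              seed = 43)
  expect_identical(intensities(r2$experiment), intensities(pe))

  # drifted isomer pair yields more rows than isomers
  sel <- sum(ppmError(peakData(pe)$mz, 434.2173) <= 20)
  expect_gt(sel, 2)

  # absent metabolites stay at the baseline floor
  x <- intensities(pe)
  absent <- which(met$name == "K-Glc-maGlc")
  rowIds <- map$peak_id[map$metabolite_id == met$metabolite_id[absent] &
                          map$role == "mono"]
  p1 <- sampleData(pe)$population == "P01"
  expect_lte(max(x[rowIds, p1]), 2e3)

  # isotope ratios follow the binomial carbon model
  ip <- truthIsotopePartners(r$truth)
  i1 <- match(ip$monoisotopic, rownames(x))
  i2 <- match(ip$plus_one, rownames(x))
  obs <- rowMeans(x[i2, ] / x[i1, ])
  carbon <- met$carbon_count[match(
    map$metabolite_id[match(ip$monoisotopic, map$peak_id)],
    met$metabolite_id)]
  expected <- carbon * 0.0107 / (1 - 0.0107)
  mcse <- apply(x[i2, ] / x[i1, ], 1, sd) / sqrt(ncol(x))
  expect_true(all(abs(obs - expected) <= 3 * mcse + 1e-3 * expected))

  # detected m/z errors stay within the simulated ppm bound
  trueMz <- met$true_mz[match(map$metabolite_id, met$metabolite_id)]
  mono <- map$role == "mono"
  expect_lte(max(ppmError(peakData(pe)$mz[match(map$peak_id[mono],
                                                peakData(pe)$peak_id)],
                          trueMz[mono])), 5 + 1e-6)
  expect_error(renderIntensityMatrix(r$truth, generateDesign(spec),
                                     noiseCv = 1.5, seed = 1))
})

test_that("a null peak shows the injected batch shift before correction", {
  r <- fastFixture()
  map <- truthPeakMap(r$truth)
  met <- truthMetabolites(r$truth)
  nullRows <- map$peak_id[map$role == "mono" &
    map$metabolite_id %in% met$metabolite_id[met$pattern == "uniform"]]
  Y <- log(intensities(r$experiment)[nullRows, ] + 1)
  an <- grassmet:::.rowOnewayF(Y, sampleData(r$experiment)$batch)
  expect_gt(mean(an$p < 0.05), 0.9)  # power of the batch ANOVA
})

test_that("pseudo spectra carry parents and successive neutral losses", {
  spec <- designSpec(seed = 8)
  truth <- simulateTruth(spec)
  spectra <- renderPseudoSpectra(truth)
  byName <- setNames(spectra, vapply(spectra, `[[`, "", "name"))
  kg <- byName[["K-Glc-maGlc"]]
  expect_equal(kg$ions$mz, c(697.1611, 449.1078, 287.0550),
               tolerance = 1e-4)
  # aglycone-only metabolite gives a single-ion spectrum
  expect_identical(nrow(byName[["thesinine"]]$ions), 1L)
  # MSP round trip preserves every ion list
  f <- tempfile(fileext = ".msp")
  writeMsp(spectra, f)
  back <- readMsp(f)
  expect_identical(length(back), length(spectra))
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$name, spectra[[i]]$name)
    expect_equal(back[[i]]$ions$mz, round(spectra[[i]]$ions$mz, 4))
  }
})
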