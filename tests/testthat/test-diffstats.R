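test_that("genotype medians collapse replicates with missing-value handling", {
  meta <- data.frame(sample_id = sprintf("s%d", 1:11), population = "P01",
                     genotype = c(rep("g1", 5), rep("g2", 5), "g3"),
                     replicate = c(1:5, 1:5, 1),
                     batch = "B01", ion_mode = "positive",
                     is_control = FALSE)
  x <- rbind(c(10, 20, 30, 40, 50, 10, 20, NA, 40, 50, 7),
             c(NA, NA, NA, NA, NA, 1, 1, 1, 1, 1, 2))
  pe <- makeToyPe(x, mz = c(100, 200), rt = c(1, 2), meta = meta)
  gm <- medianByGenotype(pe)
  expect_equal(gm$matrix["pk001", "g1"], 30)
  expect_equal(gm$matrix["pk001", "g2"], 30)  # median of 4 non-missing
  expect_equal(gm$matrix["pk001", "g3"], 7)   # single replicate
  expect_true(is.na(gm$matrix["pk002", "g1"]))
})

test_that("moderated F reduces to classical ANOVA at zero prior weight", {
  set.seed(61)
  npop <- 4; ng <- 5
  meta <- data.frame(
    sample_id = sprintf("s%03d", seq_len(npop * ng)),
    population = rep(sprintf("P%02d", 1:npop), each = ng),
    genotype = sprintf("g%03d", seq_len(npop * ng)),
    replicate = 1, batch = "B01", ion_mode = "positive",
    is_control = FALSE)
  x <- exp(matrix(rnorm(30 * npop * ng, 8, 1), 30))
  pe <- makeToyPe(x, mz = 100 + 1:30, rt = (1:30) / 10, meta = meta)
  res0 <- moderatedPopulationTest(pe, priorDf = 0, priorVar = 1)
  Y <- log(x + 1)
  pop <- meta$population
  for (i in c(1, 7, 30)) {
    fit <- anova(lm(Y[i, ] ~ pop))
    expect_equal(res0$F[i], fit$`F value`[1], tolerance = 1e-10)
    expect_equal(res0$p[i], fit$`Pr(>F)`[1], tolerance = 1e-10)
  }
  # infinite prior: F tests against the prior variance
  resInf <- moderatedPopulationTest(pe, priorDf = Inf, priorVar = 0.7)
  an <- grassmet:::.rowOnewayF(Y, pop)
  expect_equal(resInf$F, an$msb / 0.7, tolerance = 1e-12)
  # moderated F is nonnegative and BH adjustment is monotone and bounded
  res <- moderatedPopulationTest(pe)
  expect_true(all(res$F >= 0, na.rm = TRUE))
  expect_true(all(res$p_adjust >= res$p - 1e-12))
  expect_true(all(res$p_adjust >= 0 & res$p_adjust <= 1))
  ord <- order(res$p)
  expect_true(all(diff(res$p_adjust[ord]) >= -1e-12))
})

test_that("no-variation peaks give F = 0, p = 1", {
  meta <- data.frame(
    sample_id = sprintf("s%d", 1:12),
    population = rep(c("P1", "P2", "P3"), each = 4),
    genotype = sprintf("g%d", 1:12), replicate = 1,
    batch = "B01", ion_mode = "positive", is_control = FALSE)
  set.seed(62)
  x <- rbind(rep(1000, 12), exp(matrix(rnorm(60, 7, 1), 5)))
  pe <- makeToyPe(x, mz = c(100, 200, 300, 400, 500, 600), rt = 1:6,
                  meta = meta)
  res <- moderatedPopulationTest(pe)
  expect_equal(res$F[res$peak_id == "pk001"], 0)
  expect_equal(res$p[res$peak_id == "pk001"], 1)
})

test_that("truth differential peaks dominate the moderated ranking", {
  r <- fastFixture()
  pe <- mergeDuplicatePeaks(r$experiment)
  pe <- correctBatchEffects(pe)
  pe <- deisotope(pe, findIsotopeGroups(pe))
  res <- moderatedPopulationTest(pe)
  met <- truthMetabolites(r$truth)
  map <- truthPeakMap(r$truth)
  diffIds <- met$metabolite_id[met$is_differential]
  diffRows <- map$peak_id[map$metabolite_id %in% diffIds]
  hits <- res$peak_id[res$p_adjust < 0.01]
  # all differential metabolites are discovered at FDR < 0.01
  found <- unique(map$metabolite_id[map$peak_id %in% hits])
  expect_true(all(diffIds %in% found))
  # false discoveries among truly-null monoisotopic peaks stay near the
  # nominal FDR (isomer-compensating rows are genuinely differential
  # per-row, so they are excluded from the null set)
  nullRows <- map$peak_id[map$metabolite_id %in%
                            met$metabolite_id[!met$is_differential &
                                                met$pattern != "compensating"]]
  fdrObs <- sum(hits %in% nullRows) / max(length(hits), 1)
  expect_lte(fdrObs, 0.05)
})

test_that("top-k ranking gates on intensity and is order-stable", {
  res <- data.frame(
    peak_id = sprintf("p%02d", 1:10),
    F = c(5, 50, 500, 40, 30, 400, 3, 2, 1, 100),
    p = runif(10), p_adjust = runif(10),
    mean_intensity = c(rep(2e5, 6), rep(1e3, 4)))
  top <- rankTopPeaks(res, intensityMin = 1e5, k = 3)
  expect_identical(top$peak_id, c("p03", "p06", "p02"))
  expect_identical(top$rank, 1:3)
  # permuting rows does not change the output
  top2 <- rankTopPeaks(res[sample(10), ], intensityMin = 1e5, k = 3)
  expect_identical(top2, top)
  # k above the gated count returns everything gated, with a notice
  expect_message(topAll <- rankTopPeaks(res, intensityMin = 1e5, k = 50),
                 "pass the intensity gate")
  expect_identical(nrow(topAll), 6L)
  # deterministic tie-break by peak id
  res$F <- 1
  t3 <- rankTopPeaks(res, intensityMin = 1e5, k = 6)
  expect_identical(t3$peak_id, sort(t3$peak_id))
})
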