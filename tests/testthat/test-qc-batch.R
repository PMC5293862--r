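test_that("EB batch adjustment matches a direct non-vectorised implementation", {
  set.seed(11)
  n <- 24; npk <- 40
  batch <- rep(c("A", "B"), each = n / 2)
  Y <- matrix(rnorm(npk * n, 10, 1), npk, n) +
    outer(rnorm(npk, 0, 0.6), as.numeric(batch == "B"))
  mine <- grassmet:::.ebBatchAdjust(Y, batch)
  want <- oracleEbBatchAdjust(Y, batch)
  expect_lt(max(abs(mine - want)), 1e-8)
})

test_that("EB batch adjustment agrees with the reference implementation", {
  set.seed(7)
  n <- 60; npk <- 80
  batch <- factor(rep(c("A", "B", "C"), each = n / 3))
  gamma <- matrix(rnorm(npk * 3, 0, 0.8), npk, 3)
  delta <- matrix(exp(rnorm(npk * 3, 0, 0.3)), npk, 3)
  Y <- sapply(seq_len(n), function(j)
    rnorm(npk, 10, 2) * 0 + 10 + gamma[, as.integer(batch)[j]] +
      sqrt(delta[, as.integer(batch)[j]]) * rnorm(npk, 0, 0.5))
  mine <- grassmet:::.ebBatchAdjust(Y, batch)
  ref <- suppressMessages(sva::ComBat(dat = Y, batch = batch))
  expect_lt(max(abs(mine - ref)), 1e-4)
})

test_that("injected batch shifts are removed on generator data", {
  r <- fastFixture()
  pe <- correctBatchEffects(mergeDuplicatePeaks(r$experiment))
  map <- truthPeakMap(r$truth)
  met <- truthMetabolites(r$truth)
  nullMet <- met$metabolite_id[!met$is_differential &
                                 met$pattern == "uniform"]
  rows <- intersect(map$peak_id[map$metabolite_id %in% nullMet &
                                  map$role == "mono"],
                    rownames(intensities(pe)))
  Y <- log(intensities(pe)[rows, ] + 1)
  an <- grassmet:::.rowOnewayF(Y, sampleData(pe)$batch)
  # residual batch signal is gone (the filter finds almost nothing)
  expect_lt(mean(an$p < 0.05, na.rm = TRUE), 0.07)
  # per-peak batch means sit close to the peak mean relative to noise
  resid <- sqrt(an$msw)
  shift <- sqrt(pmax(an$msb, 0) / (ncol(Y) / length(unique(sampleData(pe)$batch))))
  expect_lt(median(shift / resid, na.rm = TRUE), 0.5)
  # before correction the same peaks show massive batch structure
  Yraw <- log(intensities(r$experiment)[rows, ] + 1)
  anRaw <- grassmet:::.rowOnewayF(Yraw, sampleData(r$experiment)$batch)
  expect_gt(mean(anRaw$p < 0.05, na.rm = TRUE), 0.9)
})

test_that("null batch effects leave the matrix essentially unchanged", {
  set.seed(3)
  spec <- designSpec(nPopulations = 3, genotypesPerPopulation = c(3, 3),
                     nBatches = 4, controlsPerBatch = 1, seed = 9)
  truth <- simulateTruth(spec,
                         config = defaultMetaboliteConfig(30, 0, 0),
                         batchLocationSd = 0, batchLocationPeakSd = 0,
                         batchScaleSd = 0)
  truth@batchEffects$location[] <- 0
  r <- renderIntensityMatrix(truth, generateDesign(spec), seed = 10)
  pe <- correctBatchEffects(r$experiment)
  rel <- abs(log(intensities(pe) + 1) - log(intensities(r$experiment) + 1))
  # with no injected effects the correction only removes the batch-mean
  # sampling noise (about sigma/sqrt(n_batch)), far below the replicate
  # noise sigma = 0.2
  expect_lt(median(rel), 0.1)
})

test_that("batch correction validates its inputs", {
  x <- matrix(runif(12, 1, 10), 3, 4)
  meta <- data.frame(sample_id = letters[1:4], population = "P01",
                     genotype = c("g1", "g1", "g2", "g2"),
                     replicate = c(1, 2, 1, 2),
                     batch = c("B1", "B1", "B1", "B2"),
                     ion_mode = "positive", is_control = FALSE)
  pe <- makeToyPe(x, mz = c(100, 200, 300), rt = 1:3, meta = meta)
  expect_error(correctBatchEffects(pe), "B2")
  meta$batch <- "B1"
  pe1 <- makeToyPe(x, mz = c(100, 200, 300), rt = 1:3, meta = meta)
  expect_error(correctBatchEffects(pe1), ">= 2 batches")
})

test_that("residual-batch filter removes shifted peaks, keeps constant ones, and is calibrated", {
  set.seed(21)
  n <- 40
  batch <- rep(c("B1", "B2"), each = n / 2)
  meta <- data.frame(sample_id = sprintf("s%02d", 1:n), population = "P01",
                     genotype = sprintf("g%02d", ceiling(1:n / 5)),
                     replicate = ((1:n - 1) %% 5) + 1,
                     batch = batch, ion_mode = "positive",
                     is_control = FALSE)
  huge <- exp(c(rnorm(n / 2, 5, 0.1), rnorm(n / 2, 9, 0.1)))
  flat <- rep(100, n)
  nullPk <- exp(matrix(rnorm(200 * n, 7, 0.3), 200, n))
  x <- rbind(huge, flat, nullPk)
  pe <- makeToyPe(x, mz = 100 + seq_len(nrow(x)), rt = seq_len(nrow(x)) / 50,
                  meta = meta)
  out <- filterResidualBatch(pe, alpha = 0.05)
  ids <- peakData(out)$peak_id
  expect_false("pk001" %in% ids)  # huge shift removed
  expect_true("pk002" %in% ids)   # constant retained (p defined as 1)
  # type-I calibration on the null peaks
  frac <- 1 - (length(setdiff(ids, c("pk002"))) / 200)
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(frac - 0.05), 3 * se + 1e-9)
})
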