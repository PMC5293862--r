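test_that("worked glycoside spectra annotate to their literature names", {
  # kaempferol malonyl-diglycoside: parent with hexose and malonylhexose
  # losses; kaempferol is indistinguishable from luteolin by mass
  ann <- annotateGlycoside(697.1593, c(449.1078, 287.0550),
                           adduct = "[M+H]+")
  expect_identical(ann$name, "K-Glc-maGlc")
  expect_setequal(ann$ambiguousAglycones, c("kaempferol", "luteolin"))
  expect_lt(ann$residualPpm, 20)
  expect_true(all(ann$evidence$passed))

  ann2 <- annotateGlycoside(667.1858, c(521.1286, 317.0656),
                            adduct = "[M+H]+")
  expect_identical(ann2$name, "I-acGlc-Rha")
  expect_identical(ann2$ambiguousAglycones, "isorhamnetin")

  ann3 <- annotateGlycoside(507.1128, 303.0499, adduct = "[M+H]+")
  expect_identical(ann3$name, "Q-acGlc")

  # aglycone-only parent: zero moieties
  ann4 <- annotateGlycoside(287.0550, adduct = "[M+H]+")
  expect_identical(ann4$name, "K")
  expect_identical(length(ann4$moieties), 0L)

  # nothing matches: unannotated result with evidence, not an error
  ann5 <- annotateGlycoside(912.345, c(700.1, 500.2), adduct = "[M+H]+")
  expect_true(is.na(ann5$name))
  expect_true(nrow(ann5$evidence) > 0)
})

test_that("annotations are sound: names recompose the parent m/z", {
  agl <- aglyconeLibrary("positive")
  mo <- moietyLibrary()
  set.seed(81)
  for (i in which(!is.na(agl$formula))) {
    for (trial in 1:5) {
      k <- sample(0:3, 1)
      picks <- sample(mo$symbol, k, replace = TRUE)
      parent <- agl$adductMz[i] + sum(mo$lossMass[match(picks, mo$symbol)])
      frags <- parent - cumsum(mo$lossMass[match(picks, mo$symbol)])
      ann <- annotateGlycoside(parent, frags, adduct = "[M+H]+")
      expect_false(is.na(ann$name))
      recomposed <- agl$adductMz[match(ann$aglycone, agl$name)] +
        sum(mo$lossMass[match(ann$moietySymbols, mo$symbol)])
      expect_lt(ppmError(parent, recomposed), 20)
    }
  }
})

test_that("greedy decomposition agrees with brute force when unique", {
  mo <- moietyLibrary()
  agl <- aglyconeLibrary("positive")
  kae <- agl[agl$symbol == "K", ]
  set.seed(82)
  for (trial in 1:40) {
    k <- sample(1:3, 1)
    picks <- sort(sample(mo$symbol, k, replace = TRUE))
    parent <- kae$adductMz + sum(mo$lossMass[match(picks, mo$symbol)])
    tolDa <- parent * 20 / 1e6
    sets <- oracleMoietySets(parent - kae$adductMz, mo, tolDa, maxN = 3)
    if (length(sets) != 1L) next  # only compare on unique solutions
    ann <- annotateGlycoside(parent, adduct = "[M+H]+",
                             aglycones = kae)  # mass-only route
    expect_identical(sort(ann$moietySymbols), sets[[1]],
                     info = paste(picks, collapse = "+"))
  }
})

test_that("isotopic presence requires both the partner mass and its RT", {
  x <- exp(matrix(rnorm(3 * 10, 10, 0.3), 3))
  pe <- makeToyPe(x, mz = c(697.1593, 698.1627, 698.1630),
                  rt = c(4.15, 4.15, 6.50))
  res <- checkIsotopicPresence(pe, "pk001")
  expect_true(res$passed)
  expect_identical(res$partner, "pk002")
  # partner at the right mass but outside [rtmin, rtmax] fails
  pe2 <- makeToyPe(x[c(1, 3), ], mz = c(697.1593, 698.1630),
                   rt = c(4.15, 6.50))
  expect_false(checkIsotopicPresence(pe2, "pk001")$passed)
  # no partner at all fails
  pe3 <- makeToyPe(x[1, , drop = FALSE], mz = 697.1593, rt = 4.15)
  expect_false(checkIsotopicPresence(pe3, "pk001")$passed)
})

test_that("co-eluting groups respect correlation and RT windows", {
  set.seed(83)
  n <- 40
  parent <- exp(rnorm(n, 12, 0.8))
  frag <- parent * 0.4 * exp(rnorm(n, 0, 0.03))
  unrelated <- exp(rnorm(n, 11, 0.8))
  farRt <- parent * 0.9
  x <- rbind(parent, frag, unrelated, farRt)
  pe <- makeToyPe(x, mz = c(697.16, 449.11, 350.10, 500.20),
                  rt = c(4.15, 4.15, 4.16, 5.9))
  grp <- coelutingGroup(pe, "pk001")
  expect_identical(grp, c("pk001", "pk002"))  # descending m/z, seed kept
  # seed alone when nothing correlates
  grpAlone <- coelutingGroup(pe, "pk004")
  expect_identical(grpAlone, "pk004")
})

test_that("generator glycoside fragments are recovered and annotated end-to-end", {
  r <- fastFixture()
  pe <- r$experiment
  map <- truthPeakMap(r$truth)
  met <- truthMetabolites(r$truth)
  iac <- met$metabolite_id[met$name == "I-acGlc-Rha"]
  seedPeak <- map$peak_id[map$metabolite_id == iac & map$role == "mono"]
  fragTruth <- map$peak_id[map$metabolite_id == iac & map$role == "fragment"]
  grp <- suppressMessages(coelutingGroup(pe, seedPeak))
  expect_true(all(fragTruth %in% grp))
  ann <- annotatePeaks(pe, seedPeak)
  expect_identical(ann$table$name, "I-acGlc-Rha")
  expect_true(ann$table$isotopic_presence)
})

test_that("MSP I/O validates structure and errors name the defect", {
  recs <- list(list(name = "K-Glc", precursorMz = 449.1078,
                    ions = data.frame(mz = c(449.1078, 287.0550),
                                      intensity = c(100, 40))),
               list(name = "empty-ions", precursorMz = 100,
                    ions = data.frame(mz = numeric(0),
                                      intensity = numeric(0))))
  txt <- writeMsp(recs)
  back <- readMsp(txt)
  expect_identical(length(back), 2L)
  expect_identical(back[[1]]$name, "K-Glc")
  expect_equal(back[[1]]$ions$intensity, c(100, 40))
  expect_identical(nrow(back[[2]]$ions), 0L)
  # declared/actual ion-count mismatch is an error naming the record
  bad <- sub("Num Peaks: 2", "Num Peaks: 3", txt)
  expect_error(readMsp(bad), "Num Peaks mismatch")
  # empty library round-trips to an empty record list
  expect_identical(readMsp(writeMsp(list())), list())
})
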