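test_that("peak id nomenclature formats and parses round-trip", {
  expect_identical(formatPeakId("positive", 434.2167, 4.58),
                   "CP434.2167_4.58")
  parsed <- parsePeakId("CN353.0875_5.39")
  expect_identical(parsed$ion_mode, "negative")
  expect_equal(parsed$mz, 353.0875)
  expect_equal(parsed$rt, 5.39)
  # format . parse = identity on well-formed ids
  ids <- c("CP697.1593_4.15", "CN505.0985_5.54", "CP288.1590_5.17")
  p <- parsePeakId(ids)
  expect_identical(formatPeakId(p$ion_mode, p$mz, p$rt), ids)
  expect_error(parsePeakId("XX100.1_2.0"), "malformed")
  expect_error(parsePeakId("CP100.12_2.00"), "malformed")  # 2 dp m/z
})

test_that("isotope groups require all four criteria conjointly", {
  set.seed(1)
  base <- exp(rnorm(30, log(1e6), 0.8))
  # planted triple with good spacing, correlation and ratios
  x <- rbind(base,
             base * 0.30 * exp(rnorm(30, 0, 0.01)),
             base * 0.06 * exp(rnorm(30, 0, 0.01)),
             # pair failing the ratio criterion ([M]/[M+1] = 1.5)
             b2 <- exp(rnorm(30, log(1e5), 0.8)),
             b2 / 1.5 * exp(rnorm(30, 0, 0.01)),
             # pair with perfect ratios but uncorrelated
             b3 <- exp(rnorm(30, log(1e5), 0.8)),
             exp(rnorm(30, log(mean(b3) * 0.3), 0.8)))
  mz <- c(697.1593, 698.1627, 699.1660,
          500.2000, 501.2034,
          600.3000, 601.3034)
  rt <- c(4.15, 4.15, 4.16, 2.0, 2.0, 3.0, 3.0)
  pe <- makeToyPe(x, mz, rt)
  g <- findIsotopeGroups(pe)
  expect_identical(nrow(g), 1L)
  expect_identical(g$monoisotopic, "pk001")
  expect_identical(g$plus_one, "pk002")
  expect_identical(g$plus_two, "pk003")
  expect_gt(g$r_m1, 0.9)
  expect_gt(g$ratio_m_m1, 2)
  expect_gt(g$ratio_m1_m2, 2)
  # mass-spacing invariant within the accepted group
  expect_lt(abs((mz[2] - mz[1]) - 1.00336), 20 * mz[2] / 1e6)

  out <- deisotope(pe, g)
  expect_identical(nrow(out), 5L)
  expect_false(any(c("pk002", "pk003") %in% peakData(out)$peak_id))
  expect_true("pk001" %in% peakData(out)$peak_id)
  expect_match(peakData(out)$isotope_links[1], "pk002,pk003")
  # idempotence
  g2 <- findIsotopeGroups(out)
  expect_identical(nrow(g2), 0L)
  expect_identical(intensities(deisotope(out, g2)), intensities(out))
})

test_that("de-isotoping matches the exhaustive oracle on random tables", {
  for (seed in 1:25) {
    pe <- randomIsotopeTable(seed)
    got <- findIsotopeGroups(pe)
    want <- oracleIsotopeGroups(pe)
    expect_identical(stripRn(got[, c("monoisotopic", "plus_one", "plus_two")]),
                     stripRn(want), info = paste("seed", seed))
  }
})

test_that("groups accepted at tight thresholds satisfy the loose criteria", {
  # criteria-level monotonicity: every envelope accepted under tightened
  # thresholds also passes the four criteria at the looser defaults (the
  # greedy disjointness rule may re-pair peaks freed by a tighter
  # threshold, so set-level containment is checked at the criteria level)
  for (seed in 1:10) {
    pe <- randomIsotopeTable(seed)
    for (tight in list(list(ppmTol = 5), list(rtTol = 0.05),
                       list(rMin = 0.99), list(ratioMin = 4))) {
      args <- utils::modifyList(
        list(pe = pe, ppmTol = 20, rtTol = 0.2, rMin = 0.9, ratioMin = 2),
        tight)
      g <- do.call(findIsotopeGroups, args)
      if (nrow(g) == 0) next
      for (gi in seq_len(nrow(g)))
        expect_true(groupMeetsCriteria(pe, g$monoisotopic[gi],
                                       g$plus_one[gi], g$plus_two[gi],
                                       ppmTol = 20, rtTol = 0.2,
                                       rMin = 0.9, ratioMin = 2),
                    info = paste("seed", seed, names(tight)))
    }
  }
})

test_that("generator isotope envelopes are recovered against truth", {
  # pipeline order: outlier removal precedes de-isotoping, so injected
  # replicate outliers cannot depress the envelope correlations
  r <- fastFixture()
  pe <- removeReplicateOutliers(correctBatchEffects(
    mergeDuplicatePeaks(r$experiment)))
  g <- findIsotopeGroups(pe)
  out <- deisotope(pe, g)
  ip <- truthIsotopePartners(r$truth)
  partners <- na.omit(c(ip$plus_one, ip$plus_two))
  kept <- peakData(out)$peak_id
  # every truth isotope partner removed, no monoisotopic truth peak removed
  expect_lt(mean(partners %in% kept), 0.02)
  expect_gte(mean(na.omit(c(truthIsotopePartners(r$truth)$plus_one)) %in%
                    peakData(pe)$peak_id), 0.99)
  expect_true(all(ip$monoisotopic %in% kept))
  expect_identical(nrow(pe) - nrow(out),
                   sum(!is.na(g$plus_one)) + sum(!is.na(g$plus_two)))
})
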