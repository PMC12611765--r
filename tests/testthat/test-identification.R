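test_that("fragment prediction flags oxygen retention correctly", {
  # oxTG containing FA18:2 with a hydroperoxyl group, sodiated
  sp <- parseLipidName("TG 18:1/18:1/18:2")
  ox <- sp; ox@modifications <- modificationSet(nOOH = 1L)
  fr <- predictFragments(ox, polarity = "positive")
  expect_true("[FA18:2<OOH>+Na]+" %in% fr$descriptor)
  expect_true(fr$retainsAddedOxygen[fr$descriptor == "[FA18:2<OOH>+Na]+"])
  # hydroperoxyl survives one water loss with one oxygen retained
  expect_true(fr$retainsAddedOxygen[fr$descriptor == "[FA18:2<OOH>-H2O+H]+"])
  # losing the oxidized acyl from the precursor removes the added oxygens
  expect_false(fr$retainsAddedOxygen[fr$descriptor == "[M+Na-FA18:2<OOH>]+"])

  # hydroxyl: the water loss removes the only added oxygen
  oxh <- sp; oxh@modifications <- modificationSet(nOH = 1L)
  frh <- predictFragments(oxh, polarity = "positive")
  expect_false(frh$retainsAddedOxygen[frh$descriptor ==
                                      "[FA18:2<OH>-H2O+H]+"])
  expect_true(frh$retainsAddedOxygen[frh$descriptor == "[FA18:2<OH>+Na]+"])

  # negative-mode oxPC chemistry
  pc <- parseLipidName("PC 16:0/18:2")
  oxpc <- pc; oxpc@modifications <- modificationSet(nOOH = 1L)
  frn <- predictFragments(oxpc, polarity = "negative")
  expect_true("[FA18:2<OOH>-H]-" %in% frn$descriptor)
  expect_true(frn$retainsAddedOxygen[frn$descriptor == "[FA18:2<OOH>-H]-"])
  expect_true("[FA18:2<OOH>-H2O-H]-" %in% frn$descriptor)

  expect_error(predictFragments("CE 20:4", polarity = "positive"),
               "no oxidation modification")
})

test_that("oxygen retention agrees with the formula-accounting oracle", {
  for (cand in benchmarkCandidates()) {
    fr <- predictFragments(cand, polarity = "positive")
    oxfa <- fr$origin %in% c("intact oxFA", "oxFA neutral-loss")
    expect_equal(fr$retainsAddedOxygen[oxfa],
                 vapply(fr$formula[oxfa], oracleRetainsOxygen, logical(1)),
                 ignore_attr = TRUE)
    # precursor acyl losses retain the oxygens iff the lost acyl is
    # unmodified (no modification token in the loss descriptor)
    loss <- fr$origin == "acyl loss"
    expect_equal(fr$retainsAddedOxygen[loss],
                 !grepl("<", fr$descriptor[loss]), ignore_attr = TRUE)
  }
})

test_that("spectrum matching scores planted candidates and rejects off-precursor ones", {
  cands <- benchmarkCandidates()
  cfg <- simulationConfig(seed = 3, decoyPeakRate = 0)
  sim <- simulateOxidizedSpectra(cands, cfg, nTrue = 10L, nDecoy = 0L)
  ids <- matchSpectra(sim$spectra, cands)
  expect_true(all(c("score", "isotopeScore", "rankScore") %in% names(ids)))
  expect_true(all(ids$score >= 0 & ids$score <= 100))
  # every true spectrum yields an accepted top candidate at the right m/z
  out <- benchmarkOutcome(ids, sim$truth)
  expect_equal(out$recall, 1)
  expect_equal(out$precision, 1)

  # a precursor 50 ppm off engages no candidate
  s <- sim$spectra[[1]]
  far <- centroidSpectrum(s@precursorMz * (1 + 50e-6), s@rt, s@peaks,
                          precursorIntensity = s@precursorIntensity,
                          polarity = s@polarity, spectrumId = "far")
  expect_equal(nrow(matchSpectrum(far, cands)), 0L)

  # low-intensity precursors are skipped
  dim_ <- centroidSpectrum(s@precursorMz, s@rt, s@peaks,
                           precursorIntensity = 10, polarity = s@polarity,
                           spectrumId = "dim")
  expect_equal(nrow(matchSpectrum(dim_, cands)), 0L)

  # peaks below 1% of the base peak are ignored in scoring
  pk <- s@peaks
  tiny <- rbind(pk, c(400.123, max(pk[, 2]) * 0.005))
  s2 <- centroidSpectrum(s@precursorMz, s@rt, tiny,
                         precursorIntensity = s@precursorIntensity,
                         polarity = s@polarity,
                         precursorIsotopes = s@precursorIsotopes,
                         spectrumId = "tiny")
  i1 <- matchSpectrum(s, cands)
  i2 <- matchSpectrum(s2, cands)
  expect_equal(i2$score, i1$score, tolerance = 1e-12)
})

test_that("matching is invariant to candidate order", {
  cands <- benchmarkCandidates()
  cfg <- simulationConfig(seed = 9)
  sim <- simulateOxidizedSpectra(cands, cfg, nTrue = 5L, nDecoy = 0L)
  s <- sim$spectra[[3]]
  a <- matchSpectrum(s, cands)
  set.seed(1)
  b <- matchSpectrum(s, sample(cands))
  key <- function(d) d[order(d$species), c("species", "score", "rankScore")]
  expect_equal(key(a), key(b), ignore_attr = TRUE)
})

test_that("the evidence filter removes identifications without oxygen-retaining fragments", {
  cands <- benchmarkCandidates()
  cfg <- simulationConfig(seed = 13)
  # spectra deliberately built only from oxygen-losing fragments
  sim <- simulateOxidizedSpectra(cands, cfg, nTrue = 30L, nDecoy = 0L,
                                 fragmentSelector = "non-retaining")
  ids <- matchSpectra(sim$spectra, cands)
  filtered <- oxfaEvidenceFilter(ids)
  expect_false(any(filtered$accepted))
  # identifications that passed the scores carry the rejection reason
  rejected <- filtered[ids$accepted, , drop = FALSE]
  expect_true(all(rejected$reason == "no-oxygen-retaining-fragment"))
  # filter soundness over normal output: accepted implies evidence
  sim2 <- simulateOxidizedSpectra(cands, cfg, nTrue = 20L, nDecoy = 20L)
  ids2 <- oxfaEvidenceFilter(matchSpectra(sim2$spectra, cands))
  acc <- ids2[ids2$accepted, , drop = FALSE]
  expect_true(all(vapply(acc$matched, function(m)
    any(m$retainsAddedOxygen), logical(1))))
  expect_equal(nrow(oxfaEvidenceFilter(ids2[0, ])), 0L)
})

test_that("KMD-RT filter flags exactly a planted outlier in a collinear series", {
  # ten homologues on an exact KMD-RT line plus one gross outlier
  homologSeries <- function(seed) {
    set.seed(seed)
    carbons <- seq(46, 64, 2)
    mz <- vapply(carbons, function(cc)
      adductMz(speciesFormula(sprintf("TG %d:2<OH>", cc)), "[M+Na]+"),
      numeric(1))
    df <- data.frame(species = sprintf("TG %d:2<OH>", carbons),
                     mz = mz, rt = seq(10, 19, 1))
    out <- data.frame(species = "TG 55:2<OH>",
                      mz = adductMz(speciesFormula("TG 55:2<OH>"),
                                    "[M+Na]+") + runif(1, 0.05, 0.2),
                      rt = 14.5)
    rbind(df, out)
  }
  for (seed in c(1, 2, 3)) {
    res <- kmdRtFilter(homologSeries(seed))
    expect_equal(which(res$flagged), 11L)
  }
  # all points collinear: none flagged
  clean <- homologSeries(4)[1:10, ]
  expect_false(any(kmdRtFilter(clean)$flagged))
  # groups below the minimum size pass unflagged
  expect_false(any(kmdRtFilter(clean[1:2, ])$flagged))
})

test_that("isomer collapse groups identifications by m/z tolerance", {
  ids <- data.frame(species = c("TG 54:4<2OH>", "TG 54:4<OOH>", "CE 20:4<OH>"),
                    theoreticalMz = c(911.7341, 911.7341, 711.5323),
                    score = c(80, 95, 70))
  out <- collapseIsomers(ids)
  expect_equal(nrow(out), 2L)
  expect_true("TG 54:4<OOH>" %in% out$species)  # highest score kept
  expect_equal(out$nCollapsed[out$species == "TG 54:4<OOH>"], 2L)
  # 5 ppm apart merges at 5 ppm tolerance; 20 ppm apart stays separate
  near <- data.frame(theoreticalMz = c(800, 800 * (1 + 4.9e-6)),
                     score = c(1, 2))
  expect_equal(nrow(collapseIsomers(near, 5)), 1L)
  farp <- data.frame(theoreticalMz = c(800, 800 * (1 + 20e-6)),
                     score = c(1, 2))
  expect_equal(nrow(collapseIsomers(farp, 5)), 2L)
  # a construction with 82 distinct formulas yields 82 targets
  set.seed(82)
  mzs <- sort(runif(82, 500, 1100))
  mzs <- mzs[c(TRUE, diff(mzs) / mzs[-1] * 1e6 > 20)]
  many <- data.frame(theoreticalMz = rep(mzs, each = 2) *
                       (1 + rep(c(0, 2e-6), length(mzs))),
                     score = runif(2 * length(mzs)))
  expect_equal(nrow(collapseIsomers(many, 5)), length(mzs))
})
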