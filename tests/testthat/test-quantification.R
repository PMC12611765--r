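test_that("XIC extraction sums peaks within tolerance only", {
  # synthetic run: Gaussian peak at the target plus an off-tolerance peak
  target <- 880.7160
  rts <- seq(9.5, 10.5, by = 0.01)
  h <- 1e6; sig <- 0.05
  scans <- lapply(rts, function(rt) {
    y <- h * exp(-(rt - 10)^2 / (2 * sig^2))
    list(rt = rt, peaks = cbind(c(target, target * (1 + 100e-6)),
                                c(y, 5e5)))
  })
  x <- extractXic(scans, target, 5)
  expect_s4_class(x, "Chromatogram")
  expect_equal(max(x@intensity), h, tolerance = 1e-9)
  # only the in-tolerance peak contributes
  expect_equal(x@intensity, h * exp(-(rts - 10)^2 / (2 * sig^2)),
               tolerance = 1e-9)
  # a target 100 ppm from every peak gives an all-zero trace
  far <- extractXic(scans, target * (1 - 100e-6) * (1 - 100e-6), 5)
  expect_true(all(far@intensity[abs(rts - 10) > 0.2] == 0))
})

test_that("peak integration recovers analytic areas over a linear baseline", {
  # unit-height triangle of width 1 min on a zero baseline: area 0.5
  tri <- new("Chromatogram", rt = c(0, 0.5, 1), intensity = c(0, 1, 0),
             targetMz = 500, tolPpm = 5)
  expect_equal(integratePeak(tri, c(0, 1)), 0.5)
  # all-zero trace integrates to zero
  zero <- new("Chromatogram", rt = seq(0, 1, 0.1),
              intensity = rep(0, 11), targetMz = 500, tolPpm = 5)
  expect_equal(integratePeak(zero), 0)
  # Gaussian with known closed-form integral recovered within 1%
  rts <- seq(8, 12, by = 0.01)
  h <- 2e5; sig <- 0.05
  g <- new("Chromatogram", rt = rts,
           intensity = h * exp(-(rts - 10)^2 / (2 * sig^2)),
           targetMz = 500, tolPpm = 5)
  expect_equal(integratePeak(g, c(9, 11)), gaussianArea(h, sig),
               tolerance = 0.01)
  # the endpoint-linear baseline removes a constant offset
  g2 <- g; g2@intensity <- g@intensity + 1e4
  expect_equal(integratePeak(g2, c(9, 11)), gaussianArea(h, sig),
               tolerance = 0.01)
  expect_error(integratePeak(g, c(20, 21)), "window")
})

test_that("PRM quantification recovers planted areas and flags missing transitions", {
  trans <- rbind(
    transition("A", 880.7160, 197.0808, expectedRt = 10),
    transition("B", 886.7537, 203.1190, expectedRt = 10))
  run <- simulatePrmRun(trans, c(2.0, 1.0), simulationConfig(seed = 2))
  got <- prmQuantify(run$scans, trans)
  expect_equal(got$flag, c("ok", "ok"))
  expect_equal(got$area, run$truth$area, tolerance = 0.01)
  # linearity: doubling all scan intensities doubles the areas
  run2 <- run
  run2$scans <- lapply(run$scans, function(s) {
    s$peaks[, 2] <- s$peaks[, 2] * 2; s
  })
  got2 <- prmQuantify(run2$scans, trans)
  expect_equal(got2$area, 2 * got$area, tolerance = 1e-9)
  # a transition with no matching isolation is flagged, not fatal
  trans3 <- rbind(trans, transition("C", 600.0, 200.0, expectedRt = 10))
  got3 <- prmQuantify(run$scans, trans3)
  expect_equal(got3$flag[3], "no-matching-isolation")
  expect_true(is.na(got3$area[3]))
})

test_that("normalizations are exact ratios", {
  areas <- data.frame(name = c("TG 52:2<OOH>", "CE 20:4<OH>"),
                      class = c("TG", "CE"), area = c(2e6, 3e6))
  std <- data.frame(class = c("TG", "CE"), standardArea = c(1e6, 2e6))
  out <- normalizeToInternalStandard(areas, std)
  expect_equal(out$normalized, c(2, 1.5))
  # global intensity rescaling cancels exactly
  areas2 <- areas; areas2$area <- areas2$area * 7.3
  std2 <- std; std2$standardArea <- std2$standardArea * 7.3
  expect_equal(normalizeToInternalStandard(areas2, std2)$normalized,
               out$normalized)
  # unmapped class is an explicit error
  areas3 <- rbind(areas, data.frame(name = "PC 34:1", class = "PC",
                                    area = 1e6))
  expect_error(normalizeToInternalStandard(areas3, std), "PC")

  expect_equal(normalizeToProtein(4, 2), 2)
  m <- matrix(c(4, 8, 6, 9), 2)
  expect_equal(normalizeToProtein(m, c(2, 3)), m %*% diag(c(0.5, 1 / 3)),
               ignore_attr = TRUE)
  expect_error(normalizeToProtein(4, 0), "positive")
})

test_that("isotope dilution is the exact area ratio times the spiked amount", {
  expect_equal(isotopeDilutionAmount(1e6, 1e6, 2.5), 2.5)
  expect_equal(isotopeDilutionAmount(0, 1e6, 2.5), 0)
  expect_error(isotopeDilutionAmount(1e6, 0, 2.5), "positive")
  # spike-recovery through the full PRM path, noiseless
  trans <- rbind(
    transition("analyte", 880.7160, 197.0808, expectedRt = 10),
    transition("standard", 886.7537, 203.1190, expectedRt = 10))
  run <- simulatePrmRun(trans, c(1.7, 2.5), simulationConfig(seed = 4))
  got <- prmQuantify(run$scans, trans)
  rec <- isotopeDilutionAmount(got$area[1], got$area[2], 2.5)
  expect_equal(rec, 1.7, tolerance = 0.01)
})

test_that("coenzyme Q redox metrics mirror the reduced-fraction arithmetic", {
  m <- coqRedoxMetrics(0.4, 0.6, 2000)
  expect_equal(m$total, 1)
  expect_equal(m$fractionReduced, 0.6)
  expect_equal(m$coqPerNeutralLipid, 1 / 2000)
  expect_equal(coqRedoxMetrics(1, 0)$fractionReduced, 0)
  expect_error(coqRedoxMetrics(0, 0), "undefined")
})

test_that("external calibration back-calculates and flags extrapolation", {
  cal <- externalCalibration(c(1, 2, 4, 8), c(2, 4, 8, 16))
  expect_equal(cal$slope, 2)
  expect_equal(backCalculate(cal, 10)$concentration, 5)
  expect_false(backCalculate(cal, 10)$extrapolated)
  expect_true(backCalculate(cal, 100)$extrapolated)
  expect_error(externalCalibration(c(3, 3), c(1, 2)), "two distinct")
  # noisy six-level curve: slope recovered within its own CI
  set.seed(6)
  conc <- rep(c(0.5, 1, 2, 4, 8, 16), each = 3)
  resp <- 3 + 5 * conc + rnorm(length(conc), 0, 0.5)
  cal2 <- externalCalibration(conc, resp)
  ci <- confint(cal2$fit)["concentration", ]
  expect_true(ci[1] <= 5 && 5 <= ci[2])
  expect_gt(cal2$r.squared, 0.99)
})

test_that("PRM spike recovery stays within 1% noiseless and 10% at SNR 10", {
  trans <- rbind(
    transition("analyte", 880.7160, 197.0808, expectedRt = 10),
    transition("standard", 886.7537, 203.1190, expectedRt = 10))
  noiseless <- simulatePrmRun(trans, c(1.3, 2.5), simulationConfig(seed = 1))
  a <- prmQuantify(noiseless$scans, trans)
  expect_equal(isotopeDilutionAmount(a$area[1], a$area[2], 2.5), 1.3,
               tolerance = 0.01)
  errs <- vapply(1:50, function(s) {
    run <- simulatePrmRun(trans, c(1.3, 2.5), simulationConfig(seed = s),
                          snr = 10)
    a <- prmQuantify(run$scans, trans)
    abs(isotopeDilutionAmount(a$area[1], a$area[2], 2.5) - 1.3) / 1.3
  }, numeric(1))
  expect_lt(median(errs), 0.1)
  expect_lt(max(errs), 0.25)
})
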