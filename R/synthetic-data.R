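# Seeded generators for every input the pipeline consumes. Defaults
# emulate the study conditions of the semi-targeted workflows: four
# replicates per group, log-normally distributed lipid intensities with a
# 20% coefficient of variation, centroided MS/MS spectra carrying the
# predicted fragments of sodiated oxidized neutral lipids plus decoys and
# noise, Gaussian chromatographic peaks, and two-phase (lag/propagation)
# kinetic traces.

#' Simulation configuration
#'
#' @param seed Integer seed fixing every downstream draw.
#' @param groupSizes Named integer vector of samples per group.
#' @param featuresPerClass Named integer vector of features per lipid
#'   class.
#' @param meanLog10,sdLog10 Baseline log10-intensity location per feature
#'   (drawn uniformly in `meanLog10 +/- 1`) and log10-scale biological
#'   noise; `sdLog10 = 0.0857` corresponds to a ~20% CV.
#' @param decoyPeakRate Expected number of random decoy peaks added per
#'   spectrum.
#' @param mzJitterPpm Uniform m/z jitter applied to fragment peaks.
#' @param intensityCV Multiplicative log-normal CV of peak intensities.
#' @param fragmentFraction Fraction of predicted fragments present in a
#'   true spectrum.
#' @param peakSigmaMin Gaussian chromatographic peak sigma (minutes).
#' @param lagS,propagationRate Kinetic ground truth (seconds; a.u./s).
#' @param kineticNoiseSd Additive Gaussian noise on kinetic traces (a.u.).
#' @return A named list.
#' @export
simulationConfig <- function(seed = 1L,
                             groupSizes = c(WT = 4L, KO = 4L),
                             featuresPerClass = c(TG = 60L, CE = 20L,
                               PC = 40L, PE = 30L, LPC = 10L, LPE = 10L,
                               PS = 10L, PI = 10L, PG = 10L, SM = 15L,
                               Cer = 15L, DG = 15L),
                             meanLog10 = 6, sdLog10 = 0.0857,
                             decoyPeakRate = 5, mzJitterPpm = 5,
                             intensityCV = 0.2, fragmentFraction = 0.9,
                             peakSigmaMin = 0.05,
                             lagS = 10000, propagationRate = 1,
                             kineticNoiseSd = 50) {
  stopifnot(all(groupSizes >= 1L), all(featuresPerClass >= 0L),
            sdLog10 >= 0, decoyPeakRate >= 0, mzJitterPpm >= 0,
            intensityCV >= 0, fragmentFraction >= 0, fragmentFraction <= 1,
            peakSigmaMin > 0, lagS >= 0, kineticNoiseSd >= 0)
  list(seed = as.integer(seed), groupSizes = groupSizes,
       featuresPerClass = featuresPerClass, meanLog10 = meanLog10,
       sdLog10 = sdLog10, decoyPeakRate = decoyPeakRate,
       mzJitterPpm = mzJitterPpm, intensityCV = intensityCV,
       fragmentFraction = fragmentFraction, peakSigmaMin = peakSigmaMin,
       lagS = lagS, propagationRate = propagationRate,
       kineticNoiseSd = kineticNoiseSd)
}

# random plausible shorthand names for a class, unique within the call
.randomLipidNames <- function(class, n) {
  if (n == 0L) return(character(0))
  ranges <- switch(class,
    TG = list(c = seq(46L, 60L, 2L), d = 0:9),
    DG = list(c = seq(32L, 40L, 2L), d = 0:6),
    CE = list(c = 14:22, d = 0:6),
    SM = list(c = seq(32L, 42L, 2L), d = 1:3),
    Cer = list(c = seq(32L, 42L, 2L), d = 1:3),
    list(c = seq(30L, 40L, 2L), d = 0:6))
  pool <- expand.grid(c = ranges$c, d = ranges$d)
  pool <- pool[pool$d <= pool$c - 2L, , drop = FALSE]
  if (nrow(pool) < n)
    stop("cannot generate ", n, " unique names for class ", class)
  idx <- sample.int(nrow(pool), n)
  paste0(class, " ", pool$c[idx], ":", pool$d[idx])
}

#' Simulate a lipidome intensity table with known effects
#'
#' Raw intensities are log-normal per feature; planted fold changes are
#' applied multiplicatively to the second group. The returned ground
#' truth records the true fold change of every feature.
#'
#' @param config [simulationConfig()].
#' @param effects Optional data.frame with columns `feature`, `fc` (fold
#'   change applied to the second group), or an integer `nEffects` below.
#' @param nEffects Number of randomly chosen features given fold change
#'   `effectFc` (ignored when `effects` is supplied).
#' @param effectFc Fold change planted on the chosen features.
#' @return List with `table` (a [LipidomeTable-class], raw state) and
#'   `truth` (data.frame `feature`, `class`, `fc`).
#' @export
simulateLipidome <- function(config = simulationConfig(), effects = NULL,
                             nEffects = 0L, effectFc = 4) {
  set.seed(config$seed)
  classes <- names(config$featuresPerClass)
  feats <- unlist(lapply(classes, function(cl)
    .randomLipidNames(cl, config$featuresPerClass[[cl]])), use.names = FALSE)
  nf <- length(feats)
  groups <- rep(names(config$groupSizes), config$groupSizes)
  ns <- length(groups)
  baseLog10 <- runif(nf, config$meanLog10 - 1, config$meanLog10 + 1)
  fcVec <- setNames(rep(1, nf), feats)
  if (is.null(effects) && nEffects > 0L) {
    chosen <- sample(feats, min(nEffects, nf))
    effects <- data.frame(feature = chosen, fc = effectFc,
                          stringsAsFactors = FALSE)
  }
  if (!is.null(effects)) {
    i <- match(effects$feature, feats)
    stopifnot(!anyNA(i))
    fcVec[i] <- effects$fc
  }
  secondGroup <- groups == names(config$groupSizes)[2]
  mat <- matrix(0, nf, ns, dimnames = list(feats,
    paste0(groups, "_", unlist(lapply(config$groupSizes, seq_len)))))
  for (i in seq_len(nf)) {
    mu <- baseLog10[i] * log(10)
    x <- rlnorm(ns, meanlog = mu, sdlog = config$sdLog10 * log(10))
    x[secondGroup] <- x[secondGroup] * fcVec[i]
    mat[i, ] <- x
  }
  cls <- vapply(feats, function(f) lipidClass(f), character(1))
  list(table = lipidomeTable(mat, groups),
       truth = data.frame(feature = feats, class = unname(cls),
                          fc = unname(fcVec), stringsAsFactors = FALSE))
}

# one synthetic spectrum for a candidate species: either a true spectrum
# carrying a fraction of its predicted fragments, a decoy with shuffled
# peak positions, or (fragmentSelector = "non-retaining") a spectrum whose
# fragment content deliberately lacks oxygen-retaining evidence
.simulateOneSpectrum <- function(species, id, config, truth = TRUE,
                                 polarity = "positive",
                                 fragmentSelector = c("all", "non-retaining")) {
  fragmentSelector <- match.arg(fragmentSelector)
  ad <- .candidateAdduct(species, polarity)
  precMz <- adductMz(speciesFormula(species), ad)
  frags <- predictFragments(species, ad, polarity)
  if (fragmentSelector == "non-retaining")
    frags <- frags[!frags$retainsAddedOxygen, , drop = FALSE]
  keep <- runif(nrow(frags)) < config$fragmentFraction
  if (truth && !any(keep)) keep[sample.int(nrow(frags), 1L)] <- TRUE
  frags <- frags[keep, , drop = FALSE]
  mz <- frags$mz *
    (1 + runif(nrow(frags), -config$mzJitterPpm, config$mzJitterPpm) / 1e6)
  intensity <- rlnorm(nrow(frags), log(1000), config$intensityCV)
  if (!truth) {
    # decoy: same precursor, peak m/z shuffled to random positions so the
    # precursor-level filters stay engaged but fragments do not match
    mz <- runif(length(mz), 150, precMz * 0.95)
    nExtra <- max(4L, length(mz))
    mz <- c(mz, runif(nExtra, 150, precMz * 0.95))
    intensity <- c(intensity, rlnorm(nExtra, log(1000), config$intensityCV))
  }
  nNoise <- rbinom(1L, 50L, min(config$decoyPeakRate / 50, 1))
  if (nNoise > 0L) {
    mz <- c(mz, runif(nNoise, 150, precMz))
    # noise floor well below real fragments
    intensity <- c(intensity, rlnorm(nNoise, log(15), 0.4))
  }
  centroidSpectrum(
    precursorMz = precMz * (1 + runif(1, -1, 1) / 1e6),
    rt = runif(1, 5, 30), peaks = cbind(mz, intensity),
    precursorIntensity = 10^runif(1, 4, 6), polarity = polarity,
    precursorIsotopes = .theoreticalEnvelope(speciesFormula(species)),
    spectrumId = id)
}

#' Simulate centroided MS/MS spectra for oxidized-lipid candidates
#'
#' True spectra carry a configurable fraction of the predicted fragments
#' of their (chain-resolved) species, with ppm-scale m/z jitter and
#' log-normal intensities plus low-level noise peaks; decoy spectra keep
#' the precursor but shuffle all peak positions. Ground-truth labels are
#' returned alongside.
#'
#' @param species List of chain-resolved oxidized [LipidSpecies-class]
#'   (or shorthand names).
#' @param config [simulationConfig()].
#' @param nTrue,nDecoy Number of true and decoy spectra.
#' @param polarity Spectrum polarity.
#' @param fragmentSelector `"all"` or `"non-retaining"` (true spectra are
#'   then built exclusively from oxygen-losing fragments).
#' @return List with `spectra` (list of [CentroidSpectrum-class]) and
#'   `truth` (data.frame `spectrumId`, `species`, `isTrue`).
#' @export
simulateOxidizedSpectra <- function(species, config = simulationConfig(),
                                    nTrue = 200L, nDecoy = 200L,
                                    polarity = "positive",
                                    fragmentSelector = "all") {
  set.seed(config$seed)
  species <- lapply(species, function(s)
    if (is.character(s)) parseLipidName(s) else s)
  spectra <- vector("list", nTrue + nDecoy)
  truthRows <- vector("list", nTrue + nDecoy)
  isTrue <- c(rep(TRUE, nTrue), rep(FALSE, nDecoy))
  for (i in seq_len(nTrue + nDecoy)) {
    sp <- species[[sample.int(length(species), 1L)]]
    id <- sprintf("S%04d", i)
    spectra[[i]] <- .simulateOneSpectrum(sp, id, config, truth = isTrue[i],
                                         polarity = polarity,
                                         fragmentSelector = fragmentSelector)
    truthRows[[i]] <- data.frame(spectrumId = id,
                                 species = formatLipidName(sp),
                                 isTrue = isTrue[i], stringsAsFactors = FALSE)
  }
  list(spectra = spectra, truth = do.call(rbind, truthRows))
}

#' Simulate a PRM run with known per-transition amounts
#'
#' Each transition receives a Gaussian elution peak at its expected
#' retention time whose area is `amount * responseFactor`, sampled on a
#' regular RT grid; scans carry the isolation window of their precursor.
#'
#' @param transitions data.frame of [transition()] rows; `expectedRt`
#'   must be set.
#' @param amounts Numeric vector of true amounts, one per transition.
#' @param config [simulationConfig()].
#' @param responseFactor Area counts per amount unit.
#' @param isolationWidth Isolation window width (Th, default 1.2).
#' @param rtStep Scan spacing in minutes.
#' @param snr Optional signal-to-noise ratio; `Inf` (default) for a
#'   noiseless run. Noise is additive Gaussian on each scan with sd
#'   `peakHeight / snr`.
#' @return List with `scans` (the run), `truth` (data.frame `name`,
#'   `amount`, `area`).
#' @export
simulatePrmRun <- function(transitions, amounts,
                           config = simulationConfig(),
                           responseFactor = 1e5, isolationWidth = 1.2,
                           rtStep = 0.01, snr = Inf) {
  stopifnot(nrow(transitions) == length(amounts),
            !anyNA(transitions$expectedRt))
  set.seed(config$seed)
  scans <- list()
  for (i in seq_len(nrow(transitions))) {
    tr <- transitions[i, ]
    area <- amounts[i] * responseFactor
    sigma <- config$peakSigmaMin
    height <- area / (sigma * sqrt(2 * pi))
    rts <- seq(tr$expectedRt - 0.5, tr$expectedRt + 0.5, by = rtStep)
    for (rt in rts) {
      y <- height * exp(-(rt - tr$expectedRt)^2 / (2 * sigma^2))
      # shot-noise-like model: per-scan relative noise of 1/snr
      if (is.finite(snr) && snr > 0) y <- max(y * (1 + rnorm(1, 0, 1 / snr)), 0)
      peaks <- if (y > 0) cbind(tr$productMz, y) else
        matrix(numeric(0), 0, 2)
      scans[[length(scans) + 1L]] <- list(
        rt = rt, isolationMz = tr$precursorMz,
        isolationWidth = isolationWidth, peaks = peaks)
    }
  }
  list(scans = scans,
       truth = data.frame(name = transitions$name, amount = amounts,
                          area = amounts * responseFactor,
                          stringsAsFactors = FALSE))
}

#' Simulate a two-phase inhibited-autoxidation kinetic trace
#'
#' Lag phase with a shallow baseline drift, then linear propagation from
#' the breakpoint, plus additive Gaussian noise. In coupled mode an NADH
#' autofluorescence channel decreases linearly during the lag and reaches
#' zero exactly at the breakpoint (the lag ends when the reductant is
#' consumed).
#'
#' @param config [simulationConfig()]; `lagS`, `propagationRate` and
#'   `kineticNoiseSd` set the ground truth.
#' @param duration,dt Trace span and sampling interval (seconds).
#' @param baselineRate Signal drift during the lag (a.u./s).
#' @param signal0 Signal at t = 0 (a.u.).
#' @param coupledNadh Add the NADH channel.
#' @return List with `trace` (data.frame `time`, `signal`, and `nadh`
#'   when coupled) and `truth` (list `lagS`, `propagationRate`).
#' @export
simulateKineticTrace <- function(config = simulationConfig(),
                                 duration = 15000, dt = 30,
                                 baselineRate = 0.002, signal0 = 100,
                                 coupledNadh = FALSE) {
  set.seed(config$seed)
  time <- seq(0, duration, by = dt)
  lag <- config$lagS
  rate <- config$propagationRate
  base <- signal0 + baselineRate * pmin(time, lag)
  prop <- ifelse(time > lag, rate * (time - lag), 0)
  signal <- base + prop + rnorm(length(time), 0, config$kineticNoiseSd)
  signal <- pmax(signal, 0)
  out <- data.frame(time = time, signal = signal)
  if (coupledNadh) {
    nadh0 <- 1000
    out$nadh <- pmax(nadh0 * (1 - time / max(lag, dt)), 0) +
      rnorm(length(time), 0, config$kineticNoiseSd / 10)
    out$nadh <- pmax(out$nadh, 0)
  }
  list(trace = out, truth = list(lagS = lag, propagationRate = rate))
}
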