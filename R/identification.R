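#' Construct a centroided MS/MS spectrum
#'
#' @param precursorMz,precursorIntensity Precursor ion m/z and intensity.
#' @param rt Retention time (minutes).
#' @param polarity `"positive"` or `"negative"`.
#' @param peaks Two-column matrix or data.frame of (mz, intensity); sorted
#'   by m/z on construction.
#' @param precursorIsotopes Optional MS1 isotope envelope (monoisotopic
#'   first, up to three isotopologues).
#' @param spectrumId Identifier string.
#' @return A [CentroidSpectrum-class].
#' @export
centroidSpectrum <- function(precursorMz, rt, peaks,
                             precursorIntensity = NA_real_,
                             polarity = "positive",
                             precursorIsotopes = numeric(),
                             spectrumId = NA_character_) {
  peaks <- as.matrix(peaks)
  colnames(peaks) <- c("mz", "intensity")
  peaks <- peaks[order(peaks[, 1L]), , drop = FALSE]
  new("CentroidSpectrum", precursorMz = precursorMz,
      precursorIntensity = precursorIntensity, rt = rt,
      polarity = polarity, peaks = peaks,
      precursorIsotopes = precursorIsotopes, spectrumId = spectrumId)
}

#' Match settings for oxidized-lipid identification
#'
#' Defaults are the semi-targeted identification settings: MS1 tolerance
#' 5 ppm, MS/MS tolerance 20 ppm, minimum precursor intensity 100, peaks
#' considered when above 1 percent of the base peak, score > 60, isotope
#' score > 80, rank score > 40 (all strict).
#'
#' @param ms1TolPpm,ms2TolPpm Mass tolerances in ppm.
#' @param minPrecursorIntensity Precursor intensity floor.
#' @param minRelPeakIntensity Relative peak intensity floor (fraction of
#'   base peak).
#' @param scoreMin,isotopeScoreMin,rankScoreMin Acceptance thresholds in
#'   `[0, 100]`.
#' @return A named list of validated settings.
#' @export
matchSettings <- function(ms1TolPpm = 5, ms2TolPpm = 20,
                          minPrecursorIntensity = 100,
                          minRelPeakIntensity = 0.01, scoreMin = 60,
                          isotopeScoreMin = 80, rankScoreMin = 40) {
  stopifnot(ms1TolPpm > 0, ms2TolPpm > 0,
            all(c(scoreMin, isotopeScoreMin, rankScoreMin) >= 0),
            all(c(scoreMin, isotopeScoreMin, rankScoreMin) <= 100))
  list(ms1TolPpm = ms1TolPpm, ms2TolPpm = ms2TolPpm,
       minPrecursorIntensity = minPrecursorIntensity,
       minRelPeakIntensity = minRelPeakIntensity, scoreMin = scoreMin,
       isotopeScoreMin = isotopeScoreMin, rankScoreMin = rankScoreMin)
}

# theoretical relative abundances of the first three isotopologues,
# dominated by 13C with small 2H/15N/17O/18O/33S/34S contributions
.theoreticalEnvelope <- function(formula) {
  if (is.character(formula)) formula <- parseFormula(formula)
  n <- formula@counts
  p1 <- n[["C"]] * 0.010756 + n[["H"]] * 0.000115 + n[["N"]] * 0.003653 +
    n[["O"]] * 0.000381 + n[["S"]] * 0.007893
  p2 <- p1^2 / 2 + n[["O"]] * 0.0020514 + n[["S"]] * 0.044163
  env <- c(1, p1, p2)
  env / sum(env)
}

.cosineSimilarity <- function(a, b) {
  k <- min(length(a), length(b))
  a <- a[seq_len(k)]; b <- b[seq_len(k)]
  if (sum(a) == 0 || sum(b) == 0) return(0)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

.emptyIdFrame <- function() {
  empty <- data.frame(spectrumId = character(0), species = character(0),
                      adduct = character(0), theoreticalMz = numeric(0),
                      score = numeric(0), isotopeScore = numeric(0),
                      rankScore = numeric(0), nMatched = integer(0),
                      hasOxygenRetainingFragment = logical(0),
                      accepted = logical(0), reason = character(0))
  empty$matched <- list()
  empty
}

# precompute per-candidate formula, theoretical precursor m/z and
# predicted fragments so batch matching does the expensive prediction once
.prepareCandidates <- function(candidates, polarity,
                               precursorAdduct = NULL) {
  prepared <- lapply(candidates, function(cand) {
    sp <- if (is.character(cand)) parseLipidName(cand) else cand
    ad <- if (is.null(precursorAdduct)) .candidateAdduct(sp, polarity)
          else precursorAdduct
    f <- speciesFormula(sp)
    list(species = sp, name = formatLipidName(sp), adduct = ad,
         formula = f, theoMz = adductMz(f, ad),
         frags = predictFragments(sp, ad, polarity),
         envelope = .theoreticalEnvelope(f))
  })
  attr(prepared, "polarity") <- polarity
  class(prepared) <- "preparedCandidates"
  prepared
}

# score one prepared candidate against a filtered peak list; returns NULL
# when the precursor does not match
.scoreCandidate <- function(spectrum, prep, settings, peaks) {
  theoMz <- prep$theoMz
  ppmOff <- abs(spectrum@precursorMz - theoMz) / theoMz * 1e6
  if (ppmOff > settings$ms1TolPpm) return(NULL)
  frags <- prep$frags
  nPeaks <- nrow(peaks)
  matchedPeak <- integer(0)
  matchedIdx <- logical(nrow(frags))
  for (i in seq_len(nrow(frags))) {
    tol <- frags$mz[i] * settings$ms2TolPpm / 1e6
    d <- abs(peaks[, 1L] - frags$mz[i])
    j <- which.min(d)
    if (length(j) && d[j] <= tol) {
      matchedIdx[i] <- TRUE
      matchedPeak[i] <- j
    } else matchedPeak[i] <- NA_integer_
  }
  matched <- frags[matchedIdx, , drop = FALSE]
  matchedPeaks <- matchedPeak[matchedIdx]
  fracFragments <- mean(matchedIdx)
  totalInt <- sum(peaks[, 2L])
  fracSignal <- if (totalInt > 0)
    sum(peaks[unique(matchedPeaks[!is.na(matchedPeaks)]), 2L]) / totalInt
  else 0
  score <- 100 * (0.5 * fracFragments + 0.5 * fracSignal)
  isoScore <- if (length(spectrum@precursorIsotopes) >= 2L)
    100 * .cosineSimilarity(spectrum@precursorIsotopes, prep$envelope)
  else 100
  rankScore <- if (length(matchedPeaks) && nPeaks > 0) {
    rk <- rank(-peaks[, 2L], ties.method = "first")
    100 * mean(1 - (rk[matchedPeaks] - 1) / nPeaks)
  } else 0
  list(species = prep$name, adduct = prep$adduct@name,
       theoreticalMz = theoMz, score = score, isotopeScore = isoScore,
       rankScore = rankScore, matched = matched)
}

#' Match one MS/MS spectrum against oxidized-lipid candidates
#'
#' Candidates whose theoretical precursor m/z lies within the MS1 tolerance
#' of the spectrum precursor (and whose precursor intensity passes the
#' floor) are scored against their predicted fragments using peaks above
#' the relative-intensity floor. Three scores in `[0, 100]` are computed:
#' `score` (intensity-weighted fraction of predicted fragments matched:
#' mean of the matched-fragment fraction and the fraction of considered
#' signal explained), `isotopeScore` (cosine similarity of the observed
#' and theoretical precursor isotope envelopes over the first three
#' isotopologues; 100 when no envelope was recorded) and `rankScore`
#' (mean normalized intensity rank of the matched peaks). A candidate is
#' accepted when all three exceed their thresholds strictly; the oxidized
#' fatty acid evidence rule is applied separately by
#' [oxfaEvidenceFilter()].
#'
#' @param spectrum A [CentroidSpectrum-class].
#' @param candidates List of oxidized [LipidSpecies-class] (or names).
#' @param settings [matchSettings()].
#' @param precursorAdduct Optional [Adduct-class]/name applied to all
#'   candidates (default: sodiated in positive, deprotonated in negative
#'   mode).
#' @return data.frame with one row per engaging candidate: `spectrumId`,
#'   `species`, `adduct`, `theoreticalMz`, `score`, `isotopeScore`,
#'   `rankScore`, `nMatched`, `hasOxygenRetainingFragment`, `accepted`,
#'   `reason`, plus a list-column `matched` of matched fragment
#'   annotations. Rows are sorted by decreasing score.
#' @export
matchSpectrum <- function(spectrum, candidates,
                          settings = matchSettings(),
                          precursorAdduct = NULL) {
  stopifnot(is(spectrum, "CentroidSpectrum"))
  empty <- .emptyIdFrame()
  if (!is.na(spectrum@precursorIntensity) &&
      spectrum@precursorIntensity < settings$minPrecursorIntensity)
    return(empty)
  peaks <- spectrum@peaks
  if (nrow(peaks) == 0L) return(empty)
  base <- max(peaks[, 2L])
  peaks <- peaks[peaks[, 2L] > settings$minRelPeakIntensity * base, ,
                 drop = FALSE]
  if (nrow(peaks) == 0L) return(empty)
  if (is.character(precursorAdduct)) precursorAdduct <- adduct(precursorAdduct)
  if (!inherits(candidates, "preparedCandidates"))
    candidates <- .prepareCandidates(candidates, spectrum@polarity,
                                     precursorAdduct)
  else if (!identical(attr(candidates, "polarity"), spectrum@polarity))
    stop("prepared candidates have polarity ", attr(candidates, "polarity"),
         " but the spectrum is ", spectrum@polarity)

  rows <- list()
  for (prep in candidates) {
    res <- .scoreCandidate(spectrum, prep, settings, peaks)
    if (is.null(res)) next
    scoresPass <- res$score > settings$scoreMin &&
      res$isotopeScore > settings$isotopeScoreMin &&
      res$rankScore > settings$rankScoreMin
    row <- data.frame(
      spectrumId = spectrum@spectrumId, species = res$species,
      adduct = res$adduct, theoreticalMz = res$theoreticalMz,
      score = res$score, isotopeScore = res$isotopeScore,
      rankScore = res$rankScore, nMatched = nrow(res$matched),
      hasOxygenRetainingFragment = any(res$matched$retainsAddedOxygen),
      accepted = scoresPass,
      reason = if (scoresPass) "scores-pass" else "score-below-threshold",
      stringsAsFactors = FALSE)
    row$matched <- list(res$matched)
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match many spectra against a shared candidate list
#'
#' Batch version of [matchSpectrum()]: candidate formulas, precursor m/z
#' and predicted fragments are computed once and reused across spectra.
#' All spectra must share one polarity.
#'
#' @param spectra List of [CentroidSpectrum-class] objects.
#' @inheritParams matchSpectrum
#' @return Row-bound identification data.frame (see [matchSpectrum()]).
#' @export
matchSpectra <- function(spectra, candidates, settings = matchSettings(),
                         precursorAdduct = NULL) {
  if (!length(spectra)) return(.emptyIdFrame())
  pol <- unique(vapply(spectra, function(s) s@polarity, character(1)))
  if (length(pol) != 1L)
    stop("all spectra must share one polarity; got: ",
         paste(pol, collapse = ", "))
  if (is.character(precursorAdduct)) precursorAdduct <- adduct(precursorAdduct)
  prep <- .prepareCandidates(candidates, pol, precursorAdduct)
  out <- do.call(rbind, lapply(spectra, matchSpectrum, candidates = prep,
                               settings = settings))
  rownames(out) <- NULL
  out
}

#' Oxidized fatty acid evidence filter
#'
#' An identification is retained only when at least one matched fragment
#' retains an oxygen added by the modification set (intact oxidized fatty
#' acid adducts, or water-loss fragments that keep at least one added
#' oxygen). Identifications evidenced solely by oxygen-losing fragments
#' cannot confirm a fatty acid-specific modification and are rejected with
#' a reason code.
#'
#' @param ids Identification data.frame from [matchSpectrum()].
#' @return The same data.frame with `accepted` and `reason` updated.
#' @export
oxfaEvidenceFilter <- function(ids) {
  if (!nrow(ids)) return(ids)
  hasEvidence <- vapply(ids$matched, function(m)
    nrow(m) > 0L && any(m$retainsAddedOxygen), logical(1))
  reject <- ids$accepted & !hasEvidence
  ids$accepted[reject] <- FALSE
  ids$reason[reject] <- "no-oxygen-retaining-fragment"
  ids$hasOxygenRetainingFragment <- hasEvidence
  ids
}

# least-absolute-deviations line fit (intercept, slope)
.ladFit <- function(x, y) {
  ols <- coef(lm(y ~ x))
  obj <- function(b) sum(abs(y - b[1] - b[2] * x))
  fit <- optim(ols, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  fit$par
}

#' Kendrick mass defect vs retention time false-positive filter
#'
#' Within each homologous series (same lipid class, modification set and
#' double-bond count) the Kendrick mass defect is a linear function of
#' retention time; members that deviate are flagged as false positives.
#' The fit is a least-absolute-deviations line; residuals are studentized
#' with a MAD-based scale. Groups with fewer than `minGroupSize` members
#' pass unflagged.
#'
#' @param ids data.frame with columns `species`, `mz`, `rt`.
#' @param residualThreshold Flag members with |studentized residual| above
#'   this value (default 3).
#' @param minGroupSize Minimum series size for fitting (default 3).
#' @return The input with columns `seriesKey`, `kendrickMassDefect`,
#'   `residual` and logical `flagged` appended.
#' @export
kmdRtFilter <- function(ids, residualThreshold = 3, minGroupSize = 3L) {
  stopifnot(all(c("species", "mz", "rt") %in% names(ids)))
  if (!nrow(ids)) {
    ids$seriesKey <- character(0); ids$kendrickMassDefect <- numeric(0)
    ids$residual <- numeric(0); ids$flagged <- logical(0)
    return(ids)
  }
  key <- vapply(ids$species, function(s) {
    sp <- parseLipidName(s)
    paste(sp@lipidClass, formatModifications(sp@modifications),
          sp@totalDoubleBonds, sep = "|")
  }, character(1))
  ids$seriesKey <- unname(key)
  ids$kendrickMassDefect <- kendrickMassDefect(ids$mz)$kendrickMassDefect
  ids$residual <- NA_real_
  ids$flagged <- FALSE
  for (g in unique(ids$seriesKey)) {
    idx <- which(ids$seriesKey == g)
    if (length(idx) < minGroupSize) next
    b <- .ladFit(ids$rt[idx], ids$kendrickMassDefect[idx])
    res <- ids$kendrickMassDefect[idx] - b[1] - b[2] * ids$rt[idx]
    sigma <- max(mad(res, center = 0), 1e-9 * max(1, mad(ids$kendrickMassDefect[idx])))
    stud <- res / sigma
    ids$residual[idx] <- stud
    ids$flagged[idx] <- abs(stud) > residualThreshold
  }
  ids
}

#' Collapse isomeric identifications to unique m/z targets
#'
#' Identifications are grouped by m/z within a ppm tolerance (greedy,
#' ascending m/z); each group keeps its highest-scoring member as the
#' representative target.
#'
#' @param ids data.frame with at least `theoreticalMz` (or `mz`) and
#'   `score` columns.
#' @param mzTolPpm Grouping tolerance in ppm (default 5).
#' @return data.frame of unique-m/z representatives with an added
#'   `nCollapsed` column; sorted by m/z.
#' @export
collapseIsomers <- function(ids, mzTolPpm = 5) {
  if (!nrow(ids)) {
    ids$nCollapsed <- integer(0)
    return(ids)
  }
  mzCol <- if ("theoreticalMz" %in% names(ids)) "theoreticalMz" else "mz"
  if (!"score" %in% names(ids)) ids$score <- 0
  ids <- ids[order(ids[[mzCol]]), , drop = FALSE]
  group <- integer(nrow(ids))
  gid <- 0L
  seedMz <- -Inf
  for (i in seq_len(nrow(ids))) {
    if ((ids[[mzCol]][i] - seedMz) / ids[[mzCol]][i] * 1e6 > mzTolPpm) {
      gid <- gid + 1L
      seedMz <- ids[[mzCol]][i]
    }
    group[i] <- gid
  }
  rows <- lapply(split(seq_len(nrow(ids)), group), function(idx) {
    top <- idx[which.max(ids$score[idx])]
    out <- ids[top, , drop = FALSE]
    out$nCollapsed <- length(idx)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
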