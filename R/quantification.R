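#' Extract an ion chromatogram from a centroided run
#'
#' Per scan, the summed intensity of all peaks within the symmetric ppm
#' tolerance of the target m/z; scans with no matching peak contribute 0.
#'
#' @param run A list of scans; each scan is a list with elements `rt`
#'   (minutes) and `peaks` (two-column mz/intensity matrix). PRM runs (see
#'   [simulatePrmRun()]) additionally carry `isolationMz`/`isolationWidth`.
#' @param targetMz Target m/z.
#' @param tolPpm Extraction tolerance in ppm (default 5, the mass accuracy
#'   used for extracted ion chromatogram generation).
#' @return A [Chromatogram-class].
#' @export
extractXic <- function(run, targetMz, tolPpm = 5) {
  scans <- if (!is.null(run$scans)) run$scans else run
  rt <- vapply(scans, function(s) s$rt, numeric(1))
  ord <- order(rt)
  scans <- scans[ord]
  tol <- targetMz * tolPpm / 1e6
  intensity <- vapply(scans, function(s) {
    p <- s$peaks
    if (is.null(p) || nrow(p) == 0L) return(0)
    sum(p[abs(p[, 1L] - targetMz) <= tol, 2L])
  }, numeric(1))
  new("Chromatogram", rt = rt[ord], intensity = intensity,
      targetMz = targetMz, tolPpm = tolPpm)
}

#' Integrate a chromatographic peak
#'
#' Trapezoidal area above a local linear baseline drawn between the
#' endpoints of the integration window; negative baseline-corrected area
#' is clipped at zero.
#'
#' @param chrom A [Chromatogram-class].
#' @param window Numeric length-2 RT interval (minutes).
#' @return Area (intensity x minutes), >= 0.
#' @export
integratePeak <- function(chrom, window = range(chrom@rt)) {
  stopifnot(is(chrom, "Chromatogram"), length(window) == 2L)
  idx <- which(chrom@rt >= window[1] & chrom@rt <= window[2])
  if (length(idx) < 2L)
    stop("integration window contains fewer than two chromatogram points")
  t <- chrom@rt[idx]
  y <- chrom@intensity[idx]
  n <- length(t)
  baseline <- y[1] + (y[n] - y[1]) * (t - t[1]) / (t[n] - t[1])
  yc <- y - baseline
  area <- sum(diff(t) * (yc[-1] + yc[-n]) / 2)
  max(area, 0)
}

#' Define a PRM transition
#'
#' @param precursorMz,productMz Transition m/z pair (both > 0).
#' @param precursorAdduct,productAdduct Adduct names (metadata).
#' @param name Transition label.
#' @param expectedRt Expected retention time in minutes (optional; used to
#'   centre the integration window).
#' @param collisionEnergy Metadata.
#' @param tolPpm Quantification mass accuracy on the centroided fragment
#'   signal (default 5).
#' @return A one-row data.frame.
#' @export
transition <- function(name, precursorMz, productMz,
                       precursorAdduct = NA_character_,
                       productAdduct = NA_character_,
                       expectedRt = NA_real_, collisionEnergy = NA_real_,
                       tolPpm = 5) {
  stopifnot(precursorMz > 0, productMz > 0)
  data.frame(name = name, precursorMz = precursorMz, productMz = productMz,
             precursorAdduct = precursorAdduct,
             productAdduct = productAdduct, expectedRt = expectedRt,
             collisionEnergy = collisionEnergy, tolPpm = tolPpm,
             stringsAsFactors = FALSE)
}

#' PRM relative quantification
#'
#' For each transition, the product-ion chromatogram is extracted from the
#' scans whose isolation window contains the precursor m/z and integrated
#' over a window around the expected retention time (the full trace when
#' no expected RT is given). Transitions with no matching isolation are
#' flagged, not fatal.
#'
#' @param run A PRM run: list with `scans`, each scan carrying
#'   `isolationMz`, `isolationWidth`, `rt`, `peaks`.
#' @param transitions data.frame of [transition()] rows.
#' @param rtHalfWindow Integration half-window in minutes around the
#'   expected RT (default 0.5).
#' @return data.frame with columns `name`, `area`, `nScans`, `flag`.
#' @export
prmQuantify <- function(run, transitions, rtHalfWindow = 0.5) {
  scans <- if (!is.null(run$scans)) run$scans else run
  rows <- lapply(seq_len(nrow(transitions)), function(i) {
    tr <- transitions[i, ]
    sel <- vapply(scans, function(s) {
      !is.null(s$isolationMz) &&
        abs(s$isolationMz - tr$precursorMz) <= s$isolationWidth / 2
    }, logical(1))
    if (!any(sel))
      return(data.frame(name = tr$name, area = NA_real_, nScans = 0L,
                        flag = "no-matching-isolation",
                        stringsAsFactors = FALSE))
    chrom <- extractXic(scans[sel], tr$productMz, tr$tolPpm)
    window <- if (is.na(tr$expectedRt)) range(chrom@rt)
      else c(tr$expectedRt - rtHalfWindow, tr$expectedRt + rtHalfWindow)
    window <- c(max(window[1], min(chrom@rt)), min(window[2], max(chrom@rt)))
    data.frame(name = tr$name, area = integratePeak(chrom, window),
               nScans = sum(sel), flag = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalize analyte areas to class internal standards
#'
#' Every quantified lipid class must be mapped to an internal standard
#' area (e.g. the class-specific deuterated standard of a SPLASH mix) or
#' explicitly flagged `unnormalized`; the normalized value is the exact
#' area ratio, so global intensity rescaling cancels.
#'
#' @param areas data.frame with columns `name`, `class`, `area`.
#' @param standards data.frame with columns `class`, `standardArea`, and
#'   optionally logical `unnormalized`.
#' @return `areas` with a `normalized` column appended.
#' @export
normalizeToInternalStandard <- function(areas, standards) {
  stopifnot(all(c("name", "class", "area") %in% names(areas)),
            all(c("class", "standardArea") %in% names(standards)))
  if (!"unnormalized" %in% names(standards))
    standards$unnormalized <- FALSE
  i <- match(areas$class, standards$class)
  if (anyNA(i))
    stop("no internal-standard mapping for class(es): ",
         paste(unique(areas$class[is.na(i)]), collapse = ", "))
  stdArea <- standards$standardArea[i]
  skip <- standards$unnormalized[i]
  if (any(!skip & (is.na(stdArea) | stdArea <= 0)))
    stop("internal-standard areas must be positive")
  areas$normalized <- ifelse(skip, areas$area, areas$area / stdArea)
  areas
}

#' Normalize per-sample values to protein concentration
#'
#' @param values Numeric vector or matrix (samples in columns).
#' @param protein Positive protein concentrations, one per sample; units
#'   propagate as value per protein unit.
#' @return Normalized values of the same shape.
#' @export
normalizeToProtein <- function(values, protein) {
  if (any(!is.finite(protein)) || any(protein <= 0))
    stop("protein concentrations must be positive")
  if (is.matrix(values)) {
    stopifnot(ncol(values) == length(protein))
    sweep(values, 2L, protein, "/")
  } else {
    stopifnot(length(values) == length(protein) || length(protein) == 1L)
    values / protein
  }
}

#' Isotope-dilution absolute amount
#'
#' The analyte peak area divided by the co-analysed stable-isotope
#' standard area, multiplied by the known spiked standard amount (e.g.
#' 2.5 pmol of hexadeuterated coenzyme Q10 per sample).
#'
#' @param analyteArea,standardArea Peak areas; standard must be > 0.
#' @param standardAmount Spiked amount (unit carried through).
#' @return Absolute amount in the standard's unit.
#' @export
isotopeDilutionAmount <- function(analyteArea, standardArea,
                                  standardAmount) {
  if (any(!is.finite(standardArea)) || any(standardArea <= 0))
    stop("standard area must be positive")
  (analyteArea / standardArea) * standardAmount
}

#' Coenzyme Q redox metrics
#'
#' @param amountCoQ Oxidized quinone amount.
#' @param amountCoQH2 Reduced quinol amount.
#' @param neutralLipidAmount Optional neutral lipid amount in the same
#'   molar unit; yields the quinone-per-neutral-lipid mole ratio.
#' @return List with `total`, `fractionReduced` and (when a neutral lipid
#'   amount is given) `coqPerNeutralLipid`.
#' @export
coqRedoxMetrics <- function(amountCoQ, amountCoQH2,
                            neutralLipidAmount = NA_real_) {
  total <- amountCoQ + amountCoQH2
  if (total <= 0)
    stop("total quinone amount is zero; reduced fraction undefined")
  out <- list(total = total, fractionReduced = amountCoQH2 / total)
  if (!is.na(neutralLipidAmount))
    out$coqPerNeutralLipid <- total / neutralLipidAmount
  out
}
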