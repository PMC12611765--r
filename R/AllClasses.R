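#' @import methods
#' @importFrom stats approx cor cor.test cutree dist hclust lm mad median
#'   optim p.adjust pt qt quantile rbinom residuals rlnorm rnorm runif sd
#'   setNames coef
#' @importFrom utils head read.csv write.csv tail
NULL

#' ElementalFormula: integer element counts
#'
#' An elemental composition over the supported element set (C, H, D, N, O,
#' P, Na, S). Deuterium is treated as its own element symbol so that
#' isotopically labelled standards (e.g. hexadeuterated coenzyme Q10) carry
#' exact masses. All counts are non-negative integers; arithmetic is
#' element-wise and subtraction below zero is an error.
#'
#' @slot counts Named integer vector, one entry per supported element.
#' @seealso [elementalFormula()], [parseFormula()], [monoisotopicMass()]
#' @export
setClass("ElementalFormula",
  representation(counts = "integer"),
  prototype(counts = setNames(integer(length(.SUPPORTED_ELEMENTS)),
                              .SUPPORTED_ELEMENTS)))

setValidity("ElementalFormula", function(object) {
  cnt <- object@counts
  if (!identical(names(cnt), .SUPPORTED_ELEMENTS))
    return(sprintf("counts must be named exactly: %s",
                   paste(.SUPPORTED_ELEMENTS, collapse = ", ")))
  if (anyNA(cnt) || any(cnt < 0L))
    return("element counts must be non-negative integers")
  TRUE
})

#' Adduct: ionization adduct description
#'
#' Describes how a neutral molecule M becomes the measured ion: atoms
#' gained, atoms lost, signed charge, and the electron-mass convention used
#' when converting ion mass to m/z. Under the `"proton"` convention the
#' electron mass is accounted for (physically correct, e.g. [M+H]+ adds
#' 1.007276 Da); under `"hydrogen"` the neutral hydrogen-atom mass is added
#' instead (a convention used by some instrument software).
#'
#' @slot name Display name, e.g. `"[M+H]+"`.
#' @slot gain,loss `ElementalFormula` gained/lost by the molecule.
#' @slot charge Signed integer charge, non-zero.
#' @slot electronConvention `"proton"` or `"hydrogen"`.
#' @seealso [adduct()], [adductMz()]
#' @export
setClass("Adduct",
  representation(name = "character", gain = "ElementalFormula",
                 loss = "ElementalFormula", charge = "integer",
                 electronConvention = "character"),
  prototype(electronConvention = "proton"))

setValidity("Adduct", function(object) {
  if (length(object@charge) != 1L || object@charge == 0L)
    return("charge must be a single non-zero integer")
  if (!object@electronConvention %in% c("proton", "hydrogen"))
    return("electronConvention must be 'proton' or 'hydrogen'")
  TRUE
})

#' ModificationSet: oxidation modifications on a lipid or acyl chain
#'
#' Counts of hydroxyl (`<OH>`), keto (`<oxo>`), hydroperoxyl (`<OOH>`) and
#' epoxy (`<epoxy>`) groups. The added-oxygen accounting is
#' nOH + nOxo + 2*nOOH + nEpoxy; the number of modification sites is
#' nOH + nOxo + nOOH + nEpoxy.
#'
#' @slot nOH,nOxo,nOOH,nEpoxy Non-negative integer counts.
#' @seealso [modificationSet()], [addedOxygens()], [nModificationSites()]
#' @export
setClass("ModificationSet",
  representation(nOH = "integer", nOxo = "integer", nOOH = "integer",
                 nEpoxy = "integer"),
  prototype(nOH = 0L, nOxo = 0L, nOOH = 0L, nEpoxy = 0L))

setValidity("ModificationSet", function(object) {
  v <- c(object@nOH, object@nOxo, object@nOOH, object@nEpoxy)
  if (length(v) != 4L || anyNA(v) || any(v < 0L))
    return("all modification counts must be single non-negative integers")
  TRUE
})

#' FattyAcyl: one fatty acyl/alkyl/alkenyl chain
#'
#' @slot carbons Integer >= 2.
#' @slot doubleBonds Integer >= 0, at most carbons - 2.
#' @slot bondType `"acyl"` (ester), `"ether"` (O-alkyl) or `"vinyl"`
#'   (O-alk-1-enyl, plasmalogen).
#' @slot modifications A `ModificationSet`.
#' @export
setClass("FattyAcyl",
  representation(carbons = "integer", doubleBonds = "integer",
                 bondType = "character", modifications = "ModificationSet"),
  prototype(bondType = "acyl", modifications = new("ModificationSet")))

setValidity("FattyAcyl", function(object) {
  if (object@carbons < 2L) return("carbons must be >= 2")
  if (object@doubleBonds < 0L) return("doubleBonds must be >= 0")
  if (object@doubleBonds > object@carbons - 2L)
    return("doubleBonds must be <= carbons - 2")
  if (!object@bondType %in% c("acyl", "ether", "vinyl"))
    return("bondType must be 'acyl', 'ether' or 'vinyl'")
  TRUE
})

#' LipidSpecies: a parsed shorthand lipid
#'
#' Either chain-resolved (a list of `FattyAcyl`) or species-level (total
#' carbons and double bonds only, sum composition). Oxidation modifications
#' may sit at species level (the `modifications` slot) or on individual
#' chains; when chains are given the species-level totals always equal the
#' chain sums. Named compounds (CoQ10, vitamin K1, ...) are represented with
#' `lipidClass = "compound"` and a fixed formula looked up by `compound`.
#'
#' @slot lipidClass Class token, e.g. `"TG"`, `"O-PC"`, `"FA"`, `"compound"`.
#' @slot chains List of `FattyAcyl` (may be empty for species level).
#' @slot totalCarbons,totalDoubleBonds Sum composition.
#' @slot modifications Species-level `ModificationSet`.
#' @slot snKnown `TRUE` when chain positions were given with `/`.
#' @slot compound Named-compound key or `NA`.
#' @seealso [parseLipidName()], [formatLipidName()], [speciesFormula()]
#' @export
setClass("LipidSpecies",
  representation(lipidClass = "character", chains = "list",
                 totalCarbons = "integer", totalDoubleBonds = "integer",
                 modifications = "ModificationSet", snKnown = "logical",
                 compound = "character"),
  prototype(chains = list(), modifications = new("ModificationSet"),
            snKnown = FALSE, compound = NA_character_))

setValidity("LipidSpecies", function(object) {
  if (length(object@lipidClass) != 1L) return("lipidClass must be scalar")
  if (length(object@chains)) {
    ok <- vapply(object@chains, is, logical(1), class2 = "FattyAcyl")
    if (!all(ok)) return("chains must all be FattyAcyl objects")
    if (sum(vapply(object@chains, slot, integer(1), "carbons")) !=
        object@totalCarbons)
      return("totalCarbons must equal the chain sum")
    if (sum(vapply(object@chains, slot, integer(1), "doubleBonds")) !=
        object@totalDoubleBonds)
      return("totalDoubleBonds must equal the chain sum")
  }
  TRUE
})

#' CentroidSpectrum: a centroided MS/MS spectrum
#'
#' @slot precursorMz,precursorIntensity Precursor ion m/z and intensity.
#' @slot rt Retention time in minutes.
#' @slot polarity `"positive"` or `"negative"`.
#' @slot peaks Two-column numeric matrix (mz, intensity), sorted by m/z.
#' @slot precursorIsotopes Optional MS1 isotope envelope intensities
#'   (monoisotopic first); empty when not recorded.
#' @slot spectrumId Identifier carried through identification output.
#' @export
setClass("CentroidSpectrum",
  representation(precursorMz = "numeric", precursorIntensity = "numeric",
                 rt = "numeric", polarity = "character", peaks = "matrix",
                 precursorIsotopes = "numeric", spectrumId = "character"),
  prototype(precursorIntensity = NA_real_, precursorIsotopes = numeric(),
            spectrumId = NA_character_))

setValidity("CentroidSpectrum", function(object) {
  p <- object@peaks
  if (ncol(p) != 2L) return("peaks must be a two-column (mz, intensity) matrix")
  if (nrow(p) && is.unsorted(p[, 1L])) return("peaks must be sorted by m/z")
  if (nrow(p) && any(p[, 2L] < 0)) return("peak intensities must be >= 0")
  if (!object@polarity %in% c("positive", "negative"))
    return("polarity must be 'positive' or 'negative'")
  TRUE
})

#' Chromatogram: an extracted ion chromatogram
#'
#' @slot rt Retention times in minutes, strictly increasing.
#' @slot intensity Non-negative intensities, same length as `rt`.
#' @slot targetMz Target m/z the trace was extracted for.
#' @slot tolPpm Extraction tolerance in ppm.
#' @export
setClass("Chromatogram",
  representation(rt = "numeric", intensity = "numeric",
                 targetMz = "numeric", tolPpm = "numeric"))

setValidity("Chromatogram", function(object) {
  if (length(object@rt) != length(object@intensity))
    return("rt and intensity must have equal length")
  if (length(object@rt) > 1L && any(diff(object@rt) <= 0))
    return("rt must be strictly increasing")
  if (any(object@intensity < 0)) return("intensities must be >= 0")
  TRUE
})

#' OxidationConstraints: combinatorial limits for in silico oxidation
#'
#' Defaults mirror the prediction settings used for the semi-targeted
#' workflow: at most 2 modification sites, at most 3 added oxygens, at most
#' 2 hydroxyls, 1 keto, 1 hydroperoxyl and no epoxides.
#'
#' @slot maxModSites,maxTotalO,maxOH,maxOxo,maxOOH,maxEpoxy Non-negative
#'   integer caps.
#' @seealso [oxidationConstraints()], [enumerateModificationSets()]
#' @export
setClass("OxidationConstraints",
  representation(maxModSites = "integer", maxTotalO = "integer",
                 maxOH = "integer", maxOxo = "integer", maxOOH = "integer",
                 maxEpoxy = "integer"),
  prototype(maxModSites = 2L, maxTotalO = 3L, maxOH = 2L, maxOxo = 1L,
            maxOOH = 1L, maxEpoxy = 0L))

setValidity("OxidationConstraints", function(object) {
  v <- c(object@maxModSites, object@maxTotalO, object@maxOH, object@maxOxo,
         object@maxOOH, object@maxEpoxy)
  if (anyNA(v) || any(v < 0L)) return("all constraint caps must be >= 0")
  TRUE
})

setMethod("show", "ElementalFormula", function(object) {
  cat("ElementalFormula:", formatFormula(object), "\n")
})

setMethod("show", "Adduct", function(object) {
  cat(sprintf("Adduct %s (charge %+d, %s convention)\n", object@name,
              object@charge, object@electronConvention))
})

setMethod("show", "ModificationSet", function(object) {
  cat("ModificationSet:",
      if (nModificationSites(object) == 0L) "(none)"
      else formatModifications(object), "\n")
})

setMethod("show", "LipidSpecies", function(object) {
  cat("LipidSpecies:", formatLipidName(object), "\n")
})

setMethod("show", "CentroidSpectrum", function(object) {
  cat(sprintf(
    "CentroidSpectrum %s: precursor m/z %.4f (%s), RT %.2f min, %d peaks\n",
    object@spectrumId, object@precursorMz, object@polarity, object@rt,
    nrow(object@peaks)))
})

setMethod("show", "Chromatogram", function(object) {
  cat(sprintf("Chromatogram for m/z %.4f (+/- %g ppm): %d points, RT %.2f-%.2f min\n",
              object@targetMz, object@tolPpm, length(object@rt),
              if (length(object@rt)) min(object@rt) else NA_real_,
              if (length(object@rt)) max(object@rt) else NA_real_))
})

setMethod("show", "OxidationConstraints", function(object) {
  cat(sprintf(
    "OxidationConstraints: sites<=%d, totalO<=%d, OH<=%d, oxo<=%d, OOH<=%d, epoxy<=%d\n",
    object@maxModSites, object@maxTotalO, object@maxOH, object@maxOxo,
    object@maxOOH, object@maxEpoxy))
})
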