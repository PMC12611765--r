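#' Kendrick mass and Kendrick mass defect
#'
#' Rescales m/z so that the repeating base unit (CH2 by default) has integer
#' mass: KM = mz * nominal(base) / exact(base). The defect is
#' nominal(KM) - KM with nominal(KM) = round(KM), so homologues differing
#' by the base unit share a defect and the defect lies in (-0.5, 0.5].
#'
#' @param mz Positive m/z value(s).
#' @param base Repeating-unit formula (string or [ElementalFormula-class]),
#'   default CH2.
#' @return A data.frame with columns `kendrickMass` and `kendrickMassDefect`.
#' @examples
#' kendrickMassDefect(14.01565)  # one CH2: KM 14, defect 0
#' @export
kendrickMassDefect <- function(mz, base = "CH2") {
  if (any(!is.finite(mz)) || any(mz <= 0)) stop("mz must be positive")
  if (is.character(base)) base <- parseFormula(base)
  exact <- monoisotopicMass(base)
  nominal <- sum(base@counts * round(.MONOISOTOPIC_MASS[names(base@counts)]))
  km <- mz * nominal / exact
  kmd <- round(km) - km
  # round() maps KM - round(KM) into [-0.5, 0.5); the defect is the negative
  # of that, already in (-0.5, 0.5]
  data.frame(kendrickMass = km, kendrickMassDefect = kmd)
}
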