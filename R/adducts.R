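# Registry of the adducts used across the workflows. gain/loss are atom
# strings; charge is signed.
.ADDUCT_REGISTRY <- list(
  "[M+H]+"      = list(gain = "H",    loss = "",    charge = +1L),
  "[M+NH4]+"    = list(gain = "NH4",  loss = "",    charge = +1L),
  "[M+Na]+"     = list(gain = "Na",   loss = "",    charge = +1L),
  "[M-H]-"      = list(gain = "",     loss = "H",   charge = -1L),
  "[M+H-H2O]+"  = list(gain = "H",    loss = "H2O", charge = +1L)
)

#' Construct an adduct
#'
#' Known adduct names: `[M+H]+`, `[M+NH4]+`, `[M+Na]+`, `[M-H]-`,
#' `[M+H-H2O]+`. Unicode minus signs are normalised to ASCII.
#'
#' @param name Adduct name, e.g. `"[M+Na]+"`.
#' @param electronConvention `"proton"` (default; subtracts the electron
#'   mass per positive charge so that [M+H]+ adds exactly the proton mass)
#'   or `"hydrogen"` (adds the neutral hydrogen-atom mass; reproduces
#'   values printed by software that ignores the electron).
#' @return An [Adduct-class] object.
#' @examples
#' adduct("[M+H]+")
#' adduct("[M+NH4]+")
#' @export
adduct <- function(name, electronConvention = c("proton", "hydrogen")) {
  electronConvention <- match.arg(electronConvention)
  key <- gsub("−|–", "-", name)
  entry <- .ADDUCT_REGISTRY[[key]]
  if (is.null(entry)) stop("unknown adduct: ", name)
  new("Adduct", name = key, gain = parseFormula(entry$gain),
      loss = parseFormula(entry$loss), charge = entry$charge,
      electronConvention = electronConvention)
}

#' Adduct m/z of a neutral molecule
#'
#' Ion mass is mass(M) + mass(gained atoms) - mass(lost atoms); under the
#' proton convention the electron mass is subtracted once per positive
#' charge (added per negative charge); under the hydrogen-atom convention
#' no electron correction is applied. m/z is the ion mass divided by the
#' absolute charge.
#'
#' @param formula Neutral molecule as [ElementalFormula-class] or string.
#' @param adduct An [Adduct-class] object or adduct name string.
#' @param electronConvention Override passed to [adduct()] when `adduct`
#'   is given as a name string.
#' @return m/z value.
#' @examples
#' adductMz("C10H12O4", "[M+H]+")                       # 197.0808
#' adductMz("C59H90O4", "[M+NH4]+")                     # 880.7
#' adductMz("C10H6D6O4", adduct("[M+H]+", "hydrogen"))  # 203.11904
#' @export
adductMz <- function(formula, adduct, electronConvention = "proton") {
  if (is.character(adduct))
    adduct <- adduct(adduct, electronConvention = electronConvention)
  stopifnot(is(adduct, "Adduct"))
  if (adduct@charge == 0L) stop("adduct charge must be non-zero")
  m <- monoisotopicMass(formula) + monoisotopicMass(adduct@gain) -
    monoisotopicMass(adduct@loss)
  if (adduct@electronConvention == "proton")
    m <- m - adduct@charge * .ELECTRON_MASS
  m / abs(adduct@charge)
}

# Ion mass of a bare fragment formula that already includes the adduct
# atoms (used for fragment annotations built as formula + adduct).
.ionMz <- function(neutralFormula, add) {
  adductMz(neutralFormula, add)
}
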