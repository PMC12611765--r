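# Monoisotopic atomic masses (Da), CODATA/IUPAC 2021 values.
# Pinned here so every mass in the package (and its tests) is bit-stable.
.MONOISOTOPIC_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  D  = 2.0141017778,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  Na = 22.9897692809,
  S  = 31.97207100
)

.ELECTRON_MASS <- 0.000548579909
# proton defined as H minus electron so adduct arithmetic is self-consistent
.PROTON_MASS   <- .MONOISOTOPIC_MASS[["H"]] - .ELECTRON_MASS

.SUPPORTED_ELEMENTS <- names(.MONOISOTOPIC_MASS)

#' Monoisotopic mass of a proton
#'
#' Constants used by the adduct m/z conventions. `protonMass()` is the mass
#' of H+ (hydrogen atom minus one electron); `electronMass()` the electron
#' rest mass; both in Da.
#'
#' @return A numeric scalar in Da.
#' @export
protonMass <- function() .PROTON_MASS

#' @rdname protonMass
#' @export
electronMass <- function() .ELECTRON_MASS
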