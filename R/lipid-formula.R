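# Backbone/headgroup base formulas. A full species formula is
# base + sum(free fatty acids) - one H2O per esterified chain, with ether
# (O-) chains contributed as fatty alcohols and vinyl-ether (P-) chains as
# fatty alcohols carrying one additional double-bond equivalent (the vinyl
# double bond is, by shorthand convention, not counted in the name).
# SM and Cer use the d18:1 long-chain-base convention: the printed totals
# C:D include the base, and the N-acyl is (C-18):(D-1).
.CLASS_BASE <- c(
  TG  = "C3H8O3",      # glycerol
  DG  = "C3H8O3",
  CE  = "C27H46O",     # cholesterol
  PC  = "C8H20NO6P",   # glycerophosphocholine
  PE  = "C5H14NO6P",   # glycerophosphoethanolamine
  LPC = "C8H20NO6P",
  LPE = "C5H14NO6P",
  PS  = "C6H14NO8P",   # glycerophosphoserine
  PI  = "C9H19O11P",   # glycerophosphoinositol
  PG  = "C6H15O8P"     # glycerophosphoglycerol
)

.H2O <- function() parseFormula("H2O")

# free fatty acid / fatty alcohol formula for one chain, modifications
# applied as: <OH> +O, <OOH> +2O, <oxo> +O -2H, <epoxy> +O
.chainFormula <- function(carbons, doubleBonds, bondType = "acyl",
                          modifications = modificationSet()) {
  c <- as.integer(carbons); d <- as.integer(doubleBonds)
  base <- switch(bondType,
    acyl  = elementalFormula(C = c, H = 2L * c - 2L * d, O = 2L),
    ether = elementalFormula(C = c, H = 2L * c + 2L - 2L * d, O = 1L),
    vinyl = elementalFormula(C = c, H = 2L * c - 2L * d, O = 1L),
    stop("unknown bond type: ", bondType))
  .applyModificationDelta(base, modifications)
}

.applyModificationDelta <- function(formula, mods) {
  oAdd <- addedOxygens(mods)
  hLoss <- 2L * mods@nOxo
  out <- formula + elementalFormula(O = oAdd)
  if (hLoss > 0L) out <- out - elementalFormula(H = hLoss)
  out
}

#' Elemental formula of a lipid species
#'
#' Computed as backbone/headgroup base plus the chain contributions minus
#' one water per condensed chain; oxidation modifications add oxygens (and
#' remove two hydrogens per keto group). Species-level names are expanded
#' with all chains treated as acyl except for the `O-`/`P-` prefix, which
#' marks the first linkage as ether/vinyl ether. Named compounds return
#' their tabulated formula.
#'
#' @param species A [LipidSpecies-class] or shorthand name string.
#' @return An [ElementalFormula-class].
#' @examples
#' formatFormula(speciesFormula("TG 18:1/18:1/18:1"))  # C57H104O6
#' formatFormula(speciesFormula("CoQ10"))              # C59H90O4
#' @export
speciesFormula <- function(species) {
  if (is.character(species)) species <- parseLipidName(species)
  stopifnot(is(species, "LipidSpecies"))
  if (!is.na(species@compound))
    return(parseFormula(.NAMED_COMPOUNDS[[species@compound]]))
  cls <- species@lipidClass
  core <- .coreClass(cls)
  prefix <- .etherPrefix(cls)

  if (core == "FA") {
    ch <- species@chains[[1]]
    return(.chainFormula(ch@carbons, ch@doubleBonds, ch@bondType,
                         ch@modifications))
  }
  if (core %in% c("SM", "Cer")) {
    # d18:1 sphingoid base convention; totals include the base
    cTot <- species@totalCarbons; dTot <- species@totalDoubleBonds
    if (cTot <= 18L || dTot < 1L)
      stop("SM/Cer totals must exceed the d18:1 long-chain base")
    sphingosine <- parseFormula("C18H37NO2")
    acyl <- .chainFormula(cTot - 18L, dTot - 1L, "acyl")
    out <- sphingosine + acyl - .H2O()
    if (core == "SM") out <- out + parseFormula("C5H14NO4P") - .H2O()
    return(.applyModificationDelta(out, species@modifications))
  }
  if (!core %in% names(.CLASS_BASE)) stop("unsupported lipid class: ", cls)
  base <- parseFormula(.CLASS_BASE[[core]])
  nCh <- .CLASS_N_CHAINS[[core]]

  if (length(species@chains)) {
    out <- base
    for (ch in species@chains)
      out <- out + .chainFormula(ch@carbons, ch@doubleBonds, ch@bondType,
                                 ch@modifications) - .H2O()
    # chain modifications already applied; add any species-level surplus
    chainMods <- Reduce(.modAdd, lapply(species@chains, slot, "modifications"),
                        modificationSet())
    surplus <- modificationSet(
      species@modifications@nOH - chainMods@nOH,
      species@modifications@nOxo - chainMods@nOxo,
      species@modifications@nOOH - chainMods@nOOH,
      species@modifications@nEpoxy - chainMods@nEpoxy)
    return(.applyModificationDelta(out, surplus))
  }

  # species level: all chains as one pooled acyl contribution
  cTot <- species@totalCarbons; dTot <- species@totalDoubleBonds
  pooled <- elementalFormula(C = cTot, H = 2L * cTot - 2L * dTot,
                             O = 2L * nCh)
  out <- base + pooled - nCh * .H2O()
  if (prefix == "O-") out <- out + elementalFormula(H = 2L) - elementalFormula(O = 1L)
  if (prefix == "P-") out <- out - elementalFormula(O = 1L)
  .applyModificationDelta(out, species@modifications)
}

#' Number of oxidizable double bonds of a species
#'
#' @param species A [LipidSpecies-class] or name string.
#' @return Integer total double-bond count (sum composition).
#' @export
totalDoubleBonds <- function(species) {
  if (is.character(species)) species <- parseLipidName(species)
  species@totalDoubleBonds
}

#' Lipid class accessor
#'
#' @param species A [LipidSpecies-class] or name string.
#' @return The class token (e.g. `"TG"`, `"O-PC"`).
#' @export
lipidClass <- function(species) {
  if (is.character(species)) species <- parseLipidName(species)
  species@lipidClass
}
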