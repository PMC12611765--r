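# Named compounds quantified by the targeted methods; formulas are the
# ground truth (printed m/z values are derived, never stored).
.NAMED_COMPOUNDS <- c(
  "CoQ10"      = "C59H90O4",
  "CoQ10H2"    = "C59H92O4",
  "CoQ10-d6"   = "C59H84D6O4",
  "CoQ9"       = "C54H82O4",
  "CoQ9H2"     = "C54H84O4",
  "CoQ8"       = "C49H74O4",
  "CoQ8H2"     = "C49H76O4",
  "VitaminK1"  = "C31H46O2",
  "MK-4"       = "C31H40O2",
  "aTocopherol" = "C29H50O2"
)

.LIPID_CLASSES <- c("TG", "DG", "CE", "PC", "PE", "LPC", "LPE", "PS", "PI",
                    "PG", "SM", "Cer", "FA")

# number of radyl chains each class carries when fully specified
.CLASS_N_CHAINS <- c(TG = 3L, DG = 2L, CE = 1L, PC = 2L, PE = 2L, LPC = 1L,
                     LPE = 1L, PS = 2L, PI = 2L, PG = 2L, SM = 1L, Cer = 1L,
                     FA = 1L)

#' Construct a modification set
#'
#' @param nOH,nOxo,nOOH,nEpoxy Non-negative counts of hydroxyl, keto,
#'   hydroperoxyl and epoxy groups.
#' @return A [ModificationSet-class].
#' @export
modificationSet <- function(nOH = 0L, nOxo = 0L, nOOH = 0L, nEpoxy = 0L) {
  new("ModificationSet", nOH = as.integer(nOH), nOxo = as.integer(nOxo),
      nOOH = as.integer(nOOH), nEpoxy = as.integer(nEpoxy))
}

#' Oxygen and site accounting for modification sets
#'
#' `addedOxygens()` is nOH + nOxo + 2*nOOH + nEpoxy;
#' `nModificationSites()` is nOH + nOxo + nOOH + nEpoxy.
#'
#' @param x A [ModificationSet-class].
#' @return Integer count.
#' @export
addedOxygens <- function(x) {
  stopifnot(is(x, "ModificationSet"))
  x@nOH + x@nOxo + 2L * x@nOOH + x@nEpoxy
}

#' @rdname addedOxygens
#' @export
nModificationSites <- function(x) {
  stopifnot(is(x, "ModificationSet"))
  x@nOH + x@nOxo + x@nOOH + x@nEpoxy
}

# element-wise sum of two modification sets
.modAdd <- function(a, b) {
  modificationSet(a@nOH + b@nOH, a@nOxo + b@nOxo, a@nOOH + b@nOOH,
                  a@nEpoxy + b@nEpoxy)
}

#' Format a modification set in shorthand
#'
#' Canonical order OH, oxo, OOH, epoxy with numeric multipliers, e.g.
#' `"<2OH>"`, `"<OH,OOH>"`. The empty set formats as `""`.
#'
#' @param x A [ModificationSet-class].
#' @return A string (possibly empty).
#' @export
formatModifications <- function(x) {
  stopifnot(is(x, "ModificationSet"))
  parts <- character(0)
  fmt <- function(n, tok) if (n > 0L) paste0(if (n > 1L) n else "", tok)
  parts <- c(fmt(x@nOH, "OH"), fmt(x@nOxo, "oxo"), fmt(x@nOOH, "OOH"),
             fmt(x@nEpoxy, "epoxy"))
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) return("")
  paste0("<", paste(unlist(parts), collapse = ","), ">")
}

# "<2OH,OOH>" -> ModificationSet; "" -> empty set
.parseModifications <- function(s) {
  if (is.na(s) || !nzchar(s)) return(modificationSet())
  inner <- sub("^<", "", sub(">$", "", s))
  toks <- strsplit(inner, ",", fixed = TRUE)[[1]]
  mods <- modificationSet()
  for (tok in toks) {
    m <- regmatches(tok, regexec("^([0-9]*)(OH|oxo|OOH|epoxy)$", tok))[[1]]
    if (!length(m)) stop("malformed modification token: ", tok)
    n <- if (nzchar(m[2])) as.integer(m[2]) else 1L
    delta <- switch(m[3],
      OH = modificationSet(nOH = n), oxo = modificationSet(nOxo = n),
      OOH = modificationSet(nOOH = n), epoxy = modificationSet(nEpoxy = n))
    mods <- .modAdd(mods, delta)
  }
  mods
}

#' Construct a fatty acyl chain
#'
#' @param carbons,doubleBonds Chain length and unsaturation.
#' @param bondType `"acyl"`, `"ether"` or `"vinyl"`.
#' @param modifications A [ModificationSet-class].
#' @return A [FattyAcyl-class].
#' @export
fattyAcyl <- function(carbons, doubleBonds = 0L, bondType = "acyl",
                      modifications = modificationSet()) {
  new("FattyAcyl", carbons = as.integer(carbons),
      doubleBonds = as.integer(doubleBonds), bondType = bondType,
      modifications = modifications)
}

# "18:1<OOH>" -> FattyAcyl
.parseChainToken <- function(tok, bondType = "acyl") {
  m <- regmatches(tok, regexec("^([0-9]+):([0-9]+)(<[^>]+>)?$", tok))[[1]]
  if (!length(m)) stop("malformed chain token: ", tok)
  fattyAcyl(as.integer(m[2]), as.integer(m[3]), bondType,
            .parseModifications(m[4]))
}

#' Construct a lipid species
#'
#' Either pass `chains` (chain-resolved) or `totalCarbons`/
#' `totalDoubleBonds` (species level, sum composition).
#'
#' @param lipidClass Class token, e.g. `"TG"`, `"O-PC"`.
#' @param chains List of [FattyAcyl-class] (optional).
#' @param totalCarbons,totalDoubleBonds Sum composition when no chains.
#' @param modifications Species-level [ModificationSet-class].
#' @param snKnown Whether sn-positions are known (`/` separator).
#' @param compound Named-compound key (internal use).
#' @return A [LipidSpecies-class].
#' @export
lipidSpecies <- function(lipidClass, chains = list(), totalCarbons = NULL,
                         totalDoubleBonds = NULL,
                         modifications = modificationSet(), snKnown = FALSE,
                         compound = NA_character_) {
  if (length(chains)) {
    totalCarbons <- sum(vapply(chains, slot, integer(1), "carbons"))
    totalDoubleBonds <- sum(vapply(chains, slot, integer(1), "doubleBonds"))
    chainMods <- Reduce(.modAdd, lapply(chains, slot, "modifications"),
                        modificationSet())
    if (nModificationSites(modifications) == 0L) modifications <- chainMods
  }
  new("LipidSpecies", lipidClass = lipidClass, chains = chains,
      totalCarbons = as.integer(totalCarbons),
      totalDoubleBonds = as.integer(totalDoubleBonds),
      modifications = modifications, snKnown = snKnown, compound = compound)
}

.etherPrefix <- function(lipidClass) {
  if (startsWith(lipidClass, "O-")) "O-"
  else if (startsWith(lipidClass, "P-")) "P-"
  else ""
}

.coreClass <- function(lipidClass) sub("^(O-|P-)", "", lipidClass)

#' Parse a shorthand lipid name
#'
#' Grammar: an optional ether prefix (`O-`, `P-`) plus a class token (TG,
#' DG, CE, PC, PE, LPC, LPE, PS, PI, PG, SM, Cer, FA), optional whitespace,
#' then either a species-level `C:D` token or chain tokens joined by `/`
#' (known sn-positions) or `_` (unknown). Any token may carry a
#' modification suffix such as `<OOH>` or `<OH,oxo>`. Named compounds
#' (e.g. `"CoQ10"`, `"CoQ10-d6"`) are recognised directly.
#'
#' @param name A single shorthand string, e.g. `"TG 18:1/18:1/18:1"`,
#'   `"FA18:2<OOH>"`, `"O-PC 34:2"`.
#' @return A [LipidSpecies-class].
#' @examples
#' parseLipidName("TG 18:1/18:1/18:1")
#' parseLipidName("FA18:2<OOH>")
#' @export
parseLipidName <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  s <- trimws(name)
  if (s %in% names(.NAMED_COMPOUNDS)) {
    f <- parseFormula(.NAMED_COMPOUNDS[[s]])
    return(lipidSpecies("compound", totalCarbons = elementCount(f, "C"),
                        totalDoubleBonds = 0L, compound = s))
  }
  m <- regmatches(s, regexec(
    "^(O-|P-)?(LPC|LPE|TG|DG|CE|PC|PE|PS|PI|PG|SM|Cer|FA)\\s*(.+)$", s))[[1]]
  if (!length(m)) stop("unknown lipid class in name: ", name)
  prefix <- m[2]
  core <- m[3]
  rest <- m[4]
  if (nzchar(prefix) && !core %in% c("PC", "PE", "LPC", "LPE"))
    stop("ether prefix not supported for class ", core)
  cls <- paste0(prefix, core)

  # split off a species-level trailing modification: "56:6<OOH>" keeps the
  # mods with its single token; multi-chain names carry mods on chains
  sep <- if (grepl("/", rest, fixed = TRUE)) "/"
         else if (grepl("_", rest, fixed = TRUE)) "_" else NULL
  nExpected <- .CLASS_N_CHAINS[[core]]
  if (is.null(sep)) {
    tok <- .parseChainToken(rest)
    if (nExpected == 1L) {
      # single-chain classes are chain-resolved by a single token
      bt <- if (nzchar(prefix)) c(`O-` = "ether", `P-` = "vinyl")[[prefix]]
            else "acyl"
      chain <- fattyAcyl(tok@carbons, tok@doubleBonds, bt, tok@modifications)
      return(lipidSpecies(cls, chains = list(chain),
                          modifications = tok@modifications, snKnown = TRUE))
    }
    # species-level sum composition (no chain double-bond cap applies)
    return(new("LipidSpecies", lipidClass = cls, chains = list(),
               totalCarbons = tok@carbons, totalDoubleBonds = tok@doubleBonds,
               modifications = tok@modifications, snKnown = FALSE,
               compound = NA_character_))
  }
  toks <- strsplit(rest, sep, fixed = TRUE)[[1]]
  if (length(toks) != nExpected)
    stop(sprintf("class %s expects %d chains, got %d in '%s'", cls,
                 nExpected, length(toks), name))
  chains <- lapply(seq_along(toks), function(i) {
    bt <- if (i == 1L && nzchar(prefix))
      c(`O-` = "ether", `P-` = "vinyl")[[prefix]] else "acyl"
    .parseChainToken(toks[i], bt)
  })
  mods <- Reduce(.modAdd, lapply(chains, slot, "modifications"),
                 modificationSet())
  lipidSpecies(cls, chains = chains, modifications = mods,
               snKnown = identical(sep, "/"))
}

#' Format a lipid species in shorthand
#'
#' Inverse of [parseLipidName()]: `formatLipidName(parseLipidName(x))`
#' reproduces `x` for canonical names.
#'
#' @param species A [LipidSpecies-class].
#' @return A shorthand string.
#' @export
formatLipidName <- function(species) {
  stopifnot(is(species, "LipidSpecies"))
  if (!is.na(species@compound)) return(species@compound)
  cls <- species@lipidClass
  core <- .coreClass(cls)
  chainTok <- function(ch) paste0(ch@carbons, ":", ch@doubleBonds,
                                  formatModifications(ch@modifications))
  chainMods <- Reduce(.modAdd, lapply(species@chains, slot, "modifications"),
                      modificationSet())
  if (length(species@chains) &&
      nModificationSites(species@modifications) ==
        nModificationSites(chainMods)) {
    sep <- if (species@snKnown) "/" else "_"
    body <- paste(vapply(species@chains, chainTok, character(1)),
                  collapse = sep)
  } else {
    # species-level modifications (e.g. in silico oxidation products) are
    # reported as sum composition even when parent chains are known
    body <- paste0(species@totalCarbons, ":", species@totalDoubleBonds,
                   formatModifications(species@modifications))
  }
  if (core == "FA") paste0(cls, body) else paste(cls, body)
}
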