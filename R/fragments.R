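# Fragment prediction for oxidized lipids.
#
# The diagnostic vocabulary follows the oxidized-fatty-acid evidence rules:
# in positive mode (sodiated oxTG/oxCE/oxDG) the informative fragments are
# the [oxFA+Na]+ / [oxFA+H]+ adducts of the intact oxidized fatty acid,
# their water losses, and acyl neutral losses from the precursor; in
# negative mode (oxPC/oxPE) the [oxFA-H]- adduct and its water loss.
# A fragment "retains added oxygen" when at least one oxygen introduced by
# the modification set survives fragmentation; each water loss from an
# oxidized acyl is debited against the added oxygens (dehydration occurs at
# the modified position), so e.g. [FA18:2<OOH>-H2O+H]+ retains one added
# oxygen while [FA18:2<OH>-H2O+H]+ retains none.

.POSITIVE_FRAGMENT_CLASSES <- c("TG", "CE", "DG")
.NEGATIVE_FRAGMENT_CLASSES <- c("PC", "PE", "O-PC", "O-PE", "P-PC", "P-PE",
                                "LPC", "LPE")

# fragment rows for one oxidized acyl chain
.oxFaFragments <- function(chain, mods, polarity) {
  faName <- paste0("FA", chain@carbons, ":", chain@doubleBonds,
                   formatModifications(mods))
  faFormula <- .chainFormula(chain@carbons, chain@doubleBonds, "acyl", mods)
  addedO <- addedOxygens(mods)
  rows <- list()
  addRow <- function(desc, formula, adductName, waterLosses, origin) {
    retained <- max(addedO - waterLosses, 0L)
    rows[[length(rows) + 1L]] <<- data.frame(
      descriptor = desc, formula = formatFormula(formula),
      mz = adductMz(formula, adductName),
      retainsAddedOxygen = retained >= 1L, origin = origin,
      stringsAsFactors = FALSE)
  }
  if (polarity == "positive") {
    addRow(sprintf("[%s+Na]+", faName), faFormula, "[M+Na]+", 0L,
           "intact oxFA")
    addRow(sprintf("[%s+H]+", faName), faFormula, "[M+H]+", 0L,
           "intact oxFA")
    addRow(sprintf("[%s-H2O+Na]+", faName), faFormula - .H2O(), "[M+Na]+",
           1L, "oxFA neutral-loss")
    addRow(sprintf("[%s-H2O+H]+", faName), faFormula - .H2O(), "[M+H]+",
           1L, "oxFA neutral-loss")
  } else {
    addRow(sprintf("[%s-H]-", faName), faFormula, "[M-H]-", 0L,
           "intact oxFA")
    addRow(sprintf("[%s-H2O-H]-", faName), faFormula - .H2O(), "[M-H]-",
           1L, "oxFA neutral-loss")
  }
  do.call(rbind, rows)
}

#' Predict diagnostic MS/MS fragments for an oxidized lipid
#'
#' The species-level modification set is placed, in turn, on every
#' unsaturated acyl chain; the union of the resulting fragment annotations
#' is returned (duplicates by descriptor removed). Positive mode covers
#' sodiated/protonated oxTG, oxCE and oxDG chemistry (intact oxidized fatty
#' acid adducts, their water losses, acyl neutral losses from the
#' precursor, and the cholestenyl headgroup diagnostic for CE); negative
#' mode covers oxPC/oxPE ([oxFA-H]- and its water loss, plus unmodified
#' acyl anions).
#'
#' @param species Chain-resolved oxidized [LipidSpecies-class] (or a
#'   shorthand name such as `"FA18:2<OOH>"` for a bare oxidized fatty
#'   acid). Must carry at least one modification.
#' @param precursorAdduct [Adduct-class] or name of the precursor adduct
#'   (default `"[M+Na]+"` in positive, `"[M-H]-"` in negative mode).
#' @param polarity `"positive"` or `"negative"`.
#' @return data.frame with columns `descriptor`, `formula`, `mz`,
#'   `retainsAddedOxygen`, `origin`.
#' @export
predictFragments <- function(species, precursorAdduct = NULL,
                             polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  if (is.character(species)) species <- parseLipidName(species)
  stopifnot(is(species, "LipidSpecies"))
  mods <- species@modifications
  if (nModificationSites(mods) < 1L)
    stop("species carries no oxidation modification: ",
         formatLipidName(species))
  if (is.null(precursorAdduct))
    precursorAdduct <- if (polarity == "positive") "[M+Na]+" else "[M-H]-"
  if (is.character(precursorAdduct)) precursorAdduct <- adduct(precursorAdduct)

  core <- .coreClass(species@lipidClass)
  if (core == "FA") {
    ch <- species@chains[[1]]
    plain <- fattyAcyl(ch@carbons, ch@doubleBonds, "acyl")
    out <- .oxFaFragments(plain, mods, polarity)
    return(out[!duplicated(out$descriptor), , drop = FALSE])
  }
  if (!length(species@chains))
    stop("fragment prediction requires chain-resolved species; got ",
         formatLipidName(species))
  okClass <- if (polarity == "positive") .POSITIVE_FRAGMENT_CLASSES
             else .NEGATIVE_FRAGMENT_CLASSES
  if (!species@lipidClass %in% okClass)
    stop(sprintf("no %s-mode fragment chemistry for class %s", polarity,
                 species@lipidClass))

  placements <- which(vapply(species@chains, slot, integer(1),
                             "doubleBonds") >= 1L)
  if (!length(placements))
    stop("no unsaturated chain to place the modification on: ",
         formatLipidName(species))

  rows <- list()
  for (p in placements) {
    chains <- species@chains
    oxChain <- chains[[p]]
    rows[[length(rows) + 1L]] <- .oxFaFragments(oxChain, mods, polarity)
    if (polarity == "positive") {
      # acyl neutral losses from the (sodiated) precursor: losing an
      # unmodified acyl keeps the added oxygens on the charged fragment,
      # losing the oxidized acyl removes them
      precFormula <- .placedFormula(species, p)
      for (j in seq_along(chains)) {
        chj <- chains[[j]]
        isOx <- j == p
        lossMods <- if (isOx) mods else modificationSet()
        lossName <- paste0("FA", chj@carbons, ":", chj@doubleBonds,
                           formatModifications(lossMods))
        lossFormula <- .chainFormula(chj@carbons, chj@doubleBonds, "acyl",
                                     lossMods)
        fragFormula <- precFormula - lossFormula
        rows[[length(rows) + 1L]] <- data.frame(
          descriptor = sprintf("[M%s-%s]+",
                               sub("^\\[M(.*)\\].*$", "\\1",
                                   precursorAdduct@name), lossName),
          formula = formatFormula(fragFormula),
          mz = adductMz(fragFormula, precursorAdduct@name),
          retainsAddedOxygen = !isOx, origin = "acyl loss",
          stringsAsFactors = FALSE)
      }
    } else {
      # unmodified acyl anions for the remaining chains
      for (j in setdiff(seq_along(chains), p)) {
        chj <- chains[[j]]
        if (chj@bondType != "acyl") next
        faFormula <- .chainFormula(chj@carbons, chj@doubleBonds, "acyl")
        faName <- paste0("FA", chj@carbons, ":", chj@doubleBonds)
        rows[[length(rows) + 1L]] <- data.frame(
          descriptor = sprintf("[%s-H]-", faName),
          formula = formatFormula(faFormula),
          mz = adductMz(faFormula, "[M-H]-"),
          retainsAddedOxygen = FALSE, origin = "acyl loss",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (polarity == "positive" && core == "CE") {
    chol <- parseFormula("C27H44")  # cholestenyl cation after acyl loss
    rows[[length(rows) + 1L]] <- data.frame(
      descriptor = "[Chol-H2O+H]+", formula = formatFormula(chol),
      mz = adductMz(chol, "[M+H]+"), retainsAddedOxygen = FALSE,
      origin = "headgroup", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$descriptor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# neutral formula of the species with the modification set placed on chain p
.placedFormula <- function(species, p) {
  chains <- species@chains
  chains[[p]]@modifications <- .modAdd(chains[[p]]@modifications,
                                       species@modifications)
  tmp <- lipidSpecies(species@lipidClass, chains = chains,
                      snKnown = species@snKnown)
  speciesFormula(tmp)
}

# default precursor adduct for a candidate in a given polarity
.candidateAdduct <- function(species, polarity) {
  if (polarity == "positive") adduct("[M+Na]+") else adduct("[M-H]-")
}
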