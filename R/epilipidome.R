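#' Construct oxidation constraints
#'
#' @param maxModSites Maximum number of modification groups per lipid.
#' @param maxTotalO Maximum total added oxygens.
#' @param maxOH,maxOxo,maxOOH,maxEpoxy Per-modification caps.
#' @return An [OxidationConstraints-class] with the semi-targeted defaults
#'   (2 sites, 3 O, 2 OH, 1 oxo, 1 OOH, 0 epoxy).
#' @export
oxidationConstraints <- function(maxModSites = 2L, maxTotalO = 3L,
                                 maxOH = 2L, maxOxo = 1L, maxOOH = 1L,
                                 maxEpoxy = 0L) {
  new("OxidationConstraints", maxModSites = as.integer(maxModSites),
      maxTotalO = as.integer(maxTotalO), maxOH = as.integer(maxOH),
      maxOxo = as.integer(maxOxo), maxOOH = as.integer(maxOOH),
      maxEpoxy = as.integer(maxEpoxy))
}

# constraint predicate for one candidate set
.satisfiesConstraints <- function(mods, constraints) {
  mods@nOH <= constraints@maxOH &&
    mods@nOxo <= constraints@maxOxo &&
    mods@nOOH <= constraints@maxOOH &&
    mods@nEpoxy <= constraints@maxEpoxy &&
    nModificationSites(mods) <= constraints@maxModSites &&
    nModificationSites(mods) >= 1L &&
    addedOxygens(mods) <= constraints@maxTotalO
}

#' Enumerate all admissible modification sets
#'
#' All distinct non-empty combinations of OH/oxo/OOH/epoxy counts within
#' the per-modification caps, the total-site cap and the added-oxygen cap,
#' in a canonical deterministic order. Under the default constraints this
#' yields the seven sets \{OH\}, \{2OH\}, \{oxo\}, \{OOH\}, \{OH,oxo\},
#' \{OH,OOH\}, \{oxo,OOH\}.
#'
#' @param constraints An [OxidationConstraints-class].
#' @return A list of [ModificationSet-class] objects.
#' @examples
#' length(enumerateModificationSets(oxidationConstraints()))  # 7
#' @export
enumerateModificationSets <- function(constraints = oxidationConstraints()) {
  out <- list()
  for (oh in 0:constraints@maxOH)
    for (oxo in 0:constraints@maxOxo)
      for (ooh in 0:constraints@maxOOH)
        for (ep in 0:constraints@maxEpoxy) {
          ms <- modificationSet(oh, oxo, ooh, ep)
          if (.satisfiesConstraints(ms, constraints))
            out[[length(out) + 1L]] <- ms
        }
  # canonical order: fewer sites first, then fewer added oxygens, then
  # OH-richest first
  key <- vapply(out, function(m)
    sprintf("%02d-%02d-%02d-%02d-%02d-%02d", nModificationSites(m),
            addedOxygens(m), 99L - m@nOH, 99L - m@nOxo, 99L - m@nOOH,
            99L - m@nEpoxy), character(1))
  out[order(key)]
}

#' Enumerate in silico oxidized species for a parent lipid
#'
#' A parent is eligible when it carries at least one double bond among its
#' radyl chains; each admissible modification set yields one oxidized
#' species at sum-composition (species) level. Fully saturated parents
#' return an empty list; an already-oxidized parent is an error.
#'
#' @param parent A [LipidSpecies-class] or shorthand name.
#' @param constraints An [OxidationConstraints-class].
#' @return List of oxidized [LipidSpecies-class] objects (parent excluded).
#' @examples
#' length(enumerateOxidizedSpecies("CE 20:4"))  # 7
#' @export
enumerateOxidizedSpecies <- function(parent,
                                     constraints = oxidationConstraints()) {
  if (is.character(parent)) parent <- parseLipidName(parent)
  stopifnot(is(parent, "LipidSpecies"))
  if (nModificationSites(parent@modifications) > 0L)
    stop("parent species is already oxidized: ", formatLipidName(parent))
  if (parent@totalDoubleBonds < 1L) return(list())
  lapply(enumerateModificationSets(constraints), function(ms) {
    # modifications are reported at species (sum-composition) level; the
    # parent's chains are retained so fragment prediction can place the
    # modification on an unsaturated chain later
    out <- parent
    out@modifications <- ms
    out
  })
}

#' Target-selection configuration
#'
#' @param topNByClass Named integer vector: per-class top-N by mean raw
#'   intensity (default: 10 for the six phospholipid classes PC, P-PC,
#'   O-PC, PE, P-PE, O-PE and 20 for TG and CE).
#' @param phenotype Optional numeric vector (one value per sample) used to
#'   add the top `topNCorrelated` lipids whose intensity correlates
#'   positively (Pearson) with the phenotype.
#' @param topNCorrelated Number of positively correlated lipids to add.
#' @return A list with class `"TargetSelectionConfig"`.
#' @export
targetSelectionConfig <- function(
    topNByClass = c("PC" = 10L, "P-PC" = 10L, "O-PC" = 10L, "PE" = 10L,
                    "P-PE" = 10L, "O-PE" = 10L, "TG" = 20L, "CE" = 20L),
    phenotype = NULL, topNCorrelated = 10L) {
  stopifnot(all(topNByClass >= 0L), topNCorrelated >= 0L)
  structure(list(topNByClass = topNByClass, phenotype = phenotype,
                 topNCorrelated = as.integer(topNCorrelated)),
            class = "TargetSelectionConfig")
}

#' Select the lipid subset to oxidize in silico
#'
#' Per class, the top-N features by mean raw intensity (ties broken by
#' name, ascending, for reproducibility); optionally augmented with the
#' top-N features whose intensity correlates positively with a phenotype
#' vector (e.g. sensitivity to an inducer of cell death). The union is
#' deduplicated by species name.
#'
#' @param table A [LipidomeTable-class] (raw state).
#' @param config A [targetSelectionConfig()].
#' @return Character vector of selected lipid names (parseable shorthand).
#' @export
selectTargetLipids <- function(table, config = targetSelectionConfig()) {
  mat <- assayMatrix(table, "raw")
  if (nrow(mat) == 0L) stop("empty lipidome table")
  feats <- rownames(mat)
  cls <- vapply(feats, function(f)
    tryCatch(lipidClass(f), error = function(e) NA_character_), character(1))
  meanInt <- rowMeans(mat)
  selected <- character(0)
  for (cl in names(config$topNByClass)) {
    n <- config$topNByClass[[cl]]
    if (n == 0L) next
    idx <- which(cls == cl)
    if (!length(idx)) next
    ord <- idx[order(-meanInt[idx], feats[idx])]
    selected <- c(selected, feats[head(ord, n)])
  }
  if (!is.null(config$phenotype) && config$topNCorrelated > 0L) {
    ph <- config$phenotype
    stopifnot(length(ph) == ncol(mat))
    r <- apply(mat, 1L, function(x)
      if (sd(x) == 0 || sd(ph) == 0) NA_real_ else cor(x, ph))
    pos <- which(!is.na(r) & r > 0)
    ord <- pos[order(-r[pos], feats[pos])]
    selected <- c(selected, feats[head(ord, config$topNCorrelated)])
  }
  unique(selected)
}
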