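#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   `assays<-` assayNames colData
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
NULL

#' LipidomeTable: feature x sample intensity matrix with group labels
#'
#' A thin [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' extension. The `"raw"` assay always holds the untransformed
#' intensities; [log10Transform()] and [autoscale()] add `"log10"` and
#' `"autoscaled"` assays and advance the processing-state flag (raw ->
#' log10 -> autoscaled, in that order only). Group labels live in
#' `colData(x)$group`.
#'
#' @export
setClass("LipidomeTable", contains = "SummarizedExperiment")

setValidity("LipidomeTable", function(object) {
  if (!"raw" %in% assayNames(object)) return("a 'raw' assay is required")
  if (any(assay(object, "raw") < 0, na.rm = TRUE))
    return("raw intensities must be non-negative")
  if (!"group" %in% colnames(colData(object)))
    return("colData must contain a 'group' column")
  st <- metadata(object)$state
  if (!is.character(st) || !st %in% c("raw", "log10", "autoscaled"))
    return("metadata(x)$state must be 'raw', 'log10' or 'autoscaled'")
  TRUE
})

#' Construct a lipidome table
#'
#' @param intensity Non-negative numeric matrix, features in rows (rownames
#'   are shorthand lipid names), samples in columns.
#' @param group Group label per sample (character or factor).
#' @return A [LipidomeTable-class] in `"raw"` state.
#' @export
lipidomeTable <- function(intensity, group) {
  intensity <- as.matrix(intensity)
  stopifnot(length(group) == ncol(intensity))
  se <- SummarizedExperiment(
    assays = list(raw = intensity),
    colData = DataFrame(group = as.character(group),
                        row.names = colnames(intensity)),
    metadata = list(state = "raw"))
  new("LipidomeTable", se)
}

#' Processing state of a lipidome table
#'
#' @param x A [LipidomeTable-class].
#' @return `"raw"`, `"log10"` or `"autoscaled"`.
#' @export
processingState <- function(x) metadata(x)$state

#' Group labels of a lipidome table
#'
#' @param x A [LipidomeTable-class].
#' @return Character vector of per-sample group labels.
#' @export
groupLabels <- function(x) colData(x)$group

#' Assay accessor by name with fallback to the current state
#'
#' @param x A [LipidomeTable-class].
#' @param which Assay name (`"raw"`, `"log10"`, `"autoscaled"`) or
#'   `"current"` for the assay matching the processing state.
#' @return Numeric matrix.
#' @export
assayMatrix <- function(x, which = "current") {
  if (which == "current") which <- processingState(x)
  if (!which %in% assayNames(x))
    stop(sprintf("assay '%s' not present; state is '%s'", which,
                 processingState(x)))
  assay(x, which)
}

setMethod("show", "LipidomeTable", function(object) {
  cat(sprintf("LipidomeTable: %d features x %d samples (state: %s)\n",
              nrow(object), ncol(object), processingState(object)))
  cat("groups:", paste(sprintf("%s (n=%d)",
      names(table(groupLabels(object))), table(groupLabels(object))),
      collapse = ", "), "\n")
})
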