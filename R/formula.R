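#' Construct an elemental formula
#'
#' @param ... Element counts by name, e.g. `elementalFormula(C = 10, H = 12,
#'   O = 4)`. Unsupported elements are an error.
#' @return An [ElementalFormula-class] object.
#' @examples
#' elementalFormula(C = 10, H = 12, O = 4)
#' @export
elementalFormula <- function(...) {
  args <- c(...)
  counts <- setNames(integer(length(.SUPPORTED_ELEMENTS)), .SUPPORTED_ELEMENTS)
  if (length(args)) {
    if (is.null(names(args)) || any(!nzchar(names(args))))
      stop("all element counts must be named")
    bad <- setdiff(names(args), .SUPPORTED_ELEMENTS)
    if (length(bad))
      stop("unsupported element(s): ", paste(bad, collapse = ", "))
    if (anyNA(args) || any(args < 0) || any(args != round(args)))
      stop("element counts must be non-negative integers")
    for (el in names(args)) counts[el] <- counts[el] + as.integer(args[el])
  }
  new("ElementalFormula", counts = counts)
}

#' Parse a molecular formula string
#'
#' Accepts Hill-style strings such as `"C59H90O4"` or `"C10H6D6O4"`;
#' deuterium is written `D`.
#'
#' @param x A single formula string.
#' @return An [ElementalFormula-class] object.
#' @examples
#' parseFormula("C59H90O4")
#' @export
parseFormula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  s <- gsub("\\s", "", x)
  if (!nzchar(s)) return(elementalFormula())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s))
    stop("malformed formula string: ", x)
  counts <- integer(0)
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% .SUPPORTED_ELEMENTS)
      stop("unsupported element in formula: ", el)
    counts[el] <- (if (el %in% names(counts)) counts[el] else 0L) + n
  }
  do.call(elementalFormula, as.list(counts))
}

#' Format an elemental formula as a string
#'
#' Hill order (C, H, then alphabetical), with D printed directly after H.
#'
#' @param x An [ElementalFormula-class] object.
#' @return A single string, `"(empty)"` for the zero formula.
#' @export
formatFormula <- function(x) {
  stopifnot(is(x, "ElementalFormula"))
  cnt <- x@counts
  ord <- c("C", "H", "D", setdiff(sort(.SUPPORTED_ELEMENTS), c("C", "H", "D")))
  cnt <- cnt[ord]
  cnt <- cnt[cnt > 0L]
  if (!length(cnt)) return("(empty)")
  paste0(names(cnt), ifelse(cnt == 1L, "", cnt), collapse = "")
}

#' @export
setMethod("+", signature("ElementalFormula", "ElementalFormula"),
  function(e1, e2) new("ElementalFormula", counts = e1@counts + e2@counts))

#' @export
setMethod("-", signature("ElementalFormula", "ElementalFormula"),
  function(e1, e2) {
    counts <- e1@counts - e2@counts
    if (any(counts < 0L)) {
      neg <- names(counts)[counts < 0L]
      stop("formula subtraction would give negative count(s) for: ",
           paste(neg, collapse = ", "))
    }
    new("ElementalFormula", counts = counts)
  })

#' @export
setMethod("*", signature("numeric", "ElementalFormula"), function(e1, e2) {
  if (length(e1) != 1L || e1 < 0 || e1 != round(e1))
    stop("formula multiplier must be a single non-negative integer")
  new("ElementalFormula", counts = as.integer(e1) * e2@counts)
})

#' @export
setMethod("*", signature("ElementalFormula", "numeric"),
  function(e1, e2) e2 * e1)

#' Element count accessor
#'
#' @param x An [ElementalFormula-class] object.
#' @param element Element symbol, e.g. `"O"`.
#' @return Integer count of that element.
#' @export
elementCount <- function(x, element) {
  stopifnot(is(x, "ElementalFormula"), element %in% .SUPPORTED_ELEMENTS)
  unname(x@counts[element])
}

#' Monoisotopic mass
#'
#' Sum of tabulated monoisotopic atomic masses times element counts.
#' Deterministic to well below 1e-9 Da.
#'
#' @param formula An [ElementalFormula-class] object or a formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopicMass("C10H12O4")
#' @export
monoisotopicMass <- function(formula) {
  if (is.character(formula)) formula <- parseFormula(formula)
  stopifnot(is(formula, "ElementalFormula"))
  sum(formula@counts * .MONOISOTOPIC_MASS[names(formula@counts)])
}
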