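#' Log10 transformation with zero replacement
#'
#' Elementwise base-10 logarithm of the raw intensities. Zeros (and
#' missing values) are first replaced by one fifth of the feature's
#' minimum positive value — the conventional small-value substitution for
#' metabolomics intensity tables — and the affected cells are recorded in
#' `metadata(x)$zeroReplaced`. Features with no positive value at all are
#' an error.
#'
#' @param x A [LipidomeTable-class] in `"raw"` state.
#' @return The table with a `"log10"` assay added and state advanced.
#' @export
log10Transform <- function(x) {
  stopifnot(is(x, "LipidomeTable"))
  if (processingState(x) != "raw")
    stop("log10Transform requires state 'raw', got '", processingState(x), "'")
  m <- assay(x, "raw")
  replaced <- !is.finite(m) | m <= 0
  if (any(replaced)) {
    for (i in which(apply(replaced, 1L, any))) {
      pos <- m[i, ][is.finite(m[i, ]) & m[i, ] > 0]
      if (!length(pos))
        stop("feature with no positive intensity: ", rownames(m)[i])
      m[i, replaced[i, ]] <- min(pos) / 5
    }
  }
  assays(x)$log10 <- log10(m)
  metadata(x)$state <- "log10"
  metadata(x)$zeroReplaced <- which(replaced, arr.ind = TRUE)
  x
}

#' Autoscaling (per-feature standardization)
#'
#' Centres each feature at mean zero and scales to unit sample standard
#' deviation (n - 1 denominator). Constant features become zero vectors
#' and are recorded in `metadata(x)$constantFeatures`. Applying
#' `autoscale` to an already autoscaled table is a no-op up to numerical
#' precision (idempotence).
#'
#' @param x A [LipidomeTable-class] in `"log10"` (or `"autoscaled"`) state.
#' @return The table with an `"autoscaled"` assay and state advanced.
#' @export
autoscale <- function(x) {
  stopifnot(is(x, "LipidomeTable"))
  st <- processingState(x)
  if (!st %in% c("log10", "autoscaled"))
    stop("autoscale requires state 'log10', got '", st, "'")
  m <- assayMatrix(x, st)
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, sd)
  constant <- sdv == 0
  sdv[constant] <- 1
  scaled <- (m - mu) / sdv
  assays(x)$autoscaled <- scaled
  metadata(x)$state <- "autoscaled"
  metadata(x)$constantFeatures <- rownames(m)[constant]
  x
}

# vectorised Welch two-sample t-test over matrix rows; identical to
# t.test(var.equal = FALSE) per row
.welchRows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1L, function(z) sum((z - mean(z))^2)) / (na - 1)
  vb <- apply(b, 1L, function(z) sum((z - mean(z))^2)) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  # zero-variance degenerate rows: identical groups give t = 0/0; report
  # no evidence against the null
  degenerate <- !is.finite(tstat)
  tstat[degenerate] <- 0
  p[degenerate] <- 1
  list(t = tstat, df = df, p = p)
}

#' Per-feature differential test between two groups
#'
#' Welch (unequal-variance) two-sided t-test on the processed values
#' (autoscaled by default, matching the transform-then-test pipeline),
#' with Benjamini-Hochberg q-values. Fold changes are computed on the raw
#' group means, as plotted in volcano displays.
#'
#' @param x A [LipidomeTable-class]; must contain the requested assay.
#' @param groupA,groupB Group labels to compare (A vs B; fold change is
#'   mean(A)/mean(B)).
#' @param on Assay used for testing (default `"autoscaled"`).
#' @return data.frame with columns `feature`, `fc`, `log2fc`, `t`, `df`,
#'   `p`, `q`.
#' @export
differentialTest <- function(x, groupA, groupB, on = "autoscaled") {
  stopifnot(is(x, "LipidomeTable"))
  g <- groupLabels(x)
  if (sum(g == groupA) < 2L || sum(g == groupB) < 2L)
    stop("need at least two samples per group")
  proc <- assayMatrix(x, on)
  raw <- assayMatrix(x, "raw")
  a <- proc[, g == groupA, drop = FALSE]
  b <- proc[, g == groupB, drop = FALSE]
  w <- .welchRows(a, b)
  q <- p.adjust(w$p, method = "BH")
  meanA <- rowMeans(raw[, g == groupA, drop = FALSE])
  meanB <- rowMeans(raw[, g == groupB, drop = FALSE])
  fc <- meanA / meanB
  data.frame(feature = rownames(raw), fc = fc, log2fc = log2(fc),
             t = w$t, df = w$df, p = w$p, q = q, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Volcano classification of differential-test results
#'
#' Labels features `"up"`/`"down"` when the fold change strictly exceeds
#' the threshold (in either direction) and the q-value is strictly below
#' the significance threshold; everything else is `"ns"`.
#'
#' @param results Output of [differentialTest()].
#' @param fcThreshold Fold-change threshold (default 2).
#' @param qThreshold FDR threshold (default 0.05).
#' @return `results` with a `label` column; the per-label counts are
#'   attached as `attr(, "counts")`.
#' @export
volcanoClassify <- function(results, fcThreshold = 2, qThreshold = 0.05) {
  stopifnot(all(c("fc", "q") %in% names(results)))
  label <- rep("ns", nrow(results))
  sig <- results$q < qThreshold
  label[sig & results$fc > fcThreshold] <- "up"
  label[sig & results$fc < 1 / fcThreshold] <- "down"
  results$label <- label
  attr(results, "counts") <- c(up = sum(label == "up"),
                               down = sum(label == "down"),
                               ns = sum(label == "ns"))
  results
}

#' Hierarchical clustering of features
#'
#' Ward linkage (`ward.D2`) on Euclidean distances of the processed
#' (autoscaled by default) feature profiles; deterministic and invariant
#' to input row order up to cluster relabelling.
#'
#' @param x A [LipidomeTable-class].
#' @param k Number of clusters to cut (default 2).
#' @param on Assay to cluster (default `"autoscaled"`).
#' @param method Linkage method passed to [stats::hclust()].
#' @return List with elements `hclust` and `clusters` (named integer
#'   vector of feature assignments).
#' @export
hierarchicalCluster <- function(x, k = 2L, on = "autoscaled",
                                method = "ward.D2") {
  m <- assayMatrix(x, on)
  hc <- hclust(dist(m), method = method)
  list(hclust = hc, clusters = cutree(hc, k = k))
}

#' Gene essentiality vs metabolite abundance correlation
#'
#' Standard Pearson correlation of each metabolite's abundance with a gene
#' essentiality score across cell lines, with two-sided p-values and
#' Benjamini-Hochberg q-values. Missing values are handled pairwise
#' complete; metabolites with fewer than three complete pairs or zero
#' variance are returned with `NA` and flagged.
#'
#' @param metabolites Numeric matrix, metabolites in rows, cell lines in
#'   columns.
#' @param essentiality Numeric vector, one score per cell line.
#' @return data.frame with columns `metabolite`, `r`, `n`, `p`, `q`,
#'   `flag`.
#' @export
essentialityCorrelation <- function(metabolites, essentiality) {
  metabolites <- as.matrix(metabolites)
  stopifnot(ncol(metabolites) == length(essentiality))
  rows <- lapply(seq_len(nrow(metabolites)), function(i) {
    xi <- metabolites[i, ]
    ok <- is.finite(xi) & is.finite(essentiality)
    if (sum(ok) < 3L || sd(xi[ok]) == 0 || sd(essentiality[ok]) == 0)
      return(data.frame(metabolite = rownames(metabolites)[i] %||% i,
                        r = NA_real_, n = sum(ok), p = NA_real_,
                        flag = "undefined", stringsAsFactors = FALSE))
    ct <- cor.test(xi[ok], essentiality[ok], method = "pearson")
    data.frame(metabolite = rownames(metabolites)[i] %||% i,
               r = unname(ct$estimate), n = sum(ok), p = ct$p.value,
               flag = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out[, c("metabolite", "r", "n", "p", "q", "flag")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
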