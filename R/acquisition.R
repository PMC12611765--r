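#' Build a DDA inclusion list for predicted oxidized species
#'
#' One entry per (species, adduct) pair, deduplicated at `dedupPpm`
#' (isomeric species with the same sum formula collapse to a single m/z),
#' sorted by m/z. Sodiated adducts are the default because fragments of
#' sodiated oxidized lipid ions are the most informative for oxidized
#' lipid identification.
#'
#' @param species List of [LipidSpecies-class] (or shorthand names).
#' @param adducts List of [Adduct-class] or adduct name strings
#'   (default `"[M+Na]+"`).
#' @param rtStart,rtStop Optional retention-time window (minutes) applied
#'   to every entry.
#' @param dedupPpm Tolerance for merging identical targets (default 5).
#' @return data.frame with columns `mz`, `polarity`, `adduct`, `species`,
#'   `rtStart`, `rtStop`.
#' @export
buildInclusionList <- function(species, adducts = list("[M+Na]+"),
                               rtStart = NA_real_, rtStop = NA_real_,
                               dedupPpm = 5) {
  if (!is.na(rtStart) && !is.na(rtStop) && rtStart >= rtStop)
    stop("rtStart must be < rtStop")
  rows <- list()
  for (sp in species) {
    spec <- if (is.character(sp)) parseLipidName(sp) else sp
    f <- speciesFormula(spec)
    for (ad in adducts) {
      a <- if (is.character(ad)) adduct(ad) else ad
      rows[[length(rows) + 1L]] <- data.frame(
        mz = adductMz(f, a),
        polarity = if (a@charge > 0L) "positive" else "negative",
        adduct = a@name, species = formatLipidName(spec),
        rtStart = rtStart, rtStop = rtStop, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(mz = numeric(0), polarity = character(0),
                      adduct = character(0), species = character(0),
                      rtStart = numeric(0), rtStop = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$mz, out$species), , drop = FALSE]
  # greedy dedup: drop an entry whose m/z is within tolerance of the last
  # kept entry in the same polarity
  keep <- logical(nrow(out))
  lastMz <- c(positive = -Inf, negative = -Inf)
  for (i in seq_len(nrow(out))) {
    pol <- out$polarity[i]
    if ((out$mz[i] - lastMz[[pol]]) / out$mz[i] * 1e6 > dedupPpm) {
      keep[i] <- TRUE
      lastMz[[pol]] <- out$mz[i]
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Iterative-exclusion parameters for deep DDA profiling
#'
#' Defaults are the deep-profiling settings: retention-time window 0.3 min,
#' noise count 15, m/z window 0.02 Th, maximum retention time 36 min.
#'
#' @param rtWindow Half-window in minutes around each precursor RT.
#' @param noiseCount Rank of the lowest signal defining the noise floor:
#'   precursors must exceed the intensity of the `noiseCount`-th lowest
#'   record to be excluded in later runs.
#' @param mzWindow Half-window in Th for m/z matching/merging.
#' @param maxRt Precursors beyond this RT (minutes) are not excluded.
#' @return A named list of validated parameters.
#' @export
iterativeExclusionParams <- function(rtWindow = 0.3, noiseCount = 15,
                                     mzWindow = 0.02, maxRt = 36) {
  stopifnot(rtWindow > 0, noiseCount > 0, mzWindow > 0, maxRt > 0)
  list(rtWindow = rtWindow, noiseCount = as.integer(noiseCount),
       mzWindow = mzWindow, maxRt = maxRt)
}

#' Build an iterative exclusion list from a prior DDA run
#'
#' Previously fragmented precursors above the noise floor and within the
#' retention-time limit are merged when they fall within the m/z and RT
#' windows of one another, and emitted with their exclusion windows so a
#' follow-up DDA run fragments new precursors only.
#'
#' @param priorRun data.frame with columns `mz`, `rt` (minutes),
#'   `intensity` of fragmented precursors from the previous run.
#' @param params [iterativeExclusionParams()].
#' @return data.frame with columns `mz`, `mzMin`, `mzMax`, `rt`, `rtStart`,
#'   `rtStop`, `intensity` (merged entries keep the most intense record).
#' @export
buildIterativeExclusionList <- function(priorRun,
                                        params = iterativeExclusionParams()) {
  empty <- data.frame(mz = numeric(0), mzMin = numeric(0),
                      mzMax = numeric(0), rt = numeric(0),
                      rtStart = numeric(0), rtStop = numeric(0),
                      intensity = numeric(0))
  if (is.null(priorRun) || nrow(priorRun) == 0L) return(empty)
  stopifnot(all(c("mz", "rt", "intensity") %in% names(priorRun)))
  x <- priorRun[priorRun$rt <= params$maxRt, , drop = FALSE]
  if (!nrow(x)) return(empty)
  # noise floor: the noiseCount-th lowest intensity among retained records;
  # with fewer records than noiseCount no floor is applied
  floorInt <- if (nrow(x) > params$noiseCount)
    sort(x$intensity)[params$noiseCount] else -Inf
  x <- x[x$intensity > floorInt, , drop = FALSE]
  if (!nrow(x)) return(empty)
  x <- x[order(x$mz, x$rt), , drop = FALSE]
  # greedy merge into clusters: a record joins the current cluster when it
  # is within mzWindow and rtWindow of the cluster seed
  cluster <- integer(nrow(x))
  seeds <- list()
  for (i in seq_len(nrow(x))) {
    assigned <- FALSE
    for (k in seq_along(seeds)) {
      s <- seeds[[k]]
      if (abs(x$mz[i] - s$mz) <= params$mzWindow &&
          abs(x$rt[i] - s$rt) <= params$rtWindow) {
        cluster[i] <- k
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      seeds[[length(seeds) + 1L]] <- list(mz = x$mz[i], rt = x$rt[i])
      cluster[i] <- length(seeds)
    }
  }
  rows <- lapply(split(seq_len(nrow(x)), cluster), function(idx) {
    top <- idx[which.max(x$intensity[idx])]
    data.frame(mz = x$mz[top], mzMin = x$mz[top] - params$mzWindow,
               mzMax = x$mz[top] + params$mzWindow, rt = x$rt[top],
               rtStart = x$rt[top] - params$rtWindow,
               rtStop = x$rt[top] + params$rtWindow,
               intensity = x$intensity[top])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}
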