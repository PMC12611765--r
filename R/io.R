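#' Read centroided MS/MS spectra
#'
#' Supports mzML (via the Bioconductor mzR parser; profile-mode spectra
#' are rejected with guidance to centroid during conversion) and the
#' package's JSON peak-list format: an array of objects with fields
#' `precursor_mz`, `precursor_intensity`, `rt`, `polarity`,
#' `peaks` (array of `[mz, intensity]` pairs), and optionally
#' `precursor_isotopes` and `spectrum_id`.
#'
#' @param path Path to a `.mzML` or `.json` file.
#' @return List of [CentroidSpectrum-class] objects.
#' @export
readSpectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") return(.readSpectraJson(path))
  if (ext == "mzml") return(.readSpectraMzml(path))
  stop("unsupported spectrum format '", ext,
       "'; expected mzML or JSON peak lists")
}

.readSpectraJson <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (!length(txt) || !any(nzchar(txt))) stop("empty spectrum file: ", path)
  recs <- jsonlite::fromJSON(paste(txt, collapse = "\n"),
                             simplifyDataFrame = FALSE)
  lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    peaks <- if (is.matrix(r$peaks)) r$peaks
      else do.call(rbind, lapply(r$peaks, unlist))
    if (is.null(peaks)) peaks <- matrix(numeric(0), 0, 2)
    centroidSpectrum(
      precursorMz = r$precursor_mz, rt = r$rt, peaks = peaks,
      precursorIntensity = r$precursor_intensity %||% NA_real_,
      polarity = r$polarity %||% "positive",
      precursorIsotopes = as.numeric(r$precursor_isotopes %||% numeric()),
      spectrumId = r$spectrum_id %||% sprintf("S%04d", i))
  })
}

.readSpectraMzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the mzR package; ",
         "alternatively convert to the JSON peak-list format")
  ms <- mzR::openMSfile(path)
  closeFun <- methods::selectMethod("close", class(ms)[1], optional = TRUE)
  if (!is.null(closeFun)) on.exit(closeFun(ms))
  h <- mzR::header(ms)
  if (!nrow(h)) stop("empty spectrum file: ", path)
  if (any(!is.na(h$centroided) & !h$centroided))
    stop("profile-mode spectra found; centroid during mzML conversion ",
         "(e.g. msconvert peakPicking filter)")
  idx <- which(h$msLevel >= 2L)
  lapply(idx, function(i) {
    p <- mzR::peaks(ms, i)
    centroidSpectrum(
      precursorMz = h$precursorMZ[i], rt = h$retentionTime[i] / 60,
      peaks = p,
      precursorIntensity = h$precursorIntensity[i],
      polarity = if (!is.na(h$polarity[i]) && h$polarity[i] < 0)
        "negative" else "positive",
      spectrumId = sprintf("S%04d", i))
  })
}

#' Write spectra to the JSON peak-list format
#'
#' @param spectra List of [CentroidSpectrum-class] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(spectra, path) {
  recs <- lapply(spectra, function(s) {
    r <- list(precursor_mz = s@precursorMz, rt = s@rt,
              polarity = s@polarity,
              peaks = lapply(seq_len(nrow(s@peaks)), function(i)
                c(s@peaks[i, 1L], s@peaks[i, 2L])))
    if (!is.na(s@precursorIntensity))
      r$precursor_intensity <- s@precursorIntensity
    if (length(s@precursorIsotopes))
      r$precursor_isotopes <- s@precursorIsotopes
    if (!is.na(s@spectrumId)) r$spectrum_id <- s@spectrumId
    r
  })
  writeLines(jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a lipidome intensity table from CSV
#'
#' Expects a `lipid_name` column followed by one numeric column per
#' sample.
#'
#' @param path CSV path.
#' @param group Group label per sample column.
#' @return A [LipidomeTable-class].
#' @export
readLipidomeTable <- function(path, group) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"lipid_name" %in% names(df))
    stop("expected a 'lipid_name' column in ", path)
  m <- as.matrix(df[, setdiff(names(df), "lipid_name"), drop = FALSE])
  rownames(m) <- df$lipid_name
  lipidomeTable(m, group)
}

#' Write a lipidome table to CSV
#'
#' @param x A [LipidomeTable-class].
#' @param path Output path.
#' @param which Assay to write (default current state).
#' @return `path`, invisibly.
#' @export
writeLipidomeTable <- function(x, path, which = "current") {
  m <- assayMatrix(x, which)
  df <- data.frame(lipid_name = rownames(m), m, check.names = FALSE,
                   row.names = NULL)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Tidy TSV writer with provenance header
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param comment Extra comment lines (each prefixed with `# `).
#' @return `path`, invisibly.
#' @export
writeTsv <- function(df, path, comment = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("epilipidR"))
  writeLines(c(sprintf("# epilipidR %s", ver),
               if (length(comment)) paste("#", comment)), con)
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged quinone/vitamin PRM transition table
#'
#' The targeted transitions for coenzyme Q forms, vitamin K1,
#' menaquinone-4 and alpha-tocopherol. Elemental formulas are the ground
#' truth; precursor and product m/z are computed from them at load time
#' (proton-mass convention) rather than stored.
#'
#' @param electronConvention Convention passed to [adductMz()].
#' @return data.frame of [transition()] rows with `compound`, formula and
#'   adduct metadata.
#' @export
quinoneTransitionTable <- function(electronConvention = "proton") {
  path <- system.file("extdata", "quinone_transitions.csv",
                      package = "epilipidR", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    cbind(transition(
      name = r$compound,
      precursorMz = adductMz(r$precursorFormula, r$precursorAdduct,
                             electronConvention),
      productMz = adductMz(r$productFormula, r$productAdduct,
                           electronConvention),
      precursorAdduct = r$precursorAdduct,
      productAdduct = r$productAdduct, expectedRt = r$expectedRt,
      collisionEnergy = r$collisionEnergy),
      precursorFormula = r$precursorFormula,
      productFormula = r$productFormula)
  })
  do.call(rbind, rows)
}
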