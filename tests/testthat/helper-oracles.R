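# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# independently tabulated monoisotopic masses (IUPAC) for the mass oracle
ORACLE_MASS <- c(C = 12.0, H = 1.00782503207, D = 2.0141017778,
                 N = 14.0030740048, O = 15.9949146196, P = 30.97376163,
                 Na = 22.9897692809, S = 31.97207100)

oracleMass <- function(counts) sum(ORACLE_MASS[names(counts)] * counts)

# brute-force enumeration of admissible modification sets via expand.grid,
# returned as a sorted key set for order-free comparison
oracleModSets <- function(maxModSites, maxTotalO, maxOH, maxOxo, maxOOH,
                          maxEpoxy) {
  g <- expand.grid(oh = 0:maxOH, oxo = 0:maxOxo, ooh = 0:maxOOH,
                   ep = 0:maxEpoxy)
  sites <- g$oh + g$oxo + g$ooh + g$ep
  oxy <- g$oh + g$oxo + 2 * g$ooh + g$ep
  g <- g[sites >= 1 & sites <= maxModSites & oxy <= maxTotalO, ,
         drop = FALSE]
  sort(sprintf("%d/%d/%d/%d", g$oh, g$oxo, g$ooh, g$ep))
}

modSetKey <- function(ms)
  sprintf("%d/%d/%d/%d", ms@nOH, ms@nOxo, ms@nOOH, ms@nEpoxy)

# oxygen-retention oracle for oxidized fatty acid fragments: the neutral
# fragment formula keeps at least one added oxygen iff it carries more
# oxygens than an unmodified fatty acid (two)
oracleRetainsOxygen <- function(formulaString) {
  o <- regmatches(formulaString, regexec("O([0-9]*)", formulaString))[[1]]
  n <- if (length(o) < 2 || !nzchar(o[2])) 1L else as.integer(o[2])
  if (!grepl("O", formulaString)) n <- 0L
  n >= 3L
}

# analytic area of a Gaussian peak with given height and sigma
gaussianArea <- function(height, sigma) height * sigma * sqrt(2 * pi)

# small chain-resolved oxidized benchmark candidates shared across tests
benchmarkCandidates <- function() {
  parents <- list(parseLipidName("TG 18:1/18:1/18:2"),
                  parseLipidName("CE 20:4"),
                  parseLipidName("TG 16:0/18:1/20:4"),
                  parseLipidName("CE 18:2"))
  unlist(lapply(parents, enumerateOxidizedSpecies), recursive = FALSE)
}

# identification outcome at the collapsed-isomer (unique m/z) level: the
# best accepted candidate per spectrum must match the true species m/z
benchmarkOutcome <- function(ids, truth, tolPpm = 5) {
  acc <- ids[ids$accepted, , drop = FALSE]
  if (!nrow(acc))
    return(list(precision = NA_real_, recall = 0))
  best <- do.call(rbind, lapply(split(acc, acc$spectrumId), function(d)
    d[which.max(d$score), c("spectrumId", "theoreticalMz", "score")]))
  truth$mz <- vapply(truth$species, function(s)
    adductMz(speciesFormula(s), "[M+Na]+"), numeric(1))
  m <- merge(truth, best, by = "spectrumId", all.x = TRUE)
  ok <- !is.na(m$score) & abs(m$theoreticalMz - m$mz) / m$mz * 1e6 < tolPpm
  tp <- sum(m$isTrue & ok)
  fp <- sum(!is.na(m$score) & !(m$isTrue & ok))
  list(precision = tp / max(tp + fp, 1), recall = tp / sum(m$isTrue))
}

# minimal mzML writer (uncompressed 64-bit, plain XML) for reader fixtures
writeMzmlFixture <- function(path, spectra) {
  enc <- function(x) jsonlite::base64_enc(
    writeBin(as.numeric(x), raw(), size = 8, endian = "little"))
  one <- function(i, s) {
    mzB <- enc(s$mz); intB <- enc(s$intensity)
    sprintf(paste0(
      '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="2"/>',
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan" value=""/>',
      '<scanList count="1"><scan><cvParam cvRef="MS" accession="MS:1000016" ',
      'name="scan start time" value="%f" unitCvRef="UO" ',
      'unitAccession="UO:0000031" unitName="minute"/></scan></scanList>',
      '<precursorList count="1"><precursor><selectedIonList count="1">',
      '<selectedIon><cvParam cvRef="MS" accession="MS:1000744" ',
      'name="selected ion m/z" value="%f"/>',
      '<cvParam cvRef="MS" accession="MS:1000042" name="peak intensity" value="%f"/>',
      '</selectedIon></selectedIonList><activation/></precursor></precursorList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>',
      '<binary>%s</binary></binaryDataArray>',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
      '<binary>%s</binary></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'),
      i - 1L, i, length(s$mz), s$rt, s$precursorMz, s$precursorIntensity,
      nchar(mzB), mzB, nchar(intB), intB)
  }
  body <- paste(mapply(one, seq_along(spectra), spectra), collapse = "\n")
  doc <- sprintf(paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="1"><cv id="MS" fullName="PSI-MS" URI="x"/></cvList>\n',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>',
    '</fileContent></fileDescription>\n<run id="r1">\n',
    '<spectrumList count="%d" defaultDataProcessingRef="dp">\n%s\n',
    '</spectrumList></run></mzML>'), length(spectra), body)
  writeLines(doc, path)
  path
}
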