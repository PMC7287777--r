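# mzML dialect for AIF scans: MS level 2 with an isolation window spanning
# (essentially) the full scan range, i.e. no precursor selection, plus a
# collision-energy annotation. Width threshold below which an MS2 scan is
# considered precursor-selected rather than AIF.
.aif_min_isolation_width <- 50

#' Read an interleaved full-MS/AIF run from mzML
#'
#' MS-level-1 scans become `"full"` spectra. MS-level-2 scans whose
#' isolation window spans the full scan range (no precursor selection)
#' become `"AIF"` spectra; an MS2 scan with a narrow or absent isolation
#' window has no scan-kind evidence and is an error. Mixed ESI polarities
#' in one file are an error. Retention times are converted to minutes.
#'
#' @param path Path to an mzML file.
#' @return An [aif_run()].
#' @export
read_run <- function(path) {
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  h <- mzR::header(ms)
  if (!nrow(h)) abort("mzML file contains no spectra")
  pol <- unique(h$polarity[h$polarity %in% c(0L, 1L)])
  if (length(pol) > 1) abort("mixed polarity in one run is not supported")
  if (!length(pol)) abort("mzML file carries no polarity annotation")
  width <- h$isolationWindowLowerOffset + h$isolationWindowUpperOffset
  kind <- dplyr::case_when(
    h$msLevel == 1L ~ "full",
    h$msLevel == 2L & !is.na(width) & width >= .aif_min_isolation_width ~ "AIF",
    TRUE ~ NA_character_
  )
  if (anyNA(kind)) {
    abort(paste0("no scan-kind evidence (full vs AIF) for scan index ",
                 paste(which(is.na(kind)), collapse = ", ")))
  }
  if (any(h$centroided %in% FALSE)) {
    abort("profile-mode spectra are not supported; centroid during conversion")
  }
  pk <- mzR::peaks(ms)
  if (is.matrix(pk)) pk <- list(pk)
  peaks <- purrr::map(pk, function(m) {
    m <- m[order(m[, 1]), , drop = FALSE]
    tibble(mz = m[, 1], intensity = m[, 2])
  })
  nce <- suppressWarnings(max(h$collisionEnergy[kind == "AIF"], na.rm = TRUE))
  aif_run(
    tibble(rt = h$retentionTime / 60, scan_kind = kind, peaks = peaks),
    polarity = if (pol == 1L) "positive" else "negative",
    nce = if (is.finite(nce)) nce else NA_real_
  )
}

#' Write a run to mzML
#'
#' Inverse of [read_run()]: full scans as MS1, AIF scans as MS2 with a
#' full-range isolation window and the run's collision energy. Output is
#' indexed mzML with zlib-compressed arrays (mzR/proteowizard backend),
#' readable by standard viewers. Intensities are stored as 32-bit floats.
#'
#' @param run An [aif_run()].
#' @param path Output file path (`.mzML`).
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  stopifnot(inherits(run, "aif_run"))
  s <- run$spectra
  n <- nrow(s)
  mzrange <- range(c(unlist(purrr::map(s$peaks, "mz")), 100, 2000))
  is_aif <- s$scan_kind == "AIF"
  counts <- vapply(s$peaks, nrow, integer(1))
  tic <- vapply(s$peaks, function(p) sum(p$intensity), numeric(1))
  bp <- vapply(s$peaks, function(p) {
    if (nrow(p)) p$mz[which.max(p$intensity)] else NA_real_
  }, numeric(1))
  bpi <- vapply(s$peaks, function(p) {
    if (nrow(p)) max(p$intensity) else NA_real_
  }, numeric(1))
  lo <- vapply(s$peaks, function(p) if (nrow(p)) min(p$mz) else NA_real_, numeric(1))
  hi <- vapply(s$peaks, function(p) if (nrow(p)) max(p$mz) else NA_real_, numeric(1))
  mid <- mean(mzrange); half <- diff(mzrange) / 2 + 1
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = ifelse(is_aif, 2L, 1L),
    polarity = if (run$metadata$polarity == "positive") 1L else 0L,
    peaksCount = counts, totIonCurrent = tic,
    retentionTime = s$rt * 60,
    basePeakMZ = bp, basePeakIntensity = bpi,
    collisionEnergy = ifelse(is_aif, run$metadata$nce %||% 0, NA_real_),
    ionisationEnergy = 0,
    lowMZ = lo, highMZ = hi,
    precursorScanNum = NA_integer_,
    precursorMZ = ifelse(is_aif, mid, NA_real_),
    precursorCharge = NA_integer_,
    precursorIntensity = ifelse(is_aif, 0, NA_real_),
    mergedScan = NA_integer_, mergedResultScanNum = NA_integer_,
    mergedResultStartScanNum = NA_integer_, mergedResultEndScanNum = NA_integer_,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = ifelse(is_aif, mid, NA_real_),
    isolationWindowLowerOffset = ifelse(is_aif, half, NA_real_),
    isolationWindowUpperOffset = ifelse(is_aif, half, NA_real_),
    scanWindowLowerLimit = mzrange[1], scanWindowUpperLimit = mzrange[2],
    stringsAsFactors = FALSE
  )
  pk <- purrr::map(s$peaks, ~ cbind(mz = .x$mz, intensity = .x$intensity))
  mzR::writeMSData(pk, path, header = hdr, outformat = "mzml")
  invisible(path)
}
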