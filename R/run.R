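#' In-memory MS run of interleaved full-MS and AIF scans
#'
#' A run holds RT-ordered centroid spectra in one ESI polarity, each tagged
#' as a `"full"` (MS1) or `"AIF"` (unselective all-ion-fragmentation) scan.
#' Retention times are minutes throughout.
#'
#' @param spectra A tibble with columns `rt` (minutes, non-decreasing),
#'   `scan_kind` (`"full"` or `"AIF"`) and `peaks` (list-column of
#'   two-column data frames `mz`, `intensity`, strictly increasing in mz,
#'   intensities >= 0).
#' @param polarity `"positive"` or `"negative"` (single polarity per run).
#' @param nce Normalized collision energy (%) annotated on AIF scans.
#' @param sid In-source dissociation energy (eV), if any.
#' @param instrument Free-text instrument label.
#' @return An object of class `aif_run`.
#' @export
aif_run <- function(spectra, polarity = c("negative", "positive"),
                    nce = 20, sid = 0, instrument = "simulated") {
  polarity <- match.arg(polarity)
  spectra <- as_tibble(spectra)
  stopifnot(all(c("rt", "scan_kind", "peaks") %in% names(spectra)))
  if (!nrow(spectra)) abort("a run needs at least one spectrum")
  if (is.unsorted(spectra$rt)) abort("spectrum retention times must be non-decreasing")
  if (any(spectra$rt < 0)) abort("retention times must be non-negative")
  bad <- !spectra$scan_kind %in% c("full", "AIF")
  if (any(bad)) abort("scan_kind must be 'full' or 'AIF'")
  for (i in seq_len(nrow(spectra))) {
    p <- spectra$peaks[[i]]
    if (nrow(p)) {
      if (is.unsorted(p$mz, strictly = TRUE)) {
        abort(paste0("peaks of spectrum ", i, " must be strictly increasing in m/z"))
      }
      if (any(p$intensity < 0)) abort("negative intensity")
    }
  }
  spectra$scan <- seq_len(nrow(spectra))
  structure(list(
    spectra = spectra[, c("scan", "rt", "scan_kind", "peaks")],
    metadata = list(polarity = polarity, nce = nce, sid = sid,
                    instrument = instrument)
  ), class = "aif_run")
}

#' @export
print.aif_run <- function(x, ...) {
  s <- x$spectra
  cat("<aif_run> ", nrow(s), " spectra (",
      sum(s$scan_kind == "full"), " full / ", sum(s$scan_kind == "AIF"),
      " AIF), ", x$metadata$polarity, " mode, RT ",
      round(min(s$rt), 2), "-", round(max(s$rt), 2), " min\n", sep = "")
  invisible(x)
}

#' @rdname aif_run
#' @param x An `aif_run`.
#' @export
run_polarity <- function(x) x$metadata$polarity

#' Per-run summary
#'
#' One-row overview of an `aif_run`: scan counts, RT span, polarity and
#' total ion current, in the spirit of broom's `glance()`.
#'
#' @param x An `aif_run`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.aif_run <- function(x, ...) {
  s <- x$spectra
  tibble(
    n_spectra = nrow(s),
    n_full = sum(s$scan_kind == "full"),
    n_aif = sum(s$scan_kind == "AIF"),
    rt_min = min(s$rt), rt_max = max(s$rt),
    polarity = x$metadata$polarity,
    tic = sum(purrr::map_dbl(s$peaks, ~ sum(.x$intensity)))
  )
}

#' @importFrom generics glance
#' @export
generics::glance

run_scans <- function(run, scan_kind) {
  filter(run$spectra, .data$scan_kind == !!scan_kind)
}
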