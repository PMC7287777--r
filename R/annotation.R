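#' Locate lipid-class retention bands from diagnostic AIF traces
#'
#' For each class-diagnostic ion of the run's polarity, extracts an XIC
#' over the AIF scans, detects its peaks, and emits one band per accepted
#' peak, labelled with every class sharing that diagnostic. When one
#' diagnostic yields as many bands as it has classes, the bands are
#' disambiguated by the canonical HILIC head-group elution order
#' (PG < PI < PE < LPE < PC < SM < LPC): classes are assigned to bands in
#' elution-rank order. Classes named in `expect_classes` but yielding no
#' diagnostic peak are reported mass-only with a warning.
#'
#' @param run An [aif_run()].
#' @param diagnostics A diagnostic table ([diagnostic_table()]); filtered
#'   to the run polarity automatically.
#' @param expect_classes Optional character vector of classes that must be
#'   found.
#' @param tol_ppm XIC window for the diagnostic traces.
#' @param min_snr,min_points Peak-detection settings.
#' @return A tibble of bands: `lipid_class` (comma-joined when ambiguous),
#'   `classes` (list-column), `polarity`, `rt_start`, `rt_end`, `apex_rt`,
#'   `diagnostic_mz`, `diagnostic_label`, `height`, `area`.
#' @export
locate_class_bands <- function(run, diagnostics = diagnostic_table(),
                               expect_classes = NULL, tol_ppm = 5,
                               min_snr = 3, min_points = 5) {
  pol <- run_polarity(run)
  d <- filter(diagnostics, .data$polarity == pol)
  if (!nrow(run_scans(run, "AIF"))) abort("run has no AIF scans")
  bands <- purrr::map_dfr(seq_len(nrow(d)), function(i) {
    tr <- extract_xic(run, d$mz[i], tol_ppm = tol_ppm, scan_kind = "AIF")
    pk <- detect_peaks(tr, min_snr = min_snr, min_points = min_points)
    if (!nrow(pk)) return(tibble())
    classes <- d$lipid_classes[[i]]
    ranks <- class_table()$elution_rank[match(classes,
                                              class_table()$lipid_class)]
    classes <- classes[order(ranks)]
    assigned <- if (nrow(pk) == length(classes)) {
      as.list(classes)  # one band per class, in elution order
    } else {
      rep(list(classes), nrow(pk))
    }
    tibble(
      lipid_class = purrr::map_chr(assigned, paste, collapse = ","),
      classes = assigned, polarity = pol,
      rt_start = pk$rt_start, rt_end = pk$rt_end, apex_rt = pk$apex_rt,
      diagnostic_mz = d$mz[i], diagnostic_label = d$label[i],
      height = pk$height, area = pk$area
    )
  })
  if (nrow(bands)) bands <- arrange(bands, .data$apex_rt)
  if (!is.null(expect_classes)) {
    found <- unique(unlist(bands$classes))
    missing <- setdiff(expect_classes, found)
    if (length(missing)) {
      warn(paste0("no diagnostic band for class(es) ",
                  paste(missing, collapse = ", "),
                  "; annotation will be mass-only for them"))
    }
  }
  bands
}

#' Manually specified class band
#'
#' Bands may also be supplied from known retention windows instead of
#' diagnostic traces (both are legitimate workflows).
#'
#' @param lipid_class Class name (or several, comma-joined).
#' @param rt_start,rt_end Window bounds in minutes (`rt_start < rt_end`).
#' @param polarity Band polarity.
#' @return A one-row band tibble compatible with [locate_class_bands()].
#' @export
manual_band <- function(lipid_class, rt_start, rt_end,
                        polarity = "negative") {
  stopifnot(rt_end > rt_start)
  classes <- strsplit(lipid_class, ",", fixed = TRUE)[[1]]
  tibble(lipid_class = lipid_class, classes = list(classes),
         polarity = polarity, rt_start = rt_start, rt_end = rt_end,
         apex_rt = (rt_start + rt_end) / 2, diagnostic_mz = NA_real_,
         diagnostic_label = "manual", height = NA_real_, area = NA_real_)
}

#' Annotate intact species by accurate mass within class bands
#'
#' Averages the full-MS spectrum under each band, matches its centroids
#' against the candidate list within an absolute m/z tolerance (default
#' 0.005), and keeps a match only when a full-scan XIC peak at the
#' candidate m/z apexes inside the band window. Candidates of classes not
#' covered by the band are not considered for it. Several candidates
#' within tolerance of the same centroid are all reported and flagged
#' ambiguous, not dropped.
#'
#' @param run An [aif_run()].
#' @param bands Band tibble ([locate_class_bands()] / [manual_band()]).
#' @param candidates Candidate tibble ([enumerate_candidates()]).
#' @param tol Absolute m/z matching tolerance (default 0.005).
#' @param xic_tol_ppm ppm window for the confirming precursor XIC.
#' @param min_frac Centroids below this fraction of the band's base peak
#'   are not considered (suppresses baseline).
#' @param min_snr,min_points Peak-detection settings for the confirming
#'   XIC.
#' @return A tibble: `name`, `lipid_class`, `ion`, `theoretical_mz`,
#'   `observed_mz`, `mass_error`, `apex_rt`, `area`, `height`, `band`
#'   (band label), `ambiguous`.
#' @export
annotate_species <- function(run, bands, candidates, tol = 0.005,
                             xic_tol_ppm = 5, min_frac = 1e-4,
                             min_snr = 3, min_points = 5) {
  purrr::map_dfr(seq_len(nrow(bands)), function(b) {
    band <- bands[b, ]
    spec <- average_spectrum(run, c(band$rt_start, band$rt_end), "full")
    if (!nrow(spec)) return(tibble())
    spec <- filter(spec, .data$intensity >= min_frac * max(.data$intensity))
    cand <- filter(candidates, .data$lipid_class %in% band$classes[[1]])
    if (!nrow(cand)) return(tibble())
    hits <- purrr::map_dfr(seq_len(nrow(cand)), function(j) {
      dmz <- abs(spec$mz - cand$mz[j])
      k <- which.min(dmz)
      if (!length(k) || dmz[k] > tol) return(tibble())
      tibble(name = cand$name[j], lipid_class = cand$lipid_class[j],
             ion = cand$ion[j], theoretical_mz = cand$mz[j],
             observed_mz = spec$mz[k], mass_error = spec$mz[k] - cand$mz[j],
             centroid = k)
    })
    if (!nrow(hits)) return(tibble())
    hits <- hits |>
      group_by(.data$centroid) |>
      mutate(ambiguous = n() > 1) |>
      ungroup()
    # confirm each hit with a band-confined full-scan XIC peak
    confirmed <- purrr::map_dfr(seq_len(nrow(hits)), function(j) {
      tr <- extract_xic(run, hits$theoretical_mz[j], tol_ppm = xic_tol_ppm,
                        scan_kind = "full")
      pk <- detect_peaks(tr, min_snr = min_snr, min_points = min_points)
      pk <- filter(pk, .data$apex_rt >= band$rt_start,
                   .data$apex_rt <= band$rt_end)
      if (!nrow(pk)) return(tibble())
      pk <- slice_max(pk, .data$height, n = 1, with_ties = FALSE)
      bind_cols(hits[j, ], pk[, c("apex_rt", "area", "height")])
    })
    if (!nrow(confirmed)) return(tibble())
    mutate(confirmed, band = .env$band$lipid_class,
           band_rt_start = .env$band$rt_start,
           band_rt_end = .env$band$rt_end) |>
      select(-"centroid")
  })
}

#' Slice a class band into equal retention sub-windows
#'
#' Divides a band into `n_slices` contiguous equal-width windows and
#' averages the AIF spectrum in each, exposing the within-band acyl-chain
#' composition gradient (longer / more saturated chains elute earlier).
#'
#' @param run An [aif_run()].
#' @param band A one-row band tibble.
#' @param n_slices Number of slices (>= 1, at most the number of AIF scans
#'   in the band).
#' @return A tibble: `slice`, `rt_start`, `rt_end`, `spectrum`
#'   (list-column of averaged spectra).
#' @export
band_slices <- function(run, band, n_slices) {
  stopifnot(n_slices >= 1)
  s <- run_scans(run, "AIF")
  n_avail <- sum(s$rt >= band$rt_start & s$rt <= band$rt_end)
  if (n_avail == 0) abort("band window contains no AIF scans")
  if (n_slices > n_avail) {
    abort(paste0("n_slices (", n_slices, ") exceeds the ", n_avail,
                 " AIF scans in the band"))
  }
  edges <- seq(band$rt_start, band$rt_end, length.out = n_slices + 1)
  purrr::map_dfr(seq_len(n_slices), function(i) {
    tibble(slice = i, rt_start = edges[i], rt_end = edges[i + 1],
           spectrum = list(average_spectrum(run, edges[i:(i + 1)], "AIF")))
  })
}

#' Replicate filtering and class normalization of annotations
#'
#' Keeps species annotated in every replicate whose peak-area relative
#' standard deviation is at most `max_rsd_pct` (default 20%), then
#' normalizes mean areas within each lipid class to percentages.
#'
#' @param annotation_sets A list (>= 2) of annotation tibbles from
#'   [annotate_species()], one per replicate.
#' @param max_rsd_pct Maximum area RSD in percent.
#' @return A tibble: `name`, `lipid_class`, `ion`, `n_replicates`,
#'   `mean_area`, `rsd_pct`, `class_pct`.
#' @export
replicate_filter <- function(annotation_sets, max_rsd_pct = 20) {
  if (length(annotation_sets) < 2) abort("need at least 2 replicates")
  n_rep <- length(annotation_sets)
  bind_rows(annotation_sets, .id = "replicate") |>
    group_by(.data$name, .data$lipid_class, .data$ion) |>
    summarise(n_replicates = dplyr::n_distinct(.data$replicate),
              mean_area = mean(.data$area),
              rsd_pct = 100 * sd(.data$area) / mean(.data$area),
              .groups = "drop") |>
    filter(.data$n_replicates == n_rep, .data$rsd_pct <= max_rsd_pct) |>
    group_by(.data$lipid_class) |>
    mutate(class_pct = 100 * .data$mean_area / sum(.data$mean_area)) |>
    ungroup() |>
    arrange(.data$lipid_class, desc(.data$class_pct))
}
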