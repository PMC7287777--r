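#' Align an AIF product ion to its precursor lipids
#'
#' Because AIF scans fragment everything that co-elutes, a product ion
#' must be traced back to its precursor by aligning extracted-ion
#' chromatograms: the product XIC (AIF scans) against the full-scan XIC
#' of each annotated precursor. A link requires the precursor apex within
#' `rt_tol` of the product peak apex and a Pearson correlation of the two
#' traces (precursor trace linearly interpolated onto the product RT grid
#' over the product peak bounds) of at least `min_corr`. All qualifying
#' precursors are reported, ranked by correlation.
#'
#' @param run An [aif_run()].
#' @param product_mz Product ion m/z (e.g. a carboxylate).
#' @param annotations Annotation tibble ([annotate_species()]).
#' @param rt_tol Apex RT tolerance, minutes.
#' @param min_corr Minimum trace shape correlation.
#' @param tol_ppm XIC window for both traces.
#' @return A tibble of links: `product_mz`, `product_apex_rt`, `name`,
#'   `lipid_class`, `ion`, `precursor_mz`, `precursor_apex_rt`,
#'   `rt_delta`, `shape_correlation`.
#' @export
align_precursor_product <- function(run, product_mz, annotations,
                                    rt_tol = 0.1, min_corr = 0.8,
                                    tol_ppm = 5) {
  prod_tr <- extract_xic(run, product_mz, tol_ppm = tol_ppm,
                         scan_kind = "AIF")
  prod_pk <- detect_peaks(prod_tr)
  empty <- tibble(product_mz = numeric(), product_apex_rt = numeric(),
                  name = character(), lipid_class = character(),
                  ion = character(), precursor_mz = numeric(),
                  precursor_apex_rt = numeric(), rt_delta = numeric(),
                  shape_correlation = numeric())
  if (!nrow(prod_pk) || !nrow(annotations)) return(empty)
  links <- purrr::map_dfr(seq_len(nrow(prod_pk)), function(i) {
    pk <- prod_pk[i, ]
    cand <- filter(annotations,
                   abs(.data$apex_rt - pk$apex_rt) <= rt_tol)
    if (!nrow(cand)) return(tibble())
    purrr::map_dfr(seq_len(nrow(cand)), function(j) {
      pre_tr <- extract_xic(run, cand$theoretical_mz[j], tol_ppm = tol_ppm,
                            scan_kind = "full")
      win <- prod_tr$rt >= pk$rt_start & prod_tr$rt <= pk$rt_end
      if (sum(win) < 3) return(tibble())
      pre_y <- approx(pre_tr$rt, pre_tr$intensity,
                      xout = prod_tr$rt[win], rule = 2)$y
      prod_y <- prod_tr$intensity[win]
      if (sd(pre_y) == 0 || sd(prod_y) == 0) return(tibble())
      r <- cor(prod_y, pre_y)
      if (!is.finite(r) || r < min_corr) return(tibble())
      tibble(product_mz = product_mz, product_apex_rt = pk$apex_rt,
             name = cand$name[j], lipid_class = cand$lipid_class[j],
             ion = cand$ion[j], precursor_mz = cand$theoretical_mz[j],
             precursor_apex_rt = cand$apex_rt[j],
             rt_delta = abs(cand$apex_rt[j] - pk$apex_rt),
             shape_correlation = r)
    })
  })
  if (!nrow(links)) return(empty)
  arrange(links, .data$product_apex_rt, desc(.data$shape_correlation))
}

#' Ratio of two extracted-ion chromatograms
#'
#' Pointwise intensity ratio of two XICs on the same scan grid (default:
#' AIF scans), e.g. two carboxylate traces whose ratio tracks a
#' differential acyl chain. Points where the denominator does not exceed
#' its robust noise floor are emitted as `NA` gaps, never as zeros.
#'
#' @param run An [aif_run()].
#' @param mz_num,mz_den Numerator / denominator target m/z.
#' @param scan_kind `"AIF"` (default) or `"full"`.
#' @param tol_ppm XIC window.
#' @return A tibble: `rt`, `numerator`, `denominator`, `ratio` (NA where
#'   undefined).
#' @export
ratio_trace <- function(run, mz_num, mz_den, scan_kind = c("AIF", "full"),
                        tol_ppm = 5) {
  scan_kind <- match.arg(scan_kind)
  num <- extract_xic(run, mz_num, tol_ppm = tol_ppm, scan_kind = scan_kind)
  den <- extract_xic(run, mz_den, tol_ppm = tol_ppm, scan_kind = scan_kind)
  floor_ <- trace_noise(den$intensity)
  ok <- den$intensity > pmax(floor_, 0)
  tibble(rt = num$rt, numerator = num$intensity,
         denominator = den$intensity,
         ratio = ifelse(ok, num$intensity / den$intensity, NA_real_))
}

#' Plot an extracted-ion chromatogram
#'
#' @param object An `aif_trace` from [extract_xic()].
#' @param peaks Optional peak tibble from [detect_peaks()] to shade.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aif_trace <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$rt, y = .data$intensity)) +
    ggplot2::geom_line(color = "grey25") +
    ggplot2::labs(
      x = "retention time (min)", y = "intensity",
      title = sprintf("XIC m/z %.4f (%s, %.4g ppm)",
                      attr(object, "target_mz"), attr(object, "scan_kind"),
                      attr(object, "tol_ppm"))) +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks)) {
    p <- p + ggplot2::geom_vline(data = peaks,
                                 ggplot2::aes(xintercept = .data$apex_rt),
                                 linetype = "dashed", color = "firebrick")
  }
  p
}
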