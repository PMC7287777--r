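#' Per-class fatty-acyl profile from a band's AIF spectrum
#'
#' Averages the AIF spectrum under a class band and reads the intensity at
#' each candidate acyl carboxylate m/z (within an absolute tolerance,
#' default 0.005), then normalizes over the detected chains to
#' percentages. The default mode uses averaged-spectrum intensities; an
#' area mode integrating the carboxylate XIC peak inside the band is
#' available. No sn-position bias correction is applied by default — the
#' reported percentages are the raw carboxylate signal shares; an optional
#' correction divides sn-2 attributed signal by the bias factor.
#'
#' @param run An [aif_run()].
#' @param band A one-row band tibble ([locate_class_bands()] /
#'   [manual_band()]).
#' @param chain_universe A data frame with `carbons`, `double_bonds`
#'   columns listing the chains to consider; defaults to the plasma
#'   reference chain set ([plasma_fa_reference()]).
#' @param tol Absolute m/z matching tolerance.
#' @param mode `"spectrum"` (averaged AIF spectrum intensities, default)
#'   or `"area"` (carboxylate XIC peak areas within the band).
#' @param xic_tol_ppm ppm window for area mode.
#' @param sn_bias_correction Optional numeric bias factor; `NULL` (default)
#'   reports uncorrected values.
#' @return An `fa_profile` tibble: `lipid_class`, `chain`, `carbons`,
#'   `double_bonds`, `mz` (theoretical carboxylate), `intensity`,
#'   `relative_pct`. Rows sum to 100 over detected chains. All-zero
#'   signals give a zero-row profile with a warning.
#' @export
fa_profile <- function(run, band, chain_universe = plasma_fa_reference(),
                       tol = 0.005, mode = c("spectrum", "area"),
                       xic_tol_ppm = 5, sn_bias_correction = NULL) {
  mode <- match.arg(mode)
  uni <- distinct(as_tibble(chain_universe), .data$carbons,
                  .data$double_bonds)
  uni <- mutate(uni,
                chain = paste0("FA C", .data$carbons, ":", .data$double_bonds),
                mz = carboxylate_mz(.data$carbons, .data$double_bonds))
  if (mode == "spectrum") {
    spec <- average_spectrum(run, c(band$rt_start, band$rt_end), "AIF")
    uni$intensity <- vapply(uni$mz, function(m) {
      sum(spec$intensity[abs(spec$mz - m) <= tol])
    }, numeric(1))
  } else {
    uni$intensity <- vapply(uni$mz, function(m) {
      tr <- extract_xic(run, m, tol_ppm = xic_tol_ppm, scan_kind = "AIF")
      pk <- detect_peaks(tr)
      pk <- filter(pk, .data$apex_rt >= band$rt_start,
                   .data$apex_rt <= band$rt_end)
      if (nrow(pk)) max(pk$area) else 0
    }, numeric(1))
  }
  out <- filter(uni, .data$intensity > 0)
  if (!nrow(out)) {
    warn(paste0("no carboxylate signal in band ", band$lipid_class,
                "; empty profile"))
    return(structure(mutate(uni[0, ], relative_pct = numeric(0),
                            lipid_class = character(0)),
                     class = c("fa_profile", class(tibble()))))
  }
  if (!is.null(sn_bias_correction)) {
    # uniform de-biasing is only possible with chain-resolved knowledge;
    # applied here as a flat divisor on sn-2-attributed signal share
    out$intensity <- out$intensity / ((1 + sn_bias_correction) / 2)
  }
  out <- out |>
    mutate(relative_pct = 100 * .data$intensity / sum(.data$intensity),
           lipid_class = band$lipid_class, .before = 1) |>
    select("lipid_class", "chain", "carbons", "double_bonds", "mz",
           "intensity", "relative_pct") |>
    arrange(.data$carbons, .data$double_bonds)
  structure(out, band = band, mode = mode,
            class = c("fa_profile", class(tibble())))
}

#' Combine replicate fatty-acyl profiles
#'
#' Mean and standard deviation of the relative percentages over replicate
#' profiles of the same class (a chain absent from a replicate counts as
#' 0%); means are renormalized to sum to 100.
#'
#' @param profiles A list of `fa_profile` tibbles.
#' @return An `fa_profile` tibble with `relative_pct` (mean) and `sd_pct`.
#' @export
combine_fa_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  n <- length(profiles)
  out <- bind_rows(profiles, .id = "replicate") |>
    group_by(.data$lipid_class, .data$chain, .data$carbons,
             .data$double_bonds, .data$mz) |>
    summarise(
      m = sum(.data$relative_pct) / n,
      sd_pct = if (n >= 2) sd(c(.data$relative_pct,
                                rep(0, n - dplyr::n()))) else NA_real_,
      .groups = "drop") |>
    group_by(.data$lipid_class) |>
    mutate(relative_pct = 100 * .data$m / sum(.data$m)) |>
    ungroup() |>
    select(-"m") |>
    arrange(.data$lipid_class, .data$carbons, .data$double_bonds)
  structure(out, n_replicates = n,
            class = c("fa_profile", class(tibble())))
}

#' Tidy an FA profile
#'
#' `tidy()` returns the profile as a plain tibble (chain, theoretical
#' carboxylate m/z, relative percentage and, when present, replicate sd).
#'
#' @param x An `fa_profile`.
#' @param ... Unused.
#' @export
tidy.fa_profile <- function(x, ...) {
  as_tibble(x)[, intersect(c("lipid_class", "chain", "mz", "relative_pct",
                             "sd_pct"), names(x))]
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Plot an FA profile
#'
#' Bar chart of the relative carboxylate percentages per chain, with
#' replicate error bars when available.
#'
#' @param object An `fa_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fa_profile <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$chain,
                                        y = .data$relative_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$lipid_class)) +
    ggplot2::labs(x = NULL, y = "relative abundance (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
  if ("sd_pct" %in% names(df) && any(is.finite(df$sd_pct))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$relative_pct - .data$sd_pct,
                   ymax = .data$relative_pct + .data$sd_pct), width = 0.3)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
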