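#' Simulator configuration
#'
#' Defines a synthetic HILIC-ESI run: a species table (each species an
#' ionized lipid with an abundance, a Gaussian elution band apex and
#' width), the acquisition grid (alternating full/AIF scans), AIF
#' fragment yields, the sn-position intensity bias, m/z jitter and the
#' intensity noise model. The same config plus the same seed always
#' regenerates the identical run.
#'
#' @param species A data frame with columns `name` (shorthand), `ion`,
#'   `abundance` (> 0, arbitrary units, apex height scale), `rt_apex`
#'   (minutes) and `rt_sigma` (minutes, > 0).
#' @param rt_range `c(start, end)` of the scan grid, minutes.
#' @param cycle_time Full-scan to full-scan cycle, minutes. Each cycle
#'   holds one full scan and one AIF scan half a cycle later.
#' @param carboxylate_yield,fa_loss_yield,ketene_loss_yield,head_fragment_yield
#'   Fraction of a precursor's instantaneous intensity converted, in an
#'   AIF scan, into acyl carboxylates, FA-loss ions, ketene-loss ions and
#'   head-group fragments. Inositol follow-up ions (PI) carry half of
#'   their parent loss-ion intensity.
#' @param residual_precursor_fraction Fraction of the precursor surviving
#'   the AIF scan. All fractions are in `[0, 1]` and their sum must not
#'   exceed 1.
#' @param sn_bias sn-2 / sn-1 intensity ratio applied to carboxylates and
#'   (inverted: losses of the sn-2 chain are the stronger ones) to the
#'   loss-ion series, in `[1.1, 1.5]`.
#' @param mz_jitter_ppm Gaussian m/z jitter (ppm, sd) per centroid.
#' @param noise_cv Multiplicative Gaussian intensity noise (coefficient of
#'   variation).
#' @param baseline_frac Mean intensity of additive baseline centroids,
#'   as a fraction of the largest noiseless centroid in the run.
#' @param baseline_peaks_per_scan Number of random baseline centroids per
#'   scan.
#' @param polarity `"negative"` or `"positive"`.
#' @param nce,sid Collision-energy annotations carried into run metadata.
#' @param seed Integer seed; mandatory, so every run is reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(species, rt_range = NULL, cycle_time = 0.02,
                       carboxylate_yield = 0.50, fa_loss_yield = 0.05,
                       ketene_loss_yield = 0.05, head_fragment_yield = 0.15,
                       residual_precursor_fraction = 0.20,
                       sn_bias = 1.3, mz_jitter_ppm = 2,
                       noise_cv = 0.05, baseline_frac = 0.001,
                       baseline_peaks_per_scan = 3,
                       polarity = c("negative", "positive"),
                       nce = 20, sid = 40, seed) {
  polarity <- match.arg(polarity)
  if (missing(seed)) abort("sim_config() requires an explicit seed")
  species <- as_tibble(species)
  stopifnot(all(c("name", "ion", "abundance", "rt_apex", "rt_sigma") %in%
                  names(species)))
  if (any(species$abundance <= 0) || any(species$rt_sigma <= 0)) {
    abort("species abundances and rt_sigma must be positive")
  }
  yields <- c(carboxylate_yield, fa_loss_yield, ketene_loss_yield,
              head_fragment_yield, residual_precursor_fraction)
  if (any(yields < 0) || any(yields > 1) || sum(yields) > 1 + 1e-9) {
    abort("fragment yields must be in [0, 1] and sum (incl. residual) <= 1")
  }
  if (sn_bias < 1.1 || sn_bias > 1.5) {
    abort("sn_bias must lie in [1.1, 1.5]")
  }
  if (is.null(rt_range)) {
    rt_range <- c(max(0, min(species$rt_apex) - 1), max(species$rt_apex) + 1)
  }
  if (any(species$rt_apex < rt_range[1]) || any(species$rt_apex > rt_range[2])) {
    abort("species rt_apex outside the scan-grid RT range")
  }
  structure(list(
    species = species, rt_range = rt_range, cycle_time = cycle_time,
    carboxylate_yield = carboxylate_yield, fa_loss_yield = fa_loss_yield,
    ketene_loss_yield = ketene_loss_yield,
    head_fragment_yield = head_fragment_yield,
    residual_precursor_fraction = residual_precursor_fraction,
    sn_bias = sn_bias, mz_jitter_ppm = mz_jitter_ppm, noise_cv = noise_cv,
    baseline_frac = baseline_frac,
    baseline_peaks_per_scan = baseline_peaks_per_scan,
    polarity = polarity, nce = nce, sid = sid, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Five-standard HILIC mix configuration
#'
#' The negative-mode standard mixture used to validate class separation
#' and precursor/carboxylate alignment: PG 18:0/20:4, PE 14:0/14:0,
#' LPE 13:0/0:0, PC 16:0/18:0 and LPC 17:0/0:0, eluting at 7.2, 10.2,
#' 14.0, 15.3 and 17.3 min. Choline classes are carried as their
#' in-source demethylated `[M-CH3]-` ions, the others as `[M-H]-`.
#'
#' @param seed Integer seed.
#' @param abundance Common apex height of the five standards.
#' @param rt_sigma Gaussian band sd, minutes.
#' @param ... Passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
standards_config <- function(seed, abundance = 1e6, rt_sigma = 0.08, ...) {
  species <- tibble(
    name = c("PG 18:0/20:4", "PE 14:0/14:0", "LPE 13:0/0:0",
             "PC 16:0/18:0", "LPC 17:0/0:0"),
    ion = c("[M-H]-", "[M-H]-", "[M-H]-", "[M-CH3]-", "[M-CH3]-"),
    abundance = abundance,
    rt_apex = c(7.2, 10.2, 14.0, 15.3, 17.3),
    rt_sigma = rt_sigma
  )
  sim_config(species, rt_range = c(6, 19), polarity = "negative",
             seed = seed, ...)
}

#' Plasma-like negative-mode configuration
#'
#' Builds a synthetic run whose per-class fatty-acyl ground truth equals
#' the plasma reference composition ([plasma_fa_reference()]). Each acyl
#' chain of a class becomes one species — a same-chain diacyl species for
#' PI/PE/PC (e.g. the 18:0 row of PI becomes PI 18:0/18:0) and a lyso
#' species for LPC — with abundance proportional to the reference
#' percentage. Same-chain pairing makes the class carboxylate profile
#' equal the abundance profile exactly, independent of the sn-position
#' bias. Within a band, species with longer or more saturated total acyl
#' chains elute earlier: apex offset
#' `k_c * (34 - total_carbons) + k_db * total_double_bonds`.
#'
#' @param seed Integer seed.
#' @param classes Classes to include (subset of PI, PE, PC, LPC).
#' @param class_abundance Named total apex-height scale per class.
#' @param band_rt Named band-center RTs (minutes); defaults from the class
#'   table (PI 8.5, PE 10.2, PC 15.3, LPC 17.3).
#' @param rt_sigma Band sd, minutes.
#' @param k_c,k_db Within-band RT offset coefficients (min per carbon /
#'   per double bond).
#' @param ... Passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
plasma_like_config <- function(seed, classes = c("PI", "PE", "PC", "LPC"),
                               class_abundance = c(PI = 4e5, PE = 8e5,
                                                   PC = 1e6, LPC = 5e5),
                               band_rt = NULL, rt_sigma = 0.08,
                               k_c = 0.003, k_db = 0.003, ...) {
  ref <- plasma_fa_reference()
  tab <- class_table()
  default_rt <- setNames(tab$default_rt, tab$lipid_class)
  band_rt <- c(band_rt, default_rt[setdiff(classes, names(band_rt))])
  species <- purrr::map_dfr(classes, function(cls) {
    col <- tolower(cls)
    pct <- ref[[col]]
    keep <- !is.na(pct) & pct > 0
    lyso <- tab$n_acyl[match(cls, tab$lipid_class)] == 1
    ch <- ref[keep, ]
    frac <- pct[keep] / sum(pct[keep])
    name <- if (lyso) {
      paste0(cls, " ", ch$carbons, ":", ch$double_bonds, "/0:0")
    } else {
      paste0(cls, " ", ch$carbons, ":", ch$double_bonds, "/",
             ch$carbons, ":", ch$double_bonds)
    }
    mult <- if (lyso) 1L else 2L
    tot_c <- mult * ch$carbons; tot_db <- mult * ch$double_bonds
    tibble(
      name = name,
      ion = if (isTRUE(tab$choline[match(cls, tab$lipid_class)]))
        "[M-CH3]-" else "[M-H]-",
      abundance = unname(class_abundance[cls]) * frac,
      rt_apex = unname(band_rt[cls]) + k_c * (34 - tot_c) + k_db * tot_db,
      rt_sigma = rt_sigma
    )
  })
  sim_config(species, rt_range = c(6, 19), polarity = "negative",
             seed = seed, ...)
}

#' Simulate a HILIC-ESI full-MS/AIF run
#'
#' Generates alternating full and AIF scans on the cycle grid. Full scans
#' carry each precursor as a centroid with a Gaussian elution envelope;
#' AIF scans carry, per co-eluting precursor, its acyl carboxylates (the
#' sn-2 chain `sn_bias` times the sn-1 chain), FA- and ketene-loss ions
#' (sn-2 losses stronger by the same factor), inositol follow-ups for PI,
#' the class head fragment and the residual precursor — every fragment
#' m/z taken from [predict_fragments()]. Multiplicative Gaussian noise,
#' per-centroid ppm jitter and uniform-m/z baseline centroids are then
#' applied; identical seeds give identical runs.
#'
#' @param config A [sim_config()].
#' @return A list: `run` (an [aif_run()]) and `truth` (ground truth:
#'   `species` with theoretical m/z and apexes, `class_fa_pct` with the
#'   expected per-class carboxylate percentages, and the config).
#' @export
simulate_run <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cy <- config$cycle_time
  full_rt <- seq(config$rt_range[1], config$rt_range[2], by = cy)
  grid <- tibble(
    rt = c(full_rt, full_rt + cy / 2),
    scan_kind = rep(c("full", "AIF"), each = length(full_rt))
  ) |> arrange(.data$rt)
  grid$scan <- seq_len(nrow(grid))

  sp <- config$species |>
    mutate(species = purrr::map(.data$name, parse_shorthand),
           mz = purrr::map2_dbl(.data$species, .data$ion, ion_mz))

  frag_tables <- purrr::pmap(list(sp$species, sp$ion, sp$mz),
                             function(s, i, m) sim_fragments(s, i, m, config))

  # centroid plan: for each species x matching scan, the set of (mz, frac)
  centroids <- purrr::map_dfr(seq_len(nrow(sp)), function(i) {
    env <- exp(-(grid$rt - sp$rt_apex[i])^2 / (2 * sp$rt_sigma[i]^2))
    keep <- which(env > exp(-8))  # within 4 sigma
    if (!length(keep)) return(tibble())
    g <- grid[keep, ]
    env <- env[keep] * sp$abundance[i]
    full_idx <- g$scan_kind == "full"
    full_part <- tibble(scan = g$scan[full_idx], mz = sp$mz[i],
                        intensity = env[full_idx])
    fr <- frag_tables[[i]]
    aif_g <- g[!full_idx, ]; aif_env <- env[!full_idx]
    aif_part <- tidyr::expand_grid(
      j = seq_len(nrow(fr)), k = seq_along(aif_env)) |>
      mutate(scan = aif_g$scan[.data$k], mz = fr$mz[.data$j],
             intensity = fr$frac[.data$j] * aif_env[.data$k]) |>
      select("scan", "mz", "intensity")
    bind_rows(full_part, aif_part)
  })

  max_height <- max(centroids$intensity)
  n <- nrow(centroids)
  centroids$mz <- centroids$mz *
    (1 + rnorm(n, 0, config$mz_jitter_ppm * 1e-6))
  centroids$intensity <- pmax(
    centroids$intensity * (1 + rnorm(n, 0, config$noise_cv)), 0)

  # additive baseline centroids, uniform in m/z over the scan range
  if (config$baseline_peaks_per_scan > 0 && config$baseline_frac > 0) {
    mz_lo <- max(50, min(centroids$mz) - 50)
    mz_hi <- max(centroids$mz) + 50
    nb <- config$baseline_peaks_per_scan
    base <- tibble(
      scan = rep(grid$scan, each = nb),
      mz = runif(nb * nrow(grid), mz_lo, mz_hi),
      intensity = rexp(nb * nrow(grid),
                       rate = 1 / (config$baseline_frac * max_height))
    )
    centroids <- bind_rows(centroids, base)
  }

  peaks_by_scan <- centroids |>
    filter(.data$intensity > 0) |>
    group_by(.data$scan, .data$mz) |>
    summarise(intensity = sum(.data$intensity), .groups = "drop") |>
    arrange(.data$scan, .data$mz)
  split_peaks <- split(peaks_by_scan[, c("mz", "intensity")],
                       factor(peaks_by_scan$scan, levels = grid$scan))
  grid$peaks <- purrr::map(split_peaks, as_tibble)

  run <- aif_run(grid[, c("rt", "scan_kind", "peaks")],
                 polarity = config$polarity, nce = config$nce,
                 sid = config$sid)
  truth <- list(
    species = sp |> mutate(lipid_class = purrr::map_chr(.data$species,
                                                        "lipid_class")) |>
      select("name", "lipid_class", "ion", "mz", "rt_apex", "abundance"),
    class_fa_pct = ground_truth_fa(sp, config),
    fragments = setNames(frag_tables, sp$name),
    config = config
  )
  list(run = run, truth = truth)
}

# per-species AIF fragment plan: m/z (exact, from predict_fragments) and
# fraction of the instantaneous precursor intensity
sim_fragments <- function(species, ion, parent_mz, config) {
  fr <- suppressWarnings(predict_fragments(species, ion))
  out <- list(tibble(mz = parent_mz,
                     frac = config$residual_precursor_fraction,
                     kind = "residual_precursor", chain = NA_character_))
  shares <- chain_shares(fr, config$sn_bias)
  if (nrow(shares)) {
    cb <- filter(fr, .data$kind == "carboxylate")
    cb <- left_join(cb, shares, by = "chain")
    out$cb <- tibble(mz = cb$mz,
                     frac = config$carboxylate_yield * cb$share,
                     kind = "carboxylate", chain = cb$chain)
    for (kd in c("FA_loss", "ketene_loss")) {
      yl <- if (kd == "FA_loss") config$fa_loss_yield else config$ketene_loss_yield
      ls <- filter(fr, .data$kind == kd)
      if (nrow(ls)) {
        # losing a chain leaves the other: sn-2 chain loss is the stronger
        ls <- left_join(ls, shares, by = "chain")
        out[[kd]] <- tibble(mz = ls$mz, frac = yl * ls$share,
                            kind = kd, chain = ls$chain)
        ino <- filter(fr, .data$kind == paste0("inositol_loss_after_",
                                               sub("_loss", "", kd)))
        if (nrow(ino)) {
          ino <- left_join(ino, shares, by = "chain")
          out[[paste0("ino_", kd)]] <- tibble(
            mz = ino$mz, frac = 0.5 * yl * ino$share,
            kind = ino$kind, chain = ino$chain)
        }
      }
    }
  }
  hd <- filter(fr, .data$kind %in% c("head_fragment", "sphingoid_fragment"))
  if (nrow(hd)) {
    out$head <- tibble(mz = hd$mz,
                       frac = config$head_fragment_yield / nrow(hd),
                       kind = hd$kind, chain = NA_character_)
  }
  bind_rows(out) |> filter(.data$frac > 0)
}

# sn-biased intensity share per chain (carboxylates and loss ions)
chain_shares <- function(fr, sn_bias) {
  cb <- filter(fr, .data$kind == "carboxylate")
  if (!nrow(cb)) return(tibble(chain = character(), share = numeric()))
  sn <- distinct(cb, .data$chain, .data$sn_hint)
  w <- ifelse(!is.na(sn$sn_hint) & sn$sn_hint == "sn2", sn_bias, 1)
  tibble(chain = sn$chain, share = w / sum(w))
}

ground_truth_fa <- function(sp, config) {
  purrr::map_dfr(seq_len(nrow(sp)), function(i) {
    s <- sp$species[[i]]
    if (class_info(s$lipid_class)$kind != "glycerophospholipid") {
      return(tibble())
    }
    fr <- suppressWarnings(predict_fragments(s, sp$ion[i]))
    shares <- chain_shares(fr, config$sn_bias)
    if (!nrow(shares)) return(tibble())
    cb <- distinct(filter(fr, .data$kind == "carboxylate"),
                   .data$chain, .data$mz)
    left_join(cb, shares, by = "chain") |>
      mutate(lipid_class = s$lipid_class,
             signal = sp$abundance[i] * .data$share)
  }) |>
    group_by(.data$lipid_class, .data$chain, .data$mz) |>
    summarise(signal = sum(.data$signal), .groups = "drop") |>
    group_by(.data$lipid_class) |>
    mutate(pct = 100 * .data$signal / sum(.data$signal)) |>
    ungroup() |>
    select("lipid_class", "chain", "mz", "pct")
}
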