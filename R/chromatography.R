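new_trace <- function(rt, intensity, target_mz, tol_ppm, scan_kind) {
  structure(
    tibble(rt = rt, intensity = intensity),
    target_mz = target_mz, tol_ppm = tol_ppm, scan_kind = scan_kind,
    class = c("aif_trace", class(tibble()))
  )
}

#' Extract an ion chromatogram (XIC)
#'
#' One intensity point per scan of the requested kind: the summed centroid
#' intensity within `+/- tol_ppm` of `mz` (0 where nothing matches). The
#' default window of 5 ppm is the "narrow" extraction used for diagnostic
#' and carboxylate traces; accurate-mass annotation uses its own, absolute
#' tolerance (0.005 m/z) independently of this knob.
#'
#' @param run An [aif_run()].
#' @param mz Target m/z.
#' @param tol_ppm Half-window in ppm (> 0).
#' @param scan_kind `"full"` or `"AIF"`.
#' @return An `aif_trace`: a tibble (`rt`, `intensity`) with the target
#'   m/z, tolerance and scan kind as attributes. If the run has no scans
#'   of that kind, an empty trace with a warning.
#' @export
extract_xic <- function(run, mz, tol_ppm = 5, scan_kind = c("full", "AIF")) {
  scan_kind <- match.arg(scan_kind)
  stopifnot(tol_ppm > 0)
  s <- run_scans(run, scan_kind)
  if (!nrow(s)) {
    warn(paste0("run has no '", scan_kind, "' scans; empty trace"))
    return(new_trace(numeric(0), numeric(0), mz, tol_ppm, scan_kind))
  }
  lo <- mz * (1 - tol_ppm * 1e-6); hi <- mz * (1 + tol_ppm * 1e-6)
  ints <- vapply(s$peaks, function(p) {
    i <- findInterval(c(lo, hi), p$mz)
    if (i[2] > i[1]) sum(p$intensity[(i[1] + 1):i[2]]) else 0
  }, numeric(1))
  new_trace(s$rt, ints, mz, tol_ppm, scan_kind)
}

# robust noise level: 1.4826 x MAD of the low-intensity half of the trace
trace_noise <- function(intensity) {
  low <- sort(intensity)[seq_len(ceiling(length(intensity) / 2))]
  1.4826 * median(abs(low - median(low)))
}

#' Detect and integrate chromatographic peaks
#'
#' Local maxima above `min_snr` times the robust noise level (1.4826 x MAD
#' of the low-intensity half of the trace). Peak bounds extend to the
#' nearest valley or noise crossing; overlapping peaks are split at the
#' local minimum between apexes. Areas are trapezoidal over RT (minutes).
#'
#' @param trace An `aif_trace` (or data frame with `rt`, `intensity`).
#' @param min_snr Minimum apex signal-to-noise (when the noise estimate is
#'   zero, any positive apex qualifies).
#' @param min_points Minimum scans per peak.
#' @param valley_frac Two apexes are kept as separate peaks only when the
#'   valley between them falls below this fraction of the lower apex;
#'   shallower dips (e.g. noise ripple on one chromatographic peak) are
#'   merged.
#' @param min_rel_height Peaks below this fraction of the trace maximum are
#'   never reported (guards noise-free traces, where the MAD noise level is
#'   zero).
#' @return A tibble of peaks: `apex_rt`, `rt_start`, `rt_end`, `area`,
#'   `height`, `snr`, `n_points`. Zero rows when nothing qualifies.
#' @export
detect_peaks <- function(trace, min_snr = 3, min_points = 5,
                         valley_frac = 0.8, min_rel_height = 1e-5) {
  rt <- trace$rt; y <- trace$intensity
  empty <- tibble(apex_rt = numeric(), rt_start = numeric(),
                  rt_end = numeric(), area = numeric(), height = numeric(),
                  snr = numeric(), n_points = integer())
  if (!length(y) || all(y <= 0)) return(empty)
  noise <- trace_noise(y)
  # the relative floor keeps numerically negligible tail ripple (far below
  # any real signal) from surfacing as peaks on noise-free traces
  thr <- max(if (noise > 0) min_snr * noise else 0,
             min_rel_height * max(y))
  # topology (threshold runs, apexes, valleys) is read from a cleaned
  # copy: exact-zero dropouts of <= 2 scans (a jittered centroid missing
  # the m/z window) are interpolated, then a 3-point moving mean damps
  # noise ripple; heights and areas always come from the raw trace
  ys <- fill_dropouts(y)
  ys <- moving_mean(ys, 1)
  above <- ys > thr | y > thr
  # bridge 1-2 point dropouts (e.g. a jittered centroid missing the m/z
  # window for one scan) so one chromatographic peak stays one segment
  r <- rle(above)
  gaps <- which(!r$values & r$lengths <= 2)
  gaps <- gaps[gaps > 1 & gaps < length(r$values)]
  if (length(gaps)) {
    r$values[gaps] <- TRUE
    above <- inverse.rle(r)
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  segs <- cbind(starts[runs$values], ends[runs$values])
  out <- list()
  for (k in seq_len(nrow(segs))) {
    i0 <- segs[k, 1]; i1 <- segs[k, 2]
    idx <- i0:i1
    yy <- ys[idx]
    # local maxima of the smoothed segment
    is_max <- yy >= c(-Inf, head(yy, -1)) & yy > c(tail(yy, -1), -Inf)
    apexes <- idx[is_max]
    if (!length(apexes)) apexes <- idx[which.max(yy)]
    # merge apexes separated only by shallow (noise) dips
    while (length(apexes) > 1) {
      merged <- FALSE
      for (j in seq_len(length(apexes) - 1)) {
        between <- apexes[j]:apexes[j + 1]
        valley <- min(ys[between])
        if (valley > valley_frac * min(ys[apexes[j]], ys[apexes[j + 1]])) {
          keep <- if (ys[apexes[j]] >= ys[apexes[j + 1]]) j else j + 1
          apexes <- apexes[-(j + (keep == j))]
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
    # split at the smoothed minimum between surviving apexes
    cuts <- integer(0)
    if (length(apexes) > 1) {
      for (j in seq_len(length(apexes) - 1)) {
        between <- apexes[j]:apexes[j + 1]
        cuts <- c(cuts, between[which.min(ys[between])])
      }
    }
    bounds <- c(i0, cuts, i1)
    for (j in seq_len(length(apexes))) {
      a0 <- bounds[j]; a1 <- bounds[j + 1]
      sub <- a0:a1
      if (length(sub) < min_points) next
      apex <- sub[which.max(y[sub])]
      out[[length(out) + 1]] <- tibble(
        apex_rt = rt[apex], rt_start = rt[a0], rt_end = rt[a1],
        area = trapezoid(rt[sub], y[sub]), height = y[apex],
        snr = if (noise > 0) y[apex] / noise else Inf,
        n_points = length(sub)
      )
    }
  }
  if (!length(out)) return(empty)
  arrange(bind_rows(out), .data$apex_rt)
}

# linear interpolation across interior runs of <= 2 exact zeros
fill_dropouts <- function(y) {
  r <- rle(y == 0)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  short <- which(r$values & r$lengths <= 2 & starts > 1 & ends < length(y))
  for (k in short) {
    i0 <- starts[k] - 1; i1 <- ends[k] + 1
    y[starts[k]:ends[k]] <- approx(c(i0, i1), y[c(i0, i1)],
                                   xout = starts[k]:ends[k])$y
  }
  y
}

moving_mean <- function(y, k) {
  if (length(y) < 2 * k + 1) return(y)
  n <- length(y)
  cs <- cumsum(c(0, y))
  i0 <- pmax(0, seq_len(n) - k - 1)
  i1 <- pmin(n, seq_len(n) + k)
  (cs[i1 + 1] - cs[i0 + 1]) / (i1 - i0)
}

trapezoid <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Average spectra under a retention-time window
#'
#' Pools the centroids of all scans of `scan_kind` whose RT falls in
#' `rt_window`, clusters them within +/- 0.003 m/z, and reports per
#' cluster the intensity-weighted mean m/z and the mean intensity over the
#' member scans (scans without a matching centroid contribute zero, so the
#' average of N identical spectra is that spectrum).
#'
#' @param run An [aif_run()].
#' @param rt_window `c(start, end)` in minutes; must overlap at least one
#'   scan of the requested kind.
#' @param scan_kind `"full"` or `"AIF"`.
#' @param cluster_mz Clustering half-width in m/z units.
#' @return A tibble (`mz`, `intensity`), sorted by m/z, with the window
#'   and the number of averaged scans as attributes.
#' @export
average_spectrum <- function(run, rt_window, scan_kind = c("AIF", "full"),
                             cluster_mz = 0.003) {
  scan_kind <- match.arg(scan_kind)
  s <- run_scans(run, scan_kind)
  s <- filter(s, .data$rt >= rt_window[1], .data$rt <= rt_window[2])
  if (!nrow(s)) {
    abort(paste0("no '", scan_kind, "' scan in RT window [",
                 rt_window[1], ", ", rt_window[2], "] min"))
  }
  all_pk <- bind_rows(s$peaks)
  if (!nrow(all_pk)) {
    out <- tibble(mz = numeric(), intensity = numeric())
  } else {
    all_pk <- arrange(all_pk, .data$mz)
    cl <- cumsum(c(1, diff(all_pk$mz) > cluster_mz))
    out <- all_pk |>
      mutate(cluster = cl) |>
      group_by(.data$cluster) |>
      summarise(mz = if (sum(.data$intensity) > 0)
                  sum(.data$mz * .data$intensity) / sum(.data$intensity)
                else mean(.data$mz),
                intensity = sum(.data$intensity) / nrow(s),
                .groups = "drop") |>
      select("mz", "intensity") |>
      arrange(.data$mz)
  }
  structure(out, rt_window = rt_window, n_scans = nrow(s),
            scan_kind = scan_kind, class = c("aif_spectrum", class(tibble())))
}
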