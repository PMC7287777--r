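# Shared simulated fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# standards mix with default noise
std_sim <- function() cached("std", simulate_run(standards_config(seed = 42)))

# standards mix, noise-free (exact intensity bookkeeping)
std_sim_clean <- function() {
  cached("std_clean", simulate_run(standards_config(
    seed = 7, mz_jitter_ppm = 0, noise_cv = 0, baseline_frac = 0)))
}

plasma_sim <- function() cached("plasma", simulate_run(plasma_like_config(seed = 1)))

# small synthetic trace: Gaussian peak(s) on a regular grid
gauss_trace <- function(apexes, heights, sigma = 0.08, rt = seq(0, 4, by = 0.02),
                        noise = 0) {
  y <- rep(0, length(rt))
  for (i in seq_along(apexes)) {
    y <- y + heights[i] * exp(-(rt - apexes[i])^2 / (2 * sigma^2))
  }
  if (noise > 0) y <- pmax(y + rnorm(length(rt), 0, noise), 0)
  structure(tibble::tibble(rt = rt, intensity = y),
            target_mz = 500, tol_ppm = 5, scan_kind = "full",
            class = c("aif_trace", class(tibble::tibble())))
}

# tiny two-species run for fast structural tests
tiny_run <- function(seed = 3, ...) {
  sp <- tibble::tibble(
    name = c("PG 18:0/20:4", "PC 16:0/18:0"),
    ion = c("[M-H]-", "[M-CH3]-"),
    abundance = c(1e5, 2e5),
    rt_apex = c(7.2, 15.3), rt_sigma = 0.08)
  simulate_run(sim_config(sp, rt_range = c(6.5, 16), seed = seed,
                          polarity = "negative", ...))
}
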