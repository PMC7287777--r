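test_that("identical seeds give identical runs; different seeds differ", {
  a <- simulate_run(standards_config(seed = 5))
  b <- simulate_run(standards_config(seed = 5))
  expect_identical(a$run$spectra$peaks, b$run$spectra$peaks)
  c_ <- simulate_run(standards_config(seed = 6))
  expect_false(identical(a$run$spectra$peaks, c_$run$spectra$peaks))
})

test_that("doubling abundances doubles every centroid exactly", {
  base <- standards_config(seed = 9)
  doubled <- standards_config(seed = 9, abundance = 2e6)
  a <- simulate_run(base)$run
  b <- simulate_run(doubled)$run
  for (i in seq_len(nrow(a$spectra))) {
    expect_equal(b$spectra$peaks[[i]]$intensity,
                 2 * a$spectra$peaks[[i]]$intensity, tolerance = 1e-12)
  }
})

test_that("generated fragment m/z match the fragmentation rules before jitter", {
  res <- std_sim_clean()
  frs <- res$truth$fragments
  for (nm in names(frs)) {
    sp <- res$truth$species[res$truth$species$name == nm, ]
    pred <- suppressWarnings(predict_fragments(nm, sp$ion))
    sim_mz <- frs[[nm]]$mz[frs[[nm]]$kind != "residual_precursor"]
    for (m in sim_mz) {
      expect_lt(min(abs(pred$mz - m)), 1e-4)
    }
  }
})

test_that("standards run puts band apexes on the configured retention times", {
  res <- std_sim()
  truth <- res$truth$species
  for (i in seq_len(nrow(truth))) {
    tr <- extract_xic(res$run, truth$mz[i], 5, "full")
    pk <- detect_peaks(tr)
    expect_equal(nrow(pk), 1L, info = truth$name[i])
    expect_equal(pk$apex_rt, truth$rt_apex[i], tolerance = 0.021,
                 info = truth$name[i])
  }
})

test_that("noise-free AIF carboxylate ratio reads back the sn bias exactly", {
  res <- std_sim_clean()
  bias <- res$truth$config$sn_bias
  avg <- average_spectrum(res$run, c(7.0, 7.4), "AIF")
  i204 <- avg$intensity[abs(avg$mz - carboxylate_mz(20, 4)) < 0.003]
  i180 <- avg$intensity[abs(avg$mz - carboxylate_mz(18, 0)) < 0.003]
  expect_equal(i204 / i180, bias, tolerance = 1e-9)

  # loss ions follow the same bias: losses of the sn-2 chain are stronger
  fr <- predict_fragments("PG 18:0/20:4", "[M-H]-")
  m_fa <- function(chain) fr$mz[fr$kind == "FA_loss" & fr$chain == chain]
  l204 <- avg$intensity[abs(avg$mz - m_fa("FA C20:4")) < 0.003]
  l180 <- avg$intensity[abs(avg$mz - m_fa("FA C18:0")) < 0.003]
  expect_equal(l204 / l180, bias, tolerance = 1e-9)
  sn <- sn_assignment_rule(tibble::tibble(
    chain = c("FA C18:0", "FA C20:4"), fa_loss = c(l180, l204),
    ketene_loss = c(l180, l204)))
  expect_equal(sn$sn, c("sn1", "sn2"))
})

test_that("config validation guards yields, bias, seed and RT range", {
  sp <- tibble::tibble(name = "PE 14:0/14:0", ion = "[M-H]-",
                       abundance = 1, rt_apex = 10, rt_sigma = 0.1)
  expect_error(sim_config(sp), "seed")
  expect_error(sim_config(sp, carboxylate_yield = 0.9,
                          residual_precursor_fraction = 0.3, seed = 1),
               "sum")
  expect_error(sim_config(sp, sn_bias = 2, seed = 1), "sn_bias")
  expect_error(sim_config(sp, rt_range = c(11, 12), seed = 1), "RT range")
})

test_that("plasma-like ground truth reproduces the reference composition", {
  cfg <- plasma_like_config(seed = 2)
  truth <- simulate_run(cfg)$truth$class_fa_pct
  ref <- plasma_fa_reference()
  for (cls in c("PI", "PE", "PC", "LPC")) {
    t_cls <- truth[truth$lipid_class == cls, ]
    expect_equal(sum(t_cls$pct), 100, tolerance = 1e-6)
    col <- ref[[tolower(cls)]]
    keep <- !is.na(col) & col > 0
    expected <- 100 * col[keep] / sum(col[keep])
    got <- t_cls$pct[match(ref$chain[keep], t_cls$chain)]
    expect_equal(got, expected, tolerance = 1e-6)
  }
  # spot values: LPC C16:0 and PI C18:0 as printed (column sums ~100)
  lpc <- truth[truth$lipid_class == "LPC" & truth$chain == "FA C16:0", ]
  expect_equal(lpc$pct, 40.0, tolerance = 0.05)
  pi_ <- truth[truth$lipid_class == "PI" & truth$chain == "FA C18:0", ]
  expect_equal(pi_$pct, 29.2, tolerance = 0.05)
})
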