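test_that("diagnostic traces locate class bands in HILIC elution order", {
  res <- std_sim()
  bands <- locate_class_bands(res$run)
  # 196.038 separates PE and LPE; 224.069 separates PC and LPC
  expect_setequal(bands$lipid_class, c("PE", "LPE", "PC", "LPC"))
  apex <- setNames(bands$apex_rt, bands$lipid_class)
  expect_equal(unname(apex[c("PE", "LPE", "PC", "LPC")]),
               c(10.2, 14.0, 15.3, 17.3), tolerance = 0.05)
  expect_true(apex["PE"] < apex["LPE"])
  expect_true(apex["LPE"] < apex["PC"])
  expect_true(apex["PC"] <= apex["LPC"])
  # PG has no negative-mode diagnostic: located mass-only via its precursor
  pg <- detect_peaks(extract_xic(res$run, ion_mz("PG 18:0/20:4", "[M-H]-"),
                                 5, "full"))
  expect_true(pg$apex_rt[which.max(pg$height)] < apex["PE"])
  expect_warning(locate_class_bands(res$run, expect_classes = c("PE", "PG")),
                 "mass-only")
})

test_that("a run without PI shows no 241.012 band", {
  res <- std_sim()
  bands <- locate_class_bands(res$run)
  expect_false(any(purrr::map_lgl(bands$classes, ~ "PI" %in% .x)))
})

test_that("noise-free annotation reaches full recall with no false positives", {
  res <- std_sim_clean()
  bands <- dplyr::bind_rows(
    manual_band("PG", 6.9, 7.5), locate_class_bands(res$run))
  cand <- dplyr::bind_rows(
    enumerate_candidates(c("PG", "PE", "LPE"), c(12, 44), c(0, 8), "[M-H]-"),
    enumerate_candidates(c("PC", "LPC"), c(12, 44), c(0, 8), "[M-CH3]-"))
  ann <- annotate_species(res$run, bands, cand)
  truth <- res$truth$species
  for (i in seq_len(nrow(truth))) {
    j <- which(abs(ann$theoretical_mz - truth$mz[i]) < 1e-6)
    expect_equal(length(j), 1L, info = truth$name[i])
    expect_lte(abs(ann$mass_error[j]), 0.005)
    expect_equal(ann$apex_rt[j], truth$rt_apex[i], tolerance = 0.05)
  }
  expect_equal(nrow(ann), nrow(truth))   # zero false positives
})

test_that("isobars in different bands are kept apart", {
  # [PE 40:6 - H]- and [PC 38:6 - CH3]- share one formula; HILIC bands
  # keep them apart
  expect_equal(ion_mz("PE 40:6", "[M-H]-"), ion_mz("PC 38:6", "[M-CH3]-"),
               tolerance = 1e-9)
  sp <- tibble::tibble(
    name = c("PE 18:0/22:6", "PC 16:0/22:6"),
    ion = c("[M-H]-", "[M-CH3]-"), abundance = 1e5,
    rt_apex = c(10.2, 15.3), rt_sigma = 0.08)
  res <- simulate_run(sim_config(sp, rt_range = c(9, 16.5), seed = 21,
                                 polarity = "negative"))
  bands <- locate_class_bands(res$run)
  cand <- dplyr::bind_rows(
    enumerate_candidates("PE", c(40, 40), c(6, 6), "[M-H]-"),
    enumerate_candidates("PC", c(38, 38), c(6, 6), "[M-CH3]-"))
  ann <- annotate_species(res$run, bands, cand)
  pe <- ann[ann$lipid_class == "PE", ]; pc <- ann[ann$lipid_class == "PC", ]
  expect_equal(nrow(pe), 1L); expect_equal(nrow(pc), 1L)
  expect_equal(pe$apex_rt, 10.2, tolerance = 0.05)
  expect_equal(pc$apex_rt, 15.3, tolerance = 0.05)
})

test_that("FA profiles normalize to 100 and recover generator fractions", {
  res <- plasma_sim()
  bands <- locate_class_bands(res$run)
  truth <- res$truth$class_fa_pct
  for (cls in c("PI", "PE", "PC", "LPC")) {
    band <- bands[purrr::map_lgl(bands$classes, ~ cls %in% .x), ][1, ]
    prof <- fa_profile(res$run, band)
    expect_equal(sum(prof$relative_pct), 100, tolerance = 0.1)
    t_cls <- truth[truth$lipid_class == cls, ]
    got <- prof$relative_pct[match(t_cls$chain, prof$chain)]
    got[is.na(got)] <- 0
    expect_true(all(abs(got - t_cls$pct) < 2), info = cls)
  }
})

test_that("single-chain classes profile over lyso chains only", {
  res <- plasma_sim()
  bands <- locate_class_bands(res$run)
  lpc <- bands[bands$lipid_class == "LPC", ]
  prof <- fa_profile(res$run, lpc)
  lpc_truth <- res$truth$class_fa_pct
  lpc_truth <- lpc_truth[lpc_truth$lipid_class == "LPC", ]
  expect_setequal(prof$chain, lpc_truth$chain)
})

test_that("an empty band yields an empty profile with a warning", {
  res <- std_sim()
  dead <- manual_band("PI", 8.0, 8.4)
  expect_warning(prof <- fa_profile(res$run, dead), "empty profile")
  expect_equal(nrow(prof), 0L)
})

test_that("band slices expose the within-band chain gradient", {
  # long-chain species at the band front, short-chain at the tail
  sp <- tibble::tibble(
    name = c("PC 22:6/22:6", "PC 16:0/16:0"),
    ion = "[M-CH3]-", abundance = 1e5,
    rt_apex = c(15.15, 15.45), rt_sigma = 0.05)
  res <- simulate_run(sim_config(sp, rt_range = c(14.5, 16.2), seed = 12,
                                 polarity = "negative"))
  band <- manual_band("PC", 15.0, 15.6)
  slices <- band_slices(res$run, band, 4)
  expect_equal(nrow(slices), 4L)
  mz226 <- carboxylate_mz(22, 6)
  sig <- purrr::map_dbl(slices$spectrum, function(s) {
    sum(s$intensity[abs(s$mz - mz226) < 0.005])
  })
  expect_gt(sig[1], 0)
  rel <- sig / max(sig)
  expect_lt(rel[4], 0.01)     # FA C22:6 has vanished at the band tail

  one <- band_slices(res$run, band, 1)
  avg <- average_spectrum(res$run, c(band$rt_start, band$rt_end), "AIF")
  expect_equal(one$spectrum[[1]]$mz, avg$mz)
  expect_equal(one$spectrum[[1]]$intensity, avg$intensity)
  expect_error(band_slices(res$run, band, 10000), "exceeds")
  expect_error(band_slices(res$run, manual_band("PC", 1, 1.2), 2), "no AIF")
})

test_that("precursor-product alignment links shared acyl chains", {
  sp <- tibble::tibble(
    name = c("PC 16:0/22:6", "PC 18:0/22:6", "PE 18:0/20:4"),
    ion = c("[M-CH3]-", "[M-CH3]-", "[M-H]-"),
    abundance = c(1e6, 8e5, 9e5),
    rt_apex = c(15.25, 15.32, 10.2), rt_sigma = 0.08)
  res <- simulate_run(sim_config(sp, rt_range = c(9, 16.5), seed = 5,
                                 polarity = "negative"))
  bands <- dplyr::bind_rows(manual_band("PC", 14.9, 15.7),
                            manual_band("PE", 9.8, 10.6))
  cand <- dplyr::bind_rows(
    enumerate_candidates("PC", c(38, 40), c(6, 6), "[M-CH3]-"),
    enumerate_candidates("PE", c(38, 38), c(4, 4), "[M-H]-"))
  ann <- annotate_species(res$run, bands, cand)
  links <- align_precursor_product(res$run, carboxylate_mz(22, 6), ann)
  expect_setequal(links$name, c("PC 38:6", "PC 40:6"))
  expect_true(all(links$shape_correlation >= 0.8))
  expect_true(all(links$rt_delta <= 0.1))

  # no temporally compatible precursor -> no links
  far <- align_precursor_product(res$run, carboxylate_mz(22, 6),
                                 ann[ann$lipid_class == "PE", ])
  expect_equal(nrow(far), 0L)

  # tolerance contract: shifting the candidate apex beyond rt_tol breaks it
  shifted <- ann[ann$lipid_class == "PC", ]
  shifted$apex_rt <- shifted$apex_rt + 0.5
  expect_equal(nrow(align_precursor_product(res$run, carboxylate_mz(22, 6),
                                            shifted)), 0L)
})

test_that("ratio traces emit gaps, not zeros, where undefined", {
  res <- std_sim()
  mz204 <- carboxylate_mz(20, 4)
  same <- ratio_trace(res$run, mz204, mz204)
  expect_true(all(abs(na.omit(same$ratio) - 1) < 1e-12))
  none <- ratio_trace(res$run, mz204, 1500.0)
  expect_true(all(is.na(none$ratio)))
})

test_that("the C20:3/C20:4 ratio drops when the C20:3 donor is depleted", {
  mk <- function(frac203, seed) {
    sp <- tibble::tibble(
      name = c("PI 20:3/20:3", "PI 20:4/20:4"),
      ion = "[M-H]-",
      abundance = c(frac203, 1) * 1e5,
      rt_apex = 8.5, rt_sigma = 0.08)
    simulate_run(sim_config(sp, rt_range = c(7.5, 9.5), seed = seed,
                            polarity = "negative"))
  }
  ctrl <- mk(0.75, 31); pd <- mk(0.20, 32)
  band_ratio <- function(res) {
    rt <- ratio_trace(res$run, carboxylate_mz(20, 3), carboxylate_mz(20, 4))
    median(rt$ratio[rt$rt > 8.3 & rt$rt < 8.7], na.rm = TRUE)
  }
  expect_gt(band_ratio(ctrl), 3 * band_ratio(pd))
})

test_that("replicate filtering applies the RSD rule and class percentages", {
  mk_ann <- function(area_pg, area_pc, with_pe = TRUE) {
    x <- tibble::tibble(
      name = c("PG 38:4", "PC 34:0", if (with_pe) "PE 28:0"),
      lipid_class = c("PG", "PC", if (with_pe) "PE"),
      ion = c("[M-H]-", "[M-CH3]-", if (with_pe) "[M-H]-"),
      area = c(area_pg, area_pc, if (with_pe) 50))
    x
  }
  reps <- list(mk_ann(100, 100), mk_ann(110, 160), mk_ann(90, 40, FALSE))
  out <- replicate_filter(reps, max_rsd_pct = 20)
  # (100,110,90): RSD = 10% -> kept; (100,160,40): RSD = 60% -> dropped;
  # PE missing in one replicate -> dropped
  expect_equal(out$name, "PG 38:4")
  expect_equal(out$rsd_pct, 100 * sd(c(100, 110, 90)) / 100, tolerance = 1e-9)
  expect_equal(out$class_pct, 100)
  expect_error(replicate_filter(reps[1]), "2 replicates")
})

test_that("replicate FA profiles combine to mean with sd and renormalize", {
  res <- plasma_sim()
  bands <- locate_class_bands(res$run)
  lpc <- bands[bands$lipid_class == "LPC", ]
  p1 <- fa_profile(res$run, lpc)
  res2 <- simulate_run(plasma_like_config(seed = 77))
  b2 <- locate_class_bands(res2$run)
  p2 <- fa_profile(res2$run, b2[b2$lipid_class == "LPC", ])
  comb <- combine_fa_profiles(list(p1, p2))
  expect_equal(sum(comb$relative_pct), 100, tolerance = 0.1)
  expect_true(all(is.finite(comb$sd_pct)))
  td <- tidy(comb)
  expect_true(all(c("chain", "mz", "relative_pct", "sd_pct") %in% names(td)))
})
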