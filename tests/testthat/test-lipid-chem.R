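test_that("shorthand parsing populates species and rejects bad input", {
  sp <- parse_shorthand("PC 14:0/16:0")
  expect_equal(sp$lipid_class, "PC")
  expect_equal(length(sp$chains), 2L)
  expect_equal(unname(sp$chains[[1]]), c(14L, 0L))
  expect_true(sp$sn_known)

  lyso <- parse_shorthand("LPE 13:0/0:0")
  expect_equal(lyso$lipid_class, "LPE")
  expect_equal(length(lyso$chains), 1L)
  expect_true(lyso$sn_known)

  sum_sp <- parse_shorthand("PC 30:0")
  expect_false(sum_sp$sn_known)
  expect_equal(unname(sum_sp$chains[[1]]), c(30L, 0L))

  expect_error(parse_shorthand("QX 34:1"), "unknown lipid class")
  expect_error(parse_shorthand("PC 10:8"), "double bonds")
  expect_error(parse_shorthand("PC 16:0/16:0/16:0"), "chain")
})

test_that("parse/format round-trips over a generated grammar sample", {
  set.seed(11)
  classes <- c("PC", "PE", "PG", "PI", "PS", "PA")
  names <- c(
    purrr::map_chr(1:25, function(i) {
      cls <- sample(classes, 1)
      c1 <- sample(12:22, 1); d1 <- sample(0:floor(c1 / 2), 1)
      c2 <- sample(12:22, 1); d2 <- sample(0:floor(c2 / 2), 1)
      paste0(cls, " ", c1, ":", d1, "/", c2, ":", d2)
    }),
    purrr::map_chr(1:10, function(i) {
      cls <- sample(classes, 1)
      c1 <- sample(24:44, 1); d1 <- sample(0:8, 1)
      paste0(cls, " ", c1, ":", d1)
    }),
    "LPC 17:0/0:0", "LPE 13:0/0:0", "PC O-38:6", "SM d18:1/16:0"
  )
  for (nm in names) {
    expect_identical(format_shorthand(parse_shorthand(nm)), nm)
  }
})

test_that("monoisotopic mass is strictly additive over random formula pairs", {
  set.seed(4)
  els <- c("C", "H", "N", "O", "P", "Na", "S")
  for (i in 1:40) {
    a <- el_formula(setNames(sample(0:20, length(els), replace = TRUE), els))
    b <- el_formula(setNames(sample(0:20, length(els), replace = TRUE), els))
    expect_equal(monoisotopic_mass(formula_add(a, b)),
                 monoisotopic_mass(a) + monoisotopic_mass(b),
                 tolerance = 1e-9)
  }
  expect_equal(monoisotopic_mass(el_formula()), 0)
  expect_equal(monoisotopic_mass("H2O"), 18.01056, tolerance = 1e-5)
})

test_that("formula arithmetic never yields negative counts", {
  expect_error(formula_subtract("CH4", "C2H2"), "negative")
  f <- formula_subtract("C2H6O", "H2O")
  expect_equal(unname(f$counts[c("C", "H")]), c(2, 4))
})

test_that("neutral formulas match hand-audited atom bookkeeping", {
  expect_identical(format(formula_of("PE 14:0/14:0")), "C33H66NO8P")
  expect_identical(format(formula_of("LPC 17:0/0:0")), "C25H52NO7P")
  expect_identical(format(formula_of("PI 18:0/20:4")), "C47H83O13P")
  # sum composition equals any chain split of the same totals
  expect_equal(monoisotopic_mass(formula_of("PC 34:0")),
               monoisotopic_mass(formula_of("PC 16:0/18:0")), tolerance = 1e-12)
})

test_that("ether subclass differs from diacyl by exactly O - 2H", {
  for (nm in c("PC 38:6", "PE 34:2", "LPC 16:0")) {
    di <- formula_of(nm)
    eth <- formula_of(parse_shorthand(sub(" ", " O-", nm)))
    # diacyl + H2 == ether + O, i.e. diacyl - ether = O - 2H exactly
    expect_identical(format(formula_subtract(formula_add(di, "H2"), eth)), "O")
  }
  # the demonstrative positive-mode isobar: protonated ether PC 38:6
  expect_identical(format(formula_add(formula_of("PC O-38:6"), el_formula("H"))),
                   "C46H83NO7P")
  expect_equal(round(ion_mz("PC O-38:6", "[M+H]+"), 3), 792.590)
})

test_that("ion m/z reproduces the printed precursor values", {
  expect_equal(round(ion_mz("PG 18:0/20:4", "[M-H]-"), 3), 797.534)
  expect_equal(round(ion_mz("PE 14:0/14:0", "[M-H]-"), 3), 634.445)
  expect_equal(round(ion_mz("LPE 13:0/0:0", "[M-H]-"), 3), 410.231)
  expect_equal(round(ion_mz("PC 16:0/18:0", "[M-CH3]-"), 3), 746.571)
  expect_equal(round(ion_mz("LPC 17:0/0:0", "[M-CH3]-"), 3), 494.325)
  expect_error(ion_mz("PE 34:1", "[M-CH3]-"), "choline")
})

test_that("carboxylate m/z matches the reference column and validates input", {
  expect_equal(round(carboxylate_mz(18, 0), 3), 283.264)
  expect_equal(round(carboxylate_mz(20, 4), 3), 303.233)
  expect_equal(round(carboxylate_mz(13, 0), 3), 213.186)
  expect_equal(round(carboxylate_mz(16, 0), 3), 255.233)
  ref <- plasma_fa_reference()
  expect_equal(round(ref$mz, 3),
               c(227.202, 255.233, 253.217, 269.249, 267.233, 283.264,
                 281.249, 279.233, 277.217, 309.280, 307.264, 305.248,
                 303.233, 301.217, 333.280, 331.264, 329.249, 327.233),
               tolerance = 1e-3)
  expect_error(carboxylate_mz(1, 0), "carbons")
  expect_error(carboxylate_mz(10, 5), "double bonds")
})

test_that("candidate enumeration is exhaustive, sorted and ion-aware", {
  one <- enumerate_candidates("PC", c(34, 34), c(0, 0), "[M-CH3]-")
  expect_equal(nrow(one), 1L)
  expect_equal(round(one$mz, 3), 746.571)

  pi_one <- enumerate_candidates("PI", c(38, 38), c(4, 4), "[M-H]-")
  expect_equal(round(pi_one$mz, 3), round(ion_mz("PI 18:0/20:4", "[M-H]-"), 3))

  grid <- enumerate_candidates("PE", c(30, 36), c(0, 3), "[M-H]-")
  expect_equal(nrow(grid), 7 * 4)        # odd and even carbon totals included
  expect_false(is.unsorted(grid$mz))
  expect_true(any(grid$name == "PE 33:1"))

  # [M-CH3]- silently skipped for a non-choline class
  expect_equal(nrow(enumerate_candidates("PE", c(34, 34), c(0, 0), "[M-CH3]-")), 0L)
  expect_equal(nrow(enumerate_candidates("PC", c(34, 33), c(0, 0), "[M-H]-")), 0L)
})
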