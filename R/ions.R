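.proton_mass <- 1.00727646677  # H minus electron

#' Ion (adduct) types
#'
#' The ESI ion species the pipeline works with. `mass_delta` is the signed
#' Da added to the neutral monoisotopic mass and already includes the
#' electron-mass correction; `charge` carries the sign. `[M-CH3]-` (loss of
#' a methyl radical from formate/acetate adducts under in-source
#' dissociation) is chemically restricted to choline-bearing classes
#' (PC, LPC, SM).
#'
#' @return A tibble with columns `ion`, `mass_delta`, `charge`,
#'   `choline_only`.
#' @export
ion_types <- function() {
  e <- .electron_mass
  tibble(
    ion = c("[M+H]+", "[M+Na]+", "[M-H]-", "[M-CH3]-",
            "[M+HCOO]-", "[M+CH3COO]-"),
    mass_delta = c(
      .proton_mass,
      monoisotopic_mass("Na") - e,
      -(monoisotopic_mass("H") - e),
      -(monoisotopic_mass("CH3") - e),
      monoisotopic_mass("CHO2") + e,
      monoisotopic_mass("C2H3O2") + e
    ),
    charge = c(1L, 1L, -1L, -1L, -1L, -1L),
    choline_only = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  )
}

ion_info <- function(ion) {
  tab <- ion_types()
  i <- match(ion, tab$ion)
  if (is.na(i)) abort(paste0("unknown ion type '", ion, "'"))
  as.list(tab[i, ])
}

ion_polarity <- function(ion) {
  if (ion_info(ion)$charge > 0) "positive" else "negative"
}

#' m/z of an ionized lipid or formula
#'
#' `m/z = (neutral mass + mass_delta) / |z|`. When a `lipid_species` is
#' supplied, class rules are enforced: `[M-CH3]-` is refused for classes
#' without a choline head group. Values are returned unrounded; reports
#' round to 3 decimals.
#'
#' @param x A `lipid_species`, shorthand string, or neutral `el_formula`.
#' @param ion Ion name, e.g. `"[M-H]-"` (see [ion_types()]).
#' @return m/z in Th.
#' @examples
#' ion_mz("PG 18:0/20:4", "[M-H]-")   # 797.534
#' ion_mz("PC 16:0/18:0", "[M-CH3]-") # 746.571
#' @export
ion_mz <- function(x, ion) {
  info <- ion_info(ion)
  if (is.character(x)) x <- parse_shorthand(x)
  if (inherits(x, "lipid_species")) {
    if (info$choline_only && !isTRUE(class_info(x$lipid_class)$choline)) {
      abort(paste0(ion, " applies only to choline-bearing classes, not ",
                   x$lipid_class))
    }
    x <- formula_of(x)
  }
  (monoisotopic_mass(x) + info$mass_delta) / abs(info$charge)
}

#' m/z of a fatty-acyl carboxylate anion
#'
#' The `[RCOO]-` anion of the fatty acid with `carbons` carbons and
#' `double_bonds` C=C double bonds: formula `[C_cH_(2c-1-2d)O2]-`,
#' electron mass included. These product ions report the acyl-chain
#' composition of glycerophospholipids in negative-mode AIF spectra.
#'
#' @param carbons Chain carbons (>= 2). Vectorized.
#' @param double_bonds Number of double bonds. Vectorized.
#' @return m/z in Th.
#' @examples
#' carboxylate_mz(18, 0)  # 283.264
#' carboxylate_mz(20, 4)  # 303.233
#' @export
carboxylate_mz <- function(carbons, double_bonds) {
  carbons <- unname(carbons); double_bonds <- unname(double_bonds)
  if (any(carbons < 2)) abort("carboxylate needs >= 2 carbons")
  if (any(double_bonds < 0) || any(double_bonds > (carbons - 1) / 2)) {
    abort("double bonds exceed (carbons - 1)/2")
  }
  carbons * .atomic_mass[["C"]] +
    (2 * carbons - 1 - 2 * double_bonds) * .atomic_mass[["H"]] +
    2 * .atomic_mass[["O"]] + .electron_mass
}

fatty_acid_formula <- function(carbons, double_bonds) {
  carbons <- unname(carbons); double_bonds <- unname(double_bonds)
  el_formula(c(C = carbons, H = 2 * carbons - 2 * double_bonds, O = 2))
}

#' Enumerate sum-composition annotation candidates
#'
#' Exhaustive grid of sum compositions (total carbons x total double bonds,
#' odd totals included) for a class, under each requested ion, sorted by
#' m/z. This is the combinatorial candidate list that accurate-mass
#' annotation matches against; it stands in for a curated lipid database.
#'
#' @param lipid_class Class name, e.g. `"PC"`. May be a character vector.
#' @param carbon_range `c(min, max)` total acyl carbons.
#' @param db_range `c(min, max)` total double bonds.
#' @param ions Character vector of ion names; ions inapplicable to a class
#'   (e.g. `[M-CH3]-` for PE) are skipped for that class.
#' @return A tibble: `name`, `lipid_class`, `ion`, `mz`, `species`
#'   (list-column of `lipid_species`), sorted by `mz`.
#' @export
enumerate_candidates <- function(lipid_class, carbon_range, db_range, ions) {
  grids <- purrr::map_dfr(lipid_class, function(cls) {
    info <- class_info(cls)
    if (diff(range(carbon_range)) < 0 || carbon_range[2] < carbon_range[1] ||
        db_range[2] < db_range[1]) {
      return(tibble())
    }
    tidyr::expand_grid(
      lipid_class = cls,
      carbons = seq(carbon_range[1], carbon_range[2]),
      double_bonds = seq(db_range[1], db_range[2])
    ) |>
      filter(.data$double_bonds <= .data$carbons / 2) |>
      tidyr::expand_grid(ion = ions) |>
      filter(!ion_types()$choline_only[match(.data$ion, ion_types()$ion)] |
               isTRUE(info$choline)) |>
      filter(!(info$kind == "sphingolipid" & .data$carbons < 20))
  })
  if (!nrow(grids)) {
    return(tibble(name = character(), lipid_class = character(),
                  ion = character(), mz = numeric(), species = list()))
  }
  grids |>
    mutate(
      species = purrr::pmap(list(.data$lipid_class, .data$carbons,
                                 .data$double_bonds),
        function(cls, c_, d_) {
          new_lipid_species(cls, list(c(carbons = c_, double_bonds = d_)))
        }),
      name = purrr::map_chr(.data$species, format_shorthand),
      mz = purrr::map2_dbl(.data$species, .data$ion, ion_mz)
    ) |>
    arrange(.data$mz) |>
    select("name", "lipid_class", "ion", "mz", "species")
}
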