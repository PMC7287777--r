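.inositol_loss <- "C6H10O5"  # dehydrated inositol, 162.0528 Da

#' Class-diagnostic fragment ions
#'
#' The head-group and backbone fragments that localize lipid classes in
#' AIF chromatograms: protonated phosphocholine 184.073 (PC/LPC/SM,
#' positive), the demethylated glycerophosphocholine head 224.069 (PC/LPC,
#' negative), the glycerophosphoethanolamine head 196.038 (PE/LPE,
#' negative), the inositol phosphate head 241.012 (PI, negative), and the
#' doubly dehydrated sphingoid-base cations 264.269 (d18:1), 236.237
#' (d16:1) and 262.253 (d18:2) shared by sphingolipid classes. Every m/z is
#' computed from its charged formula at load time, never stored as a
#' number.
#'
#' @param polarity Optional filter: `"positive"` or `"negative"`.
#' @param lipid_class Optional filter: keep diagnostics covering this class.
#' @return A tibble: `label`, `polarity`, `formula` (list of `el_formula`),
#'   `mz`, `lipid_classes` (list-column), `note`.
#' @examples
#' diagnostic_table("negative", "PI")$mz  # 241.012
#' @export
diagnostic_table <- function(polarity = NULL, lipid_class = NULL) {
  d <- load_class_data()$diagnostics
  if (!is.null(polarity)) d <- filter(d, .data$polarity == !!polarity)
  if (!is.null(lipid_class)) {
    d <- filter(d, purrr::map_lgl(.data$lipid_classes,
                                  ~ lipid_class %in% .x))
  }
  d
}

#' Predict AIF/CID fragments of an ionized lipid
#'
#' Negative-mode glycerophospholipids yield, per acyl chain, the
#' carboxylate anion `[RCOO]-`, the fatty-acid neutral loss
#' `[parent - RCOOH]` and the ketene neutral loss `[parent - RCH=C=O]`;
#' PI additionally loses dehydrated inositol (162.0528 Da) from both loss
#' ions. Positive mode yields the class head-group fragment(s); positive
#' sphingolipids yield the doubly dehydrated sphingoid-base cation.
#' Fragments below m/z 50 or above the parent are never emitted.
#'
#' @param species A `lipid_species` or shorthand string. Chain-resolved
#'   species give per-chain loss ions with sn hints (first chain = sn-1);
#'   sum compositions give carboxylates only if the split is unknown.
#' @param ion Parent ion name, e.g. `"[M-H]-"`.
#' @return A tibble: `kind` (`carboxylate`, `FA_loss`, `ketene_loss`,
#'   `inositol_loss_after_FA`, `inositol_loss_after_ketene`,
#'   `head_fragment`, `sphingoid_fragment`), `mz`, `chain` (label or NA),
#'   `sn_hint`, `label`. Ion/polarity combinations without defined
#'   chemistry return an empty tibble with a warning.
#' @examples
#' predict_fragments("PI 18:0/20:4", "[M-H]-")
#' @export
predict_fragments <- function(species, ion) {
  if (is.character(species)) species <- parse_shorthand(species)
  info <- class_info(species$lipid_class)
  pol <- ion_polarity(ion)
  parent_mz <- ion_mz(species, ion)
  empty <- tibble(kind = character(), mz = numeric(), chain = character(),
                  sn_hint = character(), label = character())
  out <- list()

  diag <- diagnostic_table(pol, species$lipid_class)
  if (nrow(diag)) {
    kind <- ifelse(grepl("sphingoid", diag$label), "sphingoid_fragment",
                   "head_fragment")
    out$head <- tibble(kind = kind, mz = diag$mz, chain = NA_character_,
                       sn_hint = NA_character_, label = diag$label)
  }

  if (pol == "negative" && info$kind == "glycerophospholipid") {
    chains <- species$chains
    resolved <- species$sn_known || info$n_acyl == 1
    sn <- if (resolved && length(chains) == 2) c("sn1", "sn2")
          else if (resolved) "sn1" else NA_character_
    if (resolved) {
      rows <- purrr::imap_dfr(chains, function(ch, i) {
        lab <- paste0("FA C", ch[1], ":", ch[2])
        fa <- fatty_acid_formula(ch[1], ch[2])
        base <- tibble(
          kind = c("carboxylate", "FA_loss", "ketene_loss"),
          mz = c(carboxylate_mz(ch[1], ch[2]),
                 parent_mz - monoisotopic_mass(fa),
                 parent_mz - monoisotopic_mass(formula_subtract(fa, "H2O"))),
          chain = lab, sn_hint = sn[i],
          label = c(paste0(lab, " carboxylate"),
                    paste0("loss of ", lab, " as fatty acid"),
                    paste0("loss of ", lab, " as ketene")))
        if (species$lipid_class == "PI") {
          ino <- monoisotopic_mass(.inositol_loss)
          base <- bind_rows(base, tibble(
            kind = c("inositol_loss_after_FA", "inositol_loss_after_ketene"),
            mz = base$mz[base$kind %in% c("FA_loss", "ketene_loss")] - ino,
            chain = lab, sn_hint = sn[i],
            label = paste0("inositol loss after ",
                           c("FA loss of ", "ketene loss of "), lab)))
        }
        base
      })
    } else {
      # sum composition: the acyl split is unknown; no per-chain ions
      rows <- empty
    }
    out$acyl <- rows
  }

  if (pol == "positive" && info$kind == "sphingolipid" &&
      !any(grepl("sphingoid", names(out)))) {
    # base-specific fragment when the sphingoid base is explicit
    if (!is.null(species$sphingoid)) {
      b <- species$sphingoid
      frag <- el_formula(c(C = b[[1]], H = 2 * b[[1]] - 2 - 2 * b[[2]], N = 1),
                         charge = 1L)
      out$base <- tibble(kind = "sphingoid_fragment",
                         mz = monoisotopic_mass(frag),
                         chain = paste0("d", b[1], ":", b[2]),
                         sn_hint = NA_character_,
                         label = "sphingoid base - 2 H2O")
    }
  }

  res <- bind_rows(out)
  if (!nrow(res)) {
    warn(paste0("no fragmentation chemistry defined for ",
                format_shorthand(species), " as ", ion))
    return(empty)
  }
  res |>
    filter(.data$mz >= 50, .data$mz < parent_mz) |>
    distinct(.data$kind, .data$mz, .keep_all = TRUE) |>
    arrange(.data$mz)
}

#' Assign sn-positions from FA/ketene loss intensities
#'
#' In negative-mode CID of diacyl glycerophospholipids, neutral losses of
#' the sn-2 chain (as fatty acid or ketene) give the more intense loss
#' ions, so the chain whose summed FA + ketene loss signal is lower sits at
#' sn-1. Ties or missing signals leave both chains unassigned; a single
#' chain (lyso) is sn-1 by convention.
#'
#' @param loss_intensities A data frame with columns `chain`, `fa_loss`,
#'   `ketene_loss` (intensities; NA treated as missing).
#' @return The input tibble with an `sn` column: `"sn1"`, `"sn2"` or
#'   `"unknown"`.
#' @export
sn_assignment_rule <- function(loss_intensities) {
  x <- as_tibble(loss_intensities)
  stopifnot(all(c("chain", "fa_loss", "ketene_loss") %in% names(x)))
  if (nrow(x) == 1) return(mutate(x, sn = "sn1"))
  if (nrow(x) != 2) abort("sn assignment is defined for 1 or 2 chains")
  tot <- x$fa_loss + x$ketene_loss
  if (any(is.na(tot)) || tot[1] == tot[2]) return(mutate(x, sn = "unknown"))
  mutate(x, sn = ifelse(tot == min(tot), "sn1", "sn2"))
}
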