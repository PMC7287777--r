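#' Lipid class table
#'
#' The package ships its class knowledge (glycerophospho core formulas,
#' acyl-chain counts, choline flag, HILIC elution ranks and default band
#' retention times) as a versioned YAML file under `inst/extdata`. This
#' returns it as a tibble, one row per class.
#'
#' @return A tibble with columns `lipid_class`, `kind`, `core`, `n_acyl`,
#'   `hexoses`, `choline`, `elution_rank`, `default_rt`.
#' @export
class_table <- function() {
  load_class_data()$classes
}

load_class_data <- function() {
  if (!is.null(the$class_data)) return(the$class_data)
  path <- system.file("extdata", "class_table.yaml", package = "aiflipid",
                      mustWork = TRUE)
  raw <- yaml::yaml.load_file(path)
  classes <- purrr::imap_dfr(raw$classes, function(x, nm) {
    tibble(
      lipid_class = nm,
      kind = x$kind,
      core = x$core %||% NA_character_,
      n_acyl = x$n_acyl %||% 1L,
      hexoses = x$hexoses %||% 0L,
      choline = isTRUE(x$choline),
      elution_rank = x$elution_rank %||% NA_real_,
      default_rt = x$default_rt %||% NA_real_
    )
  })
  diagnostics <- purrr::map_dfr(raw$diagnostics, function(d) {
    f <- el_formula(d$formula, charge = d$charge)
    tibble(
      label = d$label,
      polarity = d$polarity,
      formula = list(f),
      mz = monoisotopic_mass(f) / abs(d$charge),
      lipid_classes = list(unlist(d$classes)),
      note = d$note
    )
  })
  the$class_data <- list(version = raw$version, classes = classes,
                         diagnostics = diagnostics)
  the$class_data
}

class_info <- function(lipid_class) {
  tab <- class_table()
  i <- match(lipid_class, tab$lipid_class)
  if (is.na(i)) abort(paste0("unknown lipid class '", lipid_class, "'"))
  as.list(tab[i, ])
}

new_lipid_species <- function(lipid_class, chains, sn_known = FALSE,
                              ether = FALSE, sphingoid = NULL) {
  structure(list(lipid_class = lipid_class, chains = chains,
                 sn_known = sn_known, ether = ether, sphingoid = sphingoid),
            class = "lipid_species")
}

#' Parse lipid shorthand nomenclature
#'
#' Parses the shorthand `CLASS [O-]c:d[/c:d]` used for glycerophospholipids
#' and sphingolipids: e.g. `"PC 14:0/16:0"` (sn-resolved diacyl),
#' `"PC 30:0"` (sum composition, chain split unknown), `"LPE 13:0/0:0"`
#' (lyso with explicit empty sn-position), `"PC O-38:6"` (ether subclass),
#' `"SM d18:1/16:0"` (sphingoid base + N-acyl). The parse round-trips
#' through [format_shorthand()].
#'
#' @param name A single shorthand string.
#' @return A `lipid_species` object: `lipid_class`, `chains` (list of
#'   `c(carbons, double_bonds)`), `sn_known`, `ether`, and `sphingoid`
#'   (NULL unless the base was written explicitly).
#' @examples
#' parse_shorthand("PC 14:0/16:0")
#' parse_shorthand("PC 30:0")
#' @export
parse_shorthand <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  m <- regmatches(name, regexec(
    "^([A-Za-z][A-Za-z0-9]*)[ ]+(O-)?((?:d?[0-9]+:[0-9]+)(?:/[0-9]+:[0-9]+)*)$",
    name))[[1]]
  if (!length(m)) abort(paste0("cannot parse lipid shorthand: '", name, "'"))
  cls <- m[2]
  info <- class_info(cls)  # errors on unknown class token
  ether <- m[3] == "O-"
  if (ether && info$kind != "glycerophospholipid") {
    abort("ether 'O-' subclass applies to glycerophospholipids only")
  }
  toks <- strsplit(m[4], "/", fixed = TRUE)[[1]]
  sphingoid <- NULL
  if (startsWith(toks[1], "d")) {
    if (info$kind != "sphingolipid") {
      abort(paste0("'d' sphingoid prefix not valid for class ", cls))
    }
    sphingoid <- parse_chain(sub("^d", "", toks[1]), allow_zero = FALSE)
    toks <- toks[-1]
  }
  chains <- lapply(toks, parse_chain, allow_zero = TRUE)
  nonzero <- chains[vapply(chains, function(ch) ch[1] > 0, logical(1))]
  sn_known <- length(toks) > 1 || !is.null(sphingoid)
  if (info$kind == "glycerophospholipid") {
    if (length(toks) == 1) {
      sn_known <- FALSE                       # sum composition
      if (info$n_acyl == 1 && chains[[1]][1] < 2) {
        abort("lyso species needs one acyl chain with >= 2 carbons")
      }
    } else {
      if (length(nonzero) != info$n_acyl) {
        abort(paste0(cls, " expects ", info$n_acyl,
                     " acyl chain(s), got ", length(nonzero)))
      }
    }
    chains <- if (sn_known) nonzero else chains
  } else {
    if (length(toks) > 1) abort("sphingolipid shorthand takes one N-acyl chain")
    if (!is.null(sphingoid) && !length(nonzero)) {
      abort("sphingolipid with explicit base needs an N-acyl chain")
    }
  }
  new_lipid_species(cls, chains, sn_known = sn_known, ether = ether,
                    sphingoid = sphingoid)
}

parse_chain <- function(tok, allow_zero = FALSE) {
  p <- as.integer(strsplit(tok, ":", fixed = TRUE)[[1]])
  c_ <- p[1]; d_ <- p[2]
  if (c_ == 0 && d_ == 0 && allow_zero) return(c(carbons = 0L, double_bonds = 0L))
  if (c_ < 2) abort(paste0("chain '", tok, "': carbons must be >= 2"))
  if (d_ < 0 || d_ > c_ / 2) {
    abort(paste0("chain '", tok, "': double bonds exceed carbons/2"))
  }
  c(carbons = c_, double_bonds = d_)
}

#' @rdname parse_shorthand
#' @param species A `lipid_species`.
#' @export
format_shorthand <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  fmt <- function(ch) paste0(ch[1], ":", ch[2])
  base <- if (!is.null(species$sphingoid)) paste0("d", fmt(species$sphingoid))
  chains <- vapply(species$chains, fmt, character(1))
  info <- class_info(species$lipid_class)
  if (info$kind == "glycerophospholipid" && species$sn_known &&
      info$n_acyl == 1) {
    chains <- c(chains, "0:0")
  }
  paste0(species$lipid_class, " ", if (species$ether) "O-" else "",
         paste(c(base, chains), collapse = "/"))
}

#' @export
format.lipid_species <- function(x, ...) format_shorthand(x)

#' @export
print.lipid_species <- function(x, ...) {
  cat("<lipid_species> ", format_shorthand(x),
      if (!x$sn_known) "  (sum composition)", "\n", sep = "")
  invisible(x)
}

total_composition <- function(species) {
  m <- vapply(species$chains, identity, numeric(2))
  c(carbons = sum(m[1, ]), double_bonds = sum(m[2, ]))
}

#' Neutral elemental formula of a lipid species
#'
#' Glycerophospholipids: class glycerophospho core plus, per acyl chain,
#' the fatty acid `C_cH_(2c-2d)O2` condensed with loss of water; an ether
#' (O-) chain contributes `C_cH_(2c-2d)` instead, so the ether subclass is
#' exactly `- O + 2H` relative to the diacyl form. Sum compositions use the
#' chain totals directly; the split into sn-chains does not change the
#' formula. Sphingolipids: ceramide = sphingoid base (default d18:1 when
#' the shorthand gives only a sum) + fatty acid - H2O; SM adds
#' phosphocholine (C5H14NO4P) - H2O; hexosylceramides add n x C6H10O5.
#'
#' @param species A `lipid_species` (or shorthand string).
#' @param default_base Sphingoid base assumed for sphingolipid sum
#'   compositions, as `c(carbons, double_bonds)`.
#' @return Neutral `el_formula`.
#' @examples
#' formula_of(parse_shorthand("PE 14:0/14:0"))
#' @export
formula_of <- function(species, default_base = c(18L, 1L)) {
  if (is.character(species)) species <- parse_shorthand(species)
  info <- class_info(species$lipid_class)
  tot <- total_composition(species)
  if (info$kind == "glycerophospholipid") {
    n_acyl <- info$n_acyl
    # condensed acyl block: sum over chains of (C_cH_{2c-2d}O2 - H2O)
    h <- 2 * tot["carbons"] - 2 * tot["double_bonds"] - 2 * n_acyl
    counts <- c(C = tot[["carbons"]], H = unname(h), O = n_acyl)
    acyl <- el_formula(counts)
    f <- formula_add(el_formula(info$core), acyl)
    if (species$ether) {
      f <- formula_subtract(formula_add(f, el_formula("H2")), el_formula("O"))
    }
    f
  } else {
    base <- species$sphingoid
    if (is.null(base)) {
      base <- c(default_base[1], default_base[2])
      acyl_c <- tot[["carbons"]] - base[1]
      acyl_d <- tot[["double_bonds"]] - base[2]
      if (acyl_c < 2 || acyl_d < 0) {
        abort("sphingolipid sum composition incompatible with default base")
      }
    } else {
      acyl_c <- tot[["carbons"]]; acyl_d <- tot[["double_bonds"]]
    }
    # dihydroxy base C_cH_{2c+1-2d}NO2
    base_f <- el_formula(c(C = base[[1]], H = 2 * base[[1]] + 1 - 2 * base[[2]],
                           N = 1, O = 2))
    fa <- el_formula(c(C = unname(acyl_c), H = unname(2 * acyl_c - 2 * acyl_d),
                       O = 2))
    cer <- formula_subtract(formula_add(base_f, fa), el_formula("H2O"))
    f <- cer
    if (isTRUE(info$choline)) {  # SM
      f <- formula_subtract(formula_add(f, el_formula("C5H14NO4P")),
                            el_formula("H2O"))
    }
    if (info$hexoses > 0) {
      for (i in seq_len(info$hexoses)) f <- formula_add(f, el_formula("C6H10O5"))
    }
    f
  }
}
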