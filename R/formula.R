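# Monoisotopic atomic masses (NIST/CODATA), Da. C-12 defines the scale.
.atomic_mass <- c(
  H  = 1.0078250319,
  C  = 12.0,
  N  = 14.0030740052,
  O  = 15.9949146221,
  P  = 30.97376151,
  S  = 31.97207069,
  Na = 22.98976928,
  K  = 38.96370649
)

.electron_mass <- 0.00054857990

#' Elemental formula with charge
#'
#' Light container for an element -> count map plus an integer charge.
#' Counts are non-negative integers; arithmetic that would drive a count
#' negative is an error, so formulas behave like real molecular inventories.
#'
#' @param x A formula string such as `"C33H66NO8P"`, a named integer vector
#'   (names are element symbols), or an existing `el_formula` object.
#' @param charge Integer charge (sign included), default 0 (neutral).
#' @return An object of class `el_formula`.
#' @examples
#' el_formula("C5H14NO6P")
#' monoisotopic_mass(el_formula("H2O"))
#' @export
el_formula <- function(x = character(), charge = 0L) {
  if (inherits(x, "el_formula")) {
    counts <- x$counts
    if (missing(charge)) charge <- x$charge
  } else if (is.character(x)) {
    counts <- parse_formula_string(if (length(x)) x else "")
  } else if (is.numeric(x)) {
    if (length(x) && is.null(names(x))) {
      abort("numeric input to el_formula() must be a named vector")
    }
    counts <- x
  } else {
    abort("cannot build an el_formula from this input")
  }
  counts <- counts[counts != 0]
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("element counts must be non-negative integers")
  }
  unknown <- setdiff(names(counts), names(.atomic_mass))
  if (length(unknown)) {
    abort(paste0("unknown element(s): ", paste(unknown, collapse = ", ")))
  }
  counts <- counts[order(match(names(counts), c("C", "H", names(.atomic_mass))))]
  structure(list(counts = counts, charge = as.integer(charge)),
            class = "el_formula")
}

parse_formula_string <- function(s) {
  s <- gsub("\\s", "", s)
  if (!nzchar(s)) return(setNames(numeric(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  toks <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    abort(paste0("cannot parse formula string: '", s, "'"))
  }
  el <- sub("[0-9]*$", "", toks)
  n <- as.numeric(ifelse(grepl("[0-9]", toks), sub("^[A-Za-z]+", "", toks), 1))
  tapply(n, el, sum)[unique(el)]
}

#' @export
format.el_formula <- function(x, ...) {
  if (!length(x$counts)) return("(empty)")
  body <- paste0(names(x$counts),
                 ifelse(x$counts == 1, "", x$counts), collapse = "")
  z <- x$charge
  if (z == 0) body
  else paste0("[", body, "]", if (abs(z) > 1) abs(z) else "",
              if (z > 0) "+" else "-")
}

#' @export
print.el_formula <- function(x, ...) {
  cat("<el_formula> ", format(x), "  ",
      formatC(monoisotopic_mass(x), digits = 5, format = "f"), " Da\n", sep = "")
  invisible(x)
}

#' Formula arithmetic
#'
#' Element-wise sum or difference of two formulas. Subtraction failing on any
#' element (a negative count) is an error. Charges add/subtract.
#'
#' @param a,b `el_formula` objects (or inputs accepted by [el_formula()]).
#' @return An `el_formula`.
#' @export
formula_add <- function(a, b) {
  a <- el_formula(a); b <- el_formula(b)
  els <- union(names(a$counts), names(b$counts))
  counts <- setNames(numeric(length(els)), els)
  counts[names(a$counts)] <- a$counts
  counts[names(b$counts)] <- counts[names(b$counts)] + b$counts
  el_formula(counts, charge = a$charge + b$charge)
}

#' @rdname formula_add
#' @export
formula_subtract <- function(a, b) {
  a <- el_formula(a); b <- el_formula(b)
  els <- union(names(a$counts), names(b$counts))
  counts <- setNames(numeric(length(els)), els)
  counts[names(a$counts)] <- a$counts
  counts[names(b$counts)] <- counts[names(b$counts)] - b$counts
  if (any(counts < 0)) {
    abort(paste0("formula subtraction yields negative count: ",
                 format(el_formula(a)), " - ", format(el_formula(b))))
  }
  el_formula(counts, charge = a$charge - b$charge)
}

#' @export
Ops.el_formula <- function(e1, e2) {
  switch(.Generic,
    "+" = formula_add(e1, e2),
    "-" = formula_subtract(e1, e2),
    abort(paste0("operation '", .Generic, "' not defined for el_formula"))
  )
}

#' Monoisotopic mass of a formula
#'
#' Strictly additive over elements; a charged formula is corrected by the
#' electron mass (0.00054858 Da per charge: electrons are subtracted for
#' positive charge, added for negative).
#'
#' @param formula An `el_formula` (or input accepted by [el_formula()]).
#' @return Mass in Da (for charged formulas: the m/z numerator for |z| = 1).
#' @export
monoisotopic_mass <- function(formula) {
  f <- el_formula(formula)
  if (!length(f$counts)) return(0 - f$charge * .electron_mass)
  sum(.atomic_mass[names(f$counts)] * f$counts) - f$charge * .electron_mass
}
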