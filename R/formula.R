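# Molecular-formula arithmetic on named integer element counts.
# A `chem_formula` is a named numeric vector of non-negative integer counts,
# stored with zero counts dropped and names sorted, so identical compositions
# compare identical with identical().

#' Monoisotopic element masses
#'
#' Returns the table of monoisotopic element masses (Da) used throughout the
#' package. Carbon is exactly 12 by definition of the dalton; all other values
#' are CODATA/IUPAC monoisotopic masses to at least six decimal places.
#'
#' @return Named numeric vector, element symbol to monoisotopic mass in Da.
#' @seealso [electron_mass()], [monoisotopic_mass()]
#' @export
#' @examples
#' element_masses()[["C"]]  # 12 exactly
element_masses <- function() .element_masses

.element_masses <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692809,
  K  = 38.96370668,
  Cl = 34.96885268,
  F  = 18.99840322,
  Br = 78.9183371,
  I  = 126.904473
)

#' Electron rest mass in daltons
#'
#' Used by the adduct table to convert between ion m/z and neutral mass.
#'
#' @return A single numeric, Da.
#' @export
electron_mass <- function() 0.00054857990907

#' Construct a molecular formula
#'
#' @param ... Named integer element counts, e.g. `chem_formula(C = 3, H = 8,
#'   O = 3)` for glycerol. Counts must be non-negative; zero counts are
#'   dropped. With no arguments, the empty formula.
#' @return An object of class `chem_formula`.
#' @seealso [parse_chem_formula()], [formula_string()], [monoisotopic_mass()]
#' @export
#' @examples
#' water <- chem_formula(H = 2, O = 1)
#' glycerol <- parse_chem_formula("C3H8O3")
#' formula_string(glycerol - water)
chem_formula <- function(...) {
  counts <- c(...)
  if (length(counts) == 0L) {
    return(structure(stats::setNames(numeric(0), character(0)),
                     class = "chem_formula"))
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("all element counts must be named", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("element counts must be non-negative integers", call. = FALSE)
  }
  if (anyDuplicated(names(counts))) {
    counts <- tapply(counts, names(counts), sum)  # merge duplicate symbols
  }
  .mk_formula(as.numeric(counts), names(counts))
}

# internal fast constructor: counts already validated and symbol-unique
.mk_formula <- function(counts, symbols) {
  keep <- counts > 0
  counts <- counts[keep]
  symbols <- symbols[keep]
  ord <- order(symbols)
  structure(counts[ord], names = symbols[ord], class = "chem_formula")
}

.as_chem_formula <- function(x) {
  if (inherits(x, "chem_formula")) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_chem_formula(x))
  stop("expected a chem_formula or a formula string", call. = FALSE)
}

#' Parse a molecular formula string
#'
#' Accepts plain element-count strings such as `"C42H82NO8P"`. An omitted
#' count means 1. The empty string parses to the empty formula.
#'
#' @param text A single formula string.
#' @return A `chem_formula`.
#' @export
parse_chem_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (text == "") return(chem_formula())
  hit <- .formula_cache[[text]]
  if (!is.null(hit)) return(hit)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop(sprintf("malformed formula string: '%s'", text), call. = FALSE)
  }
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- sub("^[A-Z][a-z]?", "", tokens)
  cnt <- suppressWarnings(ifelse(cnt == "", 1L, as.integer(cnt)))
  out <- do.call(chem_formula, as.list(stats::setNames(cnt, sym)))
  .formula_cache[[text]] <- out
  out
}

.formula_cache <- new.env(parent = emptyenv())

#' @export
Ops.chem_formula <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "==")) {
    stop(sprintf("operation '%s' not defined for chem_formula", .Generic),
         call. = FALSE)
  }
  if (.Generic == "==") return(identical(.as_chem_formula(e1), .as_chem_formula(e2)))
  a <- .as_chem_formula(e1)
  b <- .as_chem_formula(e2)
  sign <- if (.Generic == "+") 1 else -1
  counts <- c(unclass(a), sign * unclass(b))
  symbols <- c(names(a), names(b))
  if (anyDuplicated(symbols)) {
    counts <- vapply(split(counts, symbols), sum, numeric(1))
    symbols <- names(counts)
  }
  if (any(counts < 0)) {
    stop(sprintf("formula subtraction below zero for element(s): %s",
                 paste(symbols[counts < 0], collapse = ", ")), call. = FALSE)
  }
  .mk_formula(counts, symbols)
}

#' Multiply a formula by a non-negative integer
#'
#' @param x A `chem_formula` (or formula string).
#' @param k Non-negative integer multiplier.
#' @return A `chem_formula`.
#' @export
formula_multiply <- function(x, k) {
  x <- .as_chem_formula(x)
  stopifnot(length(k) == 1L, is.finite(k), k >= 0, k == round(k))
  .mk_formula(unclass(x) * k, names(x))
}

#' Format a formula in Hill order
#'
#' Carbon first, then hydrogen, then all remaining elements alphabetically;
#' when no carbon is present all elements are alphabetical. A count of 1 is
#' omitted, matching conventional formula strings (e.g. `"C42H82NO8P"`).
#'
#' @param x A `chem_formula` (or formula string).
#' @return A single character string; `""` for the empty formula.
#' @export
formula_string <- function(x) {
  x <- .as_chem_formula(x)
  if (length(x) == 0L) return("")
  elements <- names(x)
  if ("C" %in% elements) {
    lead <- intersect(c("C", "H"), elements)
    elements <- c(lead, setdiff(sort(elements), lead))
  } else {
    elements <- sort(elements)
  }
  counts <- unclass(x)[elements]
  paste0(elements, ifelse(counts == 1, "", format(counts, scientific = FALSE, trim = TRUE)),
         collapse = "")
}

#' @export
format.chem_formula <- function(x, ...) formula_string(x)

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", formula_string(x), "\n", sep = "")
  invisible(x)
}

#' Neutral monoisotopic mass of a molecular formula
#'
#' Sums count times monoisotopic element mass over all elements. The result
#' is a neutral mass: no electron adjustment is applied (charge enters only
#' through adduct arithmetic, see [neutral_mass_from_mz()]).
#'
#' @param x A `chem_formula` or a formula string such as `"C42H82NO8P"`.
#' @param masses Element mass table; defaults to [element_masses()].
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("H2O")         # 18.010565
#' monoisotopic_mass("C42H82NO8P")  # 759.5778
monoisotopic_mass <- function(x, masses = element_masses()) {
  x <- .as_chem_formula(x)
  if (length(x) == 0L) return(0)
  unknown <- setdiff(names(x), names(masses))
  if (length(unknown)) {
    stop(sprintf("unknown element symbol(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  sum(unclass(x) * masses[names(x)])
}
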