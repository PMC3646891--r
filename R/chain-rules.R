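# Fatty-chain generation rules: which (carbons, double bonds, double-bond
# position sets) count as a valid theoretical radyl chain.
#
# Position numbering is delta-style: the carboxyl (acyl) or linkage (alkyl)
# carbon is C1 and the bond between C_k and C_{k+1} is position k, so a chain
# of c carbons has bond positions 1..c-1. Double-bond spacing follows the
# methylene-interrupted pattern dominant in natural fatty acids: consecutive
# double-bond positions differ by a positive multiple of `db_position_step`
# (default 3: difference 3 is methylene-interrupted, 6/9/... skip one or more
# allowed slots).

#' Chain-generation rules
#'
#' The chemical bounds governing enumeration of theoretical fatty chains.
#' The defaults encode the community-agreed bounds for the glycerolipid /
#' glycerophospholipid space: chains of 2 to 30 carbons, odd chain lengths
#' allowed, any number of double bonds from zero up to what the spacing
#' pattern geometrically admits, first double bond at position 2 or higher,
#' consecutive double bonds separated by a positive multiple of 3 bonds.
#'
#' @param min_carbons,max_carbons Carbon-count range, inclusive.
#' @param allow_odd_carbons Allow odd chain lengths?
#' @param min_double_bonds Lower bound on double bonds per chain.
#' @param max_double_bonds Optional hard cap on double bonds per chain;
#'   `Inf` (default) means limited only by geometric feasibility.
#' @param first_db_position Lowest admissible position for the first double
#'   bond (>= 2: never on the carboxyl/linkage bond).
#' @param db_position_step Consecutive double-bond positions must differ by a
#'   positive multiple of this step.
#' @param allow_terminal_db If `FALSE`, the last bond (position carbons - 1)
#'   is excluded as a double-bond site.
#' @return An object of class `chain_rules`.
#' @seealso [enumerate_chain_types()], [enumerate_db_position_sets()]
#' @export
#' @examples
#' chain_rules()                    # default bounds
#' chain_rules(max_carbons = 6)     # a reduced space for testing
chain_rules <- function(min_carbons = 2L, max_carbons = 30L,
                        allow_odd_carbons = TRUE,
                        min_double_bonds = 0L, max_double_bonds = Inf,
                        first_db_position = 2L, db_position_step = 3L,
                        allow_terminal_db = TRUE) {
  r <- list(
    min_carbons = as.integer(min_carbons),
    max_carbons = as.integer(max_carbons),
    allow_odd_carbons = isTRUE(allow_odd_carbons),
    min_double_bonds = as.integer(min_double_bonds),
    max_double_bonds = if (is.finite(max_double_bonds)) as.integer(max_double_bonds) else Inf,
    first_db_position = as.integer(first_db_position),
    db_position_step = as.integer(db_position_step),
    allow_terminal_db = isTRUE(allow_terminal_db)
  )
  if (r$min_carbons < 1L || r$min_carbons > r$max_carbons) {
    stop("require 1 <= min_carbons <= max_carbons", call. = FALSE)
  }
  if (r$first_db_position < 2L) stop("first_db_position must be >= 2", call. = FALSE)
  if (r$db_position_step < 1L) stop("db_position_step must be >= 1", call. = FALSE)
  if (r$min_double_bonds < 0L) stop("min_double_bonds must be >= 0", call. = FALSE)
  structure(r, class = "chain_rules")
}

#' @export
print.chain_rules <- function(x, ...) {
  cat("<chain_rules>\n")
  cat(sprintf("  carbons: %d..%d (%s odd)\n", x$min_carbons, x$max_carbons,
              if (x$allow_odd_carbons) "incl." else "excl."))
  cat(sprintf("  double bonds: %d..%s, first position >= %d, step %d, terminal %s\n",
              x$min_double_bonds,
              if (is.finite(x$max_double_bonds)) x$max_double_bonds else "geometric max",
              x$first_db_position, x$db_position_step,
              if (x$allow_terminal_db) "allowed" else "forbidden"))
  invisible(x)
}

# last admissible double-bond position for a chain of c carbons
.last_db_position <- function(carbons, rules) {
  as.integer(carbons) - 1L - if (rules$allow_terminal_db) 0L else 1L
}

.check_carbons <- function(carbons, rules) {
  if (carbons < rules$min_carbons || carbons > rules$max_carbons) {
    stop(sprintf("carbon count %d outside [%d, %d]", carbons,
                 rules$min_carbons, rules$max_carbons), call. = FALSE)
  }
  if (!rules$allow_odd_carbons && carbons %% 2L == 1L) {
    stop(sprintf("odd carbon count %d not allowed under these rules", carbons),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Maximum number of double bonds a chain length admits
#'
#' The largest `d` for which at least one valid double-bond position set
#' exists on a chain of `carbons` carbons under `rules` (capped by
#' `rules$max_double_bonds` when finite).
#'
#' @param carbons Chain length, within the rules' carbon range.
#' @param rules A [chain_rules()] object.
#' @return Integer count.
#' @export
#' @examples
#' max_double_bonds(18, chain_rules())  # 6, densest set {2,5,8,11,14,17}
max_double_bonds <- function(carbons, rules = chain_rules()) {
  .check_carbons(carbons, rules)
  last <- .last_db_position(carbons, rules)
  if (last < rules$first_db_position) return(0L)
  d <- (last - rules$first_db_position) %/% rules$db_position_step + 1L
  as.integer(min(d, rules$max_double_bonds))
}

#' Enumerate double-bond position sets
#'
#' All sorted position vectors for `n_db` double bonds on a chain of
#' `carbons` carbons: first position at least `rules$first_db_position`,
#' last position at most `carbons - 1` (one less when terminal double bonds
#' are forbidden), consecutive positions differing by a positive multiple of
#' `rules$db_position_step`. Sets are returned in lexicographic order.
#'
#' @inheritParams max_double_bonds
#' @param n_db Number of double bonds (>= 0).
#' @return A list of integer vectors; `list(integer(0))` when `n_db` is 0,
#'   `list()` when no valid set exists.
#' @seealso [count_db_position_sets()] for the closed-form count.
#' @export
#' @examples
#' enumerate_db_position_sets(9, 2)  # {2,5} {2,8} {3,6} {4,7} {5,8}
enumerate_db_position_sets <- function(carbons, n_db, rules = chain_rules()) {
  stopifnot(n_db >= 0, n_db == round(n_db))
  n_db <- as.integer(n_db)
  carbons <- as.integer(carbons)
  if (n_db == 0L) return(list(integer(0)))
  first <- rules$first_db_position
  last <- .last_db_position(carbons, rules)
  step <- rules$db_position_step
  if (n_db > rules$max_double_bonds) return(list())
  out <- list()
  recurse <- function(prefix, lo, remaining) {
    if (remaining == 0L) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    # leave room for the remaining - 1 bonds after this one
    hi <- last - (remaining - 1L) * step
    if (lo > hi) return(invisible(NULL))
    candidates <- if (length(prefix) == 0L) {
      seq.int(lo, hi)                       # first bond: any admissible position
    } else {
      seq.int(lo, hi, by = step)            # spacing: positive multiples of step
    }
    for (p in candidates) recurse(c(prefix, p), p + step, remaining - 1L)
  }
  recurse(integer(0), first, n_db)
  out
}

#' Count double-bond position sets without enumerating them
#'
#' Combinatorial twin of [enumerate_db_position_sets()]: for every input the
#' two agree, but the count is closed-form (a sum over compositions) and is
#' what makes counting the multi-million-record isomer space feasible.
#'
#' @inheritParams enumerate_db_position_sets
#' @return A double (counts can exceed integer range when combined upstream).
#' @export
#' @examples
#' count_db_position_sets(18, 1)  # 16: positions 2..17
count_db_position_sets <- function(carbons, n_db, rules = chain_rules()) {
  stopifnot(n_db >= 0, n_db == round(n_db))
  n_db <- as.integer(n_db)
  if (n_db == 0L) return(1)
  if (n_db > rules$max_double_bonds) return(0)
  first <- rules$first_db_position
  last <- .last_db_position(carbons, rules)
  step <- rules$db_position_step
  span <- last - first
  if (span < 0) return(0)
  if (n_db == 1L) return(span + 1)
  # positions p1 < ... < pd with p1 = first + a (a >= 0) and gaps step * k_i,
  # k_i >= 1: need a + step * sum(k) <= span. Sum over m = sum(k):
  # compositions of m into (d-1) positive parts = choose(m-1, d-2), and
  # a then ranges over 0..(span - step*m).
  d <- n_db
  m_max <- span %/% step
  if (m_max < d - 1L) return(0)
  m <- seq.int(d - 1L, m_max)
  sum(choose(m - 1, d - 2L) * (span - step * m + 1))
}

#' Enumerate chain types
#'
#' All (carbons, double_bonds) pairs admitted by the rules, sorted by
#' carbons then double bonds. Under the default rules there are 174 types.
#'
#' @param rules A [chain_rules()] object.
#' @return A data frame with integer columns `carbons`, `double_bonds`.
#' @export
enumerate_chain_types <- function(rules = chain_rules()) {
  carbons <- seq.int(rules$min_carbons, rules$max_carbons)
  if (!rules$allow_odd_carbons) carbons <- carbons[carbons %% 2L == 0L]
  rows <- lapply(carbons, function(c) {
    dmax <- max_double_bonds(c, rules)
    if (dmax < rules$min_double_bonds) return(NULL)
    data.frame(carbons = c, double_bonds = seq.int(rules$min_double_bonds, dmax))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(carbons = integer(0), double_bonds = integer(0))
  rownames(out) <- NULL
  out
}

#' Radyl chain constructor
#'
#' One ester-linked (acyl) or ether-linked (alkyl) chain. Positions, when
#' given, must be sorted, one per double bond.
#'
#' @param linkage `"acyl"` or `"alkyl"`.
#' @param carbons Carbon count.
#' @param double_bonds Double-bond count.
#' @param positions Optional integer vector of double-bond positions
#'   (delta numbering); `NULL` when positions are unresolved.
#' @return An object of class `lipid_chain`.
#' @export
lipid_chain <- function(linkage = c("acyl", "alkyl"), carbons, double_bonds = 0L,
                        positions = NULL) {
  linkage <- match.arg(linkage)
  carbons <- as.integer(carbons)
  double_bonds <- as.integer(double_bonds)
  stopifnot(carbons >= 1L, double_bonds >= 0L)
  if (2L * double_bonds > 2L * carbons - 2L && double_bonds > 0L) {
    stop("more double bonds than the chain length can carry", call. = FALSE)
  }
  if (!is.null(positions)) {
    positions <- as.integer(positions)
    if (length(positions) != double_bonds) {
      stop("positions must have one entry per double bond", call. = FALSE)
    }
    if (is.unsorted(positions, strictly = TRUE)) {
      stop("positions must be strictly increasing", call. = FALSE)
    }
  }
  structure(list(linkage = linkage, carbons = carbons,
                 double_bonds = double_bonds, positions = positions),
            class = "lipid_chain")
}

#' Validate a chain against chain-generation rules
#'
#' Checks the carbon range/parity, double-bond count, and (when present) the
#' double-bond position-set constraints. Errors describe the first violation.
#'
#' @param chain A [lipid_chain()].
#' @param rules A [chain_rules()] object.
#' @return `chain`, invisibly, if valid.
#' @export
validate_chain <- function(chain, rules = chain_rules()) {
  stopifnot(inherits(chain, "lipid_chain"))
  .check_carbons(chain$carbons, rules)
  if (chain$double_bonds < rules$min_double_bonds ||
      chain$double_bonds > max_double_bonds(chain$carbons, rules)) {
    stop(sprintf("double-bond count %d outside [%d, %d] for %d carbons",
                 chain$double_bonds, rules$min_double_bonds,
                 max_double_bonds(chain$carbons, rules), chain$carbons),
         call. = FALSE)
  }
  p <- chain$positions
  if (!is.null(p) && length(p) > 0L) {
    if (p[1L] < rules$first_db_position) {
      stop(sprintf("first double-bond position %d below minimum %d",
                   p[1L], rules$first_db_position), call. = FALSE)
    }
    if (p[length(p)] > .last_db_position(chain$carbons, rules)) {
      stop(sprintf("last double-bond position %d beyond position %d",
                   p[length(p)], .last_db_position(chain$carbons, rules)),
           call. = FALSE)
    }
    if (length(p) > 1L) {
      gaps <- diff(p)
      if (any(gaps <= 0L) || any(gaps %% rules$db_position_step != 0L)) {
        stop(sprintf("double-bond spacing must be a positive multiple of %d",
                     rules$db_position_step), call. = FALSE)
      }
    }
  }
  invisible(chain)
}

#' @export
print.lipid_chain <- function(x, ...) {
  pos <- if (!is.null(x$positions) && length(x$positions)) {
    paste0("(", paste(x$positions, collapse = ","), ")")
  } else ""
  cat(sprintf("<lipid_chain> %s%d:%d%s\n",
              if (x$linkage == "alkyl") "O-" else "", x$carbons,
              x$double_bonds, pos))
  invisible(x)
}

#' Molecular formula of a free chain building block
#'
#' An acyl chain of c carbons and d double bonds contributes the free fatty
#' acid C_c H_(2c-2d) O2; an alkyl chain contributes the fatty alcohol
#' C_c H_(2c+2-2d) O. Condensation onto glycerol removes one water per chain
#' (see [compose_lipid_formula()]).
#'
#' @param linkage `"acyl"` or `"alkyl"`.
#' @param carbons,double_bonds Chain composition.
#' @return A `chem_formula`.
#' @export
chain_formula <- function(linkage, carbons, double_bonds = 0L) {
  linkage <- match.arg(linkage, c("acyl", "alkyl"))
  if (linkage == "acyl") {
    chem_formula(C = carbons, H = 2L * carbons - 2L * double_bonds, O = 2L)
  } else {
    chem_formula(C = carbons, H = 2L * carbons + 2L - 2L * double_bonds, O = 1L)
  }
}
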