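# Sub-class construction: the Cartesian cross of main classes with fatty-acid
# linkage combinations. Linkage-position variants are collapsed: a sub-class
# is identified by its linkage *multiset*, not by which sn position carries
# the alkyl chain (one sub-class "monoalkyl,monoacylglycerophosphocholines",
# not two positional variants).

.linkage_prefix <- c("mono", "di", "tri")

.subclass_display_name <- function(linkage, stem) {
  n_alkyl <- sum(linkage == "alkyl")
  n_acyl <- sum(linkage == "acyl")
  parts <- character(0)
  if (n_alkyl > 0L) parts <- c(parts, paste0(.linkage_prefix[n_alkyl], "alkyl"))
  if (n_acyl > 0L) parts <- c(parts, paste0(.linkage_prefix[n_acyl], "acyl"))
  paste0(paste(parts, collapse = ","), stem)
}

#' Construct one lipid sub-class
#'
#' Usually called through [build_subclasses()]; exposed for constructing
#' ad-hoc sub-classes in reduced test spaces.
#'
#' @param main_class Main-class code (e.g. `"PC"`, `"TG"`).
#' @param linkage Character vector over `"acyl"`/`"alkyl"`: the linkage
#'   multiset, one entry per occupied glycerol position. May be empty (a
#'   bare backbone-plus-head sub-class, useful as the condensation base case).
#' @param config A [default_config()]-shaped configuration.
#' @return An object of class `lipid_subclass` with fields `category`,
#'   `main_class`, `class_code` (display code; 1-slot glycerophospholipids
#'   get an `L` prefix, e.g. `LPC`), `linkage` (canonical order: alkyl
#'   chains first), `slot_count`, `display_name`, `head` (`chem_formula`),
#'   `phospho` (logical), `backbone_positions` (radyl capacity of the
#'   backbone: 2 for glycerophospholipids, 3 for glycerolipids).
#' @export
lipid_subclass <- function(main_class, linkage, config = default_config()) {
  mc <- config$main_classes[[main_class]]
  if (is.null(mc)) {
    stop(sprintf("unknown main-class code: %s", main_class), call. = FALSE)
  }
  linkage <- as.character(linkage)
  if (!all(linkage %in% c("acyl", "alkyl"))) {
    stop("linkage entries must be 'acyl' or 'alkyl'", call. = FALSE)
  }
  if (length(linkage) > 3L) stop("at most three radyl positions", call. = FALSE)
  linkage <- linkage[order(linkage != "alkyl")]  # canonical: alkyl first
  phospho <- main_class %in% config$building_blocks$phospho_classes
  if (phospho && length(linkage) > 2L) {
    stop("glycerophospholipids carry at most two radyl chains", call. = FALSE)
  }
  head_str <- config$building_blocks$head_groups[[main_class]] %||% ""
  code <- if (phospho && length(linkage) == 1L) paste0("L", main_class) else main_class
  structure(list(
    category = mc$category,
    main_class = main_class,
    class_code = code,
    linkage = linkage,
    slot_count = length(linkage),
    display_name = .subclass_display_name(linkage, mc$stem),
    head = parse_chem_formula(head_str),
    phospho = phospho,
    backbone_positions = if (phospho) 2L else 3L
  ), class = "lipid_subclass")
}

#' @export
print.lipid_subclass <- function(x, ...) {
  cat(sprintf("<lipid_subclass> %s [%s] {%s} (%s)\n", x$display_name,
              x$class_code, paste(x$linkage, collapse = ","), x$category))
  invisible(x)
}

#' Build the sub-class table
#'
#' Performs the Cartesian cross of main classes with all linkage multisets
#' of each allowed slot count. With the default nine main classes this
#' yields 39 sub-classes: six glycerophospholipid classes each with two
#' monoradyl and three diradyl linkage multisets, plus two monoradyl-,
#' three diradyl- and four triradylglycerol sub-classes.
#'
#' @param config A [default_config()]-shaped configuration.
#' @return A list of [lipid_subclass()] objects in deterministic order
#'   (main classes in configuration order, slot count ascending, number of
#'   alkyl chains ascending).
#' @export
#' @examples
#' length(build_subclasses())  # 39 under defaults
build_subclasses <- function(config = default_config()) {
  out <- list()
  for (code in names(config$main_classes)) {
    mc <- config$main_classes[[code]]
    for (k in sort(mc$slots)) {
      for (n_alkyl in 0:k) {
        linkage <- c(rep("alkyl", n_alkyl), rep("acyl", k - n_alkyl))
        out[[length(out) + 1L]] <- lipid_subclass(code, linkage, config)
      }
    }
  }
  out
}

#' Find a sub-class by class code and linkage multiset
#'
#' @param subclasses A list from [build_subclasses()].
#' @param class_code Display code (`"PC"`, `"LPC"`, `"TG"`, ...).
#' @param n_alkyl Number of alkyl chains in the linkage multiset.
#' @return The matching `lipid_subclass`, or an error.
#' @export
find_subclass <- function(subclasses, class_code, n_alkyl = 0L) {
  for (sc in subclasses) {
    if (sc$class_code == class_code && sum(sc$linkage == "alkyl") == n_alkyl) {
      return(sc)
    }
  }
  stop(sprintf("no sub-class with code %s and %d alkyl chain(s)",
               class_code, n_alkyl), call. = FALSE)
}

#' Assemble a whole-lipid molecular formula by condensation
#'
#' Condensation arithmetic: glycerol backbone plus head-group building block
#' plus the free-chain formulas, minus one water per condensation bond. The
#' bond count is the number of chains (one ester or ether bond each) plus
#' one for the phosphodiester bond when a phospho head group is present.
#'
#' @param subclass A [lipid_subclass()].
#' @param chains List of [lipid_chain()]s whose linkage multiset must equal
#'   the sub-class linkage multiset.
#' @param config Configuration supplying the backbone and water formulas.
#' @return A `chem_formula` for the neutral lipid.
#' @export
#' @examples
#' sc <- find_subclass(build_subclasses(), "PC")
#' f <- compose_lipid_formula(sc, list(lipid_chain("acyl", 16, 0),
#'                                     lipid_chain("acyl", 18, 1)))
#' formula_string(f)  # "C42H82NO8P"
compose_lipid_formula <- function(subclass, chains, config = default_config()) {
  stopifnot(inherits(subclass, "lipid_subclass"))
  got <- sort(unname(vapply(chains, function(ch) ch$linkage, character(1))))
  want <- sort(unname(subclass$linkage))
  if (!identical(got, want)) {
    stop(sprintf("chain linkage multiset {%s} does not match sub-class {%s}",
                 paste(got, collapse = ","), paste(want, collapse = ",")),
         call. = FALSE)
  }
  backbone <- parse_chem_formula(config$building_blocks$backbone)
  water <- parse_chem_formula(config$building_blocks$water)
  # chain contributions are supported on C/H/O only, so they can be summed
  # in one step (acyl: C_c H_{2c-2d} O2; alkyl: C_c H_{2c+2-2d} O)
  chain_sum <- chem_formula(
    C = sum(vapply(chains, function(ch) ch$carbons, integer(1))),
    H = sum(vapply(chains, function(ch) {
      2L * ch$carbons - 2L * ch$double_bonds +
        if (ch$linkage == "alkyl") 2L else 0L
    }, integer(1))),
    O = sum(vapply(chains, function(ch) {
      if (ch$linkage == "alkyl") 1L else 2L
    }, integer(1)))
  )
  n_bonds <- length(chains) + as.integer(subclass$phospho)
  backbone + subclass$head + chain_sum - formula_multiply(water, n_bonds)
}

#' Species-level molecular formula from carbon/double-bond totals
#'
#' At species level only the totals are known, but the formula is still
#' well defined because the linkage multiset is fixed per sub-class: an
#' alkyl chain contributes two hydrogens more and one oxygen less than an
#' acyl chain of the same composition, independent of how the totals split
#' across chains.
#'
#' @param subclass A [lipid_subclass()].
#' @param total_carbons,total_double_bonds Chain totals.
#' @param config Configuration supplying backbone and water formulas.
#' @return A `chem_formula`.
#' @export
species_formula <- function(subclass, total_carbons, total_double_bonds,
                            config = default_config()) {
  n_alkyl <- sum(subclass$linkage == "alkyl")
  n_acyl <- subclass$slot_count - n_alkyl
  backbone <- parse_chem_formula(config$building_blocks$backbone)
  water <- parse_chem_formula(config$building_blocks$water)
  chains <- chem_formula(
    C = total_carbons,
    H = 2L * total_carbons - 2L * total_double_bonds + 2L * n_alkyl,
    O = 2L * n_acyl + n_alkyl
  )
  n_bonds <- subclass$slot_count + as.integer(subclass$phospho)
  backbone + subclass$head + chains - formula_multiply(water, n_bonds)
}
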