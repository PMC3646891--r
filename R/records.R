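# The four-level identification hierarchy. A record's level mirrors how much
# an MS experiment can resolve: Species (class + chain totals, one precursor
# mass), FasSpecies (individual chain compositions, sn positions unknown),
# SubSpecies (chains assigned to sn positions), Isomer (double-bond positions
# resolved on every unsaturated chain). Stereochemistry is above this
# hierarchy's resolution and is never represented.

.levels <- c("Species", "FasSpecies", "SubSpecies", "Isomer")

# canonical chain order at FAS level: alkyl chains first, then by
# (carbons, double_bonds) ascending
.order_chains <- function(chains) {
  if (length(chains) <= 1L) return(chains)
  key <- vapply(chains, function(ch) {
    sprintf("%d-%04d-%04d", as.integer(ch$linkage != "alkyl"), ch$carbons,
            ch$double_bonds)
  }, character(1))
  chains[order(key)]
}

.strip_positions <- function(chains) {
  lapply(chains, function(ch) {
    lipid_chain(ch$linkage, ch$carbons, ch$double_bonds)
  })
}

.new_record <- function(level, subclass, config, total_carbons = NULL,
                        total_double_bonds = NULL, chains = NULL) {
  level <- match.arg(level, .levels)
  if (level == "Species") {
    formula <- species_formula(subclass, total_carbons, total_double_bonds, config)
  } else {
    if (level == "FasSpecies") chains <- .order_chains(chains)
    total_carbons <- sum(vapply(chains, function(ch) ch$carbons, integer(1)))
    total_double_bonds <- sum(vapply(chains, function(ch) ch$double_bonds, integer(1)))
    formula <- compose_lipid_formula(subclass, chains, config)
  }
  rec <- structure(list(
    level = level, subclass = subclass,
    total_carbons = as.integer(total_carbons),
    total_double_bonds = as.integer(total_double_bonds),
    chains = chains,
    name = NA_character_, formula = formula,
    neutral_mass = monoisotopic_mass(formula)
  ), class = "lipid_record")
  rec$name <- format_name(rec)
  rec
}

#' @export
print.lipid_record <- function(x, ...) {
  cat(sprintf("<lipid_record:%s> %s  %s  %.4f Da  (%s)\n", x$level, x$name,
              formula_string(x$formula), x$neutral_mass,
              x$subclass$display_name))
  invisible(x)
}

# ---- feasible species totals -------------------------------------------

.feasible_cache <- new.env(parent = emptyenv())

# all distinct (total_carbons, total_double_bonds) sums over `slots` valid
# chains, as a data frame sorted by (carbons, double bonds)
.feasible_totals <- function(slots, rules) {
  key <- paste(slots, paste(unlist(unclass(rules)), collapse = "|"), sep = "@")
  hit <- .feasible_cache[[key]]
  if (!is.null(hit)) return(hit)
  types <- enumerate_chain_types(rules)
  acc <- types
  if (slots >= 2L) {
    for (i in 2:slots) {
      grid <- expand.grid(a = seq_len(nrow(acc)), b = seq_len(nrow(types)))
      acc <- unique(data.frame(
        carbons = acc$carbons[grid$a] + types$carbons[grid$b],
        double_bonds = acc$double_bonds[grid$a] + types$double_bonds[grid$b]))
    }
  }
  acc <- acc[order(acc$carbons, acc$double_bonds), , drop = FALSE]
  rownames(acc) <- NULL
  .feasible_cache[[key]] <- acc
  acc
}

#' Enumerate species-level records of a sub-class
#'
#' All distinct (total carbons, total double bonds) pairs realizable as the
#' sum of `slot_count` valid chains under the rules. Each record carries its
#' canonical name, molecular formula and neutral monoisotopic mass.
#'
#' @param subclass A [lipid_subclass()].
#' @param rules A [chain_rules()] object.
#' @param config Tool configuration (building blocks for the formula).
#' @return List of species-level `lipid_record`s, sorted by totals.
#' @export
enumerate_species <- function(subclass, rules = chain_rules(),
                              config = default_config()) {
  totals <- .feasible_totals(subclass$slot_count, rules)
  lapply(seq_len(nrow(totals)), function(i) {
    .new_record("Species", subclass, config,
                total_carbons = totals$carbons[i],
                total_double_bonds = totals$double_bonds[i])
  })
}

# ---- children ----------------------------------------------------------

# multisets (nondecreasing index sequences) of `m` chain types with exact
# carbon/double-bond sums; returns list of integer index vectors into types
.multisets_with_sums <- function(m, target_c, target_d, types) {
  n <- nrow(types)
  out <- list()
  recurse <- function(prefix, lo, rem, cc, dd) {
    if (rem == 0L) {
      if (cc == target_c && dd == target_d) out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (j in lo:n) {
      c2 <- cc + types$carbons[j]
      d2 <- dd + types$double_bonds[j]
      # prune: remaining chains need at least min carbons each and can add
      # at most the largest type's carbons each
      if (c2 + (rem - 1L) * min(types$carbons) > target_c) break
      if (c2 + (rem - 1L) * max(types$carbons) < target_c) next
      if (d2 > target_d) next
      recurse(c(prefix, j), j, rem - 1L, c2, d2)
    }
    invisible(NULL)
  }
  if (m == 0L) {
    if (target_c == 0L && target_d == 0L) out <- list(integer(0))
  } else {
    recurse(integer(0), 1L, m, 0L, 0L)
  }
  out
}

#' Children of a species: fatty acid scan species
#'
#' All multisets of positionless chains, with linkages assigned according
#' to the sub-class linkage multiset, whose carbon and double-bond sums
#' match the species totals.
#'
#' @param species A species-level `lipid_record`.
#' @param rules,config As in [enumerate_species()].
#' @return List of FasSpecies-level records.
#' @export
species_children <- function(species, rules = chain_rules(),
                             config = default_config()) {
  stopifnot(inherits(species, "lipid_record"), species$level == "Species")
  sc <- species$subclass
  n_alkyl <- sum(sc$linkage == "alkyl")
  n_acyl <- sc$slot_count - n_alkyl
  types <- enumerate_chain_types(rules)
  out <- list()
  # split the totals between the alkyl and acyl chain groups
  alkyl_sets <- if (n_alkyl == 0L) list(integer(0)) else NULL
  for (ca in 0:species$total_carbons) {
    for (da in 0:species$total_double_bonds) {
      if (n_alkyl == 0L && (ca > 0L || da > 0L)) next
      a_sets <- if (n_alkyl == 0L) list(integer(0)) else {
        .multisets_with_sums(n_alkyl, ca, da, types)
      }
      if (!length(a_sets)) next
      b_sets <- .multisets_with_sums(n_acyl, species$total_carbons - ca,
                                     species$total_double_bonds - da, types)
      if (!length(b_sets)) next
      for (a in a_sets) {
        for (b in b_sets) {
          chains <- c(
            lapply(a, function(j) lipid_chain("alkyl", types$carbons[j],
                                              types$double_bonds[j])),
            lapply(b, function(j) lipid_chain("acyl", types$carbons[j],
                                              types$double_bonds[j])))
          out[[length(out) + 1L]] <- .new_record("FasSpecies", sc, config,
                                                 chains = chains)
        }
      }
    }
  }
  out[order(vapply(out, function(r) r$name, character(1)))]
}

# all distinct orderings of a list of chains (chains compared by
# linkage/carbons/double_bonds)
.distinct_perms <- function(chains) {
  if (length(chains) <= 1L) return(list(chains))
  keys <- vapply(chains, function(ch) {
    paste(ch$linkage, ch$carbons, ch$double_bonds)
  }, character(1))
  perms <- list()
  recurse <- function(idx, remaining) {
    if (!length(remaining)) {
      perms[[length(perms) + 1L]] <<- idx
      return(invisible(NULL))
    }
    used <- character(0)
    for (i in remaining) {
      if (keys[i] %in% used) next
      used <- c(used, keys[i])
      recurse(c(idx, i), setdiff(remaining, i))
    }
    invisible(NULL)
  }
  recurse(integer(0), seq_along(chains))
  lapply(perms, function(idx) chains[idx])
}

#' Children of a fatty acid scan species: sub species
#'
#' All distinct ordered assignments of the chain multiset to sn positions.
#' Because linkage-position sub-class variants are collapsed, alkyl chains
#' are canonically assigned to the leading sn positions (extending the
#' drawing convention that a non-acyl linkage is shown at sn1); acyl chains
#' permute over the remaining positions, and equal chains do not generate
#' duplicate assignments.
#'
#' @param fas A FasSpecies-level `lipid_record`.
#' @param rules,config As in [enumerate_species()].
#' @return List of SubSpecies-level records.
#' @export
fas_children <- function(fas, rules = chain_rules(), config = default_config()) {
  stopifnot(inherits(fas, "lipid_record"), fas$level == "FasSpecies")
  sc <- fas$subclass
  alkyl <- Filter(function(ch) ch$linkage == "alkyl", fas$chains)
  acyl <- Filter(function(ch) ch$linkage == "acyl", fas$chains)
  out <- list()
  for (ap in .distinct_perms(alkyl)) {
    for (bp in .distinct_perms(acyl)) {
      out[[length(out) + 1L]] <- .new_record("SubSpecies", sc, config,
                                             chains = c(ap, bp))
    }
  }
  out[order(vapply(out, function(r) r$name, character(1)))]
}

#' Children of a sub species: double-bond positional isomers
#'
#' The Cartesian product over chains of their admissible double-bond
#' position sets. A fully saturated sub species has exactly one isomer
#' child (itself, with empty position sets).
#'
#' @param subspecies A SubSpecies-level `lipid_record`.
#' @param rules,config As in [enumerate_species()].
#' @return List of Isomer-level records.
#' @export
subspecies_children <- function(subspecies, rules = chain_rules(),
                                config = default_config()) {
  stopifnot(inherits(subspecies, "lipid_record"),
            subspecies$level == "SubSpecies")
  sc <- subspecies$subclass
  per_chain <- lapply(subspecies$chains, function(ch) {
    enumerate_db_position_sets(ch$carbons, ch$double_bonds, rules)
  })
  out <- list()
  recurse <- function(i, acc) {
    if (i > length(per_chain)) {
      chains <- Map(function(ch, pos) {
        lipid_chain(ch$linkage, ch$carbons, ch$double_bonds, positions = pos)
      }, subspecies$chains, acc)
      out[[length(out) + 1L]] <<- .new_record("Isomer", sc, config,
                                              chains = chains)
      return(invisible(NULL))
    }
    for (pos in per_chain[[i]]) recurse(i + 1L, c(acc, list(pos)))
    invisible(NULL)
  }
  recurse(1L, list())
  out
}

#' Parent of a record one level up the hierarchy
#'
#' Isomer to SubSpecies drops double-bond positions; SubSpecies to
#' FasSpecies forgets sn order; FasSpecies to Species sums carbons and
#' double bonds. A species has no parent within the record space.
#'
#' @param record A `lipid_record` below Species level.
#' @param config Tool configuration.
#' @return The parent `lipid_record`.
#' @export
parent_record <- function(record, config = default_config()) {
  stopifnot(inherits(record, "lipid_record"))
  sc <- record$subclass
  switch(record$level,
    Isomer = .new_record("SubSpecies", sc, config,
                         chains = .strip_positions(record$chains)),
    SubSpecies = .new_record("FasSpecies", sc, config,
                             chains = .strip_positions(record$chains)),
    FasSpecies = .new_record("Species", sc, config,
                             total_carbons = record$total_carbons,
                             total_double_bonds = record$total_double_bonds),
    Species = stop("a species has no parent within the record space",
                   call. = FALSE)
  )
}

# ---- combinatorial counting --------------------------------------------

#' Count records of a sub-class at a hierarchy level without enumeration
#'
#' Closed-form/dynamic-programming twins of the enumerators, equal to the
#' length of the corresponding enumeration for every input but usable at
#' the full multi-million-record scale. With `n` chain types and a linkage
#' multiset of `k` slots split into linkage groups of sizes `m_g`:
#' FasSpecies counts are products of multiset coefficients
#' `choose(n + m_g - 1, m_g)`, SubSpecies counts are `n^k` (ordered
#' assignments; alkyl slots are canonically leading so each linkage group
#' orders independently), and Isomer counts are `I^k` where `I` is the
#' total number of (chain type, position set) combinations.
#'
#' @param subclass A [lipid_subclass()].
#' @param level `"Species"`, `"FasSpecies"`, `"SubSpecies"` or `"Isomer"`.
#' @param rules A [chain_rules()] object.
#' @return A double (counts may exceed integer range).
#' @export
#' @examples
#' sc <- find_subclass(build_subclasses(), "PC")
#' count_records(sc, "SubSpecies")  # 174^2 = 30276
count_records <- function(subclass, level, rules = chain_rules()) {
  level <- match.arg(level, .levels)
  types <- enumerate_chain_types(rules)
  n <- nrow(types)
  n_alkyl <- sum(subclass$linkage == "alkyl")
  groups <- c(alkyl = n_alkyl, acyl = subclass$slot_count - n_alkyl)
  groups <- groups[groups > 0L]
  switch(level,
    Species = as.numeric(nrow(.feasible_totals(subclass$slot_count, rules))),
    FasSpecies = prod(choose(n + groups - 1, groups)),
    SubSpecies = prod(n ^ groups),
    Isomer = {
      per_type <- mapply(count_db_position_sets, types$carbons,
                         types$double_bonds, MoreArgs = list(rules = rules))
      sum(per_type) ^ subclass$slot_count
    }
  )
}

# ---- flat species table (search-engine backbone) -----------------------

# vectorized Hill-order formula strings over the fixed element support of
# glycerolipid/glycerophospholipid formulas
.formula_strings <- function(counts) {
  out <- rep("", nrow(counts))
  for (el in colnames(counts)) {
    n <- counts[, el]
    out <- paste0(out, ifelse(n == 0, "", paste0(el, ifelse(n == 1, "", n))))
  }
  out
}

#' Flat table of all species of a set of sub-classes
#'
#' The species-level search space as one data frame, generated on the fly
#' from the rules and sub-class definitions (about 21,600 rows under the
#' default bounds). This is the table the MS1 search engine matches
#' against; [enumerate_species()] produces the identical records as
#' objects, and the two agree by construction of the shared totals table.
#'
#' @param subclasses List from [build_subclasses()] (or a subset).
#' @param rules A [chain_rules()] object.
#' @param config Tool configuration.
#' @return Data frame with columns `level`, `name`, `class_code`,
#'   `subclass`, `category`, `total_carbons`, `total_double_bonds`,
#'   `formula`, `neutral_mass`.
#' @export
species_table <- function(subclasses = build_subclasses(),
                          rules = chain_rules(), config = default_config()) {
  backbone <- parse_chem_formula(config$building_blocks$backbone)
  water <- parse_chem_formula(config$building_blocks$water)
  masses <- element_masses()
  elements <- c("C", "H", "N", "O", "P", "S", "Na", "K", "Cl")
  fixed_counts <- function(f) {
    v <- stats::setNames(rep(0, length(elements)), elements)
    extra <- setdiff(names(f), elements)
    if (length(extra)) {
      stop(sprintf("unsupported element(s) in building blocks: %s",
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
    v[names(f)] <- unclass(f)
    v
  }
  blocks <- lapply(subclasses, function(sc) {
    totals <- .feasible_totals(sc$slot_count, rules)
    n_alkyl <- sum(sc$linkage == "alkyl")
    n_acyl <- sc$slot_count - n_alkyl
    n_bonds <- sc$slot_count + as.integer(sc$phospho)
    base <- fixed_counts(backbone) + fixed_counts(sc$head) -
      n_bonds * fixed_counts(water)
    counts <- matrix(rep(base, each = nrow(totals)), nrow = nrow(totals),
                     dimnames = list(NULL, elements))
    counts[, "C"] <- counts[, "C"] + totals$carbons
    counts[, "H"] <- counts[, "H"] + 2 * totals$carbons -
      2 * totals$double_bonds + 2 * n_alkyl
    counts[, "O"] <- counts[, "O"] + 2 * n_acyl + n_alkyl
    if (any(counts < 0)) {
      stop("negative element count while assembling species formulas",
           call. = FALSE)
    }
    prefix <- c("", "O-", "dO-", "tO-")[n_alkyl + 1L]
    data.frame(
      level = "Species",
      name = paste0(sc$class_code, " ", prefix, totals$carbons, ":",
                    totals$double_bonds),
      class_code = sc$class_code,
      subclass = sc$display_name,
      category = sc$category,
      total_carbons = totals$carbons,
      total_double_bonds = totals$double_bonds,
      formula = .formula_strings(counts),
      neutral_mass = as.numeric(counts %*% masses[elements]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
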