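# Shorthand-nomenclature grammar (single source of truth):
#   Species:    <CLASS> [O-|dO-|tO-]<C>:<D>
#   FAS:        <CLASS> <chain>(_<chain>)+          chains sorted, alkyl first
#   SubSpecies: <CLASS> <chain>(/<chain>)+          one field per backbone
#               position (2 for glycerophospholipids, 3 for glycerolipids);
#               unoccupied trailing positions render "0:0"
#   Isomer:     as SubSpecies, every chain with d > 0 carrying "(p1,p2,...)"
#   chain:      [O-]<c>:<d>[(p1,p2,...)]
# One ASCII space after the class code; no stereo descriptors. Monoradyl
# glycerophospholipid (lyso) classes use an L-prefixed class code (LPC, LPE,
# ...) so that species names stay unique across sub-classes.

.chain_token <- function(ch, with_positions = FALSE) {
  pos <- ""
  if (with_positions && ch$double_bonds > 0L) {
    pos <- paste0("(", paste(ch$positions, collapse = ","), ")")
  }
  paste0(if (ch$linkage == "alkyl") "O-" else "", ch$carbons, ":",
         ch$double_bonds, pos)
}

#' Canonical shorthand name of a record
#'
#' @param record A `lipid_record`.
#' @return A single character string.
#' @seealso [parse_name()] for the inverse.
#' @export
format_name <- function(record) {
  stopifnot(inherits(record, "lipid_record"))
  sc <- record$subclass
  code <- sc$class_code
  if (record$level == "Species") {
    n_alkyl <- sum(sc$linkage == "alkyl")
    prefix <- c("", "O-", "dO-", "tO-")[n_alkyl + 1L]
    return(paste0(code, " ", prefix, record$total_carbons, ":",
                  record$total_double_bonds))
  }
  if (record$level == "FasSpecies") {
    tokens <- vapply(.order_chains(record$chains), .chain_token, character(1))
    return(paste0(code, " ", paste(tokens, collapse = "_")))
  }
  with_pos <- record$level == "Isomer"
  tokens <- vapply(record$chains, .chain_token, character(1),
                   with_positions = with_pos)
  empty <- sc$backbone_positions - length(tokens)
  tokens <- c(tokens, rep("0:0", empty))
  paste0(code, " ", paste(tokens, collapse = "/"))
}

.parse_error <- function(text, pos, msg) {
  stop(sprintf("cannot parse '%s' at position %d: %s", text, pos, msg),
       call. = FALSE)
}

# parse one chain token; returns list(linkage, carbons, double_bonds,
# positions or NULL) or the string "empty" for the 0:0 placeholder
.parse_chain_token <- function(token, text, offset, allow_positions) {
  m <- regexec("^(O-)?([0-9]+):([0-9]+)(\\(([0-9]+(,[0-9]+)*)\\))?$", token)[[1]]
  if (m[1] == -1L) {
    .parse_error(text, offset, sprintf("malformed chain token '%s'", token))
  }
  g <- regmatches(token, list(m))[[1]]
  alkyl <- g[2] == "O-"
  carbons <- as.integer(g[3])
  dbl <- as.integer(g[4])
  pos <- NULL
  if (nzchar(g[5])) {
    if (!allow_positions) {
      .parse_error(text, offset,
                   "double-bond positions are not allowed at this level")
    }
    pos <- as.integer(strsplit(g[6], ",", fixed = TRUE)[[1]])
  }
  if (!alkyl && carbons == 0L && dbl == 0L && is.null(pos)) return("empty")
  if (carbons == 0L) .parse_error(text, offset, "chain with zero carbons")
  list(linkage = if (alkyl) "alkyl" else "acyl", carbons = carbons,
       double_bonds = dbl, positions = pos)
}

# resolve a class code to (main class, slot count); lyso glycerophospholipid
# codes carry an L prefix
.resolve_class_code <- function(code, config, text) {
  mcs <- config$main_classes
  phospho <- config$building_blocks$phospho_classes
  if (code %in% names(mcs)) {
    k <- max(mcs[[code]]$slots)
    return(list(main_class = code, slots = k))
  }
  if (startsWith(code, "L")) {
    base <- substring(code, 2L)
    if (base %in% names(mcs) && base %in% phospho &&
        1L %in% mcs[[base]]$slots) {
      return(list(main_class = base, slots = 1L))
    }
  }
  .parse_error(text, 1L, sprintf("unknown class code '%s'", code))
}

#' Parse a shorthand lipid name
#'
#' Inverse of [format_name()]: `format_name(parse_name(x))` returns the
#' canonical form of `x`, and `parse_name(format_name(record))` recovers
#' the record. The level is inferred from the separators (`/` for
#' SubSpecies/Isomer, `_` for FAS, a bare totals token for Species); names
#' that are valid at more than one level (the degenerate single-chain FAS
#' of a monoradyl class, or an all-saturated isomer, which formats exactly
#' like its parent) default to the less resolved level unless `level` is
#' given.
#'
#' @param text A shorthand name, e.g. `"PC 34:1"`, `"PC 16:0_18:1"`,
#'   `"PC 18:1(9)/16:0"`.
#' @param config Tool configuration (class codes, rules for validation).
#' @param level Optional explicit level to parse at.
#' @return A `lipid_record`.
#' @export
#' @examples
#' parse_name("PC 34:1")$neutral_mass       # 759.5778
#' format_name(parse_name("PC 18:1/16:0"))  # round-trip
parse_name <- function(text, config = default_config(), level = NULL) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (!is.null(level)) level <- match.arg(level, .levels)
  rules <- config$rules
  sp <- regexpr(" ", text, fixed = TRUE)
  if (sp == -1L) .parse_error(text, nchar(text), "missing space after class code")
  code <- substr(text, 1L, sp - 1L)
  rest <- substring(text, sp + 1L)
  if (!nzchar(code)) .parse_error(text, 1L, "empty class code")
  if (!nzchar(rest)) .parse_error(text, sp + 1L, "missing composition")
  cls <- .resolve_class_code(code, config, text)

  if (grepl("/", rest, fixed = TRUE)) {
    tokens <- strsplit(rest, "/", fixed = TRUE)[[1]]
    offsets <- sp + 1L + c(0L, cumsum(nchar(tokens) + 1L))[seq_along(tokens)]
    parsed <- Map(.parse_chain_token, tokens, offset = offsets,
                  MoreArgs = list(text = text, allow_positions = TRUE))
    is_empty <- vapply(parsed, identical, logical(1), "empty")
    if (any(is_empty) && any(!is_empty) &&
        !all(which(is_empty) > max(which(!is_empty)))) {
      .parse_error(text, offsets[which(is_empty)[1L]],
                   "unoccupied 0:0 positions must be trailing")
    }
    chains_spec <- parsed[!is_empty]
    if (length(chains_spec) != cls$slots) {
      .parse_error(text, sp + 1L,
                   sprintf("expected %d occupied position(s) for %s",
                           cls$slots, code))
    }
    sc <- .subclass_for(cls, vapply(chains_spec, `[[`, character(1), "linkage"),
                        config, text)
    if (length(tokens) != sc$backbone_positions) {
      .parse_error(text, sp + 1L,
                   sprintf("%s names carry %d '/'-separated positions",
                           sc$class_code, sc$backbone_positions))
    }
    has_pos <- vapply(chains_spec, function(p) !is.null(p$positions), logical(1))
    needs_pos <- vapply(chains_spec, function(p) p$double_bonds > 0L, logical(1))
    want_isomer <- identical(level, "Isomer") || any(has_pos)
    if (want_isomer && any(needs_pos & !has_pos)) {
      .parse_error(text, sp + 1L,
                   "isomer names must give positions for every unsaturated chain")
    }
    chains <- lapply(chains_spec, function(p) {
      ch <- lipid_chain(p$linkage, p$carbons, p$double_bonds,
                        positions = if (want_isomer) p$positions %||% integer(0))
      validate_chain(ch, rules)
    })
    lvl <- if (want_isomer) "Isomer" else "SubSpecies"
    # chains must occupy leading positions with alkyls first (canonical form)
    lk <- vapply(chains, `[[`, character(1), "linkage")
    if (is.unsorted(match(lk, c("alkyl", "acyl")))) {
      .parse_error(text, sp + 1L, "alkyl chains must precede acyl chains")
    }
    return(.new_record(lvl, sc, config, chains = chains))
  }

  if (grepl("_", rest, fixed = TRUE) || identical(level, "FasSpecies")) {
    tokens <- strsplit(rest, "_", fixed = TRUE)[[1]]
    offsets <- sp + 1L + c(0L, cumsum(nchar(tokens) + 1L))[seq_along(tokens)]
    parsed <- Map(.parse_chain_token, tokens, offset = offsets,
                  MoreArgs = list(text = text, allow_positions = FALSE))
    if (any(vapply(parsed, identical, logical(1), "empty"))) {
      .parse_error(text, sp + 1L, "0:0 placeholders are not chain-list entries")
    }
    sc <- .subclass_for(cls, vapply(parsed, `[[`, character(1), "linkage"),
                        config, text)
    if (length(parsed) != sc$slot_count) {
      .parse_error(text, sp + 1L,
                   sprintf("expected %d chain(s) for %s", sc$slot_count,
                           sc$class_code))
    }
    chains <- lapply(parsed, function(p) {
      validate_chain(lipid_chain(p$linkage, p$carbons, p$double_bonds), rules)
    })
    return(.new_record("FasSpecies", sc, config, chains = chains))
  }

  # Species: [O-|dO-|tO-]C:D
  m <- regexec("^(O-|dO-|tO-)?([0-9]+):([0-9]+)$", rest)[[1]]
  if (m[1] == -1L) {
    .parse_error(text, sp + 1L,
                 "species composition must be [O-|dO-|tO-]<carbons>:<double bonds>")
  }
  g <- regmatches(rest, list(m))[[1]]
  n_alkyl <- match(g[2], c("", "O-", "dO-", "tO-")) - 1L
  totals_c <- as.integer(g[3])
  totals_d <- as.integer(g[4])
  if (n_alkyl > cls$slots) {
    .parse_error(text, sp + 1L, "more alkyl chains than radyl positions")
  }
  linkage <- c(rep("alkyl", n_alkyl), rep("acyl", cls$slots - n_alkyl))
  sc <- lipid_subclass(cls$main_class, linkage, config)
  feas <- .feasible_totals(sc$slot_count, rules)
  if (!any(feas$carbons == totals_c & feas$double_bonds == totals_d)) {
    .parse_error(text, sp + 1L,
                 sprintf("totals %d:%d are not realizable by %d valid chain(s)",
                         totals_c, totals_d, sc$slot_count))
  }
  .new_record("Species", sc, config, total_carbons = totals_c,
              total_double_bonds = totals_d)
}

.subclass_for <- function(cls, linkages, config, text) {
  n_alkyl <- sum(linkages == "alkyl")
  n_acyl <- cls$slots - n_alkyl
  if (n_acyl < 0L) .parse_error(text, 1L, "more chains than radyl positions")
  lipid_subclass(cls$main_class,
                 c(rep("alkyl", n_alkyl), rep("acyl", n_acyl)), config)
}
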