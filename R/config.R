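# Tool configuration: chain rules, main-class table, building blocks and
# adduct table, with embedded defaults and YAML overrides.

.default_main_classes <- function() {
  list(
    PC = list(category = "glycerophospholipids", stem = "glycerophosphocholines",    slots = c(1L, 2L)),
    PE = list(category = "glycerophospholipids", stem = "glycerophosphoethanolamines", slots = c(1L, 2L)),
    PS = list(category = "glycerophospholipids", stem = "glycerophosphoserines",     slots = c(1L, 2L)),
    PG = list(category = "glycerophospholipids", stem = "glycerophosphoglycerols",   slots = c(1L, 2L)),
    PI = list(category = "glycerophospholipids", stem = "glycerophosphoinositols",   slots = c(1L, 2L)),
    PA = list(category = "glycerophospholipids", stem = "glycerophosphates",         slots = c(1L, 2L)),
    MG = list(category = "glycerolipids",        stem = "glycerols",                 slots = 1L),
    DG = list(category = "glycerolipids",        stem = "glycerols",                 slots = 2L),
    TG = list(category = "glycerolipids",        stem = "glycerols",                 slots = 3L)
  )
}

# Head-group building blocks: the full polar head including the phosphate
# where present, as condensed onto glycerol with loss of one water per
# phosphodiester bond. Validated against reference lipid formulas in the
# test suite (e.g. glycerol + C5H14NO4P + 16:0 + 18:1 - 3 H2O = C42H82NO8P).
.default_building_blocks <- function() {
  list(
    backbone = "C3H8O3",   # glycerol
    water = "H2O",
    head_groups = list(
      PC = "C5H14NO4P",    # phosphocholine
      PE = "C2H8NO4P",     # phosphoethanolamine
      PS = "C3H8NO6P",     # phosphoserine
      PG = "C3H9O6P",      # phosphoglycerol
      PI = "C6H13O9P",     # phosphoinositol
      PA = "H3O4P",        # phosphoric acid
      MG = "", DG = "", TG = ""   # glycerolipids: bare hydroxyls, no head
    ),
    phospho_classes = c("PC", "PE", "PS", "PG", "PI", "PA")
  )
}

#' Default adduct table
#'
#' Singly charged adducts with mass deltas computed from the monoisotopic
#' element masses, including the electron mass correction, plus the identity
#' `neutral` adduct (charge 0, delta 0) for searching neutral-mass lists.
#'
#' @return Data frame with columns `name`, `charge`, `mass_delta` (Da).
#' @export
default_adducts <- function() {
  m <- element_masses()
  e <- electron_mass()
  data.frame(
    name = c("[M+H]+", "[M+Na]+", "[M+NH4]+", "[M+K]+",
             "[M-H]-", "[M+Cl]-", "[M+HCOO]-", "neutral"),
    charge = c(1L, 1L, 1L, 1L, -1L, -1L, -1L, 0L),
    mass_delta = c(
      m[["H"]] - e,
      m[["Na"]] - e,
      m[["N"]] + 4 * m[["H"]] - e,
      m[["K"]] - e,
      -(m[["H"]] - e),
      m[["Cl"]] + e,
      m[["C"]] + m[["H"]] + 2 * m[["O"]] + e,
      0
    ),
    stringsAsFactors = FALSE
  )
}

#' Default tool configuration
#'
#' The embedded defaults: chain rules encoding the community-agreed
#' fatty-chain bounds (2-30 carbons, odd chains allowed, minimum 0 double
#' bonds, first double bond at position 2 or higher, methylene-interrupted
#' spacing), the nine main classes whose Cartesian cross with the linkage
#' combinations yields the 39 sub-classes, the building-block formula table,
#' and the default adduct set.
#'
#' @return A list of class `lipid_config` with elements `rules`,
#'   `main_classes`, `building_blocks`, `adducts`, `output_format`,
#'   `log_level`, `seed`.
#' @seealso [load_config()], [build_subclasses()]
#' @export
default_config <- function() {
  structure(list(
    rules = chain_rules(),
    main_classes = .default_main_classes(),
    building_blocks = .default_building_blocks(),
    adducts = default_adducts(),
    output_format = "tsv",
    log_level = "info",
    seed = NULL
  ), class = "lipid_config")
}

.rule_fields <- c("min_carbons", "max_carbons", "allow_odd_carbons",
                  "min_double_bonds", "max_double_bonds",
                  "first_db_position", "db_position_step", "allow_terminal_db")

#' Load a configuration file
#'
#' Reads a YAML configuration and merges it over the embedded defaults.
#' Absent fields fall back to the defaults; unknown keys are an error, never
#' silently ignored. The effective configuration is echoed to standard error
#' at log level `debug`.
#'
#' Recognised top-level keys: `rules` (any [chain_rules()] field),
#' `main_classes` (list of `{code, category, stem, slots, head}` entries,
#' replacing the default table), `building_blocks` (`backbone`,
#' `head_groups`, `phospho_classes`), `adducts` (list of
#' `{name, charge, mass_delta}` entries, replacing the default table),
#' `output_format`, `log_level`, `seed`.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A `lipid_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) return(cfg)
  if (!is.list(raw)) stop("config file must be a YAML mapping", call. = FALSE)
  known <- c("rules", "main_classes", "building_blocks", "adducts",
             "output_format", "log_level", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(raw$rules)) {
    bad <- setdiff(names(raw$rules), .rule_fields)
    if (length(bad)) {
      stop(sprintf("unknown key(s) in rules: %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    merged <- utils::modifyList(unclass(cfg$rules), raw$rules)
    cfg$rules <- do.call(chain_rules, merged)
  }
  if (!is.null(raw$main_classes)) {
    cfg$main_classes <- .parse_main_classes(raw$main_classes, cfg)
  }
  if (!is.null(raw$building_blocks)) {
    bb <- raw$building_blocks
    bad <- setdiff(names(bb), c("backbone", "head_groups", "phospho_classes"))
    if (length(bad)) {
      stop(sprintf("unknown key(s) in building_blocks: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    if (!is.null(bb$backbone)) cfg$building_blocks$backbone <- bb$backbone
    if (!is.null(bb$head_groups)) {
      cfg$building_blocks$head_groups <- utils::modifyList(
        cfg$building_blocks$head_groups, bb$head_groups)
    }
    if (!is.null(bb$phospho_classes)) {
      cfg$building_blocks$phospho_classes <- as.character(bb$phospho_classes)
    }
  }
  if (!is.null(raw$adducts)) {
    rows <- lapply(raw$adducts, function(a) {
      bad <- setdiff(names(a), c("name", "charge", "mass_delta"))
      if (length(bad)) {
        stop(sprintf("unknown key(s) in adduct entry: %s",
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
      data.frame(name = a$name, charge = as.integer(a$charge),
                 mass_delta = as.numeric(a$mass_delta), stringsAsFactors = FALSE)
    })
    cfg$adducts <- do.call(rbind, rows)
  }
  for (k in c("output_format", "log_level")) {
    if (!is.null(raw[[k]])) cfg[[k]] <- raw[[k]]
  }
  if (!is.null(raw$seed)) cfg$seed <- as.integer(raw$seed)
  .log_config(cfg)
  cfg
}

.parse_main_classes <- function(entries, cfg) {
  out <- list()
  for (mc in entries) {
    bad <- setdiff(names(mc), c("code", "category", "stem", "slots", "head"))
    if (length(bad)) {
      stop(sprintf("unknown key(s) in main_classes entry: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    if (is.null(mc$code)) stop("main_classes entry missing 'code'", call. = FALSE)
    out[[mc$code]] <- list(
      category = mc$category %||% "glycerophospholipids",
      stem = mc$stem %||% mc$code,
      slots = as.integer(mc$slots %||% 2L)
    )
    if (!is.null(mc$head)) {
      cfg$building_blocks$head_groups[[mc$code]] <- mc$head
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.log_config <- function(cfg) {
  if (!identical(cfg$log_level, "debug")) return(invisible(NULL))
  message("effective configuration:")
  message(paste(utils::capture.output(utils::str(unclass(cfg), max.level = 2)),
                collapse = "\n"))
  invisible(NULL)
}
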