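# MS1 precursor-ion annotation: each query m/z is pre-processed with every
# selected adduct, the implied neutral mass is matched against the
# species-level table within tolerance, and hits are reported per query.
# Only species-level identifications are claimed from a single precursor
# mass; finer levels would overstate what MS1 can resolve.

.lookup_adducts <- function(adducts, table) {
  if (is.data.frame(adducts)) return(adducts)
  idx <- match(adducts, table$name)
  if (anyNA(idx)) {
    stop(sprintf("unknown adduct(s): %s (available: %s)",
                 paste(adducts[is.na(idx)], collapse = ", "),
                 paste(table$name, collapse = ", ")), call. = FALSE)
  }
  table[idx, , drop = FALSE]
}

#' Neutral mass implied by an observed m/z under an adduct
#'
#' For a charged adduct, `|charge| * mz - mass_delta`; the `neutral` adduct
#' is the identity. [mz_from_neutral_mass()] is the exact inverse.
#'
#' @param mz Observed m/z (numeric vector).
#' @param adduct Adduct name (looked up in `adducts`) or a one-row adduct
#'   data frame.
#' @param adducts Adduct table, defaults to [default_adducts()].
#' @return Neutral mass in Da.
#' @export
#' @examples
#' neutral_mass_from_mz(760.5851, "[M+H]+")  # 759.5778
neutral_mass_from_mz <- function(mz, adduct, adducts = default_adducts()) {
  a <- .lookup_adducts(adduct, adducts)
  if (a$charge == 0L) return(mz)
  abs(a$charge) * mz - a$mass_delta
}

#' @rdname neutral_mass_from_mz
#' @param neutral Neutral mass in Da.
#' @export
mz_from_neutral_mass <- function(neutral, adduct, adducts = default_adducts()) {
  a <- .lookup_adducts(adduct, adducts)
  if (a$charge == 0L) return(neutral)
  (neutral + a$mass_delta) / abs(a$charge)
}

#' Parse a tolerance specification
#'
#' Accepts `"0.01da"`, `"0.01 Da"`, `"5ppm"` (case-insensitive), or a bare
#' number (interpreted in Da).
#'
#' @param x Tolerance string or number.
#' @return List with `value` (numeric) and `mode` (`"da"` or `"ppm"`).
#' @export
parse_tolerance <- function(x) {
  if (is.numeric(x)) return(list(value = as.numeric(x), mode = "da"))
  m <- regexec("^\\s*([0-9.eE+-]+)\\s*(da|ppm)\\s*$", tolower(x))[[1]]
  if (m[1] == -1L) {
    stop(sprintf("cannot parse tolerance '%s' (use e.g. '0.01da' or '5ppm')", x),
         call. = FALSE)
  }
  g <- regmatches(tolower(x), list(m))[[1]]
  list(value = as.numeric(g[2]), mode = g[3])
}

#' Search precursor masses against the theoretical species space
#'
#' Every adduct is tried for every query. A hit is any (query, adduct,
#' species) triple whose implied neutral mass lies within the tolerance of
#' the species' theoretical neutral mass, the species not being excluded by
#' the class filters. In `ppm` mode the tolerance is taken relative to the
#' theoretical mass. Hits are grouped by query in input order and sorted
#' within a query by absolute mass error, ties broken by canonical name.
#'
#' @param queries Numeric vector of precursor masses (m/z, or neutral
#'   masses when searching with the `neutral` adduct).
#' @param tolerance Tolerance value; a number (Da), a string such as
#'   `"0.01da"`/`"5ppm"`, or a `list(value=, mode=)`.
#' @param adducts Character vector of adduct names (or an adduct data
#'   frame). Must be non-empty.
#' @param exclude Optional list with any of `categories`, `main_classes`
#'   (class codes, matching the lyso variant too), `subclasses` (display
#'   names): matching species are removed from the search space.
#' @param subclasses Sub-class list defining the search space, default all.
#' @param rules Chain rules defining the search space.
#' @param config Tool configuration.
#' @param species Optional precomputed [species_table()], used as a cache;
#'   when supplied, `subclasses`/`rules` are ignored for table generation.
#' @return Data frame of class `ms1_hits` with columns `query_mz`,
#'   `adduct`, `species_name`, `subclass`, `category`, `theoretical_mass`,
#'   `neutral_query_mass`, `delta_mda`, `delta_ppm`.
#' @export
#' @examples
#' hits <- ms1_search(759.58, tolerance = 0.05, adducts = "neutral")
#' subset(hits, select = c(species_name, delta_mda))
ms1_search <- function(queries, tolerance, adducts = "[M+H]+",
                       exclude = NULL, subclasses = build_subclasses(),
                       rules = chain_rules(), config = default_config(),
                       species = NULL) {
  tol <- if (is.list(tolerance)) tolerance else parse_tolerance(tolerance)
  if (!tol$mode %in% c("da", "ppm")) stop("tolerance mode must be 'da' or 'ppm'",
                                          call. = FALSE)
  if (!is.finite(tol$value) || tol$value <= 0) {
    stop("tolerance must be positive", call. = FALSE)
  }
  if (length(adducts) == 0L) stop("at least one adduct is required", call. = FALSE)
  adt <- .lookup_adducts(adducts, config$adducts)
  if (is.null(species)) species <- species_table(subclasses, rules, config)
  species <- .apply_filters(species, exclude)

  hits <- list()
  for (qi in seq_along(queries)) {
    q <- queries[qi]
    per_query <- list()
    for (ai in seq_len(nrow(adt))) {
      neutral <- neutral_mass_from_mz(q, adt[ai, , drop = FALSE])
      delta <- neutral - species$neutral_mass
      lim <- if (tol$mode == "da") tol$value else {
        tol$value * 1e-6 * species$neutral_mass
      }
      sel <- which(abs(delta) <= lim)
      if (!length(sel)) next
      per_query[[length(per_query) + 1L]] <- data.frame(
        query_mz = q,
        adduct = adt$name[ai],
        species_name = species$name[sel],
        subclass = species$subclass[sel],
        category = species$category[sel],
        theoretical_mass = species$neutral_mass[sel],
        neutral_query_mass = neutral,
        delta_mda = delta[sel] * 1000,
        delta_ppm = delta[sel] / species$neutral_mass[sel] * 1e6,
        stringsAsFactors = FALSE
      )
    }
    if (!length(per_query)) next
    block <- do.call(rbind, per_query)
    block <- block[order(abs(block$delta_mda), block$species_name,
                         block$adduct), , drop = FALSE]
    hits[[length(hits) + 1L]] <- block
  }
  out <- if (length(hits)) do.call(rbind, hits) else data.frame(
    query_mz = numeric(0), adduct = character(0), species_name = character(0),
    subclass = character(0), category = character(0),
    theoretical_mass = numeric(0), neutral_query_mass = numeric(0),
    delta_mda = numeric(0), delta_ppm = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ms1_hits", "data.frame")
  out
}

.apply_filters <- function(species, exclude) {
  if (is.null(exclude)) return(species)
  bad <- setdiff(names(exclude), c("categories", "main_classes", "subclasses"))
  if (length(bad)) {
    stop(sprintf("unknown filter(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  keep <- rep(TRUE, nrow(species))
  if (!is.null(exclude$categories)) {
    keep <- keep & !(species$category %in% exclude$categories)
  }
  if (!is.null(exclude$main_classes)) {
    mc <- sub("^L", "", species$class_code)
    keep <- keep & !(mc %in% sub("^L", "", exclude$main_classes))
  }
  if (!is.null(exclude$subclasses)) {
    keep <- keep & !(species$subclass %in% exclude$subclasses)
  }
  species[keep, , drop = FALSE]
}

#' @export
print.ms1_hits <- function(x, ...) {
  cat(sprintf("<ms1_hits> %d hit(s) over %d quer%s\n", nrow(x),
              length(unique(x$query_mz)),
              if (length(unique(x$query_mz)) == 1L) "y" else "ies"))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 20L), digits = 7)
  invisible(x)
}

#' Read a precursor mass list
#'
#' Plain text, one mass per line; blank lines and `#` comments ignored.
#'
#' @param path File path.
#' @return Numeric vector of masses in input order.
#' @export
read_mass_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- suppressWarnings(as.numeric(lines))
  if (anyNA(out)) {
    stop(sprintf("non-numeric mass entry: '%s'", lines[which(is.na(out))[1L]]),
         call. = FALSE)
  }
  out
}
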