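# Table writers. Output is fully deterministic: fixed column orders, fixed
# sort orders upstream, masses rounded to four decimals at write time, so
# repeated runs with the same configuration produce byte-identical files.

.round_cols <- function(df, cols, digits = 4L) {
  for (col in intersect(cols, names(df))) {
    df[[col]] <- formatC(df[[col]], format = "f", digits = digits)
  }
  df
}

.write_df <- function(df, path, format) {
  format <- match.arg(format, c("tsv", "csv", "json"))
  if (format == "json") {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    jsonlite::stream_out(df, con, verbose = FALSE, digits = NA)
  } else {
    utils::write.table(df, file = path, sep = if (format == "tsv") "\t" else ",",
                       quote = FALSE, row.names = FALSE, col.names = TRUE,
                       fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Write an enumeration table
#'
#' Writes records (the data frame form produced by [species_table()], or
#' any records coerced with [records_table()]) with columns `level`,
#' `name`, `subclass`, `category`, `formula` (Hill order) and the neutral
#' monoisotopic mass at four decimals.
#'
#' @param records A data frame of records, or a list of `lipid_record`s.
#' @param path Output file path.
#' @param format `"tsv"`, `"csv"` or `"json"` (JSON lines).
#' @return `path`, invisibly.
#' @export
write_lipid_table <- function(records, path, format = "tsv") {
  if (!is.data.frame(records)) records <- records_table(records)
  cols <- c("level", "name", "subclass", "category", "formula", "neutral_mass")
  df <- records[, cols, drop = FALSE]
  df <- .round_cols(df, "neutral_mass")
  .write_df(df, path, format)
}

#' Flatten a list of records to a data frame
#'
#' @param records List of `lipid_record`s.
#' @return Data frame with columns `level`, `name`, `subclass`, `category`,
#'   `formula`, `neutral_mass`.
#' @export
records_table <- function(records) {
  rows <- lapply(records, function(r) {
    data.frame(level = r$level, name = r$name,
               subclass = r$subclass$display_name,
               category = r$subclass$category,
               formula = formula_string(r$formula),
               neutral_mass = r$neutral_mass, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(level = character(0), name = character(0),
                      subclass = character(0), category = character(0),
                      formula = character(0), neutral_mass = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Write MS1 search results
#'
#' Columns `query_mz`, `adduct`, `species_name`, `subclass`, `category`,
#' `theoretical_mass` (4 decimals), `delta_mda`, `delta_ppm`.
#'
#' @param hits An `ms1_hits` data frame from [ms1_search()].
#' @param path Output file path.
#' @param format `"tsv"`, `"csv"` or `"json"` (JSON lines).
#' @return `path`, invisibly.
#' @export
write_search_results <- function(hits, path, format = "tsv") {
  cols <- c("query_mz", "adduct", "species_name", "subclass", "category",
            "theoretical_mass", "delta_mda", "delta_ppm")
  df <- as.data.frame(hits)[, cols, drop = FALSE]
  df <- .round_cols(df, "theoretical_mass")
  df <- .round_cols(df, c("delta_mda", "delta_ppm"), digits = 3L)
  .write_df(df, path, format)
}
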