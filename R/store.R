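#' Open (and initialize) a feature store
#'
#' The store is a single-file SQLite database with two tables,
#' `extracellular_features` and `intracellular_features`. Rows are only ever
#' appended — reprocessing a file adds a new row with a fresh UTC timestamp,
#' preserving the full processing history.
#'
#' @param path database file path (created if missing); `":memory:"` for an
#'   in-memory store.
#' @return A `feature_store` object wrapping the DBI connection.
#' @export
feature_store <- function(path = "features.sqlite") {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  structure(list(con = con, path = path), class = "feature_store")
}

#' Close a feature store
#' @param store a [feature_store()].
#' @return invisibly, `TRUE`.
#' @export
close_store <- function(store) {
  DBI::dbDisconnect(store$con)
  invisible(TRUE)
}

store_table <- function(mode = c("extracellular", "intracellular")) {
  paste0(match.arg(mode), "_features")
}

#' Append feature rows to the store
#'
#' Each row receives a `processed_at` UTC ISO-8601 timestamp at insertion.
#' If the table exists, incoming columns must match the stored schema; a
#' mismatch raises an error naming the offending columns.
#'
#' @param features feature tibble (e.g. `run_batch()$features`).
#' @param store a [feature_store()].
#' @param mode `"extracellular"` or `"intracellular"`.
#' @return Number of rows inserted, invisibly.
#' @export
persist_features <- function(features, store, mode = c("extracellular", "intracellular")) {
  mode <- match.arg(mode)
  tbl <- store_table(mode)
  features <- as_tibble(features)
  if (nrow(features) == 0) return(invisible(0L))
  if (any(!nzchar(features$file_path))) abort("file_path must be non-empty.")
  features$processed_at <- format(
    Sys.time(), "%Y-%m-%dT%H:%M:%OS6Z", tz = "UTC"
  )
  features <- features %>%
    mutate(across(dplyr::where(is.factor), as.character))
  if (DBI::dbExistsTable(store$con, tbl)) {
    have <- DBI::dbListFields(store$con, tbl)
    extra <- setdiff(names(features), have)
    miss <- setdiff(have, names(features))
    if (length(extra) > 0 || length(miss) > 0) {
      abort(sprintf(
        "Schema mismatch for %s — unexpected: [%s]; missing: [%s]",
        tbl, paste(extra, collapse = ", "), paste(miss, collapse = ", ")
      ))
    }
    features <- features[have]
  }
  DBI::dbWriteTable(store$con, tbl, as.data.frame(features), append = TRUE)
  invisible(nrow(features))
}

#' Query feature rows from the store
#'
#' @param store a [feature_store()].
#' @param mode `"extracellular"` or `"intracellular"`.
#' @param cell_lines,compounds optional character filters (exact match); a
#'   value absent from the store simply yields zero rows.
#' @param latest_only when `TRUE`, return per `file_path` only the most
#'   recently processed row.
#' @return A tibble (empty, with the stored schema, when nothing matches or
#'   the table does not exist yet).
#' @export
query_features <- function(store, mode = c("extracellular", "intracellular"),
                           cell_lines = NULL, compounds = NULL,
                           latest_only = FALSE) {
  mode <- match.arg(mode)
  tbl <- store_table(mode)
  if (!DBI::dbExistsTable(store$con, tbl)) return(tibble())
  # rowid breaks processed_at ties: later inserts win
  df <- DBI::dbGetQuery(store$con, sprintf("SELECT rowid AS rid__, * FROM %s", tbl))
  out <- as_tibble(df)
  if (!is.null(cell_lines)) out <- filter(out, .data$cell_line %in% cell_lines)
  if (!is.null(compounds)) out <- filter(out, .data$compound %in% compounds)
  if (latest_only && nrow(out) > 0) {
    out <- out %>%
      group_by(.data$file_path) %>%
      arrange(.data$processed_at, .data$rid__, .by_group = TRUE) %>%
      slice(dplyr::n()) %>%
      ungroup()
  }
  out %>% select(-"rid__") %>% arrange(.data$file_path)
}
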