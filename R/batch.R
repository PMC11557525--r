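#' Process many recording files in parallel
#'
#' Files are processed in batches of `n_cpus` in forked worker processes
#' (shared-nothing; each worker returns its feature row by value), so one
#' file's failure cannot affect the others and the resulting feature table
#' is identical for any `n_cpus` and any completion order. Failures are
#' collected into a report and the run continues.
#'
#' @param file_list tibble from [create_file_list()]: columns `file_path`,
#'   `cell_line`, `compound`, `note`.
#' @param mode `"extracellular"` or `"intracellular"`.
#' @param n_cpus worker count (>= 1); on platforms without fork the batch
#'   degrades to sequential processing.
#' @param cfg extraction configuration, see [extraction_config()].
#' @return A list with `features` (tibble, one row per successful file,
#'   ordered by `file_path`) and `failures` (tibble `file_path`, `error`).
#' @export
run_batch <- function(file_list, mode = c("extracellular", "intracellular"),
                      n_cpus = 1, cfg = extraction_config()) {
  mode <- match.arg(mode)
  stopifnot(n_cpus >= 1)
  file_list <- arrange(as_tibble(file_list), .data$file_path)

  process_one <- function(row) {
    tryCatch({
      rec <- read_recording(
        row$file_path, signal_class = mode,
        cell_line = row$cell_line, compound = row$compound, note = row$note
      )
      feats <- if (mode == "extracellular") {
        extract_extracellular_features(rec, cfg)$features
      } else {
        extract_intracellular_features(rec)$features
      }
      list(ok = TRUE, features = feats)
    }, error = function(e) {
      list(ok = FALSE, error = conditionMessage(e))
    })
  }

  rows <- purrr::transpose(as.list(file_list))
  names(rows) <- file_list$file_path
  use_fork <- n_cpus > 1 && .Platform$OS.type == "unix"
  batches <- split(rows, ceiling(seq_along(rows) / n_cpus))
  results <- list()
  for (batch in batches) {
    res <- if (use_fork) {
      parallel::mclapply(batch, process_one, mc.cores = n_cpus)
    } else {
      lapply(batch, process_one)
    }
    results <- c(results, res)
  }

  ok <- purrr::map_lgl(results, function(r) isTRUE(r$ok))
  features <- if (any(ok)) {
    bind_rows(purrr::map(results[ok], "features")) %>%
      arrange(.data$file_path)
  } else {
    tibble()
  }
  failures <- tibble(
    file_path = names(results)[!ok],
    error = purrr::map_chr(results[!ok], function(r) {
      r$error %||% "worker failed"
    })
  )
  if (nrow(failures) > 0) {
    warn(sprintf("%d of %d files failed processing.", nrow(failures), length(rows)))
  }
  list(features = features, failures = failures)
}
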