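#' Read an HD-MEA recording from an HDF5 file
#'
#' The on-disk layout is an open fixture format (vendor formats vary and are
#' proprietary): group-free HDF5 with datasets `/signals` (electrodes x
#' samples, microvolts or millivolts), `/coords` (electrodes x 2, micrometers),
#' `/electrode_id` (integer vector) and scalar datasets `/sampling_rate` (Hz)
#' and `/gain`, plus optional string datasets `/cell_line`, `/compound`,
#' `/note`. A `reader` plug-in can be supplied for other dialects.
#'
#' @param path path to an HDF5 file.
#' @param signal_class `"extracellular"` or `"intracellular"`.
#' @param cell_line,compound,note metadata overrides; when `NULL`, values
#'   stored in the file (if any) are used.
#' @param reader optional function `(path, signal_class, ...) -> mea_recording`
#'   implementing a vendor dialect; the default reads the fixture layout.
#' @return A [mea_recording()].
#' @export
read_recording <- function(path, signal_class = c("extracellular", "intracellular"),
                           cell_line = NULL, compound = NULL, note = NULL,
                           reader = NULL) {
  signal_class <- match.arg(signal_class)
  if (!file.exists(path)) {
    abort(sprintf("Recording file does not exist: %s", path))
  }
  if (!is.null(reader)) {
    return(reader(path, signal_class))
  }
  contents <- tryCatch(
    rhdf5::h5ls(path, recursive = FALSE)$name,
    error = function(e) abort(sprintf("Not a readable HDF5 file: %s", path))
  )
  need <- c("signals", "coords", "sampling_rate")
  missing <- setdiff(need, contents)
  if (length(missing) > 0) {
    abort(sprintf(
      "Malformed recording file %s: missing dataset(s) %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  h5read1 <- function(name, default = NULL) {
    if (name %in% contents) c(rhdf5::h5read(path, name)) else default
  }
  signals <- rhdf5::h5read(path, "signals")
  coords <- rhdf5::h5read(path, "coords")
  if (length(signals) == 0 || nrow(as.matrix(signals)) == 0) {
    abort(sprintf("Empty recording (zero electrodes): %s", path))
  }
  ids <- h5read1("electrode_id", seq_len(nrow(signals)))
  rec <- mea_recording(
    signals = signals,
    electrodes = tibble(
      electrode_id = as.integer(ids),
      x = as.numeric(coords[, 1]),
      y = as.numeric(coords[, 2])
    ),
    sampling_rate = as.numeric(h5read1("sampling_rate")),
    gain = as.numeric(h5read1("gain", 1)),
    signal_class = signal_class,
    cell_line = cell_line %||% h5read1("cell_line", ""),
    compound = compound %||% h5read1("compound", ""),
    note = note %||% h5read1("note", ""),
    file_path = path
  )
  rec
}

#' Write a recording to the fixture HDF5 layout
#'
#' @param rec a [mea_recording()].
#' @param path output path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "mea_recording"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(rec$signals, path, "signals")
  rhdf5::h5write(cbind(rec$electrodes$x, rec$electrodes$y), path, "coords")
  rhdf5::h5write(as.integer(rec$electrodes$electrode_id), path, "electrode_id")
  rhdf5::h5write(rec$sampling_rate, path, "sampling_rate")
  rhdf5::h5write(rec$gain, path, "gain")
  rhdf5::h5write(rec$cell_line, path, "cell_line")
  rhdf5::h5write(rec$compound, path, "compound")
  rhdf5::h5write(rec$note, path, "note")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a recording-directory manifest
#'
#' The manifest is a CSV with header `directory,cell_line,compound,note`,
#' one row per directory of recording files.
#'
#' @param path CSV path.
#' @return A tibble with those four character columns.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("directory", "cell_line", "compound", "note")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(sprintf("Manifest lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  as_tibble(df[need])
}

#' Expand a manifest into a per-file list
#'
#' Recursively discovers recording files (by extension glob) under each
#' manifest directory; every file inherits that row's metadata. Output rows
#' are sorted lexicographically by `file_path`, so the result is invariant to
#' manifest row order and filesystem enumeration order. Nonexistent
#' directories produce a warning and are skipped.
#'
#' @param manifest tibble with columns `directory`, `cell_line`, `compound`,
#'   `note` (see [read_manifest()]).
#' @param pattern regular expression for recording files
#'   (default: `.h5` / `.hdf5` extensions).
#' @return A tibble `(file_path, cell_line, compound, note)`.
#' @export
create_file_list <- function(manifest, pattern = "\\.(h5|hdf5)$") {
  manifest <- as_tibble(manifest)
  if (nrow(manifest) == 0 || any(!nzchar(manifest$directory))) {
    abort("Every manifest entry needs a non-empty directory.")
  }
  rows <- purrr::pmap_dfr(manifest, function(directory, cell_line, compound, note, ...) {
    if (!dir.exists(directory)) {
      warn(sprintf("Manifest directory not found, skipping: %s", directory))
      return(tibble(
        file_path = character(), cell_line = character(),
        compound = character(), note = character()
      ))
    }
    files <- list.files(directory, pattern = pattern, recursive = TRUE,
                        full.names = TRUE, ignore.case = TRUE)
    tibble(
      file_path = files, cell_line = cell_line,
      compound = compound, note = note
    )
  })
  arrange(rows, .data$file_path)
}
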