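#' Construct an HD-MEA recording object
#'
#' A `mea_recording` bundles the per-electrode voltage traces of one HD-MEA
#' recording with electrode geometry and acquisition metadata. Voltages are
#' stored as an electrodes-by-samples matrix; units are microvolts for
#' extracellular recordings and millivolts for intracellular-like ones.
#' Electrode coordinates are in micrometers; all internal times are in
#' milliseconds.
#'
#' @param signals numeric matrix, electrodes x samples.
#' @param electrodes tibble with columns `electrode_id` (unique integers),
#'   `x`, `y` (micrometers, finite).
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param gain dimensionless amplifier gain.
#' @param signal_class `"extracellular"` or `"intracellular"`.
#' @param cell_line,compound,note,file_path recording metadata strings.
#'
#' @return A `mea_recording` object. `rec_duration` (seconds) is derived as
#'   `(n_samples - 1) / sampling_rate`.
#' @export
mea_recording <- function(signals, electrodes, sampling_rate, gain = 1,
                          signal_class = c("extracellular", "intracellular"),
                          cell_line = "", compound = "", note = "",
                          file_path = "") {
  signal_class <- match.arg(signal_class)
  signals <- as.matrix(signals)
  electrodes <- as_tibble(electrodes)
  stopifnot(is.numeric(signals), ncol(signals) >= 1)
  if (!all(c("electrode_id", "x", "y") %in% names(electrodes))) {
    abort("`electrodes` must have columns electrode_id, x, y.")
  }
  if (nrow(electrodes) != nrow(signals)) {
    abort("`electrodes` rows must match `signals` rows (one per electrode).")
  }
  if (anyDuplicated(electrodes$electrode_id)) {
    abort("electrode_id must be unique within a recording.")
  }
  if (!all(is.finite(electrodes$x)) || !all(is.finite(electrodes$y))) {
    abort("Electrode coordinates must be finite.")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0) {
    abort("`sampling_rate` must be a single positive number.")
  }
  structure(
    list(
      signals = signals,
      electrodes = electrodes,
      sampling_rate = as.numeric(sampling_rate),
      gain = as.numeric(gain),
      signal_class = signal_class,
      cell_line = as.character(cell_line),
      compound = as.character(compound),
      note = as.character(note),
      file_path = as.character(file_path),
      rec_duration = (ncol(signals) - 1) / sampling_rate
    ),
    class = "mea_recording"
  )
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf(
    "<mea_recording> %d electrodes x %d samples @ %g Hz (%s)\n",
    nrow(x$signals), ncol(x$signals), x$sampling_rate, x$signal_class
  ))
  cat(sprintf(
    "  duration %.3f s | gain %g | cell_line '%s' | compound '%s'\n",
    x$rec_duration, x$gain, x$cell_line, x$compound
  ))
  invisible(x)
}

#' Number of electrodes in a recording
#' @param rec a `mea_recording`.
#' @return integer count.
#' @export
n_electrodes <- function(rec) nrow(rec$signals)

#' Sample times of a recording in milliseconds
#' @param rec a `mea_recording`.
#' @return numeric vector of sample times (ms), starting at 0.
#' @export
sample_times_ms <- function(rec) {
  (seq_len(ncol(rec$signals)) - 1) / rec$sampling_rate * 1000
}

#' Tidy a recording into a long tibble
#'
#' @param x a `mea_recording`.
#' @param ... unused.
#' @return A tibble with one row per electrode and sample:
#'   `electrode_id`, `x`, `y`, `time_ms`, `voltage`.
#' @export
as_tibble.mea_recording <- function(x, ...) {
  t_ms <- sample_times_ms(x)
  purrr::map_dfr(seq_len(nrow(x$signals)), function(i) {
    tibble(
      electrode_id = x$electrodes$electrode_id[i],
      x = x$electrodes$x[i],
      y = x$electrodes$y[i],
      time_ms = t_ms,
      voltage = x$signals[i, ]
    )
  })
}
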