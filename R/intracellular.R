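#' Admit a candidate intracellular-like waveform
#'
#' A waveform qualifies as intracellular-like when its peak amplitude
#' (peak minus baseline) is strictly larger than `amp_min` and its full
#' width at half amplitude is strictly larger than `width_min`. Both
#' thresholds are configurable.
#'
#' @param amplitude peak amplitude above baseline, millivolts.
#' @param width full width at half amplitude, ms.
#' @param amp_min amplitude threshold (default 1 mV).
#' @param width_min width threshold (default 50 ms).
#' @return `TRUE` or `FALSE`.
#' @export
admit_intracellular <- function(amplitude, width, amp_min = 1, width_min = 50) {
  isTRUE(amplitude > amp_min) && isTRUE(width > width_min)
}

#' Average consecutive AP waveform windows
#'
#' Three consecutively measured, peak-aligned windows are averaged pointwise
#' into a single waveform per channel. With fewer than three windows the
#' single best window (largest peak-to-baseline amplitude) is used and the
#' result flagged.
#'
#' @param windows list of equal-length numeric vectors (mV), peak-aligned.
#' @param sampling_rate Hz.
#' @param baseline_frac fraction of the pre-peak segment treated as
#'   pre-upstroke baseline (its median is the baseline estimate).
#' @return A list of class `ap_waveform`: `samples` (mV), `sampling_rate`,
#'   `baseline`, `peak`, `peak_index`, `n_averaged`, `averaged`
#'   (FALSE when fewer than 3 windows were available).
#' @export
average_waveforms <- function(windows, sampling_rate, baseline_frac = 0.5) {
  stopifnot(is.list(windows), length(windows) >= 1)
  len <- unique(lengths(windows))
  if (length(len) != 1) abort("All waveform windows must have equal length.")
  averaged <- length(windows) >= 3
  if (averaged) {
    use <- windows[1:3]
    samples <- purrr::reduce(use, `+`) / 3
  } else {
    peak_rise <- purrr::map_dbl(windows, function(w) max(w) - median(w))
    samples <- windows[[which.max(peak_rise)]]
  }
  peak_index <- which.max(samples)
  pre <- samples[seq_len(max(1, floor((peak_index - 1) * baseline_frac)))]
  structure(
    list(
      samples = samples, sampling_rate = sampling_rate,
      baseline = median(pre), peak = samples[peak_index],
      peak_index = peak_index,
      n_averaged = if (averaged) 3L else 1L, averaged = averaged
    ),
    class = "ap_waveform"
  )
}

#' Action-potential features of an averaged waveform
#'
#' The upstroke onset is the last pre-peak upward crossing of
#' `baseline + onset_frac * (peak - baseline)` (default 10% of amplitude), a
#' convention robust to the gradual pre-upstroke voltage rise seen on
#' planar-electrode recordings. Features:
#'
#' * `AP_amplitude` — maximum minus minimum over the window (mV);
#' * `depolarization_time` — onset to the voltage peak (ms);
#' * `APD_50`, `APD_90` — onset to 50% / 90% repolarization, i.e. to the
#'   first post-peak downward crossing of the level at which 50% / 90% of
#'   the amplitude has been lost; level crossings are located with linear
#'   interpolation for sub-sample precision.
#'
#' An APD is `NA` (with `truncated = TRUE`) when the waveform never
#' repolarizes to the level within the window.
#'
#' @param wf an `ap_waveform` from [average_waveforms()].
#' @param onset_frac amplitude fraction defining the upstroke onset.
#' @return A one-row tibble: `AP_amplitude`, `depolarization_time`,
#'   `APD_50`, `APD_90`, `truncated`.
#' @export
ap_features <- function(wf, onset_frac = 0.1) {
  stopifnot(inherits(wf, "ap_waveform"))
  v <- wf$samples
  dt <- 1000 / wf$sampling_rate
  amp <- wf$peak - wf$baseline
  if (amp <= 0) abort("Waveform peak does not exceed baseline.")
  pk <- wf$peak_index

  cross_up_before_peak <- function(level) {
    pre <- which(v[seq_len(pk - 1)] < level & v[2:pk] >= level)
    if (length(pre) == 0) return(NA_real_)
    i <- max(pre) # last pre-peak upward crossing
    frac <- (level - v[i]) / (v[i + 1] - v[i])
    (i - 1 + frac) * dt
  }
  cross_down_after_peak <- function(level) {
    post <- which(v[pk:(length(v) - 1)] > level & v[(pk + 1):length(v)] <= level)
    if (length(post) == 0) return(NA_real_)
    i <- pk + min(post) - 1 # first post-peak downward crossing
    frac <- (v[i] - level) / (v[i] - v[i + 1])
    (i - 1 + frac) * dt
  }

  t_onset <- cross_up_before_peak(wf$baseline + onset_frac * amp)
  if (is.na(t_onset)) abort("No upstroke onset found before the peak.")
  t_peak <- (pk - 1) * dt
  t50 <- cross_down_after_peak(wf$baseline + 0.5 * amp)
  t90 <- cross_down_after_peak(wf$baseline + 0.1 * amp)
  tibble(
    AP_amplitude = max(v) - min(v),
    depolarization_time = t_peak - t_onset,
    APD_50 = t50 - t_onset,
    APD_90 = t90 - t_onset,
    truncated = is.na(t50) || is.na(t90)
  )
}

#' Full width at half amplitude of a waveform
#'
#' Width between the last pre-peak upward and first post-peak downward
#' crossing of the half-amplitude level, with linear interpolation.
#'
#' @param samples numeric waveform (mV).
#' @param sampling_rate Hz.
#' @param baseline baseline level (mV); default the median of the samples.
#' @return Width in ms (`NA` when the waveform never recrosses the level).
#' @export
half_amplitude_width <- function(samples, sampling_rate, baseline = NULL) {
  baseline <- baseline %||% median(samples)
  pk <- which.max(samples)
  level <- baseline + 0.5 * (samples[pk] - baseline)
  dt <- 1000 / sampling_rate
  v <- samples
  pre <- which(v[seq_len(max(pk - 1, 1))] < level & v[2:pk] >= level)
  post <- which(v[pk:(length(v) - 1)] > level & v[(pk + 1):length(v)] <= level)
  if (length(pre) == 0 || length(post) == 0) return(NA_real_)
  i1 <- max(pre)
  t1 <- (i1 - 1 + (level - v[i1]) / (v[i1 + 1] - v[i1])) * dt
  i2 <- pk + min(post) - 1
  t2 <- (i2 - 1 + (v[i2] - level) / (v[i2] - v[i2 + 1])) * dt
  t2 - t1
}

#' Extract intracellular-like AP features from a recording
#'
#' Per electrode: detects AP peaks (robust threshold on baseline-subtracted
#' signal, refractory spacing), cuts peak-aligned windows, averages three
#' consecutive waveforms, applies the intracellular-like admission rule
#' (amplitude > `amp_min` mV and half-amplitude width > `width_min` ms), and
#' computes AP features on admitted waveforms. Per-electrode features are
#' averaged into one row per recording.
#'
#' @param rec an intracellular [mea_recording()] (signals in mV).
#' @param amp_min,width_min admission thresholds, see
#'   [admit_intracellular()].
#' @param onset_frac see [ap_features()].
#' @param window_ms half-window cut around each peak
#'   `(pre_ms, post_ms)`.
#' @param refractory_ms minimum peak spacing.
#' @return A list with `features` (one-row tibble: `AP_amplitude`,
#'   `depolarization_time`, `APD_50`, `APD_90`, `n_electrodes_admitted`,
#'   recording-information columns) and `per_electrode`.
#' @export
extract_intracellular_features <- function(rec, amp_min = 1, width_min = 50,
                                           onset_frac = 0.1,
                                           window_ms = c(100, 600),
                                           refractory_ms = 300) {
  stopifnot(inherits(rec, "mea_recording"))
  if (rec$signal_class != "intracellular") {
    abort("extract_intracellular_features() needs an intracellular recording.")
  }
  dt <- 1000 / rec$sampling_rate
  pre_n <- round(window_ms[1] / dt)
  post_n <- round(window_ms[2] / dt)

  per_electrode <- purrr::map_dfr(seq_len(nrow(rec$signals)), function(i) {
    v <- rec$signals[i, ]
    peaks <- detect_ap_peaks(v, rec$sampling_rate, refractory_ms)
    peaks <- peaks[peaks - pre_n >= 1 & peaks + post_n <= length(v)]
    base_row <- tibble(
      electrode_id = rec$electrodes$electrode_id[i],
      admitted = FALSE, n_waveforms = length(peaks),
      AP_amplitude = NA_real_, depolarization_time = NA_real_,
      APD_50 = NA_real_, APD_90 = NA_real_, truncated = NA
    )
    if (length(peaks) == 0) return(base_row)
    windows <- purrr::map(peaks, ~ v[(.x - pre_n):(.x + post_n)])
    wf <- average_waveforms(windows, rec$sampling_rate)
    width <- half_amplitude_width(wf$samples, wf$sampling_rate, wf$baseline)
    ok <- admit_intracellular(wf$peak - wf$baseline, width,
                              amp_min = amp_min, width_min = width_min)
    if (!ok) return(base_row)
    feats <- ap_features(wf, onset_frac = onset_frac)
    base_row %>%
      mutate(
        admitted = TRUE,
        AP_amplitude = feats$AP_amplitude,
        depolarization_time = feats$depolarization_time,
        APD_50 = feats$APD_50, APD_90 = feats$APD_90,
        truncated = feats$truncated
      )
  })

  adm <- per_electrode %>% filter(.data$admitted)
  agg <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  features <- tibble(
    AP_amplitude = agg(adm$AP_amplitude),
    depolarization_time = agg(adm$depolarization_time),
    APD_50 = agg(adm$APD_50),
    APD_90 = agg(adm$APD_90),
    n_electrodes_admitted = nrow(adm),
    rec_duration = rec$rec_duration,
    gain = rec$gain, cell_line = rec$cell_line, compound = rec$compound,
    note = rec$note, file_path = rec$file_path
  )
  list(features = features, per_electrode = per_electrode)
}

# Peak detection for AP-shaped signals: suprathreshold regions of the
# baseline-subtracted trace, one peak per region, refractory-merged.
detect_ap_peaks <- function(v, sampling_rate, refractory_ms = 300) {
  base <- median(v)
  dev <- v - base
  noise <- mad(v, constant = 1.4826)
  thr <- if (noise > 0) 5 * noise else 0.3 * max(dev)
  if (thr <= 0) return(integer())
  hot <- which(dev > thr)
  if (length(hot) == 0) return(integer())
  gap_n <- max(1L, round(refractory_ms * sampling_rate / 1000))
  brk <- c(0L, which(diff(hot) > gap_n), length(hot))
  purrr::map_int(seq_len(length(brk) - 1), function(g) {
    ev <- hot[(brk[g] + 1):brk[g + 1]]
    ev[which.max(dev[ev])]
  })
}
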