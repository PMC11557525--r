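#' Detect R-wave spikes on one electrode trace
#'
#' Events are samples whose absolute deviation from baseline (median of the
#' trace) exceeds `threshold_sd` times a robust noise estimate
#' (`mad / 0.6745`). Suprathreshold samples closer than `refractory_ms` are
#' merged into one event; within each event the R positive peak is the
#' maximum sample and the trough is the minimum within `trough_window_ms`
#' after the peak. When the robust noise estimate is zero (noiseless or
#' mostly-flat traces) the threshold falls back to 30% of the maximum
#' absolute deflection; an entirely flat trace yields an empty spike train.
#'
#' @param voltage numeric trace in microvolts.
#' @param sampling_rate Hz.
#' @param threshold_sd detection threshold as a multiple of the noise SD.
#' @param refractory_ms minimum spacing between distinct R spikes.
#' @param trough_window_ms window after the positive peak searched for the
#'   negative trough (kept well short of the T-wave latency).
#' @param clip_run_min minimum run of consecutive samples at the trace
#'   extremes for a spike to be flagged as clipped.
#' @return A tibble with one row per spike: `t_r` (ms, positive-peak time),
#'   `r_pos_amp`, `r_neg_amp` (microvolts, baseline-relative), `t_trough`
#'   (ms), `r_amplitude` (= `r_pos_amp - r_neg_amp`), `r_width`
#'   (= `t_trough - t_r`, ms) and `clipped`.
#' @export
detect_r_spikes <- function(voltage, sampling_rate, threshold_sd = 6,
                            refractory_ms = 200, trough_window_ms = 50,
                            clip_run_min = 5) {
  empty <- tibble(
    t_r = numeric(), r_pos_amp = numeric(), r_neg_amp = numeric(),
    t_trough = numeric(), r_amplitude = numeric(), r_width = numeric(),
    clipped = logical()
  )
  if (length(voltage) == 0) return(empty)
  base <- median(voltage)
  dev <- voltage - base
  noise_sd <- mad(voltage, constant = 1.4826)
  thr <- if (noise_sd > 0) threshold_sd * noise_sd else 0.3 * max(abs(dev))
  if (thr <= 0) return(empty) # flat trace
  hot <- which(abs(dev) > thr)
  if (length(hot) == 0) return(empty)

  dt <- 1000 / sampling_rate
  refr_n <- max(1L, round(refractory_ms / dt))
  trough_n <- max(1L, round(trough_window_ms / dt))
  # split suprathreshold samples into events separated by the refractory gap
  brk <- c(0L, which(diff(hot) > refr_n), length(hot))
  lo_rail <- min(voltage)
  hi_rail <- max(voltage)

  longest_run <- function(v) {
    r <- rle(v)
    if (any(r$values)) max(r$lengths[r$values]) else 0L
  }
  n_ev <- length(brk) - 1
  t_r <- r_pos <- r_neg <- t_tr <- numeric(n_ev)
  clip <- logical(n_ev)
  for (g in seq_len(n_ev)) {
    ev <- hot[(brk[g] + 1):brk[g + 1]]
    i_pos <- ev[which.max(dev[ev])]
    w_end <- min(length(voltage), i_pos + trough_n)
    w <- i_pos:w_end
    i_neg <- w[which.min(dev[w])]
    has_trough <- dev[i_neg] < 0 && i_neg > i_pos
    seg <- voltage[ev[1]:w_end]
    clip[g] <- longest_run(seg == hi_rail) >= clip_run_min ||
      longest_run(seg == lo_rail) >= clip_run_min
    t_r[g] <- (i_pos - 1) * dt
    r_pos[g] <- dev[i_pos]
    r_neg[g] <- if (has_trough) dev[i_neg] else NA_real_
    t_tr[g] <- if (has_trough) (i_neg - 1) * dt else NA_real_
  }
  tibble(
    t_r = t_r, r_pos_amp = r_pos, r_neg_amp = r_neg, t_trough = t_tr,
    r_amplitude = r_pos - r_neg, r_width = t_tr - t_r, clipped = clip
  )
}

#' Detect the field-potential duration after one R spike
#'
#' Searches `[t_r + blank_ms, t_r + max_ms]` for the T-wave peak, defined as
#' the sample of largest absolute baseline deviation after light smoothing
#' (moving average of `smooth_ms`); the T wave may be positive or negative.
#' The result is absent (`NA`) when no candidate strictly exceeds
#' `t_amp_min` (defaulting to three times the robust noise SD).
#'
#' @param voltage numeric trace in microvolts.
#' @param sampling_rate Hz.
#' @param t_r R positive-peak time in ms.
#' @param blank_ms blanking interval after the R peak, excluding the spike
#'   recovery from the T search.
#' @param max_ms end of the search window after the R peak; windows running
#'   past the trace end are truncated.
#' @param t_amp_min minimum absolute T amplitude (microvolts); `NULL` uses
#'   `3 * mad(voltage)/0.6745`.
#' @param smooth_ms moving-average width for T detection.
#' @param baseline precomputed baseline (trace median); `NULL` computes it.
#' @return A one-row tibble with `t_t` (ms) and `fpd` (ms), or `NA`s when no
#'   T wave is found.
#' @export
detect_fpd <- function(voltage, sampling_rate, t_r, blank_ms = 80,
                       max_ms = 700, t_amp_min = NULL, smooth_ms = 5,
                       baseline = NULL) {
  base <- baseline %||% median(voltage)
  if (is.null(t_amp_min)) t_amp_min <- 3 * mad(voltage, constant = 1.4826)
  res <- fpd_core(voltage, sampling_rate, t_r, blank_ms, max_ms,
                  t_amp_min, smooth_ms, base)
  tibble(t_t = res[1], fpd = res[2])
}

# numeric core of detect_fpd: returns c(t_t, fpd) (NA, NA when absent)
fpd_core <- function(voltage, sampling_rate, t_r, blank_ms, max_ms,
                     t_amp_min, smooth_ms, base) {
  dt <- 1000 / sampling_rate
  i0 <- floor((t_r + blank_ms) / dt) + 1
  i1 <- min(length(voltage), floor((t_r + max_ms) / dt) + 1)
  if (i0 >= i1) return(c(NA_real_, NA_real_))
  seg <- voltage[i0:i1] - base
  k <- max(1L, round(smooth_ms / dt))
  if (k > 1) {
    seg <- as.numeric(stats::filter(seg, rep(1 / k, k), sides = 2))
  }
  a <- abs(seg)
  a[is.na(a)] <- -Inf
  i_pk <- which.max(a)
  if (!is.finite(a[i_pk]) || a[i_pk] <= t_amp_min) {
    return(c(NA_real_, NA_real_))
  }
  t_t <- (i0 + i_pk - 2) * dt
  c(t_t, t_t - t_r)
}

#' Group per-electrode R times into array-wide beats
#'
#' All R times are pooled and sorted; a gap larger than `sync_window` starts
#' a new cluster. Clusters joined by at least `min_fraction` of the active
#' electrodes (electrodes with any spike) are kept as beats; the consensus
#' beat time is the median member time. `n_electrodes_sync` counts
#' electrodes participating in at least `participation_fraction` of the kept
#' beats, and `active_area_in_percent = 100 * n_electrodes_sync /
#' n_electrodes_total`.
#'
#' @param spike_times tibble with columns `electrode_id` and `t_r` (ms),
#'   one row per detected spike (e.g. row-bound [detect_r_spikes()] output).
#' @param n_electrodes_total electrodes in the recording (for the active-area
#'   percentage).
#' @param sync_window ms; spikes within a gap of this size join one beat.
#' @param min_fraction minimum fraction of active electrodes for a cluster
#'   to count as a beat.
#' @param participation_fraction fraction of kept beats an electrode must
#'   join to count as synchronous.
#' @return A list with `beat_times` (ms), `assignment` (tibble
#'   `electrode_id`, `beat`, `t_r`), `n_beats`, `n_electrodes_sync`,
#'   `active_area_in_percent`.
#' @export
group_beats <- function(spike_times, n_electrodes_total,
                        sync_window = 50, min_fraction = 0.5,
                        participation_fraction = 0.9) {
  empty <- list(
    beat_times = numeric(),
    assignment = tibble(electrode_id = integer(), beat = integer(), t_r = numeric()),
    n_beats = 0L, n_electrodes_sync = 0L, active_area_in_percent = 0
  )
  if (nrow(spike_times) == 0) return(empty)
  st <- arrange(spike_times, .data$t_r)
  cluster <- cumsum(c(1, diff(st$t_r) > sync_window))
  st$cluster <- cluster
  n_active <- dplyr::n_distinct(st$electrode_id)

  summ <- st %>%
    group_by(.data$cluster) %>%
    summarise(
      time = median(.data$t_r),
      members = dplyr::n_distinct(.data$electrode_id),
      .groups = "drop"
    ) %>%
    filter(.data$members >= min_fraction * n_active) %>%
    arrange(.data$time)
  if (nrow(summ) == 0) return(empty)
  summ$beat <- seq_len(nrow(summ))

  assignment <- st %>%
    dplyr::inner_join(summ %>% select("cluster", "beat"), by = "cluster") %>%
    group_by(.data$electrode_id, .data$beat) %>%
    slice(which.min(abs(.data$t_r - summ$time[.data$beat[1]]))) %>%
    ungroup() %>%
    select("electrode_id", "beat", "t_r")

  n_beats <- nrow(summ)
  participation <- assignment %>%
    group_by(.data$electrode_id) %>%
    summarise(k = dplyr::n_distinct(.data$beat), .groups = "drop")
  n_sync <- sum(participation$k >= participation_fraction * n_beats)
  list(
    beat_times = summ$time,
    assignment = assignment,
    n_beats = as.integer(n_beats),
    n_electrodes_sync = as.integer(n_sync),
    active_area_in_percent = 100 * n_sync / n_electrodes_total
  )
}

#' Extract the full extracellular feature row of a recording
#'
#' Runs spike detection on every electrode, groups spikes into array-wide
#' beats, measures R amplitude/width and FPD per spike, fits the
#' cone-shaped latency surface per beat for conduction speed, and computes
#' time-domain HRV from the beat-to-beat intervals. Per-spike measures are
#' averaged within electrode and then across electrodes.
#'
#' @param rec an extracellular [mea_recording()].
#' @param cfg configuration list; see [extraction_config()].
#' @return A list with `features` (one-row tibble matching the feature-store
#'   schema), `per_electrode` (per-electrode feature tibble) and `beats`
#'   (the [group_beats()] result).
#' @export
extract_extracellular_features <- function(rec, cfg = extraction_config()) {
  stopifnot(inherits(rec, "mea_recording"))
  if (rec$signal_class != "extracellular") {
    abort("extract_extracellular_features() needs an extracellular recording.")
  }
  t0 <- Sys.time()
  per_el <- purrr::map_dfr(seq_len(nrow(rec$signals)), function(i) {
    sp <- detect_r_spikes(
      rec$signals[i, ], rec$sampling_rate,
      threshold_sd = cfg$threshold_sd, refractory_ms = cfg$refractory_ms,
      trough_window_ms = cfg$trough_window_ms, clip_run_min = cfg$clip_run_min
    )
    sp$electrode_id <- rec$electrodes$electrode_id[i]
    sp
  })

  beats <- group_beats(
    per_el %>% select("electrode_id", "t_r"),
    n_electrodes_total = nrow(rec$signals),
    sync_window = cfg$sync_window, min_fraction = cfg$min_fraction,
    participation_fraction = cfg$participation_fraction
  )

  # FPD per assigned spike; search window capped by the beat interval
  med_rr <- if (length(beats$beat_times) >= 2) {
    median(diff(beats$beat_times))
  } else {
    Inf
  }
  fpd_max <- min(cfg$fpd_max_ms, 0.9 * med_rr)
  # per-electrode baseline / noise floor computed once, not per spike
  el_base <- apply(rec$signals, 1, median)
  el_tmin <- if (is.null(cfg$t_amp_min)) {
    3 * apply(rec$signals, 1, mad, constant = 1.4826)
  } else {
    rep(cfg$t_amp_min, nrow(rec$signals))
  }
  names(el_base) <- names(el_tmin) <- as.character(rec$electrodes$electrode_id)
  fpd_tbl <- if (nrow(beats$assignment) > 0) {
    asg <- beats$assignment
    row_of <- match(asg$electrode_id, rec$electrodes$electrode_id)
    vals <- vapply(seq_len(nrow(asg)), function(i) {
      key <- as.character(asg$electrode_id[i])
      fpd_core(
        rec$signals[row_of[i], ], rec$sampling_rate, asg$t_r[i],
        cfg$fpd_blank_ms, fpd_max, el_tmin[[key]], cfg$fpd_smooth_ms,
        el_base[[key]]
      )
    }, numeric(2))
    tibble(
      t_t = vals[1, ], fpd = vals[2, ],
      electrode_id = asg$electrode_id, beat = asg$beat
    )
  } else {
    tibble(t_t = numeric(), fpd = numeric(), electrode_id = integer(), beat = integer())
  }

  per_electrode <- per_el %>%
    group_by(.data$electrode_id) %>%
    summarise(
      n_spikes = dplyr::n(),
      r_amplitude = mean(.data$r_amplitude, na.rm = TRUE),
      r_width = mean(.data$r_width, na.rm = TRUE),
      prop_clipped = mean(.data$clipped),
      .groups = "drop"
    ) %>%
    left_join(
      fpd_tbl %>%
        group_by(.data$electrode_id) %>%
        summarise(fpd = mean(.data$fpd, na.rm = TRUE), .groups = "drop"),
      by = "electrode_id"
    ) %>%
    left_join(rec$electrodes, by = "electrode_id")

  cond <- conduction_speed_from_beats(rec, beats, cfg)

  hrv <- if (beats$n_beats >= 4) {
    compute_hrv(diff(beats$beat_times), median_nni_mode = cfg$median_nni_mode)
  } else {
    hrv_na_row()
  }

  agg <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  features <- tibble(
    R_amplitude = agg(per_electrode$r_amplitude),
    R_width = agg(per_electrode$r_width),
    FPD = agg(per_electrode$fpd),
    conduction_speed = cond$mean_speed,
    rec_duration = rec$rec_duration,
    rec_proc_duration = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    n_beats = beats$n_beats,
    n_electrodes_sync = beats$n_electrodes_sync,
    active_area_in_percent = beats$active_area_in_percent
  ) %>%
    dplyr::bind_cols(hrv) %>%
    mutate(
      gain = rec$gain, cell_line = rec$cell_line, compound = rec$compound,
      note = rec$note, file_path = rec$file_path
    )
  list(
    features = features,
    per_electrode = per_electrode,
    beats = beats,
    cone_fits = cond$fits
  )
}

#' Default configuration for extracellular feature extraction
#'
#' @param threshold_sd spike threshold in robust-noise SD units.
#' @param refractory_ms spike refractory spacing (ms).
#' @param trough_window_ms trough search window after the R peak (ms).
#' @param clip_run_min consecutive rail samples flagging clipping.
#' @param sync_window,min_fraction,participation_fraction beat-grouping
#'   parameters, see [group_beats()].
#' @param fpd_blank_ms,fpd_max_ms,fpd_smooth_ms,t_amp_min T-wave search
#'   parameters, see [detect_fpd()].
#' @param median_nni_mode see [compute_hrv()].
#' @param surface cone-model variant, see [fit_cone()].
#' @param apex_exclude_um apex exclusion radius for local velocities;
#'   `NULL` uses one electrode pitch (the minimum inter-electrode distance).
#' @return A named list of settings.
#' @export
extraction_config <- function(threshold_sd = 6, refractory_ms = 200,
                              trough_window_ms = 50, clip_run_min = 5,
                              sync_window = 50, min_fraction = 0.5,
                              participation_fraction = 0.9,
                              fpd_blank_ms = 80, fpd_max_ms = 700,
                              fpd_smooth_ms = 5, t_amp_min = NULL,
                              median_nni_mode = "table1",
                              surface = "cone", apex_exclude_um = NULL) {
  list(
    threshold_sd = threshold_sd, refractory_ms = refractory_ms,
    trough_window_ms = trough_window_ms, clip_run_min = clip_run_min,
    sync_window = sync_window, min_fraction = min_fraction,
    participation_fraction = participation_fraction,
    fpd_blank_ms = fpd_blank_ms, fpd_max_ms = fpd_max_ms,
    fpd_smooth_ms = fpd_smooth_ms, t_amp_min = t_amp_min,
    median_nni_mode = median_nni_mode,
    surface = surface, apex_exclude_um = apex_exclude_um
  )
}

# Per-beat cone fits + mean conduction speed for a grouped recording.
conduction_speed_from_beats <- function(rec, beats, cfg) {
  if (beats$n_beats == 0) return(list(mean_speed = NA_real_, fits = list()))
  pitch <- min_electrode_pitch(rec$electrodes)
  apex <- cfg$apex_exclude_um %||% pitch
  fits <- list()
  beat_means <- numeric(0)
  for (b in seq_len(beats$n_beats)) {
    lat <- beats$assignment %>%
      filter(.data$beat == b) %>%
      left_join(rec$electrodes, by = "electrode_id") %>%
      mutate(latency = .data$t_r - min(.data$t_r)) %>%
      select("electrode_id", "x", "y", "latency")
    if (nrow(lat) < 4) next
    fit <- tryCatch(
      fit_cone(lat, surface = cfg$surface),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    fits[[length(fits) + 1]] <- fit
    sp <- local_velocities(fit, lat, apex_exclude_um = apex)
    if (nrow(sp) > 0) beat_means <- c(beat_means, mean(sp$speed))
  }
  list(
    mean_speed = if (length(beat_means) > 0) mean(beat_means) else NA_real_,
    fits = fits
  )
}

min_electrode_pitch <- function(electrodes) {
  xy <- cbind(electrodes$x, electrodes$y)
  if (nrow(xy) < 2) return(1)
  d <- as.matrix(stats::dist(xy))
  min(d[upper.tri(d)])
}
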