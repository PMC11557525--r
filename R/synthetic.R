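#' Specification for a synthetic extracellular field-potential recording
#'
#' Describes an idealized cardiomyocyte monolayer on a rectangular electrode
#' grid: each beat starts at the wave origin and propagates radially at a
#' constant speed, so the R spike on an electrode at distance `d` from the
#' origin occurs `d / speed` ms after the beat onset. Waveform templates are
#' idealized (triangular biphasic R spike, Gaussian T bump) so that every
#' feature has an analytic ground truth.
#'
#' @param grid_nx,grid_ny electrode counts along x and y.
#' @param pitch electrode pitch in micrometers.
#' @param origin length-2 numeric, wave origin (x', y') in micrometers.
#' @param speed conduction speed in micrometers per millisecond.
#' @param beat_period beat-to-beat interval in ms.
#' @param n_beats number of beats.
#' @param r_amp peak-to-trough R-spike amplitude in microvolts (positive peak
#'   at `+r_amp/2`, trough at `-r_amp/2`).
#' @param r_width ms between the R positive peak and the following trough.
#' @param t_amp T-wave bump amplitude in microvolts (0 disables the T wave).
#' @param t_sd Gaussian T-wave width parameter in ms.
#' @param fpd field-potential duration: ms from R positive peak to T peak.
#' @param noise_sd additive Gaussian noise SD in microvolts.
#' @param latency_jitter_sd per-electrode, per-beat latency jitter SD in ms.
#' @param sampling_rate sampling rate in Hz.
#' @param seed integer RNG seed; generation is deterministic per seed.
#' @return A list of class `fp_spec`.
#' @export
fp_spec <- function(grid_nx = 8, grid_ny = 8, pitch = 17.5,
                    origin = c(30, 50), speed = 400,
                    beat_period = 1000, n_beats = 10,
                    r_amp = 1000, r_width = 2,
                    t_amp = 60, t_sd = 20, fpd = 300,
                    noise_sd = 0, latency_jitter_sd = 0,
                    sampling_rate = 10000, seed = 1L) {
  spec <- list(
    grid_nx = grid_nx, grid_ny = grid_ny, pitch = pitch,
    origin = as.numeric(origin), speed = speed,
    beat_period = beat_period, n_beats = n_beats,
    r_amp = r_amp, r_width = r_width,
    t_amp = t_amp, t_sd = t_sd, fpd = fpd,
    noise_sd = noise_sd, latency_jitter_sd = latency_jitter_sd,
    sampling_rate = sampling_rate, seed = as.integer(seed)
  )
  if (spec$speed <= 0) abort("speed must be positive.")
  if (spec$fpd <= spec$r_width) abort("fpd must exceed r_width.")
  # the full waveform (R spike + T bump tail) must fit inside one beat
  if (spec$fpd + 3 * spec$t_sd > spec$beat_period) {
    abort("Waveforms overlap: fpd + 3*t_sd must not exceed beat_period.")
  }
  structure(spec, class = "fp_spec")
}

#' Specification for a synthetic intracellular-like action-potential recording
#'
#' The AP template is piecewise linear: flat baseline, a linear upstroke of
#' duration `depol_time` rising by `amplitude`, then a linear repolarization
#' of duration `repol_len` back to baseline. Under the 10%-of-amplitude
#' upstroke-onset convention the analytic feature values are
#' `APD50 = 0.9 * depol_time + 0.5 * repol_len` and
#' `APD90 = 0.9 * depol_time + 0.9 * repol_len`.
#'
#' @param baseline resting level in millivolts.
#' @param amplitude peak height above baseline in millivolts (> 0).
#' @param depol_time upstroke duration in ms.
#' @param repol_len repolarization duration in ms.
#' @param n_waveforms number of AP waveforms in the recording.
#' @param period waveform-to-waveform interval in ms.
#' @param noise_sd additive Gaussian noise SD in millivolts.
#' @param sampling_rate sampling rate in Hz.
#' @param seed integer RNG seed.
#' @return A list of class `ap_spec` with analytic ground-truth entries
#'   `apd50`, `apd90`, `ap_amplitude`, `depolarization_time`.
#' @export
ap_spec <- function(baseline = -70, amplitude = 2, depol_time = 10,
                    repol_len = 300, n_waveforms = 3, period = 1000,
                    noise_sd = 0, sampling_rate = 10000, seed = 1L) {
  if (amplitude <= 0) abort("amplitude must be positive.")
  if (depol_time <= 0 || repol_len <= 0) {
    abort("depol_time and repol_len must be positive.")
  }
  if (period < depol_time + repol_len) {
    abort("period must be at least depol_time + repol_len.")
  }
  structure(
    list(
      baseline = baseline, amplitude = amplitude, depol_time = depol_time,
      repol_len = repol_len, n_waveforms = n_waveforms, period = period,
      noise_sd = noise_sd, sampling_rate = sampling_rate,
      seed = as.integer(seed),
      apd50 = 0.9 * depol_time + 0.5 * repol_len,
      apd90 = 0.9 * depol_time + 0.9 * repol_len,
      ap_amplitude = amplitude,
      depolarization_time = 0.9 * depol_time
    ),
    class = "ap_spec"
  )
}

# Triangular biphasic R spike evaluated at times t (ms) relative to the
# positive peak: rises over r_width/2, falls through zero to -r_amp/2 at
# t = r_width, recovers over r_width/2. Slopes are equal on both flanks.
r_template <- function(t, r_amp, r_width) {
  s <- r_amp / r_width # slope, uV/ms
  v <- numeric(length(t))
  up <- t >= -r_width / 2 & t < 0
  dn <- t >= 0 & t < r_width
  rc <- t >= r_width & t <= 1.5 * r_width
  v[up] <- (t[up] + r_width / 2) * s
  v[dn] <- r_amp / 2 - t[dn] * s
  v[rc] <- -r_amp / 2 + (t[rc] - r_width) * s
  v
}

#' Generate a synthetic extracellular recording with ground truth
#'
#' Each electrode receives, per beat, a triangular biphasic R spike whose
#' positive peak occurs at `beat_onset + dist(electrode, origin) / speed`
#' (plus jitter), a trough `r_width` later, and a Gaussian T bump peaking
#' `fpd` after the R peak, with optional additive Gaussian noise.
#'
#' @param spec an [fp_spec()].
#' @return A list with elements:
#'   * `recording`: a [mea_recording()] (microvolts);
#'   * `truth`: a list holding the per-spike ground-truth tibble (`spikes`,
#'     with nominal and sample-grid-realized R peak/trough times and
#'     amplitudes from the noiseless signal), nominal `rr_intervals` (ms),
#'     `speed`, `fpd`, `r_amp`, `r_width`, `origin` and `n_beats`.
#' @export
gen_fp_recording <- function(spec) {
  stopifnot(inherits(spec, "fp_spec"))
  withr::with_seed(spec$seed, {
    grid <- tidyr::expand_grid(
      col = seq_len(spec$grid_nx) - 1,
      row = seq_len(spec$grid_ny) - 1
    ) %>%
      mutate(
        electrode_id = dplyr::row_number(),
        x = .data$col * spec$pitch,
        y = .data$row * spec$pitch,
        dist = sqrt((.data$x - spec$origin[1])^2 + (.data$y - spec$origin[2])^2)
      )
    dt <- 1000 / spec$sampling_rate # ms per sample
    dur_ms <- spec$n_beats * spec$beat_period
    t_ms <- seq(0, dur_ms - dt, by = dt)
    beat_onsets <- (seq_len(spec$n_beats) - 1) * spec$beat_period
    # lead-in so the first R spike and its rising flank are fully sampled
    lead_in <- spec$r_width

    spikes <- list()
    signals <- matrix(0, nrow(grid), length(t_ms))
    for (i in seq_len(nrow(grid))) {
      lat <- grid$dist[i] / spec$speed
      jit <- if (spec$latency_jitter_sd > 0) {
        rnorm(spec$n_beats, 0, spec$latency_jitter_sd)
      } else {
        rep(0, spec$n_beats)
      }
      tp <- beat_onsets + lead_in + lat + jit # R positive peak times
      clean <- numeric(length(t_ms))
      for (k in seq_len(spec$n_beats)) {
        rel <- t_ms - tp[k]
        idx <- which(rel >= -spec$r_width / 2 & rel <= 1.5 * spec$r_width)
        clean[idx] <- clean[idx] + r_template(rel[idx], spec$r_amp, spec$r_width)
        if (spec$t_amp != 0) {
          tw <- which(abs(rel - spec$fpd) <= 4 * spec$t_sd)
          clean[tw] <- clean[tw] +
            spec$t_amp * exp(-(rel[tw] - spec$fpd)^2 / (2 * spec$t_sd^2))
        }
      }
      # sample-grid-realized fiducials from the clean signal
      t_r_re <- t_tr_re <- amp_re <- t_t_re <- numeric(spec$n_beats)
      for (k in seq_len(spec$n_beats)) {
        w <- which(t_ms >= tp[k] - spec$r_width / 2 & t_ms <= tp[k] + 1.5 * spec$r_width)
        i_pos <- w[which.max(clean[w])]
        i_neg <- w[which.min(clean[w])]
        tw <- which(abs(t_ms - tp[k] - spec$fpd) <= 4 * spec$t_sd)
        t_r_re[k] <- t_ms[i_pos]
        t_tr_re[k] <- t_ms[i_neg]
        amp_re[k] <- clean[i_pos] - clean[i_neg]
        t_t_re[k] <- if (length(tw) > 0 && spec$t_amp != 0) {
          t_ms[tw[which.max(abs(clean[tw]))]]
        } else {
          NA_real_
        }
      }
      spikes[[i]] <- tibble(
        electrode_id = grid$electrode_id[i], beat = seq_len(spec$n_beats),
        t_r_nominal = tp, t_r = t_r_re, t_trough = t_tr_re,
        r_amp = amp_re, r_width = t_tr_re - t_r_re,
        t_t = t_t_re, fpd = t_t_re - t_r_re
      )
      if (spec$noise_sd > 0) {
        clean <- clean + rnorm(length(clean), 0, spec$noise_sd)
      }
      signals[i, ] <- clean
    }

    rec <- mea_recording(
      signals = signals,
      electrodes = grid %>% select("electrode_id", "x", "y"),
      sampling_rate = spec$sampling_rate,
      gain = 1,
      signal_class = "extracellular",
      cell_line = "synthetic",
      note = "synthetic FP recording"
    )
    list(
      recording = rec,
      truth = list(
        spikes = bind_rows(spikes),
        latencies = grid %>%
          mutate(latency = .data$dist / spec$speed) %>%
          select("electrode_id", "x", "y", "latency"),
        rr_intervals = rep(spec$beat_period, spec$n_beats - 1),
        speed = spec$speed, fpd = spec$fpd, r_amp = spec$r_amp,
        r_width = spec$r_width, origin = spec$origin, n_beats = spec$n_beats
      )
    )
  })
}

# Piecewise-linear AP template at times t (ms) relative to upstroke onset.
ap_template <- function(t, baseline, amplitude, depol_time, repol_len) {
  v <- rep(baseline, length(t))
  up <- t >= 0 & t < depol_time
  dn <- t >= depol_time & t <= depol_time + repol_len
  v[up] <- baseline + amplitude * t[up] / depol_time
  v[dn] <- baseline + amplitude * (1 - (t[dn] - depol_time) / repol_len)
  v
}

#' Generate a synthetic intracellular-like recording with ground truth
#'
#' @param spec an [ap_spec()].
#' @return A list with `recording` (single-electrode [mea_recording()] in
#'   millivolts, `signal_class = "intracellular"`) and `truth` (the analytic
#'   feature values plus per-waveform onset and peak times).
#' @export
gen_ap_recording <- function(spec) {
  stopifnot(inherits(spec, "ap_spec"))
  withr::with_seed(spec$seed, {
    dt <- 1000 / spec$sampling_rate
    lead_in <- 100 # ms of baseline before the first upstroke
    dur_ms <- lead_in + spec$n_waveforms * spec$period
    t_ms <- seq(0, dur_ms - dt, by = dt)
    onsets <- lead_in + (seq_len(spec$n_waveforms) - 1) * spec$period
    v <- rep(spec$baseline, length(t_ms))
    for (on in onsets) {
      idx <- which(t_ms >= on & t_ms <= on + spec$depol_time + spec$repol_len)
      v[idx] <- ap_template(
        t_ms[idx] - on, spec$baseline, spec$amplitude,
        spec$depol_time, spec$repol_len
      )
    }
    if (spec$noise_sd > 0) v <- v + rnorm(length(v), 0, spec$noise_sd)
    rec <- mea_recording(
      signals = matrix(v, nrow = 1),
      electrodes = tibble(electrode_id = 1L, x = 0, y = 0),
      sampling_rate = spec$sampling_rate,
      gain = 1,
      signal_class = "intracellular",
      cell_line = "synthetic",
      note = "synthetic AP recording"
    )
    list(
      recording = rec,
      truth = list(
        onsets = onsets,
        peak_times = onsets + spec$depol_time,
        apd50 = spec$apd50, apd90 = spec$apd90,
        ap_amplitude = spec$ap_amplitude,
        depolarization_time = spec$depolarization_time,
        baseline = spec$baseline
      )
    )
  })
}

#' Generate an RR-interval series
#'
#' I.i.d. normal intervals truncated to be strictly positive (nonpositive
#' draws are resampled, so small-`sd` series are unaffected).
#'
#' @param n number of intervals (>= 2).
#' @param mean,sd normal parameters in ms (`mean > 0`, `sd >= 0`).
#' @param seed integer RNG seed.
#' @return Numeric vector of `n` intervals in ms.
#' @export
gen_rr_series <- function(n, mean = 800, sd = 50, seed = 1L) {
  if (n < 2) abort("n must be at least 2.")
  if (mean <= 0 || sd < 0) abort("mean must be positive and sd nonnegative.")
  withr::with_seed(as.integer(seed), {
    rr <- rnorm(n, mean, sd)
    while (any(rr <= 0)) {
      bad <- rr <= 0
      rr[bad] <- rnorm(sum(bad), mean, sd)
    }
    rr
  })
}

#' Generate a labeled two-class feature table
#'
#' Informative features are Gaussian with class means separated by
#' `effect` standard deviations; noise features are class-independent
#' standard normals.
#'
#' @param n_per_class rows per class.
#' @param n_informative,n_noise feature counts.
#' @param effect class-mean separation in SD units.
#' @param seed integer RNG seed.
#' @return A tibble with columns `inf_1..`, `noise_1..` and a factor column
#'   `class` with levels `"A"` and `"B"`.
#' @export
gen_feature_table <- function(n_per_class = 50, n_informative = 2,
                              n_noise = 3, effect = 2, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    n <- 2 * n_per_class
    cls <- factor(rep(c("A", "B"), each = n_per_class))
    cols <- list()
    for (j in seq_len(n_informative)) {
      mu <- ifelse(cls == "A", -effect / 2, effect / 2)
      cols[[paste0("inf_", j)]] <- rnorm(n, mu, 1)
    }
    for (j in seq_len(n_noise)) {
      cols[[paste0("noise_", j)]] <- rnorm(n, 0, 1)
    }
    out <- as_tibble(cols)
    out$class <- cls
    out
  })
}
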