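# Small, fast synthetic fixtures shared across tests.

# 4x4 grid, 5 beats at 500 ms, 5 kHz: ~40k samples per electrode.
small_fp_spec <- function(...) {
  args <- utils::modifyList(
    list(
      grid_nx = 4, grid_ny = 4, pitch = 17.5, origin = c(20, 30),
      speed = 400, beat_period = 500, n_beats = 5,
      r_amp = 1000, r_width = 2, t_amp = 60, t_sd = 15, fpd = 200,
      noise_sd = 0, latency_jitter_sd = 0, sampling_rate = 5000, seed = 7L
    ),
    list(...)
  )
  do.call(fp_spec, args)
}

# Exact cone latencies for an nx-by-ny grid.
cone_latencies <- function(nx = 8, ny = 8, pitch = 17.5,
                           origin = c(100, 50), speed = 400) {
  grid <- expand.grid(x = (seq_len(nx) - 1) * pitch,
                      y = (seq_len(ny) - 1) * pitch)
  tibble::tibble(
    electrode_id = seq_len(nrow(grid)),
    x = grid$x, y = grid$y,
    latency = sqrt((grid$x - origin[1])^2 + (grid$y - origin[2])^2) / speed
  )
}

# Piecewise-linear AP window sampled at `rate` Hz (times in ms).
ap_window <- function(baseline = 0, amplitude = 2, depol_time = 10,
                      repol_len = 300, pre_ms = 100, post_ms = 600,
                      rate = 10000) {
  dt <- 1000 / rate
  t <- seq(-pre_ms, post_ms, by = dt)
  v <- rep(baseline, length(t))
  up <- t >= 0 & t < depol_time
  dn <- t >= depol_time & t <= depol_time + repol_len
  v[up] <- baseline + amplitude * t[up] / depol_time
  v[dn] <- baseline + amplitude * (1 - (t[dn] - depol_time) / repol_len)
  v
}

# Independent brute-force evaluation of the HRV metric definitions,
# written as literal loops so it shares no code path with compute_hrv().
brute_force_hrv <- function(rr) {
  n <- length(rr)
  d <- numeric(n - 1)
  for (i in seq_len(n - 1)) d[i] <- rr[i + 1] - rr[i]
  hr <- 60000 / rr
  samp_sd <- function(v) {
    m <- sum(v) / length(v)
    sqrt(sum((v - m)^2) / (length(v) - 1))
  }
  nni_50 <- 0; nni_20 <- 0
  for (x in d) {
    if (abs(x) > 50) nni_50 <- nni_50 + 1
    if (abs(x) > 20) nni_20 <- nni_20 + 1
  }
  list(
    mean_nni = sum(rr) / n,
    sdnn = samp_sd(rr),
    sdsd = samp_sd(d),
    rmssd = sqrt(sum(d^2) / (n - 1)),
    median_nni = median(abs(d)),
    nni_50 = nni_50,
    pnni_50 = nni_50 / n,
    nni_20 = nni_20,
    pnni_20 = nni_20 / n,
    range_nni = max(rr) - min(rr),
    cvsd = sqrt(sum(d^2) / (n - 1)) / (sum(rr) / n),
    cvnni = samp_sd(rr) / (sum(rr) / n),
    mean_hr = sum(hr) / n,
    max_hr = max(hr),
    min_hr = min(hr),
    std_hr = samp_sd(hr)
  )
}

# Enumeration oracle for the two-sided exact Mann-Whitney U test,
# mirroring the tail-doubling convention of the standard implementation.
enumerate_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">"))
  u_obs <- u_of(a, b)
  combs <- utils::combn(n, na)
  u_null <- apply(combs, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  mn <- na * length(b)
  p1 <- if (u_obs > mn / 2) mean(u_null >= u_obs) else mean(u_null <= u_obs)
  min(1, 2 * p1)
}

# Write a batch of small synthetic recordings (plus optional corrupt files)
# into a directory; returns a file-list tibble.
write_fp_batch <- function(dir, n_good = 4, n_corrupt = 0, seed0 = 100L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (i in seq_len(n_good)) {
    spec <- fp_spec(
      grid_nx = 3, grid_ny = 3, pitch = 17.5, origin = c(10, 20),
      speed = 400, beat_period = 400, n_beats = 5,
      r_amp = 800 + 50 * i, r_width = 2, t_amp = 50, t_sd = 12, fpd = 150,
      sampling_rate = 5000, seed = seed0 + i
    )
    p <- file.path(dir, sprintf("rec_%02d.h5", i))
    write_recording(gen_fp_recording(spec)$recording, p)
    paths <- c(paths, p)
  }
  for (i in seq_len(n_corrupt)) {
    p <- file.path(dir, sprintf("bad_%02d.h5", i))
    writeLines("this is not an HDF5 file", p)
    paths <- c(paths, p)
  }
  tibble::tibble(
    file_path = sort(paths), cell_line = "lineX", compound = "", note = ""
  )
}
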