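#' Time-domain heart-rate-variability features
#'
#' Computes the 16 time-domain HRV metrics from a series of RR (NN)
#' intervals in milliseconds:
#'
#' * `mean_nni`, `sdnn`, `median_nni`, `range_nni` — location/spread of the
#'   intervals (`sdnn` uses the sample, n-1, denominator);
#' * `sdsd`, `rmssd` — spread of successive differences (`rmssd` is the root
#'   mean square of successive differences);
#' * `nni_50`, `nni_20` — counts of successive differences with absolute
#'   value strictly greater than 50 ms / 20 ms, and `pnni_50`, `pnni_20`
#'   their proportions relative to the total number of RR intervals
#'   (fractions in `[0, 1]`);
#' * `cvsd = rmssd / mean_nni`, `cvnni = sdnn / mean_nni`;
#' * `mean_hr`, `max_hr`, `min_hr`, `std_hr` — statistics of the per-interval
#'   heart rate `60000 / RR_i` in beats/min (`std_hr` sample SD).
#'
#' `median_nni` follows its textual definition here as the median of the
#' absolute successive differences (`median_nni_mode = "table1"`); the
#' conventional median of the RR intervals themselves is available via
#' `median_nni_mode = "median_of_intervals"`.
#'
#' @param rr numeric vector of RR intervals in ms, all positive.
#' @param median_nni_mode `"table1"` (median of |successive differences|) or
#'   `"median_of_intervals"`.
#' @return A one-row tibble with the 16 metrics; all-`NA` when fewer than 3
#'   intervals are supplied.
#' @export
compute_hrv <- function(rr, median_nni_mode = c("table1", "median_of_intervals")) {
  median_nni_mode <- match.arg(median_nni_mode)
  if (length(rr) > 0 && any(rr <= 0)) {
    abort("RR intervals must all be positive.")
  }
  if (length(rr) < 3) return(hrv_na_row())
  d <- diff(rr)
  hr <- 60000 / rr
  tibble(
    mean_nni = mean(rr),
    sdnn = sd(rr),
    sdsd = sd(d),
    rmssd = sqrt(mean(d^2)),
    median_nni = if (median_nni_mode == "table1") median(abs(d)) else median(rr),
    nni_50 = sum(abs(d) > 50),
    pnni_50 = sum(abs(d) > 50) / length(rr),
    nni_20 = sum(abs(d) > 20),
    pnni_20 = sum(abs(d) > 20) / length(rr),
    range_nni = max(rr) - min(rr),
    cvsd = sqrt(mean(d^2)) / mean(rr),
    cvnni = sd(rr) / mean(rr),
    mean_hr = mean(hr),
    max_hr = max(hr),
    min_hr = min(hr),
    std_hr = sd(hr)
  )
}

hrv_na_row <- function() {
  tibble(
    mean_nni = NA_real_, sdnn = NA_real_, sdsd = NA_real_, rmssd = NA_real_,
    median_nni = NA_real_, nni_50 = NA_integer_, pnni_50 = NA_real_,
    nni_20 = NA_integer_, pnni_20 = NA_real_, range_nni = NA_real_,
    cvsd = NA_real_, cvnni = NA_real_, mean_hr = NA_real_, max_hr = NA_real_,
    min_hr = NA_real_, std_hr = NA_real_
  )
}
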