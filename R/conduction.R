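#' Fit beat latencies to a cone-shaped surface
#'
#' Models the activation latency at electrode position `(x, y)` as
#' \deqn{T(x, y) = \sqrt{a (x - x')^2 + b (y - y')^2} + c,}
#' a three-dimensional cone whose apex `(x', y')` is the wave-propagation
#' origin; `a` and `b` are squared slowness coefficients (ms/µm)^2 along the
#' two axes and `c` an offset absorbing the latency reference. For a radial
#' wave at speed `v`, `a = b = 1/v^2`. Fitting is nonlinear least squares
#' (Levenberg–Marquardt, `a, b >= 0` bounded) with multi-start
#' initialization: the apex is started at the earliest-latency electrode and
#' at the centroid, and the best fit by residual is returned. A paraboloid
#' variant (`T = a(x-x')^2 + b(y-y')^2 + c`) is available via `surface`.
#'
#' @param latencies tibble with columns `x`, `y` (micrometers) and `latency`
#'   (ms since wave onset), one row per electrode; at least 4 non-collinear
#'   electrodes.
#' @param surface `"cone"` (default) or `"paraboloid"`.
#' @return An object of class `cone_fit` with elements `a`, `b`, `x0`, `y0`,
#'   `c`, `rms_residual` (ms), `degenerate` (TRUE when `a = b = 0`, i.e. a
#'   flat latency surface), `surface`, `n` and the fitted data.
#' @export
fit_cone <- function(latencies, surface = c("cone", "paraboloid")) {
  surface <- match.arg(surface)
  lat <- as_tibble(latencies)
  stopifnot(all(c("x", "y", "latency") %in% names(lat)))
  lat <- lat[stats::complete.cases(lat[, c("x", "y", "latency")]), ]
  if (nrow(lat) < 4) {
    abort("Cone fitting needs at least 4 electrodes with latencies.")
  }
  if (qr(cbind(1, lat$x, lat$y))$rank < 3) {
    abort("Electrode positions are collinear; the surface is not identifiable.")
  }

  # flat surface: all latencies (numerically) equal
  if (diff(range(lat$latency)) < 1e-12) {
    return(new_cone_fit(0, 0, mean(lat$x), mean(lat$y), lat$latency[1],
                        rms = 0, degenerate = TRUE, surface = surface,
                        data = lat))
  }

  # with 4 points the 5-parameter anisotropic surface is underdetermined;
  # fall back to the isotropic (a = b) form there
  iso <- nrow(lat) < 5
  model_T <- function(p, x, y) {
    b <- if (iso) p["a"] else p["b"]
    q <- p["a"] * (x - p["x0"])^2 + b * (y - p["y0"])^2
    if (surface == "cone") sqrt(pmax(q, 0)) + p["c"] else q + p["c"]
  }
  resid_fun <- function(p, x, y, T) model_T(p, x, y) - T

  span <- diff(range(lat$latency)) /
    max(diff(range(lat$x)), diff(range(lat$y)), 1)
  a0 <- if (surface == "cone") span^2 else span / max(diff(range(lat$x)), 1)
  i_min <- which.min(lat$latency)
  par0 <- function(x0, y0) {
    p <- c(a = a0, b = a0, x0 = x0, y0 = y0, c = min(lat$latency))
    if (iso) p[c("a", "x0", "y0", "c")] else p
  }
  lower <- if (iso) {
    c(a = 0, x0 = -Inf, y0 = -Inf, c = -Inf)
  } else {
    c(a = 0, b = 0, x0 = -Inf, y0 = -Inf, c = -Inf)
  }
  starts <- list(
    par0(lat$x[i_min], lat$y[i_min]),
    par0(mean(lat$x), mean(lat$y))
  )
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = p0, fn = resid_fun,
        x = lat$x, y = lat$y, T = lat$latency,
        lower = lower,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)
      )),
      error = function(e) NULL
    )
    if (!is.null(fit) && fit$info > 0) {
      rss <- sum(fit$fvec^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    abort("Cone fit failed to converge from all starting points.")
  }
  p <- best$fit$par
  b_hat <- if (iso) unname(p["a"]) else unname(p["b"])
  new_cone_fit(
    a = unname(p["a"]), b = b_hat,
    x0 = unname(p["x0"]), y0 = unname(p["y0"]), c = unname(p["c"]),
    rms = sqrt(best$rss / nrow(lat)),
    degenerate = p["a"] <= 0 && b_hat <= 0,
    surface = surface, data = lat
  )
}

new_cone_fit <- function(a, b, x0, y0, c, rms, degenerate, surface, data) {
  structure(
    list(a = a, b = b, x0 = x0, y0 = y0, c = c,
         rms_residual = rms, degenerate = degenerate,
         surface = surface, n = nrow(data), data = data),
    class = "cone_fit"
  )
}

#' @export
print.cone_fit <- function(x, ...) {
  cat(sprintf(
    "<cone_fit:%s> apex (%.2f, %.2f) um | a=%.3e b=%.3e c=%.4f | rms %.2e ms | n=%d%s\n",
    x$surface, x$x0, x$y0, x$a, x$b, x$c, x$rms_residual, x$n,
    if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' @export
tidy.cone_fit <- function(x, ...) {
  tibble(
    term = c("a", "b", "x0", "y0", "c"),
    estimate = c(x$a, x$b, x$x0, x$y0, x$c)
  )
}

#' @export
glance.cone_fit <- function(x, ...) {
  tibble(
    rms_residual = x$rms_residual, n = x$n,
    degenerate = x$degenerate, surface = x$surface
  )
}

#' Local conduction velocities from a fitted latency surface
#'
#' The gradient of the fitted latency surface is the slowness vector; the
#' local conduction speed at each electrode is the reciprocal of its norm.
#' For the cone surface the gradient is singular at the apex, so electrodes
#' within `apex_exclude_um` of the apex are excluded.
#'
#' @param fit a [fit_cone()] result.
#' @param latencies the latency tibble the fit was made on (columns
#'   `x`, `y`, optionally `electrode_id`).
#' @param apex_exclude_um exclusion radius around the apex (micrometers).
#' @return A tibble with one row per retained electrode: `x`, `y`
#'   (and `electrode_id` if supplied), `speed` (µm/ms, numerically equal to
#'   mm/s). Empty (zero rows) for a degenerate flat fit.
#' @export
local_velocities <- function(fit, latencies, apex_exclude_um = 17.5) {
  stopifnot(inherits(fit, "cone_fit"))
  lat <- as_tibble(latencies)
  out_cols <- intersect(c("electrode_id", "x", "y"), names(lat))
  if (fit$degenerate) {
    out <- lat[0, out_cols]
    out$speed <- numeric(0)
    return(out)
  }
  u <- lat$x - fit$x0
  v <- lat$y - fit$y0
  r <- sqrt(u^2 + v^2)
  if (fit$surface == "cone") {
    q <- sqrt(fit$a * u^2 + fit$b * v^2)
    grad_norm <- ifelse(q > 0, sqrt(fit$a^2 * u^2 + fit$b^2 * v^2) / q, NA_real_)
  } else {
    grad_norm <- 2 * sqrt(fit$a^2 * u^2 + fit$b^2 * v^2)
  }
  keep <- r >= apex_exclude_um & is.finite(grad_norm) & grad_norm > 0
  out <- lat[keep, out_cols]
  out$speed <- 1 / grad_norm[keep]
  out
}

#' Mean conduction speed across beats
#'
#' Local speed magnitudes are averaged across electrodes within each beat,
#' then across beats.
#'
#' @param per_beat_speeds list of numeric vectors (one per beat) or of
#'   [local_velocities()] tibbles.
#' @return Mean conduction speed in µm/ms, or `NA` when no beat has speeds.
#' @export
mean_conduction_speed <- function(per_beat_speeds) {
  beat_means <- purrr::map_dbl(per_beat_speeds, function(b) {
    v <- if (is.data.frame(b)) b$speed else b
    if (length(v) == 0) NA_real_ else mean(v)
  })
  beat_means <- beat_means[!is.na(beat_means)]
  if (length(beat_means) == 0) return(NA_real_)
  mean(beat_means)
}

#' Plot a fitted latency surface
#'
#' Shows observed electrode latencies as points colored by latency, with the
#' fitted apex marked and fitted iso-latency contours.
#'
#' @param object a [fit_cone()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cone_fit <- function(object, ...) {
  lat <- object$data
  gx <- seq(min(lat$x), max(lat$x), length.out = 60)
  gy <- seq(min(lat$y), max(lat$y), length.out = 60)
  grid <- tidyr::expand_grid(x = gx, y = gy) %>%
    mutate(
      q = object$a * (.data$x - object$x0)^2 + object$b * (.data$y - object$y0)^2,
      fitted = if (object$surface == "cone") sqrt(pmax(.data$q, 0)) + object$c
               else .data$q + object$c
    )
  ggplot2::ggplot(lat, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_contour(
      data = grid, ggplot2::aes(z = .data$fitted), color = "grey60"
    ) +
    ggplot2::geom_point(ggplot2::aes(color = .data$latency), size = 3) +
    ggplot2::annotate(
      "point", x = object$x0, y = object$y0, shape = 4, size = 4, stroke = 1.5
    ) +
    ggplot2::scale_color_viridis_c(name = "latency (ms)") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (µm)", y = "y (µm)",
      title = "Activation latency and fitted cone surface"
    )
}
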