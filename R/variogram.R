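#' Empirical semivariogram of spatial residuals
#'
#' Bins all site pairs by great-circle distance into equal-width lag
#' classes and computes the classical semivariance
#' `gamma(lag) = mean(0.5 * (r_i - r_j)^2)` per class.
#'
#' @param coords two-column lon/lat matrix or a data frame with `lon`,
#'   `lat` columns (e.g. `cal$meta`).
#' @param residuals numeric residual vector, one per site; `NA` sites are
#'   dropped.
#' @param n_bins number of lag classes (default 15).
#' @param max_lag_km largest lag considered; defaults to half the maximum
#'   pairwise distance (standard geostatistical practice).
#' @return Data frame of class `empirical_variogram` with columns `lag`
#'   (bin centre, km), `gamma` and `n_pairs`.
#' @export
empirical_variogram <- function(coords, residuals, n_bins = 15,
                                max_lag_km = NULL) {
  if (is.data.frame(coords)) coords <- as.matrix(coords[, c("lon", "lat")])
  ok <- !is.na(residuals)
  coords <- coords[ok, , drop = FALSE]
  residuals <- residuals[ok]
  n <- length(residuals)
  if (n < 2) stop("need at least 2 sites with residuals")
  if (n < 30)
    warning("fewer than 30 sites; the empirical variogram will be noisy")
  D <- great_circle_matrix(coords)
  pair <- upper.tri(D)
  d <- D[pair]
  g <- 0.5 * outer(residuals, residuals, "-")^2
  g <- g[pair]
  if (is.null(max_lag_km)) max_lag_km <- max(d) / 2
  keep <- d <= max_lag_km
  d <- d[keep]; g <- g[keep]
  brk <- seq(0, max_lag_km, length.out = n_bins + 1)
  bin <- findInterval(d, brk, rightmost.closed = TRUE, all.inside = TRUE)
  out <- data.frame(
    lag = (brk[-1] + brk[-length(brk)]) / 2,
    gamma = as.numeric(tapply(g, factor(bin, levels = seq_len(n_bins)), mean)),
    n_pairs = as.integer(table(factor(bin, levels = seq_len(n_bins))))
  )
  structure(out, class = c("empirical_variogram", "data.frame"))
}

# Circular variogram model: 0 at the origin, rising to the sill at the
# range a, constant beyond.
circular_gamma <- function(d, nugget, psill, range_km) {
  u <- pmin(d / range_km, 1)
  g <- nugget + psill * (1 - (2 / pi) * acos(u) + (2 * u / pi) * sqrt(1 - u^2))
  g[d <= 0] <- 0
  g
}

#' Fit a circular variogram model
#'
#' Weighted least squares fit of the circular model
#' `gamma(d) = c0 + c * (1 - (2/pi) * acos(d/a) + (2d/(pi*a)) * sqrt(1 - (d/a)^2))`
#' for `d <= a` and `c0 + c` beyond, with nugget `c0`, partial sill `c` and
#' range `a`. Bin weights are the pair counts. The fit is multi-started
#' over a grid of initial ranges and the lowest weighted SSE is kept; for a
#' pure-nugget (flat) variogram the range collapses to the smallest
#' candidate and the fit is flagged `no_spatial_structure`.
#'
#' @param bins an [empirical_variogram()] table (columns `lag`, `gamma`,
#'   `n_pairs`) with at least 4 non-empty bins.
#' @param start_ranges optional vector of initial range values; defaults
#'   to ten values spanning the lag range.
#' @return An object of class `variogram_fit` with elements `nugget`,
#'   `partial_sill`, `range_km`, `bins`, `sse` and `no_spatial_structure`.
#' @export
fit_circular_variogram <- function(bins, start_ranges = NULL) {
  bins <- bins[bins$n_pairs > 0 & is.finite(bins$gamma), , drop = FALSE]
  if (nrow(bins) < 4) stop("need at least 4 non-empty variogram bins")
  d <- bins$lag; g <- bins$gamma; w <- bins$n_pairs
  if (is.null(start_ranges))
    start_ranges <- seq(min(d), 1.5 * max(d), length.out = 10)
  start_ranges <- sort(start_ranges)
  sill0 <- max(g)
  obj <- function(th) {
    if (th[1] < 0 || th[2] < 0 || th[3] <= 0) return(Inf)
    sum(w * (g - circular_gamma(d, th[1], th[2], th[3]))^2)
  }
  best <- NULL
  for (a0 in start_ranges) {
    fit <- tryCatch(
      optim(c(max(min(g), 0), max(sill0 - min(g), 1e-8), a0), obj,
            method = "L-BFGS-B",
            lower = c(0, 0, min(d) * 1e-3),
            upper = c(Inf, Inf, max(d) * 10)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value - 1e-12))
      best <- fit
  }
  if (is.null(best)) stop("circular variogram fit failed from every start")
  th <- best$par
  total_sill <- th[1] + th[2]
  # spatial structure must improve significantly on a flat (pure-nugget)
  # model: F-test of the 2 extra parameters in the weighted fit
  sse_flat <- sum(w * (g - sum(w * g) / sum(w))^2)
  nb <- length(g)
  f_stat <- if (best$value > 0 && nb > 3)
    ((sse_flat - best$value) / 2) / (best$value / (nb - 3)) else Inf
  flat <- total_sill <= 0 || th[2] < 0.025 * total_sill ||
    f_stat < stats::qf(0.95, 2, max(nb - 3, 1))
  if (flat) th[3] <- min(start_ranges)
  structure(list(model = "circular", nugget = th[1], partial_sill = th[2],
                 range_km = th[3], bins = bins, sse = best$value,
                 no_spatial_structure = flat),
            class = "variogram_fit")
}

#' @export
print.variogram_fit <- function(x, ...) {
  cat(sprintf("circular variogram: nugget %.4g, partial sill %.4g, range %.1f km%s\n",
              x$nugget, x$partial_sill, x$range_km,
              if (x$no_spatial_structure) " [no spatial structure]" else ""))
  invisible(x)
}

#' Predict semivariance from a fitted circular variogram
#' @param object a `variogram_fit`.
#' @param lags distances in km.
#' @param ... unused.
#' @return Fitted semivariances.
#' @export
predict.variogram_fit <- function(object, lags, ...) {
  circular_gamma(lags, object$nugget, object$partial_sill, object$range_km)
}

#' Estimate the optimal h-block radius from WA residuals
#'
#' Runs a leave-one-out cross-validation of a standard WA model (monotonic
#' deshrinking, tolerance down-weighting, square-root transform), fits a
#' circular variogram to its spatial residuals, and returns the fitted
#' range rounded up to the h-grid granularity. The range is the distance
#' beyond which residuals are spatially uncorrelated, hence the smallest
#' exclusion radius that removes pseudo-replication.
#'
#' If no spatial structure is detected (flat variogram) the estimate is
#' `h = 0`: plain leave-one-out is then unbiased.
#'
#' @param cal a [calibration_set].
#' @param response climate variable name.
#' @param granularity_km rounding granularity of the h grid (default 100).
#' @param n_bins,max_lag_km passed to [empirical_variogram()].
#' @return An object of class `best_h` with elements `h_km`,
#'   `range_km` (unrounded), `variogram` and `no_spatial_structure`.
#' @export
estimate_best_h <- function(cal, response, granularity_km = 100,
                            n_bins = 15, max_lag_km = NULL) {
  cv <- run_hblock_cv(cal, method_spec("WA"), response, h = 0)
  ev <- empirical_variogram(cal$meta, cv$sites$residual, n_bins = n_bins,
                            max_lag_km = max_lag_km)
  fit <- fit_circular_variogram(ev)
  h <- if (fit$no_spatial_structure) 0
  else ceiling(fit$range_km / granularity_km) * granularity_km
  structure(list(h_km = h, range_km = fit$range_km, variogram = fit,
                 no_spatial_structure = fit$no_spatial_structure,
                 response = response),
            class = "best_h")
}

#' @export
print.best_h <- function(x, ...) {
  if (x$no_spatial_structure)
    cat(sprintf("best h for %s: 0 km (no spatial structure in WA residuals)\n",
                x$response))
  else
    cat(sprintf("best h for %s: %g km (variogram range %.1f km)\n",
                x$response, x$h_km, x$range_km))
  invisible(x)
}
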