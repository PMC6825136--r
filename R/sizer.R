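#' SiZer map of significant trends in a reconstruction
#'
#' SiZer ("SIgnificant ZERo crossings of derivatives") classifies the local
#' trend of a time series at every combination of time point and smoothing
#' bandwidth. For each bandwidth `b` in a log-spaced grid and each point of
#' a regular time grid, a local-linear fit with Gaussian kernel weights
#' `w_i = phi((age_i - t0)/b)` estimates the slope and its standard error
#' (sandwich form, as the kernel weights are not inverse variances). A
#' simultaneous confidence interval -- the pointwise interval Bonferroni
#' adjusted for the `m(b) = max(1, age_range/(2b))` effectively independent
#' blocks at that bandwidth -- classifies each cell:
#' `"rise"` if the interval is entirely positive, `"fall"` if entirely
#' negative, `"flat"` otherwise, and `"insufficient"` where the effective
#' sample size `sum(w)/max(w)` falls below `ess_min`.
#'
#' Slopes are with respect to increasing age; set `time_forward = TRUE` to
#' flip signs so `"rise"` means rising toward the present.
#'
#' @param ages strictly monotone sample ages (cal ka).
#' @param values reconstructed values at those ages.
#' @param n_bandwidths number of bandwidths (default 25), log-spaced from
#'   `bw_min` to `bw_max`.
#' @param alpha significance level of the simultaneous interval.
#' @param n_times size of the regular time grid (default 101).
#' @param bw_min,bw_max bandwidth limits; default twice the median age
#'   spacing and half the age range.
#' @param ess_min effective-sample-size cutoff below which a cell is
#'   `"insufficient"` (default 5).
#' @param time_forward logical; report trends with respect to time running
#'   toward the present instead of increasing age.
#' @return An object of class `sizer_map`: `times`, `bandwidths`,
#'   `categories` (bandwidth x time character matrix), `ess`, `slope`,
#'   `se` matrices.
#' @export
sizer_map <- function(ages, values, n_bandwidths = 25, alpha = 0.05,
                      n_times = 101, bw_min = NULL, bw_max = NULL,
                      ess_min = 5, time_forward = FALSE) {
  ages <- as.numeric(ages); values <- as.numeric(values)
  if (length(ages) != length(values))
    stop("ages and values must have the same length")
  ok <- !is.na(ages) & !is.na(values)
  ages <- ages[ok]; values <- values[ok]
  if (length(ages) < 10) stop("need at least 10 samples")
  d <- diff(ages)
  if (!(all(d > 0) || all(d < 0)))
    stop("ages must be strictly monotone")
  if (all(d < 0)) { ages <- rev(ages); values <- rev(values) }
  rng <- diff(range(ages))
  if (is.null(bw_min)) bw_min <- 2 * median(abs(d))
  if (is.null(bw_max)) bw_max <- rng / 2
  if (bw_min >= bw_max) bw_min <- bw_max / 10
  bandwidths <- exp(seq(log(bw_min), log(bw_max), length.out = n_bandwidths))
  times <- seq(min(ages), max(ages), length.out = n_times)
  cat_m <- matrix("insufficient", n_bandwidths, n_times)
  ess_m <- slope_m <- se_m <- matrix(NA_real_, n_bandwidths, n_times)
  # numerical floor for a "non-zero" slope, on the data's own scale, so a
  # constant series is flat rather than classifying rounding noise
  slope_eps <- 1e-9 * (max(abs(values)) + .Machine$double.xmin) / rng
  for (bi in seq_len(n_bandwidths)) {
    b <- bandwidths[bi]
    m_blocks <- max(1, rng / (2 * b))
    zq <- qnorm(1 - alpha / (2 * m_blocks))
    for (ti in seq_len(n_times)) {
      t0 <- times[ti]
      w <- dnorm((ages - t0) / b)
      ess <- sum(w) / max(w)
      ess_m[bi, ti] <- ess
      if (!is.finite(ess) || ess < ess_min) next
      ll <- local_linear_slope(ages - t0, values, w)
      if (is.null(ll)) next
      slope_m[bi, ti] <- ll$slope
      se_m[bi, ti] <- ll$se
      lo <- ll$slope - zq * ll$se
      hi <- ll$slope + zq * ll$se
      cat_m[bi, ti] <- if (lo > slope_eps) "rise"
      else if (hi < -slope_eps) "fall" else "flat"
    }
  }
  if (time_forward) {
    swap <- cat_m == "rise"
    cat_m[cat_m == "fall"] <- "rise"
    cat_m[swap] <- "fall"
    slope_m <- -slope_m
  }
  structure(list(times = times, bandwidths = bandwidths,
                 categories = cat_m, ess = ess_m, slope = slope_m,
                 se = se_m, alpha = alpha, time_forward = time_forward),
            class = "sizer_map")
}

# Weighted local-linear slope with sandwich standard error.
local_linear_slope <- function(x, y, w) {
  sw <- sum(w)
  xb <- sum(w * x) / sw
  xc <- x - xb
  sxx <- sum(w * xc^2)
  if (sxx <= .Machine$double.eps * sw * (max(abs(x))^2 + 1)) return(NULL)
  slope <- sum(w * xc * y) / sxx
  icept <- sum(w * y) / sw - slope * xb
  res <- y - icept - slope * x
  ess <- sw / max(w)
  if (ess <= 2.001) return(NULL)  # too few effective points for a variance
  sigma2 <- sum(w * res^2) / sw * ess / (ess - 2)
  var_slope <- sigma2 * sum(w^2 * xc^2) / sxx^2
  list(slope = slope, se = sqrt(max(var_slope, 0)))
}

#' @export
print.sizer_map <- function(x, ...) {
  tab <- table(factor(x$categories,
                      levels = c("rise", "fall", "flat", "insufficient")))
  cat(sprintf("SiZer map: %d times x %d bandwidths (%.3g-%.3g ka), alpha %.2g\n",
              length(x$times), length(x$bandwidths), min(x$bandwidths),
              max(x$bandwidths), x$alpha))
  cat(sprintf("  rise %d | fall %d | flat %d | insufficient %d\n",
              tab["rise"], tab["fall"], tab["flat"], tab["insufficient"]))
  invisible(x)
}

#' SiZer categories as a tidy data frame
#' @param x a `sizer_map`.
#' @param ... unused.
#' @return Data frame with columns `time`, `bandwidth`, `category`.
#' @export
as.data.frame.sizer_map <- function(x, ...) {
  data.frame(time = rep(x$times, each = length(x$bandwidths)),
             bandwidth = rep(x$bandwidths, length(x$times)),
             category = as.vector(x$categories),
             stringsAsFactors = FALSE)
}
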