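#' Training indices for one h-block fold
#'
#' For a held-out test site, the h-block training set omits the test site
#' and every site within great-circle distance `h` km of it (sites at
#' exactly `h` km are excluded). At `h = 0` this is the ordinary
#' leave-one-out training set.
#'
#' @param meta site metadata data frame (`site_id`, `lon`, `lat`, ...).
#' @param test_index row index of the held-out site.
#' @param h exclusion radius in km (`>= 0`).
#' @return Integer vector of training row indices.
#' @export
hblock_training_indices <- function(meta, test_index, h) {
  if (h < 0) stop("h must be >= 0")
  d <- great_circle_km(as.matrix(meta[, c("lon", "lat")]),
                       c(meta$lon[test_index], meta$lat[test_index]))
  idx <- which(d > h & seq_len(nrow(meta)) != test_index)
  if (length(idx) == 0)
    stop(sprintf("no training sites remain for site '%s' at h = %g km",
                 meta$site_id[test_index], h))
  idx
}

#' Root-mean-square error of prediction
#'
#' @param residuals numeric vector of prediction residuals
#'   (predicted - observed); `NA` entries are excluded.
#' @return RMSEP, with attribute `"n_missing"` counting excluded entries.
#' @export
rmsep <- function(residuals) {
  n_missing <- sum(is.na(residuals))
  r <- residuals[!is.na(residuals)]
  if (length(r) == 0) stop("all residuals are missing")
  structure(sqrt(mean(r^2)), n_missing = n_missing)
}

#' Maximum bias across the environmental gradient
#'
#' Splits the observed-value range into `n_segments` equal-length intervals
#' and returns the largest absolute mean residual over the non-empty
#' intervals -- a worst-segment error diagnostic.
#'
#' @param residuals prediction residuals (predicted - observed).
#' @param observed observed values (same length).
#' @param n_segments number of gradient segments (default 10).
#' @return Maximum absolute per-segment mean residual.
#' @export
max_bias <- function(residuals, observed, n_segments = 10) {
  if (length(residuals) != length(observed))
    stop("residuals and observed must have the same length")
  ok <- !is.na(residuals) & !is.na(observed)
  residuals <- residuals[ok]; observed <- observed[ok]
  rng <- range(observed)
  if (diff(rng) == 0)
    stop("degenerate gradient: all observed values are equal")
  brk <- seq(rng[1], rng[2], length.out = n_segments + 1)
  seg <- findInterval(observed, brk, rightmost.closed = TRUE, all.inside = TRUE)
  means <- tapply(residuals, seg, mean)
  max(abs(means))
}

#' Cross-validation coefficient of determination
#'
#' Squared Pearson correlation between observed and predicted values.
#'
#' @param observed,predicted numeric vectors; `NA` pairs excluded.
#' @return R-squared in `[0, 1]`.
#' @export
r_squared <- function(observed, predicted) {
  ok <- !is.na(observed) & !is.na(predicted)
  observed <- observed[ok]; predicted <- predicted[ok]
  if (length(observed) < 2) stop("need at least 2 complete pairs")
  if (sd(observed) == 0 || sd(predicted) == 0)
    stop("zero variance in observed or predicted values")
  cor(observed, predicted)^2
}

#' Run one h-block cross-validation
#'
#' Each site in turn is held out, the calibration model is refitted on the
#' sites beyond `h` km, and the held-out site is predicted. Per-site
#' records include the residual, the remaining training-set size and the
#' squared-chord distance to the best remaining analogue (an
#' analogue-quality diagnostic). A site whose training set falls below the
#' method's minimum viable size (`max(k, n_components + 1, 10)`) receives a
#' missing prediction rather than aborting the run.
#'
#' @param cal a [calibration_set].
#' @param spec a [method_spec]. Stochastic methods are re-seeded
#'   deterministically per fold from `spec$seed` (or `seed`).
#' @param response name of the climate variable to predict.
#' @param h exclusion radius in km.
#' @param seed master seed overriding `spec$seed` for per-fold reseeding.
#' @return An object of class `cv_result`: per-site data frame `sites`
#'   (observed, predicted, residual, n_train, best_analog) and `summary`
#'   (RMSEP, max bias, R2, median data-loss fraction, median best-analogue
#'   distance).
#' @export
run_hblock_cv <- function(cal, spec, response, h, seed = NULL) {
  stopifnot(inherits(cal, "calibration_set"), inherits(spec, "method_spec"))
  y <- climate_response(cal, response)
  X <- cal$taxa$values
  P <- X / 100
  sqrtP <- sqrt(P)
  n <- nrow(X)
  seed <- seed %||% spec$seed
  min_train <- min_viable_train(spec)
  pred <- rep(NA_real_, n)
  n_train <- integer(n)
  best_analog <- rep(NA_real_, n)
  n_skipped <- 0
  for (i in seq_len(n)) {
    idx <- tryCatch(hblock_training_indices(cal$meta, i, h),
                    error = function(e) integer(0))
    n_train[i] <- length(idx)
    if (length(idx) > 0)
      best_analog[i] <- min(sq_chord_to_rows(sqrtP[idx, , drop = FALSE], P[i, ]))
    if (length(idx) < min_train) {
      n_skipped <- n_skipped + 1
      next
    }
    fold_spec <- spec
    fold_spec$seed <- fold_seed(seed, spec$code, h, i)
    fit <- fit_model(fold_spec, X[idx, , drop = FALSE], y[idx])
    pred[i] <- as.numeric(predict(fit, X[i, , drop = FALSE]))[1]
  }
  if (n_skipped > 0)
    warning(sprintf("%d site(s) had < %d training samples at h = %g km; missing predictions",
                    n_skipped, min_train, h))
  sites <- data.frame(site_id = cal$taxa$site_ids, observed = y,
                      predicted = pred, residual = pred - y,
                      n_train = n_train, best_analog = best_analog,
                      stringsAsFactors = FALSE)
  structure(list(h = h, method = spec$code, response = response,
                 sites = sites, summary = cv_summary(sites, n)),
            class = "cv_result")
}

min_viable_train <- function(spec) {
  extra <- switch(spec$code,
                  MAT = spec$params$k,
                  WAPLS = spec$params$n_components + 1,
                  0)
  max(extra, 10)
}

cv_summary <- function(sites, n) {
  has_pred <- any(!is.na(sites$predicted))
  list(
    rmsep = if (has_pred) as.numeric(rmsep(sites$residual)) else NA_real_,
    max_bias = if (has_pred) max_bias(sites$residual, sites$observed) else NA_real_,
    r2 = if (sum(!is.na(sites$predicted)) >= 2)
      tryCatch(r_squared(sites$observed, sites$predicted),
               error = function(e) NA_real_) else NA_real_,
    n_predicted = sum(!is.na(sites$predicted)),
    median_data_loss_fraction = median((n - 1 - sites$n_train) / (n - 1)),
    median_best_analog = median(sites$best_analog, na.rm = TRUE)
  )
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("h-block CV: %s, %s, h = %g km\n", x$method, x$response, x$h))
  cat(sprintf("  RMSEP %.4g | max bias %.4g | R2 %.3f | %d/%d predicted\n",
              s$rmsep, s$max_bias, s$r2, s$n_predicted, nrow(x$sites)))
  cat(sprintf("  median data loss %.3f | median best analogue %.4f\n",
              s$median_data_loss_fraction, s$median_best_analog))
  invisible(x)
}

#' Cross-validation series specification
#'
#' @param h_grid non-negative, strictly increasing radii in km
#'   (default 0, 100, ..., 1500).
#' @param methods list of [method_spec] objects.
#' @param response climate variable name.
#' @param seed master seed for per-fold reseeding of stochastic methods.
#' @return An object of class `cv_spec`.
#' @export
cv_spec <- function(h_grid = seq(0, 1500, by = 100), methods, response,
                    seed = NULL) {
  h_grid <- as.numeric(h_grid)
  if (any(h_grid < 0) || any(diff(h_grid) <= 0))
    stop("h_grid must be non-negative and strictly increasing")
  if (inherits(methods, "method_spec")) methods <- list(methods)
  stopifnot(all(vapply(methods, inherits, logical(1), "method_spec")))
  structure(list(h_grid = h_grid, methods = methods, response = response,
                 seed = seed), class = "cv_spec")
}

#' Run a variable-radius h-block cross-validation series
#'
#' Runs [run_hblock_cv()] for every combination of exclusion radius and
#' method in the specification. The series is deterministic under a fixed
#' seed; folds are independent, so results do not depend on execution
#' order.
#'
#' @param cal a [calibration_set].
#' @param cvspec a [cv_spec].
#' @return An object of class `cv_series`: a list of `cv_result` objects.
#'   Use [as.data.frame()] for tidy long-format per-site records and
#'   [summary()] for the per-(h, method) metric table.
#' @export
run_cv_series <- function(cal, cvspec) {
  stopifnot(inherits(cvspec, "cv_spec"))
  results <- list()
  for (spec in cvspec$methods) {
    for (h in cvspec$h_grid) {
      results[[length(results) + 1]] <-
        run_hblock_cv(cal, spec, cvspec$response, h, seed = cvspec$seed)
    }
  }
  structure(results, class = "cv_series")
}

#' @export
as.data.frame.cv_series <- function(x, ...) {
  do.call(rbind, lapply(x, function(r)
    cbind(h = r$h, method = r$method, r$sites, stringsAsFactors = FALSE)))
}

#' @export
summary.cv_series <- function(object, ...) {
  do.call(rbind, lapply(object, function(r)
    data.frame(h = r$h, method = r$method, response = r$response,
               rmsep = r$summary$rmsep, max_bias = r$summary$max_bias,
               r2 = r$summary$r2, n_predicted = r$summary$n_predicted,
               median_data_loss = r$summary$median_data_loss_fraction,
               median_best_analog = r$summary$median_best_analog,
               stringsAsFactors = FALSE)))
}

#' @export
print.cv_series <- function(x, ...) {
  print(summary(x))
  invisible(x)
}
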