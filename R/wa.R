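#' Fit a weighted averaging (WA) transfer function
#'
#' Classical WA with optional tolerance down-weighting, on square-root
#' transformed percentages. Each taxon's optimum is its abundance-weighted
#' mean of the response, and its tolerance the abundance-weighted standard
#' deviation (its niche breadth). Raw sample scores are abundance-weighted
#' means of the taxon optima, down-weighted by squared tolerance when
#' `tolerance_dw = TRUE`, and a deshrinking regression maps raw scores back
#' to the response scale.
#'
#' Tolerances are floored at `max(1%% of the response range, smallest
#' positive tolerance)` so that single-occurrence taxa (raw tolerance 0) do
#' not blow up the down-weighting.
#'
#' @param X site x taxon percentage matrix.
#' @param y numeric response vector.
#' @param deshrinking `"monotonic"` (isotonic regression of observed on raw
#'   scores with linear interpolation and end-slope extrapolation),
#'   `"inverse"` (OLS of y on raw scores) or `"classical"` (OLS of raw
#'   scores on y, inverted).
#' @param tolerance_dw down-weight taxa by inverse squared tolerance?
#' @return A fitted model of class `c("paleotf_WA", "paleotf_model")` whose
#'   state holds the optima `u`, tolerances `t` and the deshrinking map.
#' @export
fit_wa <- function(X, y, deshrinking = c("monotonic", "inverse", "classical"),
                   tolerance_dw = TRUE) {
  deshrinking <- match.arg(deshrinking)
  X <- as_percent_matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  Y <- sqrt_transform(X)
  zero_sites <- which(rowSums(Y) == 0)
  if (length(zero_sites) > 0)
    stop("site(s) with all-zero taxa: ",
         paste(rownames(X)[zero_sites] %||% zero_sites, collapse = ", "))
  csum <- colSums(Y)
  drop <- csum <= 0
  if (any(drop)) {
    warning("dropping zero-sum taxon column(s): ",
            paste(colnames(Y)[drop], collapse = ", "))
    Y <- Y[, !drop, drop = FALSE]
    csum <- csum[!drop]
  }
  u <- colSums(Y * y) / csum
  tol_raw <- sqrt(colSums(Y * outer(y, u, "-")^2) / csum)
  pos <- tol_raw[tol_raw > 0]
  floor_t <- max(0.01 * diff(range(y)),
                 if (length(pos) > 0) min(pos) else 0)
  tol <- pmax(tol_raw, floor_t)
  r <- wa_raw_scores(Y, u, tol, tolerance_dw)
  deshrink <- fit_deshrinking(r, y, deshrinking)
  new_model("WA",
            list(deshrinking = deshrinking, tolerance_dw = tolerance_dw),
            colnames(Y),
            state = list(u = u, tol = tol, tol_raw = tol_raw,
                         tolerance_floor = floor_t, deshrink = deshrink),
            train_range = range(y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

wa_raw_scores <- function(Y, u, tol, tolerance_dw) {
  if (tolerance_dw) {
    w <- 1 / tol^2
    num <- drop(Y %*% (u * w))
    den <- drop(Y %*% w)
  } else {
    num <- drop(Y %*% u)
    den <- rowSums(Y)
  }
  ifelse(den > 0, num / den, NA_real_)
}

#' Predict from a WA model
#'
#' Raw scores for the new samples are computed from the stored optima and
#' tolerances and passed through the fitted deshrinking map. A sample
#' sharing no taxa with the model yields `NA` with a warning.
#'
#' @param object fitted WA model.
#' @param newdata percentage matrix with the model's taxon columns (extra
#'   columns dropped at alignment are not allowed; use [align_taxa()]).
#' @param ... unused.
#' @return Numeric predictions.
#' @export
predict.paleotf_WA <- function(object, newdata, ...) {
  X <- align_columns(newdata, object$taxon_names)
  st <- object$state
  r <- wa_raw_scores(sqrt_transform(X), st$u, st$tol,
                     object$spec$params$tolerance_dw)
  if (anyNA(r))
    warning(sum(is.na(r)), " sample(s) share no taxa with the model; NA returned")
  unname(apply_deshrinking(st$deshrink, r))
}

# -- deshrinking --------------------------------------------------------------

fit_deshrinking <- function(r, y, type) {
  if (type == "inverse") {
    cf <- coef(lm.fit(cbind(1, r), y))
    list(type = "inverse", a = cf[1], b = cf[2])
  } else if (type == "classical") {
    cf <- coef(lm.fit(cbind(1, y), r))
    if (abs(cf[2]) < .Machine$double.eps)
      stop("classical deshrinking: zero slope")
    list(type = "classical", a = cf[1], b = cf[2])
  } else {
    fit_monotonic_map(r, y)
  }
}

# Isotonic (pool-adjacent-violators) regression of y on raw scores with
# linear interpolation between knots and end-slope linear extrapolation.
# A negative raw-score/response association is handled by fitting the
# antitonic map (isotonic fit to -y, negated).
fit_monotonic_map <- function(r, y) {
  ok <- is.finite(r)
  rs <- r[ok]; ys <- y[ok]
  direction <- if (cor(rs, ys) < 0) -1 else 1
  # collapse duplicate raw scores to their mean response
  ux <- sort(unique(rs))
  uy <- vapply(ux, function(v) mean(ys[rs == v]), numeric(1))
  fit <- isoreg(ux, direction * uy)
  ky <- direction * fit$yf
  kx <- ux
  if (length(kx) < 2) {
    slopes <- c(0, 0)
  } else {
    end1 <- diff(ky[1:2]) / diff(kx[1:2])
    n <- length(kx)
    end2 <- diff(ky[(n - 1):n]) / diff(kx[(n - 1):n])
    slopes <- c(end1, end2)
  }
  list(type = "monotonic", kx = kx, ky = ky, slopes = slopes)
}

apply_deshrinking <- function(d, r) {
  if (d$type == "inverse") return(d$a + d$b * r)
  if (d$type == "classical") return((r - d$a) / d$b)
  out <- approx(d$kx, d$ky, xout = r, rule = 2, ties = "ordered")$y
  lo <- which(r < d$kx[1])
  hi <- which(r > d$kx[length(d$kx)])
  out[lo] <- d$ky[1] + d$slopes[1] * (r[lo] - d$kx[1])
  out[hi] <- d$ky[length(d$ky)] + d$slopes[2] * (r[hi] - d$kx[length(d$kx)])
  out[!is.finite(r)] <- NA_real_
  out
}
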