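#' Fit a weighted averaging partial least squares (WA-PLS) model
#'
#' The iterative WA-PLS cycle on square-root transformed percentages: each
#' component's taxon scores are the abundance-weighted averages of the
#' current working response (the previous components' regression
#' residuals), site scores are the abundance-weighted averages of the taxon
#' scores, components are orthogonalized against earlier ones, and the
#' response is regressed on the component scores by ordinary least squares
#' (inverse-style deshrinking). With one component this reduces exactly to
#' WA with inverse deshrinking and no tolerance down-weighting.
#'
#' @param X site x taxon percentage matrix.
#' @param y numeric response vector.
#' @param n_components number of components (default 3). If a component is
#'   numerically degenerate the model falls back to the largest feasible
#'   count with a warning.
#' @return A fitted model of class `c("paleotf_WAPLS", "paleotf_model")`.
#'   Its state stores per-component taxon scores, orthogonalization
#'   coefficients and the final regression coefficients; element
#'   `train_rmse` gives the training RMSE per nested component count.
#' @export
fit_wapls <- function(X, y, n_components = 3) {
  X <- as_percent_matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (n_components < 1) stop("n_components must be >= 1")
  Y <- sqrt_transform(X)
  if (any(rowSums(Y) == 0))
    stop("site(s) with all-zero taxa: ",
         paste(which(rowSums(Y) == 0), collapse = ", "))
  keep <- colSums(Y) > 0
  if (!all(keep)) {
    warning("dropping zero-sum taxon column(s): ",
            paste(colnames(Y)[!keep], collapse = ", "))
    Y <- Y[, keep, drop = FALSE]
  }
  n <- nrow(Y); m <- ncol(Y)
  A <- min(n_components, n - 1, m)
  if (A < n_components)
    warning(sprintf("n_components reduced from %d to %d (rank limit)",
                    n_components, A))
  K <- colSums(Y); R <- rowSums(Y)
  U <- matrix(0, m, A, dimnames = list(colnames(Y), NULL))
  S <- matrix(0, n, A)
  orth <- vector("list", A)
  train_rmse <- numeric(A)
  x <- y
  a <- 0
  while (a < A) {
    u <- drop(crossprod(Y, x)) / K
    s <- drop(Y %*% u) / R
    cfs <- numeric(a)
    if (a > 0) for (b in seq_len(a)) {
      cfs[b] <- sum(s * S[, b]) / sum(S[, b]^2)
      s <- s - cfs[b] * S[, b]
    }
    if (sd(s) < 1e-10 * (sd(y) + 1e-12)) {
      warning(sprintf("component %d degenerate; keeping %d component(s)",
                      a + 1, a))
      A <- a
      break
    }
    a <- a + 1
    U[, a] <- u; S[, a] <- s; orth[[a]] <- cfs
    fit <- lm.fit(cbind(1, S[, seq_len(a), drop = FALSE]), y)
    x <- fit$residuals
    train_rmse[a] <- sqrt(mean(fit$residuals^2))
  }
  if (A == 0) stop("no usable WA-PLS component could be extracted")
  U <- U[, seq_len(A), drop = FALSE]
  fit <- lm.fit(cbind(1, S[, seq_len(A), drop = FALSE]), y)
  new_model("WAPLS", list(n_components = A), colnames(Y),
            state = list(U = U, orth = orth[seq_len(A)],
                         beta = coef(fit), train_rmse = train_rmse[seq_len(A)]),
            train_range = range(y))
}

#' Predict from a WA-PLS model
#'
#' Component scores for new samples are computed from the stored taxon
#' scores, orthogonalized with the training coefficients, and passed
#' through the stored regression. Samples with no taxa shared with the
#' model yield `NA` with a warning.
#'
#' @param object fitted WA-PLS model.
#' @param newdata percentage matrix with the model's taxon columns.
#' @param ... unused.
#' @return Numeric predictions.
#' @export
predict.paleotf_WAPLS <- function(object, newdata, ...) {
  X <- align_columns(newdata, object$taxon_names)
  st <- object$state
  Y <- sqrt_transform(X)
  R <- rowSums(Y)
  bad <- R == 0
  if (any(bad))
    warning(sum(bad), " sample(s) share no taxa with the model; NA returned")
  R[bad] <- NA_real_
  A <- ncol(st$U)
  S <- matrix(0, nrow(Y), A)
  for (a in seq_len(A)) {
    s <- drop(Y %*% st$U[, a]) / R
    cfs <- st$orth[[a]]
    if (length(cfs) > 0) for (b in seq_along(cfs)) s <- s - cfs[b] * S[, b]
    S[, a] <- s
  }
  unname(drop(cbind(1, S) %*% st$beta))
}
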