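#' Fit a modern analogue technique (MAT) model
#'
#' MAT is k-nearest-neighbour prediction in assemblage space: for a new
#' sample the k compositionally closest training samples (squared chord
#' distance on proportions) are found and the prediction is their
#' inverse-distance-weighted mean response. No parameters are estimated at
#' fit time; the training data are stored.
#'
#' @param X site x taxon percentage matrix with taxon column names.
#' @param y numeric response vector (one value per row of `X`).
#' @param k number of analogues (default 5).
#' @return A fitted model of class `c("paleotf_MAT", "paleotf_model")`.
#' @export
fit_mat <- function(X, y, k = 5) {
  X <- as_percent_matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(X)) stop(sprintf("k = %d exceeds the %d training samples", k, nrow(X)))
  P <- X / 100
  new_model("MAT", list(k = k), colnames(X),
            state = list(P = P, sqrtP = sqrt(P), y = y),
            train_range = range(y))
}

#' Predict from a MAT model
#'
#' For each new sample the `k` smallest squared-chord training distances
#' are located (ties at the k-th distance broken by training-row order) and
#' the prediction is the mean of their responses weighted by inverse
#' distance. Analogues at effectively zero distance (`< 1e-12`) short-cut
#' to their unweighted mean.
#'
#' @param object fitted MAT model.
#' @param newdata percentage matrix with the model's taxon columns.
#' @param ... unused.
#' @return Numeric predictions with attribute `"min_sqchord"`, the
#'   per-sample distance to the best analogue.
#' @export
predict.paleotf_MAT <- function(object, newdata, ...) {
  X <- align_columns(newdata, object$taxon_names)
  st <- object$state
  k <- object$spec$params$k
  if (k > nrow(st$P))
    stop(sprintf("k = %d exceeds the %d stored training samples", k, nrow(st$P)))
  n <- nrow(X)
  pred <- numeric(n)
  mind <- numeric(n)
  for (i in seq_len(n)) {
    d <- sq_chord_to_rows(st$sqrtP, X[i, ] / 100)
    sel <- order(d)[seq_len(k)]  # stable: ties broken by row order
    dsel <- d[sel]
    mind[i] <- dsel[1]
    zero <- dsel < 1e-12
    pred[i] <- if (any(zero)) mean(st$y[sel[zero]])
    else sum(st$y[sel] / dsel) / sum(1 / dsel)
  }
  attr(pred, "min_sqchord") <- mind
  pred
}

# -- shared fitted-model plumbing --------------------------------------------

new_model <- function(code, params, taxon_names, state, train_range,
                      seed = NULL) {
  structure(
    list(spec = structure(list(code = code, params = params, seed = seed),
                          class = "method_spec"),
         taxon_names = taxon_names, state = state,
         train_range = as.numeric(train_range)),
    class = c(paste0("paleotf_", code), "paleotf_model"))
}

#' @export
print.paleotf_model <- function(x, ...) {
  cat(sprintf("fitted %s model: %d taxa, training response range [%g, %g]\n",
              x$spec$code, length(x$taxon_names),
              x$train_range[1], x$train_range[2]))
  invisible(x)
}

as_percent_matrix <- function(X) {
  if (inherits(X, "taxon_table")) {
    if (X$unit != "percent") stop("taxon_table must be in percent")
    X <- X$values
  }
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) stop("X must have taxon column names")
  if (anyNA(X) || any(X < 0)) stop("X must be non-negative without NA")
  X
}

align_columns <- function(newdata, taxon_names) {
  X <- as_percent_matrix(newdata)
  if (!identical(colnames(X), taxon_names)) {
    if (!all(taxon_names %in% colnames(X)))
      stop("newdata is missing model taxa: ",
           paste(setdiff(taxon_names, colnames(X)), collapse = ", "))
    extra <- setdiff(colnames(X), taxon_names)
    if (length(extra) > 0)
      stop("newdata has taxa unknown to the model: ",
           paste(extra, collapse = ", "))
    X <- X[, taxon_names, drop = FALSE]
  }
  X
}
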