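#' Calibration method specification
#'
#' A method code plus its hyperparameters and an optional seed. The eight
#' supported codes span four families: the modern analogue technique
#' (`MAT`), the unimodal transfer functions (`WA`, `WAPLS`), regression
#' tree ensembles (`RF`, `ETREES`, `BRT`) and single-hidden-layer neural
#' networks (`NNET`, `ELM`). Defaults follow the standard pollen-climate
#' parameterizations (see [method_defaults()]); `NNET` and `ELM` have
#' dataset-specific hidden-layer sizes and therefore require
#' `hidden_units` explicitly.
#'
#' @param code one of `"MAT"`, `"WA"`, `"WAPLS"`, `"RF"`, `"ETREES"`,
#'   `"BRT"`, `"NNET"`, `"ELM"`.
#' @param ... hyperparameter overrides (see Details).
#' @param seed integer seed for stochastic methods, or `NULL`.
#'
#' @details Recognized parameters and defaults:
#' * `MAT`: `k = 5` analogues, inverse squared-chord-distance weights.
#' * `WA`: `deshrinking = "monotonic"` (`"inverse"`, `"classical"` also
#'   available), `tolerance_dw = TRUE`.
#' * `WAPLS`: `n_components = 3`.
#' * `RF`: `n_trees = 100`.
#' * `ETREES`: `n_trees = 100`, `n_random_cuts = 5`.
#' * `BRT`: `max_trees = 3000`, `learning_rate = 0.025`, `tree_depth = 4`,
#'   `bag_fraction = 0.5`, `cv_folds = 5` (tree count chosen by internal CV).
#' * `NNET`: `hidden_units` (required), `maxit = 500`, linear output.
#' * `ELM`: `hidden_units` (required), `n_networks = 5`, rectified-linear
#'   hidden activation.
#' @return An object of class `method_spec`.
#' @examples
#' method_spec("MAT", k = 5)
#' method_spec("BRT", seed = 1)
#' @export
method_spec <- function(code, ..., seed = NULL) {
  code <- match.arg(toupper(code), METHOD_CODES)
  params <- utils::modifyList(default_params(code), list(...))
  validate_params(code, params)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(code = code, params = params, seed = seed),
            class = "method_spec")
}

METHOD_CODES <- c("MAT", "WA", "WAPLS", "RF", "ETREES", "BRT", "NNET", "ELM")

default_params <- function(code) {
  switch(code,
    MAT = list(k = 5),
    WA = list(deshrinking = "monotonic", tolerance_dw = TRUE),
    WAPLS = list(n_components = 3),
    RF = list(n_trees = 100),
    ETREES = list(n_trees = 100, n_random_cuts = 5),
    BRT = list(max_trees = 3000, learning_rate = 0.025, tree_depth = 4,
               bag_fraction = 0.5, cv_folds = 5),
    NNET = list(hidden_units = NULL, maxit = 500),
    ELM = list(hidden_units = NULL, n_networks = 5)
  )
}

validate_params <- function(code, p) {
  chk <- function(cond, msg) if (!isTRUE(cond)) stop(code, ": ", msg)
  switch(code,
    MAT = chk(is.numeric(p$k) && p$k >= 1, "k must be >= 1"),
    WA = {
      chk(p$deshrinking %in% c("inverse", "classical", "monotonic"),
          "deshrinking must be inverse, classical or monotonic")
      chk(is.logical(p$tolerance_dw), "tolerance_dw must be logical")
    },
    WAPLS = chk(is.numeric(p$n_components) && p$n_components >= 1,
                "n_components must be >= 1"),
    RF = chk(p$n_trees >= 1, "n_trees must be >= 1"),
    ETREES = chk(p$n_trees >= 1 && p$n_random_cuts >= 1,
                 "n_trees and n_random_cuts must be >= 1"),
    BRT = chk(p$max_trees >= 1 && p$learning_rate > 0 && p$tree_depth >= 1 &&
                p$bag_fraction > 0 && p$bag_fraction <= 1,
              "invalid boosting parameters"),
    NNET = chk(is.null(p$hidden_units) || p$hidden_units >= 1,
               "hidden_units must be >= 1"),
    ELM = chk(p$n_networks >= 1 &&
                (is.null(p$hidden_units) || p$hidden_units >= 1),
              "n_networks and hidden_units must be >= 1")
  )
  invisible(TRUE)
}

#' @export
print.method_spec <- function(x, ...) {
  pstr <- paste(names(x$params),
                vapply(x$params, function(v)
                  if (is.null(v)) "<required>" else paste(v, collapse = ","),
                  character(1)),
                sep = "=", collapse = ", ")
  cat(sprintf("method_spec %s (%s)%s\n", x$code, pstr,
              if (is.null(x$seed)) "" else paste0(", seed=", x$seed)))
  invisible(x)
}

#' Standard method parameterizations
#'
#' Returns the default hyperparameter table for all eight calibration
#' methods, including the dataset-specific hidden-layer sizes used for the
#' North American and European pollen-climate models (the neural-network
#' layer sizes are calibration-set specific and must be supplied for new
#' datasets).
#'
#' @return Data frame with one row per method.
#' @export
method_defaults <- function() {
  data.frame(
    code = METHOD_CODES,
    parameters = c(
      "weighted mean of 5 closest analogues (inverse squared-chord weights)",
      "monotonic deshrinking, tolerance down-weighting, sqrt-transformed species data",
      "3-component model, sqrt-transformed species data",
      "100 trees",
      "100 trees, 5 random cuts per split",
      "max 3000 trees (internal 5-fold CV), learning rate 0.025, tree depth 4, bag fraction 0.5",
      "linear output; hidden units 18 (Europe T_jul), 19 (Europe T_jan), 13 (N America T_jul), 8 (N America water balance)",
      "mean of 5 networks, rectified linear activation; hidden units 180 (Europe T_jul), 130 (Europe T_jan), 290 (N America T_jul), 280 (N America water balance)"
    ),
    stringsAsFactors = FALSE
  )
}

#' Squared chord distance between two proportion vectors
#'
#' The standard compositional dissimilarity for pollen assemblages:
#' `sum((sqrt(p) - sqrt(q))^2)`, with range 0 (identical) to 2 (no shared
#' taxa).
#'
#' @param p,q non-negative vectors of equal length, each summing to 1
#'   within 1e-6.
#' @return Scalar distance in `[0, 2]`.
#' @examples
#' sq_chord(c(0.5, 0.5), c(1, 0))  # 2 - sqrt(2)
#' @export
sq_chord <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have the same length")
  if (any(p < 0) || any(q < 0)) stop("proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("p and q must each sum to 1")
  sum((sqrt(p) - sqrt(q))^2)
}

# Row-wise squared chord distances from each row of sqrtP to sqrt of x.
sq_chord_to_rows <- function(sqrtP, x) {
  dif <- sweep(sqrtP, 2, sqrt(x))
  rowSums(dif * dif)
}
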