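#' Fit a machine-learning calibration model
#'
#' Thin adapters over standard regression backends, all behind the common
#' fit/predict contract and all taking raw percentages (the square-root
#' transform is reserved for WA/WA-PLS):
#' * `RF` -- 100-tree bagged regression forest (randomForest).
#' * `ETREES` -- extremely randomized trees: no bootstrap, all predictors
#'   considered at each split, 5 random cut candidates (ranger,
#'   `splitrule = "extratrees"`).
#' * `BRT` -- squared-error gradient boosting, depth-4 trees, shrinkage
#'   0.025, bag fraction 0.5; the tree count (up to 3000) is chosen by
#'   internal 5-fold cross-validation on the training partition (xgboost).
#' * `NNET` -- one sigmoid hidden layer, linear output, squared-error
#'   training (nnet); `hidden_units` must be supplied.
#' * `ELM` -- extreme learning machine: 5 independent single-hidden-layer
#'   networks with uniform random `U(-1, 1)` hidden weights, rectified
#'   ("positive") linear activation, output weights by least squares,
#'   predictions averaged; `hidden_units` must be supplied.
#'
#' Predictor columns for the neural methods are divided by 100
#' (proportions). All stochastic fits are seeded from `spec$seed`, so the
#' same seed reproduces the fit exactly.
#'
#' @param spec a [method_spec] with code `RF`, `ETREES`, `BRT`, `NNET` or
#'   `ELM`.
#' @param X site x taxon percentage matrix.
#' @param y numeric response vector.
#' @return A fitted model of class `c("paleotf_<code>", "paleotf_model")`.
#' @export
fit_ml <- function(spec, X, y) {
  stopifnot(inherits(spec, "method_spec"))
  X <- as_percent_matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  p <- spec$params
  state <- switch(spec$code,
    RF = with_rng_seed(spec$seed,
      list(fit = randomForest::randomForest(x = X, y = y, ntree = p$n_trees))),
    ETREES = list(fit = ranger::ranger(
      x = X, y = y, num.trees = p$n_trees, splitrule = "extratrees",
      num.random.splits = p$n_random_cuts, replace = FALSE,
      sample.fraction = 1, mtry = ncol(X), num.threads = 1,
      seed = spec$seed %||% 1L)),
    BRT = with_rng_seed(spec$seed, fit_brt(X, y, p)),
    NNET = {
      if (is.null(p$hidden_units))
        stop("NNET requires hidden_units; the standard values are dataset-specific (see method_defaults())")
      with_rng_seed(spec$seed,
        list(fit = nnet::nnet(x = X / 100, y = y, size = p$hidden_units,
                              linout = TRUE, maxit = p$maxit, decay = 0,
                              trace = FALSE, MaxNWts = 1e5)))
    },
    ELM = {
      if (is.null(p$hidden_units))
        stop("ELM requires hidden_units; the standard values are dataset-specific (see method_defaults())")
      with_rng_seed(spec$seed, fit_elm(X / 100, y, p$hidden_units, p$n_networks))
    },
    stop("fit_ml handles RF, ETREES, BRT, NNET, ELM; got ", spec$code)
  )
  m <- new_model(spec$code, p, colnames(X), state, range(y), seed = spec$seed)
  m
}

fit_brt <- function(X, y, p) {
  d <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  params <- list(objective = "reg:squarederror", eta = p$learning_rate,
                 max_depth = p$tree_depth, subsample = p$bag_fraction,
                 nthread = 1)
  nfold <- min(p$cv_folds, nrow(X))
  n_trees <- if (nfold >= 2 && nrow(X) >= 2 * nfold) {
    cv <- xgboost::xgb.cv(params = params, data = d, nrounds = p$max_trees,
                          nfold = nfold, early_stopping_rounds = 50,
                          verbose = 0)
    cv$early_stop$best_iteration
  } else p$max_trees
  fit <- xgboost::xgb.train(params = params, data = d, nrounds = n_trees,
                            verbose = 0)
  list(fit = fit, n_trees = n_trees)
}

fit_elm <- function(Xs, y, hidden_units, n_networks) {
  nets <- lapply(seq_len(n_networks), function(j) {
    W <- matrix(runif(hidden_units * (ncol(Xs) + 1), -1, 1),
                nrow = ncol(Xs) + 1)
    H <- pmax(cbind(1, Xs) %*% W, 0)  # rectified linear hidden layer
    beta <- coef(lm.fit(cbind(1, H), y))
    beta[is.na(beta)] <- 0
    list(W = W, beta = beta)
  })
  list(nets = nets)
}

#' @export
predict.paleotf_RF <- function(object, newdata, ...) {
  X <- align_columns(newdata, object$taxon_names)
  unname(predict(object$state$fit, X))
}

#' @export
predict.paleotf_ETREES <- function(object, newdata, ...) {
  X <- align_columns(newdata, object$taxon_names)
  predict(object$state$fit, data = as.data.frame(X, check.names = FALSE),
          num.threads = 1)$predictions
}

#' @export
predict.paleotf_BRT <- function(object, newdata, ...) {
  X <- align_columns(newdata, object$taxon_names)
  predict(object$state$fit, xgboost::xgb.DMatrix(X, nthread = 1))
}

#' @export
predict.paleotf_NNET <- function(object, newdata, ...) {
  X <- align_columns(newdata, object$taxon_names)
  drop(predict(object$state$fit, X / 100))
}

#' @export
predict.paleotf_ELM <- function(object, newdata, ...) {
  X <- align_columns(newdata, object$taxon_names) / 100
  preds <- vapply(object$state$nets, function(net) {
    H <- pmax(cbind(1, X) %*% net$W, 0)
    drop(cbind(1, H) %*% net$beta)
  }, numeric(nrow(X)))
  if (nrow(X) == 1) mean(preds) else rowMeans(preds)
}

#' Relative influence of predictor taxa in a BRT model
#'
#' Per-taxon reduction-in-loss contributions of the boosted ensemble,
#' normalized to sum to 100 and sorted descending -- the standard tool for
#' checking that a pollen-climate model leans on ecologically credible
#' indicator taxa.
#'
#' @param model a fitted BRT model from [fit_ml()] or [fit_model()].
#' @return Data frame with columns `taxon` and `contribution` (percent).
#' @export
relative_influence <- function(model) {
  if (!inherits(model, "paleotf_BRT"))
    stop("relative_influence is defined for BRT models only")
  contrib <- setNames(rep(0, length(model$taxon_names)), model$taxon_names)
  if (length(model$taxon_names) == 1) {
    contrib[] <- 100
    return(data.frame(taxon = names(contrib), contribution = unname(contrib),
                      stringsAsFactors = FALSE))
  }
  imp <- xgboost::xgb.importance(model = model$state$fit)
  if (nrow(imp) == 0) {
    # ensemble made no splits (e.g. constant response): spread evenly
    contrib[] <- 100 / length(contrib)
  } else {
    contrib[imp$Feature] <- imp$Gain
    contrib <- 100 * contrib / sum(contrib)
  }
  ord <- order(-contrib, names(contrib))
  data.frame(taxon = names(contrib)[ord], contribution = unname(contrib[ord]),
             stringsAsFactors = FALSE)
}

#' Fit any calibration method from its specification
#'
#' Single entry point dispatching to [fit_mat()], [fit_wa()],
#' [fit_wapls()] or [fit_ml()] according to `spec$code`.
#'
#' @param spec a [method_spec].
#' @param X site x taxon percentage matrix.
#' @param y numeric response vector.
#' @return A fitted `paleotf_model`; predict with `predict(model, newdata)`.
#' @examples
#' X <- matrix(c(80, 20, 60, 40, 30, 70, 10, 90), 4, 2, byrow = TRUE,
#'             dimnames = list(NULL, c("Pinus", "Betula")))
#' m <- fit_model(method_spec("WA"), X, c(10, 12, 14, 16))
#' predict(m, X)
#' @export
fit_model <- function(spec, X, y) {
  stopifnot(inherits(spec, "method_spec"))
  p <- spec$params
  switch(spec$code,
    MAT = fit_mat(X, y, k = p$k),
    WA = fit_wa(X, y, deshrinking = p$deshrinking,
                tolerance_dw = p$tolerance_dw),
    WAPLS = fit_wapls(X, y, n_components = p$n_components),
    fit_ml(spec, X, y))
}
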