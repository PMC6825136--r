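#' Spearman correlation matrix of climate variables
#'
#' Pairwise Spearman rank correlations (average-rank tie handling) among
#' the candidate climate variables of a calibration set or climate table.
#'
#' @param climate a [calibration_set], or a data frame of climate values
#'   (a `site_id` column, if present, is ignored).
#' @return Symmetric correlation matrix of class `spearman_matrix` with
#'   attribute `"n"` (sample size).
#' @export
spearman_matrix <- function(climate) {
  if (inherits(climate, "calibration_set")) climate <- climate$climate
  climate <- as.data.frame(climate)
  climate$site_id <- NULL
  if (nrow(climate) < 3) stop("need at least 3 sites")
  if (ncol(climate) < 2) stop("need at least 2 variables")
  const <- names(climate)[vapply(climate, function(v) sd(v) == 0, logical(1))]
  if (length(const) > 0)
    stop("constant variable(s): ", paste(const, collapse = ", "))
  m <- cor(as.matrix(climate), method = "spearman")
  structure(m, n = nrow(climate), class = c("spearman_matrix", "matrix"))
}

#' Largest subset of mutually weakly correlated variables
#'
#' Finds a maximum-cardinality subset of variables in which every pairwise
#' absolute Spearman correlation is below `threshold`. For 25 or fewer
#' variables the search is exact (maximum independent set of the conflict
#' graph); above that a greedy max-degree-removal heuristic is used. Ties
#' between equally large subsets are broken deterministically by
#' variable-name order. Variables named in `keep` are forced into the
#' subset (an error if they conflict with each other).
#'
#' @param cm a [spearman_matrix()] (any symmetric correlation matrix works).
#' @param threshold pairwise absolute-correlation ceiling (default 0.7).
#' @param keep character vector of variables forced into the subset.
#' @return Character vector of selected variable names, in name order.
#' @export
max_uncorrelated_subset <- function(cm, threshold = 0.7, keep = NULL) {
  vars <- colnames(cm)
  A <- abs(unclass(cm)) >= threshold
  diag(A) <- FALSE
  if (!is.null(keep)) {
    miss <- setdiff(keep, vars)
    if (length(miss) > 0) stop("unknown keep variable(s): ",
                               paste(miss, collapse = ", "))
    if (length(keep) > 1 && any(A[keep, keep]))
      stop("forced variables are mutually correlated at |rho| >= ", threshold)
    cand <- setdiff(vars, keep)
    cand <- cand[!apply(A[cand, keep, drop = FALSE], 1, any)]
  } else {
    keep <- character(0)
    cand <- vars
  }
  if (length(cand) == 0) return(sort(keep))
  sub <- A[cand, cand, drop = FALSE]
  sel <- if (length(vars) <= 25) exact_independent_set(sub)
  else greedy_independent_set(sub)
  out <- sort(c(keep, sel))
  stopifnot(!any(A[out, out]))  # post-hoc contract check
  out
}

# Exact maximum independent set via igraph; lexicographically smallest
# (by sorted names) among the maximum-size sets.
exact_independent_set <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  ivs <- igraph::largest_ivs(g)
  sets <- lapply(ivs, function(s) sort(colnames(A)[as.integer(s)]))
  keys <- vapply(sets, paste, character(1), collapse = "\r")
  sets[[order(keys)[1]]]
}

# Greedy: repeatedly drop the highest-degree conflicted variable
# (alphabetically last among ties, so earlier names survive).
greedy_independent_set <- function(A) {
  alive <- colnames(A)
  repeat {
    deg <- rowSums(A[alive, alive, drop = FALSE])
    if (all(deg == 0)) break
    worst <- alive[deg == max(deg)]
    alive <- setdiff(alive, sort(worst)[length(worst)])
  }
  sort(alive)
}

#' Ensemble cross-validated R-squared ranking of climate variables
#'
#' For each candidate variable, fits every method in `model_set` under
#' cross-validation and records the cross-validated R-squared; variables
#' are ranked by the mean R-squared across methods. This quantifies how
#' much of each variable's variation the assemblage data can explain,
#' which is the statistical leg of variable selection (ecological
#' credibility and ordination independence remain expert judgement).
#'
#' @param cal a [calibration_set].
#' @param variables character vector of climate variable names.
#' @param model_set list of [method_spec] objects (default: the eight
#'   standard methods; note NNET/ELM then need `hidden_units`).
#' @param h exclusion radius for the CV (default 0 = leave-one-out).
#' @param seed master seed for stochastic methods.
#' @return An object of class `variable_ranking`: data frame with one row
#'   per variable, per-method R-squared columns and `mean_r2`, sorted
#'   descending by `mean_r2` (name order on ties).
#' @export
ensemble_r2_ranking <- function(cal, variables, model_set = NULL, h = 0,
                                seed = NULL) {
  if (is.null(model_set))
    model_set <- lapply(METHOD_CODES, method_spec)
  if (inherits(model_set, "method_spec")) model_set <- list(model_set)
  stopifnot(length(model_set) > 0)
  miss <- setdiff(variables, climate_variables(cal))
  if (length(miss) > 0)
    stop("variable(s) not in calibration set: ", paste(miss, collapse = ", "))
  codes <- vapply(model_set, function(s) s$code, character(1))
  r2 <- matrix(NA_real_, length(variables), length(model_set),
               dimnames = list(variables, make.unique(codes)))
  for (v in variables) {
    for (j in seq_along(model_set)) {
      cv <- run_hblock_cv(cal, model_set[[j]], v, h = h, seed = seed)
      r2[v, j] <- cv$summary$r2
    }
  }
  out <- data.frame(variable = variables, r2, mean_r2 = rowMeans(r2),
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_r2, out$variable), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("variable_ranking", "data.frame"))
}
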