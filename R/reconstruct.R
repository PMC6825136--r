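#' Reconstruct palaeoclimate from a fossil sequence
#'
#' Aligns the fossil and calibration taxa (intersection, re-normalized to
#' 100), fits each requested calibration method on the full aligned
#' calibration set, and applies it to every fossil sample. The per-sample
#' squared-chord distance to the closest modern assemblage is recorded as
#' an analogue-quality diagnostic, and the row-wise median and inter-method
#' range are appended.
#'
#' @param fossil a [fossil_sequence].
#' @param cal a [calibration_set].
#' @param specs a [method_spec] or list of them.
#' @param response climate variable name to reconstruct.
#' @return An object of class `reconstruction_table`: data frame with
#'   `age_ka`, one column per method code, `best_analog`, `median` and
#'   `range`. Attribute `"align_report"` carries the taxon-alignment
#'   report.
#' @export
reconstruct <- function(fossil, cal, specs, response) {
  if (inherits(specs, "method_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "method_spec")))
  al <- align_taxa(cal, fossil)
  y <- climate_response(cal, response)
  preds <- list()
  for (spec in specs) {
    p <- tryCatch({
      fit <- fit_model(spec, al$cal_percent, y)
      as.numeric(predict(fit, al$fossil_percent))
    }, error = function(e) {
      warning(sprintf("%s reconstruction failed: %s", spec$code,
                      conditionMessage(e)))
      rep(NA_real_, nrow(al$fossil_percent))
    })
    preds[[spec$code]] <- p
  }
  M <- do.call(cbind, preds)
  sqrtP <- sqrt(al$cal_percent / 100)
  best_analog <- vapply(seq_len(nrow(al$fossil_percent)), function(i)
    min(sq_chord_to_rows(sqrtP, al$fossil_percent[i, ] / 100)), numeric(1))
  sm <- if (ncol(M) >= 2) multi_method_summary(M)
  else data.frame(median = M[, 1], range = ifelse(is.na(M[, 1]), NA_real_, 0))
  out <- data.frame(age_ka = fossil$ages, M, best_analog = best_analog,
                    median = sm$median, range = sm$range,
                    check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "align_report") <- al$report
  attr(out, "response") <- response
  attr(out, "methods") <- names(preds)
  class(out) <- c("reconstruction_table", "data.frame")
  out
}

#' Row-wise summary across reconstruction methods
#'
#' @param rt a `reconstruction_table` (its method columns are used) or a
#'   numeric matrix with one column per method.
#' @return Data frame with per-sample `median`, `min`, `max` and `range`,
#'   ignoring missing values; rows with no finite value give `NA`.
#' @export
multi_method_summary <- function(rt) {
  M <- if (inherits(rt, "reconstruction_table"))
    as.matrix(rt[, attr(rt, "methods"), drop = FALSE])
  else as.matrix(rt)
  if (ncol(M) < 2) stop("need at least 2 method columns")
  stat <- function(f) apply(M, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0) NA_real_ else f(r)
  })
  data.frame(median = stat(median), min = stat(min), max = stat(max),
             range = stat(function(r) diff(range(r))))
}

#' @export
print.reconstruction_table <- function(x, ...) {
  cat(sprintf("reconstruction of %s: %d samples, methods %s\n",
              attr(x, "response"), nrow(x),
              paste(attr(x, "methods"), collapse = ", ")))
  print.data.frame(head(as.data.frame(x), 5), digits = 4)
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}
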