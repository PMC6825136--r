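#' Site-by-taxon abundance table
#'
#' The basic container for pollen (or other microfossil) assemblage data:
#' a non-negative site x taxon matrix of abundances, either raw counts or
#' percentages. Percentages are the canonical storage unit throughout the
#' package (each row sums to 100); proportions (0--1) are derived internally
#' where a formula requires them.
#'
#' @param values numeric matrix, sites in rows, taxa in columns, all
#'   entries non-negative.
#' @param site_ids character vector of unique site identifiers; defaults to
#'   `rownames(values)`.
#' @param taxon_names character vector of unique taxon names; defaults to
#'   `colnames(values)`.
#' @param unit `"counts"` or `"percent"`. With `"percent"`, every row must
#'   sum to 100 within a relative tolerance of 1e-6.
#' @return An object of class `taxon_table`: a list with elements
#'   `site_ids`, `taxon_names`, `values` (dimnamed matrix) and `unit`.
#' @examples
#' tt <- taxon_table(matrix(c(30, 70, 25, 75), 2, byrow = TRUE),
#'                   site_ids = c("a", "b"),
#'                   taxon_names = c("Pinus", "Betula"), unit = "percent")
#' @export
taxon_table <- function(values, site_ids = rownames(values),
                        taxon_names = colnames(values),
                        unit = c("counts", "percent")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(site_ids)) site_ids <- paste0("site", seq_len(nrow(values)))
  if (is.null(taxon_names)) taxon_names <- paste0("taxon", seq_len(ncol(values)))
  site_ids <- as.character(site_ids)
  taxon_names <- as.character(taxon_names)
  if (length(site_ids) != nrow(values))
    stop("length(site_ids) must equal nrow(values)")
  if (length(taxon_names) != ncol(values))
    stop("length(taxon_names) must equal ncol(values)")
  if (anyDuplicated(site_ids))
    stop("duplicate site_ids: ",
         paste(unique(site_ids[duplicated(site_ids)]), collapse = ", "))
  if (anyDuplicated(taxon_names))
    stop("duplicate taxon_names: ",
         paste(unique(taxon_names[duplicated(taxon_names)]), collapse = ", "))
  if (anyNA(values)) stop("values must not contain NA")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative abundance at site '%s', taxon '%s'",
                 site_ids[neg[1, 1]], taxon_names[neg[1, 2]]))
  if (unit == "percent") {
    rs <- rowSums(values)
    bad <- which(abs(rs - 100) > 1e-6 * 100)
    if (length(bad) > 0)
      stop(sprintf("unit = 'percent' but row sum of site '%s' is %g, not 100",
                   site_ids[bad[1]], rs[bad[1]]))
  }
  dimnames(values) <- list(site_ids, taxon_names)
  structure(list(site_ids = site_ids, taxon_names = taxon_names,
                 values = values, unit = unit),
            class = "taxon_table")
}

#' @export
print.taxon_table <- function(x, ...) {
  cat(sprintf("taxon_table: %d sites x %d taxa (%s)\n",
              length(x$site_ids), length(x$taxon_names), x$unit))
  invisible(x)
}

#' @export
dim.taxon_table <- function(x) dim(x$values)

#' Rescale abundance rows to percentages
#'
#' Converts counts (or any non-negative abundances) to percentages by
#' rescaling each row to sum to 100. Idempotent: an already-percent table is
#' returned unchanged up to floating-point tolerance.
#'
#' @param table a [taxon_table].
#' @return A `taxon_table` with `unit = "percent"`.
#' @export
percent_normalize <- function(table) {
  stopifnot(inherits(table, "taxon_table"))
  rs <- rowSums(table$values)
  zero <- which(rs == 0)
  if (length(zero) > 0)
    stop("cannot percent-normalize site(s) with zero total abundance: ",
         paste(table$site_ids[zero], collapse = ", "))
  taxon_table(table$values * (100 / rs), site_ids = table$site_ids,
              taxon_names = table$taxon_names, unit = "percent")
}

#' Square-root transform of percentage data
#'
#' Element-wise square root of a percentage table, the standard variance
#' stabilization for compositional pollen data. Used by the weighted
#' averaging (WA) and WA-PLS calibration methods only; the other methods
#' take raw percentages.
#'
#' @param table a [taxon_table] with `unit = "percent"`, or a non-negative
#'   numeric matrix of percentages.
#' @return Numeric matrix of square-rooted percentages.
#' @export
sqrt_transform <- function(table) {
  m <- if (inherits(table, "taxon_table")) {
    if (table$unit != "percent")
      stop("sqrt_transform expects percentage data; call percent_normalize() first")
    table$values
  } else as.matrix(table)
  if (anyNA(m) || any(m < 0)) stop("sqrt_transform: input must be non-negative")
  sqrt(m)
}
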