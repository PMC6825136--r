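#' Modern pollen-climate calibration set
#'
#' Bundles the three aligned components of a modern training dataset: the
#' site x taxon percentage table, per-site geography (longitude, latitude,
#' elevation) and per-site climate values. The three components must share
#' an identical `site_id` set and ordering.
#'
#' @param taxa a [taxon_table] with `unit = "percent"`.
#' @param meta data frame with columns `site_id`, `lon`, `lat`, `elevation`.
#' @param climate data frame with a `site_id` column followed by one numeric
#'   column per climate variable (all values finite).
#' @return An object of class `calibration_set`.
#' @export
calibration_set <- function(taxa, meta, climate) {
  stopifnot(inherits(taxa, "taxon_table"))
  if (taxa$unit != "percent")
    stop("calibration_set taxa must be in percent; call percent_normalize()")
  meta <- validate_site_meta(meta)
  climate <- validate_climate(climate)
  ids <- taxa$site_ids
  if (length(ids) < 2) stop("calibration_set needs at least 2 sites")
  if (length(taxa$taxon_names) < 2) stop("calibration_set needs at least 2 taxa")
  if (!identical(ids, as.character(meta$site_id)))
    stop("site_id set/order of meta does not match taxa")
  if (!identical(ids, as.character(climate$site_id)))
    stop("site_id set/order of climate does not match taxa")
  structure(list(taxa = taxa, meta = meta, climate = climate),
            class = "calibration_set")
}

validate_site_meta <- function(meta) {
  meta <- as.data.frame(meta)
  need <- c("site_id", "lon", "lat", "elevation")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0)
    stop("site metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$site_id))
    stop("duplicate site_id in metadata: ",
         paste(unique(meta$site_id[duplicated(meta$site_id)]), collapse = ", "))
  meta$lon <- normalize_lon(as.numeric(meta$lon))
  meta$lat <- as.numeric(meta$lat)
  meta$elevation <- as.numeric(meta$elevation)
  to_lonlat_matrix(meta[, c("lon", "lat")])  # bounds check
  meta
}

# Wrap longitudes into [-180, 180].
normalize_lon <- function(lon) {
  lon <- ((lon + 180) %% 360) - 180
  lon[lon == -180] <- 180
  lon
}

validate_climate <- function(climate) {
  climate <- as.data.frame(climate)
  if (!"site_id" %in% names(climate))
    stop("climate table is missing the site_id column")
  vars <- setdiff(names(climate), "site_id")
  if (length(vars) == 0) stop("climate table has no variable columns")
  for (v in vars) {
    if (!is.numeric(climate[[v]]) || !all(is.finite(climate[[v]])))
      stop(sprintf("climate variable '%s' has non-finite or non-numeric values", v))
    climate[[v]] <- as.numeric(climate[[v]])
  }
  climate
}

#' @export
print.calibration_set <- function(x, ...) {
  cat(sprintf("calibration_set: %d sites, %d taxa, climate variables: %s\n",
              length(x$taxa$site_ids), length(x$taxa$taxon_names),
              paste(setdiff(names(x$climate), "site_id"), collapse = ", ")))
  invisible(x)
}

#' Climate variable names of a calibration set
#' @param cal a [calibration_set].
#' @return Character vector of variable names.
#' @export
climate_variables <- function(cal) setdiff(names(cal$climate), "site_id")

#' Extract the response vector for one climate variable
#' @param cal a [calibration_set].
#' @param response name of the climate variable.
#' @return Numeric vector in site order.
#' @export
climate_response <- function(cal, response) {
  if (!response %in% climate_variables(cal))
    stop(sprintf("response variable '%s' not found; available: %s", response,
                 paste(climate_variables(cal), collapse = ", ")))
  cal$climate[[response]]
}

#' Dated fossil pollen sequence from a single site
#'
#' @param taxa a [taxon_table] (`unit = "percent"`), one row per sample.
#' @param ages numeric vector of sample ages in cal ka, strictly monotone
#'   (increasing or decreasing).
#' @param site single-row data frame (or list) with `site_id`, `lon`, `lat`,
#'   `elevation` for the fossil site.
#' @return An object of class `fossil_sequence` with an `ages_increasing`
#'   flag recording the declared age direction.
#' @export
fossil_sequence <- function(taxa, ages, site) {
  stopifnot(inherits(taxa, "taxon_table"))
  if (taxa$unit != "percent")
    stop("fossil_sequence taxa must be in percent")
  ages <- as.numeric(ages)
  if (length(ages) != nrow(taxa$values))
    stop("length(ages) must equal the number of fossil samples")
  d <- diff(ages)
  if (length(d) > 0 && !(all(d > 0) || all(d < 0)))
    stop("ages must be strictly monotone (increasing or decreasing)")
  site <- validate_site_meta(as.data.frame(site))
  if (nrow(site) != 1) stop("fossil_sequence takes exactly one site record")
  structure(list(taxa = taxa, ages = ages, site = site,
                 ages_increasing = length(d) == 0 || all(d > 0)),
            class = "fossil_sequence")
}

#' @export
print.fossil_sequence <- function(x, ...) {
  cat(sprintf("fossil_sequence '%s': %d samples, %.2f-%.2f cal ka, %d taxa\n",
              x$site$site_id, length(x$ages), min(x$ages), max(x$ages),
              length(x$taxa$taxon_names)))
  invisible(x)
}

#' Load a calibration set from CSV files
#'
#' Reads the three standard CSV components (taxa, site metadata, climate),
#' inner-joins them on `site_id` keeping the taxa-file row order, drops
#' unmatched sites with a warning, and percent-normalizes abundances.
#'
#' @param taxa_path CSV with a `site_id` column followed by taxon columns
#'   (counts or percentages).
#' @param meta_path CSV with columns `site_id`, `lon`, `lat`, `elevation`.
#' @param climate_path CSV with `site_id` plus one column per climate variable.
#' @return A [calibration_set]; attribute `"dropped"` lists site_ids present
#'   in the taxa file but absent from meta or climate.
#' @export
load_calibration <- function(taxa_path, meta_path, climate_path) {
  taxa_df <- read.csv(taxa_path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- read.csv(meta_path, check.names = FALSE, stringsAsFactors = FALSE)
  climate <- read.csv(climate_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"site_id" %in% names(taxa_df))
    stop("taxa file must have a site_id column")
  if (anyDuplicated(taxa_df$site_id))
    stop("duplicate site_id in taxa file: ",
         paste(unique(taxa_df$site_id[duplicated(taxa_df$site_id)]),
               collapse = ", "))
  meta <- validate_site_meta(meta)
  climate <- validate_climate(climate)
  ids <- as.character(taxa_df$site_id)
  keep <- ids %in% meta$site_id & ids %in% climate$site_id
  dropped <- ids[!keep]
  if (length(dropped) > 0)
    warning("dropping site(s) absent from meta or climate: ",
            paste(dropped, collapse = ", "))
  ids <- ids[keep]
  if (length(ids) == 0) stop("no sites shared between taxa, meta and climate files")
  vals <- as.matrix(taxa_df[keep, setdiff(names(taxa_df), "site_id"), drop = FALSE])
  tt <- percent_normalize(taxon_table(vals, site_ids = ids, unit = "counts"))
  cal <- calibration_set(
    tt,
    meta[match(ids, meta$site_id), , drop = FALSE],
    climate[match(ids, climate$site_id), , drop = FALSE]
  )
  attr(cal, "dropped") <- dropped
  cal
}

#' Save a calibration set to CSV files
#'
#' Writes the three-component CSV layout read back by [load_calibration()].
#' Numeric values are written with full double precision (`%.17g`) so a
#' save/load round trip reproduces the object exactly.
#'
#' @param cal a [calibration_set].
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
save_calibration <- function(cal, dir) {
  stopifnot(inherits(cal, "calibration_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("taxa.csv", "meta.csv", "climate.csv"))
  taxa_df <- data.frame(site_id = cal$taxa$site_ids, check.names = FALSE)
  taxa_df <- cbind(taxa_df, as.data.frame(cal$taxa$values, check.names = FALSE))
  write_csv_full(taxa_df, paths[1])
  write_csv_full(cal$meta, paths[2])
  write_csv_full(cal$climate, paths[3])
  invisible(paths)
}

# write.csv with round-trip-exact formatting of doubles
write_csv_full <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Restrict calibration and fossil data to their shared taxa
#'
#' Both matrices are restricted to the intersection of their taxon lists
#' (in calibration order), and rows are re-normalized to sum to 100. The
#' attached report records the taxa dropped from each side and the
#' percentage mass each sample lost in the restriction.
#'
#' @param cal a [calibration_set].
#' @param fossil a [fossil_sequence].
#' @return List with elements `cal_percent` and `fossil_percent` (aligned
#'   percentage matrices), `taxon_names`, and `report` (dropped taxa and
#'   per-sample mass lost).
#' @export
align_taxa <- function(cal, fossil) {
  stopifnot(inherits(cal, "calibration_set"), inherits(fossil, "fossil_sequence"))
  shared <- intersect(cal$taxa$taxon_names, fossil$taxa$taxon_names)
  if (length(shared) == 0)
    stop("calibration and fossil data share no taxa")
  renorm <- function(m, who) {
    rs <- rowSums(m)
    zero <- which(rs == 0)
    if (length(zero) > 0)
      stop(sprintf("%s sample(s) retain no shared taxa: %s", who,
                   paste(rownames(m)[zero], collapse = ", ")))
    list(m = m * (100 / rs), lost = 100 - rs)
  }
  cal_r <- renorm(cal$taxa$values[, shared, drop = FALSE], "calibration")
  fos_r <- renorm(fossil$taxa$values[, shared, drop = FALSE], "fossil")
  list(
    cal_percent = cal_r$m,
    fossil_percent = fos_r$m,
    taxon_names = shared,
    report = list(
      dropped_from_cal = setdiff(cal$taxa$taxon_names, shared),
      dropped_from_fossil = setdiff(fossil$taxa$taxon_names, shared),
      cal_mass_lost = setNames(cal_r$lost, cal$taxa$site_ids),
      fossil_mass_lost = setNames(fos_r$lost, rownames(fossil$taxa$values))
    )
  )
}

#' Validate a CSV dataset directory
#'
#' Checks the standard dataset layout (`taxa.csv`, `meta.csv`,
#' `climate.csv`, optionally `fossil_*.csv`) against all container
#' invariants and returns a human-readable report.
#'
#' @param dir dataset directory.
#' @return Character vector of report lines (invisibly printed).
#' @export
validate_dataset <- function(dir) {
  lines <- character()
  cal <- load_calibration(file.path(dir, "taxa.csv"), file.path(dir, "meta.csv"),
                          file.path(dir, "climate.csv"))
  lines <- c(lines, sprintf("calibration: %d sites, %d taxa, variables: %s",
                            length(cal$taxa$site_ids), length(cal$taxa$taxon_names),
                            paste(climate_variables(cal), collapse = ", ")))
  dropped <- attr(cal, "dropped")
  if (length(dropped) > 0)
    lines <- c(lines, paste("dropped (unmatched) sites:", paste(dropped, collapse = ", ")))
  for (f in list.files(dir, pattern = "^fossil.*\\.csv$", full.names = TRUE)) {
    fos <- load_fossil(f, site = cal$meta[1, ])
    lines <- c(lines, sprintf("%s: %d samples, %.2f-%.2f cal ka", basename(f),
                              length(fos$ages), min(fos$ages), max(fos$ages)))
  }
  lines <- c(lines, "all invariants satisfied")
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Load a fossil sequence from CSV
#'
#' @param path CSV with columns `sample_id`, `age_ka`, then taxon columns.
#' @param site single-row site metadata for the fossil site (`site_id`,
#'   `lon`, `lat`, `elevation`).
#' @return A [fossil_sequence].
#' @export
load_fossil <- function(path, site) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "age_ka")
  if (!all(need %in% names(df)))
    stop("fossil file must have sample_id and age_ka columns")
  vals <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
  tt <- percent_normalize(taxon_table(vals, site_ids = as.character(df$sample_id),
                                      unit = "counts"))
  fossil_sequence(tt, df$age_ka, site)
}

#' Save a fossil sequence to CSV
#' @param fossil a [fossil_sequence].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
save_fossil <- function(fossil, path) {
  df <- data.frame(sample_id = fossil$taxa$site_ids, age_ka = fossil$ages,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(fossil$taxa$values, check.names = FALSE))
  write_csv_full(df, path)
  invisible(path)
}
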