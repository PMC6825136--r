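#' Configuration for the synthetic pollen-climate generator
#'
#' The generator emulates the statistical structure that pollen-climate
#' calibration analyses assume: two spatially autocorrelated climate
#' surfaces (a primary variable and a weakly correlated secondary one),
#' unimodal (Gaussian) taxon responses to both, and multinomial
#' compositional count noise. The defaults give a desk-scale dataset
#' (300 sites, 30 taxa, 400-km spatial range, cross-correlation 0.05,
#' pollen sum 300 per sample) small enough for minutes-scale CV series.
#'
#' @param n_sites number of calibration sites.
#' @param extent_km width/height of the (square) study region in km.
#' @param ref_lon,ref_lat centre of the region in decimal degrees.
#' @param var_names names of the two climate variables.
#' @param range_km spatial autocorrelation range (circular covariance) of
#'   each variable, km; length 2.
#' @param nugget nugget fraction (0--1) of each climate field's variance.
#' @param clim_mean,clim_sd affine mapping of the unit-variance fields to
#'   climate units; length 2 each (defaults emulate July and January air
#'   temperature in degC).
#' @param rho target cross-correlation between the two variables, induced
#'   by shared-component mixing.
#' @param n_taxa number of taxa.
#' @param prop_primary,prop_secondary fractions of taxa responding only to
#'   variable 1 and (mainly) to variable 2; the rest respond to both.
#' @param opt_spread taxon optima are drawn uniformly over
#'   `clim_mean +- opt_spread * clim_sd`; the default 2.5 keeps optima
#'   inside the sampled gradient, the regime weighted averaging assumes.
#' @param tol_frac Gaussian niche breadth, as a fraction of the six-sigma
#'   climate gradient; length-2 range from which tolerances are drawn. The
#'   default 0.1--0.2 spans the gradient with 5--10 niche breadths.
#' @param count_depth pollen count sum per sample (`Inf` for the noiseless
#'   limit where percentages equal normalized expected abundances).
#' @param seed integer seed; the generator is a deterministic function of
#'   the configuration (seed included).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sites = 300, extent_km = 2000,
                             ref_lon = 10, ref_lat = 50,
                             var_names = c("T_jul", "T_jan"),
                             range_km = c(400, 400), nugget = c(0.05, 0.05),
                             clim_mean = c(15, -8), clim_sd = c(2.8, 6),
                             rho = 0.05, n_taxa = 30,
                             prop_primary = 0.5, prop_secondary = 0.2,
                             opt_spread = 2.5, tol_frac = c(0.1, 0.2),
                             count_depth = 300, seed = 1) {
  stopifnot(n_sites >= 2, n_taxa >= 2, all(range_km > 0),
            abs(rho) <= 1, count_depth >= 50, opt_spread > 0,
            all(tol_frac > 0), prop_primary + prop_secondary <= 1)
  structure(list(n_sites = n_sites, extent_km = extent_km,
                 ref_lon = ref_lon, ref_lat = ref_lat,
                 var_names = var_names, range_km = range_km, nugget = nugget,
                 clim_mean = clim_mean, clim_sd = clim_sd, rho = rho,
                 n_taxa = n_taxa, prop_primary = prop_primary,
                 prop_secondary = prop_secondary, opt_spread = opt_spread,
                 tol_frac = tol_frac,
                 count_depth = count_depth, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Circular (2-D analogue of spherical) correlation function, unit variance.
circular_cov <- function(d, range_km) {
  u <- pmin(d / range_km, 1)
  (2 / pi) * (acos(u) - u * sqrt(1 - u^2))
}

#' Generate site coordinates and spatially autocorrelated climate surfaces
#'
#' Sites are placed uniformly over the study region; each climate variable
#' is a zero-mean unit-variance Gaussian process with circular covariance
#' of the configured range (computed from great-circle distances of the
#' final lon/lat coordinates, so the planted range is exact in the metric
#' the variogram estimator uses), affinely mapped to climate units. The
#' second variable shares a component with the first to hit the target
#' cross-correlation.
#'
#' @param config a [synthetic_config].
#' @return List with `meta` (site metadata data frame) and `climate`
#'   (data frame `site_id` + the two variables); attribute `"truth"` holds
#'   the standardized fields.
#' @export
gen_climate_surface <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_rng_seed(config$seed, {
    n <- config$n_sites
    xy <- matrix(runif(2 * n, 0, config$extent_km), n, 2)
    km_per_deg <- pi / 180 * .EARTH_RADIUS_KM
    lat <- config$ref_lat + (xy[, 2] - config$extent_km / 2) / km_per_deg
    lon <- config$ref_lon + (xy[, 1] - config$extent_km / 2) /
      (km_per_deg * cos(config$ref_lat * pi / 180))
    D <- great_circle_matrix(cbind(lon, lat))
    draw_field <- function(range_km, nugget) {
      C <- (1 - nugget) * circular_cov(D, range_km)
      diag(C) <- 1 + 1e-8
      drop(t(chol(C)) %*% rnorm(n))
    }
    z1 <- draw_field(config$range_km[1], config$nugget[1])
    z2i <- draw_field(config$range_km[2], config$nugget[2])
    # mix against the in-sample-orthogonalized second field, so the sample
    # correlation hits the target rather than only its expectation (spatial
    # autocorrelation leaves far fewer effective replicates than n_sites)
    z1s <- (z1 - mean(z1)) / sd(z1)
    z2p <- z2i - z1s * sum(z2i * z1s) / sum(z1s^2)
    z2p <- (z2p - mean(z2p)) / sd(z2p)
    z2 <- config$rho * z1s + sqrt(1 - config$rho^2) * z2p
    meta <- data.frame(site_id = sprintf("S%03d", seq_len(n)),
                       lon = lon, lat = lat, elevation = 0,
                       stringsAsFactors = FALSE)
    climate <- data.frame(site_id = meta$site_id,
                          stringsAsFactors = FALSE)
    climate[[config$var_names[1]]] <- config$clim_mean[1] + config$clim_sd[1] * z1
    climate[[config$var_names[2]]] <- config$clim_mean[2] + config$clim_sd[2] * z2
    out <- list(meta = meta, climate = climate)
    attr(out, "truth") <- list(z1 = z1, z2 = z2, xy_km = xy)
    out
  })
}

# Per-taxon Gaussian response parameters, drawn deterministically from the
# config seed so calibration and fossil data share one taxon community.
gen_taxon_params <- function(config) {
  with_rng_seed(config$seed + 1L, {
    nt <- config$n_taxa
    n1 <- round(config$prop_primary * nt)
    n2 <- round(config$prop_secondary * nt)
    role <- c(rep("primary", n1), rep("secondary", n2),
              rep("both", nt - n1 - n2))
    # optima inside the sampled gradient; tolerances relative to the
    # six-sigma gradient span
    sp <- config$opt_spread
    g1 <- config$clim_mean[1] + c(-sp, sp) * config$clim_sd[1]
    g2 <- config$clim_mean[2] + c(-sp, sp) * config$clim_sd[2]
    span1 <- 6 * config$clim_sd[1]
    span2 <- 6 * config$clim_sd[2]
    tolf <- runif(nt, config$tol_frac[1], config$tol_frac[2])
    tolf2 <- runif(nt, config$tol_frac[1], config$tol_frac[2])
    wide <- 1e6  # effectively flat response
    data.frame(
      taxon = sprintf("T%02d", seq_len(nt)),
      role = role,
      opt1 = runif(nt, g1[1], g1[2]),
      tol1 = ifelse(role == "secondary", wide, tolf * span1),
      opt2 = runif(nt, g2[1], g2[2]),
      tol2 = ifelse(role == "primary", wide, tolf2 * span2),
      max_abundance = runif(nt, 0.3, 1),
      stringsAsFactors = FALSE
    )
  })
}

# Expected (unnormalized) abundance matrix for sites with climates x1, x2.
expected_abundance <- function(x1, x2, tp) {
  E <- sapply(seq_len(nrow(tp)), function(k)
    tp$max_abundance[k] *
      exp(-(x1 - tp$opt1[k])^2 / (2 * tp$tol1[k]^2)) *
      exp(-(x2 - tp$opt2[k])^2 / (2 * tp$tol2[k]^2)))
  E <- matrix(E, nrow = length(x1))
  colnames(E) <- tp$taxon
  E
}

#' Generate a taxon percentage table from site climates
#'
#' Expected abundances follow bivariate Gaussian (unimodal) responses to
#' the two climate variables; counts are drawn multinomially with
#' `count_depth` grains per sample and converted to percentages. With
#' `count_depth = Inf` the percentages are the exact normalized
#' expectations (noiseless limit).
#'
#' @param climate data frame with the two configured climate variables
#'   (as from [gen_climate_surface()]).
#' @param config a [synthetic_config].
#' @param taxon_params optional taxon parameter table (defaults to the
#'   community drawn deterministically from the config seed).
#' @param seed_offset RNG stream offset for the count noise (internal).
#' @return A [taxon_table] in percent; attribute `"taxon_params"` carries
#'   the response parameters.
#' @export
gen_taxa <- function(climate, config, taxon_params = NULL, seed_offset = 2L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(taxon_params)) taxon_params <- gen_taxon_params(config)
  x1 <- climate[[config$var_names[1]]]
  x2 <- climate[[config$var_names[2]]]
  E <- expected_abundance(x1, x2, taxon_params)
  rs <- rowSums(E)
  if (any(rs <= 1e-300))
    stop("all taxon expectations are zero at site(s) ",
         paste(which(rs <= 1e-300), collapse = ", "))
  probs <- E / rs
  vals <- if (is.infinite(config$count_depth)) {
    100 * probs
  } else {
    with_rng_seed(config$seed + seed_offset, {
      counts <- t(apply(probs, 1, function(p)
        rmultinom(1, config$count_depth, p)[, 1]))
      100 * counts / rowSums(counts)
    })
  }
  ids <- if (!is.null(climate$site_id)) as.character(climate$site_id)
  else sprintf("S%03d", seq_along(x1))
  tt <- taxon_table(vals, site_ids = ids, taxon_names = taxon_params$taxon,
                    unit = "percent")
  attr(tt, "taxon_params") <- taxon_params
  tt
}

#' Generate a complete synthetic calibration set
#'
#' Combines [gen_climate_surface()] and [gen_taxa()]; any site whose
#' expected abundances vanish everywhere (possible with very narrow
#' niches) has its location redrawn, up to 10 times.
#'
#' @param config a [synthetic_config].
#' @return A [calibration_set]; attribute `"truth"` holds the planted
#'   taxon parameters, standardized climate fields and the configuration.
#' @export
gen_calibration <- function(config) {
  surf <- gen_climate_surface(config)
  tp <- gen_taxon_params(config)
  tries <- 0
  repeat {
    tt <- tryCatch(gen_taxa(surf$climate, config, taxon_params = tp),
                   error = function(e) e)
    if (!inherits(tt, "error")) break
    tries <- tries + 1
    if (tries > 10) stop("could not place all sites on the response surface")
    warning("redrawing site locations with zero total expected abundance")
    cfg2 <- config; cfg2$seed <- config$seed + 100L + tries
    surf <- gen_climate_surface(cfg2)
  }
  cal <- calibration_set(tt, surf$meta, surf$climate)
  attr(cal, "truth") <- c(attr(surf, "truth"),
                          list(taxon_params = tp, config = config))
  cal
}

#' Generate a synthetic fossil sequence from a climate trajectory
#'
#' Fossil samples are generated from the trajectory climates with the same
#' taxon response model (and taxon community) as [gen_calibration()] under
#' the same configuration, so reconstructions can be scored against the
#' known trajectory.
#'
#' @param trajectory data frame with columns `age_ka` and the two
#'   configured climate variables; ages strictly monotone.
#' @param config a [synthetic_config].
#' @param site single-row site metadata for the fossil site (defaults to
#'   the region centre).
#' @return A [fossil_sequence]; attribute `"truth"` holds the trajectory.
#' @export
gen_fossil <- function(trajectory, config, site = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  need <- c("age_ka", config$var_names)
  miss <- setdiff(need, names(trajectory))
  if (length(miss) > 0)
    stop("trajectory is missing column(s): ", paste(miss, collapse = ", "))
  climate <- trajectory[, config$var_names, drop = FALSE]
  climate$site_id <- sprintf("F%03d", seq_len(nrow(trajectory)))
  tt <- gen_taxa(climate, config, seed_offset = 3L)
  if (is.null(site))
    site <- data.frame(site_id = "fossil_site", lon = config$ref_lon,
                       lat = config$ref_lat, elevation = 0,
                       stringsAsFactors = FALSE)
  fos <- fossil_sequence(tt, trajectory$age_ka, site)
  attr(fos, "truth") <- list(trajectory = trajectory, config = config)
  fos
}
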