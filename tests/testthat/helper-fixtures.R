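# Shared fixtures, built in code. Synthetic datasets are memoised so the
# heavier generator calls run once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A tiny handmade calibration set: 5 sites, 4 taxa, two climate variables.
toy_cal <- function() {
  vals <- matrix(c(40, 30, 20, 10,
                   10, 50, 30, 10,
                   25, 25, 25, 25,
                   60, 10, 10, 20,
                   5, 15, 40, 40), 5, 4, byrow = TRUE,
                 dimnames = list(NULL, c("Pinus", "Betula", "Quercus", "Alnus")))
  tt <- taxon_table(vals, site_ids = paste0("s", 1:5), unit = "percent")
  meta <- data.frame(site_id = paste0("s", 1:5),
                     lon = c(10, 11, 12, 13, 14),
                     lat = c(50, 50.5, 51, 51.5, 52), elevation = 0)
  climate <- data.frame(site_id = paste0("s", 1:5),
                        T_jul = c(10, 12, 14, 16, 18),
                        T_jan = c(-12, -9, -6, -3, 0))
  calibration_set(tt, meta, climate)
}

# Default-condition synthetic calibration sets, memoised.
cal_default_120 <- function()
  cached("cal120", gen_calibration(synthetic_config(n_sites = 120, seed = 42)))

cal_default_100 <- function()
  cached("cal100", gen_calibration(synthetic_config(n_sites = 100, seed = 42)))

cal_default_200 <- function()
  cached("cal200", gen_calibration(synthetic_config(n_sites = 200, seed = 11)))

# Noiseless, primary-variable-only community (for recovery oracles).
cal_noiseless_primary <- function(seed = 3)
  cached(paste0("calN", seed),
         gen_calibration(synthetic_config(n_sites = 300, count_depth = Inf,
                                          prop_primary = 1, prop_secondary = 0,
                                          seed = seed)))

# Random percent matrix with row sums 100.
random_percent <- function(n, m, seed = 1) {
  set.seed(seed)
  v <- matrix(runif(n * m), n, m,
              dimnames = list(paste0("s", seq_len(n)), paste0("t", seq_len(m))))
  100 * v / rowSums(v)
}
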