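test_that("taxon_table enforces its invariants", {
  expect_error(taxon_table(matrix(c(-1, 2, 3, 4), 2,
                                  dimnames = list(NULL, c("a", "b")))),
               "negative abundance")
  expect_error(taxon_table(matrix(1, 2, 2), site_ids = c("x", "x"),
                           taxon_names = c("a", "b")), "duplicate site_ids")
  expect_error(taxon_table(matrix(c(30, 60, 40, 60), 2), unit = "percent"),
               "row sum")
  tt <- taxon_table(matrix(c(30, 70, 25, 75), 2, byrow = TRUE,
                           dimnames = list(c("a", "b"), c("P", "B"))),
                    unit = "percent")
  expect_s3_class(tt, "taxon_table")
  expect_equal(dim(tt), c(2L, 2L))
})

test_that("percent_normalize rescales rows to 100 and is idempotent", {
  tt <- taxon_table(matrix(c(1, 1, 2), 1, dimnames = list("s1", c("a", "b", "c"))))
  pn <- percent_normalize(tt)
  expect_equal(unname(pn$values[1, ]), c(25, 25, 50))

  set.seed(4)
  rand <- taxon_table(matrix(runif(60), 10, 6,
                             dimnames = list(NULL, paste0("t", 1:6))))
  pn <- percent_normalize(rand)
  expect_true(all(abs(rowSums(pn$values) - 100) < 1e-9))
  again <- percent_normalize(pn)
  expect_equal(again$values, pn$values)

  zr <- taxon_table(matrix(c(0, 0, 1, 2), 2, byrow = TRUE,
                           dimnames = list(c("empty", "ok"), c("a", "b"))))
  expect_error(percent_normalize(zr), "empty")
})

test_that("sqrt_transform evaluates element-wise on percentages", {
  tt <- taxon_table(matrix(c(0, 100, 25, 75), 2, byrow = TRUE,
                           dimnames = list(NULL, c("a", "b"))),
                    unit = "percent")
  s <- sqrt_transform(tt)
  expect_equal(unname(s[1, ]), c(0, 10))
  expect_equal(unname(s[2, ]), c(5, 8.660254037844387), tolerance = 1e-12)
  counts <- taxon_table(matrix(1:4, 2, dimnames = list(NULL, c("a", "b"))))
  expect_error(sqrt_transform(counts), "percent")
  expect_error(sqrt_transform(matrix(-1)), "non-negative")
})

test_that("great_circle_km matches closed forms and an independent oracle", {
  expect_equal(great_circle_km(c(12, 47), c(12, 47)), 0)
  expect_equal(great_circle_km(c(0, 0), c(180, 0)), pi * 6371.0088,
               tolerance = 1e-10)
  expect_equal(great_circle_km(c(25, 60), c(26, 60)), 55.6, tolerance = 0.2 / 55)
  # independent haversine implementation (geosphere), same sphere radius
  set.seed(9)
  pts <- cbind(runif(25, -180, 180), runif(25, -85, 85))
  ours <- great_circle_km(pts[1:24, ], pts[2:25, ])
  ref <- geosphere::distHaversine(pts[1:24, ], pts[2:25, ], r = 6371008.8) / 1000
  expect_equal(ours, ref, tolerance = 1e-10)
  expect_error(great_circle_km(c(200, 0), c(0, 0)), "longitude")
  expect_error(great_circle_km(c(0, 95), c(0, 0)), "latitude")
})

test_that("great-circle distance is symmetric and satisfies the triangle inequality", {
  set.seed(31)
  for (i in 1:50) {
    p <- cbind(runif(3, -180, 180), runif(3, -90, 90))
    dab <- great_circle_km(p[1, ], p[2, ])
    dba <- great_circle_km(p[2, ], p[1, ])
    dbc <- great_circle_km(p[2, ], p[3, ])
    dac <- great_circle_km(p[1, ], p[3, ])
    expect_equal(dab, dba, tolerance = 1e-12)
    expect_lte(dac, dab + dbc + 1e-6)
  }
  D <- great_circle_matrix(cbind(runif(12, -30, 30), runif(12, 30, 60)))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
})

test_that("bilinear climate extraction honours cell centres, midpoints and the lapse rate", {
  lon <- c(10, 11, 12); lat <- c(50, 51)
  val <- matrix(c(5, 6, 7,
                  8, 9, 10), 2, 3, byrow = TRUE)
  elev <- matrix(c(100, 200, 300,
                   400, 500, 600), 2, 3, byrow = TRUE)
  g <- climate_grid(lon, lat, val, elev)
  # exactly at a cell centre, site elevation equal to cell elevation
  expect_equal(extract_climate(g, list(lon = 11, lat = 50, elevation = 200)), 6)
  # midpoint of two equal-valued cells
  g2 <- climate_grid(lon, lat, matrix(4, 2, 3), matrix(0, 2, 3))
  expect_equal(extract_climate(g2, list(lon = 10.5, lat = 50, elevation = 0)), 4)
  # 1000 m above the interpolated surface: minus one lapse rate
  expect_equal(extract_climate(g, list(lon = 11, lat = 50, elevation = 1200)),
               6 - 6.4)
  expect_equal(extract_climate(g, list(lon = 11, lat = 50, elevation = 1200),
                               apply_lapse = FALSE), 6)
  expect_error(extract_climate(g, list(lon = 20, lat = 50, elevation = 0)),
               "outside")
})

test_that("constant grids interpolate to the constant and nodata cells drop out", {
  lon <- seq(0, 4); lat <- seq(40, 44)
  g <- climate_grid(lon, lat, matrix(7.5, 5, 5), matrix(0, 5, 5))
  set.seed(2)
  for (i in 1:20) {
    s <- list(lon = runif(1, 0, 4), lat = runif(1, 40, 44), elevation = 0)
    expect_equal(extract_climate(g, s, apply_lapse = FALSE), 7.5)
  }
  val <- matrix(7.5, 5, 5); val[1, 1] <- -9999
  gn <- climate_grid(lon, lat, val, matrix(0, 5, 5), nodata = -9999)
  expect_equal(extract_climate(gn, list(lon = 0.3, lat = 40.3, elevation = 0),
                               apply_lapse = FALSE), 7.5)
  all_bad <- climate_grid(c(0, 1), c(40, 41), matrix(-9999, 2, 2),
                          matrix(0, 2, 2), nodata = -9999)
  expect_true(is.na(extract_climate(all_bad,
                                    list(lon = 0.5, lat = 40.5, elevation = 0))))
})

test_that("ESRI ASCII grids round-trip through the reader", {
  asc <- c("ncols 3", "nrows 2", "xllcorner 9.5", "yllcorner 49.5",
           "cellsize 1.0", "NODATA_value -9999",
           "7 8 9", "4 5 -9999")
  f <- tempfile(fileext = ".asc")
  writeLines(asc, f)
  g <- read_asc(f)
  expect_equal(g$lon, c(10, 11, 12))
  expect_equal(g$lat, c(50, 51))
  # first data line is the northern row
  expect_equal(g$values[2, ], c(7, 8, 9))
  expect_equal(g$values[1, ], c(4, 5, -9999))
  expect_equal(g$nodata, -9999)
})

test_that("load_calibration joins on site_id, drops unmatched sites, normalizes", {
  dir <- tempfile(); dir.create(dir)
  write.csv(data.frame(site_id = c("a", "b", "c"), Pinus = c(10, 20, 5),
                       Betula = c(30, 20, 5)),
            file.path(dir, "taxa.csv"), row.names = FALSE)
  write.csv(data.frame(site_id = c("b", "a"), lon = c(11, 10),
                       lat = c(51, 50), elevation = c(0, 0)),
            file.path(dir, "meta.csv"), row.names = FALSE)
  write.csv(data.frame(site_id = c("a", "b", "c"), T_jul = c(10, 12, 14)),
            file.path(dir, "climate.csv"), row.names = FALSE)
  expect_warning(
    cal <- load_calibration(file.path(dir, "taxa.csv"), file.path(dir, "meta.csv"),
                            file.path(dir, "climate.csv")),
    "dropping")
  expect_equal(cal$taxa$site_ids, c("a", "b"))  # taxa-file order kept
  expect_equal(attr(cal, "dropped"), "c")
  expect_equal(unname(cal$taxa$values["a", ]), c(25, 75))
  expect_equal(cal$climate$T_jul, c(10, 12))
})

test_that("save/load round-trips a calibration set exactly", {
  cal <- toy_cal()
  dir <- tempfile()
  save_calibration(cal, dir)
  cal2 <- load_calibration(file.path(dir, "taxa.csv"), file.path(dir, "meta.csv"),
                           file.path(dir, "climate.csv"))
  expect_identical(cal2$taxa$values, cal$taxa$values)
  expect_identical(cal2$climate$T_jul, cal$climate$T_jul)
  expect_identical(cal2$meta$lon, cal$meta$lon)
  # and a second round trip is also an identity
  dir2 <- tempfile()
  save_calibration(cal2, dir2)
  cal3 <- load_calibration(file.path(dir2, "taxa.csv"), file.path(dir2, "meta.csv"),
                           file.path(dir2, "climate.csv"))
  expect_identical(cal3$taxa$values, cal$taxa$values)
})

test_that("align_taxa restricts to shared taxa and reports lost mass", {
  cal <- toy_cal()
  # fossil with one extra taxon at 10% in one sample, missing Alnus
  fvals <- matrix(c(40, 30, 20, 10,
                    50, 30, 20, 0), 2, 4, byrow = TRUE,
                  dimnames = list(NULL, c("Pinus", "Betula", "Quercus", "Ghost")))
  fos <- fossil_sequence(
    taxon_table(fvals, site_ids = c("f1", "f2"), unit = "percent"),
    ages = c(1, 2),
    site = data.frame(site_id = "core", lon = 12, lat = 51, elevation = 0))
  al <- align_taxa(cal, fos)
  expect_equal(al$taxon_names, c("Pinus", "Betula", "Quercus"))
  expect_true(all(abs(rowSums(al$cal_percent) - 100) < 1e-9))
  expect_true(all(abs(rowSums(al$fossil_percent) - 100) < 1e-9))
  expect_equal(al$report$dropped_from_fossil, "Ghost")
  expect_equal(al$report$dropped_from_cal, "Alnus")
  expect_equal(unname(al$report$fossil_mass_lost["f1"]), 10)
  # identical taxon lists: unchanged matrices, empty report
  fos2 <- fossil_sequence(cal$taxa, ages = c(1, 2, 3, 4, 5), site = cal$meta[1, ])
  al2 <- align_taxa(cal, fos2)
  expect_equal(al2$cal_percent, cal$taxa$values)
  expect_length(al2$report$dropped_from_cal, 0)
})

test_that("fossil_sequence requires strictly monotone ages", {
  tt <- taxon_table(random_percent(3, 4), unit = "percent")
  site <- data.frame(site_id = "x", lon = 0, lat = 0, elevation = 0)
  expect_error(fossil_sequence(tt, c(1, 1, 2), site), "monotone")
  expect_s3_class(fossil_sequence(tt, c(3, 2, 1), site), "fossil_sequence")
  expect_false(fossil_sequence(tt, c(3, 2, 1), site)$ages_increasing)
})
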