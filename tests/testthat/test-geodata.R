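test_that("settlement loading filters to bounds and flags bad rows", {
  b <- tiny_bounds()
  inside <- sahelsim:::.km_to_lonlat(c(10, 50, 90), c(10, 50, 90), b)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(lon = c(inside[, 1], b$lon_max + 1),
                       lat = c(inside[, 2], b$lat_min),
                       name = letters[1:4]),
            f, row.names = FALSE)
  s <- load_settlements(f, b)
  expect_equal(nrow(s), 3)
  expect_equal(s$id, 0:2)
  expect_equal(s$name, c("a", "b", "c"))

  write.csv(data.frame(lon = c(inside[1, 1], inside[2, 1]),
                       lat = c("NaN", inside[2, 2])), f, row.names = FALSE)
  expect_warning(s2 <- load_settlements(f, b), "row\\(s\\): 1")
  expect_equal(nrow(s2), 1)

  write.csv(data.frame(lon = b$lon_max + 1, lat = b$lat_min), f,
            row.names = FALSE)
  expect_error(load_settlements(f, b), "no settlements")
})

test_that("a generated landscape round-trips through the text loaders", {
  spec <- landscape_spec(seed = 9, side_km = 80, n_settlements = 100,
                         n_parents = 8, cluster_sd_km = 5, years = 1,
                         water_density = c(perennial = 1, nonperennial = 2))
  ls <- generate_landscape(spec)
  dir <- withr::local_tempdir()
  write_landscape(ls, dir)
  ls2 <- read_landscape(dir)
  expect_equal(nrow(ls2$settlements), 100)
  expect_equal(ls2$settlements$id, 0:99)
  expect_equal(ls2$settlements$lon, ls$settlements$lon, tolerance = 1e-9)
  # total water length preserved within 0.1%
  expect_equal(unname(water_length_total(ls2$water)),
               unname(water_length_total(ls$water)), tolerance = 1e-3)
  expect_equal(ls2$water$perennial, ls$water$perennial)
  # weekly rainfall totals reproduced from the daily dump
  expect_equal(ls2$rainfall$values, ls$rainfall$values, tolerance = 1e-9)
})

test_that("water-course loading converts polygons to rings and clips lines", {
  b <- tiny_bounds()
  # a 10 km square polygon fully inside -> one ring of length 40 km
  sq <- sahelsim:::.km_to_lonlat(c(20, 30, 30, 20, 20), c(20, 20, 30, 30, 20), b)
  f <- withr::local_tempfile(fileext = ".geojson")
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature",
         properties = list(class = "perennial or permanent"),
         geometry = list(type = "Polygon", coordinates = list(
           lapply(seq_len(nrow(sq)), function(i) as.numeric(sq[i, ])))))))
  jsonlite::write_json(gj, f, auto_unbox = TRUE, digits = NA)
  w <- load_water_courses(f, b)
  expect_equal(nrow(w), 1)
  expect_true(w$perennial)
  expect_equal(sum(vapply(w$coords, segment_length_km, numeric(1))), 40,
               tolerance = 1e-3)

  # a horizontal line crossing the west edge: only the inside half remains
  line <- sahelsim:::.km_to_lonlat(c(-50, 50), c(50, 50), b)
  gj$features[[1]] <- list(
    type = "Feature",
    properties = list(class = "non-perennial, intermittent, or fluctuating"),
    geometry = list(type = "LineString", coordinates = list(
      as.numeric(line[1, ]), as.numeric(line[2, ]))))
  jsonlite::write_json(gj, f, auto_unbox = TRUE, digits = NA)
  w2 <- load_water_courses(f, b)
  expect_equal(nrow(w2), 1)
  expect_false(w2$perennial)
  expect_equal(segment_length_km(w2$coords[[1]]), 50, tolerance = 1e-2)

  # unknown class string is fatal; point geometry is skipped with a warning
  gj$features[[1]]$properties$class <- "sometimes wet"
  jsonlite::write_json(gj, f, auto_unbox = TRUE, digits = NA)
  expect_error(load_water_courses(f, b), "sometimes wet")
  gj$features[[1]] <- list(
    type = "Feature", properties = list(class = "perennial or permanent"),
    geometry = list(type = "Point", coordinates = c(-1.7, 12.3)))
  jsonlite::write_json(gj, f, auto_unbox = TRUE, digits = NA)
  expect_warning(w3 <- load_water_courses(f, b), "Point")
  expect_equal(nrow(w3), 0)
})

test_that("rainfall loading aggregates days to weeks and validates the axis", {
  b <- tiny_bounds(60)
  grid <- flat_rainfall(b, 0, weeks = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  mk <- function(days, precip) {
    do.call(rbind, lapply(days, function(d) {
      data.frame(lon = grid$cells$lon, lat = grid$cells$lat, day = d,
                 precip_mm = precip)
    }))
  }
  write.csv(mk(1:14, 2), f, row.names = FALSE)
  rg <- load_rainfall(f, b)
  expect_equal(rg$n_weeks, 2)
  expect_true(all(rg$values == 14))

  write.csv(mk(1:14, 0), f, row.names = FALSE)
  expect_true(all(load_rainfall(f, b)$values == 0))

  df <- mk(1:14, 2); df$precip_mm[3] <- -1
  write.csv(df, f, row.names = FALSE)
  expect_error(load_rainfall(f, b), "negative")

  write.csv(mk(c(1:6, 8:15), 2), f, row.names = FALSE)
  expect_error(load_rainfall(f, b), "contiguous")
})

test_that("weekly totals of a seasonal sinusoid match the analytic integral", {
  # daily rain 5*(1 + sin(2*pi*day/365)): annual total is 5*365 exactly
  b <- tiny_bounds(60)
  grid <- flat_rainfall(b, 0, weeks = 52)
  days <- 1:365
  daily <- 5 * (1 + sin(2 * pi * days / 365))
  f <- withr::local_tempfile(fileext = ".csv")
  df <- do.call(rbind, lapply(days, function(d) {
    data.frame(lon = grid$cells$lon, lat = grid$cells$lat, day = d,
               precip_mm = daily[d])
  }))
  write.csv(df, f, row.names = FALSE)
  expect_warning(rg <- load_rainfall(f, b), "partial week")
  got <- sum(rg$values[1, ])
  want <- sum(daily[1:(52 * 7)])   # discrete weekly aggregation, days 1..364
  expect_equal(got, want, tolerance = 1e-8)
  expect_equal(got, 5 * 365, tolerance = 0.05)  # closed-form annual total
})

test_that("haversine distances behave like great-circle distances", {
  expect_equal(distance_km(3, 10, 3, 10), 0)
  # one degree of latitude is ~111.2 km at any longitude
  expect_equal(distance_km(0, 0, 0, 1), 111.195, tolerance = 1e-4)
  expect_equal(distance_km(-120, 40, -120, 41), 111.195, tolerance = 1e-4)
  set.seed(1)
  lon <- runif(60, -5, 2); lat <- runif(60, 9, 16)
  lon2 <- lon + rnorm(60, 0, 0.5); lat2 <- lat + rnorm(60, 0, 0.5)
  d_pkg <- distance_km(lon, lat, lon2, lat2)
  # independent spherical implementation (different formula, same metric)
  d_vin <- geosphere::distVincentySphere(cbind(lon, lat), cbind(lon2, lat2),
                                         r = 6371)
  expect_lt(max(abs(d_pkg - d_vin) / d_vin), 1e-9)
  # WGS84 geodesic: spherical approximation stays within ~0.6% at this extent
  d_geo <- geosphere::distGeo(cbind(lon, lat), cbind(lon2, lat2)) / 1000
  expect_lt(max(abs(d_pkg - d_geo) / d_geo), 0.006)
  # symmetry and triangle inequality on random triples
  for (k in 1:20) {
    i <- sample(60, 3)
    ab <- distance_km(lon[i[1]], lat[i[1]], lon[i[2]], lat[i[2]])
    ba <- distance_km(lon[i[2]], lat[i[2]], lon[i[1]], lat[i[1]])
    bc <- distance_km(lon[i[2]], lat[i[2]], lon[i[3]], lat[i[3]])
    ac <- distance_km(lon[i[1]], lat[i[1]], lon[i[3]], lat[i[3]])
    expect_equal(ab, ba)
    expect_lte(ac, ab + bc + 1e-9)
  }
})

test_that("water length within a radius is exact on chords and random soups", {
  b <- tiny_bounds()
  ls <- hand_landscape(cbind(50, 50), b)
  s <- ls$settlements
  # no water at all
  none <- water_length_within(s$lon, s$lat, ls$water, 2)
  expect_equal(unname(none[1, ]), c(0, 0))
  # a perennial chord through the centre: exactly 2 * L_w inside the disc
  w <- hand_water(c(20, 50), c(80, 50), TRUE, b)
  got <- water_length_within(s$lon, s$lat, w, 2)
  expect_equal(unname(got[1, "W_p"]), 4, tolerance = 1e-4)
  expect_equal(unname(got[1, "W_n"]), 0)
  # random segment soup vs dense point-resampling oracle
  set.seed(42)
  soup <- do.call(rbind, lapply(1:12, function(i) {
    a <- runif(2, 40, 60); bb <- a + runif(2, -8, 8)
    hand_water(a, bb, i %% 2 == 0, b)
  }))
  soup$segment_id <- seq_len(nrow(soup))
  L_w <- 5
  got <- water_length_within(s$lon, s$lat, soup, L_w)
  oracle <- c(W_p = 0, W_n = 0)
  for (i in seq_len(nrow(soup))) {
    cc <- soup$coords[[i]]
    # resample the polyline at ~1 m spacing and sum step lengths inside
    for (k in seq_len(nrow(cc) - 1)) {
      step_len <- distance_km(cc[k, 1], cc[k, 2], cc[k + 1, 1], cc[k + 1, 2])
      m <- max(2L, ceiling(step_len / 0.001))
      px <- seq(cc[k, 1], cc[k + 1, 1], length.out = m)
      py <- seq(cc[k, 2], cc[k + 1, 2], length.out = m)
      mid_x <- (px[-1] + px[-m]) / 2
      mid_y <- (py[-1] + py[-m]) / 2
      inside <- distance_km(mid_x, mid_y, s$lon[1], s$lat[1]) <= L_w
      cls <- if (soup$perennial[i]) "W_p" else "W_n"
      oracle[cls] <- oracle[cls] + sum(inside) * (step_len / (m - 1))
    }
  }
  expect_equal(unname(got[1, "W_p"]), unname(oracle["W_p"]), tolerance = 0.01)
  expect_equal(unname(got[1, "W_n"]), unname(oracle["W_n"]), tolerance = 0.01)
})

test_that("every settlement maps to exactly one rainfall cell", {
  ls <- generate_landscape(landscape_spec(seed = 3, side_km = 120,
                                          n_settlements = 80, years = 1))
  cells <- rainfall_cell(ls$rainfall, ls$settlements$lon, ls$settlements$lat)
  expect_length(cells, 80)
  expect_true(all(cells >= 1 & cells <= nrow(ls$rainfall$cells)))
  # the mapped cell actually contains the settlement
  cd <- ls$rainfall$cell_deg
  expect_true(all(abs(ls$settlements$lon - ls$rainfall$cells$lon[cells]) <= cd / 2))
  expect_true(all(abs(ls$settlements$lat - ls$rainfall$cells$lat[cells]) <= cd / 2))
  expect_error(rainfall_cell(ls$rainfall, 50, 0), "outside")
})
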