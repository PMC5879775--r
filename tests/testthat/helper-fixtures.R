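# Shared fixtures, built in code at test time.

# a small square for hand-made scenes: 100 km centred on the study region
tiny_bounds <- function(side_km = 100) sim_bounds(side_km = side_km)

# a flat rainfall grid covering `bounds`: constant `mm` every week
flat_rainfall <- function(bounds, mm, weeks = 52, cell_deg = 0.5) {
  nx <- ceiling((bounds$lon_max - bounds$lon_min) / cell_deg)
  ny <- ceiling((bounds$lat_max - bounds$lat_min) / cell_deg)
  cells <- tibble::tibble(
    cell = seq_len(nx * ny),
    lon = rep(bounds$lon_min + (seq_len(nx) - 0.5) * cell_deg, times = ny),
    lat = rep(bounds$lat_min + (seq_len(ny) - 0.5) * cell_deg, each = nx))
  sahelsim:::new_rainfall_grid(cells, matrix(mm, nx * ny, weeks), cell_deg,
                               weeks)
}

# hand-made landscape: settlements at given km offsets from the SW corner
hand_landscape <- function(xy_km, bounds = tiny_bounds(), water = NULL,
                           rain_mm = 20, weeks = 52) {
  ll <- sahelsim:::.km_to_lonlat(xy_km[, 1], xy_km[, 2], bounds)
  if (is.null(water)) {
    water <- tibble::tibble(segment_id = integer(0), source_id = integer(0),
                            perennial = logical(0), coords = list())
  }
  landscape(
    settlements = tibble::tibble(id = seq_len(nrow(ll)) - 1L,
                                 lon = ll[, 1], lat = ll[, 2]),
    water = water,
    rainfall = flat_rainfall(bounds, rain_mm, weeks),
    bounds = bounds)
}

# a single straight water course between two km-offset points
hand_water <- function(from_km, to_km, perennial, bounds = tiny_bounds(),
                       n_pts = 50) {
  xs <- seq(from_km[1], to_km[1], length.out = n_pts)
  ys <- seq(from_km[2], to_km[2], length.out = n_pts)
  tibble::tibble(segment_id = 1L, source_id = 1L, perennial = perennial,
                 coords = list(sahelsim:::.km_to_lonlat(xs, ys, bounds)))
}

# landscape with two rainfall regimes: settlement 1 in a year-round wet
# cell (unless wet_first = FALSE), all other cells rain only in weeks 1..12
# of each year (a short rainy season) and are bone dry otherwise
wet_dry_landscape <- function(xy_km = rbind(c(10, 10), c(10, 90)),
                              weeks = 11 * 52, wet_mm = 25, side = 100,
                              wet_first = TRUE) {
  b <- tiny_bounds(side)
  ls <- hand_landscape(xy_km, b, rain_mm = 0, weeks = weeks)
  cells <- rainfall_cell(ls$rainfall, ls$settlements$lon, ls$settlements$lat)
  v <- ls$rainfall$values
  wk_doy <- ((seq_len(ncol(v)) - 1) * 7) %% 364
  v[, ] <- 0
  v[, wk_doy < 12 * 7] <- wet_mm
  if (wet_first) v[cells[1], ] <- wet_mm
  ls$rainfall$values <- v
  ls
}

# run the engine's within-settlement daily demography (no movement) for an
# isolated settlement at constant alpha; returns days x (J_T, M, V, F) matrix
run_isolated_site <- function(dem, alpha, days,
                              init = c(M = 500, F = 500),
                              aest = aestivation_params()) {
  st <- new_population_state(1, dem)
  st$M[1, 1] <- init[["M"]]
  st$F[1, 1] <- init[["F"]]
  out <- matrix(0, days, 4, dimnames = list(NULL, c("J_T", "M", "V", "F")))
  for (t in seq_len(days)) {
    st <- step_juveniles(st, alpha, dem)
    em <- emerge(st$emergers)
    st$M[, 1] <- st$M[, 1] + em$males
    st$V[, 1] <- st$V[, 1] + em$females
    st <- step_adults(st, dem, aest, (t - 1L) %% 365L + 1L)
    st <- oviposit(st, dem)
    out[t, ] <- c(sum(st$J), sum(st$M), sum(st$V), sum(st$F))
  }
  out
}
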