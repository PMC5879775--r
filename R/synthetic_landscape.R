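#' Specification for a synthetic landscape
#'
#' Bundles every knob of the synthetic-landscape generator: a clustered
#' (Thomas-process) settlement pattern, random-walk water courses of the two
#' perennial classes, and a weekly rainfall grid with a north-south aridity
#' gradient, a single annual rainy season and lognormal interannual
#' variation. Defaults emulate a semi-arid study region in miniature.
#'
#' @param seed integer RNG seed; generation is fully reproducible given it.
#' @param side_km side of the simulation square, km.
#' @param centre_lon,centre_lat centre of the square, degrees.
#' @param n_settlements number of settlements to place (> 0).
#' @param n_parents expected number of Thomas-process parent clusters.
#' @param cluster_sd_km Gaussian dispersion of offspring about parents, km.
#' @param settlement_clusters optional explicit cluster layout: a data frame
#'   with columns `x_km`, `y_km` (from the south-west corner), `sd_km`, `n`;
#'   overrides the Thomas process when supplied.
#' @param water_density km of water course per 100 km^2, named vector with
#'   entries `perennial` and `nonperennial`.
#' @param course_length_km length of each random-walk water course, km.
#' @param perennial_south_bias exponent biasing perennial course origins
#'   toward the south edge (0 = uniform in latitude).
#' @param perennial_max_northness perennial course origins are confined to
#'   the southern fraction of the square given here (1 = anywhere).
#' @param water_explicit optional list of extra water courses, each a list
#'   with `coords_km` (two-column x/y matrix, km from the SW corner) and
#'   `perennial` (logical); appended to the generated network.
#' @param rain_peak_south_mm peak weekly rainfall at the south edge, mm/week.
#' @param rain_gradient fractional reduction of peak rainfall from the south
#'   to the north edge (0 = no gradient, 0.9 = the north gets 10%).
#' @param season_centre_doy,season_width_days centre (day-of-year, 365-day
#'   calendar) and Gaussian width of the annual rainy season.
#' @param dry_floor_south_mm year-round weekly rainfall floor at the south
#'   edge, mm/week (0 = fully seasonal everywhere).
#' @param dry_floor_power exponent with which the floor decays northward.
#' @param interannual_sd standard deviation of the log yearly rainfall
#'   multiplier (lognormal with mean 1, shared by all cells within a year).
#' @param interannual_ar1 optional AR(1) coefficient for the log yearly
#'   multiplier (0 = independent years, the default).
#' @param years number of 365-day years of rainfall to generate.
#' @param cell_deg rainfall grid resolution, degrees.
#' @param trace_mm weekly totals below this are treated as dry (0 mm).
#' @return an object of class `landscape_spec`.
#' @export
landscape_spec <- function(seed = 1L, side_km = 300,
                           centre_lon = -1.737, centre_lat = 12.274,
                           n_settlements = 200,
                           n_parents = 40, cluster_sd_km = 8,
                           settlement_clusters = NULL,
                           water_density = c(perennial = 1.2, nonperennial = 2.5),
                           course_length_km = 20,
                           perennial_south_bias = 0,
                           perennial_max_northness = 1,
                           water_explicit = NULL,
                           rain_peak_south_mm = 60,
                           rain_gradient = 0.85,
                           season_centre_doy = 240,
                           season_width_days = 28,
                           dry_floor_south_mm = 0,
                           dry_floor_power = 4,
                           interannual_sd = 0.25,
                           interannual_ar1 = 0,
                           years = 12,
                           cell_deg = 0.5,
                           trace_mm = 0.1) {
  spec <- as.list(environment())
  stopifnot(spec$n_settlements > 0, spec$side_km > 0,
            all(spec$water_density >= 0), spec$rain_peak_south_mm >= 0,
            spec$rain_gradient >= 0, spec$rain_gradient <= 1,
            spec$interannual_sd >= 0, spec$years >= 1)
  structure(spec, class = "landscape_spec")
}

# km offsets from the SW corner -> lon/lat, consistent with sim_bounds()
.km_to_lonlat <- function(x_km, y_km, bounds) {
  cbind(lon = bounds$lon_min +
          x_km / (KM_PER_DEG * cos(bounds$centre_lat * pi / 180)),
        lat = bounds$lat_min + y_km / KM_PER_DEG)
}

.northness <- function(lat, bounds) {
  pmin(1, pmax(0, (lat - bounds$lat_min) / (bounds$lat_max - bounds$lat_min)))
}

# Thomas cluster process conditioned on the exact number of points: parents
# are uniform over the square, each point picks a parent uniformly and is
# displaced by an isotropic Gaussian; points falling outside are redrawn.
.thomas_points <- function(n, side, n_parents, sd_km) {
  np <- max(1L, stats::rpois(1, n_parents))
  px <- stats::runif(np, 0, side)
  py <- stats::runif(np, 0, side)
  x <- numeric(n); y <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      k <- sample.int(np, 1)
      xi <- px[k] + stats::rnorm(1, 0, sd_km)
      yi <- py[k] + stats::rnorm(1, 0, sd_km)
      if (xi >= 0 && xi <= side && yi >= 0 && yi <= side) break
    }
    x[i] <- xi; y[i] <- yi
  }
  cbind(x, y)
}

.cluster_points <- function(clusters, side) {
  parts <- lapply(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    x <- numeric(cl$n); y <- numeric(cl$n)
    for (j in seq_len(cl$n)) {
      repeat {
        xi <- cl$x_km + stats::rnorm(1, 0, cl$sd_km)
        yi <- cl$y_km + stats::rnorm(1, 0, cl$sd_km)
        if (xi >= 0 && xi <= side && yi >= 0 && yi <= side) break
      }
      x[j] <- xi; y[j] <- yi
    }
    cbind(x, y)
  })
  do.call(rbind, parts)
}

# one random-walk water course of the requested length, reflected at the
# square's edges; ~1 km steps with a slowly drifting heading
.walk_course <- function(len_km, side, y0_max, south_bias) {
  step <- 1
  n_steps <- max(1L, ceiling(len_km / step))
  x <- stats::runif(1, 0, side)
  y <- y0_max * side * stats::runif(1)^(1 + south_bias)
  heading <- stats::runif(1, 0, 2 * pi)
  out <- matrix(0, n_steps + 1L, 2)
  out[1, ] <- c(x, y)
  remaining <- len_km
  for (k in seq_len(n_steps)) {
    heading <- heading + stats::rnorm(1, 0, 0.4)
    s <- min(step, remaining)
    x <- x + s * cos(heading)
    y <- y + s * sin(heading)
    if (x < 0) { x <- -x; heading <- pi - heading }
    if (x > side) { x <- 2 * side - x; heading <- pi - heading }
    if (y < 0) { y <- -y; heading <- -heading }
    if (y > side) { y <- 2 * side - y; heading <- -heading }
    out[k + 1L, ] <- c(x, y)
    remaining <- remaining - s
  }
  out
}

.generate_water <- function(spec, bounds) {
  segs <- list()
  add <- function(coords_km, perennial) {
    ll <- .km_to_lonlat(coords_km[, 1], coords_km[, 2], bounds)
    segs[[length(segs) + 1L]] <<- list(perennial = perennial, coords = ll)
  }
  area <- spec$side_km^2
  for (cls in c("perennial", "nonperennial")) {
    target <- spec$water_density[[cls]] * area / 100
    done <- 0
    while (done < target - 1e-9) {
      len <- min(spec$course_length_km, target - done)
      coords <- .walk_course(len, spec$side_km,
                             if (cls == "perennial") spec$perennial_max_northness else 1,
                             if (cls == "perennial") spec$perennial_south_bias else 0)
      add(coords, cls == "perennial")
      done <- done + len
    }
  }
  for (w in spec$water_explicit) add(w$coords_km, w$perennial)
  tibble::tibble(
    segment_id = seq_along(segs),
    source_id = seq_along(segs),
    perennial = vapply(segs, `[[`, logical(1), "perennial"),
    coords = lapply(segs, `[[`, "coords"))
}

.generate_rainfall <- function(spec, bounds) {
  cd <- spec$cell_deg
  nx <- ceiling((bounds$lon_max - bounds$lon_min) / cd)
  ny <- ceiling((bounds$lat_max - bounds$lat_min) / cd)
  lons <- bounds$lon_min + (seq_len(nx) - 0.5) * cd
  lats <- bounds$lat_min + (seq_len(ny) - 0.5) * cd
  cells <- tibble::tibble(cell = seq_len(nx * ny),
                          lon = rep(lons, times = ny),
                          lat = rep(lats, each = nx))
  # round up so the series covers a full `years` engine-years of days
  n_weeks <- as.integer(ceiling(spec$years * 365 / 7))
  # yearly lognormal multiplier with mean 1, optionally AR(1) in log space
  z <- stats::rnorm(spec$years)
  if (spec$interannual_ar1 != 0) {
    rho <- spec$interannual_ar1
    for (y in seq_len(spec$years)[-1]) {
      z[y] <- rho * z[y - 1] + sqrt(1 - rho^2) * z[y]
    }
  }
  mult <- exp(spec$interannual_sd * z - spec$interannual_sd^2 / 2)
  mid <- (seq_len(n_weeks) - 1L) * 7L + 4L         # mid-day of each week
  wk_year <- pmin((mid - 1L) %/% 365L + 1L, spec$years)
  wk_doy <- (mid - 1L) %% 365L + 1L
  ddoy <- pmin(abs(wk_doy - spec$season_centre_doy),
               365 - abs(wk_doy - spec$season_centre_doy))
  bump <- exp(-ddoy^2 / (2 * spec$season_width_days^2))
  u <- .northness(cells$lat, bounds)
  peak <- spec$rain_peak_south_mm * (1 - spec$rain_gradient * u)
  floorv <- spec$dry_floor_south_mm * (1 - u)^spec$dry_floor_power
  values <- (floorv %o% rep(1, n_weeks) + peak %o% bump) *
    rep(mult[wk_year], each = nrow(cells))
  values[values < spec$trace_mm] <- 0
  new_rainfall_grid(cells, values, cd, n_weeks)
}

#' Generate a synthetic landscape
#'
#' Draws a clustered settlement pattern, a random-walk water-course network
#' with perennial and non-perennial classes, and a weekly rainfall grid with
#' a north-south aridity gradient and a single annual rainy season, and
#' binds them into a [landscape()]. Fully reproducible: the RNG is
#' initialised from `spec$seed` with the Mersenne-Twister generator.
#'
#' @param spec a [landscape_spec()].
#' @return a `sahel_landscape`.
#' @export
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  if (spec$n_settlements <= 0) stop("n_settlements must be positive",
                                    call. = FALSE)
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  bounds <- sim_bounds(spec$centre_lon, spec$centre_lat, spec$side_km)
  pts <- if (is.null(spec$settlement_clusters)) {
    .thomas_points(spec$n_settlements, spec$side_km, spec$n_parents,
                   spec$cluster_sd_km)
  } else {
    .cluster_points(spec$settlement_clusters, spec$side_km)
  }
  ll <- .km_to_lonlat(pts[, 1], pts[, 2], bounds)
  settlements <- tibble::tibble(id = seq_len(nrow(ll)) - 1L,
                                lon = ll[, 1], lat = ll[, 2])
  water <- .generate_water(spec, bounds)
  rainfall <- .generate_rainfall(spec, bounds)
  ls <- landscape(settlements, water, rainfall, bounds)
  attr(ls, "spec") <- spec
  ls
}

#' Reference landscape presets
#'
#' Named [landscape_spec()] presets spanning the qualitative regimes of the
#' study region:
#' \describe{
#'   \item{`wet-south`}{a year-round rainfall floor in the southern rows;
#'     persistence there does not require surface water.}
#'   \item{`arid-north`}{a fully seasonal north with a 6+ month dry season;
#'     persistent populations exist only near perennial water or in the
#'     extreme south. The work-horse preset for dispersal/aestivation/
#'     migration experiments.}
#'   \item{`sahel-remote`}{a sparse northern settlement cluster at least
#'     30 km from any perennial water course.}
#'   \item{`island-mainland`}{an explicit mainland (dense southern
#'     settlement band on a perennial river) plus island clusters at a range
#'     of distances, including dense-but-remote ones; used to separate the
#'     distance-to-source and settlement-density correlates of occupancy.}
#' }
#'
#' @return a named list of `landscape_spec` objects.
#' @export
reference_scenarios <- function() {
  list(
    "wet-south" = landscape_spec(
      seed = 101L, side_km = 250, n_settlements = 150, n_parents = 25,
      cluster_sd_km = 7,
      water_density = c(perennial = 2, nonperennial = 3),
      rain_peak_south_mm = 70, rain_gradient = 0.85,
      dry_floor_south_mm = 8, dry_floor_power = 2),
    "arid-north" = landscape_spec(
      seed = 202L, side_km = 300, n_settlements = 200, n_parents = 20,
      cluster_sd_km = 20,
      water_density = c(perennial = 1.2, nonperennial = 2.5),
      perennial_south_bias = 2, perennial_max_northness = 0.6,
      rain_peak_south_mm = 60, rain_gradient = 0.85,
      dry_floor_south_mm = 5, dry_floor_power = 6),
    "sahel-remote" = landscape_spec(
      seed = 303L, side_km = 200, n_settlements = 105,
      settlement_clusters = data.frame(
        x_km = c(40, 90, 150, 60, 130, 100),
        y_km = c(12, 10, 15, 40, 35, 180),
        sd_km = c(6, 6, 6, 5, 5, 4),
        n = c(25, 25, 20, 10, 10, 15)),
      water_density = c(perennial = 1.5, nonperennial = 2),
      perennial_south_bias = 2, perennial_max_northness = 0.35,
      rain_peak_south_mm = 55, rain_gradient = 0.9,
      season_width_days = 25,
      dry_floor_south_mm = 4, dry_floor_power = 6),
    "island-mainland" = landscape_spec(
      seed = 404L, side_km = 200, n_settlements = 173,
      settlement_clusters = data.frame(
        x_km = c(60, 140, 60, 64, 58, 120, 150, 50),
        y_km = c(8, 8, 22, 34, 46, 60, 150, 160),
        sd_km = c(6, 6, 3, 3, 3, 4, 5, 4),
        n = c(50, 30, 6, 6, 6, 10, 40, 25)),
      water_density = c(perennial = 0, nonperennial = 1.5),
      water_explicit = list(list(
        coords_km = cbind(seq(0, 200, by = 2), 6), perennial = TRUE)),
      rain_peak_south_mm = 60, rain_gradient = 0.3,
      dry_floor_south_mm = 0))
}

## ---- round-trip writers ----------------------------------------------------

#' Write a landscape to plain-text files
#'
#' Writes `settlements.csv`, `water.geojson`, `rainfall.csv` (daily long
#' format; weekly totals split evenly over days) and `bounds.json` into a
#' directory, in exactly the dialects the loaders read, so a landscape
#' round-trips through [read_landscape()].
#'
#' @param ls a `sahel_landscape`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(ls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(ls$settlements, file.path(dir, "settlements.csv"),
                   row.names = FALSE)
  cls <- names(.default_class_map)
  feats <- lapply(seq_len(nrow(ls$water)), function(i) {
    cc <- ls$water$coords[[i]]
    list(type = "Feature",
         properties = list(class = cls[match(!ls$water$perennial[i], c(FALSE, TRUE))]),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(cc)),
                                              function(k) as.numeric(cc[k, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file.path(dir, "water.geojson"), auto_unbox = TRUE,
                       digits = NA)
  rg <- ls$rainfall
  nd <- rg$n_weeks * 7L
  day <- seq_len(nd)
  df <- data.frame(
    lon = rep(rg$cells$lon, times = nd),
    lat = rep(rg$cells$lat, times = nd),
    day = rep(day, each = nrow(rg$cells)),
    precip_mm = as.vector(rg$values[, (day - 1L) %/% 7L + 1L]) / 7)
  utils::write.csv(df, file.path(dir, "rainfall.csv"), row.names = FALSE)
  jsonlite::write_json(list(centre_lon = ls$bounds$centre_lon,
                            centre_lat = ls$bounds$centre_lat,
                            side_km = ls$bounds$side_km,
                            cell_deg = rg$cell_deg),
                       file.path(dir, "bounds.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a landscape written by [write_landscape()]
#'
#' @param dir directory holding the four landscape files.
#' @return a `sahel_landscape`.
#' @export
read_landscape <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "bounds.json"))
  bounds <- sim_bounds(meta$centre_lon, meta$centre_lat, meta$side_km)
  landscape(
    settlements = load_settlements(file.path(dir, "settlements.csv"), bounds),
    water = load_water_courses(file.path(dir, "water.geojson"), bounds),
    rainfall = load_rainfall(file.path(dir, "rainfall.csv"), bounds,
                             cell_deg = meta$cell_deg),
    bounds = bounds)
}
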