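#' sahelsim: individual-based mosquito metapopulation dynamics
#'
#' Simulates Anopheles gambiae s.l. populations on a network of human
#' settlements in seasonally arid West Africa, with rainfall- and
#' water-course-driven carrying capacity, daily stochastic demography,
#' local dispersal, aestivation, seasonal long-distance migration and
#' cryptic permanent larval sites.
#'
#' @keywords internal
"_PACKAGE"

# kilometres per degree of latitude on a sphere of radius 6371 km
KM_PER_DEG <- 6371 * pi / 180

#' Define the simulation square
#'
#' The simulation region is a square of given side length centred on a
#' lon/lat point. Degree extents are computed on a spherical Earth
#' (R = 6371 km) with the longitude scale taken at the centre latitude.
#' Defaults reproduce the study region: a 1000 km square centred on the
#' mid-point of Burkina Faso.
#'
#' @param centre_lon,centre_lat centre of the square, decimal degrees (WGS84).
#' @param side_km side length in kilometres.
#' @return an object of class `sim_bounds`.
#' @export
sim_bounds <- function(centre_lon = -1.737, centre_lat = 12.274,
                       side_km = 1000) {
  stopifnot(is.finite(centre_lon), is.finite(centre_lat), side_km > 0)
  half <- side_km / 2
  dlat <- half / KM_PER_DEG
  dlon <- half / (KM_PER_DEG * cos(centre_lat * pi / 180))
  structure(
    list(centre_lon = centre_lon, centre_lat = centre_lat, side_km = side_km,
         lon_min = centre_lon - dlon, lon_max = centre_lon + dlon,
         lat_min = centre_lat - dlat, lat_max = centre_lat + dlat),
    class = "sim_bounds")
}

#' @export
print.sim_bounds <- function(x, ...) {
  cat(sprintf("simulation square: %g km side centred (%.3f, %.3f)\n",
              x$side_km, x$centre_lon, x$centre_lat))
  cat(sprintf("  lon [%.3f, %.3f]  lat [%.3f, %.3f]\n",
              x$lon_min, x$lon_max, x$lat_min, x$lat_max))
  invisible(x)
}

#' Test whether points fall inside the simulation square
#'
#' Points exactly on the boundary are counted as inside.
#'
#' @param lon,lat coordinate vectors, decimal degrees.
#' @param bounds a [sim_bounds()] object.
#' @return logical vector.
#' @export
in_bounds <- function(lon, lat, bounds) {
  lon >= bounds$lon_min & lon <= bounds$lon_max &
    lat >= bounds$lat_min & lat <= bounds$lat_max
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a spherical Earth of radius 6371 km, vectorised
#' and recycled over the longer argument.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees.
#' @return distances in km.
#' @export
distance_km <- function(lon1, lat1, lon2, lat2) {
  stopifnot(all(is.finite(lon1)), all(is.finite(lat1)),
            all(is.finite(lon2)), all(is.finite(lat2)))
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

# local equirectangular projection (km) about a reference point; accurate to
# well under 0.1% at the few-km scales where it is used
.project_km <- function(lon, lat, lon0, lat0) {
  cbind(x = (lon - lon0) * KM_PER_DEG * cos(lat0 * pi / 180),
        y = (lat - lat0) * KM_PER_DEG)
}

#' Load settlement points from a delimited text file
#'
#' Reads a CSV/TSV of settlement coordinates, drops records with
#' missing or unparseable coordinates (with a row-indexed warning), and
#' keeps only points inside the simulation square. Duplicate coordinates
#' are retained: each row is its own potential population site.
#'
#' @param path path to a delimited text file.
#' @param bounds a [sim_bounds()] object.
#' @param lon_col,lat_col candidate column names for the coordinates; the
#'   first match (case-insensitive) is used.
#' @param sep field separator, `","` by default.
#' @return a tibble with columns `id`, `lon`, `lat` and any of
#'   `name`, `region`, `country` present in the file. Ids are taken from an
#'   `id` column if present, otherwise assigned `0:(n-1)` in file order.
#' @export
load_settlements <- function(path, bounds,
                             lon_col = c("lon", "longitude", "x"),
                             lat_col = c("lat", "latitude", "y"),
                             sep = ",") {
  raw <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE)
  nm <- tolower(names(raw))
  pick <- function(cands, what) {
    i <- which(nm %in% tolower(cands))[1]
    if (is.na(i)) stop("no ", what, " column found in ", path, call. = FALSE)
    i
  }
  lon <- suppressWarnings(as.numeric(raw[[pick(lon_col, "longitude")]]))
  lat <- suppressWarnings(as.numeric(raw[[pick(lat_col, "latitude")]]))
  bad <- !is.finite(lon) | !is.finite(lat)
  if (any(bad)) {
    warning("dropped ", sum(bad), " record(s) with unparseable coordinates ",
            "at row(s): ", paste(which(bad), collapse = ", "), call. = FALSE)
  }
  keep <- !bad & in_bounds(lon, lat, bounds)
  if (!any(keep)) stop("no settlements inside the simulation square",
                       call. = FALSE)
  out <- tibble::tibble(lon = lon[keep], lat = lat[keep])
  if ("id" %in% nm) {
    out$id <- raw[[which(nm == "id")[1]]][keep]
  } else {
    out$id <- seq_len(nrow(out)) - 1L
  }
  for (extra in c("name", "region", "country")) {
    if (extra %in% nm) out[[extra]] <- raw[[which(nm == extra)[1]]][keep]
  }
  out[, c("id", "lon", "lat",
          intersect(c("name", "region", "country"), names(out)))]
}

## ---- water courses ---------------------------------------------------------

# Liang-Barsky clip of one polyline to a lon/lat rectangle. Returns a list of
# coordinate matrices (possibly empty); a clipped edge may split the polyline
# into several pieces.
.clip_polyline <- function(coords, bounds) {
  xr <- c(bounds$lon_min, bounds$lon_max)
  yr <- c(bounds$lat_min, bounds$lat_max)
  pieces <- list()
  cur <- NULL
  push <- function(p) if (!is.null(p) && nrow(p) >= 2) pieces[[length(pieces) + 1L]] <<- p
  for (k in seq_len(nrow(coords) - 1L)) {
    p <- coords[k, ]; q <- coords[k + 1L, ]
    dx <- q[1] - p[1]; dy <- q[2] - p[2]
    t0 <- 0; t1 <- 1; ok <- TRUE
    for (side in 1:4) {
      pp <- switch(side, -dx, dx, -dy, dy)
      qq <- switch(side, p[1] - xr[1], xr[2] - p[1], p[2] - yr[1], yr[2] - p[2])
      if (pp == 0) {
        if (qq < 0) { ok <- FALSE; break }
      } else {
        r <- qq / pp
        if (pp < 0) t0 <- max(t0, r) else t1 <- min(t1, r)
        if (t0 > t1) { ok <- FALSE; break }
      }
    }
    if (!ok) { push(cur); cur <- NULL; next }
    a <- c(p[1] + t0 * dx, p[2] + t0 * dy)
    b <- c(p[1] + t1 * dx, p[2] + t1 * dy)
    if (t0 > 0 || is.null(cur)) { push(cur); cur <- rbind(a) }
    cur <- rbind(cur, b)
    if (t1 < 1) { push(cur); cur <- NULL }
  }
  push(cur)
  pieces
}

#' Polyline length in kilometres
#'
#' @param coords a two-column lon/lat matrix of ordered vertices.
#' @return total haversine length, km.
#' @export
segment_length_km <- function(coords) {
  n <- nrow(coords)
  if (is.null(n) || n < 2) return(0)
  sum(distance_km(coords[-n, 1], coords[-n, 2], coords[-1, 1], coords[-1, 2]))
}

.default_class_map <- c("perennial or permanent" = TRUE,
                        "non-perennial, intermittent, or fluctuating" = FALSE)

.geometry_to_lines <- function(geom) {
  cm <- function(cc) do.call(rbind, lapply(cc, function(p) c(p[[1]], p[[2]])))
  switch(geom$type,
    LineString = list(cm(geom$coordinates)),
    MultiLineString = lapply(geom$coordinates, cm),
    # polygon boundaries are treated as linear habitat (periphery breeding)
    Polygon = lapply(geom$coordinates, cm),
    MultiPolygon = unlist(lapply(geom$coordinates,
                                 function(rs) lapply(rs, cm)), recursive = FALSE),
    NULL)
}

#' Load water courses from GeoJSON
#'
#' Reads a GeoJSON FeatureCollection of line and polygon water bodies.
#' Polygon geometries contribute their boundary rings, treated as linear
#' breeding habitat. Geometries are clipped to the simulation square
#' (an edge-crossing course keeps only its inside portion, possibly split
#' into several segments); the perennial/non-perennial class flag is
#' preserved through clipping.
#'
#' @param path path to a GeoJSON file.
#' @param bounds a [sim_bounds()] object.
#' @param class_field name of the property holding the water-course class.
#' @param class_map named logical vector mapping class strings to the
#'   perennial flag; defaults to the two source classes
#'   "perennial or permanent" and "non-perennial, intermittent, or fluctuating".
#' @return a tibble with columns `segment_id`, `source_id` (input feature
#'   index), `perennial` (logical) and `coords` (list of lon/lat matrices).
#' @export
load_water_courses <- function(path, bounds, class_field = "class",
                               class_map = .default_class_map) {
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  segs <- list()
  for (fi in seq_along(feats)) {
    f <- feats[[fi]]
    cls <- f$properties[[class_field]]
    if (is.null(cls) || !cls %in% names(class_map)) {
      stop("unknown water-course class ", deparse(cls), " in feature ", fi,
           call. = FALSE)
    }
    lines <- .geometry_to_lines(f$geometry)
    if (is.null(lines)) {
      warning("skipping feature ", fi, " with non-line/polygon geometry ",
              f$geometry$type, call. = FALSE)
      next
    }
    for (ln in lines) {
      for (piece in .clip_polyline(ln, bounds)) {
        if (segment_length_km(piece) > 0) {
          segs[[length(segs) + 1L]] <- list(source_id = fi,
                                            perennial = unname(class_map[cls]),
                                            coords = piece)
        }
      }
    }
  }
  tibble::tibble(
    segment_id = seq_along(segs),
    source_id = vapply(segs, `[[`, integer(1), "source_id"),
    perennial = vapply(segs, `[[`, logical(1), "perennial"),
    coords = lapply(segs, `[[`, "coords"))
}

## ---- rainfall --------------------------------------------------------------

new_rainfall_grid <- function(cells, values, cell_deg, n_weeks) {
  structure(list(cells = cells, values = values, cell_deg = cell_deg,
                 n_weeks = n_weeks,
                 lon0 = min(cells$lon) - cell_deg / 2,
                 lat0 = min(cells$lat) - cell_deg / 2,
                 nx = length(unique(cells$lon)),
                 ny = length(unique(cells$lat))),
            class = "rainfall_grid")
}

#' @export
print.rainfall_grid <- function(x, ...) {
  cat(sprintf("rainfall grid: %d x %d cells of %g deg, %d weeks\n",
              x$nx, x$ny, x$cell_deg, x$n_weeks))
  invisible(x)
}

#' Load gridded rainfall from a daily long-format CSV
#'
#' Reads a long table with columns `lon`, `lat` (cell centres), `day`
#' (integer day index from the start of the covered period, 1-based) and
#' `precip_mm` (daily total). Daily values are summed into calendar weeks
#' counted from the first day of the period; week t's total is the value of
#' the rainfall forcing r(x, t) for all days of that week. A trailing
#' partial week is dropped with a warning.
#'
#' @param path path to the CSV file.
#' @param bounds a [sim_bounds()] object; the grid must cover it.
#' @param cell_deg grid resolution in degrees (0.5 by default).
#' @return a `rainfall_grid` object: cell-centre table plus a
#'   cells-by-weeks matrix of weekly totals (mm/week).
#' @export
load_rainfall <- function(path, bounds, cell_deg = 0.5) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lon", "lat", "day", "precip_mm")
  if (!all(need %in% names(raw))) {
    stop("rainfall CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(raw$precip_mm < 0)) stop("negative precipitation in ", path,
                                   call. = FALSE)
  days <- sort(unique(raw$day))
  if (!identical(as.integer(days), seq_len(length(days)))) {
    stop("gaps in the rainfall time axis: days must be contiguous from 1",
         call. = FALSE)
  }
  cells <- unique(raw[, c("lon", "lat")])
  cells <- cells[order(cells$lat, cells$lon), ]
  cells <- tibble::tibble(cell = seq_len(nrow(cells)),
                          lon = cells$lon, lat = cells$lat)
  eps <- 1e-9
  if (min(cells$lon) - cell_deg / 2 > bounds$lon_min + eps ||
      max(cells$lon) + cell_deg / 2 < bounds$lon_max - eps ||
      min(cells$lat) - cell_deg / 2 > bounds$lat_min + eps ||
      max(cells$lat) + cell_deg / 2 < bounds$lat_max - eps) {
    stop("rainfall grid does not cover the simulation square", call. = FALSE)
  }
  n_days <- length(days)
  n_weeks <- n_days %/% 7
  if (n_days %% 7 != 0) {
    warning("dropping trailing partial week (", n_days %% 7, " day(s))",
            call. = FALSE)
  }
  ci <- match(paste(raw$lon, raw$lat), paste(cells$lon, cells$lat))
  wk <- (raw$day - 1L) %/% 7L + 1L
  keep <- wk <= n_weeks
  totals <- stats::xtabs(precip_mm ~ ci + wk,
                         data = data.frame(precip_mm = raw$precip_mm,
                                           ci = ci, wk = wk)[keep, ])
  values <- matrix(0, nrow(cells), n_weeks)
  values[as.integer(rownames(totals)), as.integer(colnames(totals))] <- totals
  # a cell missing on some day would leave a silent zero; require full cover
  counts <- table(ci)
  if (length(unique(counts)) != 1 || counts[1] != n_days) {
    stop("gaps in the rainfall time axis: not all cells cover all days",
         call. = FALSE)
  }
  new_rainfall_grid(cells, values, cell_deg, n_weeks)
}

#' Map points to rainfall cells
#'
#' Containing-cell lookup (no interpolation): each point maps to the single
#' grid cell whose half-open square `[centre - cell/2, centre + cell/2)`
#' contains it.
#'
#' @param grid a `rainfall_grid`.
#' @param lon,lat coordinate vectors.
#' @return integer vector of cell indices into `grid$cells`.
#' @export
rainfall_cell <- function(grid, lon, lat) {
  ix <- floor((lon - grid$lon0) / grid$cell_deg) + 1L
  iy <- floor((lat - grid$lat0) / grid$cell_deg) + 1L
  if (any(ix < 1 | ix > grid$nx | iy < 1 | iy > grid$ny)) {
    stop("point(s) outside the rainfall grid", call. = FALSE)
  }
  as.integer((iy - 1L) * grid$nx + ix)
}

## ---- water length within a radius -----------------------------------------

# flatten all water segments into an edge table (lon/lat endpoints + class),
# with a per-edge bounding box used to prefilter radius queries
.water_edges <- function(water) {
  if (nrow(water) == 0) {
    return(data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), perennial = logical(0)))
  }
  parts <- lapply(seq_len(nrow(water)), function(i) {
    cc <- water$coords[[i]]
    n <- nrow(cc)
    if (n < 2) return(NULL)
    data.frame(x1 = cc[-n, 1], y1 = cc[-n, 2], x2 = cc[-1, 1], y2 = cc[-1, 2],
               perennial = water$perennial[i])
  })
  do.call(rbind, parts)
}

# portion of one set of edges (already projected to km about the query point)
# lying inside the disc of radius L; exact chord clipping per edge
.edge_length_in_disc <- function(ax, ay, bx, by, L) {
  dx <- bx - ax; dy <- by - ay
  a <- dx^2 + dy^2
  b <- 2 * (ax * dx + ay * dy)
  cc <- ax^2 + ay^2 - L^2
  disc <- b^2 - 4 * a * cc
  len <- numeric(length(ax))
  ok <- disc > 0 & a > 0
  if (any(ok)) {
    sq <- sqrt(disc[ok])
    t0 <- pmax(0, (-b[ok] - sq) / (2 * a[ok]))
    t1 <- pmin(1, (-b[ok] + sq) / (2 * a[ok]))
    len[ok] <- pmax(0, t1 - t0) * sqrt(a[ok])
  }
  sum(len)
}

#' Length of water courses within a radius of a point
#'
#' Returns the total length of perennial (`W_p`) and non-perennial (`W_n`)
#' water-course portions lying within the disc of radius `L_w` around each
#' query point. Edges are clipped to the disc exactly (chord clipping) in a
#' local equirectangular projection about the point.
#'
#' @param lon,lat query point coordinate vectors (settlement locations).
#' @param water a water-course tibble from [load_water_courses()] or
#'   [generate_landscape()].
#' @param L_w search radius in km (> 0).
#' @return a two-column matrix with columns `W_p` and `W_n`, km.
#' @export
water_length_within <- function(lon, lat, water, L_w) {
  stopifnot(L_w > 0)
  n <- length(lon)
  out <- matrix(0, n, 2, dimnames = list(NULL, c("W_p", "W_n")))
  edges <- .water_edges(water)
  if (nrow(edges) == 0) return(out)
  exl <- pmin(edges$x1, edges$x2); exu <- pmax(edges$x1, edges$x2)
  eyl <- pmin(edges$y1, edges$y2); eyu <- pmax(edges$y1, edges$y2)
  dlat <- L_w / KM_PER_DEG
  for (i in seq_len(n)) {
    dlon <- L_w / (KM_PER_DEG * cos(lat[i] * pi / 180))
    near <- exu >= lon[i] - dlon & exl <= lon[i] + dlon &
            eyu >= lat[i] - dlat & eyl <= lat[i] + dlat
    if (!any(near)) next
    e <- edges[near, ]
    p1 <- .project_km(e$x1, e$y1, lon[i], lat[i])
    p2 <- .project_km(e$x2, e$y2, lon[i], lat[i])
    for (cls in c(TRUE, FALSE)) {
      j <- e$perennial == cls
      if (any(j)) {
        out[i, if (cls) "W_p" else "W_n"] <-
          .edge_length_in_disc(p1[j, 1], p1[j, 2], p2[j, 1], p2[j, 2], L_w)
      }
    }
  }
  out
}

## ---- uniform grid index for point neighbour queries ------------------------

# Uniform spatial grid over the simulation square with cell size >= radius,
# so any neighbour within `radius` of a point lies in the 3x3 cell block
# around it. Results are identical to a brute-force all-pairs scan.
.build_point_index <- function(lon, lat, bounds, cell_km) {
  dlat <- cell_km / KM_PER_DEG
  dlon <- cell_km / (KM_PER_DEG * cos(bounds$centre_lat * pi / 180))
  ix <- floor((lon - bounds$lon_min) / dlon)
  iy <- floor((lat - bounds$lat_min) / dlat)
  key <- paste(ix, iy)
  list(ix = ix, iy = iy, members = split(seq_along(lon), key))
}

.index_candidates <- function(index, i) {
  keys <- as.vector(outer(index$ix[i] + (-1:1), index$iy[i] + (-1:1), paste))
  unlist(index$members[keys], use.names = FALSE)
}

## ---- landscape container ---------------------------------------------------

#' Bind settlements, water courses and rainfall into a landscape
#'
#' @param settlements settlement tibble (`id`, `lon`, `lat`, ...).
#' @param water water-course tibble (see [load_water_courses()]).
#' @param rainfall a `rainfall_grid`.
#' @param bounds a [sim_bounds()] object.
#' @return an object of class `sahel_landscape`.
#' @export
landscape <- function(settlements, water, rainfall, bounds) {
  x <- structure(list(settlements = settlements, water = water,
                      rainfall = rainfall, bounds = bounds),
                 class = "sahel_landscape")
  validate_landscape(x)
  x
}

#' Validate a landscape object
#'
#' Checks the geographic-scene invariants: unique settlement ids with finite
#' coordinates inside the square, positive-length water segments with at
#' least two vertices, non-negative rainfall, and that every settlement maps
#' to exactly one rainfall cell.
#'
#' @param x a `sahel_landscape`.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_landscape <- function(x) {
  s <- x$settlements
  stopifnot(nrow(s) >= 1, !anyDuplicated(s$id),
            all(is.finite(s$lon)), all(is.finite(s$lat)))
  if (!all(in_bounds(s$lon, s$lat, x$bounds))) {
    stop("settlement(s) outside the simulation square", call. = FALSE)
  }
  if (nrow(x$water) > 0) {
    nv <- vapply(x$water$coords, nrow, integer(1))
    stopifnot(all(nv >= 2))
    lens <- vapply(x$water$coords, segment_length_km, numeric(1))
    stopifnot(all(lens > 0), is.logical(x$water$perennial))
  }
  stopifnot(all(x$rainfall$values >= 0))
  cells <- rainfall_cell(x$rainfall, s$lon, s$lat)  # errors if unmapped
  stopifnot(length(cells) == nrow(s))
  invisible(x)
}

#' @export
print.sahel_landscape <- function(x, ...) {
  wl <- if (nrow(x$water)) {
    tapply(vapply(x$water$coords, segment_length_km, numeric(1)),
           x$water$perennial, sum)
  } else c("FALSE" = 0, "TRUE" = 0)
  cat(sprintf(paste0(
    "sahel_landscape: %d settlements, %.0f km perennial + %.0f km ",
    "non-perennial water, %d rainfall weeks\n"),
    nrow(x$settlements), sum(wl[names(wl) == "TRUE"]),
    sum(wl[names(wl) == "FALSE"]), x$rainfall$n_weeks))
  print(x$bounds)
  invisible(x)
}

#' Total water-course length by class
#'
#' @param water a water-course tibble.
#' @return named numeric: total km for `perennial` and `nonperennial`.
#' @export
water_length_total <- function(water) {
  lens <- vapply(water$coords, segment_length_km, numeric(1))
  c(perennial = sum(lens[water$perennial]),
    nonperennial = sum(lens[!water$perennial]))
}
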