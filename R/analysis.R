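#' Per-replicate unoccupied fraction
#'
#' Fraction of settlements without an active adult population on the
#' reference day, per output year and replicate.
#'
#' @param result a `sahel_result`.
#' @return a tibble with columns `rep`, `year`, `fraction`.
#' @export
unoccupied_fraction <- function(result) {
  occ <- occupancy_on_date(result)
  nrep <- dim(occ)[3]
  ny <- dim(occ)[2]
  tibble::tibble(
    rep = rep(seq_len(nrep), each = ny),
    year = rep(result$out_years[seq_len(ny)], times = nrep),
    fraction = as.vector(apply(occ, c(2, 3), function(z) mean(!z))))
}

#' Unoccupied-fraction curve over a parameter sweep
#'
#' Collates the rainy-season unoccupied fraction across a set of runs that
#' share a landscape but differ in one swept setting (e.g. the local
#' dispersal rate d, an aestivation or migration parameter pair, or the
#' small-permanent-site moments).
#'
#' @param results named list of `sahel_result` objects (names label the
#'   swept setting).
#' @param values optional numeric vector aligned with `results` giving the
#'   swept parameter value; defaults to the names.
#' @return a list with `detail` (tibble: `value`, `rep`, `year`,
#'   `fraction`) and `summary` (tibble: `value`, `mean`, `sd`, `n_reps`,
#'   where `mean`/`sd` summarise per-replicate means across replicates).
#' @export
unoccupied_fraction_curve <- function(results, values = NULL) {
  stopifnot(length(results) >= 1)
  fps <- lapply(results, `[[`, "landscape_fingerprint")
  if (length(unique(fps)) != 1) {
    stop("results do not share a landscape", call. = FALSE)
  }
  if (is.null(values)) values <- names(results)
  detail <- do.call(rbind, lapply(seq_along(results), function(k) {
    d <- unoccupied_fraction(results[[k]])
    tibble::tibble(value = values[k], rep = d$rep, year = d$year,
                   fraction = d$fraction)
  }))
  per_rep <- stats::aggregate(fraction ~ value + rep, detail, mean)
  summary <- do.call(rbind, lapply(split(per_rep, per_rep$value), function(g) {
    tibble::tibble(value = g$value[1], mean = mean(g$fraction),
                   sd = stats::sd(g$fraction), n_reps = nrow(g))
  }))
  summary <- summary[match(unique(detail$value), summary$value), ]
  list(detail = tibble::as_tibble(detail),
       summary = tibble::as_tibble(summary))
}

#' Distance to the nearest persistent settlement
#'
#' @param ls a `sahel_landscape`.
#' @param persistent logical persistent flag per settlement (from
#'   [classify_persistent()]).
#' @return numeric vector, km; 0 for persistent settlements, `Inf` if no
#'   settlement is persistent.
#' @export
distance_to_persistent <- function(ls, persistent) {
  s <- ls$settlements
  if (!any(persistent)) return(rep(Inf, nrow(s)))
  pl <- s[persistent, ]
  out <- numeric(nrow(s))
  for (i in seq_len(nrow(s))) {
    out[i] <- if (persistent[i]) 0 else
      min(distance_km(s$lon[i], s$lat[i], pl$lon, pl$lat))
  }
  out
}

#' Number of settlements within a radius
#'
#' @param ls a `sahel_landscape`.
#' @param radius_km neighbourhood radius (default 10 km).
#' @return integer vector: settlements within `radius_km` of each focal
#'   settlement, excluding itself.
#' @export
settlement_density <- function(ls, radius_km = 10) {
  s <- ls$settlements
  n <- nrow(s)
  out <- integer(n)
  for (i in seq_len(n)) {
    dd <- distance_km(s$lon[i], s$lat[i], s$lon, s$lat)
    out[i] <- sum(dd <= radius_km) - 1L
  }
  out
}

#' Occupancy correlates of settlement status
#'
#' For every settlement: distance to the nearest persistent population,
#' local settlement density, occupancy probability across output years and
#' replicates, and a three-way class (persistent / colonised / unoccupied,
#' with colonised meaning occupied in at least `colonised_threshold` of
#' year-replicates). Also reports the two point-biserial correlations over
#' non-persistent settlements: colonised status against (minus) distance
#' and against density. In island-mainland dynamics occupancy is governed
#' by proximity to a persistent source, so the distance correlation
#' dominates the density one.
#'
#' @param result a `sahel_result`.
#' @param persistent logical flag per settlement.
#' @param ls the shared `sahel_landscape`.
#' @param density_radius_km radius for the settlement-density count.
#' @param colonised_threshold occupancy-probability threshold for the
#'   colonised class.
#' @return a list with `table` (per-settlement tibble) and the two
#'   correlations `cor_distance` (occupied vs distance) and `cor_density`
#'   (occupied vs density), computed over non-persistent settlements.
#' @export
site_correlates <- function(result, persistent, ls,
                            density_radius_km = 10,
                            colonised_threshold = 0.5) {
  stopifnot(length(persistent) == result$n_settlements)
  occ <- occupancy_on_date(result)
  occ_prob <- apply(occ, 1, mean)
  dist <- distance_to_persistent(ls, persistent)
  dens <- settlement_density(ls, density_radius_km)
  class <- ifelse(persistent, "persistent",
                  ifelse(occ_prob >= colonised_threshold, "colonised",
                         "unoccupied"))
  tab <- tibble::tibble(id = ls$settlements$id, persistent = persistent,
                        occ_prob = occ_prob, dist_km = dist,
                        density = dens, class = class)
  np <- !persistent
  colonised <- as.numeric(class[np] == "colonised")
  cor_or_na <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
    else stats::cor(x, y)
  }
  list(table = tab,
       cor_distance = cor_or_na(colonised, dist[np]),
       cor_density = cor_or_na(colonised, dens[np]))
}

#' Lifetime probability of an inter-settlement move
#'
#' Closed form `d / (d + mu_A - d * mu_A)`: the probability that an adult
#' makes at least one local inter-settlement move before dying, when each
#' day it attempts dispersal with probability `d` and then survives the day
#' with probability `1 - mu_A` (a dispersal attempt made on the day of
#' death still counts as a move, as it would in a mark-release-recapture
#' study). This is the quantity that maps field recapture estimates of
#' between-village movement onto the daily dispersal rate d.
#'
#' @param d daily dispersal probability.
#' @param mu_A daily adult mortality probability.
#' @return probability, vectorised.
#' @export
lifetime_movement_probability <- function(d, mu_A) {
  stopifnot(all(d >= 0), all(d <= 1), all(mu_A >= 0), all(mu_A <= 1))
  ifelse(d + mu_A == 0, 0, d / (d + mu_A - d * mu_A))
}

#' Monte-Carlo cross-check of the lifetime movement probability
#'
#' Simulates `n` independent adult lifetimes: a geometric lifespan with
#' daily mortality `mu_A` (the death day included, matching the counting
#' convention of [lifetime_movement_probability()]) and a daily dispersal
#' Bernoulli with probability `d`.
#'
#' @inheritParams lifetime_movement_probability
#' @param n number of simulated lifetimes.
#' @return a list with the point estimate `p_hat`, its standard error
#'   `se`, and `n`.
#' @export
simulate_lifetime_movements <- function(d, mu_A, n = 1e6) {
  stopifnot(mu_A > 0)
  days_alive <- stats::rgeom(n, mu_A) + 1L
  moved <- stats::runif(n) < 1 - (1 - d)^days_alive
  p <- mean(moved)
  list(p_hat = p, se = sqrt(p * (1 - p) / n), n = n)
}

.site_F_series <- function(result, sites) {
  lapply(result$reps, function(rp) {
    if (!is.null(rp$site_F)) {
      rs <- result$config$record_sites
      idx <- match(sites, rs)
      if (any(is.na(idx))) {
        stop("requested site(s) not in record_sites", call. = FALSE)
      }
      rp$site_F[idx, , drop = FALSE]
    } else if (!is.null(rp$series)) {
      rp$series$F[sites, , drop = FALSE]
    } else {
      stop("result holds no mated-female series: record daily series or ",
           "set record_sites", call. = FALSE)
    }
  })
}

#' Seasonal dynamics signatures under the dry-season hypotheses
#'
#' Extracts the daily active mated-female series of selected settlements
#' (typically sites remote from any persistent population) from one run per
#' dry-season hypothesis, and computes per site, output year and replicate:
#' the seasonal peak, the resurgence day (first day of year at or after
#' `season_start_doy` on which the series reaches `threshold_frac` of that
#' year's peak; NA when the peak stays below `peak_floor`, i.e. the site
#' was not colonised that year) and the dry-season mean and minimum over
#' the `dry_window` days of year. Aestivation produces early, synchronised
#' resurgence; migration later and more variable resurgence; permanent
#' larval sites a nonzero dry-season floor.
#'
#' @param results named list of `sahel_result` objects, one per hypothesis;
#'   each must carry the mated-female series for `sites` (daily record or
#'   `record_sites`).
#' @param sites settlement row indices to profile.
#' @param season_start_doy first day of year from which resurgence is
#'   sought.
#' @param threshold_frac resurgence threshold as a fraction of the
#'   site-year peak (scale-free).
#' @param peak_floor minimum site-year peak for the site to count as
#'   colonised.
#' @param dry_window two days of year bounding the dry-season window.
#' @return a tibble with columns `hypothesis`, `site`, `year`, `rep`,
#'   `peak`, `resurgence_doy`, `dry_mean`, `dry_min`.
#' @export
local_dynamics_profiles <- function(results, sites,
                                    season_start_doy = 140,
                                    threshold_frac = 0.1,
                                    peak_floor = 20,
                                    dry_window = c(30, 140)) {
  rows <- list()
  for (h in names(results)) {
    res <- results[[h]]
    days <- res$days
    series <- .site_F_series(res, sites)
    for (r in seq_along(series)) {
      Fm <- series[[r]]
      for (y in res$out_years) {
        cols <- which(days$year == y)
        doys <- days$doy[cols]
        dry_cols <- cols[doys >= dry_window[1] & doys <= dry_window[2]]
        for (k in seq_along(sites)) {
          fy <- Fm[k, cols]
          peak <- max(fy)
          res_doy <- NA_integer_
          if (peak >= peak_floor) {
            hit <- which(fy >= threshold_frac * peak & doys >= season_start_doy)
            if (length(hit)) res_doy <- doys[hit[1]]
          }
          rows[[length(rows) + 1L]] <- tibble::tibble(
            hypothesis = h, site = sites[k], year = y, rep = r, peak = peak,
            resurgence_doy = res_doy,
            dry_mean = mean(Fm[k, dry_cols]),
            dry_min = min(Fm[k, dry_cols]))
        }
      }
    }
  }
  do.call(rbind, rows)
}
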