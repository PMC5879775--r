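#' Assemble a simulation configuration
#'
#' Binds a landscape and all parameter blocks into a validated
#' configuration. Time is day-indexed on a 365-day no-leap calendar; day 1
#' is the first day of the rainfall series. Every settlement is seeded with
#' a fixed adult inoculum on day `start_doy` of year 1 (by default early in
#' the rainy-season build-up), the first `burn_in_years` calendar years are
#' treated as burn-in, and the following `years` years are the output
#' period.
#'
#' @param landscape a `sahel_landscape`.
#' @param habitat a [habitat_params()].
#' @param demography a [demography_params()].
#' @param aestivation an [aestivation_params()].
#' @param movement a [movement_params()].
#' @param years number of output (post-burn-in) years.
#' @param burn_in_years calendar years excluded from outputs.
#' @param start_doy day of year on which populations are inoculated.
#' @param inoculum named vector: initial `males` and mated `females` placed
#'   at every settlement.
#' @param replicates number of independent stochastic replicates.
#' @param seed master seed; replicate seeds and the per-replicate redraw of
#'   the small-permanent-site constants derive from it deterministically.
#' @param reference_doy day of year defining rainy-season occupancy
#'   (default 292 = 19 October).
#' @param record `"daily"` stores full per-settlement daily series of
#'   J_T, M, V, F and the aestivation ledger total; `"summary"` stores only
#'   occupancy and year-end presence (plus any `record_sites` series).
#' @param record_sites optional settlement row indices whose daily
#'   mated-female series is stored even under `record = "summary"`.
#' @param audit if `TRUE`, per-day conservation bookkeeping is recorded
#'   (adult totals before/after movement, movement deaths, aestivation
#'   ledger flows) and non-negativity/integrality of all counts is checked
#'   every day.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(landscape,
                              habitat = habitat_params(),
                              demography = demography_params(),
                              aestivation = aestivation_params(),
                              movement = movement_params(),
                              years = 3, burn_in_years = 2,
                              start_doy = 160L,
                              inoculum = c(males = 500, females = 500),
                              replicates = 1, seed = 1,
                              reference_doy = 292L,
                              record = c("daily", "summary"),
                              record_sites = NULL,
                              audit = FALSE) {
  stopifnot(inherits(landscape, "sahel_landscape"),
            inherits(habitat, "habitat_params"),
            inherits(demography, "demography_params"),
            inherits(aestivation, "aestivation_params"),
            inherits(movement, "movement_params"),
            years >= 1, burn_in_years >= 0,
            start_doy >= 1, start_doy <= 365,
            all(c("males", "females") %in% names(inoculum)),
            all(inoculum >= 0), replicates >= 1,
            reference_doy >= 1, reference_doy <= 365)
  record <- match.arg(record)
  total_years <- burn_in_years + years
  have_days <- landscape$rainfall$n_weeks * 7L
  if (total_years * 365L > have_days) {
    stop("rainfall series too short: need ", total_years * 365L,
         " days, have ", have_days, call. = FALSE)
  }
  structure(list(landscape = landscape, habitat = habitat,
                 demography = demography, aestivation = aestivation,
                 movement = movement, years = as.integer(years),
                 burn_in_years = as.integer(burn_in_years),
                 start_doy = as.integer(start_doy), inoculum = inoculum,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 reference_doy = as.integer(reference_doy), record = record,
                 record_sites = record_sites, audit = audit),
            class = "simulation_config")
}

.landscape_fingerprint <- function(ls) {
  c(n = nrow(ls$settlements),
    lon = round(sum(ls$settlements$lon), 6),
    lat = round(sum(ls$settlements$lat), 6))
}

.check_counts <- function(state, day) {
  for (f in c("J", "M", "V", "F", "E")) {
    x <- state[[f]]
    if (any(x < 0) || any(x %% 1 != 0)) {
      stop("non-integer or negative count in ", f, " on day ", day,
           call. = FALSE)
    }
  }
}

#' Run the individual-based simulation
#'
#' Executes the fixed daily event order over all settlements and days, for
#' each replicate: weekly refresh of the larval-competition scale alpha;
#' juvenile survival and ageing; emergence; adult survival, mating and
#' aestivation exit/entry; oviposition; local dispersal; long-distance
#' migration. Fully reproducible given the master seed. With
#' `psi = d_M = alpha0 = 0` this is the baseline model in which aestivation,
#' migration and cryptic permanent larval sites are all absent. Extinction
#' of the whole metapopulation ends a replicate early (remaining days are
#' all-zero) and is flagged in the result.
#'
#' @param config a [simulation_config()].
#' @return an object of class `sahel_result`: per-replicate occupancy flags
#'   (settlements by output years, on `reference_doy`), year-end presence
#'   (settlements by all years), daily series when recorded, audit tables
#'   when requested, plus run metadata.
#' @export
run_simulation <- function(config) {
  cf <- config
  ls <- cf$landscape
  n <- nrow(ls$settlements)
  dem <- cf$demography; aest <- cf$aestivation; mv <- cf$movement
  set.seed(cf$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  rep_seeds <- sample.int(.Machine$integer.max - 1L, cf$replicates)
  habitat <- build_habitat(ls, cf$habitat)
  network <- if (mv$d > 0) build_network(ls, mv$L_D) else NULL
  wedges <- if (mv$d_M > 0) build_wedges(ls) else NULL

  total_years <- cf$burn_in_years + cf$years
  start_day <- cf$start_doy
  total_days <- total_years * 365L
  n_days <- total_days - start_day + 1L
  out_years <- seq.int(cf$burn_in_years + 1L, total_years)
  ref_days <- (out_years - 1L) * 365L + cf$reference_doy
  ref_days <- ref_days[ref_days >= start_day]
  yearend_days <- seq_len(total_years) * 365L

  reps <- vector("list", cf$replicates)
  for (r in seq_len(cf$replicates)) {
    set.seed(rep_seeds[r], kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
    alpha0 <- sample_small_permanent_sites(n, cf$habitat)
    st <- new_population_state(n, dem)
    st$M[, 1] <- cf$inoculum[["males"]]
    st$F[, 1] <- cf$inoculum[["females"]]
    occ <- matrix(NA, n, length(ref_days))
    yearend <- matrix(NA, n, total_years)
    series <- NULL
    if (cf$record == "daily") {
      zi <- function() matrix(0L, n, n_days)
      series <- list(J_T = zi(), M = zi(), V = zi(), F = zi(), E = zi())
    }
    site_F <- if (!is.null(cf$record_sites)) {
      matrix(0L, length(cf$record_sites), n_days)
    } else NULL
    audit <- if (cf$audit) {
      matrix(0, n_days, 8, dimnames = list(NULL, c(
        "day", "active_pre_move", "active_post_disp", "active_post_mig",
        "migration_deaths", "E_total", "E_released", "E_entered")))
    } else NULL
    extinct_day <- NA_integer_
    week_cur <- -1L

    for (day in start_day:total_days) {
      t_idx <- day - start_day + 1L
      doy <- (day - 1L) %% 365L + 1L
      wk <- (day - 1L) %/% 7L + 1L
      if (wk != week_cur) {
        alpha <- weekly_alpha(habitat, ls$rainfall, wk, alpha0)
        week_cur <- wk
      }
      st <- step_juveniles(st, alpha, dem)
      em <- emerge(st$emergers)
      st$M[, 1] <- st$M[, 1] + em$males
      st$V[, 1] <- st$V[, 1] + em$females
      E_before <- sum(st$E)
      E_due <- sum(st$E[, doy])
      st <- step_adults(st, dem, aest, doy)
      st <- oviposit(st, dem)
      mig_deaths <- 0
      if (cf$audit) {
        active_pre <- sum(st$M) + sum(st$V) + sum(st$F)
      }
      if (mv$d > 0) st <- apply_local_dispersal(st, network, mv$d)
      if (cf$audit) {
        active_disp <- sum(st$M) + sum(st$V) + sum(st$F)
      }
      if (!is.null(wedges)) {
        st <- apply_migration(st, wedges, mv, doy)
        mig_deaths <- attr(st, "migration_deaths")
      }
      tot <- state_totals(st)
      if (cf$audit) {
        E_after <- sum(st$E)
        audit[t_idx, ] <- c(day, active_pre, active_disp,
                            sum(tot$active), mig_deaths, E_after, E_due,
                            E_after - E_before + E_due)
        .check_counts(st, day)
      }
      if (!is.null(series)) {
        series$J_T[, t_idx] <- tot$J_T
        series$M[, t_idx] <- tot$M
        series$V[, t_idx] <- tot$V
        series$F[, t_idx] <- tot$F
        series$E[, t_idx] <- tot$E
      }
      if (!is.null(site_F)) {
        site_F[, t_idx] <- tot$F[cf$record_sites]
      }
      if (day %in% ref_days) {
        occ[, match(day, ref_days)] <- tot$active >= 1
      }
      if (day %in% yearend_days) {
        yr <- day %/% 365L
        yearend[, yr] <- (tot$J_T + tot$active + tot$E) > 0
      }
      if (sum(tot$J_T) + sum(tot$active) + sum(tot$E) == 0) {
        extinct_day <- day
        # absorbing state: remaining records stay at their zero defaults
        later_ref <- ref_days[ref_days > day]
        if (length(later_ref)) occ[, match(later_ref, ref_days)] <- FALSE
        later_ye <- which(yearend_days > day)
        if (length(later_ye)) yearend[, later_ye] <- FALSE
        if (cf$audit && t_idx < n_days) {
          audit[(t_idx + 1L):n_days, "day"] <-
            seq(day + 1L, total_days)
        }
        break
      }
    }
    reps[[r]] <- list(occupancy = occ, yearend = yearend, series = series,
                      site_F = site_F, audit = audit,
                      extinct_day = extinct_day)
  }

  structure(list(
    reps = reps,
    n_settlements = n,
    days = tibble::tibble(day = start_day:total_days,
                          year = (start_day:total_days - 1L) %/% 365L + 1L,
                          doy = (start_day:total_days - 1L) %% 365L + 1L),
    out_years = out_years,
    ref_days = ref_days,
    config = cf[setdiff(names(cf), "landscape")],
    rep_seeds = rep_seeds,
    landscape_fingerprint = .landscape_fingerprint(ls)),
    class = "sahel_result")
}

#' @export
print.sahel_result <- function(x, ...) {
  cat(sprintf(
    "sahel_result: %d settlements, years %d..%d output, %d replicate(s)\n",
    x$n_settlements, min(x$out_years), max(x$out_years), length(x$reps)))
  frac <- unoccupied_fraction(x)
  cat(sprintf("  mean unoccupied fraction on doy %d: %.3f\n",
              x$config$reference_doy, mean(frac$fraction)))
  invisible(x)
}

#' Classify settlements as harbouring persistent populations
#'
#' Runs the model in full isolation mode -- no local dispersal, no
#' aestivation, no migration, no small permanent larval sites -- for
#' `years` years and classifies a settlement as persistent if a population
#' (any life stage) is present at every year-end, by majority vote across
#' replicates. These are the settlements that survive indefinitely on their
#' local rainfall and water-course habitat alone.
#'
#' @param config a [simulation_config()]; its movement, aestivation and
#'   small-permanent-site settings are overridden.
#' @param years persistence horizon in years (default 10).
#' @param replicates replicates for the majority vote (default 3).
#' @return logical vector: persistent flag per settlement.
#' @export
classify_persistent <- function(config, years = 10, replicates = 3) {
  hb <- config$habitat
  hb$alpha0_mean <- 0
  hb$alpha0_var <- 0
  mv <- config$movement
  mv$d <- 0
  mv$d_M <- 0
  ae <- config$aestivation
  ae$psi <- 0
  cf <- simulation_config(
    landscape = config$landscape, habitat = hb,
    demography = config$demography, aestivation = ae, movement = mv,
    years = years, burn_in_years = 0, start_doy = config$start_doy,
    inoculum = config$inoculum, replicates = replicates,
    seed = config$seed, reference_doy = config$reference_doy,
    record = "summary")
  res <- run_simulation(cf)
  votes <- vapply(res$reps, function(rp) {
    as.numeric(rowSums(rp$yearend) == ncol(rp$yearend))
  }, numeric(res$n_settlements))
  rowMeans(matrix(votes, res$n_settlements)) > 0.5
}

#' Occupancy flags on a given day of year
#'
#' A settlement counts as occupied when at least one active adult
#' (M + V + F; aestivating females excluded) is present on that day.
#' Requires a result recorded with `record = "daily"` unless `doy` is the
#' configured reference day, whose flags are always stored.
#'
#' @param result a `sahel_result`.
#' @param doy day of year (default: the configured reference day).
#' @return a 3-d logical array: settlements x output years x replicates.
#' @export
occupancy_on_date <- function(result, doy = NULL) {
  if (is.null(doy)) doy <- result$config$reference_doy
  nrep <- length(result$reps)
  n <- result$n_settlements
  if (doy == result$config$reference_doy) {
    out <- vapply(result$reps, function(rp) rp$occupancy,
                  matrix(NA, n, length(result$ref_days)))
    return(array(out, c(n, length(result$ref_days), nrep)) == 1)
  }
  if (is.null(result$reps[[1]]$series)) {
    stop("daily series not recorded: rerun with record = \"daily\" ",
         "or use the reference day", call. = FALSE)
  }
  days_wanted <- (result$out_years - 1L) * 365L + as.integer(doy)
  idx <- match(days_wanted, result$days$day)
  if (any(is.na(idx))) stop("date outside the simulated range", call. = FALSE)
  out <- vapply(result$reps, function(rp) {
    with(rp$series, M[, idx, drop = FALSE] + V[, idx, drop = FALSE] +
           F[, idx, drop = FALSE]) >= 1
  }, matrix(NA, n, length(idx)))
  array(out, c(n, length(idx), nrep)) == 1
}
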