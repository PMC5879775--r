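#' Demographic life-history parameters
#'
#' Daily per-settlement vital rates of the mosquito population model. The
#' juvenile stage spans all immature stages from egg to pre-reproductive
#' adult and lasts exactly `T_L` days. `mu_A = 0.125` and `beta = 100` are
#' fixed by the study design; the remaining defaults are literature-guided
#' placeholders (see the methods vignette).
#'
#' @param T_L egg-to-adult duration, integer days (>= 1).
#' @param mu_J daily density-independent juvenile mortality fraction; the
#'   factor `(1 - mu_J)` multiplies the daily density-dependent survival
#'   term, so density-independent survival over development is
#'   `(1 - mu_J)^T_L`.
#' @param mu_A daily adult mortality probability.
#' @param theta expected eggs per mated female per day.
#' @param beta male population size at which the daily mating probability of
#'   a virgin female is 0.5.
#' @param max_adult_age optional maximum adult longevity in days (the 30-day
#'   cap variant); `NULL` (default) disables adult age structure.
#' @return an object of class `demography_params`.
#' @export
demography_params <- function(T_L = 12L, mu_J = 0.03, mu_A = 0.125,
                              theta = 9, beta = 100, max_adult_age = NULL) {
  stopifnot(T_L >= 1, T_L == as.integer(T_L),
            mu_J >= 0, mu_J <= 1, mu_A >= 0, mu_A <= 1,
            theta >= 0, beta > 0,
            is.null(max_adult_age) || max_adult_age >= 1)
  structure(list(T_L = as.integer(T_L), mu_J = mu_J, mu_A = mu_A,
                 theta = theta, beta = beta,
                 max_adult_age = if (is.null(max_adult_age)) NULL
                                 else as.integer(max_adult_age)),
            class = "demography_params")
}

#' Aestivation parameters
#'
#' During an annual entry window, mated females enter dormancy with daily
#' probability `psi`; a fraction `1 - mu_E` survives dormancy, and each
#' survivor emerges on a uniform-random integer day within the emergence
#' window and resumes normal activity. Day-of-year windows use a 365-day
#' no-leap calendar and are closed intervals with `t1 <= t2`; the two
#' windows must not overlap.
#'
#' @param psi daily aestivation-entry probability of a mated female.
#' @param mu_E probability of dying over the course of aestivation.
#' @param t_A1,t_A2 entry window, days of year.
#' @param t_A3,t_A4 emergence window, days of year.
#' @return an object of class `aestivation_params`.
#' @export
aestivation_params <- function(psi = 0, mu_E = 0.9,
                               t_A1 = 280L, t_A2 = 340L,
                               t_A3 = 160L, t_A4 = 200L) {
  stopifnot(psi >= 0, psi <= 1, mu_E >= 0, mu_E <= 1,
            t_A1 >= 1, t_A2 <= 365, t_A1 <= t_A2,
            t_A3 >= 1, t_A4 <= 365, t_A3 <= t_A4)
  if (max(t_A1, t_A3) <= min(t_A2, t_A4)) {
    stop("aestivation entry and emergence windows overlap", call. = FALSE)
  }
  structure(list(psi = psi, mu_E = mu_E,
                 t_A1 = as.integer(t_A1), t_A2 = as.integer(t_A2),
                 t_A3 = as.integer(t_A3), t_A4 = as.integer(t_A4)),
            class = "aestivation_params")
}

.in_window <- function(doy, t1, t2) doy >= t1 & doy <= t2

#' Create an empty population state
#'
#' Integer-valued counts for `n` settlements: a juveniles-by-age matrix
#' (ages 1..T_L), adult males `M`, virgin females `V` and mated females `F`
#' (each an n-by-A matrix, where A is 1 without the longevity cap and
#' `max_adult_age` age classes with it), and an aestivation ledger `E`
#' (n by 365, column = booked day-of-year of emergence).
#'
#' @param n number of settlements.
#' @param params a [demography_params()].
#' @return an object of class `population_state`.
#' @export
new_population_state <- function(n, params) {
  A <- if (is.null(params$max_adult_age)) 1L else params$max_adult_age
  z <- function(k) matrix(0, n, k)
  structure(list(J = z(params$T_L), M = z(A), V = z(A), F = z(A),
                 E = z(365L), n = as.integer(n), T_L = params$T_L, A = A),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf(
    "population_state: %d settlement(s)  J_T=%d M=%d V=%d F=%d E=%d\n",
    x$n, sum(x$J), sum(x$M), sum(x$V), sum(x$F), sum(x$E)))
  invisible(x)
}

#' Totals per settlement
#'
#' @param state a `population_state`.
#' @return a list of per-settlement vectors `J_T`, `M`, `V`, `F`, `E` and
#'   `active` (= M + V + F; aestivators excluded).
#' @export
state_totals <- function(state) {
  M <- rowSums(state$M); V <- rowSums(state$V); F <- rowSums(state$F)
  list(J_T = rowSums(state$J), M = M, V = V, F = F,
       E = rowSums(state$E), active = M + V + F)
}

#' Daily juvenile survival probability
#'
#' `p_s = [alpha / (alpha + J_T)]^(1/T_L) * (1 - mu_J)`: the chance that a
#' juvenile survives one day, combining density-dependent larval
#' competition (with scale `alpha`, evaluated at the pre-update juvenile
#' total `J_T`) and density-independent mortality. With `J_T = alpha` and
#' `mu_J = 0`, cumulative density-dependent mortality over the `T_L` days of
#' development is exactly 0.5. `alpha = 0` gives 0.
#'
#' @param alpha larval-competition scale, juveniles (>= 0).
#' @param J_T total juveniles in the population (>= 0).
#' @param params a [demography_params()].
#' @return survival probability in `[0, 1]`, vectorised.
#' @export
juvenile_survival_prob <- function(alpha, J_T, params) {
  stopifnot(all(alpha >= 0), all(J_T >= 0))
  ratio <- ifelse(alpha + J_T == 0, 0, alpha / (alpha + J_T))
  ratio^(1 / params$T_L) * (1 - params$mu_J)
}

#' Advance juveniles by one day
#'
#' Each age class survives as a binomial draw with probability
#' [juvenile_survival_prob()] computed from the pre-update juvenile total;
#' survivors age by one day, and survivors of age `T_L` leave the juvenile
#' pool as the day's emergers (stored in `state$emergers`). Age class 1 is
#' left empty for the day's eggs.
#'
#' @param state a `population_state`.
#' @param alpha per-settlement larval-competition scale for the current
#'   week, juveniles.
#' @param params a [demography_params()].
#' @return the updated state, with `$emergers` set.
#' @export
step_juveniles <- function(state, alpha, params) {
  n <- state$n
  ps <- juvenile_survival_prob(alpha, rowSums(state$J), params)
  surv <- vapply(seq_len(state$T_L),
                 function(a) stats::rbinom(n, state$J[, a], ps),
                 numeric(n))
  surv <- matrix(surv, n, state$T_L)
  state$emergers <- surv[, state$T_L]
  state$J <- cbind(0, surv[, -state$T_L, drop = FALSE])
  state
}

#' Split emergers into adult males and virgin females
#'
#' Each emerging adult becomes a male or a virgin female with equal
#' probability (a binomial split; totals conserved).
#'
#' @param emergers per-settlement emerger counts.
#' @return a list with vectors `males` and `females`.
#' @export
emerge <- function(emergers) {
  males <- stats::rbinom(length(emergers), emergers, 0.5)
  list(males = males, females = emergers - males)
}

#' Daily mating probability of a virgin female
#'
#' `p_m = M / (beta + M)`: monotone in the male count `M`, equal to 0.5 at
#' `M = beta`, and 0 when no males are present.
#'
#' @param M male population size (>= 0).
#' @param beta half-saturation male population size (> 0).
#' @return probability in `[0, 1)`, vectorised over `M`.
#' @export
mating_prob <- function(M, beta) {
  stopifnot(all(M >= 0), beta > 0)
  M / (beta + M)
}

#' Release aestivating females due to emerge today
#'
#' Ledger entries booked to the current day of year move to the mated-female
#' class (age class 1 under the longevity-cap variant); the ledger is
#' otherwise conserved.
#'
#' @param state a `population_state`.
#' @param day_of_year integer in 1..365.
#' @return the updated state.
#' @export
release_aestivators <- function(state, day_of_year) {
  due <- state$E[, day_of_year]
  if (any(due > 0)) {
    state$F[, 1] <- state$F[, 1] + due
    state$E[, day_of_year] <- 0
  }
  state
}

#' Advance adults by one day
#'
#' In order: (1) binomial survival of males, virgin and mated females with
#' daily mortality `mu_A` (under the longevity-cap variant, survivors also
#' age by one day and adults exceeding `max_adult_age` are removed);
#' (2) surviving virgins mate with probability [mating_prob()] evaluated at
#' the post-survival male total and move to the mated class; (3) aestivation
#' exit: ledger entries due today are released to the mated class;
#' (4) aestivation entry (only within the entry window): each mated female
#' enters dormancy with probability `psi`; entrants surviving the
#' `1 - mu_E` draw are booked to a uniform-random emergence day within the
#' emergence window, the rest are removed.
#'
#' @param state a `population_state`.
#' @param params a [demography_params()].
#' @param aest an [aestivation_params()].
#' @param day_of_year integer in 1..365.
#' @return the updated state; attribute `deaths` holds the day's adult
#'   deaths (mortality + cap removals + failed aestivation entries).
#' @export
step_adults <- function(state, params, aest, day_of_year) {
  n <- state$n
  A <- state$A
  deaths <- 0
  surv_class <- function(X) {
    before <- sum(X)
    for (a in seq_len(A)) X[, a] <- stats::rbinom(n, X[, a], 1 - params$mu_A)
    if (A > 1L) {
      # survivors age one day; age class A would exceed the cap and is removed
      X <- cbind(0, X[, -A, drop = FALSE])
    }
    deaths <<- deaths + before - sum(X)
    X
  }
  state$M <- surv_class(state$M)
  state$V <- surv_class(state$V)
  state$F <- surv_class(state$F)
  pm <- mating_prob(rowSums(state$M), params$beta)
  for (a in seq_len(A)) {
    mated <- stats::rbinom(n, state$V[, a], pm)
    state$V[, a] <- state$V[, a] - mated
    state$F[, a] <- state$F[, a] + mated
  }
  state <- release_aestivators(state, day_of_year)
  if (aest$psi > 0 && .in_window(day_of_year, aest$t_A1, aest$t_A2)) {
    span <- aest$t_A4 - aest$t_A3 + 1L
    for (a in seq_len(A)) {
      entrants <- stats::rbinom(n, state$F[, a], aest$psi)
      if (!any(entrants > 0)) next
      state$F[, a] <- state$F[, a] - entrants
      survivors <- stats::rbinom(n, entrants, 1 - aest$mu_E)
      deaths <- deaths + sum(entrants - survivors)
      for (i in which(survivors > 0)) {
        days <- aest$t_A3 - 1L + sample.int(span, survivors[i], replace = TRUE)
        state$E[i, ] <- state$E[i, ] + tabulate(days, nbins = 365L)
      }
    }
  }
  attr(state, "deaths") <- deaths
  state
}

#' Daily oviposition
#'
#' Each mated female lays a Poisson(`theta`) number of eggs; by
#' superposition the settlement total is Poisson(`theta * F`). Eggs are
#' appended to juvenile age class 1.
#'
#' @param state a `population_state`.
#' @param params a [demography_params()].
#' @return the updated state; attribute `eggs` holds the per-settlement egg
#'   counts.
#' @export
oviposit <- function(state, params) {
  eggs <- stats::rpois(state$n, params$theta * rowSums(state$F))
  state$J[, 1] <- state$J[, 1] + eggs
  attr(state, "eggs") <- eggs
  state
}

## ---- deterministic-limit oracle -------------------------------------------

#' Expectation (deterministic-limit) trajectory of an isolated settlement
#'
#' Replaces every random draw of the daily update by its expectation,
#' yielding a difference-equation model for a single settlement with
#' constant larval-competition scale `alpha` and no movement or
#' aestivation. The event order matches the stochastic engine exactly:
#' juvenile survival/ageing, emergence, adult survival, mating,
#' oviposition.
#'
#' @param params a [demography_params()] (the longevity cap is ignored).
#' @param alpha constant larval-competition scale, juveniles.
#' @param days number of days to iterate.
#' @param init named vector with initial `M` (males) and `F` (mated
#'   females); juveniles and virgins start at zero.
#' @return a tibble with columns `day`, `J_T`, `M`, `V`, `F`.
#' @export
deterministic_trajectory <- function(params, alpha, days,
                                     init = c(M = 500, F = 500)) {
  J <- rep(0, params$T_L)
  M <- unname(init["M"]); V <- 0; F <- unname(init["F"])
  out <- matrix(0, days, 4, dimnames = list(NULL, c("J_T", "M", "V", "F")))
  for (t in seq_len(days)) {
    ps <- juvenile_survival_prob(alpha, sum(J), params)
    surv <- J * ps
    emergers <- surv[params$T_L]
    J <- c(0, surv[-params$T_L])
    M <- M + emergers / 2
    V <- V + emergers / 2
    M <- M * (1 - params$mu_A)
    V <- V * (1 - params$mu_A)
    F <- F * (1 - params$mu_A)
    pm <- mating_prob(M, params$beta)
    F <- F + V * pm
    V <- V * (1 - pm)
    J[1] <- params$theta * F
    out[t, ] <- c(sum(J), M, V, F)
  }
  tibble::tibble(day = seq_len(days), J_T = out[, 1], M = out[, 2],
                 V = out[, 3], F = out[, 4])
}

#' Fixed point of the deterministic-limit model
#'
#' Brute-force iteration of the expectation difference equation from a
#' given start until the daily state change falls below `tol` (relative),
#' locating the equilibrium of an isolated settlement with constant alpha.
#'
#' @inheritParams deterministic_trajectory
#' @param tol relative convergence tolerance on the full state vector.
#' @param max_days iteration cap (errors if reached without converging).
#' @return a named vector `J_T`, `M`, `V`, `F` at the fixed point.
#' @export
deterministic_fixed_point <- function(params, alpha,
                                      init = c(M = 500, F = 500),
                                      tol = 1e-10, max_days = 200000) {
  J <- rep(0, params$T_L)
  M <- unname(init["M"]); V <- 0; F <- unname(init["F"])
  for (t in seq_len(max_days)) {
    ps <- juvenile_survival_prob(alpha, sum(J), params)
    surv <- J * ps
    emergers <- surv[params$T_L]
    Jn <- c(0, surv[-params$T_L])
    Mn <- (M + emergers / 2) * (1 - params$mu_A)
    Vn <- (V + emergers / 2) * (1 - params$mu_A)
    Fn <- F * (1 - params$mu_A)
    pm <- mating_prob(Mn, params$beta)
    Fn <- Fn + Vn * pm
    Vn <- Vn * (1 - pm)
    Jn[1] <- params$theta * Fn
    delta <- max(abs(c(Jn - J, Mn - M, Vn - V, Fn - F)) /
                   pmax(1, abs(c(J, M, V, F))))
    J <- Jn; M <- Mn; V <- Vn; F <- Fn
    if (delta < tol) {
      return(c(J_T = sum(J), M = M, V = V, F = F))
    }
  }
  stop("fixed-point iteration did not converge within max_days",
       call. = FALSE)
}
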