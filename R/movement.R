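#' Movement parameters
#'
#' Local dispersal and seasonal long-distance migration. Adults of all
#' classes disperse daily with probability `d` to settlements within the
#' neighbourhood radius `L_D`, with kernel weight proportional to
#' `L_D - d_ij`. During two annual day-of-year windows, mated females
#' initiate wind-aligned long-distance migration with daily probability
#' `d_M`: NE to SW in the first window, SW to NE in the second. A migrant
#' survives the journey with probability `1 - mu_M` and relocates to a
#' settlement drawn uniformly from the directional wedge of candidate
#' destinations. Default windows are documented guesses at the regional
#' wind seasons (Harmattan, then monsoon onset).
#'
#' @param d daily local dispersal probability per adult.
#' @param L_D neighbourhood radius, km (> 0).
#' @param d_M daily migration-initiation probability for mated females.
#' @param mu_M probability of dying during migration.
#' @param t_D1,t_D2 NE-to-SW migration window, days of year (closed,
#'   `t_D1 <= t_D2`).
#' @param t_D3,t_D4 SW-to-NE migration window, days of year.
#' @return an object of class `movement_params`.
#' @export
movement_params <- function(d = 0.01, L_D = 10, d_M = 0, mu_M = 0.99,
                            t_D1 = 1L, t_D2 = 60L,
                            t_D3 = 160L, t_D4 = 220L) {
  stopifnot(d >= 0, d <= 1, L_D > 0, d_M >= 0, d_M <= 1,
            mu_M >= 0, mu_M <= 1,
            t_D1 >= 1, t_D2 <= 365, t_D1 <= t_D2,
            t_D3 >= 1, t_D4 <= 365, t_D3 <= t_D4)
  if (max(t_D1, t_D3) <= min(t_D2, t_D4)) {
    stop("migration windows overlap", call. = FALSE)
  }
  structure(list(d = d, L_D = L_D, d_M = d_M, mu_M = mu_M,
                 t_D1 = as.integer(t_D1), t_D2 = as.integer(t_D2),
                 t_D3 = as.integer(t_D3), t_D4 = as.integer(t_D4)),
            class = "movement_params")
}

#' Build the local dispersal network
#'
#' For every settlement, finds the neighbours at great-circle distance
#' strictly less than `L_D` (excluding itself; a pair at exactly `L_D`
#' gets zero weight and is dropped) and precomputes the normalised kernel
#' weights `w_ij = (L_D - d_ij) / sum_k (L_D - d_ik)`. Candidate pairs are
#' served by a uniform spatial grid index with cell size `L_D`; results are
#' identical to a brute-force all-pairs scan.
#'
#' @param ls a `sahel_landscape`.
#' @param L_D neighbourhood radius, km.
#' @return an object of class `dispersal_network`: lists `neighbours`,
#'   `dists`, `weights` indexed by settlement row, plus `L_D` and the
#'   logical vector `has_neighbours`.
#' @export
build_network <- function(ls, L_D) {
  stopifnot(L_D > 0)
  s <- ls$settlements
  n <- nrow(s)
  idx <- .build_point_index(s$lon, s$lat, ls$bounds, L_D)
  neighbours <- vector("list", n)
  dists <- vector("list", n)
  weights <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- .index_candidates(idx, i)
    cand <- cand[cand != i]
    if (length(cand)) {
      dd <- distance_km(s$lon[i], s$lat[i], s$lon[cand], s$lat[cand])
      keep <- dd < L_D
      cand <- cand[keep]; dd <- dd[keep]
    }
    if (length(cand)) {
      w <- L_D - dd
      neighbours[[i]] <- as.integer(cand)
      dists[[i]] <- dd
      weights[[i]] <- w / sum(w)
    } else {
      neighbours[[i]] <- integer(0)
      dists[[i]] <- numeric(0)
      weights[[i]] <- numeric(0)
    }
  }
  structure(list(neighbours = neighbours, dists = dists, weights = weights,
                 L_D = L_D,
                 has_neighbours = lengths(neighbours) > 0),
            class = "dispersal_network")
}

#' Apply one day of local dispersal
#'
#' Each adult (males, virgin and mated females; never juveniles or
#' aestivators) leaves its settlement with probability `d` (a binomial draw
#' per class), provided the settlement has at least one neighbour.
#' Emigrants are allocated to neighbours multinomially by the kernel
#' weights: every emigrant picks its destination independently, so one
#' multinomial draw per sending settlement covers all classes and age
#' columns, which are then split exchangeably over the destination slots.
#' Totals are conserved exactly.
#'
#' @param state a `population_state` covering all settlements.
#' @param network a [build_network()] result.
#' @param d daily dispersal probability.
#' @return the updated state.
#' @export
apply_local_dispersal <- function(state, network, d) {
  if (d <= 0) return(state)
  n <- state$n
  A <- state$A
  mask <- which(network$has_neighbours)
  if (!length(mask)) return(state)
  NB <- network$neighbours
  W <- network$weights
  if (A == 1L) {
    # unstructured adults: per-class destination draws (each emigrant picks
    # its destination independently, so the classes are independent
    # multinomials)
    M <- state$M; V <- state$V; F <- state$F
    eM <- numeric(n); eV <- numeric(n); eF <- numeric(n)
    eM[mask] <- stats::rbinom(length(mask), M[mask, 1L], d)
    eV[mask] <- stats::rbinom(length(mask), V[mask, 1L], d)
    eF[mask] <- stats::rbinom(length(mask), F[mask, 1L], d)
    M[, 1L] <- M[, 1L] - eM
    V[, 1L] <- V[, 1L] - eV
    F[, 1L] <- F[, 1L] - eF
    for (i in which(eM + eV + eF > 0)) {
      w <- W[[i]]
      nb <- NB[[i]]
      if (eM[i]) M[nb, 1L] <- M[nb, 1L] + stats::rmultinom(1L, eM[i], w)
      if (eV[i]) V[nb, 1L] <- V[nb, 1L] + stats::rmultinom(1L, eV[i], w)
      if (eF[i]) F[nb, 1L] <- F[nb, 1L] + stats::rmultinom(1L, eF[i], w)
    }
    state$M <- M; state$V <- V; state$F <- F
    return(state)
  }
  K <- 3L * A   # emigrant cells: M ages, then V ages, then F ages
  emig <- matrix(0, n, K)
  off <- 0L
  for (cls in c("M", "V", "F")) {
    X <- state[[cls]]
    for (a in seq_len(A)) {
      e <- numeric(n)
      e[mask] <- stats::rbinom(length(mask), X[mask, a], d)
      X[, a] <- X[, a] - e
      emig[, off + a] <- e
    }
    state[[cls]] <- X
    off <- off + A
  }
  tot <- rowSums(emig)
  for (i in which(tot > 0)) {
    nb <- NB[[i]]
    k <- length(nb)
    ti <- tot[i]
    dest_counts <- as.vector(stats::rmultinom(1, ti, W[[i]]))
    cells <- rep.int(seq_len(K), emig[i, ])
    if (ti > 1) cells <- cells[sample.int(ti)]
    dests <- rep.int(seq_len(k), dest_counts)
    tab <- matrix(tabulate((dests - 1L) * K + cells, nbins = k * K),
                  k, K, byrow = TRUE)
    state$M[nb, ] <- state$M[nb, ] + tab[, seq_len(A), drop = FALSE]
    state$V[nb, ] <- state$V[nb, ] + tab[, A + seq_len(A), drop = FALSE]
    state$F[nb, ] <- state$F[nb, ] + tab[, 2L * A + seq_len(A), drop = FALSE]
  }
  state
}

#' Build directional migration wedges
#'
#' For each settlement, the candidate destinations of NE-to-SW migration
#' are the settlements whose initial great-circle bearing from the focal
#' site lies strictly within 45 degrees of south-west (bearing 225); the
#' SW-to-NE wedge mirrors it about north-east (bearing 45). A settlement is
#' never its own destination; a site due north or due east of the focal
#' site (exactly on a wedge edge) belongs to neither set.
#'
#' @param ls a `sahel_landscape` with at least 2 settlements.
#' @return an object of class `migration_wedges`: lists `ne_sw` and
#'   `sw_ne` of candidate destination index vectors.
#' @export
build_wedges <- function(ls) {
  s <- ls$settlements
  n <- nrow(s)
  stopifnot(n >= 2)
  ne_sw <- vector("list", n)
  sw_ne <- vector("list", n)
  p <- cbind(s$lon, s$lat)
  for (i in seq_len(n)) {
    b <- geosphere::bearing(p[i, , drop = FALSE], p) %% 360
    ang_sw <- pmin(abs(b - 225), 360 - abs(b - 225))
    ang_ne <- pmin(abs(b - 45), 360 - abs(b - 45))
    ne_sw[[i]] <- setdiff(which(ang_sw < 45), i)
    sw_ne[[i]] <- setdiff(which(ang_ne < 45), i)
  }
  structure(list(ne_sw = ne_sw, sw_ne = sw_ne), class = "migration_wedges")
}

#' Apply one day of long-distance migration
#'
#' Active only when the day of year lies in one of the two migration
#' windows. Each mated female initiates migration with probability `d_M`
#' (females whose directional wedge is empty do not migrate); initiators
#' die en route with probability `mu_M`, and survivors relocate to a
#' destination drawn uniformly from the wedge. The adult total changes by
#' exactly the en-route deaths, recorded in the `migration_deaths`
#' attribute.
#'
#' @param state a `population_state`.
#' @param wedges a [build_wedges()] result.
#' @param params a [movement_params()].
#' @param day_of_year integer in 1..365.
#' @return the updated state with attribute `migration_deaths`.
#' @export
apply_migration <- function(state, wedges, params, day_of_year) {
  attr(state, "migration_deaths") <- 0
  if (params$d_M <= 0) return(state)
  sets <- if (.in_window(day_of_year, params$t_D1, params$t_D2)) {
    wedges$ne_sw
  } else if (.in_window(day_of_year, params$t_D3, params$t_D4)) {
    wedges$sw_ne
  } else {
    return(state)
  }
  n <- state$n
  mask <- lengths(sets) > 0
  if (!any(mask)) return(state)
  deaths <- 0
  for (a in seq_len(state$A)) {
    init <- integer(n)
    init[mask] <- stats::rbinom(sum(mask), state$F[mask, a], params$d_M)
    if (!any(init > 0)) next
    state$F[, a] <- state$F[, a] - init
    survivors <- stats::rbinom(n, init, 1 - params$mu_M)
    deaths <- deaths + sum(init - survivors)
    for (i in which(survivors > 0)) {
      w <- sets[[i]]
      dest <- w[sample.int(length(w), survivors[i], replace = TRUE)]
      arr <- tabulate(dest, nbins = n)
      state$F[, a] <- state$F[, a] + arr
    }
  }
  attr(state, "migration_deaths") <- deaths
  state
}

#' Mean local-dispersal distance per settlement
#'
#' The kernel-weighted mean distance of a single dispersal event from each
#' settlement (NA for isolated settlements). Dispersal from isolated,
#' sparsely neighboured settlements is typically longer-range than from
#' settlements inside dense clusters.
#'
#' @param network a [build_network()] result.
#' @return numeric vector of mean distances, km.
#' @export
mean_dispersal_distance <- function(network) {
  vapply(seq_along(network$neighbours), function(i) {
    if (!network$has_neighbours[i]) return(NA_real_)
    sum(network$weights[[i]] * network$dists[[i]])
  }, numeric(1))
}
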