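#' Carrying-capacity (larval habitat) parameters
#'
#' Parameters of the per-settlement, per-week larval-competition scale
#' alpha(x, t): the juvenile count at which density-dependent mortality over
#' development is 50%. It is the sum of a cryptic small-permanent-site
#' constant alpha0(x), a rainfall term saturating at `alpha1`, and a
#' water-course term saturating at `alpha2` in which non-perennial courses
#' are replenished by rain at rate `delta`.
#'
#' The saturation constants are calibration placeholders chosen to give
#' plausible village-scale populations (see the methods vignette); they are
#' not field estimates.
#'
#' @param alpha1 asymptote of the rainfall term, juveniles.
#' @param alpha2 asymptote of the water-course term, juveniles.
#' @param phi per-mm rainfall saturation rate, 1/mm.
#' @param kappa per-km water-density saturation rate, 1/km.
#' @param delta per-mm replenishment rate of intermittent courses, 1/mm.
#' @param L_w water-search radius around each settlement, km.
#' @param alpha0_mean,alpha0_var natural-scale mean and variance of the
#'   lognormal small-permanent-site constant across settlements, juveniles
#'   and juveniles^2; both 0 in the baseline model.
#' @return an object of class `habitat_params`.
#' @export
habitat_params <- function(alpha1 = 20000, alpha2 = 40000,
                           phi = 0.05, kappa = 0.1, delta = 0.05,
                           L_w = 2, alpha0_mean = 0, alpha0_var = 0) {
  p <- as.list(environment())
  stopifnot(all(unlist(p) >= 0), p$L_w > 0)
  if (p$alpha0_var > 0 && p$alpha0_mean == 0) {
    stop("alpha0_var > 0 with alpha0_mean = 0: lognormal undefined",
         call. = FALSE)
  }
  structure(p, class = "habitat_params")
}

#' Larval-competition scale alpha(x, t)
#'
#' Evaluates
#' `alpha = alpha0 + alpha1 (1 - exp(-phi r)) +
#'    alpha2 (1 - exp(-kappa [W_p + W_n (1 - exp(-delta r))]))`,
#' the juvenile density scale at settlement habitat (`W_p`, `W_n`, `alpha0`)
#' under weekly rainfall `r`. Vectorised over settlements; non-decreasing in
#' every argument. Under heavy rain the intermittent-course term converges
#' to the perennial one, so intermittent courses then provide the same
#' breeding habitat density as permanent ones.
#'
#' @param params a [habitat_params()].
#' @param r weekly rainfall, mm/week (>= 0).
#' @param W_p,W_n perennial and non-perennial water-course length within
#'   `L_w` of the settlement, km.
#' @param alpha0 small-permanent-site constant, juveniles.
#' @return alpha, juveniles.
#' @export
compute_alpha <- function(params, r, W_p = 0, W_n = 0, alpha0 = 0) {
  if (any(r < 0)) stop("negative rainfall", call. = FALSE)
  alpha0 +
    params$alpha1 * (1 - exp(-params$phi * r)) +
    params$alpha2 *
      (1 - exp(-params$kappa * (W_p + W_n * (1 - exp(-params$delta * r)))))
}

#' Draw small-permanent-site constants
#'
#' I.i.d. lognormal draws of alpha0(x) across settlements, parameterised by
#' the natural-scale mean `alpha0_mean` and variance `alpha0_var` (converted
#' internally to log-scale parameters). `alpha0_mean = 0` gives all zeros;
#' `alpha0_var = 0` gives the constant `alpha0_mean`.
#'
#' @param n number of settlements.
#' @param params a [habitat_params()].
#' @return numeric vector of length `n` (juveniles). Uses the current RNG
#'   stream; seed it with [set.seed()] for reproducibility.
#' @export
sample_small_permanent_sites <- function(n, params) {
  m <- params$alpha0_mean
  v <- params$alpha0_var
  if (m == 0) {
    if (v > 0) stop("alpha0_var > 0 with alpha0_mean = 0: lognormal undefined",
                    call. = FALSE)
    return(rep(0, n))
  }
  if (v == 0) return(rep(m, n))
  sdlog2 <- log(1 + v / m^2)
  stats::rlnorm(n, meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Build per-settlement habitat descriptors
#'
#' Computes, for every settlement of a landscape, the perennial and
#' non-perennial water-course length within `L_w` (via
#' [water_length_within()]), a draw of the small-permanent-site constant,
#' and the index of the rainfall cell supplying its weekly forcing r(x, t).
#'
#' @param ls a `sahel_landscape`.
#' @param params a [habitat_params()].
#' @return an object of class `sahel_habitat`: a list with `table` (tibble
#'   `id`, `W_p`, `W_n`, `alpha0`, `cell`) and `params`.
#' @export
build_habitat <- function(ls, params) {
  s <- ls$settlements
  W <- water_length_within(s$lon, s$lat, ls$water, params$L_w)
  alpha0 <- sample_small_permanent_sites(nrow(s), params)
  cell <- rainfall_cell(ls$rainfall, s$lon, s$lat)
  structure(list(
    table = tibble::tibble(id = s$id, W_p = W[, "W_p"], W_n = W[, "W_n"],
                           alpha0 = alpha0, cell = cell),
    params = params), class = "sahel_habitat")
}

#' Per-settlement alpha for one week
#'
#' @param habitat a `sahel_habitat`.
#' @param rainfall a `rainfall_grid`.
#' @param week week index into the rainfall series.
#' @param alpha0 optional replacement draw of the small-permanent-site
#'   constants (e.g. a per-replicate redraw); defaults to the one stored in
#'   `habitat`.
#' @return numeric vector of alpha values, juveniles.
#' @export
weekly_alpha <- function(habitat, rainfall, week, alpha0 = NULL) {
  stopifnot(week >= 1, week <= rainfall$n_weeks)
  h <- habitat$table
  if (is.null(alpha0)) alpha0 <- h$alpha0
  r <- rainfall$values[h$cell, week]
  compute_alpha(habitat$params, r, h$W_p, h$W_n, alpha0)
}
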