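.call_filtered <- function(fun, args) {
  if (is.null(args)) args <- list()
  do.call(fun, args[intersect(names(args), names(formals(fun)))])
}

#' Read a simulation configuration from YAML
#'
#' The YAML file has sections `landscape` (either `preset:` naming one of
#' [reference_scenarios()], with an optional `seed` override, or `dir:`
#' pointing at files written by [write_landscape()]), `habitat`,
#' `demography`, `aestivation`, `movement` (fields named after the model
#' symbols: alpha1, phi, kappa, delta, L_w, T_L, mu_J, mu_A, theta, beta,
#' d, L_D, psi, mu_E, t_A1..t_A4, d_M, mu_M, t_D1..t_D4, alpha0_mean,
#' alpha0_var) and `engine` (years, burn_in_years, start_doy, replicates,
#' seed, reference_doy, record, inoculum_males, inoculum_females). Missing
#' fields take the package defaults.
#'
#' @param path path to a YAML file.
#' @return a [simulation_config()].
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  lsec <- y$landscape
  if (!is.null(lsec$dir)) {
    ls <- read_landscape(lsec$dir)
  } else if (!is.null(lsec$preset)) {
    spec <- reference_scenarios()[[lsec$preset]]
    if (is.null(spec)) stop("unknown landscape preset ", lsec$preset,
                            call. = FALSE)
    if (!is.null(lsec$seed)) spec$seed <- lsec$seed
    ls <- generate_landscape(spec)
  } else {
    stop("config landscape section needs `preset` or `dir`", call. = FALSE)
  }
  eng <- if (is.null(y$engine)) list() else y$engine
  inoc <- c(males = eng$inoculum_males %||% 500,
            females = eng$inoculum_females %||% 500)
  eng <- eng[intersect(names(eng),
                       c("years", "burn_in_years", "start_doy", "replicates",
                         "seed", "reference_doy", "record"))]
  do.call(simulation_config, c(
    list(landscape = ls,
         habitat = .call_filtered(habitat_params, y$habitat),
         demography = .call_filtered(demography_params, y$demography),
         aestivation = .call_filtered(aestivation_params, y$aestivation),
         movement = .call_filtered(movement_params, y$movement),
         inoculum = inoc),
    eng))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write per-settlement habitat descriptors to CSV
#'
#' @param habitat a `sahel_habitat` from [build_habitat()].
#' @param path output CSV path (columns id, W_p, W_n, alpha0).
#' @return `path`, invisibly.
#' @export
write_habitat_csv <- function(habitat, path) {
  utils::write.csv(habitat$table[, c("id", "W_p", "W_n", "alpha0")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write the dispersal network to CSV
#'
#' @param network a [build_network()] result.
#' @param ls the `sahel_landscape` the network was built from (for ids).
#' @param path output CSV path (columns i, j, d_ij, w_ij, using settlement
#'   ids).
#' @return `path`, invisibly.
#' @export
write_network_csv <- function(network, ls, path) {
  ids <- ls$settlements$id
  rows <- do.call(rbind, lapply(seq_along(network$neighbours), function(i) {
    nb <- network$neighbours[[i]]
    if (!length(nb)) return(NULL)
    data.frame(i = ids[i], j = ids[nb], d_ij = network$dists[[i]],
               w_ij = network$weights[[i]])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write recorded daily series to CSV
#'
#' One row per settlement and day: settlement id, day index, day of year,
#' year, J_T, M, V, F and the aestivation-ledger total E.
#'
#' @param result a `sahel_result` recorded with `record = "daily"`.
#' @param path output CSV path.
#' @param rep replicate to dump (default 1).
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(result, path, rep = 1) {
  sr <- result$reps[[rep]]$series
  if (is.null(sr)) stop("daily series not recorded", call. = FALSE)
  n <- result$n_settlements
  nd <- nrow(result$days)
  df <- data.frame(
    id = rep(seq_len(n) - 1L, times = nd),
    day = rep(result$days$day, each = n),
    year = rep(result$days$year, each = n),
    doy = rep(result$days$doy, each = n),
    J_T = as.vector(sr$J_T), M = as.vector(sr$M), V = as.vector(sr$V),
    F = as.vector(sr$F), E = as.vector(sr$E))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
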