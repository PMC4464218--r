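#' Simulation configuration
#'
#' @param n_cells Cells sampled per induction (default 10,000).
#' @param hsl_grid Ascending vector of inducer concentrations (nM),
#'   non-negative; defaults to [default_hsl_grid()].
#' @param master_seed Integer master seed. Per-site, per-induction child
#'   seeds are derived deterministically from it, so any single induction
#'   can be re-simulated in isolation.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cells = 10000, hsl_grid = default_hsl_grid(),
                       master_seed = 1) {
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 2)
    stop("'n_cells' must be an integer >= 2", call. = FALSE)
  if (!is.numeric(hsl_grid) || length(hsl_grid) == 0L)
    stop("'hsl_grid' must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(hsl_grid)) || any(hsl_grid < 0))
    stop("'hsl_grid' values must be finite and non-negative", call. = FALSE)
  if (is.unsorted(hsl_grid, strictly = TRUE))
    stop("'hsl_grid' must be strictly ascending", call. = FALSE)
  structure(list(n_cells = as.integer(n_cells), hsl_grid = hsl_grid,
                 master_seed = master_seed),
            class = "sim_config")
}

#' Simulate single-cell outputs of a noisy cascade
#'
#' For every induction level, draws `n_cells` single-cell trajectories
#' through the cascade. Stage 1's deterministic output is evaluated at the
#' inducer concentration; if the stage carries a noise site, the
#' (optionally mean-corrected) value is multiplied per cell by a lognormal
#' factor. Each later stage evaluates its Hill function on each cell's
#' upstream output — cells are tracked through the cascade, not re-sampled —
#' and then applies its own noise site, if any. When the network's `rho` is
#' positive, the first two noisy sites share correlated Gaussian log-noise.
#'
#' Under the `constant_var` law at a downstream site the deterministic value
#' differs between cells, so `sigma2` is computed per cell from each cell's
#' own deterministic output, keeping the per-cell variance contract.
#'
#' @param network A [network_spec()].
#' @param sim A [sim_config()].
#' @return List of `population_sample` objects, one per stage; each holds
#'   the stage name, the induction grid, an `n_cells x n_inductions` matrix
#'   of single-cell values and per-induction summaries (mean and 2.5/97.5
#'   percentiles).
#' @examples
#' net <- two_module_network(noise_sites = list(
#'   noise_spec("constant_cv", 0.15), NULL))
#' pops <- simulate_network(net, sim_config(n_cells = 500, master_seed = 7))
#' population_summary_df(pops)
#' @export
simulate_network <- function(network, sim) {
  if (!inherits(network, "network_spec"))
    stop("'network' must be a network_spec", call. = FALSE)
  if (!inherits(sim, "sim_config"))
    stop("'sim' must be a sim_config", call. = FALSE)
  grid <- sim$hsl_grid
  n <- sim$n_cells
  stages <- network$stages
  sites <- network$noise_sites
  S <- length(stages)
  noisy <- which(vapply(sites, function(s) s$model != "none", logical(1)))
  pair <- if (network$rho > 0 && length(noisy) >= 2) noisy[1:2] else NULL
  cells <- lapply(seq_len(S), function(s)
    matrix(NA_real_, nrow = n, ncol = length(grid)))

  for (i in seq_along(grid)) {
    # standard-normal draws per noisy site; a correlated pair is drawn
    # jointly under the first site's child seed
    z <- vector("list", S)
    for (s in noisy) {
      if (!is.null(pair) && s == pair[2L]) next
      sd_si <- child_seed(sim$master_seed, site = s, induction = i)
      if (!is.null(pair) && s == pair[1L]) {
        zz <- correlated_std_normal(network$rho, n, sd_si)
        z[[pair[1L]]] <- zz[, 1L]
        z[[pair[2L]]] <- zz[, 2L]
      } else {
        z[[s]] <- with_rng_seed(sd_si, stats::rnorm(n))
      }
    }
    up <- NULL
    for (s in seq_len(S)) {
      det <- if (s == 1L) rep(hill_response(stages[[s]], grid[i]), n)
             else hill_response(stages[[s]], up)
      spec <- sites[[s]]
      if (spec$model != "none") {
        if (any(det <= 0))
          stop("noise site at stage ", s,
               " has non-positive deterministic output", call. = FALSE)
        s2 <- switch(spec$model,
          constant_cv  = sigma2_from_cv(spec$level),
          constant_var = sigma2_from_var(spec$level, det))
        base <- if (spec$corrected) det * exp(-s2 / 2) else det
        val <- base * exp(sqrt(s2) * z[[s]])
      } else {
        val <- det
      }
      cells[[s]][, i] <- val
      up <- val
    }
  }

  lapply(seq_len(S), function(s) {
    m <- cells[[s]]
    sm <- t(apply(m, 2L, summarize_population))
    structure(
      list(stage = names(stages)[s], hsl = grid, cells = m,
           mean = sm[, 1L], lo95 = sm[, 2L], hi95 = sm[, 3L]),
      class = "population_sample")
  })
}

#' @export
print.population_sample <- function(x, ...) {
  cat(sprintf("<population_sample> stage '%s': %d cells x %d inductions\n",
              x$stage, nrow(x$cells), length(x$hsl)))
  print(utils::head(population_summary_df(list(x)), 5L))
  invisible(x)
}

#' Summarize a single-cell population
#'
#' Arithmetic mean and the 2.5th/97.5th empirical percentiles of a
#' single-cell output distribution. The percentile band describes
#' cell-to-cell spread, not the standard error of the mean.
#'
#' @param cells Numeric vector of at least 2 single-cell values.
#' @return Named numeric vector `c(mean, lo95, hi95)`.
#' @export
summarize_population <- function(cells) {
  if (!is.numeric(cells) || length(cells) < 2L)
    stop("need at least 2 single-cell values", call. = FALSE)
  q <- stats::quantile(cells, c(0.025, 0.975), names = FALSE)
  c(mean = mean(cells), lo95 = q[1L], hi95 = q[2L])
}

#' Tidy exports of population samples
#'
#' `population_cells_df()` returns one row per (stage, induction, cell);
#' `population_summary_df()` one row per (stage, induction) with mean and
#' 95% cell-to-cell interval.
#'
#' @param pops List of `population_sample` objects from
#'   [simulate_network()].
#' @return A `data.frame`.
#' @export
population_cells_df <- function(pops) {
  do.call(rbind, lapply(pops, function(p) {
    data.frame(
      stage = p$stage,
      hsl_nM = rep(p$hsl, each = nrow(p$cells)),
      cell_index = rep(seq_len(nrow(p$cells)), times = length(p$hsl)),
      value = as.vector(p$cells),
      stringsAsFactors = FALSE)
  }))
}

#' @rdname population_cells_df
#' @export
population_summary_df <- function(pops) {
  do.call(rbind, lapply(pops, function(p) {
    data.frame(stage = p$stage, hsl_nM = p$hsl, mean = p$mean,
               lo95 = p$lo95, hi95 = p$hi95, stringsAsFactors = FALSE)
  }))
}
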