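#' Configuration of a module-characterization study
#'
#' Bundles everything one in-silico study needs: the cascade, the noise law
#' and its entities (one simulated experiment per entity), the optional
#' second noise site and its extrinsic correlation, the simulation settings
#' and the generating ("true") parameters of the module under study.
#'
#' @param network A [network_spec()] holding the noiseless cascade (its own
#'   noise sites are ignored; the study installs them per entity).
#' @param model Noise law, `"constant_cv"` or `"constant_var"`.
#' @param entities Vector of noise levels, one simulated experiment per
#'   entity: CVs for `constant_cv` (study defaults 0.15, 0.55, 0.75),
#'   variances in RPU^2 for `constant_var` (defaults 0.05, 0.1, 0.15).
#' @param sim A [sim_config()].
#' @param true_params Generating [hill_params()] of the module under study;
#'   defaults to the network's stage-2 parameters.
#' @param module_stage Index of the stage whose transfer function is fitted
#'   (default 2: averaged stage-2 output against averaged stage-1 output).
#' @param rho Log-noise correlation between the two noise sites (only
#'   meaningful with `output2_level`).
#' @param output2_level Optional noise entity applied to the module-under-
#'   study output itself (same law as `model`); `NULL` for noise on the
#'   upstream output only.
#' @param output2_corrected Mean-correction flag for the second site.
#' @return An object of class `study_config`.
#' @export
study_config <- function(network,
                         model = c("constant_cv", "constant_var"),
                         entities = NULL,
                         sim = sim_config(),
                         true_params = NULL,
                         module_stage = 2,
                         rho = 0,
                         output2_level = NULL,
                         output2_corrected = TRUE) {
  model <- match.arg(model)
  if (!inherits(network, "network_spec"))
    stop("'network' must be a network_spec", call. = FALSE)
  if (is.null(entities))
    entities <- if (model == "constant_cv") c(0.15, 0.55, 0.75)
                else c(0.05, 0.10, 0.15)
  if (!is.numeric(entities) || length(entities) < 1L ||
      any(!is.finite(entities)) || any(entities < 0))
    stop("'entities' must be non-negative noise levels", call. = FALSE)
  module_stage <- as.integer(module_stage)
  if (module_stage < 2L || module_stage > length(network$stages))
    stop("'module_stage' must index a downstream stage", call. = FALSE)
  if (is.null(true_params)) true_params <- network$stages[[module_stage]]
  if (!is.null(output2_level) &&
      (!is.numeric(output2_level) || output2_level < 0))
    stop("'output2_level' must be a non-negative level", call. = FALSE)
  structure(
    list(network = network, model = model, entities = entities, sim = sim,
         true_params = true_params, module_stage = module_stage, rho = rho,
         output2_level = output2_level,
         output2_corrected = isTRUE(output2_corrected)),
    class = "study_config")
}

#' Sample CV across repeated estimates
#'
#' Coefficient of variation, in percent, of a set of parameter estimates:
#' sample standard deviation (n - 1 denominator) over the mean, times 100.
#'
#' @param estimates At least 2 finite values.
#' @return CV in percent; `NaN` (with a warning) if the mean is zero.
#' @examples
#' cv_across(c(3.00, 3.04, 3.06))  # 1.0
#' @export
cv_across <- function(estimates) {
  if (!is.numeric(estimates) || sum(is.finite(estimates)) < 2L)
    stop("need at least 2 finite estimates", call. = FALSE)
  estimates <- estimates[is.finite(estimates)]
  m <- mean(estimates)
  if (m == 0) {
    warning("mean of estimates is zero; CV undefined", call. = FALSE)
    return(NaN)
  }
  100 * stats::sd(estimates) / m
}

#' Maximum percentage difference from a reference value
#'
#' `max(|estimate - truth| / truth) * 100` over a set of estimates, the
#' deviation statistic used to compare estimated with generating
#' parameters. The denominator is always the reference value.
#'
#' @param estimates Numeric estimates.
#' @param truth Positive reference value.
#' @return Maximum percentage difference.
#' @export
max_pct_diff <- function(estimates, truth) {
  if (!is.numeric(truth) || length(truth) != 1L || !is.finite(truth) ||
      truth <= 0)
    stop("'truth' must be a single positive value", call. = FALSE)
  max(abs(estimates - truth) / truth) * 100
}

# per-parameter spread and deviation summary; delta is reported but kept
# out of the headline statistics (it sits near the bound and its relative
# spread is uninformative)
comparison_summary <- function(estimates, true_params,
                               headline = c("alpha", "k", "eta")) {
  pars <- c("alpha", "delta", "k", "eta")
  cv <- vapply(pars, function(p) {
    if (sum(is.finite(estimates[[p]])) < 2L) return(NA_real_)
    suppressWarnings(cv_across(estimates[[p]]))
  }, numeric(1))
  md <- vapply(pars, function(p) {
    tr <- true_params[[p]]
    if (tr <= 0) return(NA_real_)
    max_pct_diff(estimates[[p]], tr)
  }, numeric(1))
  structure(list(cv_pct = cv, max_pct_diff = md, headline = headline,
                 true_params = true_params, estimates = estimates),
            class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat("<comparison_summary>\n")
  tab <- data.frame(cv_pct = round(x$cv_pct, 2),
                    max_pct_diff = round(x$max_pct_diff, 2))
  tab$headline <- ifelse(rownames(tab) %in% x$headline, "*", "")
  print(tab)
  invisible(x)
}

#' Characterize a module from population-averaged data
#'
#' The central single-module study: for each noise entity, simulate the
#' cascade with that entity's noise on the upstream (stage-1) output — and,
#' if configured, correlated noise on the module output itself — average
#' the single-cell outputs per induction, and fit the module's Hill
#' function to averaged module output versus averaged upstream output.
#' Spread (CV) across the entity-wise estimates and maximum percentage
#' difference from the generating parameters are then summarized, with
#' `delta` excluded from the headline statistics.
#'
#' @param cfg A [study_config()].
#' @return An object of class `module_characterization`: `estimates` (one
#'   row per entity with fitted parameters and fit diagnostics), `fits`
#'   (the underlying `fit_result`s) and `summary` (a `comparison_summary`).
#' @examples
#' \donttest{
#' cfg <- study_config(two_module_network(),
#'                     sim = sim_config(master_seed = 1))
#' characterize_module(cfg)$summary
#' }
#' @export
characterize_module <- function(cfg) {
  if (!inherits(cfg, "study_config"))
    stop("'cfg' must be a study_config", call. = FALSE)
  st <- cfg$module_stage
  logic <- cfg$network$stages[[st]]$logic
  fits <- vector("list", length(cfg$entities))
  rows <- vector("list", length(cfg$entities))
  for (j in seq_along(cfg$entities)) {
    sites <- rep(list(noise_spec("none")), length(cfg$network$stages))
    sites[[1L]] <- noise_spec(cfg$model, cfg$entities[j])
    if (!is.null(cfg$output2_level))
      sites[[st]] <- noise_spec(cfg$model, cfg$output2_level,
                                corrected = cfg$output2_corrected)
    net <- network_spec(cfg$network$stages, noise_sites = sites,
                        input_name = cfg$network$input_name, rho = cfg$rho)
    sim_j <- sim_config(cfg$sim$n_cells, cfg$sim$hsl_grid,
                        child_seed(cfg$sim$master_seed, entity = j))
    pops <- simulate_network(net, sim_j)
    f <- fit_hill(pops[[st - 1L]]$mean, pops[[st]]$mean, logic = logic)
    fits[[j]] <- f
    rows[[j]] <- data.frame(
      entity = cfg$entities[j],
      alpha = f$params$alpha, delta = f$params$delta,
      k = f$params$k, eta = f$params$eta,
      residual_norm = f$residual_norm, converged = f$converged,
      stringsAsFactors = FALSE)
  }
  estimates <- do.call(rbind, rows)
  structure(
    list(estimates = estimates, fits = fits,
         summary = comparison_summary(estimates, cfg$true_params),
         config = cfg),
    class = "module_characterization")
}

#' @export
print.module_characterization <- function(x, ...) {
  cat(sprintf("<module_characterization> %s, %d entities\n",
              x$config$model, nrow(x$estimates)))
  print(x$estimates, digits = 4)
  print(x$summary)
  invisible(x)
}

#' Sensitivity of identification statistics to gate parameters
#'
#' Repeats [characterize_module()] while one structural parameter of the
#' module under study (`k` or `eta`) is moved across a grid, all other
#' parameters held at their nominal values. Collects the CV-across-entities
#' and max-percentage-difference curves for every parameter.
#'
#' @param varied `"k"` or `"eta"`.
#' @param grid Values for the varied parameter. Defaults:
#'   `k` in {0.1, 0.2, 0.5, 1, 1.5, 2} RPU, `eta` in {0.5, 1, ..., 3.5}.
#' @param cfg A [study_config()]; its network's module-under-study
#'   parameters provide the nominal values.
#' @return `data.frame` with columns `varied`, `value`, `param`, `cv_pct`,
#'   `max_pct_diff`.
#' @export
sensitivity_scan <- function(varied = c("k", "eta"), grid = NULL, cfg) {
  varied <- match.arg(varied)
  if (is.null(grid))
    grid <- if (varied == "k") c(0.1, 0.2, 0.5, 1, 1.5, 2)
            else seq(0.5, 3.5, by = 0.5)
  out <- vector("list", length(grid))
  for (g in seq_along(grid)) {
    p0 <- cfg$network$stages[[cfg$module_stage]]
    p1 <- hill_params(
      alpha = p0$alpha, delta = p0$delta,
      k = if (varied == "k") grid[g] else p0$k,
      eta = if (varied == "eta") grid[g] else p0$eta,
      logic = p0$logic)
    stages <- cfg$network$stages
    stages[[cfg$module_stage]] <- p1
    cfg_g <- cfg
    cfg_g$network <- network_spec(stages,
                                  input_name = cfg$network$input_name,
                                  rho = cfg$network$rho)
    cfg_g$true_params <- p1
    ch <- characterize_module(cfg_g)
    pars <- c("alpha", "delta", "k", "eta")
    out[[g]] <- data.frame(
      varied = varied, value = grid[g], param = pars,
      cv_pct = unname(ch$summary$cv_pct[pars]),
      max_pct_diff = unname(ch$summary$max_pct_diff[pars]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Extrinsic-noise sweep
#'
#' Varies the log-noise correlation `rho` between the upstream noise site
#' and a noise site on the module output itself, re-running the
#' characterization at each value. `rho` tunes the proportion of extrinsic
#' (shared-resource) noise: 0 is purely intrinsic, 1 purely extrinsic.
#' With an uncorrected second site the generating `alpha` and `delta` are
#' rescaled by the mean of the uncompensated lognormal factor before
#' computing percentage differences.
#'
#' @param rho_values Correlations in `[0, 1]` (default
#'   {0, 0.25, 0.5, 0.75, 1}).
#' @param cfg A [study_config()]; if its `output2_level` is unset, a
#'   constant-CV level of 0.15 (or variance 0.15 under `constant_var`) is
#'   installed on the module output.
#' @return `data.frame` with columns `rho`, `param`, `cv_pct`,
#'   `max_pct_diff`.
#' @export
extrinsic_sweep <- function(rho_values = c(0, 0.25, 0.5, 0.75, 1), cfg) {
  if (any(rho_values < 0 | rho_values > 1))
    stop("'rho_values' must lie in [0, 1]", call. = FALSE)
  if (is.null(cfg$output2_level)) cfg$output2_level <- 0.15
  out <- vector("list", length(rho_values))
  for (r in seq_along(rho_values)) {
    cfg_r <- cfg
    cfg_r$rho <- rho_values[r]
    ch <- characterize_module(cfg_r)
    truth <- cfg$true_params
    if (!cfg$output2_corrected && cfg$model == "constant_cv") {
      ave <- lognormal_moments(sigma2_from_cv(cfg$output2_level))$ave
      truth <- new_hill_params(truth$alpha * ave, truth$delta * ave,
                               truth$k, truth$eta, truth$logic)
    }
    sm <- comparison_summary(ch$estimates, truth)
    pars <- c("alpha", "delta", "k", "eta")
    out[[r]] <- data.frame(
      rho = rho_values[r], param = pars,
      cv_pct = unname(sm$cv_pct[pars]),
      max_pct_diff = unname(sm$max_pct_diff[pars]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# coerce a module_characterization / data.frame / list of hill_params into
# a list of hill_params with the given logic
as_param_sets <- function(x, logic) {
  if (inherits(x, "module_characterization")) x <- x$estimates
  if (is.data.frame(x)) {
    return(lapply(seq_len(nrow(x)), function(i)
      new_hill_params(x$alpha[i], x$delta[i], x$k[i], x$eta[i], logic)))
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "hill_params")))
    return(x)
  stop("cannot interpret parameter sets", call. = FALSE)
}

#' Black-box prediction from individually characterized modules
#'
#' Composes every combination of the stage-2 and stage-3 estimate sets
#' (typically 3 noise entities each, giving 9 combinations) with the
#' nominal input device, without noise, and fits the black-box Hill
#' function of the inducer to each composed response. The spread of the
#' starred parameters across combinations measures how much the noise
#' context of module characterization propagates into network predictions.
#'
#' @param gate_sets,gate3_sets Parameter sets for the two downstream
#'   modules: a `module_characterization`, a `data.frame` with columns
#'   `alpha`, `delta`, `k`, `eta`, or a list of [hill_params()].
#' @param input_params Nominal [hill_params()] of the input device.
#' @param hsl_grid Induction grid for the composition and fit.
#' @param gate_logic,gate3_logic Logic of the two downstream modules.
#' @return An object of class `blackbox_study`: `estimates` (one row per
#'   combination), `fits`, and `cv_pct` (per starred parameter).
#' @export
blackbox_prediction_study <- function(gate_sets, gate3_sets,
                                      input_params = default_params()$hsl_input,
                                      hsl_grid = default_hsl_grid(),
                                      gate_logic = "repressing",
                                      gate3_logic = "repressing") {
  a <- as_param_sets(gate_sets, gate_logic)
  b <- as_param_sets(gate3_sets, gate3_logic)
  rows <- list(); fits <- list(); r <- 0L
  for (i in seq_along(a)) for (j in seq_along(b)) {
    r <- r + 1L
    f <- predict_blackbox(input_params, list(a[[i]], b[[j]]),
                          hsl_grid = hsl_grid)
    fits[[r]] <- f
    rows[[r]] <- data.frame(
      gate_set = i, gate3_set = j,
      alpha = f$params$alpha, delta = f$params$delta,
      k = f$params$k, eta = f$params$eta,
      converged = f$converged, stringsAsFactors = FALSE)
  }
  estimates <- do.call(rbind, rows)
  cv <- vapply(c("alpha", "delta", "k", "eta"),
               function(p) suppressWarnings(cv_across(estimates[[p]])),
               numeric(1))
  structure(list(estimates = estimates, fits = fits, cv_pct = cv),
            class = "blackbox_study")
}

#' @export
print.blackbox_study <- function(x, ...) {
  cat(sprintf("<blackbox_study> %d fitted black-box functions\n",
              nrow(x$estimates)))
  print(x$estimates, digits = 4)
  cat("CV (%):\n"); print(round(x$cv_pct, 2))
  invisible(x)
}

#' Deterministic black-box reference
#'
#' Fits the black-box Hill function to the noiseless three-module cascade
#' built from the generating parameters — the reference against which
#' noise-influenced predictions are measured.
#'
#' @param input_params,gate_params,gate3_params Generating
#'   [hill_params()] for the three stages.
#' @param hsl_grid Induction grid; a dense grid by default.
#' @return A `fit_result`.
#' @export
blackbox_noiseless_reference <- function(input_params = default_params()$hsl_input,
                                         gate_params = default_params()$tetr_ptet,
                                         gate3_params = default_params()$laci_plac,
                                         hsl_grid = dense_hsl_grid()) {
  predict_blackbox(input_params, list(gate_params, gate3_params),
                   hsl_grid = hsl_grid)
}

#' Black-box identification from noisy network simulations
#'
#' Simulates the full three-module network with noise on both the stage-1
#' and stage-2 outputs, for every pairing of the configured entities
#' (3 x 3 = 9 conditions by default), averages the end output per
#' induction, and fits the black-box Hill function of the inducer. This is
#' the in-silico analogue of measuring a deployed network whose noise
#' context differs from the one its modules were characterized in.
#'
#' @param cfg A [study_config()] for the three-module network; `entities`
#'   are applied to both noise sites (all ordered pairs), `rho` couples
#'   them (independent sites by default).
#' @return A `blackbox_study` with one row per `(entity1, entity2)` pair.
#' @export
blackbox_simulation_study <- function(cfg) {
  if (!inherits(cfg, "study_config"))
    stop("'cfg' must be a study_config", call. = FALSE)
  if (length(cfg$network$stages) < 3L)
    stop("the simulation study needs a three-stage network", call. = FALSE)
  ents <- cfg$entities
  rows <- list(); fits <- list(); r <- 0L
  for (a in seq_along(ents)) for (b in seq_along(ents)) {
    r <- r + 1L
    sites <- rep(list(noise_spec("none")), length(cfg$network$stages))
    sites[[1L]] <- noise_spec(cfg$model, ents[a])
    sites[[2L]] <- noise_spec(cfg$model, ents[b])
    net <- network_spec(cfg$network$stages, noise_sites = sites,
                        input_name = cfg$network$input_name, rho = cfg$rho)
    sim_r <- sim_config(cfg$sim$n_cells, cfg$sim$hsl_grid,
                        child_seed(cfg$sim$master_seed, entity = r))
    pops <- simulate_network(net, sim_r)
    last <- length(pops)
    f <- fit_hill(cfg$sim$hsl_grid, pops[[last]]$mean, logic = "activating")
    fits[[r]] <- f
    rows[[r]] <- data.frame(
      entity1 = ents[a], entity2 = ents[b],
      alpha = f$params$alpha, delta = f$params$delta,
      k = f$params$k, eta = f$params$eta,
      converged = f$converged, stringsAsFactors = FALSE)
  }
  estimates <- do.call(rbind, rows)
  cv <- vapply(c("alpha", "delta", "k", "eta"),
               function(p) suppressWarnings(cv_across(estimates[[p]])),
               numeric(1))
  structure(list(estimates = estimates, fits = fits, cv_pct = cv),
            class = "blackbox_study")
}

#' Cross-compare predicted and simulated black-box parameter sets
#'
#' Compares every predicted black-box parameter set against every simulated
#' one (9 x 9 = 81 ordered pairs by default). For each parameter the
#' percentage difference is `|simulated - predicted| / predicted * 100`
#' (the predicted set is the reference), and the maximum over all pairs is
#' reported together with the identities of the pair attaining it.
#'
#' @param predicted,simulated `blackbox_study` objects or data.frames with
#'   columns `alpha`, `delta`, `k`, `eta`.
#' @return `data.frame` with one row per parameter: `param`,
#'   `max_pct_diff`, `pred_row`, `sim_row`.
#' @export
cross_compare <- function(predicted, simulated) {
  p <- if (inherits(predicted, "blackbox_study")) predicted$estimates
       else predicted
  s <- if (inherits(simulated, "blackbox_study")) simulated$estimates
       else simulated
  pars <- c("alpha", "delta", "k", "eta")
  out <- lapply(pars, function(pa) {
    d <- abs(outer(p[[pa]], s[[pa]], function(pp, ss) ss - pp)) /
      p[[pa]] * 100
    w <- which(d == max(d), arr.ind = TRUE)[1L, ]
    data.frame(param = pa, max_pct_diff = max(d),
               pred_row = unname(w[1L]), sim_row = unname(w[2L]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
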