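#' List built-in study configurations
#'
#' The package ships one YAML configuration per study of the reference
#' analysis: single-module characterizations for each gate and noise law,
#' sensitivity scans, the extrinsic-noise sweep, the deterministic
#' black-box reference, the black-box prediction and simulation studies and
#' their cross-comparison.
#'
#' @return Named character vector of config file paths.
#' @export
list_studies <- function() {
  dir <- system.file("studies", package = "noisecascade", mustWork = TRUE)
  paths <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  stats::setNames(paths, sub("\\.yaml$", "", basename(paths)))
}

study_kinds <- c("characterize", "sensitivity", "extrinsic",
                 "blackbox_reference", "blackbox_prediction",
                 "blackbox_simulation", "cross_comparison")

validate_study_config <- function(cfg) {
  # YAML sequences mixing ints and doubles arrive as lists; flatten them
  for (f in c("entities", "rho_values", "varied_grid"))
    if (!is.null(cfg[[f]])) cfg[[f]] <- as.numeric(unlist(cfg[[f]]))
  bad <- character(0)
  req_num <- function(field, min = -Inf, optional = FALSE) {
    v <- cfg[[field]]
    if (is.null(v)) { if (!optional) bad <<- c(bad, field); return() }
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < min))
      bad <<- c(bad, field)
  }
  if (is.null(cfg$study) || !cfg$study %in% study_kinds)
    stop("unknown study '", cfg$study %||% "<missing>", "'; valid: ",
         paste(study_kinds, collapse = ", "), call. = FALSE)
  if (is.null(cfg$name) || !nzchar(cfg$name)) bad <- c(bad, "name")
  req_num("seed")
  req_num("n_cells", min = 2, optional = TRUE)
  req_num("entities", min = 0, optional = TRUE)
  req_num("rho", min = 0, optional = TRUE)
  req_num("rho_values", min = 0, optional = TRUE)
  req_num("output2_level", min = 0, optional = TRUE)
  if (!is.null(cfg$gate) &&
      !cfg$gate %in% c("tetr_ptet", "laci_plac", "yes_gate"))
    bad <- c(bad, "gate")
  if (!is.null(cfg$model) &&
      !cfg$model %in% c("constant_cv", "constant_var"))
    bad <- c(bad, "model")
  if (!is.null(cfg$varied) && !cfg$varied %in% c("k", "eta"))
    bad <- c(bad, "varied")
  if (length(bad))
    stop("invalid study config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_sim <- function(cfg) {
  grid <- default_hsl_grid(n = cfg$grid_points %||% 14,
                           lo = cfg$grid_lo %||% 1e-1,
                           hi = cfg$grid_hi %||% 1e5)
  sim_config(n_cells = cfg$n_cells %||% 10000, hsl_grid = grid,
             master_seed = cfg$seed)
}

config_study <- function(cfg, seed_offset = 0) {
  sim <- config_sim(cfg)
  sim$master_seed <- child_seed(sim$master_seed, entity = seed_offset)
  net <- two_module_network(gate = cfg$gate %||% "tetr_ptet")
  study_config(net, model = cfg$model %||% "constant_cv",
               entities = cfg$entities, sim = sim,
               rho = cfg$rho %||% 0,
               output2_level = cfg$output2_level)
}

run_study_impl <- function(cfg, output_dir) {
  nm <- cfg$name
  files <- character(0)
  emit <- function(df, suffix) {
    path <- file.path(output_dir, paste0(nm, "_", suffix, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  summary_df <- function(sm) {
    pars <- c("alpha", "delta", "k", "eta")
    data.frame(param = pars, cv_pct = unname(sm$cv_pct[pars]),
               max_pct_diff = unname(sm$max_pct_diff[pars]),
               headline = pars %in% sm$headline)
  }
  bb_df <- function(bb) {
    est <- bb$estimates
    est$cv_pct_alpha <- bb$cv_pct[["alpha"]]
    est$cv_pct_k <- bb$cv_pct[["k"]]
    est$cv_pct_eta <- bb$cv_pct[["eta"]]
    est
  }
  switch(cfg$study,
    characterize = {
      ch <- characterize_module(config_study(cfg))
      emit(ch$estimates, "estimates")
      emit(summary_df(ch$summary), "summary")
    },
    sensitivity = {
      sc <- sensitivity_scan(varied = cfg$varied %||% "eta",
                             grid = cfg$varied_grid,
                             cfg = config_study(cfg))
      emit(sc, "scan")
    },
    extrinsic = {
      sw <- extrinsic_sweep(rho_values = cfg$rho_values %||%
                              c(0, 0.25, 0.5, 0.75, 1),
                            cfg = config_study(cfg))
      emit(sw, "sweep")
    },
    blackbox_reference = {
      f <- blackbox_noiseless_reference(
        hsl_grid = dense_hsl_grid(n = cfg$grid_points %||% 50))
      emit(as.data.frame(f$params), "reference")
    },
    blackbox_prediction = {
      tet <- characterize_module(config_study(cfg, seed_offset = 1))
      lac_cfg <- cfg; lac_cfg$gate <- "laci_plac"
      lac <- characterize_module(config_study(lac_cfg, seed_offset = 2))
      bb <- blackbox_prediction_study(tet, lac,
                                      hsl_grid = config_sim(cfg)$hsl_grid)
      emit(bb_df(bb), "prediction")
    },
    blackbox_simulation = {
      sim <- config_sim(cfg)
      sim$master_seed <- child_seed(sim$master_seed, entity = 3)
      bcfg <- study_config(three_module_network(),
                           model = cfg$model %||% "constant_cv",
                           entities = cfg$entities, sim = sim,
                           rho = cfg$rho %||% 0)
      bb <- blackbox_simulation_study(bcfg)
      emit(bb_df(bb), "simulation")
    },
    cross_comparison = {
      tet <- characterize_module(config_study(cfg, seed_offset = 1))
      lac_cfg <- cfg; lac_cfg$gate <- "laci_plac"
      lac <- characterize_module(config_study(lac_cfg, seed_offset = 2))
      pred <- blackbox_prediction_study(tet, lac,
                                        hsl_grid = config_sim(cfg)$hsl_grid)
      sim <- config_sim(cfg)
      sim$master_seed <- child_seed(sim$master_seed, entity = 3)
      bcfg <- study_config(three_module_network(),
                           model = cfg$model %||% "constant_cv",
                           entities = cfg$entities, sim = sim,
                           rho = cfg$rho %||% 0)
      simd <- blackbox_simulation_study(bcfg)
      emit(bb_df(pred), "prediction")
      emit(bb_df(simd), "simulation")
      emit(cross_compare(pred, simd), "comparison")
    })
  files
}

#' Run one study from a configuration file
#'
#' Executes the study named in a flat-key YAML configuration, writes its
#' CSV outputs and a JSON run manifest (resolved configuration, seed, file
#' checksums, timestamp) into `output_dir`, and returns the manifest.
#' Given the same configuration and seed, output CSVs are byte-identical
#' across runs.
#'
#' @param config Path to a YAML study configuration, or an equivalent named
#'   list. See [list_studies()] for the packaged examples.
#' @param output_dir Output directory (created if missing).
#' @param seed_override Optional integer replacing the config's seed.
#' @return The manifest, invisibly.
#' @export
run_study <- function(config, output_dir, seed_override = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.null(seed_override)) cfg$seed <- seed_override
  cfg <- validate_study_config(cfg)
  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  message(sprintf("[noisecascade] study=%s name=%s seed=%s n_cells=%s",
                  cfg$study, cfg$name, cfg$seed,
                  cfg$n_cells %||% 10000))
  files <- run_study_impl(cfg, output_dir)
  manifest <- list(
    study = cfg$study, name = cfg$name, config = cfg, seed = cfg$seed,
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))),
    package_version = as.character(utils::packageVersion("noisecascade")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  mpath <- file.path(output_dir, paste0(cfg$name, "_manifest.json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Run every built-in study
#'
#' Executes all packaged study configurations end-to-end with a single
#' seed, writing each study's CSVs and manifest into `output_dir`.
#' Individual study failures are recorded and the remaining studies still
#' run.
#'
#' @param output_dir Output directory.
#' @param seed Integer seed applied to every study.
#' @return Named list of manifests (or `try-error`s), invisibly.
#' @export
reproduce_all <- function(output_dir, seed = 1) {
  paths <- list_studies()
  out <- lapply(names(paths), function(nm) {
    tryCatch(run_study(paths[[nm]], output_dir, seed_override = seed),
             error = function(e) {
               warning("study '", nm, "' failed: ", conditionMessage(e),
                       call. = FALSE)
               e
             })
  })
  names(out) <- names(paths)
  invisible(out)
}
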