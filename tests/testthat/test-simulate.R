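test_that("a noise-free network reproduces the deterministic cascade exactly", {
  net <- three_module_network()
  sim <- small_sim(seed = 2, n = 50)
  pops <- simulate_network(net, sim)
  det <- cascade_response(net, sim$hsl_grid)
  for (s in seq_along(pops)) {
    expect_equal(pops[[s]]$mean, unname(det[, s]), tolerance = 1e-14)
    # every cell identical
    expect_true(all(apply(pops[[s]]$cells, 2, function(col)
      diff(range(col)) == 0)))
  }
})

test_that("mean-corrected noise preserves the population mean", {
  # basal induction: mean OUTPUT1 stays at delta_IN = 0.05 within 3 SE
  net <- two_module_network(noise_sites = list(
    noise_spec("constant_cv", 0.15), NULL))
  sim <- sim_config(n_cells = 10000, master_seed = 9)
  pops <- simulate_network(net, sim)
  se <- 0.05 * 0.15 / sqrt(10000)
  expect_lt(abs(pops[[1]]$mean[1] - 0.05), 3 * se)
  # mean invariance across noise entities at every induction
  det <- hill_response(ref$hsl_input, sim$hsl_grid)
  for (cv in c(0.15, 0.55, 0.75)) {
    netj <- two_module_network(noise_sites = list(
      noise_spec("constant_cv", cv), NULL))
    pj <- simulate_network(netj, sim)
    se_j <- det * cv / sqrt(10000)
    expect_true(all(abs(pj[[1]]$mean - det) < 3 * se_j))
  }
})

test_that("the realized cell-to-cell CV matches the requested entity", {
  net <- two_module_network(noise_sites = list(
    noise_spec("constant_cv", 0.75), NULL))
  pops <- simulate_network(net, sim_config(n_cells = 10000, master_seed = 4))
  cells <- pops[[1]]$cells
  cvs <- apply(cells, 2, function(v) sd(v) / mean(v))
  expect_true(all(cvs > 0.72 & cvs < 0.78))
})

test_that("cells are tracked through the cascade, not re-sampled", {
  net <- two_module_network(noise_sites = list(
    noise_spec("constant_cv", 0.55), NULL))
  pops <- simulate_network(net, small_sim(seed = 3, n = 200))
  expect_equal(pops[[2]]$cells[, 5],
               hill_response(ref$tetr_ptet, pops[[1]]$cells[, 5]),
               tolerance = 1e-14)
})

test_that("simulation is reproducible and seeds isolate inductions", {
  net <- two_module_network(noise_sites = list(
    noise_spec("constant_cv", 0.55), NULL))
  a <- simulate_network(net, small_sim(seed = 31, n = 300))
  b <- simulate_network(net, small_sim(seed = 31, n = 300))
  expect_identical(a[[2]]$cells, b[[2]]$cells)
  # truncating the grid leaves earlier inductions untouched
  g <- default_hsl_grid()
  c3 <- simulate_network(net, sim_config(300, g[1:5], 31))
  expect_identical(c3[[1]]$cells[, 3], a[[1]]$cells[, 3])
})

test_that("summarize_population gives mean and 95% cell-to-cell band", {
  expect_equal(summarize_population(rep(2.2, 10)),
               c(mean = 2.2, lo95 = 2.2, hi95 = 2.2))
  set.seed(1)
  v <- 2.05 * draw_noise(sigma2_from_cv(0.15), 10000, seed = 12)$samples *
    exp(-sigma2_from_cv(0.15) / 2)
  s <- summarize_population(v)
  expect_gt(s[["mean"]], 2.04); expect_lt(s[["mean"]], 2.06)
  expect_lt(s[["lo95"]], s[["mean"]]); expect_gt(s[["hi95"]], s[["mean"]])
  expect_error(summarize_population(3), "at least 2")
})

test_that("NOT gates attenuate and YES gates amplify correlated noise", {
  sim <- sim_config(n_cells = 4000, master_seed = 17)
  pop_cv <- function(gate, rho) {
    net <- two_module_network(gate, noise_sites = list(
      noise_spec("constant_var", 0.1),
      noise_spec("constant_var", 0.1)), rho = rho)
    pops <- simulate_network(net, sim)
    cvs <- apply(pops[[2]]$cells, 2, function(v) sd(v) / mean(v))
    mean(cvs)
  }
  expect_lt(pop_cv("tetr_ptet", 0.5), pop_cv("tetr_ptet", 0))
  expect_gt(pop_cv("yes_gate", 0.5), pop_cv("yes_gate", 0))
})

test_that("noise on a stage with non-positive deterministic value errors", {
  gate0 <- hill_params(1, 0, 0.5, 1, "activating")
  zero_delta_input <- hill_params(4, 0, 700, 0.9, "activating")
  net <- network_spec(list(input = zero_delta_input, gate = gate0),
                      noise_sites = list(noise_spec("constant_cv", 0.5),
                                         NULL))
  expect_error(simulate_network(net, small_sim(n = 10)), "non-positive")
})

test_that("tidy exports are shaped correctly", {
  net <- two_module_network(noise_sites = list(
    noise_spec("constant_cv", 0.15), NULL))
  sim <- small_sim(seed = 5, n = 20)
  pops <- simulate_network(net, sim)
  cells <- population_cells_df(pops)
  expect_identical(names(cells), c("stage", "hsl_nM", "cell_index", "value"))
  expect_equal(nrow(cells), 2 * 20 * length(sim$hsl_grid))
  sm <- population_summary_df(pops)
  expect_identical(names(sm), c("stage", "hsl_nM", "mean", "lo95", "hi95"))
  expect_equal(nrow(sm), 2 * length(sim$hsl_grid))
})
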