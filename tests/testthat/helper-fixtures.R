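# nominal device parameters used across tests
ref <- default_params()

# independent scalar Hill oracle: plain arithmetic, no package code
hill_oracle <- function(alpha, delta, k, eta, x, activating) {
  if (activating) {
    if (x == 0) return(delta)
    delta + alpha / (1 + (k / x)^eta)
  } else {
    delta + alpha / (1 + (x / k)^eta)
  }
}

small_sim <- function(seed = 1, n = 2000, grid = default_hsl_grid())
  sim_config(n_cells = n, hsl_grid = grid, master_seed = seed)

# random valid Hill parameters under a fixed-seed stream
random_hill <- function(logic) {
  hill_params(alpha = runif(1, 0.2, 5), delta = runif(1, 0, 0.2),
              k = 10^runif(1, -1, 1), eta = runif(1, 0.6, 3.2),
              logic = logic)
}
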