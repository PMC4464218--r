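#' Nominal device parameter sets
#'
#' Loads the packaged parameter sets for the four reference devices: the
#' 3OC6-HSL-inducible LuxR/Plux input device, the TetR/Ptet NOT gate, the
#' LacI/Plac NOT gate and the A/PA YES gate (a mock activator with the same
#' structural parameters as the TetR gate). These are the nominal ("true")
#' transfer functions used throughout the study drivers.
#'
#' @return Named list of [hill_params()]:
#'   `hsl_input`, `tetr_ptet`, `laci_plac`, `yes_gate`.
#' @examples
#' default_params()$tetr_ptet
#' @export
default_params <- function() {
  read_params_json(system.file("extdata", "device_params.json",
                               package = "noisecascade", mustWork = TRUE))
}

#' Read / write Hill parameter sets as JSON
#'
#' Parameter sets are stored as a JSON document keyed by module name, each
#' entry holding fields `alpha`, `delta`, `k`, `eta` and `logic`.
#'
#' @param path File path.
#' @return `read_params_json()`: a named list of [hill_params()].
#' @export
read_params_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(doc, function(e) {
    hill_params(alpha = e$alpha, delta = e$delta, k = e$k, eta = e$eta,
                logic = e$logic)
  })
  names(out) <- names(doc)
  out
}

#' @rdname read_params_json
#' @param params Named list of [hill_params()].
#' @export
write_params_json <- function(params, path) {
  doc <- lapply(params, function(p)
    list(alpha = p$alpha, delta = p$delta, k = p$k, eta = p$eta,
         logic = p$logic))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Reference network constructors
#'
#' Convenience builders for the cascades studied by the package drivers.
#' `two_module_network()` chains the inducible input device into one gate
#' (by default the TetR/Ptet NOT gate); `three_module_network()` appends the
#' LacI/Plac NOT gate downstream of the TetR gate.
#'
#' @param gate A [hill_params()] for the downstream module, or one of the
#'   names `"tetr_ptet"`, `"laci_plac"`, `"yes_gate"`.
#' @param input_params [hill_params()] of the input device.
#' @param noise_sites,rho Passed to [network_spec()].
#' @return A [network_spec()].
#' @export
two_module_network <- function(gate = "tetr_ptet",
                               input_params = default_params()$hsl_input,
                               noise_sites = NULL, rho = 0) {
  if (is.character(gate)) {
    nm <- match.arg(gate, c("tetr_ptet", "laci_plac", "yes_gate"))
    gate <- default_params()[[nm]]
    gname <- nm
  } else gname <- "gate"
  stages <- list(input = input_params, gate = gate)
  names(stages) <- c("input", gname)
  network_spec(stages, noise_sites = noise_sites, rho = rho)
}

#' @rdname two_module_network
#' @export
three_module_network <- function(input_params = default_params()$hsl_input,
                                 gate = default_params()$tetr_ptet,
                                 gate3 = default_params()$laci_plac,
                                 noise_sites = NULL, rho = 0) {
  network_spec(list(input = input_params, tetr_ptet = gate,
                    laci_plac = gate3),
               noise_sites = noise_sites, rho = rho)
}

#' Induction grids
#'
#' `default_hsl_grid()` is the induction grid used by the study drivers:
#' zero inducer plus `n` log-spaced concentrations between `lo` and `hi`
#' (nM). The default spans 1e-1 to 1e5 nM, i.e. at least three decades on
#' each side of the input device's half-effect concentration (700 nM).
#' `dense_hsl_grid()` is the same construction with 50 points, used for
#' deterministic black-box fits.
#'
#' @param n Number of log-spaced points (excluding zero).
#' @param lo,hi Grid endpoints (nM).
#' @return Sorted numeric vector starting at 0.
#' @export
default_hsl_grid <- function(n = 14, lo = 1e-1, hi = 1e5) {
  stopifnot(n >= 2, lo > 0, hi > lo)
  c(0, 10^seq(log10(lo), log10(hi), length.out = n))
}

#' @rdname default_hsl_grid
#' @export
dense_hsl_grid <- function(n = 50, lo = 1e-1, hi = 1e5) {
  default_hsl_grid(n = n, lo = lo, hi = hi)
}
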