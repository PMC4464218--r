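#' Hill transfer-function parameters for a genetic module
#'
#' A steady-state genetic module (an inducible device, a NOT gate or a YES
#' gate) is described by four parameters of a Hill equation plus its logic.
#' For an activating module the response to input `x` is
#' `delta + alpha / (1 + (k/x)^eta)`; for a repressing module it is
#' `delta + alpha / (1 + (x/k)^eta)`. In both cases `delta` is the basal
#' synthesis rate, `delta + alpha` the maximal rate, `k` the half-effect
#' input level and `eta` the Hill coefficient (steepness).
#'
#' Units: `alpha` and `delta` are in Relative Promoter Units (RPU), a
#' standardized proxy for per-cell protein synthesis rate. `k` is expressed
#' in the units of the module input: nM of inducer for the external-input
#' device, RPU for modules driven by an upstream module. `eta` is
#' dimensionless. No unit conversion is performed by the package.
#'
#' @param alpha Maximal synthesis-rate increment (RPU), strictly positive.
#' @param delta Basal synthesis rate (RPU), non-negative.
#' @param k Half-effect input level (nM or RPU), strictly positive.
#' @param eta Hill coefficient, strictly positive.
#' @param logic `"activating"` (output increases with input) or
#'   `"repressing"` (output decreases with input).
#' @return An object of class `hill_params`.
#' @examples
#' tet <- hill_params(alpha = 3, delta = 0.05, k = 0.2, eta = 2,
#'                    logic = "repressing")
#' hill_response(tet, c(0, 0.2, 2.05))
#' @export
hill_params <- function(alpha, delta, k, eta,
                        logic = c("activating", "repressing")) {
  logic <- match.arg(logic)
  for (nm in c("alpha", "delta", "k", "eta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (alpha <= 0) stop("'alpha' must be > 0", call. = FALSE)
  if (delta < 0) stop("'delta' must be >= 0", call. = FALSE)
  if (k <= 0) stop("'k' must be > 0", call. = FALSE)
  if (eta <= 0) stop("'eta' must be > 0", call. = FALSE)
  new_hill_params(alpha, delta, k, eta, logic)
}

# internal constructor without validation; fitting routines may need to hold
# boundary estimates (e.g. delta exactly 0, alpha at a bound) for reporting
new_hill_params <- function(alpha, delta, k, eta, logic) {
  structure(
    list(alpha = unname(alpha), delta = unname(delta), k = unname(k),
         eta = unname(eta), logic = logic),
    class = "hill_params"
  )
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf(
    "<hill_params> %s: alpha=%.4g delta=%.4g k=%.4g eta=%.4g\n",
    x$logic, x$alpha, x$delta, x$k, x$eta))
  invisible(x)
}

#' @export
as.data.frame.hill_params <- function(x, ...) {
  data.frame(alpha = x$alpha, delta = x$delta, k = x$k, eta = x$eta,
             logic = x$logic, stringsAsFactors = FALSE)
}

#' Evaluate a Hill transfer function
#'
#' Computes the deterministic steady-state output of a module for one or more
#' input values. Evaluation is vectorized and scalar/vector calls agree
#' elementwise. At `input = 0` an activating module returns its basal level
#' `delta` (the continuous limit of the Hill form, and the module's activity
#' when no inducer is present).
#'
#' @param params A [hill_params()] object.
#' @param input Non-negative finite numeric vector (nM or RPU, matching the
#'   units of `params$k`).
#' @return Numeric vector of outputs (RPU), same length as `input`. Outputs
#'   lie in `[delta, delta + alpha]`, monotone increasing in the input for
#'   activating logic and decreasing for repressing logic.
#' @examples
#' inp <- hill_params(4, 0.05, 700, 0.9, "activating")
#' hill_response(inp, 700)  # half-maximal: delta + alpha/2 = 2.05
#' @export
hill_response <- function(params, input) {
  if (!inherits(params, "hill_params"))
    stop("'params' must be a hill_params object", call. = FALSE)
  if (!is.numeric(input) || length(input) == 0L)
    stop("'input' must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(input)))
    stop("'input' must be finite", call. = FALSE)
  if (any(input < 0))
    stop("'input' must be non-negative", call. = FALSE)
  out <- if (params$logic == "activating") {
    r <- params$delta + params$alpha / (1 + (params$k / input)^params$eta)
    r[input == 0] <- params$delta
    r
  } else {
    params$delta + params$alpha / (1 + (input / params$k)^params$eta)
  }
  unname(out)
}

#' Specify a transcriptional cascade
#'
#' A network is an ordered cascade of modules: stage 1 consumes the external
#' inducer (3OC6-HSL by default) and each later stage consumes the previous
#' stage's output. Each stage may carry a noise site (a [noise_spec()]);
#' `rho` is the correlation between the Gaussian log-noise components of the
#' first two noisy sites and models the extrinsic (shared-resource) component
#' of cell-to-cell noise: `rho = 0` is purely intrinsic (independent) noise,
#' `rho = 1` purely extrinsic.
#'
#' @param stages Named list of [hill_params()], in cascade order.
#' @param noise_sites Optional list of [noise_spec()] objects, one per stage
#'   (`NULL` entries mean no noise). Defaults to no noise anywhere.
#' @param input_name Label of the external inducer.
#' @param rho Correlation in `[0, 1]` between the log-noise of the first two
#'   noisy stages. Ignored when fewer than two stages carry noise.
#' @return An object of class `network_spec`.
#' @seealso [two_module_network()], [three_module_network()]
#' @export
network_spec <- function(stages, noise_sites = NULL,
                         input_name = "3OC6-HSL", rho = 0) {
  if (!is.list(stages) || length(stages) == 0L)
    stop("'stages' must be a non-empty list of hill_params", call. = FALSE)
  if (is.null(names(stages)) || any(!nzchar(names(stages))))
    stop("'stages' must be a fully named list", call. = FALSE)
  ok <- vapply(stages, inherits, logical(1), what = "hill_params")
  if (!all(ok))
    stop("all stages must be hill_params objects", call. = FALSE)
  if (is.null(noise_sites))
    noise_sites <- rep(list(noise_spec("none")), length(stages))
  if (length(noise_sites) != length(stages))
    stop("'noise_sites' must have one entry per stage", call. = FALSE)
  noise_sites <- lapply(noise_sites, function(s) {
    if (is.null(s)) noise_spec("none")
    else if (inherits(s, "noise_spec")) s
    else stop("noise_sites entries must be noise_spec or NULL", call. = FALSE)
  })
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) ||
      rho < 0 || rho > 1)
    stop("'rho' must be a single value in [0, 1]", call. = FALSE)
  structure(
    list(stages = stages, noise_sites = noise_sites,
         input_name = input_name, rho = rho),
    class = "network_spec"
  )
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %d-stage cascade driven by %s (rho=%g)\n",
              length(x$stages), x$input_name, x$rho))
  for (i in seq_along(x$stages)) {
    p <- x$stages[[i]]
    ns <- x$noise_sites[[i]]
    cat(sprintf("  [%d] %-12s %-10s alpha=%.3g delta=%.3g k=%.3g eta=%.3g noise=%s\n",
                i, names(x$stages)[i], p$logic, p$alpha, p$delta, p$k, p$eta,
                format(ns)))
  }
  invisible(x)
}

#' Deterministic cascade response
#'
#' Propagates an inducer grid through every stage of a network without noise:
#' stage 1 is evaluated on the inducer concentrations, each later stage on the
#' previous stage's output.
#'
#' @param network A [network_spec()].
#' @param hsl Non-negative numeric vector of inducer concentrations (nM).
#' @return Numeric matrix with one row per inducer value and one column per
#'   stage (RPU), with the grid attached as attribute `"hsl"`.
#' @examples
#' net <- three_module_network()
#' cascade_response(net, c(0, 700, 1e7))
#' @export
cascade_response <- function(network, hsl) {
  if (!inherits(network, "network_spec"))
    stop("'network' must be a network_spec", call. = FALSE)
  if (!is.numeric(hsl) || length(hsl) == 0L)
    stop("inducer grid must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(hsl)) || any(hsl < 0))
    stop("inducer grid must be finite and non-negative", call. = FALSE)
  out <- matrix(NA_real_, nrow = length(hsl), ncol = length(network$stages),
                dimnames = list(NULL, names(network$stages)))
  up <- hsl
  for (s in seq_along(network$stages)) {
    up <- hill_response(network$stages[[s]], up)
    out[, s] <- up
  }
  attr(out, "hsl") <- hsl
  out
}
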