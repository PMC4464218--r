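#' Fit a Hill transfer function to averaged data
#'
#' Least-squares estimation of `(alpha, delta, k, eta)` from
#' (input, population-averaged output) pairs, minimizing linear-scale
#' residuals `y - hill(x)` under lower bounds of 0 on every parameter
#' (Levenberg-Marquardt, [minpack.lm::nls.lm()]). `delta` is always
#' estimated, never fixed, even though it is typically poorly determined
#' from data that do not reach the basal plateau.
#'
#' Starting values default to a data-driven heuristic
#' (`delta0 = min(y)`, `alpha0 = max(y) - min(y)`, `k0` = the `x` whose `y`
#' is closest to mid-range, `eta0 = 1`). To guard against local minima the
#' fit is repeated from `n_starts` deterministic starts (the heuristic
#' start, and copies with `k` and `eta` scaled by 3 and by 1/3); the lowest
#' residual wins, ties going to the earliest start. The whole procedure is
#' deterministic in `(x, y, init)`.
#'
#' Non-convergence is reported through the `converged` flag rather than an
#' error; flat-response data yield a flagged result with the heuristic
#' parameters.
#'
#' @param x Non-negative inputs (nM or RPU), length >= 5.
#' @param y Positive averaged outputs (RPU), same length.
#' @param logic Module logic, `"activating"` or `"repressing"`.
#' @param init Optional [hill_params()] starting point (its `logic` is
#'   ignored in favour of `logic`).
#' @param n_starts Number of deterministic starts (1-3).
#' @return An object of class `fit_result`: `params` (`hill_params`),
#'   `residual_norm` (sum of squared residuals), `converged`, `init`,
#'   `bounds_hit` (names of parameters at the zero bound).
#' @examples
#' tet <- hill_params(3, 0.05, 0.2, 2, "repressing")
#' x <- seq(0.05, 3, length.out = 20)
#' fit_hill(x, hill_response(tet, x), "repressing")$params
#' @export
fit_hill <- function(x, y, logic = c("activating", "repressing"),
                     init = NULL, n_starts = 3) {
  logic <- match.arg(logic)
  if (length(x) != length(y) || length(x) < 5L)
    stop("'x' and 'y' must have equal length >= 5", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop("'x' must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(y)) || any(y <= 0))
    stop("'y' must be finite and positive", call. = FALSE)
  n_starts <- max(1L, min(3L, as.integer(n_starts)))

  if (is.null(init)) {
    d0 <- min(y)
    a0 <- max(y) - min(y)
    k0 <- x[which.min(abs(y - (min(y) + max(y)) / 2))]
    if (k0 <= 0) k0 <- max(min(x[x > 0]), .Machine$double.eps)
    if (a0 <= 0) a0 <- max(y) # flat data; flagged below
    e0 <- 1
    init <- new_hill_params(a0, d0, k0, e0, logic)
  } else {
    if (!inherits(init, "hill_params"))
      stop("'init' must be a hill_params object", call. = FALSE)
    init <- new_hill_params(init$alpha, init$delta, init$k, init$eta, logic)
  }

  flat <- diff(range(y)) <= sqrt(.Machine$double.eps) * max(abs(y))
  if (flat) {
    return(structure(
      list(params = init, residual_norm = sum((y - mean(y))^2),
           converged = FALSE, init = init, bounds_hit = character(0)),
      class = "fit_result"))
  }

  resid_fn <- function(p)
    y - (p[2L] + p[1L] / (1 + if (logic == "activating")
      ifelse(x == 0, Inf, (p[3L] / x)^p[4L]) else (x / p[3L])^p[4L]))

  starts <- list(c(1, 1), c(3, 3), c(1 / 3, 1 / 3))[seq_len(n_starts)]
  best <- NULL
  for (m in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = c(init$alpha, init$delta, init$k * m[1L], init$eta * m[2L]),
      lower = rep(0, 4L), fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    return(structure(
      list(params = init, residual_norm = sum(resid_fn(
             c(init$alpha, init$delta, init$k, init$eta))^2),
           converged = FALSE, init = init, bounds_hit = character(0)),
      class = "fit_result"))
  }
  par <- best$par
  names(par) <- c("alpha", "delta", "k", "eta")
  bhit <- names(par)[par <= 1e-12]
  structure(
    list(params = new_hill_params(par[["alpha"]], par[["delta"]],
                                  par[["k"]], par[["eta"]], logic),
         residual_norm = best$deviance,
         converged = best$info %in% 1:3,
         init = init,
         bounds_hit = bhit),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<fit_result> %s: alpha=%.4g delta=%.4g k=%.4g eta=%.4g (SSR=%.3g%s)\n",
    p$logic, p$alpha, p$delta, p$k, p$eta, x$residual_norm,
    if (x$converged) "" else ", NOT converged"))
  if (length(x$bounds_hit))
    cat("  at zero bound:", paste(x$bounds_hit, collapse = ", "), "\n")
  invisible(x)
}

#' Predict the black-box transfer function of a composed network
#'
#' Composes an input device with a list of downstream module transfer
#' functions deterministically (no noise) over an induction grid, then fits
#' a single activating Hill function of the inducer to the end output. The
#' fitted "starred" parameters describe the whole network as one black box.
#'
#' @param input_params [hill_params()] of the inducer-driven input device.
#' @param downstream_params List of [hill_params()] for the downstream
#'   modules, in cascade order (may be empty, in which case the input
#'   device is fitted to itself).
#' @param hsl_grid Induction grid (nM); defaults to [dense_hsl_grid()].
#' @param init,n_starts Passed to [fit_hill()].
#' @return A `fit_result` holding the black-box `hill_params`.
#' @examples
#' p <- default_params()
#' predict_blackbox(p$hsl_input, list(p$tetr_ptet, p$laci_plac))$params
#' @export
predict_blackbox <- function(input_params, downstream_params = list(),
                             hsl_grid = dense_hsl_grid(), init = NULL,
                             n_starts = 3) {
  stages <- c(list(input = input_params), downstream_params)
  names(stages) <- paste0("m", seq_along(stages))
  net <- network_spec(stages)
  resp <- cascade_response(net, hsl_grid)
  fit_hill(hsl_grid, resp[, ncol(resp)], logic = "activating",
           init = init, n_starts = n_starts)
}
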