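#' Specify a lognormal noise site
#'
#' Cell-to-cell variability is modelled as multiplicative lognormal noise on
#' a module's output: each cell's output is the deterministic value times
#' `exp(g)` with `g ~ N(0, sigma2)`. Two laws relate `sigma2` to the noise
#' entity: under `constant_cv` the coefficient of variation of the noisy
#' output is held at `level` for every induction; under `constant_var` the
#' absolute variance is held at `level` (RPU^2), so `sigma2` depends on the
#' local deterministic value.
#'
#' Because the lognormal factor has mean `exp(sigma2/2) > 1`, applying it
#' raw would inflate the population mean. With `corrected = TRUE` (the
#' default) the deterministic value is first rescaled by `exp(-sigma2/2)` so
#' the population mean is preserved exactly — the construction that lets
#' different noise entities share identical population-averaged signals.
#'
#' @param model `"none"`, `"constant_cv"` or `"constant_var"`.
#' @param level CV (dimensionless) for `constant_cv`, variance (RPU^2) for
#'   `constant_var`. Ignored for `"none"`.
#' @param corrected Preserve the population mean (see Details).
#' @param label Optional free-text label.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(model = c("none", "constant_cv", "constant_var"),
                       level = 0, corrected = TRUE, label = NULL) {
  model <- match.arg(model)
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
      level < 0)
    stop("'level' must be a single non-negative number", call. = FALSE)
  if (!is.logical(corrected) || length(corrected) != 1L || is.na(corrected))
    stop("'corrected' must be TRUE or FALSE", call. = FALSE)
  structure(list(model = model, level = if (model == "none") 0 else level,
                 corrected = corrected, label = label),
            class = "noise_spec")
}

#' @export
format.noise_spec <- function(x, ...) {
  if (x$model == "none") "none"
  else sprintf("%s(%g%s)", x$model, x$level,
               if (x$corrected) "" else ", uncorrected")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat("<noise_spec>", format(x), "\n")
  invisible(x)
}

#' Log-scale variance from a target CV or variance
#'
#' For lognormal multiplicative noise the coefficient of variation of the
#' noise factor is `sqrt(exp(sigma2) - 1)`, so a target CV fixes
#' `sigma2 = log(1 + CV^2)` independently of the operating point. A target
#' absolute variance `var` on an output with (preserved) population mean
#' `y_pop` instead gives `sigma2 = log(1 + var / y_pop^2)`, different at
#' every induction.
#'
#' @param cv Non-negative target coefficient of variation.
#' @return Log-scale Gaussian variance `sigma2` (dimensionless).
#' @examples
#' sigma2_from_cv(0.75)            # log(1.5625)
#' sigma2_from_var(0.15, 2.05)
#' @export
sigma2_from_cv <- function(cv) {
  if (!is.numeric(cv) || any(!is.finite(cv)) || any(cv < 0))
    stop("'cv' must be non-negative and finite", call. = FALSE)
  log(1 + cv^2)
}

#' @rdname sigma2_from_cv
#' @param var Non-negative target variance (RPU^2).
#' @param y_pop Positive population-mean output (RPU); vectorized, so a
#'   per-cell deterministic value can be supplied directly.
#' @export
sigma2_from_var <- function(var, y_pop) {
  if (!is.numeric(var) || any(!is.finite(var)) || any(var < 0))
    stop("'var' must be non-negative and finite", call. = FALSE)
  if (!is.numeric(y_pop) || any(!is.finite(y_pop)) || any(y_pop <= 0))
    stop("'y_pop' must be positive and finite", call. = FALSE)
  log(1 + var / y_pop^2)
}

#' Moments of the lognormal noise factor
#'
#' Mean and variance of `exp(g)` with `g ~ N(0, sigma2)`:
#' `AVE = exp(sigma2/2)` and `VAR = exp(sigma2) * (exp(sigma2) - 1)`.
#'
#' @param sigma2 Non-negative log-scale variance.
#' @return Named list with elements `ave` and `var`.
#' @export
lognormal_moments <- function(sigma2) {
  if (!is.numeric(sigma2) || any(!is.finite(sigma2)) || any(sigma2 < 0))
    stop("'sigma2' must be non-negative and finite", call. = FALSE)
  list(ave = exp(sigma2 / 2), var = exp(sigma2) * (exp(sigma2) - 1))
}

#' Mean-preserving correction of a deterministic value
#'
#' Rescales a deterministic output by `exp(-sigma2/2)` so that after
#' multiplication by a lognormal noise factor with the same `sigma2` the
#' population mean equals the original value exactly.
#'
#' @param y_pop Positive deterministic (target population-mean) value.
#' @param sigma2 Non-negative log-scale variance.
#' @return Corrected deterministic value, `y_pop * exp(-sigma2/2)`.
#' @export
mean_correction <- function(y_pop, sigma2) {
  if (!is.numeric(y_pop) || any(!is.finite(y_pop)) || any(y_pop <= 0))
    stop("'y_pop' must be positive and finite", call. = FALSE)
  if (!is.numeric(sigma2) || any(!is.finite(sigma2)) || any(sigma2 < 0))
    stop("'sigma2' must be non-negative and finite", call. = FALSE)
  y_pop * exp(-sigma2 / 2)
}

# run code under a fixed RNG seed, restoring the caller's RNG state
with_rng_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic child-seed derivation: distinct streams per noise site and
# induction index, all below 2^31
child_seed <- function(master, entity = 0L, site = 0L, induction = 0L) {
  ((as.numeric(master) %% 2147483647) + 86028157 * entity + 7907 * site +
     104729 * induction) %% 2147483646 + 1
}

#' Draw lognormal noise factors
#'
#' Generates `n` independent multiplicative noise factors `exp(g)` with
#' `g ~ N(0, sigma2)`. The caller's RNG state is left untouched; the draw is
#' fully determined by `seed`.
#'
#' @param sigma2 Non-negative log-scale variance; a scalar, or a length-`n`
#'   vector for per-cell variances (the constant-VAR law downstream of a
#'   noisy stage).
#' @param n Number of cells (>= 1).
#' @param seed Integer seed.
#' @return An object of class `noise_draw`: list with `samples` (positive
#'   factors), `sigma2` and `seed`.
#' @export
draw_noise <- function(sigma2, n, seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  if (any(!is.finite(sigma2)) || any(sigma2 < 0))
    stop("'sigma2' must be non-negative and finite", call. = FALSE)
  if (!length(sigma2) %in% c(1L, n))
    stop("'sigma2' must be scalar or length n", call. = FALSE)
  z <- with_rng_seed(seed, stats::rnorm(n))
  structure(list(samples = exp(sqrt(sigma2) * z), sigma2 = sigma2,
                 seed = seed),
            class = "noise_draw")
}

# standard-normal pair with correlation rho between components
correlated_std_normal <- function(rho, n, seed) {
  z <- with_rng_seed(seed, matrix(stats::rnorm(2L * n), ncol = 2L))
  cbind(z[, 1L], rho * z[, 1L] + sqrt(1 - rho^2) * z[, 2L])
}

#' Draw a correlated pair of lognormal noise factors
#'
#' Models the extrinsic component of noise shared by two network sites: the
#' Gaussian log-noise components have variances `sigma2_a`, `sigma2_b` and
#' correlation `rho`. `rho = 0` gives independent (purely intrinsic) noise;
#' `rho = 1` makes the log-noise of the two sites identical up to scale
#' (purely extrinsic). Note `rho` is the correlation on the log scale; the
#' correlation of the lognormal factors themselves is slightly smaller.
#'
#' @inheritParams draw_noise
#' @param sigma2_a,sigma2_b Non-negative log-scale variances (scalars or
#'   length-`n` vectors).
#' @param rho Correlation in `[0, 1]` of the Gaussian components.
#' @return List of two `noise_draw` objects (`a`, `b`).
#' @export
draw_correlated_noise <- function(sigma2_a, sigma2_b, rho, n, seed) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) ||
      rho < 0 || rho > 1)
    stop("'rho' must be a single value in [0, 1]", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  for (s2 in list(sigma2_a, sigma2_b))
    if (any(!is.finite(s2)) || any(s2 < 0))
      stop("variances must be non-negative and finite", call. = FALSE)
  z <- correlated_std_normal(rho, n, seed)
  list(
    a = structure(list(samples = exp(sqrt(sigma2_a) * z[, 1L]),
                       sigma2 = sigma2_a, seed = seed),
                  class = "noise_draw"),
    b = structure(list(samples = exp(sqrt(sigma2_b) * z[, 2L]),
                       sigma2 = sigma2_b, seed = seed),
                  class = "noise_draw")
  )
}
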