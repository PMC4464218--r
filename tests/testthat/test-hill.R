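test_that("hill_response matches closed-form values for the reference devices", {
  # input device at its half-effect concentration: delta + alpha/2
  expect_equal(hill_response(ref$hsl_input, 700), 2.05, tolerance = 1e-12)
  # repressor absent gives the full level delta + alpha
  expect_equal(hill_response(ref$tetr_ptet, 0), 3.05, tolerance = 1e-12)
  # direct evaluation at a mid-curve input, frozen from the scalar oracle
  expect_equal(hill_response(ref$tetr_ptet, 2.05),
               hill_oracle(3, 0.05, 0.2, 2, 2.05, activating = FALSE),
               tolerance = 1e-12)
  expect_equal(hill_response(ref$tetr_ptet, 2.05), 0.07828521,
               tolerance = 1e-7)
  # activating logic at zero input returns the basal level
  expect_identical(hill_response(ref$hsl_input, 0), 0.05)
})

test_that("scalar and vector evaluation agree elementwise", {
  x <- c(0, 0.01, 0.2, 1.7, 700, 1e6)
  for (p in list(ref$hsl_input, ref$tetr_ptet, ref$yes_gate)) {
    vec <- hill_response(p, x)
    sca <- vapply(x, function(xi) hill_response(p, xi), numeric(1))
    expect_identical(vec, sca)
  }
})

test_that("hill_response is monotone and bounded for random parameter draws", {
  set.seed(42)
  grid <- c(0, 10^seq(-4, 4, length.out = 60))
  for (i in 1:20) {
    logic <- if (i %% 2) "activating" else "repressing"
    p <- random_hill(logic)
    y <- hill_response(p, grid)
    d <- diff(y)
    if (logic == "activating") expect_true(all(d >= -1e-12))
    else expect_true(all(d <= 1e-12))
    expect_true(all(y >= p$delta - 1e-12 & y <= p$delta + p$alpha + 1e-12))
    # limits: basal level and plateau, to 1e-9
    lo <- hill_response(p, 0)
    hi <- hill_response(p, p$k * 10^(12 / p$eta))
    if (logic == "activating") {
      expect_equal(lo, p$delta, tolerance = 1e-9)
      expect_equal(hi, p$delta + p$alpha, tolerance = 1e-9)
    } else {
      expect_equal(lo, p$delta + p$alpha, tolerance = 1e-9)
      expect_equal(hi, p$delta, tolerance = 1e-9)
    }
  }
})

test_that("invalid parameters and inputs are rejected", {
  expect_error(hill_params(0, 0.05, 0.2, 2), "alpha")
  expect_error(hill_params(3, -0.1, 0.2, 2), "delta")
  expect_error(hill_params(3, 0.05, 0, 2), "k")
  expect_error(hill_params(3, 0.05, 0.2, -1), "eta")
  expect_error(hill_response(ref$tetr_ptet, -1), "non-negative")
  expect_error(hill_response(ref$tetr_ptet, NaN), "finite")
  expect_error(hill_response(ref$tetr_ptet, Inf), "finite")
})

test_that("cascade_response chains modules and matches closed-form limits", {
  net <- three_module_network()
  # basal chain, computed step by step with the scalar oracle
  y1 <- hill_oracle(4, 0.05, 700, 0.9, 0, TRUE)
  y2 <- hill_oracle(3, 0.05, 0.2, 2, y1, FALSE)
  y3 <- hill_oracle(0.5, 1e-5, 3.2, 1.9, y2, FALSE)
  resp0 <- cascade_response(net, 0)
  expect_equal(unname(resp0[1, 3]), y3, tolerance = 1e-12)
  expect_equal(unname(resp0[1, 3]), 0.2754787, tolerance = 1e-6)
  # saturating induction drives the end output to its plateau
  resphi <- cascade_response(net, 1e7)
  expect_equal(unname(resphi[1, 3]), 0.4997704, tolerance = 1e-6)
  # two-module chain at the input half-effect point
  net2 <- two_module_network()
  expect_equal(unname(cascade_response(net2, 700)[1, 2]), 0.07828521,
               tolerance = 1e-7)
  # stage i consumes stage i-1's output
  g <- c(0, 1, 700, 5000)
  resp <- cascade_response(net, g)
  expect_equal(resp[, 2], hill_response(ref$tetr_ptet, resp[, 1]))
  expect_equal(resp[, 3], hill_response(ref$laci_plac, resp[, 2]))
  expect_error(cascade_response(net, numeric(0)), "non-empty")
  expect_error(cascade_response(net, c(1, -2)), "non-negative")
})

test_that("parameter sets round-trip through JSON", {
  tmp <- tempfile(fileext = ".json")
  write_params_json(ref, tmp)
  back <- read_params_json(tmp)
  expect_identical(names(back), names(ref))
  for (nm in names(ref)) {
    expect_equal(back[[nm]]$alpha, ref[[nm]]$alpha)
    expect_equal(back[[nm]]$k, ref[[nm]]$k)
    expect_identical(back[[nm]]$logic, ref[[nm]]$logic)
  }
  unlink(tmp)
})
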