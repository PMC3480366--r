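# Generalized Gaussian density: evaluation, moments, sampling, estimation,
# and the closed-form KL divergence.

test_that("density evaluates known special cases and normalizes", {
  expect_equal(ggd_pdf(0, ggd_params(1, 2)), 1 / sqrt(pi), tolerance = 1e-9)
  expect_equal(ggd_pdf(0, ggd_params(2, 1)), 0.25, tolerance = 1e-12)
  for (i in seq_len(nrow(ggd_grid()))) {
    p <- ggd_params(ggd_grid()$alpha[i], ggd_grid()$beta[i])
    s <- ggd_sigma(p)
    expect_equal(
      stats::integrate(ggd_pdf, -50 * s, 50 * s, p = p,
                       rel.tol = 1e-12, subdivisions = 2000L)$value,
      1, tolerance = 1e-9)
  }
})

test_that("density is symmetric and rejects bad input", {
  p <- ggd_params(1.3, 1.7)
  x <- seq(0.1, 20, length.out = 50)
  expect_equal(ggd_pdf(x, p), ggd_pdf(-x, p))
  expect_error(ggd_params(-1, 2), class = "texdiv_domain_error")
  expect_error(ggd_params(1, 0), class = "texdiv_domain_error")
  expect_error(ggd_pdf(NaN, p), class = "texdiv_domain_error")
})

test_that("standard deviation follows the Gamma-ratio form", {
  expect_equal(ggd_sigma(ggd_params(sqrt(2), 2)), 1, tolerance = 1e-12)
  expect_equal(ggd_sigma(ggd_params(1, 1)), sqrt(2), tolerance = 1e-12)
  # near-uniform limit: sd of U(-alpha, alpha) is alpha/sqrt(3)
  expect_equal(ggd_sigma(ggd_params(1, 200)), 1 / sqrt(3), tolerance = 1e-2)
})

test_that("entropy matches closed forms and the scale property", {
  expect_equal(ggd_entropy(ggd_params(sqrt(2), 2)), 0.5 * log(2 * pi * exp(1)),
               tolerance = 1e-9)
  expect_equal(ggd_entropy(ggd_params(1, 1)), 1 + log(2), tolerance = 1e-12)
  for (beta in c(0.7, 1.4, 3)) {
    expect_equal(ggd_entropy(ggd_params(2.6, beta)) - ggd_entropy(ggd_params(1.3, beta)),
                 log(2), tolerance = 1e-12)
  }
  # numerical-integration oracle on the parameter grid
  for (i in seq_len(nrow(ggd_grid()))) {
    p <- ggd_params(ggd_grid()$alpha[i], ggd_grid()$beta[i])
    expect_equal(ggd_entropy(p), numeric_entropy(p), tolerance = 1e-6)
  }
})

test_that("sampler is seeded, unbiased and reproduces tail behavior", {
  p <- ggd_params(sqrt(2), 2)
  expect_identical(ggd_sample(p, 100, seed = 9), ggd_sample(p, 100, seed = 9))
  x <- ggd_sample(p, 1e5, seed = 1)
  expect_lt(abs(sd(x) - 1), 0.02)
  expect_lt(abs(mean(x)), 0.02)
  # heavy-tailed shape: excess kurtosis above the Gaussian value
  y <- ggd_sample(ggd_params(1, 0.7), 1e5, seed = 2)
  kurt <- mean(y^4) / mean(y^2)^2
  expect_gt(kurt, 3)
  expect_error(ggd_sample(p, 0), class = "texdiv_domain_error")
})

test_that("moment matching recovers Gaussian and Laplacian shapes", {
  g <- ggd_fit_moment(ggd_sample(ggd_params(sqrt(2), 2), 1e5, seed = 3))
  expect_gt(g$beta, 1.9); expect_lt(g$beta, 2.1)
  lap <- ggd_fit_moment(ggd_sample(ggd_params(1, 1), 1e5, seed = 4))
  expect_gt(lap$beta, 0.93); expect_lt(lap$beta, 1.07)
  expect_error(ggd_fit_moment(rep(3, 100)), class = "texdiv_degenerate_error")
  expect_error(ggd_fit_moment(ggd_sample(ggd_params(1, 2), 10, seed = 1)),
               class = "texdiv_degenerate_error")
})

test_that("maximum likelihood recovers parameters and dominates moment fit", {
  x <- ggd_sample(ggd_params(2, 1.5), 1e4, seed = 11)
  f <- ggd_fit_mle(x)
  expect_lt(abs(f$alpha - 2) / 2, 0.05)
  expect_lt(abs(f$beta - 1.5) / 1.5, 0.05)
  m <- ggd_fit_moment(x)
  expect_gte(texdiv:::ggd_loglik(x, f), texdiv:::ggd_loglik(x, m))
  # asymptotic agreement of the two consistent estimators
  xg <- ggd_sample(ggd_params(sqrt(2), 2), 1e5, seed = 21)
  expect_lt(abs(ggd_fit_mle(xg)$beta - ggd_fit_moment(xg)$beta), 0.05)
  expect_error(ggd_fit_mle(rep(1, 200)), class = "texdiv_degenerate_error")
})

test_that("estimator error shrinks with sample size", {
  err_at <- function(n, beta) {
    mean(vapply(1:20, function(s) {
      x <- ggd_sample(ggd_params(1.5, beta), n, seed = 100 * beta + s)
      abs(ggd_fit_mle(x)$beta - beta) / beta
    }, numeric(1)))
  }
  for (beta in c(1, 2)) {
    e <- vapply(c(1e3, 1e4, 1e5), err_at, numeric(1), beta = beta)
    expect_true(all(diff(e) < 0))
  }
})

test_that("closed-form KL matches quadrature, known values, and is a divergence", {
  gauss1 <- ggd_params(sqrt(2), 2); gauss2 <- ggd_params(2 * sqrt(2), 2)
  expect_equal(kl_ggd(gauss1, gauss2), log(2) + 1 / 8 - 1 / 2, tolerance = 1e-9)
  expect_equal(kl_ggd(ggd_params(1, 1), ggd_params(2, 1)), log(2) - 1 / 2,
               tolerance = 1e-9)
  expect_identical(kl_ggd(gauss1, gauss1), 0)
  # asymmetry of the directed divergence
  expect_false(isTRUE(all.equal(kl_ggd(gauss1, gauss2), kl_ggd(gauss2, gauss1))))
  grid <- ggd_grid()
  for (i in seq_len(nrow(grid))) for (j in seq_len(nrow(grid))) {
    p1 <- ggd_params(grid$alpha[i], grid$beta[i])
    p2 <- ggd_params(grid$alpha[j], grid$beta[j])
    v <- kl_ggd(p1, p2)
    expect_gte(v, 0)
    if (i == j) expect_equal(v, 0, tolerance = 1e-12) else expect_gt(v, 0)
  }
})
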