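fixed_state <- function(lf, x = NULL, sigma2 = 0.5, omega = 0.3, lam = 1.2)
  list(x = x %||% numeric(ncol(lf$H)), sigma2 = sigma2, omega = omega,
       lam = lam)

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("spike weight saturates at the omega limits", {
  lf <- tiny_lf(2, 3, seed = 1)
  y <- c(1, -0.5)
  c0 <- coordinate_conditional(1, y, fixed_state(lf, omega = 0), lf)
  expect_equal(c0$w, c(1, 0, 0))
  c1 <- coordinate_conditional(1, y, fixed_state(lf, omega = 1), lf)
  expect_equal(c1$w[1], 0)
  expect_equal(sum(c1$w), 1, tolerance = 1e-12)
})

test_that("mixture weights match the quadrature oracle on a fixed toy", {
  lf <- tiny_lf(2, 3, seed = 7)
  y <- c(1.3, -0.4)
  st <- fixed_state(lf, x = c(0.5, 0, -0.2), sigma2 = 0.3, omega = 0.4,
                    lam = 0.8)
  for (i in 1:3) {
    cond <- coordinate_conditional(i, y, st, lf)
    nu <- y - lf$H %*% st$x + lf$H[, i] * st$x[i]
    w_q <- quadrature_weights(as.numeric(nu), lf$H[, i], st$sigma2, st$lam,
                              st$omega)
    expect_equal(cond$w, w_q, tolerance = 1e-6)
    expect_equal(sum(cond$w), 1, tolerance = 1e-12)
  }
})

test_that("weights stay finite and normalized far into the tails", {
  # |mu|/sigma_i up to 50: naive exp((mu/sigma)^2/2) would overflow
  lf <- manual_lf(matrix(c(1, 0), 1, 2))
  for (scale in c(5, 20, 50)) {
    st <- list(x = c(0, 0), sigma2 = 1, omega = 0.3, lam = 1)
    cond <- coordinate_conditional(1, scale, st, lf)   # mu ~ scale, sigma_i = 1
    expect_true(all(is.finite(cond$w)))
    expect_equal(sum(cond$w), 1, tolerance = 1e-12)
    expect_gt(cond$w[2], 0.99)  # strongly positive evidence
  }
})

test_that("coordinate draws honour component choice and truncation", {
  base <- list(w = c(1, 0, 0), mu_plus = 2, mu_minus = -2, sigma2_i = 1)
  set.seed(1)
  expect_identical(sample_coordinate(base), 0)

  pos <- list(w = c(0, 1, 0), mu_plus = 5, mu_minus = -5, sigma2_i = 1e-20)
  set.seed(2)
  expect_equal(sample_coordinate(pos), 5, tolerance = 1e-6)

  # far-tail truncated normal matches its closed-form mean
  tail_cond <- list(w = c(0, 1, 0), mu_plus = -3, mu_minus = 0, sigma2_i = 1)
  set.seed(3)
  draws <- replicate(1e5, sample_coordinate(tail_cond))
  expect_true(all(draws > 0))
  expect_equal(mean(draws), truncnorm_pos_mean(-3, 1), tolerance = 5e-3)

  bad <- list(w = c(NaN, NaN, NaN), mu_plus = 0, mu_minus = 0, sigma2_i = 1)
  expect_error(sample_coordinate(bad), "non-finite")
})

test_that("noise-variance conditional matches inverse-gamma moments", {
  lf <- tiny_lf(6, 12, seed = 2)
  x <- numeric(12)
  set.seed(4)
  y <- rnorm(6)
  rss <- sum((y - lf$H %*% x)^2)
  set.seed(5)
  draws <- replicate(1e5, sample_noise_variance(y, x, lf))
  m_exp <- (rss / 2) / (6 / 2 - 1)
  expect_lt(abs(mean(draws) - m_exp), 0.02 * m_exp)
  # zero residual hits the floor deterministically
  y0 <- as.numeric(lf$H %*% x)
  expect_identical(sample_noise_variance(y0, x, lf, floor = 1e-8), 1e-8)
  set.seed(9); d1 <- sample_noise_variance(y, x, lf)
  set.seed(9); d2 <- sample_noise_variance(y, x, lf)
  expect_identical(d1, d2)
})

test_that("activity-weight conditional matches Beta moments", {
  set.seed(6)
  d0 <- replicate(1e5, sample_bernoulli_weight(numeric(10)))
  expect_true(all(d0 >= 0 & d0 <= 1))
  expect_lt(abs(mean(d0) - 1 / 12), 0.02 * (1 / 12))
  d1 <- replicate(1e5, sample_bernoulli_weight(rep(1, 10)))
  expect_lt(abs(mean(d1) - 11 / 12), 0.02 * (11 / 12))
})

test_that("Laplace-scale conditional matches inverse-gamma moments", {
  set.seed(7)
  # fallback: no active source -> InvGamma(a0, b0)
  d0 <- replicate(1e5, sample_laplace_scale(numeric(5), a0 = 3, b0 = 2))
  expect_true(all(d0 > 0))
  expect_lt(abs(mean(d0) - 1), 0.02)
  x <- c(0.5, 0, -1.5, 0, 2)
  d1 <- replicate(1e5, sample_laplace_scale(x, a0 = 3, b0 = 2))
  m_exp <- (2 + 4) / (3 + 3 - 1)
  expect_lt(abs(mean(d1) - m_exp), 0.03 * m_exp)
})
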