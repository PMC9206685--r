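test_that("chain bookkeeping: length, determinism, engine agreement", {
  lf <- tiny_lf(8, 20, seed = 3)
  set.seed(5)
  xtrue <- numeric(20); xtrue[c(4, 13)] <- c(2, -1.5)
  y <- as.numeric(lf$H %*% xtrue) + rnorm(8, sd = 0.05)

  ch1 <- run_gibbs(y, lf, gibbs_config(n_iter = 51, burn_in = 50, seed = 2))
  expect_identical(nrow(ch1$x), 1L)

  cfg <- gibbs_config(n_iter = 120, burn_in = 40, seed = 7)
  chA <- run_gibbs(y, lf, cfg)
  chB <- run_gibbs(y, lf, cfg)
  expect_identical(chA$x, chB$x)

  cfgR <- cfg; cfgR$engine <- "reference"
  chR <- run_gibbs(y, lf, cfgR)
  expect_equal(chA$x, chR$x, tolerance = 1e-10)
  expect_equal(chA$sigma2, chR$sigma2, tolerance = 1e-10)
  expect_equal(chA$omega, chR$omega, tolerance = 1e-10)

  cfgS <- cfg; cfgS$random_scan <- TRUE
  cfgSR <- cfgS; cfgSR$engine <- "reference"
  expect_equal(run_gibbs(y, lf, cfgS)$x, run_gibbs(y, lf, cfgSR)$x,
               tolerance = 1e-10)
})

test_that("noiseless single-source toy recovers the exhaustive 1-sparse LS fit", {
  lf <- tiny_lf(8, 20, seed = 11)
  j_true <- 6L
  y <- as.numeric(lf$H[, j_true] * 2)
  # oracle: best single-source least-squares fit over all 20 placements
  rss <- vapply(1:20, function(j) {
    b <- sum(lf$H[, j] * y) / sum(lf$H[, j]^2)
    sum((y - lf$H[, j] * b)^2)
  }, numeric(1))
  expect_identical(which.min(rss), j_true)

  ch <- run_gibbs(y, lf, gibbs_config(n_iter = 800, burn_in = 300, seed = 1))
  s <- summarize_posterior(ch)
  expect_identical(s$support, j_true)
  expect_equal(s$x_mean[j_true], 2, tolerance = 0.05)
})

test_that("shrinking omega never increases the expected L0 norm", {
  lf <- tiny_lf(6, 12, seed = 4)
  set.seed(8)
  y <- rnorm(6)
  x <- c(rnorm(3), numeric(9))
  exp_l0 <- vapply(c(0.5, 0.1, 0.01), function(om) {
    st <- list(x = x, sigma2 = 0.5, omega = om, lam = 1)
    sum(vapply(1:12, function(i)
      1 - coordinate_conditional(i, y, st, lf)$w[1], numeric(1)))
  }, numeric(1))
  expect_true(all(diff(exp_l0) < 0))
})

test_that("posterior summaries aggregate kept samples correctly", {
  fake <- structure(list(x = matrix(c(1, 1, 0, 0, 2, 0), 2, 3, byrow = TRUE),
                         sigma2 = c(0.1, 0.1), omega = c(0.2, 0.2),
                         lam = c(1, 1),
                         config = gibbs_config(inclusion_threshold = 0.5)),
                    class = "gibbs_chain")
  s <- summarize_posterior(fake)
  expect_equal(s$x_mean, c(0.5, 1.5, 0))
  expect_equal(s$inclusion_prob, c(0.5, 1, 0))
  expect_identical(s$support, c(1L, 2L))
  cfg0 <- fake$config; cfg0$inclusion_threshold <- 0
  expect_identical(summarize_posterior(fake, cfg0)$support, 1:3)
  empty <- fake; empty$x <- fake$x[0, , drop = FALSE]
  expect_error(summarize_posterior(empty), "empty")
})

test_that("restricted least squares reproduces noiseless time courses", {
  spec <- emotion_dataset_spec(n_subjects = 2, trials_per_subject = 2,
                               n_sensors = 8, n_sources = 20,
                               active_sets = list(positive = c(3L, 11L),
                                                  negative = c(7L, 16L)),
                               snr_db = Inf, seed = 31)
  ds <- generate_dataset(spec)
  ep <- ds$epochs$epochs[[1]]
  gt <- ds$ground_truth[[1]]
  est <- estimate_epoch_sources(ep, ds$lead_field, support = gt$support)
  expect_lt(max(abs(est$signals - gt$x_t[gt$support, ])), 1e-8)
})

test_that("snapshot-merged localization recovers correlated time courses", {
  spec <- emotion_dataset_spec(n_subjects = 2, trials_per_subject = 2,
                               n_sensors = 16, n_sources = 60,
                               active_sets = list(positive = c(10L, 30L, 50L),
                                                  negative = c(20L, 40L, 55L)),
                               snr_db = 15, epoch_s = 2, seed = 41)
  ds <- generate_dataset(spec)
  ep <- ds$epochs$epochs[[1]]
  gt <- ds$ground_truth[[1]]
  est <- estimate_epoch_sources(ep, ds$lead_field,
                                gibbs_config(n_iter = 500, burn_in = 200,
                                             seed = 2),
                                n_snapshots = 4)
  expect_gte(support_f1(est$support, gt$support), 0.8)
  common <- intersect(est$support, gt$support)
  cors <- vapply(common, function(j)
    cor(est$signals[match(j, est$support), ], gt$x_t[j, ]), numeric(1))
  expect_gte(min(cors), 0.9)
})

test_that("ill-posed restricted solves are refused", {
  lf <- tiny_lf(4, 10, seed = 6)
  ep <- structure(list(y_t = matrix(rnorm(4 * 5), 4), fs = 100,
                       sigma2_n = 0, subject_id = 1L, trial_id = 1L),
                  class = "sensor_recording")
  expect_error(estimate_epoch_sources(ep, lf, support = 1:4), "ill-posed")
})
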