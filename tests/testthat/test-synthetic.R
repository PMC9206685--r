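spec_small <- function(...)
  emotion_dataset_spec(n_subjects = 2, trials_per_subject = 4,
                       n_sensors = 8, n_sources = 20,
                       active_sets = list(positive = c(3L, 11L),
                                          negative = c(7L, 16L)), ...)

test_that("active rows are oscillatory, inactive rows exactly zero", {
  spec <- spec_small()
  set.seed(1)
  src <- simulate_source_activity(spec, "positive")
  expect_identical(sort(src$support), c(3L, 11L))
  expect_true(all(src$x_t[-src$support, ] == 0))
  expect_true(all(abs(src$x_t[src$support, ]) > 0))
  expect_equal(ncol(src$x_t), round(spec$fs * spec$epoch_s))
})

test_that("perfect within-class correlation makes active rows proportional", {
  spec <- spec_small(within_class_correlation = 1)
  set.seed(2)
  src <- simulate_source_activity(spec, "positive")
  expect_equal(cor(src$x_t[3, ], src$x_t[11, ]), 1, tolerance = 1e-12)
})

test_that("empty active set is rejected", {
  spec <- spec_small()
  spec$active_sets$positive <- integer(0)
  expect_error(simulate_source_activity(spec, "positive"), "empty active set")
})

test_that("pairwise correlation is calibrated to the requested value", {
  spec <- spec_small(within_class_correlation = 0.7)
  cors <- vapply(1:50, function(s) {
    set.seed(s)
    src <- simulate_source_activity(spec, "negative", n_samples = 2000)
    cor(src$x_t[7, ], src$x_t[16, ])
  }, numeric(1))
  expect_lt(abs(mean(cors) - 0.7), 0.1)
})

test_that("sensor projection respects the forward model and SNR", {
  spec <- spec_small()
  lf <- build_lead_field(8, 20, seed = 4)
  set.seed(3)
  src <- simulate_source_activity(spec, "positive")
  rec_inf <- project_to_sensors(lf, src, Inf)
  expect_equal(rec_inf$y_t, lf$H %*% src$x_t)   # conservation at SNR = Inf
  expect_identical(rec_inf$sigma2_n, 0)

  zero_src <- src; zero_src$x_t[] <- 0
  expect_error(project_to_sensors(lf, zero_src, 20), "SNR undefined")

  snrs <- vapply(1:20, function(s) {
    set.seed(s)
    srcl <- simulate_source_activity(spec, "positive", n_samples = 5000)
    rec <- project_to_sensors(lf, srcl, 20)
    clean <- lf$H %*% srcl$x_t
    10 * log10(sum(clean^2) / sum((rec$y_t - clean)^2))
  }, numeric(1))
  expect_lt(abs(mean(snrs) - 20), 0.5)
})

test_that("generate_dataset balances classes and is reproducible", {
  spec <- spec_small(snr_db = 10, seed = 11)
  ds <- generate_dataset(spec)
  expect_length(ds$epochs$epochs, 8L)
  expect_equal(as.vector(table(ds$epochs$labels)), c(4L, 4L))
  ds2 <- generate_dataset(spec)
  expect_identical(ds$epochs$epochs[[5]]$y_t, ds2$epochs$epochs[[5]]$y_t)
  expect_error(emotion_dataset_spec(trials_per_subject = 1), "at least 2")
  expect_error(emotion_dataset_spec(trials_per_subject = 5), "even")
})

test_that("noiseless epochs localize into the true active set via sLORETA", {
  spec <- spec_small(snr_db = Inf, seed = 21)
  ds <- generate_dataset(spec)
  op <- minimum_norm_operator(ds$lead_field, alpha = 1e-10)
  hits <- mapply(function(ep, gt) {
    which.max(sloreta_power(op, ep$y_t)$power) %in% gt$support
  }, ds$epochs$epochs, ds$ground_truth)
  expect_gte(mean(hits), 0.9)
})

test_that("class separability grows with disjointness and coherence", {
  fisher <- function(overlap, rho, seed = 5) {
    pos <- c(3L, 11L)
    neg <- if (overlap) c(3L, 16L) else c(7L, 16L)
    spec <- emotion_dataset_spec(n_subjects = 2, trials_per_subject = 10,
                                 n_sensors = 8, n_sources = 20,
                                 active_sets = list(positive = pos,
                                                    negative = neg),
                                 within_class_correlation = rho,
                                 snr_db = 20, seed = seed)
    ds <- generate_dataset(spec)
    covs <- lapply(ds$epochs$epochs, function(e) tcrossprod(e$y_t) / ncol(e$y_t))
    idx_p <- ds$epochs$labels == "positive"
    Cp <- Reduce(`+`, covs[idx_p]) / sum(idx_p)
    Cn <- Reduce(`+`, covs[!idx_p]) / sum(!idx_p)
    within <- mean(mapply(function(C, lab)
      norm(C - if (lab == "positive") Cp else Cn, "F"),
      covs, as.character(ds$epochs$labels)))
    norm(Cp - Cn, "F") / within
  }
  f1 <- fisher(overlap = TRUE, rho = 0.3)
  f2 <- fisher(overlap = FALSE, rho = 0.6)
  f3 <- fisher(overlap = FALSE, rho = 0.95)
  expect_lt(f1, f2)
  expect_lt(f2, f3)
})
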