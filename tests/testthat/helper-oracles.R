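# Shared fixtures and independent oracles used across test files.

tiny_lf <- function(n = 8, m = 20, seed = 3, model = "random")
  build_lead_field(n, m, model = model, seed = seed)

# Hand-built lead_field wrapper for matrices the constructor would refuse
# (square toys etc.).
manual_lf <- function(H)
  structure(list(H = H, sensor_positions = NULL, source_positions = NULL,
                 model_tag = "manual"), class = "lead_field")

# Quadrature oracle for the spike/slab mixture weights of one coordinate.
# Integrates the unnormalized conditional density directly (common Gaussian
# factor divided out), independent of the log-domain implementation.
quadrature_weights <- function(nu, h_i, sigma2, lam, omega) {
  hn2 <- sum(h_i^2)
  hv <- sum(h_i * nu)
  g <- function(x)
    omega / (2 * lam) * exp(-abs(x) / lam +
                              (2 * x * hv - x^2 * hn2) / (2 * sigma2))
  si <- sqrt(sigma2 / hn2)
  mu0 <- hv / hn2
  lo <- mu0 - 25 * si; hi <- mu0 + 25 * si
  ipos <- stats::integrate(g, max(0, lo), max(hi, si), rel.tol = 1e-10)$value
  ineg <- stats::integrate(g, min(lo, -si), min(0, hi), rel.tol = 1e-10)$value
  u <- c(1 - omega, ipos, ineg)
  u / sum(u)
}

# Kolmogorov-Smirnov distance between samples and a mixed CDF (continuous
# part + one atom at zero): sup over |F_n(x) - F(x)| using right-continuous
# empirical/theoretical values and their left limits at the tied atom.
ks_mixed <- function(draws, cdf_le, cdf_lt) {
  vals <- sort(unique(draws))
  emp_le <- stats::ecdf(draws)(vals)
  emp_lt <- c(0, emp_le[-length(emp_le)])
  max(abs(emp_le - cdf_le(vals)), abs(emp_lt - cdf_lt(vals)))
}

# Quadrature-normalized CDF of the same conditional (atom at zero plus the
# two truncated slabs), evaluated at arbitrary points by interpolation.
# `left = TRUE` gives the left limit F(x-) (atom counted only for x > 0).
quadrature_cdf <- function(q, nu, h_i, sigma2, lam, omega, left = FALSE) {
  hn2 <- sum(h_i^2)
  hv <- sum(h_i * nu)
  gfun <- function(x)
    omega / (2 * lam) * exp(-abs(x) / lam +
                              (2 * x * hv - x^2 * hn2) / (2 * sigma2))
  si <- sqrt(sigma2 / hn2)
  mu0 <- hv / hn2
  grid <- seq(mu0 - 25 * si, mu0 + 25 * si, length.out = 40001)
  grid <- sort(unique(c(grid, 0)))
  dens <- gfun(grid)
  cum <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(grid)))
  total <- (1 - omega) + cum[length(cum)]
  base <- stats::approx(grid, cum, xout = q, rule = 2)$y
  atom <- if (left) (q > 0) else (q >= 0)
  (base + (1 - omega) * atom) / total
}

# Mean of N(mu, sd^2) truncated to (0, Inf).
truncnorm_pos_mean <- function(mu, sd) {
  a <- -mu / sd
  mu + sd * dnorm(a) / (1 - pnorm(a))
}

# Dense spectral filtering oracle: z = U g(Lambda) U^T x with
# g(lambda) = sum_k theta_k T_k(lambda_scaled).
spectral_filter_oracle <- function(W, theta, x) {
  L <- diag(rowSums(W)) - W
  e <- eigen(L, symmetric = TRUE)
  lmax <- max(e$values)
  lam_t <- 2 * e$values / lmax - 1
  K <- length(theta)
  Tk <- matrix(0, length(lam_t), K)
  Tk[, 1] <- 1
  if (K >= 2) Tk[, 2] <- lam_t
  if (K >= 3) for (k in 3:K) Tk[, k] <- 2 * lam_t * Tk[, k - 1] - Tk[, k - 2]
  gl <- as.numeric(Tk %*% unlist(theta))
  e$vectors %*% (gl * crossprod(e$vectors, as.matrix(x)))
}

support_f1 <- function(est, truth) {
  tp <- length(intersect(est, truth))
  if (tp == 0) return(0)
  prec <- tp / length(est); rec <- tp / length(truth)
  2 * prec * rec / (prec + rec)
}

# Connectivity-discriminative dataset: identical active sets, identical
# bands, class-specific coherent subgroups.
connectivity_spec_overrides <- function(seed) {
  act <- c(20L, 50L, 80L, 110L, 140L, 170L)
  list(seed = seed,
       dataset = list(active_sets = list(positive = act, negative = act),
                      oscillation_bands = list(positive = c(8, 12),
                                               negative = c(8, 12)),
                      within_class_correlation = 0.9,
                      correlation_groups = list(positive = list(1:3),
                                                negative = list(4:6))))
}
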