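#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically stable log(sum(exp(x)))
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Draw one sample from N(mu, sd^2) truncated to (0, Inf).
#'
#' Inverse-CDF in the bulk; Robert's exponential-rejection sampler when the
#' truncation point lies deep in the upper tail (mu/sd < -6), where the
#' inverse CDF loses all precision.  The C++ Gibbs engine follows the exact
#' same branch structure and consumes the same RNG stream, so reference and
#' compiled chains are draw-for-draw identical under one seed.
#' @noRd
rtnorm_pos <- function(mu, sd) {
  a <- -mu / sd  # standardized lower bound
  if (a < 6) {
    plo <- pnorm(a)
    u <- runif(1)
    z <- qnorm(plo + u * (1 - plo))
    # qnorm can return Inf if plo rounds to 1; fall through to tail sampler
    if (is.finite(z)) return(mu + sd * z)
  }
  # Robert (1995) shifted-exponential rejection for z >= a, a > 0
  lambda <- (a + sqrt(a * a + 4)) / 2
  repeat {
    z <- a + rexp(1, rate = lambda)
    if (runif(1) <= exp(-(z - lambda)^2 / 2)) return(mu + sd * z)
  }
}

#' Check a numeric scalar
#' @noRd
assert_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a finite scalar in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

#' Hamming window of length n (periodic symmetric form)
#' @noRd
hamming_window <- function(n) {
  if (n == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}
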