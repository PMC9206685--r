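#' Build a synthetic lead field
#'
#' Constructs the N x M propagation matrix `H` mapping dipole amplitudes at M
#' cortical sources to potentials at N scalp sensors, together with sensor
#' and source geometry.  The EEG inverse problem is under-determined, so
#' `n_sensors < n_sources` is enforced.
#'
#' Two generative models are available:
#' \describe{
#'   \item{`random`}{i.i.d. standard Gaussian entries with every column
#'     rescaled to unit Euclidean norm.  Scale-free and well conditioned in
#'     the row space; the workhorse for simulation studies.}
#'   \item{`spherical`}{sensors on a unit outer sphere, sources on an inner
#'     sphere (radius 0.7), both laid out on deterministic Fibonacci
#'     lattices; entries are the closed-form surface potential of a radial
#'     dipole inside a homogeneous conducting sphere with insulating
#'     exterior, \eqn{V \propto 2(u - f)/g^3 + (1/f)(1/g - 1)} with
#'     \eqn{f = b/R}, \eqn{u = \cos\gamma} and
#'     \eqn{g = \sqrt{1 - 2fu + f^2}}.}
#' }
#'
#' @param n_sensors Number of scalp electrodes N (at least 2).
#' @param n_sources Number of candidate dipoles M; must exceed `n_sensors`.
#' @param model `"random"` or `"spherical"`.
#' @param seed Integer seed; the construction is a pure function of the
#'   arguments.
#' @return An object of class `lead_field` with elements `H`
#'   (`n_sensors x n_sources` matrix), `sensor_positions`, `source_positions`
#'   (3-column matrices) and `model_tag`.
#' @examples
#' lf <- build_lead_field(8, 20, model = "random", seed = 1)
#' colSums(lf$H^2)  # all exactly 1
#' @export
build_lead_field <- function(n_sensors, n_sources,
                             model = c("random", "spherical"), seed = 1L) {
  model <- match.arg(model)
  if (n_sensors < 2L) stop("need at least 2 sensors", call. = FALSE)
  if (n_sensors >= n_sources)
    stop("under-determinacy violated: n_sensors must be < n_sources",
         call. = FALSE)

  sensor_pos <- fibonacci_sphere(n_sensors, radius = 1)
  source_pos <- fibonacci_sphere(n_sources, radius = 0.7)

  H <- withr_seed(seed, {
    if (model == "random") {
      H0 <- matrix(rnorm(n_sensors * n_sources), n_sensors, n_sources)
      sweep(H0, 2L, sqrt(colSums(H0^2)), "/")
    } else {
      spherical_potentials(sensor_pos, source_pos)
    }
  })

  if (any(!is.finite(H))) stop("lead field contains non-finite entries")
  if (any(colSums(H^2) <= 0)) stop("lead field has a silent source column")

  structure(list(H = H,
                 sensor_positions = sensor_pos,
                 source_positions = source_pos,
                 model_tag = model),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("<lead_field> %d sensors x %d sources, model = %s\n",
              nrow(x$H), ncol(x$H), x$model_tag))
  invisible(x)
}

# Evaluate an expression under a local RNG seed without disturbing the
# caller's RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Near-uniform deterministic point set on a sphere (golden-angle lattice).
fibonacci_sphere <- function(n, radius = 1) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(x = sin(phi) * cos(theta),
                 y = sin(phi) * sin(theta),
                 z = cos(phi))
}

# Surface potential of radial dipoles in a homogeneous sphere (unit moment,
# unit conductivity). sensors: rows on sphere radius R; sources: rows at
# radius b < R.
spherical_potentials <- function(sensor_pos, source_pos) {
  R <- sqrt(sum(sensor_pos[1L, ]^2))
  b <- sqrt(rowSums(source_pos^2))
  f <- b / R
  # cos of angle between each sensor and each source
  u <- (sensor_pos %*% t(source_pos)) /
    outer(rep(R, nrow(sensor_pos)), b)
  u <- pmin(pmax(u, -1), 1)
  fm <- matrix(f, nrow(sensor_pos), length(f), byrow = TRUE)
  g <- sqrt(pmax(1 - 2 * fm * u + fm^2, .Machine$double.eps))
  (2 * (u - fm) / g^3 + (1 / fm) * (1 / g - 1)) / (4 * pi * R^2)
}
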