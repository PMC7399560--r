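# Small numerical helpers shared across modules. All lengths are in nm unless a
# function name says otherwise; angles are in radians.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `angle` (radians) about the (not necessarily unit)
#' vector `axis`. A zero axis returns the identity.
#'
#' @param axis numeric length-3 vector.
#' @param angle rotation angle in radians.
#' @return a 3x3 rotation matrix.
#' @keywords internal
rotation_about <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < .Machine$double.eps) return(diag(3))
  a <- axis / n
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Uniform random rotation matrix
#'
#' Drawn from the Haar measure on SO(3) via a normalized Gaussian quaternion;
#' consumes four deviates from R's RNG stream.
#'
#' @return a 3x3 rotation matrix.
#' @keywords internal
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

#' Composite Simpson quadrature on a uniform grid
#'
#' Integrates samples `y` taken at uniform spacing `h`. If the number of
#' intervals is odd the last interval is handled by the trapezoidal rule.
#'
#' @param y numeric vector of integrand samples.
#' @param h grid spacing.
#' @return the integral estimate.
#' @keywords internal
simpson_uniform <- function(y, h) {
  n <- length(y)
  if (n < 2) return(0)
  if (n == 2) return(h * (y[1] + y[2]) / 2)
  m <- if ((n - 1) %% 2 == 0) n else n - 1
  idx <- seq_len(m)
  w <- rep(c(4, 2), length.out = m - 2)
  s <- h / 3 * (y[1] + sum(w * y[2:(m - 1)]) + y[m])
  if (m < n) s <- s + h * (y[n - 1] + y[n]) / 2
  s
}

#' Derive a per-stage RNG seed from a global seed
#'
#' Counter-based fan-out so pipeline stages can be rerun independently while
#' remaining reproducible under one global seed. The result is always a valid
#' 32-bit integer seed.
#'
#' @param seed global integer seed.
#' @param stage stage name or integer counter.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stages <- c("generate", "import", "spectra", "twistwrithe", "kernel",
              "odf", "elastic", "pitch", "binodal", "pmf", "bootstrap")
  k <- if (is.character(stage)) {
    i <- match(stage, stages)
    if (is.na(i)) sum(utf8ToInt(stage)) %% 997L else i
  } else as.integer(stage)
  as.integer((as.numeric(seed) + 9973 * (k + 1)) %% 2147483629)
}

# second Legendre polynomial, used for the nematic order parameter
p2_legendre <- function(x) 0.5 * (3 * x^2 - 1)

# physical constants (SI)
.const <- list(
  kB = 1.380649e-23,    # J/K
  e  = 1.602176634e-19, # C
  avogadro = 6.02214076e23, # 1/mol
  eps0 = 8.8541878128e-12, # F/m
  bp_mass_da = 650      # Da per base pair, used for g/L conversions
)
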