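# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  v / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  if (x > upper)
    stop(sprintf("'%s' must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}

# minimal rotation taking the +z axis onto unit vector `a` (Rodrigues form);
# continuous in `a` except at a = -z where the x axis is used as rotation axis
rotation_from_z <- function(a) {
  a <- unitize(a)
  z <- c(0, 0, 1)
  c_ <- sum(z * a)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  ax <- c(z[2] * a[3] - z[3] * a[2],
          z[3] * a[1] - z[1] * a[3],
          z[1] * a[2] - z[2] * a[1])
  s <- sqrt(sum(ax^2))
  ax <- ax / s
  K <- matrix(c(0, -ax[3], ax[2],
                ax[3], 0, -ax[1],
                -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
  diag(3) + s * K + (1 - c_) * (K %*% K)
}

# rotation matrix about unit axis `u` by angle `phi` (radians)
rotation_about <- function(u, phi) {
  u <- unitize(u)
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(phi) * K + (1 - cos(phi)) * (K %*% K)
}

# deterministic, near-uniform set of n points on the unit sphere
# (Fibonacci / golden-spiral lattice); used for all powder averages
sphere_grid <- function(n) {
  stopifnot_scalar(n, "n", lower = 10)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- 2 * pi * i * (2 / (1 + sqrt(5)))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}
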