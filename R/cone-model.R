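#' Wobbling-in-a-cone generator specification
#'
#' Describes uniaxial diffusion of a unit vector inside a cone: the vector is
#' uniformly distributed over solid angle within the cone at equilibrium and
#' reorients diffusively with a tunable correlation time.  The correlation
#' time is defined operationally as the decay time recovered by a
#' monoexponential fit of the P2 autocorrelation function with the plateau
#' fixed at S^2 (see [fit_acf_monoexp()]).
#'
#' @param semi_angle cone semi-angle in degrees, in \[0, 90\].
#' @param tau target correlation time in ns (> 0).
#' @param dt frame spacing in ns (> 0).
#' @param n_frames number of frames (>= 2).
#' @param seed integer seed.
#' @return a `cone_spec` object.
#' @seealso [gen_cone_orientations()], [cone_order_parameter()]
#' @export
cone_spec <- function(semi_angle, tau, dt = 1, n_frames, seed = 1L) {
  stopifnot_scalar(semi_angle, "semi_angle", lower = 0, upper = 90)
  stopifnot_scalar(tau, "tau", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(n_frames, "n_frames", lower = 2)
  structure(list(semi_angle = semi_angle, tau = tau, dt = dt,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "cone_spec")
}

#' Composite fast + slow motion specification
#'
#' Two nested cone motions: a slow cone motion of the segment axis and a fast
#' wobble of the vector about the instantaneous slow axis.  Assuming
#' statistical independence, the total order parameter is the product of the
#' two cone order parameters.
#'
#' @param fast,slow [cone_spec()] objects; `fast$tau` must be smaller than
#'   `slow$tau`, and both must share `dt` and `n_frames`.
#' @param seed integer seed (overrides the component seeds).
#' @return a `composite_spec` object.
#' @export
composite_spec <- function(fast, slow, seed = 1L) {
  stopifnot(inherits(fast, "cone_spec"), inherits(slow, "cone_spec"))
  if (!(fast$tau < slow$tau))
    stop("'fast$tau' must be smaller than 'slow$tau'")
  if (fast$dt != slow$dt || fast$n_frames != slow$n_frames)
    stop("fast and slow specs must share dt and n_frames")
  structure(list(fast = fast, slow = slow, seed = as.integer(seed)),
            class = "composite_spec")
}

#' Closed-form cone order parameter and its inverse
#'
#' For uniform (solid-angle) occupation of a cone of semi-angle `theta_c`
#' the second-rank order parameter is
#' `S = cos(theta_c) * (1 + cos(theta_c)) / 2`.  `cone_semi_angle()` inverts
#' the relation through `cos(theta) = (-1 + sqrt(1 + 8 S)) / 2`, converting a
#' measured order parameter into the motional amplitude of the bond vector.
#'
#' @param semi_angle cone semi-angle in degrees.
#' @param S order parameter in \[0, 1\] (vectorized).
#' @return `cone_order_parameter()`: the order parameter;
#'   `cone_semi_angle()`: the semi-angle in degrees.
#' @examples
#' cone_semi_angle(0.57)  # about 47 degrees
#' cone_semi_angle(0.67)  # about 40 degrees
#' @export
cone_order_parameter <- function(semi_angle) {
  if (any(!is.finite(semi_angle)) || any(semi_angle < 0 | semi_angle > 90))
    stop("'semi_angle' must be in [0, 90] degrees")
  x <- cos(deg2rad(semi_angle))
  x * (1 + x) / 2
}

#' @rdname cone_order_parameter
#' @export
cone_semi_angle <- function(S) {
  if (any(!is.finite(S)) || any(S < 0 | S > 1))
    stop("'S' must be in [0, 1]")
  x <- (-1 + sqrt(1 + 8 * S)) / 2
  rad2deg(acos(pmin(1, x)))
}

# Effective correlation time of the P2 ACF for diffusion in a cone, in the
# form g(x0) = D * tau_eff * (1 - S^2) with x0 = cos(theta_c)
# (Lipari-Szabo integral result for the wobbling-in-a-cone model).
cone_tau_integral <- function(x0) {
  x0^2 * (1 + x0)^2 * (log((1 + x0) / 2) + (1 - x0) / 2) / (2 * (x0 - 1)) +
    (1 - x0) * (6 + 8 * x0 - x0^2 - 12 * x0^3 - 7 * x0^4) / 24
}

# Ratio of the monoexponential-fit decay time (plateau fixed at S^2, window =
# first third of lags up to 10 tau) to the integral effective time, measured
# once from long fine-step simulations (2e6 frames, D chosen so tau ~ 100
# frames); interpolated linearly in theta_c.
.cone_fit_calibration <- list(
  theta = c(5, 10, 20, 30, 40, 47.2, 60, 75, 89, 90),
  ratio = c(1.25, 1.19, 1.048, 1.035, 1.027, 1.024, 1.024, 1.013, 0.966, 0.96)
)

# diffusion coefficient (rad^2/ns) giving the requested monoexponential-fit
# correlation time for a cone of the given semi-angle (degrees)
cone_diffusion_coefficient <- function(semi_angle, tau) {
  x0 <- cos(deg2rad(semi_angle))
  S <- x0 * (1 + x0) / 2
  r <- approx(.cone_fit_calibration$theta, .cone_fit_calibration$ratio,
              xout = semi_angle, rule = 2)$y
  r * cone_tau_integral(x0) / ((1 - S^2) * tau)
}

# core walk: returns an n x 3 matrix of unit vectors confined to the cone
# about +z; consumes R's RNG stream
cone_walk_about_z <- function(semi_angle, tau, dt, n_frames) {
  theta_c <- deg2rad(semi_angle)
  if (semi_angle == 0)
    return(matrix(rep(c(0, 0, 1), n_frames), ncol = 3, byrow = TRUE))
  # equilibrium start: cos(theta) uniform on [cos(theta_c), 1]
  c0 <- runif(1, cos(theta_c), 1)
  ph <- runif(1, 0, 2 * pi)
  s0 <- sqrt(1 - c0^2)
  v0 <- c(s0 * cos(ph), s0 * sin(ph), c0)
  D <- cone_diffusion_coefficient(semi_angle, tau)
  step_sd <- sqrt(2 * D * dt)
  .cone_walk(as.integer(n_frames), theta_c, step_sd, v0)
}

#' Generate a cone-diffusion orientation series
#'
#' Realizes the specification as a geodesic random walk on the unit sphere
#' with a reflecting boundary at the cone semi-angle.  The equilibrium
#' density is uniform over solid angle within the cone, so the long-series
#' order parameter converges to [cone_order_parameter()]; the step size is
#' calibrated so that the correlation time recovered by [fit_acf_monoexp()]
#' matches `spec$tau`.  Identical spec and seed give identical output.
#'
#' @param spec a [cone_spec()].
#' @param axis cone axis (default +z); the walk is generated about +z and
#'   rotated onto `axis`.
#' @return an [orientation_series()].
#' @export
gen_cone_orientations <- function(spec, axis = c(0, 0, 1)) {
  stopifnot(inherits(spec, "cone_spec"))
  set.seed(spec$seed)
  V <- cone_walk_about_z(spec$semi_angle, spec$tau, spec$dt, spec$n_frames)
  axis <- unitize(axis)
  if (any(abs(axis - c(0, 0, 1)) > 1e-12))
    V <- V %*% t(rotation_from_z(axis))
  orientation_series(V, dt = spec$dt,
                     label = sprintf("cone %.3g deg, tau %.3g ns", spec$semi_angle, spec$tau))
}

#' Generate a composite fast + slow orientation series
#'
#' The slow cone motion moves the segment axis; the fast cone motion wobbles
#' the vector about the instantaneous slow axis.  When `fast$tau <= dt` the
#' fast wobble is drawn independently from the cone equilibrium at every
#' frame (it is then fully decorrelated between frames by construction).
#' Ground truth: `S_total = S_fast * S_slow`.
#'
#' @param spec a [composite_spec()].
#' @return an [orientation_series()] with attribute `ground_truth`
#'   (list with `S_fast`, `S_slow`, `S_total`).
#' @export
gen_composite_orientations <- function(spec) {
  stopifnot(inherits(spec, "composite_spec"))
  set.seed(spec$seed)
  n <- spec$slow$n_frames
  dt <- spec$slow$dt
  W <- cone_walk_about_z(spec$slow$semi_angle, spec$slow$tau, dt, n)
  if (spec$fast$semi_angle == 0) {
    V <- W
  } else if (spec$fast$tau <= dt) {
    theta_c <- deg2rad(spec$fast$semi_angle)
    cth <- runif(n, cos(theta_c), 1)
    ph <- runif(n, 0, 2 * pi)
    sth <- sqrt(1 - cth^2)
    F <- cbind(sth * cos(ph), sth * sin(ph), cth)
    V <- compose_about_axes(F, W)
  } else {
    F <- cone_walk_about_z(spec$fast$semi_angle, spec$fast$tau, dt, n)
    V <- compose_about_axes(F, W)
  }
  S_fast <- cone_order_parameter(spec$fast$semi_angle)
  S_slow <- cone_order_parameter(spec$slow$semi_angle)
  out <- orientation_series(V, dt = dt, label = "composite fast+slow cone")
  attr(out, "ground_truth") <- list(S_fast = S_fast, S_slow = S_slow,
                                    S_total = S_fast * S_slow)
  out
}

# rotate each fast vector F[i,] (defined about +z) onto the frame whose z axis
# is the slow vector W[i,]; minimal rotation carrying z to W is used
compose_about_axes <- function(F, W) {
  n <- nrow(F)
  V <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    R <- rotation_from_z(W[i, ])
    V[i, ] <- R %*% F[i, ]
  }
  V
}
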