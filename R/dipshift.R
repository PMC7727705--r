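#' Rigid-limit heteronuclear dipolar couplings
#'
#' Effective one-bond 1H-13C couplings of immobile groups, as determined from
#' separated-local-field experiments on crystalline amino acids at low
#' temperature.  The methyl value is pre-averaged by the fast three-site
#' methyl rotation, so the CH3 group is treated as an axially symmetric
#' coupling along the C3 axis.  All values are configurable constants in kHz.
#'
#' @param CH,CH2,CH3 per-class rigid-limit couplings in kHz.
#' @return named numeric vector of couplings.
#' @export
rigid_limits <- function(CH = 21.5, CH2 = 21.5, CH3 = 7.2) {
  out <- c(CH = CH, CH2 = CH2, CH3 = CH3)
  if (any(out <= 0)) stop("rigid-limit couplings must be positive")
  out
}

#' Dephasing curve container
#'
#' Normalized DipShift dephasing intensities over one rotor period.
#'
#' @param t1_fraction evolution times as fractions of one rotor period, in
#'   \[0, 1\], starting at 0.
#' @param intensity normalized intensities; `intensity[t1 = 0]` must be 1 and
#'   all values within \[-1, 1\] (a small tolerance is allowed for noise).
#' @param mas_kHz magic-angle spinning rate in kHz.
#' @param scaling homonuclear-decoupling scaling factor.
#' @param group_class one of `"CH"`, `"CH2"`, `"CH3"`.
#' @return a `dephasing_curve` object.
#' @export
dephasing_curve <- function(t1_fraction, intensity, mas_kHz,
                            scaling = 1 / sqrt(3), group_class = "CH") {
  if (length(t1_fraction) != length(intensity))
    stop("'t1_fraction' and 'intensity' must have equal length")
  if (any(t1_fraction < 0 | t1_fraction > 1)) stop("'t1_fraction' must lie in [0, 1]")
  if (abs(t1_fraction[1]) > 1e-9 || abs(intensity[1] - 1) > 0.05)
    stop("curve must start at t1 = 0 with intensity 1")
  if (any(abs(intensity) > 1.5)) stop("intensities far outside [-1, 1]")
  stopifnot_scalar(mas_kHz, "mas_kHz", lower = 0, strict_lower = TRUE)
  structure(list(t1_fraction = t1_fraction, intensity = intensity,
                 mas_kHz = mas_kHz, scaling = scaling,
                 group_class = match.arg(group_class, c("CH", "CH2", "CH3"))),
            class = "dephasing_curve")
}

#' @export
print.dephasing_curve <- function(x, ...) {
  cat(sprintf("DipShift dephasing curve (%s): %d t1 points, MAS %.3g kHz, scaling %.3f\n",
              x$group_class, length(x$t1_fraction), x$mas_kHz, x$scaling))
  cat(sprintf("  minimum intensity %.3f at t1/Tr = %.2f\n",
              min(x$intensity), x$t1_fraction[which.min(x$intensity)]))
  invisible(x)
}

# MAS geometry constants: B0 direction in the rotor frame traces a cone at the
# magic angle; the zz lab component of a rotor-frame tensor M becomes a
# second-harmonic trig polynomial with these prefactors
.MAGIC <- list(s2 = 2 / 3,            # sin^2(theta_m)
               s2c2 = 2 * sqrt(2) / 3) # 2 sin(theta_m) cos(theta_m)

# Phase accumulated from 0 to each t1 for crystallite tensors given by their
# trig coefficients; a* are N-vectors (kHz), t1 in ms, mas in kHz.
# Returns N x length(t1) matrix of phases (radians).
.dephasing_phase <- function(a1c, a1s, a2c, a2s, t1, mas_kHz) {
  wr <- 2 * pi * mas_kHz              # rad / ms
  s1 <- sin(wr * t1) / wr
  c1 <- (1 - cos(wr * t1)) / wr
  s2 <- sin(2 * wr * t1) / (2 * wr)
  c2 <- (1 - cos(2 * wr * t1)) / (2 * wr)
  2 * pi * (outer(a1c, s1) + outer(a1s, c1) + outer(a2c, s2) + outer(a2s, c2))
}

# trig coefficients of the instantaneous frequency for a set of rotor-frame
# tensors M (list of component vectors), in kHz
.tensor_coeffs <- function(Mxx, Myy, Mxy, Mxz, Myz) {
  list(a1c = .MAGIC$s2c2 * Mxz,
       a1s = .MAGIC$s2c2 * Myz,
       a2c = .MAGIC$s2 * (Mxx - Myy) / 2,
       a2s = .MAGIC$s2 * Mxy)
}

#' Simulate DipShift dipolar dephasing over one rotor period
#'
#' Powder-averaged dephasing `I(t1) = < cos(phase accumulated from 0 to t1) >`
#' where the instantaneous frequency of each crystallite is the standard
#' MAS-modulated heteronuclear dipolar coupling, scaled by the homonuclear
#' decoupling factor.  Orientational averaging uses a deterministic
#' golden-spiral grid.  `CH` uses a single bond; `CH2` multiplies the
#' dephasing of two bonds at the tetrahedral angle (independent-proton
#' approximation); `CH3` multiplies three identical couplings along the
#' methyl-rotation-averaged C3 axis.  At `t1 = 0` and at one full rotor
#' period the anisotropic phase refocuses (rotor echo) and the intensity
#' returns to 1 up to grid error.
#'
#' @param coupling_kHz motionally averaged per-bond coupling (>= 0), kHz,
#'   before decoupling scaling.
#' @param mas_kHz spinning frequency, kHz (> 0).
#' @param scaling homonuclear decoupling scale; default `1/sqrt(3)` (ideal
#'   Lee-Goldburg condition).
#' @param group_class `"CH"`, `"CH2"` or `"CH3"`.
#' @param n_grid crystallite orientations (default 10000; a warning flag is
#'   attached below 1000).
#' @param n_t1 number of evenly spaced t1 points across the rotor period.
#' @param n_gamma third-angle subdivisions for multi-bond classes.
#' @return a [dephasing_curve()]; attribute `flag` notes an undersized grid.
#' @export
simulate_dephasing <- function(coupling_kHz, mas_kHz, scaling = 1 / sqrt(3),
                               group_class = "CH", n_grid = 10000,
                               n_t1 = 16, n_gamma = 8) {
  stopifnot_scalar(coupling_kHz, "coupling_kHz", lower = 0)
  stopifnot_scalar(mas_kHz, "mas_kHz", lower = 0, strict_lower = TRUE)
  group_class <- match.arg(group_class, c("CH", "CH2", "CH3"))
  flag <- if (n_grid < 1000) "grid_small" else NULL
  Tr <- 1 / mas_kHz                     # rotor period, ms
  frac <- seq(0, 1, length.out = n_t1 + 1)
  t1 <- frac * Tr
  d <- coupling_kHz * scaling
  if (coupling_kHz == 0) {
    out <- dephasing_curve(frac, rep(1, length(frac)), mas_kHz, scaling, group_class)
    attr(out, "flag") <- flag
    return(out)
  }
  if (group_class == "CH" || group_class == "CH3") {
    u <- sphere_grid(n_grid)
    co <- .tensor_coeffs(d * (3 * u[, 1]^2 - 1) / 2,
                         d * (3 * u[, 2]^2 - 1) / 2,
                         d * 3 * u[, 1] * u[, 2] / 2,
                         d * 3 * u[, 1] * u[, 3] / 2,
                         d * 3 * u[, 2] * u[, 3] / 2)
    ph <- .dephasing_phase(co$a1c, co$a1s, co$a2c, co$a2s, t1, mas_kHz)
    I <- if (group_class == "CH") colMeans(cos(ph)) else colMeans(cos(ph)^3)
  } else {
    # CH2: two bonds at the tetrahedral angle, crystallites from a spiral
    # grid of molecular z directions x n_gamma azimuths
    half <- acos(1 / sqrt(3))           # half the tetrahedral angle
    bonds <- rbind(c(sin(half), 0, cos(half)), c(-sin(half), 0, cos(half)))
    dirs <- sphere_grid(max(100, floor(n_grid / n_gamma)))
    beta <- acos(pmin(1, pmax(-1, dirs[, 3])))
    alpha <- atan2(dirs[, 2], dirs[, 1])
    I <- 0
    for (g in seq_len(n_gamma)) {
      gam <- 2 * pi * (g - 1) / n_gamma
      prod_cos <- 1
      for (b in 1:2) {
        ub <- c(cos(gam) * bonds[b, 1] - sin(gam) * bonds[b, 2],
                sin(gam) * bonds[b, 1] + cos(gam) * bonds[b, 2],
                bonds[b, 3])
        # rotor-frame bond = Rz(alpha) Ry(beta) ub, vectorized over crystallites
        px <- cos(beta) * ub[1] + sin(beta) * ub[3]
        py <- rep(ub[2], length(beta))
        pz <- -sin(beta) * ub[1] + cos(beta) * ub[3]
        bx <- cos(alpha) * px - sin(alpha) * py
        by <- sin(alpha) * px + cos(alpha) * py
        bz <- pz
        co <- .tensor_coeffs(d * (3 * bx^2 - 1) / 2, d * (3 * by^2 - 1) / 2,
                             d * 3 * bx * by / 2, d * 3 * bx * bz / 2,
                             d * 3 * by * bz / 2)
        ph <- .dephasing_phase(co$a1c, co$a1s, co$a2c, co$a2s, t1, mas_kHz)
        prod_cos <- prod_cos * cos(ph)
      }
      I <- I + colMeans(prod_cos)
    }
    I <- I / n_gamma
  }
  out <- dephasing_curve(frac, I, mas_kHz, scaling, group_class)
  attr(out, "flag") <- flag
  out
}

#' Generate a noisy synthetic dephasing curve
#'
#' Forward model [simulate_dephasing()] plus seeded additive Gaussian noise.
#'
#' @inheritParams simulate_dephasing
#' @param noise_sd standard deviation of the additive noise.
#' @param seed integer seed.
#' @param ... further arguments passed to [simulate_dephasing()].
#' @return a [dephasing_curve()].
#' @export
gen_dephasing_curve <- function(coupling_kHz, mas_kHz, scaling = 1 / sqrt(3),
                                noise_sd = 0, seed = 1L, ...) {
  cur <- simulate_dephasing(coupling_kHz, mas_kHz, scaling = scaling, ...)
  if (noise_sd > 0) {
    set.seed(seed)
    noisy <- cur$intensity + rnorm(length(cur$intensity), 0, noise_sd)
    noisy[1] <- cur$intensity[1]   # normalization point is the reference
    cur$intensity <- noisy
  }
  cur
}

#' Fit the dipolar coupling of a dephasing curve
#'
#' One-parameter least-squares fit of simulated dephasing curves to the data
#' over the coupling strength; the result carries the order parameter
#' `S = coupling / rigid_limit` for the group class and the corresponding
#' wobbling-in-a-cone semi-angle.  `S > 1.05` or a failed optimization is
#' flagged rather than silently returned.
#'
#' @param curve a [dephasing_curve()].
#' @param limits rigid-limit couplings from [rigid_limits()].
#' @param group_class group class; defaults to the curve's.
#' @param n_grid crystallite orientations used in the fit forward model.
#' @return an object of class `dipshift_fit` with `coupling` (kHz), `S`,
#'   `cone_semi_angle` (degrees), `group_class`, `rss` and `flag`.
#' @export
fit_dipolar_coupling <- function(curve, limits = rigid_limits(),
                                 group_class = NULL, n_grid = 4000) {
  stopifnot(inherits(curve, "dephasing_curve"))
  group_class <- group_class %||% curve$group_class
  rigid <- limits[[group_class]]
  n_t1 <- length(curve$t1_fraction) - 1L
  obj <- function(d) {
    sim <- simulate_dephasing(d, curve$mas_kHz, curve$scaling, group_class,
                              n_grid = n_grid, n_t1 = n_t1)
    sum((sim$intensity - curve$intensity)^2)
  }
  # flat curves fit to zero coupling without optimization noise
  if (max(abs(curve$intensity - 1)) < 1e-6) {
    res <- list(minimum = 0, objective = obj(0))
  } else {
    res <- optimize(obj, c(0, 1.4 * rigid), tol = 1e-4 * rigid)
    names(res) <- c("minimum", "objective")
  }
  S <- res$minimum / rigid
  flag <- if (S > 1.05) "order_parameter_above_1" else NULL
  out <- list(coupling = res$minimum, S = S,
              cone_semi_angle = if (S <= 1) cone_semi_angle(S) else NA_real_,
              group_class = group_class, rigid_limit = rigid,
              rss = res$objective, flag = flag)
  class(out) <- "dipshift_fit"
  out
}

#' @export
print.dipshift_fit <- function(x, ...) {
  cat(sprintf("DipShift coupling fit (%s, rigid limit %.3g kHz)\n",
              x$group_class, x$rigid_limit))
  cat(sprintf("  coupling = %.3f kHz, S = %.3f, cone semi-angle = %s\n",
              x$coupling, x$S,
              if (is.na(x$cone_semi_angle)) "-" else
                sprintf("%.1f deg", x$cone_semi_angle)))
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' @export
coef.dipshift_fit <- function(object, ...) {
  c(coupling_kHz = object$coupling, S = object$S,
    cone_semi_angle_deg = object$cone_semi_angle)
}

# dephasing intensity for an arbitrary traceless symmetric coupling tensor
# `M` (kHz, already scaled), powder-averaged over a spiral grid of tensor-z
# directions x n_gamma azimuths; used by the trajectory-based DipShift
# estimator where motional averaging can leave a biaxial tensor
dephasing_from_tensor <- function(M, mas_kHz, n_grid = 2000, n_t1 = 16,
                                  n_gamma = 8) {
  Tr <- 1 / mas_kHz
  frac <- seq(0, 1, length.out = n_t1 + 1)
  t1 <- frac * Tr
  dirs <- sphere_grid(max(100, floor(n_grid / n_gamma)))
  beta <- acos(pmin(1, pmax(-1, dirs[, 3])))
  alpha <- atan2(dirs[, 2], dirs[, 1])
  ca <- cos(alpha); sa <- sin(alpha); cb <- cos(beta); sb <- sin(beta)
  I <- 0
  for (g in seq_len(n_gamma)) {
    gam <- 2 * pi * (g - 1) / n_gamma
    cg <- cos(gam); sg <- sin(gam)
    acc <- matrix(0, length(beta), length(t1))
    # R = Rz(alpha) Ry(beta) Rz(gamma); build rows vectorized over crystallites
    r11 <- ca * cb * cg - sa * sg; r12 <- -ca * cb * sg - sa * cg; r13 <- ca * sb
    r21 <- sa * cb * cg + ca * sg; r22 <- -sa * cb * sg + ca * cg; r23 <- sa * sb
    r31 <- -sb * cg;               r32 <- sb * sg;                r33 <- cb
    # Mrot = R M R', elementwise over crystallites
    m <- M
    RM1 <- cbind(r11 * m[1, 1] + r12 * m[2, 1] + r13 * m[3, 1],
                 r11 * m[1, 2] + r12 * m[2, 2] + r13 * m[3, 2],
                 r11 * m[1, 3] + r12 * m[2, 3] + r13 * m[3, 3])
    RM2 <- cbind(r21 * m[1, 1] + r22 * m[2, 1] + r23 * m[3, 1],
                 r21 * m[1, 2] + r22 * m[2, 2] + r23 * m[3, 2],
                 r21 * m[1, 3] + r22 * m[2, 3] + r23 * m[3, 3])
    RM3 <- cbind(r31 * m[1, 1] + r32 * m[2, 1] + r33 * m[3, 1],
                 r31 * m[1, 2] + r32 * m[2, 2] + r33 * m[3, 2],
                 r31 * m[1, 3] + r32 * m[2, 3] + r33 * m[3, 3])
    Mxx <- RM1[, 1] * r11 + RM1[, 2] * r12 + RM1[, 3] * r13
    Myy <- RM2[, 1] * r21 + RM2[, 2] * r22 + RM2[, 3] * r23
    Mxy <- RM1[, 1] * r21 + RM1[, 2] * r22 + RM1[, 3] * r23
    Mxz <- RM1[, 1] * r31 + RM1[, 2] * r32 + RM1[, 3] * r33
    Myz <- RM2[, 1] * r31 + RM2[, 2] * r32 + RM2[, 3] * r33
    co <- .tensor_coeffs(Mxx, Myy, Mxy, Mxz, Myz)
    ph <- .dephasing_phase(co$a1c, co$a1s, co$a2c, co$a2s, t1, mas_kHz)
    I <- I + colMeans(cos(ph))
  }
  dephasing_curve(frac, I / n_gamma, mas_kHz, scaling = 1, group_class = "CH")
}
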