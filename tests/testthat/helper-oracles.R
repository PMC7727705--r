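# Independent reference implementations used as oracles.  These deliberately
# avoid the package's production code paths.

# brute-force P2 ACF: double loop over all frame pairs
oracle_p2_acf <- function(V, max_lag) {
  n <- nrow(V)
  vapply(0:max_lag, function(k) {
    s <- 0
    for (t in seq_len(n - k)) {
      d <- sum(V[t, ] * V[t + k, ])
      s <- s + (3 * d^2 - 1) / 2
    }
    s / (n - k)
  }, numeric(1))
}

# brute-force MAS dephasing at selected t1 values for a single axial coupling:
# Monte-Carlo powder of random crystallites, numerical (trapezoid) phase
# integration on a fine time grid
oracle_dephasing <- function(coupling_kHz, mas_kHz, scaling, t1_ms,
                             n_cryst = 1e5, n_steps = 500, seed = 99) {
  set.seed(seed)
  d <- coupling_kHz * scaling
  wr <- 2 * pi * mas_kHz
  out <- numeric(length(t1_ms))
  chunk <- 10000
  done <- 0
  acc <- numeric(length(t1_ms))
  while (done < n_cryst) {
    m <- min(chunk, n_cryst - done)
    u <- matrix(rnorm(3 * m), m, 3)
    u <- u / sqrt(rowSums(u^2))
    cb <- u[, 3]
    beta <- acos(pmin(1, pmax(-1, cb)))
    gam <- atan2(u[, 2], u[, 1])
    for (j in seq_along(t1_ms)) {
      tt <- seq(0, t1_ms[j], length.out = n_steps + 1)
      # omega(t) = d/2 * [ sqrt(2) sin(2 beta) cos(wr t + gam)
      #                    + sin(beta)^2 cos(2 wr t + 2 gam) ]  (kHz)
      f <- outer(sqrt(2) * sin(2 * beta), rep(1, length(tt))) *
        cos(outer(rep(1, m), wr * tt) + gam) +
        outer(sin(beta)^2, rep(1, length(tt))) *
        cos(outer(rep(1, m), 2 * wr * tt) + 2 * gam)
      f <- d / 2 * f
      dt <- tt[2] - tt[1]
      phase <- 2 * pi * (rowSums(f) - (f[, 1] + f[, ncol(f)]) / 2) * dt
      acc[j] <- acc[j] + sum(cos(phase))
    }
    done <- done + m
  }
  acc / n_cryst
}

# exhaustive cylinder-axis search: 1-degree grid over the hemisphere with an
# algebraic in-plane circle center, then local refinement of the best cell
oracle_cylinder_axis <- function(coords) {
  coords <- as.matrix(coords)
  ctr <- colMeans(coords)
  X <- sweep(coords, 2, ctr)
  objective <- function(th, ph) {
    u <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    e <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    b1 <- e - sum(e * u) * u; b1 <- b1 / sqrt(sum(b1^2))
    b2 <- c(u[2] * b1[3] - u[3] * b1[2], u[3] * b1[1] - u[1] * b1[3],
            u[1] * b1[2] - u[2] * b1[1])
    x1 <- X %*% b1; x2 <- X %*% b2
    A <- cbind(2 * x1, 2 * x2, 1)
    cc <- tryCatch(qr.solve(A, x1^2 + x2^2), error = function(e) c(0, 0, 0))
    d <- sqrt((x1 - cc[1])^2 + (x2 - cc[2])^2)
    sum((d - mean(d))^2)
  }
  best <- c(Inf, 0, 0)
  for (th_deg in seq(0, 90, by = 1)) {
    for (ph_deg in seq(0, 359, by = 1)) {
      v <- objective(th_deg * pi / 180, ph_deg * pi / 180)
      if (v < best[1]) best <- c(v, th_deg, ph_deg)
    }
  }
  ref <- optim(c(best[2], best[3]) * pi / 180,
               function(p) objective(p[1], p[2]),
               method = "Nelder-Mead", control = list(reltol = 1e-14))
  th <- ref$par[1]; ph <- ref$par[2]
  c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}

# angle between two axes in degrees, sign-blind
axis_angle_deg <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  acos(min(1, abs(sum(a * b)))) * 180 / pi
}

# trajectory in which residue 1's CA sits at the origin and its HA tracks a
# supplied orientation series: turns bond dynamics into a ca_trajectory
bond_fixture_trajectory <- function(series, bond_length = 1.09) {
  V <- as.matrix(series)
  n <- nrow(V)
  xyz <- array(0, c(n, 2, 3))
  xyz[, 2, ] <- V * bond_length
  ca_trajectory(xyz, data.frame(resid = c(1L, 1L), name = c("CA", "HA")),
                dt = if (inherits(series, "orientation_series")) series$dt else 1)
}
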