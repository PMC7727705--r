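test_that("total order parameter handles limits and degeneracy", {
  V <- matrix(rep(c(0, 0, 1), 10), ncol = 3, byrow = TRUE)
  expect_equal(as.numeric(order_parameter_total(V)), 1)

  set.seed(5)
  U <- matrix(rnorm(3 * 2e4), ncol = 3)
  U <- U / sqrt(rowSums(U^2))
  expect_lt(abs(as.numeric(order_parameter_total(U))), 0.03)

  # symmetric two-site hop: mean vector vanishes, fall back to the tensor axis
  W <- matrix(rep(c(0, 0, 1, 0, 0, -1), 50), ncol = 3, byrow = TRUE)
  S <- order_parameter_total(W)
  expect_identical(attr(S, "flag"), "mean_vector_degenerate")
  expect_equal(as.numeric(S), 1)

  expect_error(order_parameter_total(V[1, , drop = FALSE]), "2 frames")
})

test_that("P2 ACF has exact limits and the FFT path equals the double loop", {
  os <- gen_cone_orientations(cone_spec(45, 10, 1, 500, seed = 19))
  a_fft <- p2_acf(os, max_lag = 100, method = "fft")
  a_dir <- p2_acf(os, max_lag = 100, method = "direct")
  expect_equal(a_fft$acf, a_dir$acf, tolerance = 1e-10)
  expect_equal(a_fft$acf[1], 1, tolerance = 1e-12)

  # against the standalone double-loop oracle
  ref <- oracle_p2_acf(os$vectors[1:200, ], 50)
  expect_equal(p2_acf(os$vectors[1:200, ], 50, method = "fft")$acf, ref,
               tolerance = 1e-10)

  cst <- matrix(rep(c(0, 1, 0), 40), ncol = 3, byrow = TRUE)
  expect_true(all(abs(p2_acf(cst, 10)$acf - 1) < 1e-12))
  expect_error(p2_acf(cst, 40), "max_lag")
})

test_that("cone ACFs decay from 1 to the squared order parameter", {
  os <- gen_cone_orientations(cone_spec(47.2, 10, 1, 2e5, seed = 29))
  a <- p2_acf(os, max_lag = 500)
  S2 <- cone_order_parameter(47.2)^2
  plateau <- mean(a$acf[a$lag > 200])
  expect_equal(plateau, S2, tolerance = 0.05)
  expect_gt(a$acf[2], plateau)
  expect_true(all(a$acf[a$lag > 100] > 0))
})

test_that("fast/slow split reproduces the stated arithmetic and clamps", {
  acf <- data.frame(lag = 0:10, acf = c(1, 0.81, rep(0.5, 9)))
  sp <- fast_slow_split(acf, S_total = 0.6)
  expect_equal(sp$S_fast, 0.9)
  expect_equal(sp$S_slow, 0.6 / 0.9, tolerance = 1e-12)
  expect_null(sp$flag)
  expect_equal(sp$S_fast * sp$S_slow, 0.6, tolerance = 1e-12)

  # no fast motion
  acf1 <- data.frame(lag = 0:10, acf = c(1, 1, rep(0.9, 9)))
  sp1 <- fast_slow_split(acf1, S_total = 0.7)
  expect_equal(sp1$S_fast, 1)
  expect_equal(sp1$S_slow, 0.7)

  # noise pushes ACF(1) below S_total^2: clamped, identity preserved
  acf2 <- data.frame(lag = 0:10, acf = c(1, 0.3, rep(0.3, 9)))
  sp2 <- fast_slow_split(acf2, S_total = 0.9)
  expect_identical(sp2$flag, "clamped")
  expect_equal(sp2$S_fast * sp2$S_slow, 0.9)
  expect_lte(sp2$S_slow, 1)

  expect_error(fast_slow_split(data.frame(lag = 0:2, acf = c(1, -0.1, 0)), 0.5),
               "negative")
})

test_that("composite series round-trips its fast and slow order parameters", {
  n <- 2e5
  cs <- composite_spec(cone_spec(cone_semi_angle(0.9), 0.5, 1, n),
                       cone_spec(cone_semi_angle(0.8), 100, 1, n), seed = 37)
  co <- gen_composite_orientations(cs)
  dec <- decompose_motion(co, max_lag = 2000)
  expect_lt(abs(dec$S_fast - 0.9), 0.03)
  expect_lt(abs(dec$S_slow - 0.8), 0.03)
  expect_equal(dec$S_fast * dec$S_slow, dec$S_total, tolerance = 1e-9)
})

test_that("monoexponential ACF fits recover exact parameters", {
  for (tau in c(10, 100, 1000, 5000)) {
    t <- 0:3000
    S_total <- 0.8
    acf <- data.frame(lag = t, time = t,
                      acf = 0.3 * exp(-t / tau) + S_total^2)
    fit <- fit_acf_monoexp(acf, S_total)
    expect_lt(abs(fit$A - 0.3) / 0.3, 0.01)
    expect_lt(abs(fit$tau - tau) / tau, 0.01)
  }
  # flat ACF: amplitude zero, tau undefined and flagged
  flat <- data.frame(lag = 0:100, time = 0:100, acf = rep(0.64, 101))
  f0 <- fit_acf_monoexp(flat, 0.8)
  expect_equal(f0$A, 0)
  expect_true(is.na(f0$tau))
  expect_identical(f0$flag, "amplitude_zero")
})

test_that("generator correlation times are recovered by the ACF fit", {
  os <- gen_cone_orientations(cone_spec(47.2, 200, 1, 2e5, seed = 43))
  a <- p2_acf(os, max_lag = 2000)
  fit <- fit_acf_monoexp(a, as.numeric(order_parameter_total(os)))
  expect_lt(abs(fit$tau - 200) / 200, 0.15)
})

test_that("Welch test matches the exact t distribution and conventions", {
  r <- welch_ttest(10, 1, 10, 12, 1, 10)
  expect_equal(r$t, -4.4721360, tolerance = 1e-6)
  expect_equal(r$df, 18)
  expect_equal(r$p, 2.9456427e-4, tolerance = 1e-6)

  same <- welch_ttest(5, 2, 8, 5, 2, 8)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # degenerate zero-variance convention
  expect_equal(welch_ttest(3, 0, 5, 3, 0, 5)$p, 1)
  expect_equal(welch_ttest(3, 0, 5, 4, 0, 5)$p, 0)
  expect_error(welch_ttest(1, 1, 1, 2, 1, 5), "n1")

  # against t.test on raw data with matching summaries
  set.seed(3)
  x <- rnorm(12); y <- rnorm(15, 0.8)
  ref <- t.test(x, y)
  r2 <- welch_ttest(mean(x), sd(x), 12, mean(y), sd(y), 15)
  expect_equal(r2$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(r2$df, unname(ref$parameter), tolerance = 1e-9)
  expect_equal(r2$p, ref$p.value, tolerance = 1e-9)
})

test_that("paired test handles degeneracy and matches a permutation oracle", {
  expect_equal(paired_ttest(cbind(1:5, 1:5))$p, 1)
  deg <- paired_ttest(cbind(c(1, 2, 3), c(2, 3, 4)))
  expect_identical(deg$flag, "zero_variance")
  expect_equal(deg$p, 0)
  expect_error(paired_ttest(cbind(1, 2)), "two rows")

  # permutation oracle: sign-flip reference distribution of the mean diff
  set.seed(7)
  x <- rnorm(8, 0.5)
  y <- rnorm(8)
  r <- paired_ttest(cbind(x, y))
  d <- x - y
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 8)))
  perm_means <- abs(signs %*% d) / 8
  p_perm <- mean(perm_means >= abs(mean(d)) - 1e-12)
  # exact sign-flip p and t p-value agree closely for symmetric data
  expect_lt(abs(r$p - p_perm), 0.05)
  expect_equal(sign(r$t), sign(mean(d)))
})

test_that("segment summaries follow the per-run-then-per-class arithmetic", {
  res <- data.frame(
    segment = rep(c("A", "B", "C"), each = 3),
    state = "apo",
    topo_class = rep(c("helix_extracellular", "helix_extracellular",
                       "loop_intracellular"), each = 3),
    run = rep(1:3, 3),
    S_total = c(0.90, 0.92, 0.94, 0.80, 0.82, 0.84, 0.50, 0.60, 0.70))
  sm <- summarize_segments(res)
  ps <- sm$per_segment
  expect_equal(ps$mean[ps$segment == "A"], 0.92)
  expect_equal(ps$sd[ps$segment == "C"], 0.1)
  pc <- sm$per_class
  expect_equal(pc$mean[pc$topo_class == "helix_extracellular"], (0.92 + 0.82) / 2)
  expect_equal(pc$n_segments, c(2, 1))

  one <- summarize_segments(res[res$segment == "A" & res$run == 1, ])
  expect_equal(one$per_segment$mean, 0.90)
  expect_true(is.na(one$per_segment$sd))
})
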