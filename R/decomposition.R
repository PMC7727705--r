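#' Total order parameter of an orientation series
#'
#' Computes `S_total = < 3 (v_t . vbar)^2 - 1 >_t / 2` where `vbar` is the
#' normalized arithmetic mean orientation vector.  When the series has no
#' preferred direction (`|vbar| < 1e-6`, e.g. a symmetric two-site jump) the
#' mean-vector formula is undefined; the dominant eigenvector of the averaged
#' second-rank tensor is used instead and the result is flagged.
#'
#' @param series an [orientation_series()] or an n x 3 matrix of unit vectors.
#' @return numeric S_total with attribute `flag` (`NULL` or
#'   `"mean_vector_degenerate"`).
#' @export
order_parameter_total <- function(series) {
  V <- if (inherits(series, "orientation_series")) series$vectors else as.matrix(series)
  if (nrow(V) < 2) stop("need at least 2 frames")
  vb <- colMeans(V)
  flag <- NULL
  if (sqrt(sum(vb^2)) < 1e-6) {
    # fall back to the dominant axis of the averaged tensor <3vv' - I>/2
    Q <- (3 * crossprod(V) / nrow(V) - diag(3)) / 2
    e <- eigen(Q, symmetric = TRUE)
    vb <- e$vectors[, which.max(abs(e$values))]
    flag <- "mean_vector_degenerate"
  }
  vb <- unitize(vb)
  proj <- V %*% vb
  S <- mean((3 * proj^2 - 1) / 2)
  attr(S, "flag") <- flag
  S
}

#' P2 orientation autocorrelation function
#'
#' `ACF(k) = < 3 (v_t . v_{t+k})^2 - 1 >_t / 2`, averaged over all valid frame
#' pairs for each lag.  The default path evaluates the average through the
#' correlation of the six unique components of the outer-product tensor using
#' FFTs, which is algebraically identical to the direct double loop; the
#' direct path is available for oracle comparison and small inputs.
#'
#' @param series an [orientation_series()] or n x 3 unit-vector matrix.
#' @param max_lag largest lag (in frames) to evaluate; must be < n.
#' @param method `"fft"` (default) or `"direct"`.
#' @return data.frame with `lag` (frames), `time` (ns) and `acf`.
#' @export
p2_acf <- function(series, max_lag = NULL, method = c("fft", "direct")) {
  method <- match.arg(method)
  if (inherits(series, "orientation_series")) {
    V <- series$vectors; dt <- series$dt
  } else {
    V <- as.matrix(series); dt <- 1
  }
  n <- nrow(V)
  if (is.null(max_lag)) max_lag <- n %/% 2
  max_lag <- as.integer(max_lag)
  if (max_lag >= n) stop("'max_lag' must be smaller than the series length")
  if (max_lag < 0) stop("'max_lag' must be >= 0")
  if (method == "direct") {
    acf <- vapply(0:max_lag, function(k) {
      idx <- seq_len(n - k)
      d <- rowSums(V[idx, , drop = FALSE] * V[idx + k, , drop = FALSE])
      mean((3 * d^2 - 1) / 2)
    }, numeric(1))
  } else {
    # (v_t . v_s)^2 = sum_ij (v_i v_j)_t (v_i v_j)_s over the 6 unique products
    comps <- cbind(V[, 1]^2, V[, 2]^2, V[, 3]^2,
                   V[, 1] * V[, 2], V[, 1] * V[, 3], V[, 2] * V[, 3])
    w <- c(1, 1, 1, 2, 2, 2)
    m <- 2^ceiling(log2(2 * n))
    acc <- numeric(max_lag + 1)
    for (k in 1:6) {
      x <- c(comps[, k], rep(0, m - n))
      f <- fft(x)
      cc <- Re(fft(f * Conj(f), inverse = TRUE)) / m
      acc <- acc + w[k] * cc[1:(max_lag + 1)]
    }
    acf <- (3 * acc / (n - 0:max_lag) - 1) / 2
  }
  data.frame(lag = 0:max_lag, time = (0:max_lag) * dt, acf = acf)
}

#' Split an order parameter into fast and slow contributions
#'
#' Any motion faster than the first ACF lag is counted as fast: the ACF value
#' at the first lag equals the square of the fast order parameter, and under
#' the assumption that fast and slow motions are statistically independent
#' `S_total^2 = S_slow^2 * S_fast^2`, so `S_slow = S_total / S_fast`.  When
#' noise drives `ACF(first lag)` below `S_total^2` the split is clamped to
#' `S_fast = S_total`, `S_slow = 1` and flagged, preserving the product
#' identity without an unphysical `S_slow > 1`.
#'
#' @param acf data.frame from [p2_acf()] (or any with `lag` and `acf`).
#' @param S_total total order parameter of the same series.
#' @param first_lag lag (in frames) defining the fast/slow boundary; default 1.
#' @return list with `S_fast`, `S_slow` and `flag`.
#' @export
fast_slow_split <- function(acf, S_total, first_lag = 1L) {
  if (!all(c("lag", "acf") %in% names(acf))) stop("'acf' must have columns lag and acf")
  row <- match(first_lag, acf$lag)
  if (is.na(row)) stop(sprintf("ACF has no lag-%d point", first_lag))
  a1 <- acf$acf[row]
  if (a1 < 0) stop("ACF at the first lag is negative; inconsistent input")
  flag <- NULL
  if (a1 < S_total^2) {
    S_fast <- S_total
    S_slow <- 1
    flag <- "clamped"
  } else {
    S_fast <- sqrt(a1)
    S_slow <- if (S_fast > 0) S_total / S_fast else 0
  }
  list(S_fast = S_fast, S_slow = S_slow, flag = flag)
}

#' Fit a monoexponential decay to a P2 ACF
#'
#' Least-squares fit of `ACF(t) = A * exp(-t / tau) + S_total^2` with the
#' plateau fixed at the known `S_total^2`, leaving two free parameters.  Only
#' the first third of the available lags is used, since ACFs become noisy at
#' long delays.
#'
#' @param acf data.frame from [p2_acf()] with `time` in ns.
#' @param S_total total order parameter (plateau = `S_total^2`).
#' @param window fraction of the lags used for fitting (default 1/3).
#' @return an object of class `acf_fit` with `A`, `tau` (ns), `flag`
#'   (`NULL`, `"amplitude_zero"` or `"not_converged"`) and the fit window.
#' @export
fit_acf_monoexp <- function(acf, S_total, window = 1 / 3) {
  n_use <- max(2L, floor(nrow(acf) * window))
  d <- acf[seq_len(n_use), ]
  d <- d[d$lag > 0, ]
  if (nrow(d) < 2) stop("need at least 2 nonzero lags in the fit window")
  plateau <- S_total^2
  y <- d$acf
  t <- d$time
  A0 <- max(y[1] - plateau, 1e-4)
  flag <- NULL
  if (max(y) - plateau < 1e-4) {
    out <- list(A = 0, tau = NA_real_, flag = "amplitude_zero")
  } else {
    # log-parametrized tau keeps the search positive
    obj <- function(p) sum((y - (p[1] * exp(-t / exp(p[2])) + plateau))^2)
    # crude tau init: first lag where the excess drops below A0/e
    ex <- y - plateau
    i0 <- which(ex < A0 / exp(1))
    tau0 <- if (length(i0)) max(t[i0[1]], d$time[1]) else max(t) / 3
    fit <- optim(c(A0, log(tau0)), obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-12))
    if (fit$convergence != 0) flag <- "not_converged"
    out <- list(A = fit$par[1], tau = exp(fit$par[2]), flag = flag)
  }
  out$S_total <- S_total
  out$window_lags <- range(d$lag)
  out$residual_ss <- if (is.na(out$tau)) sum((y - plateau)^2) else
    sum((y - (out$A * exp(-t / out$tau) + plateau))^2)
  class(out) <- "acf_fit"
  out
}

#' @export
print.acf_fit <- function(x, ...) {
  cat("Monoexponential ACF fit (plateau fixed at S_total^2)\n")
  cat(sprintf("  A = %.4f, tau = %s ns, plateau = %.4f\n", x$A,
              if (is.na(x$tau)) "undefined" else sprintf("%.4g", x$tau),
              x$S_total^2))
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' @export
coef.acf_fit <- function(object, ...) c(A = object$A, tau = object$tau)

#' Full order decomposition of an orientation series
#'
#' Convenience wrapper running [order_parameter_total()], [p2_acf()],
#' [fast_slow_split()] and [fit_acf_monoexp()] on one series.
#'
#' @param series an [orientation_series()].
#' @param max_lag largest ACF lag in frames (default half the series).
#' @param first_lag fast/slow boundary lag in frames.
#' @param acf_method passed to [p2_acf()].
#' @return an object of class `order_decomposition` with `S_total`, `S_fast`,
#'   `S_slow`, `A`, `tau`, flags and the label of the series.
#' @export
decompose_motion <- function(series, max_lag = NULL, first_lag = 1L,
                             acf_method = "fft") {
  S_total <- order_parameter_total(series)
  acf <- p2_acf(series, max_lag = max_lag, method = acf_method)
  sp <- fast_slow_split(acf, as.numeric(S_total), first_lag = first_lag)
  fit <- fit_acf_monoexp(acf, as.numeric(S_total))
  structure(list(label = series$label,
                 S_total = as.numeric(S_total),
                 S_fast = sp$S_fast, S_slow = sp$S_slow,
                 A = fit$A, tau = fit$tau,
                 flags = c(attr(S_total, "flag"), sp$flag, fit$flag),
                 acf = acf),
            class = "order_decomposition")
}

#' @export
print.order_decomposition <- function(x, ...) {
  cat(sprintf("Order decomposition%s\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'")))
  cat(sprintf("  S_total = %.4f  (S_fast = %.4f, S_slow = %.4f)\n",
              x$S_total, x$S_fast, x$S_slow))
  cat(sprintf("  ACF fit: A = %.4f, tau = %s ns\n", x$A,
              if (is.na(x$tau)) "undefined" else sprintf("%.4g", x$tau)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Summarize segment decompositions by topological class
#'
#' Takes per-segment, per-run decomposition results and aggregates them in the
#' style of the segment-dynamics analysis: arithmetic mean and standard
#' deviation over runs within each segment, then the mean over segments in
#' each (state, class) group.
#'
#' @param results data.frame with columns `segment`, `state`, `topo_class`,
#'   `run` and one or more numeric value columns (e.g. `S_total`, `tau`).
#' @param value name of the value column to summarize (default `"S_total"`).
#' @return list with `per_segment` (mean/sd over runs) and `per_class`
#'   (mean/sd over segment means) data.frames.  Empty groups are dropped with
#'   a warning.
#' @export
summarize_segments <- function(results, value = "S_total") {
  need <- c("segment", "state", "topo_class", "run", value)
  if (!all(need %in% names(results)))
    stop("missing columns: ", paste(setdiff(need, names(results)), collapse = ", "))
  v <- results[[value]]
  keep <- is.finite(v)
  if (!all(keep)) {
    warning(sum(!keep), " non-finite values dropped from summary")
    results <- results[keep, ]
    v <- v[keep]
  }
  key <- interaction(results$state, results$topo_class, results$segment, drop = TRUE)
  per_segment <- do.call(rbind, lapply(split(seq_along(v), key), function(i) {
    data.frame(state = results$state[i[1]],
               topo_class = results$topo_class[i[1]],
               segment = results$segment[i[1]],
               n_runs = length(i),
               mean = mean(v[i]),
               sd = if (length(i) > 1) sd(v[i]) else NA_real_)
  }))
  rownames(per_segment) <- NULL
  key2 <- interaction(per_segment$state, per_segment$topo_class, drop = TRUE)
  per_class <- do.call(rbind, lapply(split(seq_len(nrow(per_segment)), key2), function(i) {
    data.frame(state = per_segment$state[i[1]],
               topo_class = per_segment$topo_class[i[1]],
               n_segments = length(i),
               mean = mean(per_segment$mean[i]),
               sd = if (length(i) > 1) sd(per_segment$mean[i]) else NA_real_)
  }))
  rownames(per_class) <- NULL
  list(per_segment = per_segment, per_class = per_class, value = value)
}
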