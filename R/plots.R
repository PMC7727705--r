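# base-graphics plot methods for the fitted objects

#' @export
plot.dephasing_curve <- function(x, ...) {
  graphics::plot(x$t1_fraction, x$intensity, type = "b", pch = 16,
                 xlab = "t1 / rotor period", ylab = "normalized intensity",
                 main = sprintf("DipShift dephasing (%s, MAS %.3g kHz)",
                                x$group_class, x$mas_kHz), ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' @export
plot.cp_fit <- function(x, times = NULL, ...) {
  if (is.null(x$times)) stop("fit carries no contact times; supply 'times'")
  tt <- times %||% seq(min(x$times), max(x$times), length.out = 200)
  yi <- predict(x, tt, "iso")
  ya <- predict(x, tt, "aniso")
  graphics::matplot(tt / 1000, cbind(yi, ya), type = "l", lty = 1,
                    col = c("red3", "gray25"),
                    xlab = "contact time (ms)", ylab = "area",
                    main = "I-S cross-polarization buildup", ...)
  graphics::legend("topright", c("isotropic", "anisotropic"),
                   col = c("red3", "gray25"), lty = 1, bty = "n")
  invisible(x)
}

#' @export
plot.order_decomposition <- function(x, ...) {
  a <- x$acf
  graphics::plot(a$time, a$acf, type = "l", col = "gray40",
                 xlab = "lag (ns)", ylab = "P2 ACF",
                 main = x$label %||% "order decomposition", ...)
  graphics::abline(h = x$S_total^2, lty = 3)
  if (!is.na(x$tau))
    graphics::lines(a$time, x$A * exp(-a$time / x$tau) + x$S_total^2,
                    col = "red3")
  graphics::legend("topright",
                   sprintf("S_total=%.3f S_fast=%.3f S_slow=%.3f tau=%.3g ns",
                           x$S_total, x$S_fast, x$S_slow, x$tau), bty = "n")
  invisible(x)
}

#' @export
plot.residue_order_profile <- function(x, ...) {
  graphics::plot(x$resid, x$S, type = "h", lwd = 2, ylim = c(0, 1),
                 xlab = "residue", ylab = "S",
                 main = sprintf("C-H order parameters (%s)",
                                attr(x, "variant") %||% "total"), ...)
  invisible(x)
}
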