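#' Built-in Y1R segment registry
#'
#' The neuropeptide Y receptor type 1 segment definitions used for
#' segment-resolved dynamics: each transmembrane helix split at its kink into
#' an extracellular and an intracellular half, loops split into sub-segments
#' of similar length, plus the termini and the short amphipathic Helix 8.
#' Residue numbers are 1-based inclusive and follow the numbering of the Y1R
#' crystal structure (PDB 5ZBQ).  Residues falling between sub-segments
#' (e.g. 171) are deliberately unassigned.
#'
#' @return data.frame with columns `name`, `sub_segment`, `first`, `last`,
#'   `topo_class` (one of `helix_extracellular`, `helix_intracellular`,
#'   `loop_extracellular`, `loop_intracellular`, `terminus`, `helix8`) and
#'   `side` (`extracellular` / `intracellular`).
#' @export
builtin_y1r_segments <- function() {
  seg <- function(name, sub, first, last, cls, side)
    data.frame(name = name, sub_segment = sub, first = first, last = last,
               topo_class = cls, side = side)
  out <- rbind(
    seg("NTER", "1", 18, 24, "terminus", "extracellular"),
    seg("NTER", "2", 24, 30, "terminus", "extracellular"),
    seg("NTER", "3", 30, 36, "terminus", "extracellular"),
    seg("Helix 1", "extracellular", 38, 47, "helix_extracellular", "extracellular"),
    seg("Helix 1", "intracellular", 49, 67, "helix_intracellular", "intracellular"),
    seg("ICL1", "1", 68, 70, "loop_intracellular", "intracellular"),
    seg("ICL1", "2", 70, 73, "loop_intracellular", "intracellular"),
    seg("Helix 2", "intracellular", 75, 91, "helix_intracellular", "intracellular"),
    seg("Helix 2", "extracellular", 95, 103, "helix_extracellular", "extracellular"),
    seg("ECL1", "1", 104, 106, "loop_extracellular", "extracellular"),
    seg("ECL1", "2", 106, 109, "loop_extracellular", "extracellular"),
    seg("Helix 3", "extracellular", 111, 116, "helix_extracellular", "extracellular"),
    seg("Helix 3", "intracellular", 119, 138, "helix_intracellular", "intracellular"),
    seg("ICL2", "1", 144, 147, "loop_intracellular", "intracellular"),
    seg("ICL2", "2", 147, 151, "loop_intracellular", "intracellular"),
    seg("Helix 4", "intracellular", 153, 170, "helix_intracellular", "intracellular"),
    seg("Helix 4", "extracellular", 172, 176, "helix_extracellular", "extracellular"),
    seg("ECL2", "1", 177, 181, "loop_extracellular", "extracellular"),
    seg("ECL2", "2", 181, 186, "loop_extracellular", "extracellular"),
    seg("ECL2", "3", 186, 191, "loop_extracellular", "extracellular"),
    seg("ECL2", "4", 191, 196, "loop_extracellular", "extracellular"),
    seg("ECL2", "5", 196, 201, "loop_extracellular", "extracellular"),
    seg("ECL2", "6", 201, 204, "loop_extracellular", "extracellular"),
    seg("Helix 5", "extracellular", 205, 218, "helix_extracellular", "extracellular"),
    seg("Helix 5", "intracellular", 223, 233, "helix_intracellular", "intracellular"),
    seg("ICL3", "1", 245, 248, "loop_intracellular", "intracellular"),
    seg("ICL3", "2", 248, 251, "loop_intracellular", "intracellular"),
    seg("Helix 6", "intracellular", 264, 277, "helix_intracellular", "intracellular"),
    seg("Helix 6", "extracellular", 279, 288, "helix_extracellular", "extracellular"),
    seg("ECL3", "1", 289, 292, "loop_extracellular", "extracellular"),
    seg("ECL3", "2", 292, 295, "loop_extracellular", "extracellular"),
    seg("Helix 7", "extracellular", 297, 314, "helix_extracellular", "extracellular"),
    seg("Helix 7", "intracellular", 316, 323, "helix_intracellular", "intracellular"),
    seg("Helix 8", "-", 326, 334, "helix8", "intracellular"),
    seg("CTER", "-", 335, 339, "terminus", "intracellular"))
  stopifnot(all(out$first < out$last), all(out$first >= 18), all(out$last <= 339))
  out
}

#' Read a segment registry from TSV
#'
#' Columns: `name`, `sub_segment`, `first`, `last`, `topo_class` and
#' optionally `side` (derived from `topo_class` when absent; termini default
#' to the extracellular side unless named `CTER`).
#'
#' @param path TSV file path.
#' @return data.frame in the format of [builtin_y1r_segments()].
#' @export
read_segments <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("name", "sub_segment", "first", "last", "topo_class")
  if (!all(need %in% names(df)))
    stop("segment table must have columns ", paste(need, collapse = ", "))
  ok <- c("helix_extracellular", "helix_intracellular", "loop_extracellular",
          "loop_intracellular", "terminus", "helix8")
  if (!all(df$topo_class %in% ok))
    stop("unknown topo_class: ",
         paste(setdiff(df$topo_class, ok), collapse = ", "))
  if (any(df$first >= df$last)) stop("segment ranges must satisfy first < last")
  if (is.null(df$side))
    df$side <- ifelse(df$topo_class %in% c("helix_extracellular", "loop_extracellular"),
                      "extracellular",
                      ifelse(df$topo_class == "terminus" & df$name == "CTER",
                             "intracellular",
                             ifelse(df$topo_class == "terminus", "extracellular",
                                    "intracellular")))
  df
}

# orthonormal basis perpendicular to unit vector u
.perp_basis <- function(u) {
  e <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  b1 <- unitize(c(u[2] * e[3] - u[3] * e[2],
                  u[3] * e[1] - u[1] * e[3],
                  u[1] * e[2] - u[2] * e[1]))
  b2 <- c(u[2] * b1[3] - u[3] * b1[2],
          u[3] * b1[1] - u[1] * b1[3],
          u[1] * b1[2] - u[2] * b1[1])
  rbind(b1, b2)
}

#' Fit a straight line axis through C-alpha positions
#'
#' Total-least-squares line (first principal component of the centered
#' coordinates).  The axis sign follows the N-to-C convention: positive
#' projection of (last point - first point).  Suitable for loops, termini and
#' partially unfolded helices, where a cylinder is not defined.
#'
#' @param coords n x 3 matrix of positions (Angstrom), ordered N to C.
#' @return an `axis_fit` object: `axis` (unit vector), `centroid`,
#'   `mean_radius` (`NA` for line fits), `objective` (sum of squared
#'   point-to-line distances) and `method`.
#' @export
fit_line_axis <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3) stop("need at least 3 points")
  ctr <- colMeans(coords)
  X <- sweep(coords, 2, ctr)
  if (max(abs(X)) < 1e-8) stop("points are coincident; axis undefined")
  e <- eigen(crossprod(X), symmetric = TRUE)
  ax <- e$vectors[, 1]
  span <- coords[nrow(coords), ] - coords[1, ]
  if (sum(ax * span) < 0) ax <- -ax
  obj <- sum(e$values[2:3])
  structure(list(axis = ax, centroid = ctr, mean_radius = NA_real_,
                 objective = obj, method = "line", flag = NULL),
            class = "axis_fit")
}

# algebraic (Kasa) circle center for 2D points; used to initialize the
# in-plane axis position of the cylinder fit
.circle_kasa <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) c(mean(x), mean(y), 0))
  c(sol[1], sol[2])
}

# cylinder objective: variance of point-to-axis distances
.cyl_objective <- function(par, coords, ctr) {
  th <- par[1]; ph <- par[2]
  u <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  B <- .perp_basis(u)
  X <- sweep(coords, 2, ctr)
  x1 <- X %*% B[1, ] - par[3]
  x2 <- X %*% B[2, ] - par[4]
  d <- sqrt(x1^2 + x2^2)
  sum((d - mean(d))^2)
}

#' Fit a cylinder axis to helical C-alpha positions
#'
#' Finds the axis direction and position minimizing the variance of the
#' point-to-axis distances `sum_i (d_i - dbar)^2`.  Unlike the straight-line
#' fit, this criterion is insensitive to the systematic tilt that the
#' residues at the helix ends induce in a least-squares line, because a
#' helix's C-alpha atoms lie on a cylinder, not on a line.  The optimization
#' is initialized from the line fit (plus angular perturbations) with the
#' in-plane center seeded by an algebraic circle fit.
#'
#' @param coords n x 3 matrix of helical positions (>= 5, non-collinear),
#'   ordered N to C.
#' @return an `axis_fit` object with `axis`, `centroid` (point on the fitted
#'   axis), `mean_radius` (mean point-to-axis distance, the helix radius) and
#'   `objective` (residual distance variance).
#' @export
fit_cylinder_axis <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 5) stop("need at least 5 points for a cylinder fit")
  line <- fit_line_axis(coords)
  ctr <- line$centroid
  X <- sweep(coords, 2, ctr)
  ev <- eigen(crossprod(X), symmetric = TRUE)$values
  if (ev[2] < 1e-10 * ev[1])
    stop("points are collinear; use fit_line_axis() instead")
  th0 <- acos(min(1, max(-1, line$axis[3])))
  ph0 <- atan2(line$axis[2], line$axis[1])
  starts <- rbind(c(th0, ph0),
                  c(th0 + 0.12, ph0), c(th0 - 0.12, ph0),
                  c(th0, ph0 + 0.12), c(th0, ph0 - 0.12))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    u <- c(sin(starts[s, 1]) * cos(starts[s, 2]),
           sin(starts[s, 1]) * sin(starts[s, 2]),
           cos(starts[s, 1]))
    B <- .perp_basis(u)
    x1 <- X %*% B[1, ]; x2 <- X %*% B[2, ]
    cc <- .circle_kasa(x1, x2)
    fit <- optim(c(starts[s, ], cc), .cyl_objective, coords = coords, ctr = ctr,
                 method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  th <- best$par[1]; ph <- best$par[2]
  ax <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  span <- coords[nrow(coords), ] - coords[1, ]
  if (sum(ax * span) < 0) ax <- -ax
  B <- .perp_basis(c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th)))
  point <- ctr + best$par[3] * B[1, ] + best$par[4] * B[2, ]
  Xc <- sweep(coords, 2, point)
  u <- ax
  d <- sqrt(rowSums((Xc - (Xc %*% u) %*% t(u))^2))
  structure(list(axis = ax, centroid = point, mean_radius = mean(d),
                 objective = best$value, method = "cylinder",
                 flag = if (best$convergence == 0) NULL else "not_converged"),
            class = "axis_fit")
}

#' @export
print.axis_fit <- function(x, ...) {
  cat(sprintf("%s axis fit: axis (%.4f, %.4f, %.4f), objective %.4g",
              x$method, x$axis[1], x$axis[2], x$axis[3], x$objective))
  if (!is.na(x$mean_radius)) cat(sprintf(", mean radius %.2f A", x$mean_radius))
  cat("\n")
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Per-frame orientation axis of one segment
#'
#' For every (strided) frame, fits the class-appropriate axis to the
#' segment's C-alpha positions: cylinder fit for transmembrane helix halves,
#' straight-line fit for loops, termini and Helix 8.  Axis sign continuity is
#' enforced frame-to-frame (an axis is flipped if its dot product with the
#' previous frame's axis is negative).
#'
#' @param traj a [ca_trajectory()].
#' @param segment one row of a segment registry (list or single-row
#'   data.frame with `first`, `last`, `topo_class`, `name`, `sub_segment`).
#' @param stride keep every `stride`-th frame.
#' @return an [orientation_series()].
#' @export
segment_orientation_series <- function(traj, segment, stride = 1L) {
  stopifnot(inherits(traj, "ca_trajectory"))
  if (is.data.frame(segment)) segment <- as.list(segment[1, ])
  resids <- segment$first:segment$last
  idx <- match(resids, traj$atoms$resid[traj$atoms$name == "CA"])
  ca_rows <- which(traj$atoms$name == "CA")[idx]
  if (anyNA(idx))
    stop("segment residues missing from topology: ",
         paste(resids[is.na(idx)], collapse = ", "))
  frames <- seq(1, dim(traj$xyz)[1], by = stride)
  use_cyl <- segment$topo_class %in% c("helix_extracellular", "helix_intracellular")
  V <- matrix(0, length(frames), 3)
  prev <- NULL
  for (i in seq_along(frames)) {
    coords <- traj$xyz[frames[i], ca_rows, , drop = TRUE]
    fit <- if (use_cyl) fit_cylinder_axis(coords) else fit_line_axis(coords)
    a <- fit$axis
    if (!is.null(prev) && sum(a * prev) < 0) a <- -a
    V[i, ] <- a
    prev <- a
  }
  orientation_series(V, dt = traj$dt * stride,
                     label = paste(segment$name, segment$sub_segment))
}
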