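#' Orientation time series
#'
#' Container for the time-stamped unit vectors describing the orientation of
#' one rigid segment or bond.  Times are in nanoseconds and must be uniformly
#' spaced; every vector is normalized to unit length (a deviation larger than
#' 1e-6 is an error).
#'
#' @param vectors numeric matrix with one row per frame and columns x, y, z.
#' @param dt frame spacing in ns (default 1).
#' @param times optional explicit time stamps in ns; must be uniformly spaced.
#' @param label optional character label carried through the analyses.
#' @return an object of class `orientation_series` with elements `times`,
#'   `vectors`, `dt` and `label`.
#' @examples
#' os <- orientation_series(matrix(rep(c(0, 0, 1), 5), ncol = 3, byrow = TRUE))
#' order_parameter_total(os)
#' @export
orientation_series <- function(vectors, dt = 1, times = NULL, label = NULL) {
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != 3L) stop("'vectors' must have 3 columns (x, y, z)")
  if (nrow(vectors) < 1L) stop("'vectors' must have at least one row")
  nrm <- sqrt(rowSums(vectors^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("all orientation vectors must have unit length (tolerance 1e-6)")
  vectors <- vectors / nrm
  if (is.null(times)) {
    stopifnot_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
    times <- (seq_len(nrow(vectors)) - 1) * dt
  } else {
    if (length(times) != nrow(vectors))
      stop("'times' must match the number of frames")
    if (length(times) > 1) {
      dts <- diff(times)
      if (any(abs(dts - dts[1]) > 1e-9 * max(abs(dts[1]), 1)))
        stop("'times' must be uniformly spaced")
      dt <- dts[1]
    }
  }
  structure(list(times = as.numeric(times), vectors = unname(vectors),
                 dt = dt, label = label),
            class = "orientation_series")
}

#' @export
print.orientation_series <- function(x, ...) {
  cat(sprintf("Orientation series%s: %d frames, dt = %g ns (%.4g ns total)\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              nrow(x$vectors), x$dt, max(x$times) - min(x$times)))
  vb <- colMeans(x$vectors)
  cat(sprintf("  mean vector (%.3f, %.3f, %.3f), |mean| = %.3f\n",
              vb[1], vb[2], vb[3], sqrt(sum(vb^2))))
  invisible(x)
}

#' @export
length.orientation_series <- function(x) nrow(x$vectors)

#' @export
as.matrix.orientation_series <- function(x, ...) x$vectors

#' Write / read an orientation series as annotated TSV
#'
#' The file carries a commented header stating columns, units and any
#' key/value metadata (seed, generator spec, ...), followed by
#' `time_ns  x  y  z` columns.
#'
#' @param series an [orientation_series()].
#' @param path file path.
#' @param metadata named list written into the `#` header.
#' @return `write_orientation_series` returns `path` invisibly;
#'   `read_orientation_series` returns an [orientation_series()].
#' @export
write_orientation_series <- function(series, path, metadata = list()) {
  stopifnot(inherits(series, "orientation_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# orientation series: columns time_ns, x, y, z (unit vector)", con)
  if (!is.null(series$label)) metadata$label <- series$label
  for (k in names(metadata))
    writeLines(sprintf("# %s: %s", k, paste(format(metadata[[k]]), collapse = " ")), con)
  df <- data.frame(time_ns = series$times, x = series$vectors[, 1],
                   y = series$vectors[, 2], z = series$vectors[, 3])
  write.table(format(df, digits = 12, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_orientation_series
#' @export
read_orientation_series <- function(path) {
  hdr <- readLines(path, n = 50)
  lab <- sub("^# label: ", "", grep("^# label: ", hdr, value = TRUE))
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  orientation_series(as.matrix(df[, c("x", "y", "z")]), times = df$time_ns,
                     label = if (length(lab)) lab[1] else NULL)
}
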