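test_that("built-in Y1R segment registry matches the published table", {
  seg <- builtin_y1r_segments()
  expect_equal(nrow(seg), 35)
  h1e <- seg[seg$name == "Helix 1" & seg$sub_segment == "extracellular", ]
  expect_equal(c(h1e$first, h1e$last), c(38, 47))
  icl3 <- seg[seg$name == "ICL3" & seg$sub_segment == "1", ]
  expect_equal(c(icl3$first, icl3$last), c(245, 248))
  h8 <- seg[seg$name == "Helix 8", ]
  expect_equal(c(h8$first, h8$last), c(326, 334))
  expect_equal(h8$topo_class, "helix8")
  expect_true(all(seg$first < seg$last))
  expect_true(all(seg$first >= 18 & seg$last <= 339))
  # residue 171 between the Helix 4 halves stays unassigned
  expect_false(any(seg$first <= 171 & seg$last >= 171))
  # seven helices, each with an extra- and an intracellular half
  expect_equal(sum(seg$topo_class == "helix_extracellular"), 7)
  expect_equal(sum(seg$topo_class == "helix_intracellular"), 7)
})

test_that("segment registry TSV round trip and validation", {
  seg <- builtin_y1r_segments()
  p <- tempfile(fileext = ".tsv")
  write.table(seg, p, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_segments(p)
  expect_equal(back$first, seg$first)
  expect_equal(back$topo_class, seg$topo_class)
  bad <- seg
  bad$topo_class[1] <- "nonsense"
  write.table(bad, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_segments(p), "topo_class")
  unlink(p)
})

test_that("line fit recovers collinear axes and rejects degenerate input", {
  z <- cbind(0, 0, seq(0, 10, length.out = 6))
  f <- fit_line_axis(z)
  expect_equal(f$axis, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(f$objective, 0, tolerance = 1e-20)
  expect_error(fit_line_axis(z[1:2, ]), "3 points")
  expect_error(fit_line_axis(matrix(1, 5, 3)), "coincident")
  # N-to-C sign convention
  f_rev <- fit_line_axis(z[6:1, ])
  expect_equal(f_rev$axis, c(0, 0, -1), tolerance = 1e-12)
})

test_that("cylinder fit is exact on ideal helices and rotation-equivariant", {
  mk_helix <- function(n) {
    tr <- gen_helix_trajectory(helix_geometry(n),
                               orientation_series(matrix(c(0, 0, 1), 1)),
                               with_h = FALSE)
    tr$xyz[1, , ]
  }
  for (n in c(5, 8, 14)) {
    co <- mk_helix(n)
    f <- fit_cylinder_axis(co)
    expect_lt(axis_angle_deg(f$axis, c(0, 0, 1)), 0.1)
    expect_lt(f$objective, 1e-8)
    expect_equal(f$mean_radius, 2.3, tolerance = 1e-3)
  }
  # rotation equivariance for both fits
  set.seed(31)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  co <- mk_helix(9)
  f0 <- fit_cylinder_axis(co)
  fr <- fit_cylinder_axis(co %*% t(R))
  expect_lt(axis_angle_deg(fr$axis, R %*% f0$axis), 1e-3)
  l0 <- fit_line_axis(co)
  lr <- fit_line_axis(co %*% t(R))
  expect_lt(axis_angle_deg(lr$axis, R %*% l0$axis), 1e-3)

  expect_error(fit_cylinder_axis(co[1:4, ]), "5 points")
  expect_error(fit_cylinder_axis(cbind(0, 0, 1:6)), "collinear")
})

test_that("cylinder criterion beats the line fit on short helices", {
  # the line fit tilts toward the end residues; the cylinder criterion avoids
  # this, which is the point of using it for transmembrane helices
  tr <- gen_helix_trajectory(helix_geometry(6),
                             orientation_series(matrix(c(0, 0, 1), 1)),
                             with_h = FALSE)
  co <- tr$xyz[1, , ]
  err_cyl <- axis_angle_deg(fit_cylinder_axis(co)$axis, c(0, 0, 1))
  err_line <- axis_angle_deg(fit_line_axis(co)$axis, c(0, 0, 1))
  expect_lt(err_cyl, err_line)
  expect_lt(err_cyl, 0.5)

  # cylinder objective never exceeds the line axis evaluated under the
  # cylinder criterion
  eval_cyl_criterion <- function(coords, axis) {
    ctr <- colMeans(coords)
    X <- sweep(coords, 2, ctr)
    d <- sqrt(rowSums((X - (X %*% axis) %*% t(axis))^2))
    sum((d - mean(d))^2)
  }
  for (n in c(6, 8, 12)) {
    tr <- gen_helix_trajectory(helix_geometry(n),
                               orientation_series(matrix(c(0, 0, 1), 1)),
                               with_h = FALSE)
    co <- tr$xyz[1, , ]
    expect_lte(fit_cylinder_axis(co)$objective,
               eval_cyl_criterion(co, fit_line_axis(co)$axis) + 1e-12)
  }
})

test_that("cylinder fit agrees with an exhaustive axis grid search", {
  set.seed(17)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  tr <- gen_helix_trajectory(helix_geometry(7),
                             orientation_series(matrix(c(0, 0, 1), 1)),
                             with_h = FALSE)
  co <- tr$xyz[1, , ] %*% t(R)
  prod_axis <- fit_cylinder_axis(co)$axis
  grid_axis <- oracle_cylinder_axis(co)
  expect_lt(axis_angle_deg(prod_axis, grid_axis), 0.5)
})

test_that("per-frame segment orientation series behave as constructed", {
  # static structure: constant axis, S_total = 1
  tr <- gen_helix_trajectory(helix_geometry(10),
                             orientation_series(matrix(rep(c(0, 0, 1), 5),
                                                       ncol = 3, byrow = TRUE)))
  seg <- list(name = "H", sub_segment = "x", first = 1, last = 10,
              topo_class = "helix_extracellular")
  ser <- segment_orientation_series(tr, seg)
  expect_equal(as.numeric(order_parameter_total(ser)), 1, tolerance = 1e-9)

  # driven: recovered within 1 degree per frame
  drv <- gen_cone_orientations(cone_spec(30, 10, 1, 200, seed = 23))
  trj <- gen_helix_trajectory(helix_geometry(12), drv, first_resid = 38)
  seg2 <- list(name = "H1", sub_segment = "ec", first = 38, last = 49,
               topo_class = "helix_extracellular")
  ser2 <- segment_orientation_series(trj, seg2)
  ang <- acos(pmin(1, rowSums(ser2$vectors * drv$vectors))) * 180 / pi
  expect_lt(max(ang), 1)

  # stride bookkeeping
  drv3 <- gen_cone_orientations(cone_spec(20, 10, 1, 1000, seed = 2))
  trj3 <- gen_helix_trajectory(helix_geometry(8), drv3)
  ser3 <- segment_orientation_series(
    trj3, list(name = "H", sub_segment = "x", first = 1, last = 8,
               topo_class = "helix_intracellular"), stride = 10)
  expect_equal(length(ser3), 100)
  expect_equal(ser3$dt, 10)

  expect_error(
    segment_orientation_series(
      trj, list(name = "H", sub_segment = "x", first = 38, last = 60,
                topo_class = "helix_extracellular")),
    "missing")
})
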