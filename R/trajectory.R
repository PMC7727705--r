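#' Coordinate trajectory container
#'
#' Minimal in-memory trajectory: a frames x atoms x 3 coordinate array
#' (Angstrom) plus an atom table (`resid`, `name`) and the frame spacing in
#' ns.  Built by the synthetic generators and by [load_trajectory()].
#'
#' @param xyz numeric array with dimensions (frames, atoms, 3).
#' @param atoms data.frame with columns `resid` and `name` ("CA", "HA", ...).
#' @param dt frame spacing in ns.
#' @return a `ca_trajectory` object.
#' @export
ca_trajectory <- function(xyz, atoms, dt = 1) {
  if (length(dim(xyz)) != 3 || dim(xyz)[3] != 3)
    stop("'xyz' must be a (frames x atoms x 3) array")
  if (nrow(atoms) != dim(xyz)[2])
    stop("'atoms' must describe each atom of 'xyz'")
  if (!all(c("resid", "name") %in% names(atoms)))
    stop("'atoms' needs columns resid and name")
  stopifnot_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  structure(list(xyz = xyz, atoms = atoms, dt = dt), class = "ca_trajectory")
}

#' @export
print.ca_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames, %d atoms (%d residues), dt = %g ns\n",
              dim(x$xyz)[1], dim(x$xyz)[2], length(unique(x$atoms$resid)), x$dt))
  invisible(x)
}

#' Ideal alpha-helix geometry
#'
#' @param n_residues number of residues (>= 4).
#' @param rise_per_residue rise along the helix axis, Angstrom (default 1.5).
#' @param twist_per_residue rotation per residue, degrees (default 100).
#' @param radius C-alpha radius from the helix axis, Angstrom (default 2.3).
#' @return a `helix_geometry` object.
#' @export
helix_geometry <- function(n_residues, rise_per_residue = 1.5,
                           twist_per_residue = 100, radius = 2.3) {
  stopifnot_scalar(n_residues, "n_residues", lower = 4)
  stopifnot_scalar(radius, "radius", lower = 0)
  stopifnot_scalar(rise_per_residue, "rise_per_residue", lower = 0,
                   strict_lower = TRUE)
  structure(list(n_residues = as.integer(n_residues),
                 rise_per_residue = rise_per_residue,
                 twist_per_residue = twist_per_residue, radius = radius),
            class = "helix_geometry")
}

# C-alpha (and radial pseudo-H) coordinates of the ideal helix in its own
# frame, axis along +z, centroid at the origin
.helix_coords <- function(geom, with_h = TRUE, ha_length = 1.09) {
  i <- seq_len(geom$n_residues) - 1
  phi <- deg2rad(i * geom$twist_per_residue)
  z <- i * geom$rise_per_residue
  z <- z - mean(z)
  ca <- cbind(geom$radius * cos(phi), geom$radius * sin(phi), z)
  if (!with_h) return(list(ca = ca, ha = NULL))
  ha <- ca + ha_length * cbind(cos(phi), sin(phi), 0)
  list(ca = ca, ha = ha)
}

#' Generate an ideal-helix trajectory driven by an axis series
#'
#' Builds, for every frame of `axis_series`, an ideal alpha-helix whose
#' cylinder axis equals that frame's axis vector (the helix is rotated
#' rigidly from +z onto the axis; the centroid stays at the origin).  Each
#' residue also carries a pseudo H atom placed radially 1.09 Angstrom from
#' its C-alpha, so the C-H bond vectors move rigidly with the helix body.
#' This fixture exercises the axis-fitting and order-parameter machinery with
#' exactly known ground truth.
#'
#' @param geom a [helix_geometry()].
#' @param axis_series an [orientation_series()] of cylinder-axis directions.
#' @param first_resid residue number of the first residue.
#' @param with_h also emit the pseudo H atoms (default TRUE).
#' @return a [ca_trajectory()].
#' @export
gen_helix_trajectory <- function(geom, axis_series, first_resid = 1L,
                                 with_h = TRUE) {
  stopifnot(inherits(geom, "helix_geometry"),
            inherits(axis_series, "orientation_series"))
  base <- .helix_coords(geom, with_h = with_h)
  n_res <- geom$n_residues
  n_frames <- nrow(axis_series$vectors)
  atoms <- data.frame(resid = first_resid - 1 + seq_len(n_res), name = "CA")
  coords0 <- base$ca
  if (with_h) {
    atoms <- rbind(atoms,
                   data.frame(resid = first_resid - 1 + seq_len(n_res), name = "HA"))
    coords0 <- rbind(base$ca, base$ha)
  }
  xyz <- array(0, c(n_frames, nrow(coords0), 3))
  for (f in seq_len(n_frames)) {
    R <- rotation_from_z(axis_series$vectors[f, ])
    xyz[f, , ] <- coords0 %*% t(R)
  }
  ca_trajectory(xyz, atoms, dt = axis_series$dt)
}

#' Write / load a trajectory as a multi-model PDB file
#'
#' `write_trajectory_pdb()` writes one MODEL block per frame (CA/HA atoms,
#' residues named ALA, occupancy 1); `load_trajectory()` reads a PDB topology
#' (multi-model files become multi-frame trajectories) through
#' [bio3d::read.pdb()], optionally filtered by residue numbers and atom
#' names.
#'
#' @param traj a [ca_trajectory()].
#' @param path PDB file path.
#' @param topology PDB file path.
#' @param resid optional residue numbers to keep.
#' @param atom_names optional atom names to keep (e.g. `"CA"`).
#' @param dt frame spacing in ns to stamp on the loaded trajectory.
#' @return `load_trajectory()` returns a [ca_trajectory()].
#' @export
write_trajectory_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "ca_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  nf <- dim(traj$xyz)[1]
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    ord <- order(traj$atoms$resid, traj$atoms$name)
    for (k in seq_along(ord)) {
      a <- ord[k]
      writeLines(sprintf(
        "ATOM  %5d %-4s%3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
        k, paste0(" ", traj$atoms$name[a]), "ALA", traj$atoms$resid[a],
        traj$xyz[f, a, 1], traj$xyz[f, a, 2], traj$xyz[f, a, 3], 1, 0), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @rdname write_trajectory_pdb
#' @export
load_trajectory <- function(topology, resid = NULL, atom_names = NULL, dt = 1) {
  if (!file.exists(topology)) stop("topology file not found: ", topology)
  pdb <- bio3d::read.pdb(topology, multi = TRUE)
  atoms <- data.frame(resid = pdb$atom$resno, name = trimws(pdb$atom$elety))
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(resid)) keep <- keep & atoms$resid %in% resid
  if (!is.null(atom_names)) keep <- keep & atoms$name %in% atom_names
  if (!any(keep)) stop("selection matches zero atoms")
  xyz_mat <- pdb$xyz
  if (is.null(dim(xyz_mat))) xyz_mat <- matrix(xyz_mat, nrow = 1)
  nf <- nrow(xyz_mat)
  na <- nrow(atoms)
  xyz <- array(0, c(nf, sum(keep), 3))
  sel <- which(keep)
  for (f in seq_len(nf)) {
    m <- matrix(xyz_mat[f, ], ncol = 3, byrow = TRUE)
    xyz[f, , ] <- m[sel, , drop = FALSE]
  }
  ca_trajectory(xyz, atoms[keep, , drop = FALSE], dt = dt)
}

#' Remove global rigid-body motion from a trajectory
#'
#' Superposes every frame onto a reference frame by least-squares rigid-body
#' fitting of the C-alpha atoms (Kabsch superposition via
#' [bio3d::fit.xyz()]); the resulting trajectory contains only internal
#' motion, so order parameters computed from it are internal order
#' parameters.  Re-aligning an aligned trajectory leaves it unchanged.
#'
#' @param traj a [ca_trajectory()].
#' @param reference_frame frame index used as the reference (default 1).
#' @return a [ca_trajectory()] with superposed coordinates.
#' @export
remove_global_motion <- function(traj, reference_frame = 1L) {
  stopifnot(inherits(traj, "ca_trajectory"))
  nf <- dim(traj$xyz)[1]
  na <- dim(traj$xyz)[2]
  if (reference_frame < 1 || reference_frame > nf)
    stop("'reference_frame' out of range")
  ca_rows <- which(traj$atoms$name == "CA")
  if (length(ca_rows) < 3) stop("need at least 3 CA atoms for superposition")
  # bio3d xyz convention: frames x (3 * atoms), columns x1 y1 z1 x2 ...
  xyz_mat <- matrix(aperm(traj$xyz, c(1, 3, 2)), nrow = nf)
  xyz_mat <- matrix(0, nf, 3 * na)
  for (f in seq_len(nf)) xyz_mat[f, ] <- as.numeric(t(traj$xyz[f, , ]))
  inds <- as.integer(rbind(3 * (ca_rows - 1) + 1, 3 * (ca_rows - 1) + 2,
                           3 * (ca_rows - 1) + 3))
  fitted <- bio3d::fit.xyz(fixed = xyz_mat[reference_frame, ],
                           mobile = xyz_mat,
                           fixed.inds = inds, mobile.inds = inds)
  out <- array(0, dim(traj$xyz))
  for (f in seq_len(nf)) out[f, , ] <- matrix(fitted[f, ], ncol = 3, byrow = TRUE)
  ca_trajectory(out, traj$atoms, dt = traj$dt)
}

# unit C-alpha/H bond vectors for one residue across frames; H atoms are used
# when present, otherwise the bond is rebuilt from the local backbone
# geometry (radial bisector direction from the flanking C-alpha positions)
.residue_bond_vectors <- function(traj, res, rebuild_h) {
  rows_ha <- which(traj$atoms$resid == res & grepl("^HA", traj$atoms$name))
  row_ca <- which(traj$atoms$resid == res & traj$atoms$name == "CA")
  nf <- dim(traj$xyz)[1]
  if (length(rows_ha) > 0 && length(row_ca) == 1) {
    lapply(rows_ha, function(rh) {
      U <- traj$xyz[, rh, , drop = TRUE] - traj$xyz[, row_ca, , drop = TRUE]
      U <- matrix(U, nrow = nf)
      U / sqrt(rowSums(U^2))
    })
  } else if (rebuild_h && length(row_ca) == 1) {
    ca_res <- sort(unique(traj$atoms$resid[traj$atoms$name == "CA"]))
    prev <- which(traj$atoms$resid == res - 1 & traj$atoms$name == "CA")
    nxt <- which(traj$atoms$resid == res + 1 & traj$atoms$name == "CA")
    if (length(prev) != 1 || length(nxt) != 1) return(NULL)
    mid <- (traj$xyz[, prev, , drop = TRUE] + traj$xyz[, nxt, , drop = TRUE]) / 2
    U <- matrix(traj$xyz[, row_ca, , drop = TRUE] - mid, nrow = nf)
    list(U / sqrt(rowSums(U^2)))
  } else if (length(row_ca) == 1) {
    stop(sprintf("residue %d has no HA atom and H rebuilding is disabled", res))
  } else NULL
}

# order parameter from the time-averaged second-rank tensor of unit vectors:
# with Q_t = (3 u u' - I)/2, S = sqrt(2/3 * sum_ij <Q>_ij^2)
.tensor_order <- function(U) {
  Q <- (3 * crossprod(U) / nrow(U) - diag(3)) / 2
  sqrt(2 / 3 * sum(Q^2))
}

#' Per-residue backbone C-H order parameters from a trajectory
#'
#' For each residue, the C-alpha/H-alpha unit bond vector is tracked over the
#' (strided) frames and its order parameter computed.  The default
#' `"tensor"` estimator is the magnitude of the time-averaged second-rank
#' tensor, `S = sqrt(2/3 sum <Q>_ij^2)`; the `"dipshift"` estimator instead
#' forward-simulates the MAS dipolar dephasing of the averaged coupling
#' tensor and fits an axially symmetric coupling to it, mirroring how
#' experimental order parameters are extracted.  The two agree exactly for
#' uniaxial motional averaging and can differ when the residual tensor is
#' strongly biaxial; no silent preference is made — run both and compare.
#' Residues with multiple HA atoms (glycine) average S over the bonds.
#' Values marginally above 1 from numerical noise are clipped with a warning.
#'
#' @param traj a [ca_trajectory()].
#' @param selection residue numbers to analyze (default: all with a CA atom).
#' @param stride frame stride.
#' @param estimator `"tensor"` (default) or `"dipshift"`.
#' @param variant label recorded on the profile: `"total"` for raw
#'   trajectories, `"internal"` after [remove_global_motion()].
#' @param rebuild_h rebuild missing H alpha atoms from the flanking C-alpha
#'   geometry (chain-end residues are skipped).
#' @param mas_kHz,limits DipShift settings for the `"dipshift"` estimator.
#' @return data.frame (`resid`, `S`) of class `residue_order_profile` with
#'   attributes `variant`, `estimator` and `n_replicas` (= 1).
#' @export
residue_CH_order <- function(traj, selection = NULL, stride = 1L,
                             estimator = c("tensor", "dipshift"),
                             variant = "total", rebuild_h = TRUE,
                             mas_kHz = 5, limits = rigid_limits()) {
  stopifnot(inherits(traj, "ca_trajectory"))
  estimator <- match.arg(estimator)
  frames <- seq(1, dim(traj$xyz)[1], by = stride)
  sub <- traj
  sub$xyz <- traj$xyz[frames, , , drop = FALSE]
  residues <- selection %||% sort(unique(traj$atoms$resid[traj$atoms$name == "CA"]))
  out <- lapply(residues, function(res) {
    bonds <- .residue_bond_vectors(sub, res, rebuild_h)
    if (is.null(bonds)) return(NULL)
    S <- vapply(bonds, function(U) {
      if (estimator == "tensor") {
        .tensor_order(U)
      } else {
        # forward-simulate the dephasing of the motion-averaged coupling
        # tensor and fit it exactly as an experimental curve would be; the
        # decoupling scale factor cancels between simulation and fit, so the
        # tensor is taken at the unscaled rigid-limit coupling
        Q <- (3 * crossprod(U) / nrow(U) - diag(3)) / 2
        rigid <- limits[["CH"]]
        cur <- dephasing_from_tensor(rigid * Q, mas_kHz)
        fit_dipolar_coupling(cur, limits, "CH")$S
      }
    }, numeric(1))
    data.frame(resid = res, S = mean(S))
  })
  prof <- do.call(rbind, out)
  if (is.null(prof) || nrow(prof) == 0) stop("no analyzable residues found")
  if (any(prof$S > 1)) {
    if (any(prof$S > 1 + 1e-6))
      warning("order parameters above 1 clipped (max ",
              format(max(prof$S)), ")")
    prof$S <- pmin(prof$S, 1)
  }
  structure(prof, variant = variant, estimator = estimator, n_replicas = 1L,
            class = c("residue_order_profile", "data.frame"))
}

#' Average residue order profiles over replicas
#'
#' Arithmetic per-residue mean over simulation replicas; the replica count is
#' carried on the result.  All profiles must cover the same residues.
#'
#' @param profiles list of profiles from [residue_CH_order()].
#' @return a `residue_order_profile` data.frame.
#' @export
average_profiles <- function(profiles) {
  if (!length(profiles)) stop("no profiles supplied")
  ref <- profiles[[1]]$resid
  for (p in profiles)
    if (!identical(p$resid, ref)) stop("profiles cover different residue sets")
  S <- rowMeans(matrix(vapply(profiles, function(p) p$S, numeric(length(ref))),
                       nrow = length(ref)))
  structure(data.frame(resid = ref, S = S),
            variant = attr(profiles[[1]], "variant"),
            estimator = attr(profiles[[1]], "estimator"),
            n_replicas = sum(vapply(profiles, function(p)
              attr(p, "n_replicas") %||% 1L, integer(1))),
            class = c("residue_order_profile", "data.frame"))
}
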