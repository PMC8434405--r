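# Structural fluctuation metrics: RMSF, rigid-body superposition, RMSD,
# and solvent-accessible surface area.

#' Root mean square fluctuation per atom
#'
#' For each selected atom, the square root of the time-averaged squared
#' deviation from its time-mean position,
#' `RMSF_i = sqrt( (1/T) * sum_t |x_i(t) - xbar_i|^2 )`. With
#' `align_first`, every frame is first least-squares superposed onto the
#' first frame over the selection, so the profile measures internal motion
#' rather than global drift.
#'
#' @param traj `md_trajectory` with at least 2 frames.
#' @param selection atom selection (see [select_atoms()]); default all.
#' @param align_first superpose each frame onto frame 1 before averaging.
#' @param by_residue aggregate to residues (unweighted mean over each
#'   residue's selected atoms).
#' @return data.frame with columns `atom_id`, `rmsf` (nm), or
#'   `residue_id`, `rmsf` when `by_residue`.
#' @export
rmsf <- function(traj, selection = "all", align_first = FALSE, by_residue = FALSE) {
  sel <- select_atoms(traj, selection)
  if (!length(sel)) hs_stop("empty selection", "hs_parameter_error")
  nf <- n_frames(traj)
  if (nf < 2) hs_stop("RMSF needs at least 2 frames", "hs_parameter_error")
  x <- traj$coords[sel, , , drop = FALSE]
  if (align_first) {
    ref <- matrix(x[, , 1], ncol = 3)
    for (t in 2:nf) {
      fit <- superpose(matrix(x[, , t], ncol = 3), ref)
      x[, , t] <- fit$transformed
    }
  }
  xbar <- apply(x, c(1, 2), mean)
  dev2 <- sweep(x, c(1, 2), xbar)^2
  prof <- sqrt(apply(dev2, 1, sum) / nf)
  out <- data.frame(atom_id = sel, rmsf = prof)
  if (by_residue) {
    res <- traj$topology$atoms$residue_id[sel]
    agg <- tapply(out$rmsf, res, mean)
    out <- data.frame(residue_id = as.integer(names(agg)), rmsf = as.numeric(agg))
  }
  rownames(out) <- NULL
  out
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fit of a mobile coordinate set onto a reference: the
#' proper rotation (determinant +1) and translation minimizing the RMSD,
#' obtained from the SVD of the centered cross-covariance matrix with the
#' usual sign correction to exclude reflections.
#'
#' @param mobile,reference n x 3 matrices (n >= 3, not collinear).
#' @return List: `rotation` (3x3, applied on the right to centered row
#'   vectors), `translation` (length 3), `rmsd_after` (nm), and
#'   `transformed` (the fitted mobile coordinates). The fit is
#'   `transformed = (mobile - cm_mobile) %*% rotation + cm_reference`.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3) {
    hs_stop("mobile and reference must be equal-sized n x 3 matrices", "hs_parameter_error")
  }
  n <- nrow(mobile)
  if (n < 3) hs_stop("superposition needs >= 3 points", "hs_degeneracy_error")
  cm_m <- colMeans(mobile); cm_r <- colMeans(reference)
  a <- sweep(mobile, 2, cm_m); b <- sweep(reference, 2, cm_r)
  # collinearity check: rank of either centered set < 2
  if (svd(a)$d[2] < 1e-10 * max(svd(a)$d[1], 1e-30) ||
      svd(b)$d[2] < 1e-10 * max(svd(b)$d[1], 1e-30)) {
    hs_stop("degenerate (collinear) point set", "hs_degeneracy_error")
  }
  h <- crossprod(a, b)           # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)   # right-multiplication matrix
  fitted <- a %*% rot
  rmsd_after <- sqrt(mean(rowSums((fitted - b)^2)))
  transformed <- sweep(fitted, 2, cm_r, `+`)
  list(rotation = rot, translation = as.numeric(cm_r - drop(cm_m %*% rot)),
       rmsd_after = rmsd_after, transformed = transformed)
}

#' Time-resolved RMSD against a reference frame
#'
#' Per frame, `sqrt(mean_i |v_i - w_i|^2)` over the selection against the
#' positions in a reference frame, after optional rigid-body superposition
#' (the default, so the series reflects internal mobility).
#'
#' @param traj `md_trajectory`.
#' @param reference_frame frame index used as reference (default 1).
#' @param selection atom selection; conventionally the alpha carbons.
#' @param superpose_flag least-squares superpose each frame first.
#' @return data.frame with columns `time` (ps), `rmsd` (nm); attribute
#'   `"superposed"`.
#' @export
rmsd_series <- function(traj, reference_frame = 1, selection = "all",
                        superpose_flag = TRUE) {
  sel <- select_atoms(traj, selection)
  if (!length(sel)) hs_stop("empty selection", "hs_parameter_error")
  nf <- n_frames(traj)
  if (!is_count(reference_frame) || reference_frame < 1 || reference_frame > nf) {
    hs_stop("reference frame %s does not exist", "hs_parameter_error",
            format(reference_frame))
  }
  ref <- matrix(traj$coords[sel, , reference_frame], ncol = 3)
  vals <- vapply(seq_len(nf), function(t) {
    cur <- matrix(traj$coords[sel, , t], ncol = 3)
    if (superpose_flag) {
      superpose(cur, ref)$rmsd_after
    } else {
      sqrt(mean(rowSums((cur - ref)^2)))
    }
  }, numeric(1))
  out <- data.frame(time = traj$time, rmsd = vals)
  attr(out, "superposed") <- superpose_flag
  out
}

# Bondi van der Waals radii (nm); conventional water-probe SASA set.
bondi_radii <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180,
                 P = 0.180, F = 0.147, CL = 0.175, BR = 0.185, I = 0.198)

# Quasi-uniform points on the unit sphere (golden-spiral lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (sphere-point burial counting)
#'
#' Shrake-Rupley-style numerical SASA: for each selected atom, quasi-
#' uniform test points are placed on the sphere of radius `r_vdw + probe`;
#' a point is buried if it falls inside any neighbour's extended sphere.
#' The per-atom area is the exposed fraction times `4*pi*(r+probe)^2`.
#' Periodic images are ignored (the molecule is assumed whole).
#'
#' @param traj `md_trajectory` (or a single-frame one).
#' @param frame frame index to analyse.
#' @param selection atom selection.
#' @param radii named per-element van der Waals radii (nm); defaults to
#'   Bondi values. An error names any element with no radius.
#' @param probe probe radius (nm); 0.14 nm is the conventional water probe.
#' @param n_sphere_points number of test points per atom (>= 32; default
#'   960, giving about 1% accuracy on sphere-cap geometry).
#' @return List: `total` (nm^2) and `per_atom` (data.frame atom_id, area).
#' @export
sasa <- function(traj, frame = 1, selection = "heavy", radii = NULL,
                 probe = 0.14, n_sphere_points = 960) {
  if (!is_count(n_sphere_points) || n_sphere_points < 32) {
    hs_stop("n_sphere_points must be >= 32", "hs_parameter_error")
  }
  check_scalar(probe, "probe", 0)
  sel <- select_atoms(traj, selection)
  if (!length(sel)) hs_stop("empty selection", "hs_parameter_error")
  radii <- radii %||% bondi_radii
  el <- toupper(traj$topology$atoms$element[sel])
  r <- unname(radii[el])
  if (anyNA(r)) {
    hs_stop("no van der Waals radius for element(s): %s", "hs_parameter_error",
            paste(unique(el[is.na(r)]), collapse = ", "))
  }
  xyz <- matrix(traj$coords[sel, , frame], ncol = 3)
  ext <- r + probe
  pts <- sphere_points(n_sphere_points)
  n <- length(sel)
  area <- numeric(n)
  for (i in seq_len(n)) {
    test <- sweep(pts * ext[i], 2, xyz[i, ], `+`)
    d0 <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(d0 < ext[i] + ext & seq_len(n) != i)
    exposed <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      dj <- sweep(test, 2, xyz[j, ])
      exposed <- exposed & (rowSums(dj * dj) > ext[j]^2)
    }
    area[i] <- mean(exposed) * 4 * pi * ext[i]^2
  }
  list(total = sum(area), per_atom = data.frame(atom_id = sel, area = area))
}
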