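# Periodic-boundary geometry (orthorhombic boxes only).

# Vectorized minimum-image remap of a displacement matrix (n x 3) so each
# component lies in [-L/2, L/2).
minimum_image <- function(disp, box) {
  if (is.null(box)) return(disp)
  if (is.null(dim(disp))) disp <- matrix(disp, ncol = 3)
  for (k in 1:3) disp[, k] <- disp[, k] - box[k] * floor(disp[, k] / box[k] + 0.5)
  disp
}

#' Minimum-image displacement between two positions
#'
#' Returns `b - a` shifted by integer lattice vectors so that each component
#' lies in `[-L/2, L/2)`, i.e. the displacement to the nearest periodic
#' image of `b`. Every distance-based estimator in the package measures
#' distances this way.
#'
#' @param a,b positions (length-3 numeric, nm) or n x 3 matrices.
#' @param box orthorhombic box edge lengths (length-3 numeric, nm) or a
#'   diagonal 3x3 matrix; non-orthorhombic boxes are rejected.
#' @return Displacement vector(s) with the same shape as the inputs (nm).
#' @examples
#' minimum_image_displacement(c(0.1, 0, 0), c(6.9, 0, 0), c(7, 7, 7))
#' @export
minimum_image_displacement <- function(a, b, box) {
  box <- check_box(box)
  vec <- is.null(dim(a)) && is.null(dim(b))
  a <- if (is.null(dim(a))) matrix(a, ncol = 3, byrow = TRUE) else a
  b <- if (is.null(dim(b))) matrix(b, ncol = 3, byrow = TRUE) else b
  out <- minimum_image(b - a, box)
  if (vec && nrow(out) == 1L) drop(out) else out
}

# Minimum-image distances from one point to a matrix of points.
min_image_dist <- function(p, pts, box) {
  d <- sweep(pts, 2, p)
  if (!is.null(box)) d <- minimum_image(d, box)
  sqrt(rowSums(d * d))
}

#' Wrap coordinates into the primary box
#'
#' Maps every coordinate component into `[0, L)`. Inverse companion of
#' [unwrap_coordinates()] for trajectories whose per-frame jumps stay below
#' half the box edge.
#'
#' @param traj an `md_trajectory` with a periodic box.
#' @return The trajectory with wrapped coordinates.
#' @export
wrap_coordinates <- function(traj) {
  if (is.null(traj$box)) hs_stop("trajectory has no box to wrap into", "hs_box_error")
  for (k in 1:3) {
    x <- traj$coords[, k, , drop = FALSE]
    traj$coords[, k, ] <- x - traj$box[k] * floor(x / traj$box[k])
  }
  traj
}

#' Remove periodic wrapping from a trajectory
#'
#' Reconstructs continuous particle paths from box-wrapped coordinates:
#' each frame-to-frame displacement of the output equals the minimum-image
#' displacement of the input, with the first frame left unchanged. This is
#' the prerequisite for mean-square-displacement analysis on periodic data.
#' Reliable only while true per-frame displacements stay below half the box
#' edge; atoms whose apparent jumps reach that bound are reported in a
#' warning.
#'
#' @param traj an `md_trajectory` with a periodic box.
#' @param selection atoms to unwrap (default all); others are untouched.
#' @return The trajectory with unwrapped coordinates for the selection.
#' @export
unwrap_coordinates <- function(traj, selection = NULL) {
  if (is.null(traj$box)) return(traj)
  sel <- if (is.null(selection)) seq_len(n_atoms(traj)) else select_atoms(traj, selection)
  nf <- n_frames(traj)
  if (nf < 2) return(traj)
  flagged <- integer(0)
  near_half <- 0.5 * traj$box * (1 - 1e-9)
  input <- traj$coords[sel, , , drop = FALSE]  # wrapped originals
  out_prev <- matrix(input[, , 1], ncol = 3)
  for (t in 2:nf) {
    step <- minimum_image(matrix(input[, , t], ncol = 3) -
                            matrix(input[, , t - 1], ncol = 3), traj$box)
    big <- which(abs(step[, 1]) >= near_half[1] | abs(step[, 2]) >= near_half[2] |
                   abs(step[, 3]) >= near_half[3])
    if (length(big)) flagged <- union(flagged, sel[big])
    out_prev <- out_prev + step
    traj$coords[sel, , t] <- out_prev
  }
  if (length(flagged)) {
    hs_warn("unwrapping unreliable: %d atom(s) jumped >= half the box edge (atoms %s)",
            "hs_unwrap_warning", length(flagged),
            paste(utils::head(flagged, 10), collapse = ", "))
    attr(traj, "unwrap_flagged") <- flagged
  }
  traj
}
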