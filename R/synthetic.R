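# Synthetic trajectory generators with known ground-truth dynamics.
# These play the role of reference MD output: every estimator in the
# package can be checked against the analytic behaviour of the generator
# (Einstein relation, l=1 rotational diffusion decay, two-state Markov
# occupancy correlations), at desk scale and deterministically under seed.

#' Brownian particles in a periodic box
#'
#' Generates `n_particles` independent random walks whose per-step
#' displacements are i.i.d. Gaussian with variance `2 * D * dt` per
#' Cartesian component, so the unwrapped mean square displacement obeys the
#' 3-D Einstein relation MSD = 6 D t. Coordinates are wrapped into the box;
#' the unwrapped ground truth is kept in the `"unwrapped"` attribute.
#'
#' @param n_particles number of particles.
#' @param D translational diffusion coefficient (nm^2/ps), >= 0.
#' @param box_edge cubic box edge (nm).
#' @param dt frame spacing (ps).
#' @param n_frames number of frames (>= 2).
#' @param seed RNG seed (fixed seed gives identical output).
#' @return `md_trajectory` (atoms named OW, one per particle) with attribute
#'   `"unwrapped"` (the unwrapped coordinate array) and `"ground_truth"`.
#' @export
gen_brownian <- function(n_particles, D, box_edge, dt, n_frames, seed = 1) {
  if (!is.numeric(D) || length(D) != 1 || is.na(D) || D < 0) {
    hs_stop("diffusion coefficient D must be >= 0", "hs_parameter_error")
  }
  check_scalar(box_edge, "box_edge", 0, strict = TRUE)
  check_scalar(dt, "dt", 0, strict = TRUE)
  if (!is_count(n_frames) || n_frames < 2) hs_stop("n_frames must be >= 2", "hs_parameter_error")
  if (!is_count(n_particles) || n_particles < 1) hs_stop("n_particles must be >= 1", "hs_parameter_error")
  box <- rep(box_edge, 3)
  sd_step <- sqrt(2 * D * dt)
  coords <- with_seed(seed, {
    x0 <- matrix(stats::runif(n_particles * 3, 0, box_edge), ncol = 3)
    steps <- array(stats::rnorm(n_particles * 3 * (n_frames - 1), sd = sd_step),
                   c(n_particles, 3, n_frames - 1))
    out <- array(0, c(n_particles, 3, n_frames))
    out[, , 1] <- x0
    for (t in 2:n_frames) out[, , t] <- out[, , t - 1] + steps[, , t - 1]
    out
  })
  top <- topology(data.frame(atom_id = seq_len(n_particles), atom_name = "OW",
                             element = "O", residue_id = seq_len(n_particles),
                             residue_name = "SOL", stringsAsFactors = FALSE))
  traj <- trajectory(top, coords, box, (seq_len(n_frames) - 1) * dt)
  unwrapped <- traj$coords
  traj <- wrap_coordinates(traj)
  attr(traj, "unwrapped") <- unwrapped
  attr(traj, "ground_truth") <- list(D_trans = D, seed = seed)
  traj
}

# Vectorized Rodrigues rotation of row-vectors v (n x 3) by rotation
# vectors w (n x 3): angle |w| about axis w/|w|.
rotate_rows <- function(v, w) {
  theta <- sqrt(rowSums(w * w))
  small <- theta < 1e-12
  k <- w / ifelse(theta > 0, theta, 1)
  ct <- cos(theta); st <- sin(theta)
  kxv <- cbind(k[, 2] * v[, 3] - k[, 3] * v[, 2],
               k[, 3] * v[, 1] - k[, 1] * v[, 3],
               k[, 1] * v[, 2] - k[, 2] * v[, 1])
  kdv <- rowSums(k * v)
  out <- v * ct + kxv * st + k * (kdv * (1 - ct))
  out[small, ] <- v[small, , drop = FALSE]
  out
}

# SPC/E rigid water geometry: O-H 0.1 nm, H-O-H 109.47 deg; dipole along
# the bisector of the two O-H bonds.
spce_sites <- function() {
  half <- (109.47 / 2) * pi / 180
  rbind(O = c(0, 0, 0),
        H1 = 0.1 * c(sin(half), cos(half), 0),
        H2 = 0.1 * c(-sin(half), cos(half), 0))
}

#' Rigid water-like rotors under isotropic rotational diffusion
#'
#' Generates rigid 3-site (SPC/E geometry) molecules at fixed positions
#' whose orientations evolve by small random rotations: at each step the
#' molecule is rotated by a rotation vector with i.i.d. Gaussian components
#' of variance `2 * D_rot * dt` per axis, the small-step sampling of
#' isotropic rotational diffusion. Any body-fixed unit vector u then decays
#' as the rank-1 correlation `<u(0).u(t)> = exp(-2 * D_rot * t)`, so the
#' dipole reorientation time is `1 / (2 * D_rot)`.
#'
#' @param n_molecules number of molecules.
#' @param D_rot rotational diffusion coefficient (1/ps), >= 0. The step
#'   must satisfy `dt * D_rot <= 0.05` (small-rotation validity).
#' @param dt frame spacing (ps).
#' @param n_frames number of frames (>= 2).
#' @param seed RNG seed.
#' @param box_edge cubic box edge (nm); molecules are placed on a loose
#'   grid inside it.
#' @return `md_trajectory` of SOL waters with attribute `"ground_truth"`.
#' @export
gen_rotors <- function(n_molecules, D_rot, dt, n_frames, seed = 1, box_edge = NULL) {
  if (!is.numeric(D_rot) || length(D_rot) != 1 || is.na(D_rot) || D_rot < 0) {
    hs_stop("D_rot must be >= 0", "hs_parameter_error")
  }
  check_scalar(dt, "dt", 0, strict = TRUE)
  if (dt * D_rot > 0.05) {
    hs_stop("dt * D_rot = %.3g exceeds 0.05: reduce dt for valid small-step rotational diffusion",
            "hs_parameter_error", dt * D_rot)
  }
  if (!is_count(n_frames) || n_frames < 2) hs_stop("n_frames must be >= 2", "hs_parameter_error")
  sites <- spce_sites()
  n_side <- ceiling(n_molecules^(1 / 3))
  spacing <- 0.6
  box_edge <- box_edge %||% max(3, n_side * spacing + 1)
  idx <- seq_len(n_molecules) - 1L
  centers <- cbind(idx %% n_side, (idx %/% n_side) %% n_side,
                   idx %/% (n_side^2)) * spacing + 0.5
  sdw <- sqrt(2 * D_rot * dt)
  coords <- with_seed(seed, {
    # random initial orientations: rotate body frame by a uniform rotation
    # (rotation vector with uniform axis, uniform angle is not uniform on
    # SO(3), but initial orientation only needs to be non-degenerate)
    w0 <- matrix(stats::rnorm(n_molecules * 3), ncol = 3)
    w0 <- w0 / sqrt(rowSums(w0 * w0)) * stats::runif(n_molecules, 0, pi)
    body <- lapply(1:3, function(s) {
      v <- matrix(rep(sites[s, ], each = n_molecules), ncol = 3)
      rotate_rows(v, w0)
    })
    out <- array(0, c(3 * n_molecules, 3, n_frames))
    # atom order: O,H1,H2 per molecule (rows 3m-2, 3m-1, 3m)
    place <- function(body_now) {
      m <- matrix(0, 3 * n_molecules, 3)
      for (s in 1:3) m[seq(s, by = 3, length.out = n_molecules), ] <-
          centers + body_now[[s]]
      m
    }
    out[, , 1] <- place(body)
    if (n_frames >= 2) for (t in 2:n_frames) {
      w <- matrix(stats::rnorm(n_molecules * 3, sd = sdw), ncol = 3)
      body <- lapply(body, rotate_rows, w = w)
      out[, , t] <- place(body)
    }
    out
  })
  atoms_df <- data.frame(
    atom_id = seq_len(3 * n_molecules),
    atom_name = rep(c("OW", "HW1", "HW2"), n_molecules),
    element = rep(c("O", "H", "H"), n_molecules),
    residue_id = rep(seq_len(n_molecules), each = 3),
    residue_name = "SOL", stringsAsFactors = FALSE)
  bonds <- cbind(rep(seq(1, 3 * n_molecules, 3), each = 2),
                 c(rbind(seq(2, 3 * n_molecules, 3), seq(3, 3 * n_molecules, 3))))
  top <- topology(atoms_df, bonds)
  traj <- trajectory(top, coords, rep(box_edge, 3), (seq_len(n_frames) - 1) * dt)
  attr(traj, "ground_truth") <- list(D_rot = D_rot, seed = seed)
  traj
}

#' Two-state Markov indicator series
#'
#' Discrete-time sampling of independent on/off (1/0) continuous-time
#' Markov chains with first-order per-step transition probabilities
#' `P(0->1) = k_on * dt` and `P(1->0) = k_off * dt`. Stationary occupancy
#' is `p = k_on / (k_on + k_off)`; the indicator autocorrelation decays as
#' `p + (1 - p) * exp(-(k_on + k_off) * t)` and on-state dwell times are
#' exponential with mean `1 / k_off`. Used as the generative model for
#' hydrogen-bond population operators and hydration-shell occupancy.
#'
#' @param n_series number of independent series (rows).
#' @param k_on,k_off transition rates (1/ps), > 0 (except `k_off = 0`
#'   allowed for the absorbing on-state limit); requires
#'   `dt * (k_on + k_off) <= 0.1`.
#' @param dt sampling interval (ps).
#' @param n_frames frames per series.
#' @param seed RNG seed.
#' @param start `"stationary"` (initial state Bernoulli(p)) or `"on"`.
#' @return Integer matrix `n_series x n_frames` of 0/1 with attributes
#'   `"dt"` and `"ground_truth"`.
#' @export
gen_two_state_series <- function(n_series, k_on, k_off, dt, n_frames, seed = 1,
                                 start = c("stationary", "on")) {
  start <- match.arg(start)
  check_scalar(k_on, "k_on", 0); check_scalar(k_off, "k_off", 0)
  check_scalar(dt, "dt", 0, strict = TRUE)
  if (dt * (k_on + k_off) > 0.1) {
    hs_stop("dt * (k_on + k_off) = %.3g exceeds 0.1: reduce dt", "hs_parameter_error",
            dt * (k_on + k_off))
  }
  if (!is_count(n_series) || n_series < 1 || !is_count(n_frames) || n_frames < 1) {
    hs_stop("n_series and n_frames must be positive counts", "hs_parameter_error")
  }
  p_on <- k_on * dt; p_off <- k_off * dt
  p_stat <- if (k_on + k_off > 0) k_on / (k_on + k_off) else 0
  h <- with_seed(seed, {
    out <- matrix(0L, n_series, n_frames)
    state <- if (start == "on") rep(1L, n_series) else
      as.integer(stats::runif(n_series) < p_stat)
    out[, 1] <- state
    if (n_frames >= 2) for (t in 2:n_frames) {
      r <- stats::runif(n_series)
      state <- ifelse(state == 1L, as.integer(r >= p_off), as.integer(r < p_on))
      out[, t] <- state
    }
    out
  })
  attr(h, "dt") <- dt
  attr(h, "ground_truth") <- list(k_on = k_on, k_off = k_off, seed = seed,
                                  p_stationary = p_stat)
  h
}

#' Shell-occupancy system with geometry tied to a known indicator matrix
#'
#' Embeds [gen_two_state_series()] occupancy into coordinates: a single
#' fixed reference site sits at the box center; each water molecule is
#' placed with its oxygen uniformly inside radius `0.9 * cutoff` of the
#' site when its series reads 1, and uniformly in the box at distance
#' greater than `1.1 * cutoff` when it reads 0. The margin around the
#' cutoff makes geometric shell-membership recovery exact by construction,
#' so [shell_membership()] applied to the output must reproduce the
#' generating indicator matrix.
#'
#' @param n_waters number of water molecules (3-site, rigid).
#' @param k_on,k_off,dt,n_frames,seed as in [gen_two_state_series()].
#' @param cutoff shell radius (nm); must satisfy `cutoff < box_edge / 2`.
#' @param box_edge cubic box edge (nm).
#' @return `md_trajectory` (reference site atom 1, then waters) with
#'   attributes `"occupancy"` (the indicator matrix), `"water_oxygens"`,
#'   and `"ground_truth"`.
#' @export
gen_shell_system <- function(n_waters, k_on, k_off, cutoff, box_edge, dt,
                             n_frames, seed = 1) {
  check_scalar(cutoff, "cutoff", 0, strict = TRUE)
  check_scalar(box_edge, "box_edge", 0, strict = TRUE)
  if (cutoff >= box_edge / 2) {
    hs_stop("cutoff must be < box_edge / 2", "hs_parameter_error")
  }
  occ <- if (n_waters > 0) {
    gen_two_state_series(n_waters, k_on, k_off, dt, n_frames, seed = seed)
  } else {
    matrix(integer(0), 0, n_frames)
  }
  center <- rep(box_edge / 2, 3)
  sites <- spce_sites()
  nat <- 1L + 3L * n_waters
  coords <- with_seed(seed + 1, {
    out <- array(0, c(nat, 3, n_frames))
    for (t in seq_len(n_frames)) out[1, , t] <- center
    if (n_waters > 0) {
      for (t in seq_len(n_frames)) {
        # uniform directions
        u <- matrix(stats::rnorm(n_waters * 3), ncol = 3)
        u <- u / sqrt(rowSums(u * u))
        r_in <- (0.9 * cutoff) * stats::runif(n_waters)^(1 / 3)
        pos_in <- sweep(u * r_in, 2, center, `+`)
        # outside: rejection-sample uniform in box beyond 1.1*cutoff
        pos_out <- matrix(0, n_waters, 3)
        need <- rep(TRUE, n_waters)
        while (any(need)) {
          k <- sum(need)
          cand <- matrix(stats::runif(3 * k, 0, box_edge), ncol = 3)
          d <- min_image_dist(center, cand, rep(box_edge, 3))
          ok <- d > 1.1 * cutoff
          rows <- which(need)[ok]
          pos_out[rows, ] <- cand[ok, , drop = FALSE]
          need[rows] <- FALSE
        }
        o_pos <- ifelse(matrix(occ[, t] == 1L, n_waters, 3), pos_in, pos_out)
        for (s in 1:3) {
          out[1L + seq(s, by = 3, length.out = n_waters), , t] <-
            o_pos + matrix(rep(sites[s, ], each = n_waters), ncol = 3)
        }
      }
    }
    out
  })
  atoms_df <- data.frame(
    atom_id = seq_len(nat),
    atom_name = c("NRF", if (n_waters > 0) rep(c("OW", "HW1", "HW2"), n_waters)),
    element = c("N", if (n_waters > 0) rep(c("O", "H", "H"), n_waters)),
    residue_id = c(1L, if (n_waters > 0) rep(1L + seq_len(n_waters), each = 3)),
    residue_name = c("REF", if (n_waters > 0) rep("SOL", 3 * n_waters)),
    stringsAsFactors = FALSE)
  bonds <- if (n_waters > 0) {
    o_idx <- 1L + seq(1, by = 3, length.out = n_waters)
    cbind(rep(o_idx, each = 2), c(rbind(o_idx + 1L, o_idx + 2L)))
  } else NULL
  top <- topology(atoms_df, bonds)
  traj <- trajectory(top, coords, rep(box_edge, 3), (seq_len(n_frames) - 1) * dt)
  attr(traj, "occupancy") <- occ
  attr(traj, "water_oxygens") <- if (n_waters > 0) 1L + seq(1, by = 3, length.out = n_waters) else integer(0)
  attr(traj, "ground_truth") <- list(k_on = k_on, k_off = k_off, cutoff = cutoff,
                                     seed = seed)
  traj
}

#' Piecewise-linear observable with optional noise
#'
#' Fixture for breakpoint detection: a continuous piecewise-linear function
#' with one slope change at `break_x`, plus i.i.d. Gaussian noise.
#'
#' @param x ordered grid (e.g. temperatures in K).
#' @param break_x breakpoint location, inside `range(x)`.
#' @param slope1,slope2 slopes before/after the break.
#' @param intercept value at `x[1]`.
#' @param noise_sd Gaussian noise standard deviation (0 for none).
#' @param seed RNG seed.
#' @return data.frame with columns `x`, `y`.
#' @export
gen_piecewise_linear <- function(x, break_x, slope1, slope2, intercept = 0,
                                 noise_sd = 0, seed = 1) {
  if (is.unsorted(x, strictly = TRUE)) hs_stop("x must be strictly increasing", "hs_parameter_error")
  if (break_x < min(x) || break_x > max(x)) {
    hs_stop("break_x must lie inside the grid range", "hs_parameter_error")
  }
  y <- ifelse(x <= break_x,
              intercept + slope1 * (x - x[1]),
              intercept + slope1 * (break_x - x[1]) + slope2 * (x - break_x))
  if (noise_sd > 0) y <- y + with_seed(seed, stats::rnorm(length(x), sd = noise_sd))
  data.frame(x = x, y = y)
}
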