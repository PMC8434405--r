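# Shared fixtures and independent brute-force oracles. Every oracle here
# is a direct transcription of the estimator's definition (double loops,
# exhaustive image search, closed forms); none share code with the package
# internals they check.

# -- exhaustive 27-image minimum-image search ------------------------------
oracle_min_image <- function(a, b, box) {
  best <- NULL; bestd <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- (b + c(i, j, k) * box) - a
    if (sum(d * d) < bestd) { bestd <- sum(d * d); best <- d }
  }
  best
}

# -- direct double-loop MSD over origins and lags --------------------------
oracle_msd <- function(x, dt, max_lag_frames, origin_stride = 1) {
  nf <- dim(x)[3]
  vapply(0:max_lag_frames, function(l) {
    tot <- 0; cnt <- 0
    for (o in seq(1, nf, by = origin_stride)) {
      if (o + l > nf) next
      for (i in seq_len(dim(x)[1])) {
        d <- x[i, , o + l] - x[i, , o]
        tot <- tot + sum(d * d); cnt <- cnt + 1
      }
    }
    tot / cnt
  }, numeric(1))
}

# -- direct residence correlation (intermittent) ---------------------------
oracle_residence <- function(occ, dt, max_lag_frames, origin_stride = 1) {
  nf <- ncol(occ)
  vapply(0:max_lag_frames, function(l) {
    fr <- c()
    for (o in seq(1, nf, by = origin_stride)) {
      if (o + l > nf) next
      n0 <- sum(occ[, o])
      if (n0 == 0) next
      fr <- c(fr, sum(occ[, o] * occ[, o + l]) / n0)
    }
    mean(fr)
  }, numeric(1))
}

# -- direct dipole autocorrelation -----------------------------------------
oracle_dipole_corr <- function(dips, max_lag_frames, origin_stride = 1,
                               occ = NULL) {
  nf <- length(dips)
  vapply(0:max_lag_frames, function(l) {
    vals <- c()
    for (o in seq(1, nf, by = origin_stride)) {
      if (o + l > nf) next
      sel <- if (is.null(occ)) seq_len(nrow(dips[[o]])) else which(occ[, o] == 1)
      if (!length(sel)) next
      dots <- numeric(length(sel))
      for (ii in seq_along(sel)) {
        dots[ii] <- sum(dips[[o]][sel[ii], ] * dips[[o + l]][sel[ii], ])
      }
      vals <- c(vals, mean(dots))
    }
    mean(vals)
  }, numeric(1))
}

# -- direct intermittent population correlation ----------------------------
oracle_intermittent <- function(h, max_lag_frames, origin_stride = 1) {
  nf <- ncol(h)
  vapply(0:max_lag_frames, function(l) {
    num <- 0; den <- 0
    for (o in seq(1, nf, by = origin_stride)) {
      if (o + l > nf) next
      for (i in seq_len(nrow(h))) {
        num <- num + h[i, o] * h[i, o + l]
        den <- den + h[i, o]
      }
    }
    num / den
  }, numeric(1))
}

# -- exhaustive all-triples hydrogen-bond search ---------------------------
# plain geometry, independent of the package's vectorized path
oracle_hbonds <- function(traj, frame, criterion) {
  top <- traj$topology
  at <- top$atoms
  xyz <- matrix(traj$coords[, , frame], ncol = 3)
  res <- list()
  mi <- function(v) {
    if (is.null(traj$box)) return(v)
    for (k in 1:3) v[k] <- v[k] - traj$box[k] * floor(v[k] / traj$box[k] + 0.5)
    v
  }
  for (d in which(at$is_donor)) {
    hs <- integer(0)
    for (r in seq_len(nrow(top$bonds))) {
      p <- top$bonds[r, ]
      if (p[1] == d && at$is_hydrogen[p[2]]) hs <- c(hs, p[2])
      if (p[2] == d && at$is_hydrogen[p[1]]) hs <- c(hs, p[1])
    }
    for (a in which(at$is_acceptor)) {
      if (a == d || at$molecule_id[a] == at$molecule_id[d]) next
      da <- mi(xyz[a, ] - xyz[d, ])
      dist <- sqrt(sum(da * da))
      if (dist >= criterion$da_cutoff) next
      for (h in hs) {
        dh <- mi(xyz[h, ] - xyz[d, ])
        ang <- acos(max(-1, min(1, sum(da * dh) / (dist * sqrt(sum(dh * dh)))))) * 180 / pi
        if (ang < criterion$angle_cutoff) {
          res[[length(res) + 1]] <- c(d, h, a)
        }
      }
    }
  }
  if (!length(res)) return(matrix(integer(0), 0, 3))
  m <- do.call(rbind, res)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# -- rigid-fit oracle: numerical minimization over Euler angles ------------
oracle_superpose_rmsd <- function(mobile, reference) {
  a <- sweep(mobile, 2, colMeans(mobile))
  b <- sweep(reference, 2, colMeans(reference))
  rotmat <- function(p) {
    cx <- cos(p[1]); sx <- sin(p[1]); cy <- cos(p[2]); sy <- sin(p[2])
    cz <- cos(p[3]); sz <- sin(p[3])
    rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    rz %*% ry %*% rx
  }
  obj <- function(p) sqrt(mean(rowSums((a %*% t(rotmat(p)) - b)^2)))
  best <- Inf
  for (s in list(c(0, 0, 0), c(1, 1, 1), c(2, 0.5, -1), c(-1, 2, 0.3),
                 c(3, -2, 1.5), c(0.2, -0.7, 2.5))) {
    o <- stats::optim(s, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-15))
    o <- stats::optim(o$par, obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
    best <- min(best, o$value)
  }
  best
}

# -- analytic SASA for two equal overlapping spheres -----------------------
two_sphere_sasa <- function(r_ext, d) {
  if (d >= 2 * r_ext) return(2 * 4 * pi * r_ext^2)
  cap_h <- r_ext - d / 2
  2 * (4 * pi * r_ext^2 - 2 * pi * r_ext * cap_h)
}

# -- small fixture builders ------------------------------------------------
make_point_traj <- function(xyz_list, box = NULL, dt = 1,
                            element = "C", resname = "UNK") {
  n <- nrow(xyz_list[[1]])
  top <- topology(data.frame(atom_id = seq_len(n), atom_name = element,
                             element = element, residue_id = seq_len(n),
                             residue_name = resname, stringsAsFactors = FALSE))
  coords <- array(unlist(xyz_list), c(n, 3, length(xyz_list)))
  trajectory(top, coords, box, (seq_along(xyz_list) - 1) * dt)
}

# a box of randomly placed/oriented rigid waters plus one fixed N-H donor
# site, for hydrogen-bond geometry tests
make_water_box <- function(n_waters, box_edge, seed) {
  tr <- gen_rotors(n_waters, 0, 0.1, 2, seed = seed, box_edge = box_edge)
  set.seed(seed + 1000)
  # scatter the molecules uniformly (gen_rotors grids them)
  shift <- matrix(runif(n_waters * 3, 0, box_edge), ncol = 3) -
    tr$coords[seq(1, 3 * n_waters, 3), , 1]
  for (s in 0:2) tr$coords[seq(1 + s, 3 * n_waters, 3), , 1] <-
    tr$coords[seq(1 + s, 3 * n_waters, 3), , 1] + shift
  trajectory(tr$topology, tr$coords[, , 1, drop = FALSE], tr$box)
}

expect_close <- function(actual, expected, tol) {
  testthat::expect_lt(max(abs(actual - expected)), tol)
}
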