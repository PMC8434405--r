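# Hydrogen-bond detection and population dynamics: geometric criterion,
# per-frame counts, continuous lifetimes (tau_HB), intermittent population
# correlation c(t), and the slow relaxation time tau_R (1/e decay of c).

#' Geometric hydrogen-bond criterion
#'
#' A donor-hydrogen-acceptor triple is bonded when the minimum-image
#' donor-acceptor distance is strictly less than `da_cutoff` and the angle
#' at the donor between the D->H and D->A vectors is strictly less than
#' `angle_cutoff`. Defaults are the conventional 0.35 nm (3.5 Angstrom)
#' and 30 degrees.
#'
#' @param da_cutoff donor-acceptor distance cutoff (nm), > 0.
#' @param angle_cutoff hydrogen-donor-acceptor angle cutoff (degrees),
#'   < 90.
#' @return List of class `hbond_criterion`.
#' @export
hbond_criterion <- function(da_cutoff = 0.35, angle_cutoff = 30) {
  check_scalar(da_cutoff, "da_cutoff", 0, strict = TRUE)
  check_scalar(angle_cutoff, "angle_cutoff", 0, strict = TRUE)
  if (angle_cutoff >= 90) hs_stop("angle_cutoff must be < 90 degrees", "hs_parameter_error")
  structure(list(da_cutoff = da_cutoff, angle_cutoff = angle_cutoff),
            class = "hbond_criterion")
}

#' Detect hydrogen bonds in one frame
#'
#' Registers every (donor, hydrogen, acceptor) triple satisfying the
#' geometric criterion, with donors drawn from `donors_from` and acceptors
#' from `acceptors_from`. Same-molecule pairs and D = A are excluded.
#'
#' @param traj `md_trajectory` whose topology carries donor/acceptor/
#'   hydrogen flags (see [topology()]).
#' @param frame frame index.
#' @param donors_from,acceptors_from atom selections restricting the
#'   search (donor atoms must be flagged donors, acceptors flagged
#'   acceptors).
#' @param criterion an [hbond_criterion()].
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor`
#'   (atom ids), `distance` (nm), `angle` (degrees).
#' @export
detect_hbonds <- function(traj, frame = 1, donors_from = "all",
                          acceptors_from = "all",
                          criterion = hbond_criterion()) {
  top <- traj$topology
  at <- top$atoms
  d_sel <- intersect(select_atoms(traj, donors_from), which(at$is_donor))
  a_sel <- intersect(select_atoms(traj, acceptors_from), which(at$is_acceptor))
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0))
  if (!length(d_sel) || !length(a_sel)) return(empty)
  hyd <- bonded_hydrogens(top, d_sel)
  no_h <- d_sel[vapply(hyd, length, 1L) == 0]
  if (length(no_h)) {
    hs_stop("donor atom(s) without bonded hydrogen: %s", "hs_topology_error",
            paste(no_h, collapse = ", "))
  }
  xyz <- matrix(traj$coords[, , frame], ncol = 3)
  mol <- at$molecule_id
  cosmax <- cos(criterion$angle_cutoff * pi / 180)
  out <- vector("list", length(d_sel))
  a_xyz <- xyz[a_sel, , drop = FALSE]
  for (k in seq_along(d_sel)) {
    d_at <- d_sel[k]
    da <- sweep(a_xyz, 2, xyz[d_at, ], `-`)
    if (!is.null(traj$box)) da <- minimum_image(da, traj$box)
    dist <- sqrt(rowSums(da * da))
    cand <- which(dist < criterion$da_cutoff & a_sel != d_at & mol[a_sel] != mol[d_at])
    if (!length(cand)) next
    rows <- list()
    for (h_at in hyd[[k]]) {
      dh <- xyz[h_at, ] - xyz[d_at, ]
      if (!is.null(traj$box)) dh <- drop(minimum_image(matrix(dh, ncol = 3), traj$box))
      dh_n <- dh / sqrt(sum(dh * dh))
      cosang <- (da[cand, , drop = FALSE] %*% dh_n) / dist[cand]
      hit <- which(cosang > cosmax)
      if (length(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          donor = d_at, hydrogen = h_at, acceptor = a_sel[cand[hit]],
          distance = dist[cand[hit]],
          angle = acos(pmin(pmax(cosang[hit], -1), 1)) * 180 / pi)
      }
    }
    if (length(rows)) out[[k]] <- do.call(rbind, rows)
  }
  out <- Filter(Negate(is.null), out)
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# bonds with donor in one group and acceptor in the other (both directions);
# within-group when the groups coincide.
frame_group_bonds <- function(traj, frame, group_a, group_b, criterion) {
  same <- identical(sort(group_a), sort(group_b))
  if (same) {
    detect_hbonds(traj, frame, group_a, group_a, criterion)
  } else {
    ab <- detect_hbonds(traj, frame, group_a, group_b, criterion)
    ba <- detect_hbonds(traj, frame, group_b, group_a, criterion)
    unique(rbind(ab, ba))
  }
}

#' Per-frame hydrogen-bond counts between two groups
#'
#' Counts bonds with the donor in one group and the acceptor in the other
#' (both directions). When the two groups are identical (e.g. water-water),
#' bonds within the group are counted once per (D, H, A) triple.
#'
#' @param traj `md_trajectory`.
#' @param group_a,group_b atom selections.
#' @param criterion an [hbond_criterion()].
#' @return List: `counts` (per frame), `mean`, `sd` (sample sd), `time`.
#' @export
hbond_count_series <- function(traj, group_a, group_b,
                               criterion = hbond_criterion()) {
  ga <- select_atoms(traj, group_a); gb <- select_atoms(traj, group_b)
  if (!length(ga) || !length(gb)) hs_stop("empty group selection", "hs_parameter_error")
  nf <- n_frames(traj)
  counts <- vapply(seq_len(nf), function(f) {
    nrow(frame_group_bonds(traj, f, ga, gb, criterion))
  }, numeric(1))
  list(counts = counts, mean = mean(counts), sd = stats::sd(counts),
       time = traj$time)
}

#' Hydrogen-bond existence matrix
#'
#' Builds the population bookkeeping for bond kinetics: the union of all
#' (donor, hydrogen, acceptor) triples ever bonded between the two groups,
#' with a per-frame 0/1 indicator row `h_i(t)` for each triple.
#'
#' @inheritParams hbond_count_series
#' @return Object of class `hbond_series`: list with `pairs` (data.frame
#'   donor, hydrogen, acceptor), `h` (n_pairs x n_frames integer matrix),
#'   `dt`, `time`. An all-empty system returns zero rows with attribute
#'   `"empty" = TRUE`.
#' @export
hbond_existence <- function(traj, group_a, group_b,
                            criterion = hbond_criterion()) {
  ga <- select_atoms(traj, group_a); gb <- select_atoms(traj, group_b)
  if (!length(ga) || !length(gb)) hs_stop("empty group selection", "hs_parameter_error")
  nf <- n_frames(traj)
  per_frame <- lapply(seq_len(nf), function(f) {
    b <- frame_group_bonds(traj, f, ga, gb, criterion)
    paste(b$donor, b$hydrogen, b$acceptor)
  })
  keys <- unique(unlist(per_frame))
  if (!length(keys)) {
    out <- structure(list(pairs = data.frame(donor = integer(0),
                                             hydrogen = integer(0),
                                             acceptor = integer(0)),
                          h = matrix(integer(0), 0, nf),
                          dt = traj$dt, time = traj$time),
                     class = "hbond_series")
    attr(out, "empty") <- TRUE
    return(out)
  }
  h <- matrix(0L, length(keys), nf)
  for (f in seq_len(nf)) h[match(per_frame[[f]], keys), f] <- 1L
  km <- do.call(rbind, lapply(strsplit(keys, " "), as.integer))
  structure(list(pairs = data.frame(donor = km[, 1], hydrogen = km[, 2],
                                    acceptor = km[, 3]),
                 h = h, dt = traj$dt, time = traj$time),
            class = "hbond_series")
}

# Build an hbond_series-like object from a plain indicator matrix (e.g.
# two-state Markov output), for the kinetics estimators.
as_hbond_series <- function(h, dt = NULL) {
  if (inherits(h, "hbond_series")) return(h)
  dt <- dt %||% attr(h, "dt")
  if (is.null(dt)) hs_stop("indicator matrix needs a dt", "hs_parameter_error")
  structure(list(pairs = NULL, h = h, dt = dt,
                 time = (seq_len(ncol(h)) - 1) * dt),
            class = "hbond_series")
}

#' Continuous hydrogen-bond lifetime
#'
#' `tau_HB`: the mean duration of maximal runs of consecutive bonded
#' frames (run length x dt), the average time a given bond remains intact
#' without interruption. Runs touching either trajectory end are censored
#' and excluded.
#'
#' @param series `hbond_series` (or an indicator matrix with a `dt`
#'   attribute, e.g. from [gen_two_state_series()]).
#' @param dt sampling interval, if `series` is a bare matrix without one.
#' @return List: `tau_hb` (ps), `n_runs`, `run_lengths` (ps).
#' @export
continuous_lifetime <- function(series, dt = NULL) {
  s <- as_hbond_series(series, dt)
  h <- s$h
  nf <- ncol(h)
  acc <- vector("list", nrow(h))
  for (i in seq_len(nrow(h))) {
    r <- rle(h[i, ])
    if (length(r$lengths) == 0) next
    on <- which(r$values == 1L)
    if (!length(on)) next
    # censor runs touching either trajectory end
    keep <- on
    if (length(keep) && keep[1] == 1L) keep <- keep[-1]
    if (length(keep) && keep[length(keep)] == length(r$lengths)) keep <- keep[-length(keep)]
    if (length(keep)) acc[[i]] <- r$lengths[keep]
  }
  runs <- unlist(acc)
  if (!length(runs)) {
    hs_stop("no completed bonded intervals (only censored runs); use a longer trajectory",
            "hs_analysis_error")
  }
  list(tau_hb = mean(runs) * s$dt, n_runs = length(runs),
       run_lengths = runs * s$dt)
}

#' Intermittent hydrogen-bond population correlation
#'
#' `c(t) = <h(0) h(t)> / <h>`: the probability that a pair bonded at a
#' random origin is also bonded a lag t later, regardless of intermediate
#' breaks. Averaged over pairs and time origins on the stride grid; the
#' normalization uses the same origin set, so `c(0) = 1` exactly.
#'
#' @param series `hbond_series` or indicator matrix.
#' @param max_lag maximum lag (ps).
#' @param origin_stride origin spacing in frames.
#' @param dt sampling interval for bare matrices.
#' @return A `correlation_series` data.frame.
#' @export
intermittent_correlation <- function(series, max_lag, origin_stride = 1, dt = NULL) {
  s <- as_hbond_series(series, dt)
  h <- s$h
  nf <- ncol(h)
  if (!nrow(h) || sum(h) == 0) hs_stop("series has no bonded frames (<h> = 0)", "hs_analysis_error")
  lmax <- floor(max_lag / s$dt + 1e-9)
  if (lmax > nf - 1) hs_stop("max_lag exceeds series span", "hs_parameter_error")
  origins_all <- seq(1, nf, by = origin_stride)
  vals <- numeric(lmax + 1); n_or <- integer(lmax + 1)
  for (l in 0:lmax) {
    o <- origins_all[origins_all + l <= nf]
    h0 <- h[, o, drop = FALSE]
    denom <- sum(h0)
    if (denom == 0) { vals[l + 1] <- NA_real_; n_or[l + 1] <- length(o); next }
    vals[l + 1] <- sum(h0 * h[, o + l, drop = FALSE]) / denom
    n_or[l + 1] <- length(o)
  }
  correlation_series((0:lmax) * s$dt, vals, n_or)
}

#' Slow hydrogen-bond relaxation time
#'
#' `tau_R`: the lag at which the intermittent correlation `c(t)` first
#' decays to 1/e, located by linear interpolation between the bracketing
#' lags. If the curve plateaus above 1/e (large stationary occupancy), an
#' error names the plateau value unless exponential-tail extrapolation is
#' explicitly enabled.
#'
#' @param c_curve `correlation_series` from [intermittent_correlation()].
#' @param extrapolate fit an exponential tail and extrapolate when no
#'   crossing is sampled (result flagged `extrapolated`).
#' @return List: `tau_r` (ps), `extrapolated`.
#' @export
relaxation_time <- function(c_curve, extrapolate = FALSE) {
  t <- c_curve$lag; y <- c_curve$value
  target <- exp(-1)
  below <- which(y < target)
  if (length(below)) {
    i <- below[1]
    if (i == 1) return(list(tau_r = t[1], extrapolated = FALSE))
    t0 <- t[i - 1]; t1 <- t[i]; y0 <- y[i - 1]; y1 <- y[i]
    tau <- t0 + (y0 - target) / (y0 - y1) * (t1 - t0)
    return(list(tau_r = tau, extrapolated = FALSE))
  }
  if (!extrapolate) {
    plateau <- mean(utils::tail(y, max(3, length(y) %/% 5)))
    hs_stop("c(t) never crosses 1/e within the sampled lags (tail plateau %.4f); enable extrapolation or sample longer",
            "hs_analysis_error", plateau)
  }
  tail_n <- max(5, length(y) %/% 2)
  ti <- utils::tail(t, tail_n); yi <- utils::tail(y, tail_n)
  pos <- yi > 0
  if (sum(pos) < 3) hs_stop("tail not positive; cannot extrapolate", "hs_analysis_error")
  lf <- stats::lm.fit(cbind(1, ti[pos]), log(yi[pos]))
  slope <- lf$coefficients[2]
  if (slope >= 0) hs_stop("tail not decaying; cannot extrapolate", "hs_analysis_error")
  tau <- (log(target) - lf$coefficients[1]) / slope
  list(tau_r = unname(tau), extrapolated = TRUE)
}

#' Per-frame hydration-shell water counts
#'
#' Column sums of [shell_membership()]: the number of waters within the
#' cutoff of the reference selection at each frame (e.g. within 0.5 nm of
#' a tryptophan site).
#'
#' @inheritParams shell_membership
#' @return List: `counts` (per frame), `mean`, `sd`, `time`, `membership`.
#' @export
shell_water_count <- function(traj, reference_selection, cutoff = 0.5) {
  if (cutoff == 0) {
    nf <- n_frames(traj)
    return(list(counts = rep(0L, nf), mean = 0, sd = 0, time = traj$time,
                membership = NULL))
  }
  mem <- shell_membership(traj, reference_selection, cutoff)
  counts <- colSums(mem$occupancy)
  list(counts = counts, mean = mean(counts), sd = stats::sd(counts),
       time = traj$time, membership = mem)
}
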