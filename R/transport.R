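# Translational transport: multi-origin MSD, windowed MSD summaries,
# Einstein-relation diffusion coefficients, radial distribution functions
# with first-peak statistics, and dynamical-transition breakpoint detection.

# Heuristic: a trajectory still carrying periodic wrapping shows apparent
# frame-to-frame jumps comparable to the box edge.
check_unwrapped <- function(x, box, what = "MSD") {
  if (is.null(box)) return(invisible(TRUE))
  nf <- dim(x)[3]
  if (nf < 2) return(invisible(TRUE))
  probe <- unique(round(seq(2, nf, length.out = min(nf - 1, 25))))
  for (t in probe) {
    step <- abs(matrix(x[, , t], ncol = 3) - matrix(x[, , t - 1], ncol = 3))
    if (any(sweep(step, 2, 0.5 * box, `>`))) {
      hs_stop("%s requires unwrapped coordinates (apparent jumps ~ box edge detected); apply unwrap_coordinates() first",
              "hs_parameter_error", what)
    }
  }
  invisible(TRUE)
}

#' Mean square displacement (multiple time origins)
#'
#' For each lag `D` on the frame grid up to `max_lag`, the average of
#' `|r_i(t0 + D) - r_i(t0)|^2` over all selected atoms and all origins
#' `t0` on the stride grid with `t0 + D` in range. Coordinates must be
#' unwrapped (a wrapped-trajectory heuristic raises an error).
#'
#' @param traj `md_trajectory` with unwrapped coordinates.
#' @param selection atom selection.
#' @param max_lag largest lag (ps); defaults to half the span.
#' @param origin_stride origin spacing in frames (default 1 = every frame).
#' @return data.frame with columns `lag` (ps), `msd` (nm^2), `n_samples`.
#' @export
msd <- function(traj, selection = "all", max_lag = NULL, origin_stride = 1) {
  sel <- select_atoms(traj, selection)
  if (!length(sel)) hs_stop("empty selection", "hs_parameter_error")
  nf <- n_frames(traj)
  span <- traj$time[nf] - traj$time[1]
  max_lag <- max_lag %||% (span / 2)
  if (max_lag > span + 1e-9) hs_stop("max_lag exceeds trajectory span", "hs_parameter_error")
  x <- traj$coords[sel, , , drop = FALSE]
  check_unwrapped(x, traj$box, "MSD")
  lmax <- floor(max_lag / traj$dt + 1e-9)
  origins_all <- seq(1, nf, by = origin_stride)
  lag_f <- 0:lmax
  out_msd <- numeric(lmax + 1); out_n <- integer(lmax + 1)
  na <- length(sel)
  for (li in seq_along(lag_f)) {
    l <- lag_f[li]
    orig <- origins_all[origins_all + l <= nf]
    s <- 0
    for (o in orig) {
      d <- matrix(x[, , o + l], ncol = 3) - matrix(x[, , o], ncol = 3)
      s <- s + sum(d * d)
    }
    out_msd[li] <- s / (length(orig) * na)
    out_n[li] <- length(orig) * na
  }
  data.frame(lag = lag_f * traj$dt, msd = out_msd, n_samples = out_n)
}

#' Windowed squared-displacement summary
#'
#' Divides the trajectory into non-overlapping windows of the given length;
#' in each window the squared displacement between the window start and end
#' frames is averaged over the selected atoms; the mean and standard
#' deviation over windows are returned. This is the per-period displacement
#' statistic used for temperature scans of protein and hydration-water
#' mobility.
#'
#' @param traj `md_trajectory` (unwrapped).
#' @param selection atom selection.
#' @param window window length (ps); the span must hold at least 2 windows.
#' @return List: `mean` (nm^2), `sd` (nm^2), `n_windows`, `per_window`.
#' @export
msd_windowed <- function(traj, selection = "all", window) {
  sel <- select_atoms(traj, selection)
  if (!length(sel)) hs_stop("empty selection", "hs_parameter_error")
  nf <- n_frames(traj)
  span <- traj$time[nf] - traj$time[1]
  if (window > span) hs_stop("window longer than trajectory", "hs_parameter_error")
  wf <- round(window / traj$dt)
  if (wf < 1) hs_stop("window shorter than one frame interval", "hs_parameter_error")
  n_win <- floor((nf - 1) / wf)
  if (n_win < 2) hs_stop("window must divide the span into >= 2 periods", "hs_parameter_error")
  x <- traj$coords[sel, , , drop = FALSE]
  check_unwrapped(x, traj$box, "windowed MSD")
  vals <- vapply(seq_len(n_win), function(w) {
    a <- (w - 1) * wf + 1; b <- a + wf
    d <- matrix(x[, , b], ncol = 3) - matrix(x[, , a], ncol = 3)
    mean(rowSums(d * d))
  }, numeric(1))
  list(mean = mean(vals), sd = stats::sd(vals), n_windows = n_win, per_window = vals)
}

#' Diffusion coefficient from the Einstein relation
#'
#' Least-squares slope of MSD versus lag over `[fit_min, fit_max]`,
#' divided by 6 (three dimensions). The fit's R-squared is reported so a
#' non-diffusive (e.g. ballistic, quadratic) regime is visible.
#'
#' @param msd_series data.frame from [msd()] (columns `lag`, `msd`).
#' @param fit_min,fit_max lag window (ps) for the linear fit (>= 3 lags).
#' @return List: `D` (nm^2/ps), `se` (standard error), `r_squared`,
#'   `n_lags`, `fit` (the `lm` object).
#' @export
diffusion_coefficient <- function(msd_series, fit_min, fit_max) {
  keep <- msd_series$lag >= fit_min & msd_series$lag <= fit_max
  if (sum(keep) < 3) hs_stop("fit window contains fewer than 3 lags", "hs_parameter_error")
  dat <- msd_series[keep, , drop = FALSE]
  fit <- stats::lm(msd ~ lag, data = dat)
  sm <- suppressWarnings(summary(fit))  # exact lines trip lm's perfect-fit warning
  list(D = unname(stats::coef(fit)["lag"]) / 6,
       se = sm$coefficients["lag", "Std. Error"] / 6,
       r_squared = sm$r.squared, n_lags = nrow(dat), fit = fit)
}

#' Radial distribution function
#'
#' Histogram of minimum-image center-target distances, normalized per frame
#' by the spherical shell volume `4*pi*r^2*dr` and the target bulk density
#' `N_B / V`, averaged over frames and centers. Self-pairs are excluded,
#' and when a center atom also belongs to the target set the bulk density
#' seen by that center uses `N_B - 1`, keeping the ideal-gas limit
#' `g(r) = 1` unbiased.
#'
#' @param traj `md_trajectory` with a periodic box.
#' @param center_selection,target_selection atom selections.
#' @param r_max histogram range (nm); at most half the smallest box edge.
#' @param bin_width histogram bin (nm).
#' @return data.frame with columns `r` (bin centers, nm), `g`; attributes
#'   `bin_width`, `n_center`, `n_target`, `per_frame` (matrix of per-frame
#'   g values, for error estimation).
#' @export
rdf <- function(traj, center_selection, target_selection, r_max = 3.0,
                bin_width = 0.002) {
  if (is.null(traj$box)) hs_stop("RDF requires a periodic box", "hs_parameter_error")
  if (r_max > min(traj$box) / 2 + 1e-9) {
    hs_stop("r_max = %g exceeds half the smallest box edge (%g nm)",
            "hs_parameter_error", r_max, min(traj$box) / 2)
  }
  centers <- select_atoms(traj, center_selection)
  targets <- select_atoms(traj, target_selection)
  if (!length(centers)) hs_stop("empty center selection", "hs_parameter_error")
  breaks <- seq(0, r_max, by = bin_width)
  if (abs(breaks[length(breaks)] - r_max) > 1e-12) breaks <- c(breaks, r_max)
  nb <- length(breaks) - 1
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  nf <- n_frames(traj)
  vol <- prod(traj$box)
  shell <- 4 * pi * mid^2 * diff(breaks)
  per_frame <- matrix(0, nf, nb)
  n_t <- length(targets)
  if (n_t > 0) {
    # effective partner count: a center that is itself a target sees N_B - 1
    overlap <- mean(centers %in% targets)
    dens <- (n_t - overlap) / vol
    for (f in seq_len(nf)) {
      xyz_t <- matrix(traj$coords[targets, , f], ncol = 3)
      counts <- numeric(nb)
      for (ci in seq_along(centers)) {
        c_at <- centers[ci]
        d <- min_image_dist(traj$coords[c_at, , f], xyz_t, traj$box)
        d <- d[targets != c_at]
        d <- d[d < r_max]
        if (length(d)) {
          counts <- counts + tabulate(findInterval(d, breaks,
                                                   rightmost.closed = TRUE), nb)
        }
      }
      per_frame[f, ] <- counts / (length(centers) * shell * dens)
    }
  }
  out <- data.frame(r = mid, g = colMeans(per_frame))
  attr(out, "bin_width") <- bin_width
  attr(out, "n_center") <- length(centers)
  attr(out, "n_target") <- n_t
  attr(out, "per_frame") <- per_frame
  out
}

#' First-peak statistics of an RDF curve
#'
#' Locates the first local maximum after the first non-zero bin and the
#' first local minimum after that maximum (optionally after moving-average
#' smoothing), and reports the de-packing ratio `g_min / g_max` of the
#' first hydration layer. The first-minimum position is the conventional
#' hydration-layer thickness.
#'
#' @param curve data.frame from [rdf()] (columns `r`, `g`).
#' @param smoothing_window moving-average width in bins (odd; 1 = none;
#'   default 5).
#' @return List: `first_max_r`, `first_max_g`, `first_min_r`,
#'   `first_min_g`, `ratio`.
#' @export
rdf_peak_stats <- function(curve, smoothing_window = 5) {
  g <- curve$g; r <- curve$r
  if (smoothing_window > 1) {
    k <- rep(1 / smoothing_window, smoothing_window)
    g <- stats::filter(g, k, sides = 2)
    keep <- !is.na(g)
    g <- as.numeric(g[keep]); r <- r[keep]
  }
  nz <- which(g > 0)
  if (!length(nz)) hs_stop("curve is identically zero", "hs_analysis_error")
  start <- nz[1]
  n <- length(g)
  if (start >= n - 1) hs_stop("too few non-zero bins for extremum search", "hs_analysis_error")
  is_max <- function(i) i > 1 && i < n && g[i] >= g[i - 1] && g[i] > g[i + 1]
  is_min <- function(i) i > 1 && i < n && g[i] <= g[i - 1] && g[i] < g[i + 1]
  imax <- NA_integer_
  for (i in seq(max(start, 2), n - 1)) if (is_max(i)) { imax <- i; break }
  if (is.na(imax)) {
    hs_stop("no first maximum found; try smoothing or longer sampling", "hs_analysis_error")
  }
  imin <- NA_integer_
  for (i in seq(imax + 1, n - 1)) if (is_min(i)) { imin <- i; break }
  if (is.na(imin)) {
    hs_stop("no first minimum found after the maximum; try smoothing or longer sampling",
            "hs_analysis_error")
  }
  list(first_max_r = r[imax], first_max_g = g[imax],
       first_min_r = r[imin], first_min_g = g[imin],
       ratio = g[imin] / g[imax])
}

#' Two-segment breakpoint detection
#'
#' Exhaustive scan over interior grid points: for each candidate break the
#' data are split into two overlapping-at-the-break segments, each fitted
#' by its own least-squares line (continuity not enforced); the breakpoint
#' minimizing the total squared error is returned. Intended for small
#' temperature grids where an observable (MSD, H-bond count) changes trend,
#' as at a protein dynamical transition.
#'
#' @param x ordered grid (>= 5 points), e.g. temperature in K.
#' @param y observable values.
#' @param slope_tol relative slope difference below which the fit is
#'   flagged degenerate (no real trend change).
#' @return List: `breakpoint`, `sse`, `slope1`, `slope2`, `degenerate`,
#'   `candidates` (per-candidate SSE table).
#' @export
detect_transition <- function(x, y, slope_tol = 1e-6) {
  n <- length(x)
  if (n < 5) hs_stop("breakpoint detection needs >= 5 points", "hs_parameter_error")
  if (length(y) != n) hs_stop("x and y lengths differ", "hs_parameter_error")
  if (is.unsorted(x, strictly = TRUE)) hs_stop("x must be strictly increasing", "hs_parameter_error")
  # interior candidates: both segments need >= 2 points for a line
  cand <- 2:(n - 1)
  sse <- vapply(cand, function(k) {
    f1 <- stats::lm.fit(cbind(1, x[1:k]), y[1:k])
    f2 <- stats::lm.fit(cbind(1, x[k:n]), y[k:n])
    sum(f1$residuals^2) + sum(f2$residuals^2)
  }, numeric(1))
  kbest <- cand[which.min(sse)]
  f1 <- stats::lm.fit(cbind(1, x[1:kbest]), y[1:kbest])
  f2 <- stats::lm.fit(cbind(1, x[kbest:n]), y[kbest:n])
  s1 <- f1$coefficients[2]; s2 <- f2$coefficients[2]
  scale <- max(abs(s1), abs(s2), 1e-300)
  list(breakpoint = x[kbest], sse = min(sse),
       slope1 = unname(s1), slope2 = unname(s2),
       degenerate = abs(s1 - s2) / scale < slope_tol,
       candidates = data.frame(x = x[cand], sse = sse))
}
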