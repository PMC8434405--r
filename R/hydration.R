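# Hydration-shell residence and water reorientation dynamics:
# distance-defined shell membership, intermittent residence correlation
# C_r(t) with biphasic stretched-exponential fitting, and dipole
# autocorrelation C_mu(t) with single-exponential fitting.

#' Hydration-shell membership of water molecules
#'
#' A water occupies the shell at a frame iff the minimum-image distance
#' from its oxygen to the nearest reference atom is at most the cutoff
#' (0.6 nm is the conventional protein-wide shell; 0.5 nm a tighter local
#' shell around a single residue).
#'
#' @param traj `md_trajectory` containing water molecules.
#' @param reference_selection atoms defining the shell (e.g. protein heavy
#'   atoms, or one residue's atoms).
#' @param cutoff shell radius (nm), > 0.
#' @return Object of class `shell_membership`: list with `water_ids`
#'   (molecule ids), `oxygen_ids` (atom ids), `occupancy` (n_waters x
#'   n_frames 0/1 integer matrix), `cutoff`, `reference_selection`, `dt`,
#'   `time`.
#' @export
shell_membership <- function(traj, reference_selection, cutoff = 0.6) {
  check_scalar(cutoff, "cutoff", 0)
  ref <- select_atoms(traj, reference_selection)
  if (!length(ref)) hs_stop("empty reference selection", "hs_parameter_error")
  waters <- water_molecules(traj$topology)
  if (!nrow(waters)) hs_stop("no water molecules identified in topology", "hs_input_error")
  nf <- n_frames(traj)
  occ <- matrix(0L, nrow(waters), nf)
  for (f in seq_len(nf)) {
    ox <- matrix(traj$coords[waters$o, , f], ncol = 3)
    mind <- rep(Inf, nrow(waters))
    for (r_at in ref) {
      d <- min_image_dist(traj$coords[r_at, , f], ox, traj$box)
      mind <- pmin(mind, d)
    }
    occ[, f] <- as.integer(mind <= cutoff)
  }
  structure(list(water_ids = waters$molecule_id, oxygen_ids = waters$o,
                 occupancy = occ, cutoff = cutoff,
                 reference_selection = ref, dt = traj$dt, time = traj$time),
            class = "shell_membership")
}

#' @export
print.shell_membership <- function(x, ...) {
  cat(sprintf("shell_membership: %d waters x %d frames, cutoff %.3g nm, mean occupancy %.3g\n",
              nrow(x$occupancy), ncol(x$occupancy), x$cutoff, mean(x$occupancy)))
  invisible(x)
}

# Shared correlation-series constructor.
correlation_series <- function(lag, value, n_origins) {
  structure(data.frame(lag = lag, value = value, n_origins = n_origins),
            class = c("correlation_series", "data.frame"))
}

#' Residence correlation of shell waters
#'
#' Intermittent survival fraction of the shell population:
#' `C_r(t) = < (1/N_t0) * sum_{i in shell(t0)} delta_i(t0 + t) >` averaged
#' over time origins on the stride grid, where `delta_i(t)` is the
#' occupancy indicator (re-entries count; this is the intermittent
#' convention). Origins with an empty shell are skipped and counted in the
#' `n_origins` column. A continuous variant (each water discounted
#' permanently after its first exit) is available via `convention`.
#'
#' @param membership a [shell_membership()] result.
#' @param window maximum lag (ps).
#' @param origin_stride origin spacing in frames.
#' @param convention `"intermittent"` (default) or `"continuous"`.
#' @return A `correlation_series` data.frame: `lag` (ps), `value`,
#'   `n_origins`.
#' @export
residence_correlation <- function(membership, window, origin_stride = 1,
                                  convention = c("intermittent", "continuous")) {
  convention <- match.arg(convention)
  occ <- membership$occupancy
  nf <- ncol(occ)
  dt <- membership$dt
  lmax <- floor(window / dt + 1e-9)
  if (lmax > nf - 1) hs_stop("window exceeds trajectory span", "hs_parameter_error")
  origins <- seq(1, nf, by = origin_stride)
  n0 <- colSums(occ)[origins]
  if (all(n0 == 0)) hs_stop("all origins have empty shells", "hs_analysis_error")
  vals <- numeric(lmax + 1); n_or <- integer(lmax + 1)
  for (l in 0:lmax) {
    ok <- origins + l <= nf & n0 > 0
    o <- origins[ok]
    if (!length(o)) { vals[l + 1] <- NA_real_; n_or[l + 1] <- 0L; next }
    if (convention == "intermittent") {
      num <- colSums(occ[, o, drop = FALSE] * occ[, o + l, drop = FALSE])
    } else {
      # continuous: water must have been in the shell at every frame since t0
      num <- vapply(o, function(t0) {
        seg <- occ[, t0:(t0 + l), drop = FALSE]
        sum(apply(seg, 1, min) == 1L & occ[, t0] == 1L)
      }, numeric(1))
    }
    vals[l + 1] <- mean(num / n0[ok])
    n_or[l + 1] <- length(o)
  }
  correlation_series((0:lmax) * dt, vals, n_or)
}

# --- model functions ------------------------------------------------------

# Biphasic residence model: stretched-exponential slow branch plus a fast
# single exponential. C_r(t) = n_s exp(-(t/tau_s)^gamma) + n_1 exp(-t/tau_1)
model_biexp_stretched <- function(t, n_s, tau_s, gamma, n_1, tau_1) {
  n_s * exp(-(t / tau_s)^gamma) + n_1 * exp(-t / tau_1)
}

model_single_exp <- function(t, A, tau) A * exp(-t / tau)

#' Fit the biphasic stretched-exponential residence model
#'
#' Nonlinear least squares of
#' `C_r(t) = n_s * exp(-(t/tau_s)^gamma) + n_1 * exp(-t/tau_1)`
#' (Kohlrausch-Williams-Watts slow branch plus a fast exponential) with
#' box bounds and multi-start (at least 5 seeded restarts), keeping the
#' best-objective converged fit. Times are ordered post hoc so the
#' stretched branch is the slow one (`tau_s > tau_1`). Uncertainties come
#' from the local quadratic approximation at the optimum. The amplitudes
#' are not constrained to sum to 1; a warning is issued if
#' `|n_s + n_1 - 1| > 0.1`.
#'
#' @param series `correlation_series` (>= 10 lag points, values in
#'   (-0.1, 1.1]).
#' @param initial optional named list of starting values
#'   (`n_s, tau_s, gamma, n_1, tau_1`).
#' @param bounds optional named list of `c(lower, upper)` overrides.
#' @param fix_gamma fix the stretch exponent (e.g. `1` for a pure
#'   biexponential); `NULL` to fit it.
#' @param n_starts number of multi-start restarts (>= 5).
#' @param seed seed for the restart jitter.
#' @return Object of class `fit_result`: list with `model`, `params`,
#'   `param_uncertainty`, `rms_residual`, `converged`, plus `reordered`.
#' @export
fit_residence <- function(series, initial = NULL, bounds = NULL,
                          fix_gamma = NULL, n_starts = 7, seed = 42) {
  t <- series$lag; y <- series$value
  keep <- is.finite(y)
  t <- t[keep]; y <- y[keep]
  if (length(t) < 10) hs_stop("need >= 10 lag points", "hs_parameter_error")
  if (any(y <= -0.1) || any(y > 1.1)) {
    hs_stop("correlation values outside (-0.1, 1.1]", "hs_parameter_error")
  }
  if (max(y) - min(y) < 1e-3) {
    return(fit_failure("biexp_stretched",
                       c("n_s", "tau_s", "gamma", "n_1", "tau_1"),
                       "series shows no decay"))
  }
  dt <- min(diff(t)); span <- max(t) - min(t)
  lower <- c(n_s = 0, tau_s = dt, gamma = 0.2, n_1 = 0, tau_1 = dt)
  upper <- c(n_s = 1.5, tau_s = 10 * span, gamma = 1, n_1 = 1.5, tau_1 = 10 * span)
  for (nm in names(bounds)) { lower[nm] <- bounds[[nm]][1]; upper[nm] <- bounds[[nm]][2] }
  fixed_gamma <- !is.null(fix_gamma)
  if (fixed_gamma) check_scalar(fix_gamma, "fix_gamma", 0, strict = TRUE)
  # crude time scale for starts: lag where y first drops below y0/e
  y0 <- y[1]
  tau0 <- { i <- which(y < y0 / exp(1))[1]; if (is.na(i)) span / 2 else max(t[i], 2 * dt) }
  base_start <- list(n_s = 0.5 * y0, tau_s = min(max(4 * tau0, 3 * dt), 5 * span),
                     gamma = 0.8, n_1 = 0.5 * y0,
                     tau_1 = min(max(tau0 / 2, 1.5 * dt), span))
  if (!is.null(initial)) base_start[names(initial)] <- initial
  starts <- with_seed(seed, {
    lapply(seq_len(max(n_starts, 5)), function(k) {
      s <- base_start
      if (k > 1) {
        jit <- function(v, lo, hi) min(max(v * exp(stats::rnorm(1, sd = 0.7)), lo * 1.001), hi * 0.999)
        s$tau_s <- jit(s$tau_s, lower["tau_s"], upper["tau_s"])
        s$tau_1 <- jit(s$tau_1, lower["tau_1"], upper["tau_1"])
        s$gamma <- min(max(s$gamma + stats::rnorm(1, sd = 0.15), 0.25), 1)
        s$n_s <- min(max(s$n_s + stats::rnorm(1, sd = 0.15), 0.01), 1.4)
        s$n_1 <- min(max(1 - s$n_s + stats::rnorm(1, sd = 0.05), 0.01), 1.4)
      }
      if (s$tau_s < s$tau_1) { tmp <- s$tau_s; s$tau_s <- s$tau_1; s$tau_1 <- tmp }
      s
    })
  })
  dat <- data.frame(t = t, y = y)
  best <- NULL; best_obj <- Inf
  for (s in starts) {
    if (fixed_gamma) {
      form <- y ~ n_s * exp(-(t / tau_s)^g0) + n_1 * exp(-t / tau_1)
      dat$g0 <- fix_gamma
      st <- s[c("n_s", "tau_s", "n_1", "tau_1")]
      lo <- lower[c("n_s", "tau_s", "n_1", "tau_1")]
      up <- upper[c("n_s", "tau_s", "n_1", "tau_1")]
    } else {
      form <- y ~ n_s * exp(-(t / tau_s)^gamma) + n_1 * exp(-t / tau_1)
      st <- s; lo <- lower; up <- upper
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = st, lower = lo, upper = up,
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      obj <- sum(stats::residuals(fit)^2)
      if (obj < best_obj) { best <- fit; best_obj <- obj }
    }
  }
  if (is.null(best)) {
    return(fit_failure("biexp_stretched",
                       c("n_s", "tau_s", "gamma", "n_1", "tau_1"),
                       "no restart converged"))
  }
  par <- stats::coef(best)
  se <- tryCatch(sqrt(diag(stats::vcov(best))), error = function(e) rep(NA_real_, length(par)))
  names(se) <- names(par)
  if (fixed_gamma) {
    par <- c(par, gamma = unname(fix_gamma))[c("n_s", "tau_s", "gamma", "n_1", "tau_1")]
    se <- c(se, gamma = 0)[c("n_s", "tau_s", "gamma", "n_1", "tau_1")]
  }
  reordered <- FALSE
  if (par["tau_s"] < par["tau_1"]) {
    # report the slow branch as tau_s; gamma stays with the reported slow one
    par[c("n_s", "tau_s", "n_1", "tau_1")] <- par[c("n_1", "tau_1", "n_s", "tau_s")]
    se[c("n_s", "tau_s", "n_1", "tau_1")] <- se[c("n_1", "tau_1", "n_s", "tau_s")]
    reordered <- TRUE
  }
  if (abs(par["n_s"] + par["n_1"] - 1) > 0.1) {
    hs_warn("amplitudes n_s + n_1 = %.3f deviate from 1 by more than 0.1",
            "hs_fit_warning", par["n_s"] + par["n_1"])
  }
  structure(list(model = "biexp_stretched", params = as.list(par),
                 param_uncertainty = as.list(se),
                 rms_residual = sqrt(best_obj / length(t)),
                 converged = TRUE, reordered = reordered, fit = best),
            class = "fit_result")
}

fit_failure <- function(model, param_names, reason) {
  na <- stats::setNames(as.list(rep(NA_real_, length(param_names))), param_names)
  structure(list(model = model, params = na, param_uncertainty = na,
                 rms_residual = NA_real_, converged = FALSE, reason = reason),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result [%s] converged=%s\n", x$model, x$converged))
  if (x$converged) {
    p <- unlist(x$params); s <- unlist(x$param_uncertainty)
    for (nm in names(p)) cat(sprintf("  %-6s %.6g +/- %.3g\n", nm, p[nm], s[nm]))
    cat(sprintf("  rms residual %.3g\n", x$rms_residual))
  } else cat(sprintf("  reason: %s\n", x$reason %||% "unknown"))
  invisible(x)
}

#' Water dipole unit vectors for one frame
#'
#' The geometric dipole direction of each water: the unit vector from the
#' oxygen along the bisector of the two O-H bonds (for 3-site SPC/E-like
#' waters this coincides with the charge dipole). Hydrogen positions are
#' taken relative to the oxygen under the minimum-image convention, so
#' molecules straddling the periodic boundary are handled correctly.
#'
#' @param traj `md_trajectory`.
#' @param frame frame index.
#' @return n_waters x 3 matrix of unit vectors; rownames are molecule ids.
#' @export
water_dipoles <- function(traj, frame = 1) {
  waters <- water_molecules(traj$topology, require_h = TRUE)
  if (!nrow(waters)) hs_stop("no complete water molecules in topology", "hs_topology_error")
  o <- matrix(traj$coords[waters$o, , frame], ncol = 3)
  h1 <- matrix(traj$coords[waters$h1, , frame], ncol = 3)
  h2 <- matrix(traj$coords[waters$h2, , frame], ncol = 3)
  v1 <- if (is.null(traj$box)) h1 - o else minimum_image(h1 - o, traj$box)
  v2 <- if (is.null(traj$box)) h2 - o else minimum_image(h2 - o, traj$box)
  v1 <- v1 / sqrt(rowSums(v1 * v1))
  v2 <- v2 / sqrt(rowSums(v2 * v2))
  mu <- v1 + v2
  mu <- mu / sqrt(rowSums(mu * mu))
  rownames(mu) <- waters$molecule_id
  mu
}

#' Dipole reorientation autocorrelation
#'
#' `C_mu(t) = < mu(t0) . mu(t0 + t) >`, the rank-1 orientational
#' correlation of water dipole unit vectors, averaged over waters and time
#' origins. Optionally restricted per origin to the waters inside a
#' hydration shell at that origin.
#'
#' @param traj `md_trajectory` with complete waters.
#' @param water_subset optional [shell_membership()]: at each origin only
#'   waters occupying the shell then are included.
#' @param max_lag maximum lag (ps).
#' @param origin_stride origin spacing in frames.
#' @return A `correlation_series` data.frame.
#' @export
dipole_autocorrelation <- function(traj, water_subset = NULL, max_lag,
                                   origin_stride = 1) {
  nf <- n_frames(traj)
  dt <- traj$dt
  lmax <- floor(max_lag / dt + 1e-9)
  if (lmax > nf - 1) hs_stop("max_lag exceeds trajectory span", "hs_parameter_error")
  dips <- lapply(seq_len(nf), function(f) water_dipoles(traj, f))
  nw <- nrow(dips[[1]])
  if (!is.null(water_subset)) {
    if (nrow(water_subset$occupancy) != nw) {
      hs_stop("shell membership water count does not match trajectory", "hs_parameter_error")
    }
  }
  origins <- seq(1, nf, by = origin_stride)
  vals <- numeric(lmax + 1); n_or <- integer(lmax + 1)
  for (l in 0:lmax) {
    o_ok <- origins[origins + l <= nf]
    acc <- 0; cnt <- 0L
    for (o in o_ok) {
      sel <- if (is.null(water_subset)) seq_len(nw) else which(water_subset$occupancy[, o] == 1L)
      if (!length(sel)) next
      acc <- acc + mean(rowSums(dips[[o]][sel, , drop = FALSE] *
                                  dips[[o + l]][sel, , drop = FALSE]))
      cnt <- cnt + 1L
    }
    if (cnt == 0L) hs_stop("empty water subset at every origin", "hs_analysis_error")
    vals[l + 1] <- acc / cnt
    n_or[l + 1] <- cnt
  }
  correlation_series((0:lmax) * dt, vals, n_or)
}

#' Fit a single-exponential reorientation decay
#'
#' Least-squares fit of `C_mu(t) = A_mu * exp(-t / t_mu)`; `t_mu` is the
#' characteristic reorientation time of the water dipoles.
#'
#' @param series `correlation_series` (>= 5 lag points).
#' @return `fit_result` with params `A_mu`, `t_mu`.
#' @export
fit_reorientation <- function(series) {
  t <- series$lag; y <- series$value
  keep <- is.finite(y)
  t <- t[keep]; y <- y[keep]
  if (length(t) < 5) hs_stop("need >= 5 lag points", "hs_parameter_error")
  if (max(y) - min(y) < 1e-3) {
    return(fit_failure("single_exp", c("A_mu", "t_mu"), "series shows no decay"))
  }
  if (mean(y > 0) < 0.5) {
    return(fit_failure("single_exp", c("A_mu", "t_mu"),
                       "non-positive values dominate the series"))
  }
  # log-linear start on the positive part
  pos <- y > 0.02 * max(y)
  lf <- stats::lm.fit(cbind(1, t[pos]), log(y[pos]))
  tau0 <- -1 / min(lf$coefficients[2], -1e-12)
  span <- max(t) - min(t)
  tau0 <- min(max(tau0, min(diff(t))), 100 * span)
  dat <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-t / tau), data = dat,
                      start = list(A = max(y), tau = tau0),
                      lower = c(A = 0, tau = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fit_failure("single_exp", c("A_mu", "t_mu"), "fit did not converge"))
  par <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(NA_real_, NA_real_))
  structure(list(model = "single_exp",
                 params = list(A_mu = unname(par["A"]), t_mu = unname(par["tau"])),
                 param_uncertainty = list(A_mu = unname(se[1]), t_mu = unname(se[2])),
                 rms_residual = sqrt(mean(stats::residuals(fit)^2)),
                 converged = TRUE, fit = fit),
            class = "fit_result")
}
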