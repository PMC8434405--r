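# Shell membership, residence correlation + stretched-exponential fit,
# dipole reorientation + exponential fit.

# minimal one-water + one-reference-site system at a chosen O distance
water_at <- function(dist, box = c(4, 4, 4)) {
  atoms <- data.frame(
    atom_id = 1:4,
    atom_name = c("NRF", "OW", "HW1", "HW2"),
    element = c("N", "O", "H", "H"),
    residue_id = c(1, 2, 2, 2),
    residue_name = c("REF", "SOL", "SOL", "SOL"))
  top <- topology(atoms, bonds = rbind(c(2L, 3L), c(2L, 4L)))
  xyz <- rbind(c(2, 2, 2), c(2 + dist, 2, 2),
               c(2 + dist + 0.07, 2.07, 2), c(2 + dist - 0.07, 2.07, 2))
  trajectory(top, array(xyz, c(4, 3, 1)), box)
}

test_that("shell membership honours the distance cutoff inclusively", {
  expect_equal(shell_membership(water_at(0.55), 1, 0.6)$occupancy[1, 1], 1L)
  expect_equal(shell_membership(water_at(0.65), 1, 0.6)$occupancy[1, 1], 0L)
  # boundary is inclusive: distance exactly at the cutoff counts as inside
  expect_equal(shell_membership(water_at(0.5), 1, 0.5)$occupancy[1, 1], 1L)
  # distances are minimum-image: a water across the boundary is near
  far <- water_at(3.8)  # 3.8 in a 4 nm box -> min-image distance 0.2
  expect_equal(shell_membership(far, 1, 0.6)$occupancy[1, 1], 1L)
  no_water <- make_point_traj(list(matrix(0, 2, 3)))
  expect_error(shell_membership(no_water, 1, 0.6), class = "hs_input_error")
})

test_that("residence correlation: trivial populations and oracle equality", {
  mk <- function(occ) {
    structure(list(water_ids = seq_len(nrow(occ)), oxygen_ids = seq_len(nrow(occ)),
                   occupancy = occ, cutoff = 0.6, reference_selection = 1L,
                   dt = 1, time = seq_len(ncol(occ)) - 1),
              class = "shell_membership")
  }
  all_on <- mk(matrix(1L, 4, 30))
  expect_equal(residence_correlation(all_on, window = 10)$value, rep(1, 11))
  # every water leaves after its first frame and never returns
  leave <- mk(rbind(c(1L, rep(0L, 9)), c(1L, rep(0L, 9))))
  cr <- residence_correlation(leave, window = 2)
  expect_equal(cr$value[1], 1)
  expect_equal(cr$value[2], 0)
  # estimator vs direct double loop, intermittent convention
  occ <- gen_two_state_series(8, 0.2, 0.8, 0.1, 60, seed = 5)
  m <- mk(matrix(as.integer(occ), nrow(occ)))
  m$dt <- 0.1
  for (stride in c(1, 4)) {
    got <- residence_correlation(m, window = 2, origin_stride = stride)
    want <- oracle_residence(m$occupancy, 0.1, 20, origin_stride = stride)
    expect_close(got$value, want, 1e-10)
  }
  expect_error(residence_correlation(mk(matrix(0L, 2, 10)), window = 3),
               class = "hs_analysis_error")
})

test_that("residence correlation matches the two-state closed form", {
  k_on <- 0.1; k_off <- 1.0; dt <- 0.05
  occ <- gen_two_state_series(1500, k_on, k_off, dt, 3000, seed = 13)
  m <- structure(list(water_ids = 1:1500, oxygen_ids = 1:1500,
                      occupancy = matrix(as.integer(occ), 1500), cutoff = 0.6,
                      reference_selection = 1L, dt = dt,
                      time = (0:2999) * dt), class = "shell_membership")
  cr <- residence_correlation(m, window = 1, origin_stride = 11)
  p <- k_on / (k_on + k_off)
  theo <- p + (1 - p) * exp(-(k_on + k_off) * cr$lag)
  expect_lt(max(abs(cr$value - theo)), 0.01)
})

test_that("stretched-exponential fit recovers exact model parameters", {
  t <- seq(0, 300, 0.5)
  truth <- c(n_s = 0.3, tau_s = 50, gamma = 0.8, n_1 = 0.7, tau_1 = 5)
  y <- truth["n_s"] * exp(-(t / truth["tau_s"])^truth["gamma"]) +
    truth["n_1"] * exp(-t / truth["tau_1"])
  cs <- data.frame(lag = t, value = y, n_origins = 1)
  fit <- fit_residence(cs)
  expect_true(fit$converged)
  got <- unlist(fit$params)[names(truth)]
  expect_true(all(abs(got - truth) / truth < 0.01))
  expect_gt(got["tau_s"], got["tau_1"])
  # pure single exponential: nested-model limit fits to the noise floor
  y1 <- exp(-t / 8)
  fit1 <- fit_residence(data.frame(lag = t, value = y1, n_origins = 1))
  expect_true(fit1$converged)
  expect_lt(fit1$rms_residual, 1e-6)
  # constant series: no decay, flagged unusable
  fitc <- fit_residence(data.frame(lag = t, value = rep(1, length(t)),
                                   n_origins = 1))
  expect_false(fitc$converged)
})

test_that("gamma can be pinned for the pure two-state mapping", {
  k <- 0.22
  t <- seq(0, 40, 0.2)
  y <- 1 / 11 + (10 / 11) * exp(-k * t)
  fit <- fit_residence(data.frame(lag = t, value = y, n_origins = 1),
                       fix_gamma = 1)
  expect_true(fit$converged)
  expect_lt(abs(1 / fit$params$tau_1 - k) / k, 0.10)
})

test_that("water dipoles: bisector geometry, periodic images, unit norm", {
  atoms <- data.frame(atom_id = 1:3, atom_name = c("OW", "HW1", "HW2"),
                      element = c("O", "H", "H"), residue_id = 1,
                      residue_name = "SOL")
  top <- topology(atoms, bonds = rbind(c(1L, 2L), c(1L, 3L)))
  xyz <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(0, 0.1, 0))
  tr <- trajectory(top, array(xyz, c(3, 3, 1)), c(5, 5, 5))
  mu <- water_dipoles(tr, 1)
  expect_close(mu[1, ], c(1, 1, 0) / sqrt(2), 1e-12)
  expect_lt(abs(sqrt(sum(mu^2)) - 1), 1e-12)
  # water straddling the boundary: same dipole as its re-imaged copy
  xyz2 <- rbind(c(4.95, 0, 0), c(0.05, 0, 0), c(4.95, 0.1, 0))
  tr2 <- trajectory(top, array(xyz2, c(3, 3, 1)), c(5, 5, 5))
  expect_close(water_dipoles(tr2, 1)[1, ], mu[1, ], 1e-12)
  # dipoles of a generated ensemble are unit norm
  ro <- gen_rotors(50, 0.05, 0.05, 3, seed = 9)
  norms <- sqrt(rowSums(water_dipoles(ro, 2)^2))
  expect_lt(max(abs(norms - 1)), 1e-12)
})

test_that("dipole autocorrelation: frozen, antipodal, oracle, closed form", {
  frozen <- gen_rotors(30, 0, 0.1, 20, seed = 4)
  cm <- dipole_autocorrelation(frozen, max_lag = 1)
  expect_equal(cm$value, rep(1, 11), tolerance = 1e-12)
  # single water flipped 180 degrees between frames
  atoms <- data.frame(atom_id = 1:3, atom_name = c("OW", "HW1", "HW2"),
                      element = c("O", "H", "H"), residue_id = 1,
                      residue_name = "SOL")
  top <- topology(atoms, bonds = rbind(c(1L, 2L), c(1L, 3L)))
  up <- rbind(c(1, 1, 1), c(1.07, 1.07, 1), c(0.93, 1.07, 1))
  dn <- rbind(c(1, 1, 1), c(1.07, 0.93, 1), c(0.93, 0.93, 1))
  tr <- trajectory(top, array(c(up, dn), c(3, 3, 2)), c(5, 5, 5))
  flip <- dipole_autocorrelation(tr, max_lag = 1)
  expect_equal(flip$value, c(1, -1), tolerance = 1e-12)
  # estimator vs direct double loop, with and without shell restriction
  ro <- gen_rotors(6, 0.08, 0.05, 40, seed = 6)
  dips <- lapply(1:40, function(f) water_dipoles(ro, f))
  for (stride in c(1, 3)) {
    got <- dipole_autocorrelation(ro, max_lag = 0.5, origin_stride = stride)
    want <- oracle_dipole_corr(dips, 10, origin_stride = stride)
    expect_close(got$value, want, 1e-10)
  }
  occ <- gen_two_state_series(6, 0.5, 0.5, 0.05, 40, seed = 7)
  mem <- structure(list(water_ids = 1:6, oxygen_ids = seq(1, 18, 3),
                        occupancy = matrix(as.integer(occ), 6), cutoff = 0.6,
                        reference_selection = 1L, dt = 0.05,
                        time = ro$time), class = "shell_membership")
  got <- dipole_autocorrelation(ro, water_subset = mem, max_lag = 0.5)
  want <- oracle_dipole_corr(dips, 10, occ = mem$occupancy)
  expect_close(got$value, want, 1e-10)
})

test_that("reorientation fit: exact exponential, rotor recovery, degeneracy", {
  t <- seq(0, 20, 0.5)
  fit <- fit_reorientation(data.frame(lag = t, value = exp(-t / 4.8),
                                      n_origins = 1))
  expect_true(fit$converged)
  expect_lt(abs(fit$params$t_mu - 4.8), 1e-6)
  expect_lt(abs(fit$params$A_mu - 1), 1e-6)
  const <- fit_reorientation(data.frame(lag = t, value = rep(0.8, length(t)),
                                        n_origins = 1))
  expect_false(const$converged)
  # parameter recovery from the rotor generator: t_mu = 1 / (2 D_rot)
  ro <- gen_rotors(600, 0.1, 0.05, 301, seed = 10)
  cm <- dipole_autocorrelation(ro, max_lag = 10, origin_stride = 15)
  rfit <- fit_reorientation(cm)
  expect_lt(abs(rfit$params$t_mu - 5) / 5, 0.05)
})
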