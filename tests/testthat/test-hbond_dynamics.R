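# Geometric H-bond detection and population kinetics.

# donor(O)-H ... acceptor(O) triple with tunable D-A distance and
# H-D-A angle (H placed off-axis by `angle` degrees at 0.1 nm)
dha_fixture <- function(da_dist, angle_deg, box = c(5, 5, 5)) {
  ang <- angle_deg * pi / 180
  atoms <- data.frame(atom_id = 1:3, atom_name = c("OD", "HD", "OA"),
                      element = c("O", "H", "O"),
                      residue_id = c(1, 1, 2), residue_name = c("R1", "R1", "HOH"),
                      stringsAsFactors = FALSE)
  top <- topology(atoms, bonds = cbind(1L, 2L))
  xyz <- rbind(c(1, 1, 1),
               c(1 + 0.1 * cos(ang), 1 + 0.1 * sin(ang), 1),
               c(1 + da_dist, 1, 1))
  trajectory(top, array(xyz, c(3, 3, 1)), box)
}

test_that("detection truth table at the 0.35 nm / 30 degree criterion", {
  b <- detect_hbonds(dha_fixture(0.30, 0))
  expect_equal(nrow(b), 1L)
  expect_equal(b$distance, 0.3)
  expect_equal(b$angle, 0, tolerance = 1e-8)
  expect_equal(nrow(detect_hbonds(dha_fixture(0.36, 0))), 0L)   # distance fail
  expect_equal(nrow(detect_hbonds(dha_fixture(0.30, 45))), 0L)  # angle fail
  # strict boundaries: exactly at the cutoffs is excluded
  expect_equal(nrow(detect_hbonds(dha_fixture(0.35, 0))), 0L)
  expect_equal(nrow(detect_hbonds(dha_fixture(0.30, 30))), 0L)
})

test_that("detection equals the all-triples oracle on random water boxes", {
  crit <- hbond_criterion()
  n_found <- 0L
  for (seed in c(1, 2, 3, 4)) {
    tr <- make_water_box(40, 1.4, seed)
    got <- detect_hbonds(tr, 1)
    gm <- matrix(as.integer(as.matrix(got[c("donor", "hydrogen", "acceptor")])),
                 ncol = 3)
    gm <- gm[order(gm[, 1], gm[, 2], gm[, 3]), , drop = FALSE]
    want <- oracle_hbonds(tr, 1, crit)
    storage.mode(want) <- "integer"
    expect_equal(unname(gm), unname(want))
    n_found <- n_found + nrow(want)
  }
  expect_gt(n_found, 10)  # the fixtures genuinely exercise the geometry
})

test_that("detection is invariant under rigid rotation plus translation", {
  tr <- make_water_box(30, 2.0, 17)
  before <- detect_hbonds(tr, 1)
  th <- 0.7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr2 <- tr
  tr2$box <- NULL  # rotation breaks box alignment; compare without PBC
  tr$box <- NULL
  xyz <- matrix(tr$coords[, , 1], ncol = 3)
  tr2$coords[, , 1] <- sweep(xyz %*% t(rot), 2, c(3, -1, 2), `+`)
  after <- detect_hbonds(tr2, 1)
  expect_equal(detect_hbonds(tr, 1)[c("donor", "hydrogen", "acceptor")],
               after[c("donor", "hydrogen", "acceptor")])
})

test_that("count series: permanent bond, empty system, crafted 2/3/4 bonds", {
  tr <- dha_fixture(0.30, 0)
  tr100 <- trajectory(tr$topology, array(rep(tr$coords[, , 1], 100),
                                         c(3, 3, 100)), tr$box)
  cs <- hbond_count_series(tr100, 1:2, 3)
  expect_equal(cs$mean, 1)
  expect_equal(cs$sd, 0)
  far <- dha_fixture(1.5, 0)
  expect_equal(hbond_count_series(far, 1:2, 3)$mean, 0)
  # crafted three-frame fixture with 2, 3, 4 bonds by construction:
  # four acceptors approach a 4-hydrogen donor center one at a time
  atoms <- data.frame(atom_id = 1:9,
                      atom_name = c("ND", rep("HD", 4), rep("OA", 4)),
                      element = c("N", rep("H", 4), rep("O", 4)),
                      residue_id = c(1, 1, 1, 1, 1, 2, 3, 4, 5),
                      residue_name = c(rep("R1", 5), rep("HOH", 4)))
  top <- topology(atoms, bonds = cbind(1L, 2:5))
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  mk_frame <- function(n_close) {
    xyz <- matrix(0, 9, 3)
    xyz[1, ] <- c(2, 2, 2)
    xyz[2:5, ] <- sweep(dirs * 0.1, 2, c(2, 2, 2), `+`)
    d <- ifelse(seq_len(4) <= n_close, 0.3, 1.4)
    xyz[6:9, ] <- sweep(dirs * d, 2, c(2, 2, 2), `+`)
    xyz
  }
  tr3 <- trajectory(top, array(c(mk_frame(2), mk_frame(3), mk_frame(4)),
                               c(9, 3, 3)), c(6, 6, 6))
  cs3 <- hbond_count_series(tr3, 1:5, 6:9)
  expect_equal(cs3$counts, c(2, 3, 4))
  expect_equal(cs3$mean, 3)
  expect_equal(cs3$sd, 1)
})

test_that("existence matrix tracks bonds per frame and matches detection", {
  tr <- dha_fixture(0.30, 0)
  near <- tr$coords[, , 1]
  away <- near; away[3, 1] <- near[3, 1] + 1  # acceptor pulled away
  tr3 <- trajectory(tr$topology, array(c(near, away, near), c(3, 3, 3)), tr$box)
  hb <- hbond_existence(tr3, 1:2, 3)
  expect_equal(nrow(hb$h), 1L)
  expect_equal(hb$h[1, ], c(1L, 0L, 1L))
  for (f in 1:3) {
    det <- detect_hbonds(tr3, f, 1:2, 3)
    expect_equal(hb$h[1, f], as.integer(nrow(det) > 0))
  }
  none <- hbond_existence(trajectory(tr$topology,
                                     array(away, c(3, 3, 1)), tr$box), 1:2, 3)
  expect_true(isTRUE(attr(none, "empty")))
})

test_that("continuous lifetime: single runs, censoring, dwell law", {
  row1 <- matrix(c(0, 1, 1, 1, 0), 1)
  expect_equal(continuous_lifetime(row1, dt = 1)$tau_hb, 3)
  rows <- rbind(c(0, 1, 0, 0, 0, 0), c(0, 1, 1, 1, 0, 0))
  expect_equal(continuous_lifetime(rows, dt = 1)$tau_hb, 2)
  # runs touching the ends are censored
  cens <- matrix(c(1, 1, 0, 1, 0, 1, 1), 1)
  expect_equal(continuous_lifetime(cens, dt = 1)$tau_hb, 1)
  expect_error(continuous_lifetime(matrix(c(1, 1, 1), 1), dt = 1),
               class = "hs_analysis_error")
  # dwell-time law on the two-state generator
  h <- gen_two_state_series(800, 0.1, 1.0, 0.01, 5000, seed = 19)
  expect_lt(abs(continuous_lifetime(h)$tau_hb - 1.0) / 1.0, 0.05)
})

test_that("intermittent correlation: permanence, oracle, bounds", {
  perm <- matrix(1L, 2, 50)
  ct <- intermittent_correlation(perm, max_lag = 20, dt = 1)
  expect_equal(ct$value, rep(1, 21))
  h <- gen_two_state_series(5, 0.3, 0.7, 0.1, 100, seed = 23)
  for (stride in c(1, 3)) {
    got <- intermittent_correlation(h, max_lag = 2, origin_stride = stride)
    want <- oracle_intermittent(h, 20, origin_stride = stride)
    expect_close(got$value, want, 1e-10)
  }
  expect_equal(got$value[1], 1)
  expect_true(all(got$value >= 0 & got$value <= 1))
  expect_error(intermittent_correlation(matrix(0L, 2, 10), max_lag = 3, dt = 1),
               class = "hs_analysis_error")
})

test_that("relaxation time: interpolated 1/e crossing and plateau error", {
  t <- seq(0, 40, 0.5)
  res <- relaxation_time(data.frame(lag = t, value = exp(-t / 10), n_origins = 1))
  expect_lt(abs(res$tau_r - 10), 0.05)
  expect_false(res$extrapolated)
  # symmetric two-state (p = 0.5): plateau above 1/e, no crossing
  plateau <- data.frame(lag = t, value = 0.5 + 0.5 * exp(-t / 2), n_origins = 1)
  expect_error(relaxation_time(plateau), "0.5", class = "hs_analysis_error")
  # extrapolation policy on a curve truncated before the crossing
  short <- data.frame(lag = seq(0, 3, 0.1), value = exp(-seq(0, 3, 0.1) / 10))
  ext <- relaxation_time(short, extrapolate = TRUE)
  expect_true(ext$extrapolated)
  expect_lt(abs(ext$tau_r - 10) / 10, 0.05)
})

test_that("tau_hb <= tau_r on intermittently re-forming two-state systems", {
  h <- gen_two_state_series(1000, 0.1, 1.0, 0.01, 4000, seed = 29)
  tau_hb <- continuous_lifetime(h)$tau_hb
  ct <- intermittent_correlation(h, max_lag = 1.5, origin_stride = 5)
  tau_r <- relaxation_time(ct)$tau_r
  expect_lte(tau_hb, tau_r)
})

test_that("shell water counts equal membership column sums", {
  tr <- gen_shell_system(12, 0.05, 0.3, 0.5, 4, 0.2, 40, seed = 31)
  swc <- shell_water_count(tr, 1, 0.5)
  mem <- shell_membership(tr, 1, 0.5)
  expect_equal(swc$counts, colSums(mem$occupancy))
  zero <- shell_water_count(tr, 1, 0)
  expect_true(all(zero$counts == 0))
})
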