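# Readers, periodic geometry, unwrapping, and tabular round trips.

write_gro_fixture <- function(path, box = "   7.00000   7.00000   7.00000",
                              t = NULL) {
  title <- if (is.null(t)) "water" else sprintf("water t= %.3f", t)
  writeLines(c(
    title,
    "    3",
    "    1SOL     OW    1   3.500   3.500   3.500",
    "    1SOL    HW1    2   3.580   3.560   3.500",
    "    1SOL    HW2    3   3.420   3.560   3.500",
    box), path)
}

write_pdb_fixture <- function(path, n_atoms = 3, conect = TRUE) {
  lines <- c(
    "CRYST1   70.000   70.000   70.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  O   HOH A   1      35.000  35.000  35.000  1.00  0.00           O",
    "ATOM      2  H1  HOH A   1      35.800  35.600  35.000  1.00  0.00           H",
    "ATOM      3  H2  HOH A   1      34.200  35.600  35.000  1.00  0.00           H")
  if (n_atoms > 3) {
    for (i in 4:n_atoms) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  C   UNK A%4d      %6.3f  10.000  10.000  1.00  0.00           C",
        i, i, 10 + i))
    }
  }
  if (conect) lines <- c(lines, "CONECT    1    2    3")
  writeLines(c(lines, "END"), path)
}

test_that("GRO reader recovers box, coordinates, and water chemistry", {
  f <- withr::local_tempfile(fileext = ".gro")
  write_gro_fixture(f)
  tr <- read_trajectory(f)
  expect_equal(tr$box, c(7, 7, 7))
  expect_equal(n_frames(tr), 1L)
  expect_equal(n_atoms(tr), 3L)
  expect_equal(frame_coords(tr, 1)[1, ], c(3.5, 3.5, 3.5))
  at <- tr$topology$atoms
  expect_equal(at$element, c("O", "H", "H"))
  # bond inference + role assignment: O is donor and acceptor, H flagged
  expect_true(at$is_donor[1]); expect_true(at$is_acceptor[1])
  expect_true(all(at$is_hydrogen[2:3]))
  expect_equal(nrow(tr$topology$bonds), 2L)
})

test_that("multi-frame GRO carries times and frames in order", {
  f <- withr::local_tempfile(fileext = ".gro")
  con <- file(f, "w")
  for (t in c(0, 10, 20)) {
    writeLines(c(sprintf("w t= %.1f", t), "    1",
                 sprintf("    1SOL     OW    1   %.3f   0.500   0.500", 0.5 + t / 100),
                 "   7.0   7.0   7.0"), con)
  }
  close(con)
  tr <- read_trajectory(f)
  expect_equal(n_frames(tr), 3L)
  expect_equal(tr$time, c(0, 10, 20))
  expect_equal(tr$dt, 10)
  expect_equal(tr$coords[1, 1, ], c(0.5, 0.6, 0.7))
})

test_that("PDB reader converts Angstrom to nm and honours CONECT", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_fixture(f)
  tr <- read_trajectory(f)
  expect_equal(tr$box, c(7, 7, 7))
  expect_equal(unname(frame_coords(tr, 1)[1, ]), c(3.5, 3.5, 3.5))
  at <- tr$topology$atoms
  expect_true(at$is_donor[1] && at$is_acceptor[1])
  expect_equal(sort(tr$topology$bonds[, 2]), c(2L, 3L))
})

test_that("atom-count mismatch and unsupported formats raise format errors", {
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_fixture(p, n_atoms = 5)
  g <- withr::local_tempfile(fileext = ".gro")
  write_gro_fixture(g)  # 3 atoms != 5
  expect_error(read_trajectory(p, g), class = "hs_format_error")
  expect_error(read_trajectory(p, "traj.xtc"), class = "hs_format_error")
  expect_error(read_trajectory("nope.gro"), class = "hs_io_error")
})

test_that("GRO write/read round-trips coordinates to format precision", {
  tr <- gen_brownian(20, 1e-3, 3, 1, 4, seed = 9)
  f <- withr::local_tempfile(fileext = ".gro")
  write_gro(tr, f)
  back <- read_trajectory(f)
  expect_lt(max(abs(back$coords - tr$coords)), 1e-3)
  expect_equal(back$box, tr$box)
  expect_equal(back$time, tr$time)
})

test_that("minimum-image displacement handles wrap-around and identity", {
  d <- minimum_image_displacement(c(0.1, 0, 0), c(6.9, 0, 0), c(7, 7, 7))
  expect_equal(d, c(-0.2, 0, 0))
  expect_equal(sqrt(sum(d^2)), 0.2)
  expect_equal(minimum_image_displacement(c(1, 2, 3), c(1, 2, 3), c(7, 7, 7)),
               c(0, 0, 0))
  # non-orthorhombic rejected
  bad <- matrix(c(7, 0.5, 0, 0, 7, 0, 0, 0, 7), 3, 3)
  expect_error(minimum_image_displacement(c(0, 0, 0), c(1, 1, 1), bad),
               class = "hs_box_error")
})

test_that("minimum-image displacement equals exhaustive 27-image search", {
  set.seed(41)
  box <- c(3.1, 4.7, 2.3)
  for (k in 1:60) {
    a <- runif(3, -5, 8); b <- runif(3, -5, 8)
    got <- minimum_image_displacement(a, b, box)
    want <- oracle_min_image(a %% box, b %% box, box)
    expect_close(got, want, 1e-12)
    # invariant: norm bounded by (sqrt(3)/2) * max edge
    expect_lte(sqrt(sum(got^2)), sqrt(3) / 2 * max(box) + 1e-12)
  }
})

test_that("unwrapping recovers constant-velocity and Brownian paths", {
  # +0.3 nm/frame in a 1 nm box
  xs <- lapply(0:4, function(t) matrix(c(0.3 * t %% 1, 0.5, 0.5), 1))
  tr <- make_point_traj(xs, box = c(1, 1, 1))
  tr$coords[1, 1, ] <- (0.3 * (0:4)) %% 1
  un <- unwrap_coordinates(tr)
  expect_equal(un$coords[1, 1, ], c(0, 0.3, 0.6, 0.9, 1.2))
  # already-unwrapped small motion: unchanged
  small <- make_point_traj(lapply(0:3, function(t) matrix(c(1 + 0.01 * t, 1, 1), 1)),
                           box = c(7, 7, 7))
  expect_equal(unwrap_coordinates(small)$coords, small$coords)
  # round trip on a Brownian walk
  tr2 <- gen_brownian(50, 5e-4, 2, 1, 200, seed = 12)
  un2 <- unwrap_coordinates(tr2)
  expect_lt(max(abs(un2$coords - attr(tr2, "unwrapped"))), 1e-9)
})

test_that("unwrapping warns when jumps reach half the box edge", {
  xs <- lapply(0:3, function(t) matrix(c((0.5 * t) %% 1, 0.2, 0.2), 1))
  tr <- make_point_traj(xs, box = c(1, 1, 1))
  expect_warning(unwrap_coordinates(tr), class = "hs_unwrap_warning")
})

test_that("write_series round-trips values and degenerate tables", {
  set.seed(5)
  tab <- data.frame(lag = 0:49, value = rnorm(50))
  for (fmt in c("csv", "tsv", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_series(tab, f, fmt, meta = c(seed = 5))
    back <- read_series(f)
    expect_lt(max(abs(back$value - tab$value)), 1e-12)
    expect_equal(back$lag, tab$lag)
  }
  # empty table -> header-only payload
  f <- withr::local_tempfile(fileext = ".csv")
  write_series(data.frame(a = numeric(0), b = numeric(0)), f, "csv")
  back <- read_series(f)
  expect_equal(nrow(back), 0L)
  expect_equal(names(back), c("a", "b"))
  # metadata header carries the tool stamp
  expect_true(any(grepl("hydrashell", attr(back, "meta"))))
  expect_error(write_series(tab, file.path(tempdir(), "no/such/dir/x.csv")),
               class = "hs_io_error")
})

test_that("selections resolve keywords and reject unknown ones", {
  tr <- gen_shell_system(5, 0.05, 0.3, 0.6, 4, 0.2, 3, seed = 2)
  expect_equal(select_atoms(tr, "water_oxygen"), attr(tr, "water_oxygens"))
  expect_equal(select_atoms(tr, "protein"), 1L)
  expect_length(select_atoms(tr, "water"), 15L)
  expect_error(select_atoms(tr, "bogus"), class = "hs_parameter_error")
  expect_error(select_atoms(tr, 999), class = "hs_parameter_error")
})
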