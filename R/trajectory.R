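#' Construct a topology
#'
#' A topology describes the static chemistry of a system: atom names,
#' elements, residue membership, covalent bonds, and hydrogen-bonding roles
#' (donor / acceptor / hydrogen flags). All estimators in the package take
#' their chemical information from this object.
#'
#' @param atoms data.frame with columns `atom_id` (1-based, contiguous
#'   integers), `atom_name`, `element`, `residue_id`, `residue_name`.
#'   Optional columns `molecule_id`, `is_hydrogen`, `is_donor`,
#'   `is_acceptor` are derived if absent.
#' @param bonds two-column integer matrix of bonded atom-id pairs (may have
#'   zero rows). If `NULL`, no bonds are recorded; see
#'   [infer_bonds()] for the distance heuristic.
#' @param infer logical; derive missing `molecule_id` (connected components
#'   of the bond graph) and hydrogen/donor/acceptor flags (N and O atoms are
#'   acceptors; N/O with at least one bonded H are donors).
#'
#' @return An object of class `topology`: a list with elements `atoms`
#'   (data.frame) and `bonds` (integer matrix).
#' @export
topology <- function(atoms, bonds = NULL, infer = TRUE) {
  required <- c("atom_id", "atom_name", "element", "residue_id", "residue_name")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    hs_stop("topology atoms missing column(s): %s", "hs_format_error",
            paste(missing_cols, collapse = ", "))
  }
  n <- nrow(atoms)
  if (n > 0 && !identical(as.integer(atoms$atom_id), seq_len(n))) {
    hs_stop("atom ids must be unique and contiguous from 1", "hs_format_error")
  }
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) && (any(bonds < 1) || any(bonds > n))) {
    hs_stop("bond indices out of range", "hs_format_error")
  }
  atoms$atom_name <- as.character(atoms$atom_name)
  atoms$element <- as.character(atoms$element)
  atoms$residue_name <- as.character(atoms$residue_name)
  top <- structure(list(atoms = atoms, bonds = bonds), class = "topology")
  if (infer) top <- assign_roles(top)
  top
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d residues, %d bonds\n",
              nrow(x$atoms), length(unique(x$atoms$residue_id)), nrow(x$bonds)))
  invisible(x)
}

#' Number of atoms
#' @param x a `topology` or `md_trajectory`.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) UseMethod("n_atoms")
#' @export
n_atoms.topology <- function(x) nrow(x$atoms)
#' @export
n_atoms.md_trajectory <- function(x) nrow(x$topology$atoms)

# Covalent radii (nm) for the elements that occur in biomolecular systems.
covalent_radius <- c(H = 0.031, C = 0.076, N = 0.071, O = 0.066, S = 0.105,
                     P = 0.107, F = 0.057, CL = 0.102, NA. = 0.166, K = 0.203,
                     MG = 0.141, CA = 0.176, ZN = 0.122, FE = 0.132)

#' Infer covalent bonds from interatomic distances
#'
#' Bonds are assigned between atom pairs closer than 1.2 times the sum of
#' their covalent radii. Intended for files lacking connectivity records
#' (e.g. PDB waters without CONECT lines). Distances use the minimum-image
#' convention when a periodic box is supplied.
#'
#' @param top topology.
#' @param xyz n_atoms x 3 coordinate matrix (nm).
#' @param box optional box edge lengths (nm) for periodic distances.
#' @param scale multiplier on the covalent-radius sum (default 1.2).
#' @return The topology with its `bonds` matrix replaced.
#' @export
infer_bonds <- function(top, xyz, box = NULL, scale = 1.2) {
  n <- n_atoms(top)
  if (n < 2) { top$bonds <- matrix(integer(0), ncol = 2); return(top) }
  el <- toupper(top$atoms$element)
  rad <- unname(covalent_radius[el])
  rad[is.na(rad)] <- 0.077  # fallback: carbon-like
  pairs <- list()
  # all-pairs scan, vectorized per row; adequate for the system sizes this
  # package targets (bond inference is only needed when records are absent)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d <- xyz[j, , drop = FALSE]
    d <- sweep(d, 2, xyz[i, ])
    if (!is.null(box)) d <- minimum_image(d, box)
    dist2 <- rowSums(d * d)
    cut <- (scale * (rad[i] + rad[j]))^2
    hit <- j[dist2 > 1e-12 & dist2 <= cut]
    if (length(hit)) pairs[[length(pairs) + 1L]] <- cbind(i, hit)
  }
  top$bonds <- if (length(pairs)) do.call(rbind, pairs) else matrix(integer(0), ncol = 2)
  storage.mode(top$bonds) <- "integer"
  assign_roles(top)
}

# Derive molecule ids (bond-graph components) and H/donor/acceptor flags.
assign_roles <- function(top) {
  at <- top$atoms
  n <- nrow(at)
  # union-find over bonds
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(top$bonds)) {
    for (k in seq_len(nrow(top$bonds))) {
      a <- find(top$bonds[k, 1]); b <- find(top$bonds[k, 2])
      if (a != b) parent[a] <- b
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  at$molecule_id <- match(comp, unique(comp))
  el <- toupper(at$element)
  at$is_hydrogen <- el == "H"
  bonded_h <- rep(FALSE, n)
  if (nrow(top$bonds)) {
    b1 <- top$bonds[, 1]; b2 <- top$bonds[, 2]
    heavy_with_h <- c(b1[at$is_hydrogen[b2]], b2[at$is_hydrogen[b1]])
    bonded_h[unique(heavy_with_h)] <- TRUE
  }
  at$is_acceptor <- el %in% c("N", "O")
  at$is_donor <- at$is_acceptor & bonded_h
  top$atoms <- at
  top
}

# Bonded hydrogens of each donor atom; list indexed by donor atom id.
bonded_hydrogens <- function(top, donors) {
  b <- top$bonds
  ish <- top$atoms$is_hydrogen
  out <- vector("list", length(donors))
  names(out) <- as.character(donors)
  if (!nrow(b)) return(out)
  h1 <- b[ish[b[, 2]], , drop = FALSE]  # (heavy, H)
  h2 <- b[ish[b[, 1]], 2:1, drop = FALSE]
  hb <- rbind(h1, h2)
  for (k in seq_along(donors)) out[[k]] <- hb[hb[, 1] == donors[k], 2]
  out
}

water_residue_names <- c("SOL", "HOH", "WAT", "TIP3", "TIP4", "TIP5", "SPC", "SPCE", "W")

is_water_atom <- function(top) toupper(top$atoms$residue_name) %in% water_residue_names

#' Construct a trajectory
#'
#' The central container: a topology plus a time-ordered stack of coordinate
#' frames in a periodic (orthorhombic) box. Coordinates are in nm, times in
#' ps, following the GROMACS convention; values from formats in Angstrom
#' are converted by the readers (0.1 nm/A).
#'
#' @param top topology.
#' @param coords numeric array of dimension `c(n_atoms, 3, n_frames)`, nm.
#' @param box length-3 numeric, orthorhombic box edge lengths (nm), or
#'   `NULL` for a non-periodic system. A 3x3 matrix is accepted if diagonal.
#' @param time frame times (ps); defaults to `0:(n_frames-1)`. Must be
#'   strictly increasing and uniformly spaced.
#'
#' @return Object of class `md_trajectory`: list with elements `topology`,
#'   `coords`, `box`, `time`, `dt`.
#' @export
trajectory <- function(top, coords, box = NULL, time = NULL) {
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  d <- dim(coords)
  if (length(d) != 3L || d[2] != 3L) {
    hs_stop("coords must be an n_atoms x 3 x n_frames array", "hs_format_error")
  }
  if (d[1] != n_atoms(top)) {
    hs_stop("coordinate matrix has %d atoms but topology has %d",
            "hs_format_error", d[1], n_atoms(top))
  }
  box <- check_box(box)
  nf <- d[3]
  if (is.null(time)) time <- as.numeric(seq_len(nf) - 1L)
  if (length(time) != nf) hs_stop("time vector length != frame count", "hs_format_error")
  dt <- NA_real_
  if (nf >= 2) {
    steps <- diff(time)
    if (any(steps <= 0)) hs_stop("frame times must be strictly increasing", "hs_format_error")
    if (diff(range(steps)) > 1e-6) {
      hs_stop("frame times must be uniformly spaced (within 1e-6 ps)", "hs_format_error")
    }
    dt <- mean(steps)
  }
  structure(list(topology = top, coords = coords, box = box,
                 time = as.numeric(time), dt = dt),
            class = "md_trajectory")
}

check_box <- function(box) {
  if (is.null(box)) return(NULL)
  if (is.matrix(box)) {
    if (!all(dim(box) == c(3, 3))) hs_stop("box matrix must be 3x3", "hs_format_error")
    off <- box; diag(off) <- 0
    if (any(abs(off) > 1e-9)) {
      hs_stop("only orthorhombic (diagonal) boxes are supported", "hs_box_error")
    }
    box <- diag(box)
  }
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
    hs_stop("box edges must be three positive finite lengths (nm)", "hs_box_error")
  }
  box
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d atoms, %d frames, dt = %s ps, box = %s\n",
              n_atoms(x), n_frames(x),
              if (is.na(x$dt)) "NA" else format(x$dt),
              if (is.null(x$box)) "none" else paste(format(x$box), collapse = " x ")))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Coordinates of one frame
#' @param traj an `md_trajectory`.
#' @param i frame index (1-based).
#' @return n_atoms x 3 matrix (nm).
#' @export
frame_coords <- function(traj, i) {
  if (!is_count(i) || i < 1 || i > n_frames(traj)) {
    hs_stop("frame index %s out of range", "hs_parameter_error", format(i))
  }
  traj$coords[, , i, drop = TRUE]
}

#' Select atoms by role, name, or element
#'
#' Resolves a selection to 1-based atom indices. Keywords: `"all"`,
#' `"protein"` (non-water, non-ion residues), `"water"`, `"water_oxygen"`,
#' `"heavy"` (non-hydrogen), `"protein_heavy"`, `"ca"` (alpha carbons),
#' `"donors"`, `"acceptors"`. Alternatively pass an integer vector of atom
#' ids (returned as-is after range checking), or a list with any of
#' `residue_name`, `residue_id`, `atom_name`, `element` to intersect.
#'
#' @param traj `md_trajectory` (or a `topology`).
#' @param what keyword string, integer vector, or criterion list.
#' @return Sorted integer vector of atom indices.
#' @export
select_atoms <- function(traj, what = "all") {
  top <- if (inherits(traj, "md_trajectory")) traj$topology else traj
  at <- top$atoms
  n <- nrow(at)
  if (is.numeric(what)) {
    idx <- as.integer(what)
    if (length(idx) && (min(idx) < 1 || max(idx) > n)) {
      hs_stop("atom indices out of range 1..%d", "hs_parameter_error", n)
    }
    return(sort(unique(idx)))
  }
  if (is.list(what)) {
    keep <- rep(TRUE, n)
    known <- c("residue_name", "residue_id", "atom_name", "element")
    bad <- setdiff(names(what), known)
    if (length(bad)) hs_stop("unknown selection key(s): %s", "hs_parameter_error",
                             paste(bad, collapse = ", "))
    for (k in names(what)) keep <- keep & (at[[k]] %in% what[[k]])
    return(which(keep))
  }
  water <- is_water_atom(top)
  ion <- toupper(at$residue_name) %in% c("NA", "CL", "K", "MG", "CA", "ZN", "NA+", "CL-")
  switch(what,
    all = seq_len(n),
    protein = which(!water & !ion),
    water = which(water),
    water_oxygen = which(water & toupper(at$element) == "O"),
    heavy = which(!at$is_hydrogen),
    protein_heavy = which(!water & !ion & !at$is_hydrogen),
    ca = which(!water & at$atom_name == "CA"),
    donors = which(at$is_donor),
    acceptors = which(at$is_acceptor),
    hs_stop("unknown selection keyword '%s'", "hs_parameter_error", what)
  )
}

# Water molecules: returns list(molecule_id, o, h1, h2 indices) for waters
# with exactly one O; malformed waters reported by the caller as needed.
water_molecules <- function(top, require_h = FALSE) {
  at <- top$atoms
  w <- which(is_water_atom(top))
  if (!length(w)) return(data.frame(molecule_id = integer(0), o = integer(0),
                                    h1 = integer(0), h2 = integer(0)))
  # group waters by residue_id (one residue per water in all common formats)
  key <- paste(at$residue_id[w], at$molecule_id[w])
  grp <- split(w, key)
  res <- lapply(grp, function(idx) {
    o <- idx[toupper(at$element[idx]) == "O"]
    h <- idx[toupper(at$element[idx]) == "H"]
    if (length(o) != 1L) return(NULL)
    if (require_h && length(h) != 2L) return(list(bad = idx))
    c(mol = at$molecule_id[o], o = o,
      h1 = if (length(h) >= 1) h[1] else NA_integer_,
      h2 = if (length(h) >= 2) h[2] else NA_integer_)
  })
  bad <- Filter(function(x) is.list(x) && !is.null(x$bad), res)
  if (length(bad)) {
    hs_stop("malformed water molecule(s) (need 1 O + 2 H): atoms %s",
            "hs_topology_error",
            paste(unlist(lapply(bad, `[[`, "bad")), collapse = ", "))
  }
  res <- do.call(rbind, Filter(Negate(is.null), res))
  out <- data.frame(molecule_id = res[, "mol"], o = res[, "o"],
                    h1 = res[, "h1"], h2 = res[, "h2"])
  out[order(out$o), , drop = FALSE]
}

# Guess the chemical element from a PDB/GRO atom name.
element_from_name <- function(name) {
  name <- toupper(trimws(name))
  first <- substr(gsub("^[0-9']+", "", name), 1, 1)
  two <- substr(gsub("^[0-9']+", "", name), 1, 2)
  ifelse(two %in% c("CL", "BR", "MG", "ZN", "FE", "MN") & nchar(name) <= 2, two,
         ifelse(first %in% c("H", "C", "N", "O", "S", "P", "F", "K", "I"), first, first))
}
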