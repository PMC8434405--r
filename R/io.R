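#' Read a trajectory from standard structure/trajectory files
#'
#' Builds an [trajectory()] from a coordinate file (PDB or GRO; single or
#' multi frame) and, optionally, a separate trajectory file (multi-frame
#' GRO or PDB, or binary DCD). Elements are inferred from atom names when
#' the file does not record them; covalent bonds are taken from CONECT
#' records when present and otherwise inferred by a covalent-radius
#' distance heuristic on the first frame. All coordinates are converted to
#' nm, times to ps.
#'
#' @param coordinate_path PDB or GRO file defining the topology (and one or
#'   more frames).
#' @param trajectory_path optional GRO/PDB/DCD file supplying the frames;
#'   must match the topology atom count. XTC is not supported and raises a
#'   format error.
#' @param dt frame spacing in ps, used when the files carry no time stamps
#'   (default 1 ps).
#' @return An `md_trajectory`.
#' @export
read_trajectory <- function(coordinate_path, trajectory_path = NULL, dt = 1) {
  if (!file.exists(coordinate_path)) {
    hs_stop("cannot read coordinate file '%s'", "hs_io_error", coordinate_path)
  }
  ext <- tolower(tools::file_ext(coordinate_path))
  base <- switch(ext,
    gro = read_gro(coordinate_path, dt = dt),
    pdb = read_pdb_file(coordinate_path, dt = dt),
    hs_stop("unsupported coordinate format '.%s' (need .pdb or .gro)",
            "hs_format_error", ext)
  )
  if (is.null(trajectory_path)) return(base)
  text <- tolower(tools::file_ext(trajectory_path))
  if (text == "xtc") {
    hs_stop(paste0("XTC input is not supported (compressed XDR binary); ",
                   "convert to DCD or multi-frame GRO/PDB"), "hs_format_error")
  }
  if (!file.exists(trajectory_path)) {
    hs_stop("cannot read trajectory file '%s'", "hs_io_error", trajectory_path)
  }
  frames <- switch(text,
    gro = read_gro(trajectory_path, dt = dt),
    pdb = read_pdb_file(trajectory_path, dt = dt),
    dcd = read_dcd_file(trajectory_path, dt = dt, fallback_box = base$box),
    hs_stop("unsupported trajectory format '.%s'", "hs_format_error", text)
  )
  if (n_atoms(frames) != n_atoms(base)) {
    hs_stop("atom-count mismatch: topology has %d atoms, trajectory has %d",
            "hs_format_error", n_atoms(base), n_atoms(frames))
  }
  trajectory(base$topology, frames$coords, frames$box %||% base$box, frames$time)
}

# --- GRO (hand-parsed: fixed columns, nm units; no installed R reader) ----

read_gro <- function(path, dt = 1) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); times <- numeric(0); boxes <- list()
  i <- 1L; nframe <- 0L
  atoms_df <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    if (i + 1L > length(lines)) hs_stop("truncated GRO file at frame %d", "hs_io_error", nframe + 1L)
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat < 0) hs_stop("bad atom count at frame %d of '%s'",
                                       "hs_format_error", nframe + 1L, path)
    if (i + 1L + nat + 1L > length(lines)) {
      hs_stop("truncated GRO file at frame %d", "hs_io_error", nframe + 1L)
    }
    al <- lines[(i + 2L):(i + 1L + nat)]
    xyz <- cbind(as.numeric(substr(al, 21, 28)),
                 as.numeric(substr(al, 29, 36)),
                 as.numeric(substr(al, 37, 44)))
    if (anyNA(xyz)) hs_stop("unparseable coordinates at frame %d of '%s'",
                            "hs_io_error", nframe + 1L, path)
    if (is.null(atoms_df)) {
      name <- trimws(substr(al, 11, 15))
      atoms_df <- data.frame(
        atom_id = seq_len(nat),
        atom_name = name,
        element = element_from_name(name),
        residue_id = as.integer(substr(al, 1, 5)),
        residue_name = trimws(substr(al, 6, 10)),
        stringsAsFactors = FALSE)
    }
    bl <- as.numeric(strsplit(trimws(lines[i + 2L + nat]), "\\s+")[[1]])
    if (length(bl) < 3 || anyNA(bl[1:3])) {
      hs_stop("bad box line at frame %d of '%s'", "hs_format_error", nframe + 1L, path)
    }
    if (length(bl) > 3 && any(abs(bl[-(1:3)]) > 1e-9)) {
      hs_stop("only orthorhombic boxes are supported (triclinic GRO box)", "hs_box_error")
    }
    nframe <- nframe + 1L
    frames[[nframe]] <- xyz
    boxes[[nframe]] <- bl[1:3]
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    times[nframe] <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else NA_real_
    i <- i + nat + 3L
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (nframe == 0L) hs_stop("no frames found in '%s'", "hs_io_error", path)
  coords <- array(unlist(frames), c(nrow(frames[[1]]), 3, nframe))
  box <- boxes[[1]]
  if (all(box == 0)) box <- NULL
  time <- if (anyNA(times)) (seq_len(nframe) - 1) * dt else times
  top <- topology(atoms_df, bonds = NULL, infer = FALSE)
  top <- infer_bonds(top, coords[, , 1], box = box)
  trajectory(top, coords, box, time)
}

#' Write a trajectory as (multi-frame) GRO
#'
#' @param traj an `md_trajectory`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_gro <- function(traj, path) {
  at <- traj$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  box <- traj$box %||% c(0, 0, 0)
  for (f in seq_len(n_frames(traj))) {
    xyz <- matrix(traj$coords[, , f], ncol = 3)
    writeLines(sprintf("hydrashell t= %.5f", traj$time[f]), con)
    writeLines(sprintf("%d", nrow(at)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       at$residue_id %% 100000L, substr(at$residue_name, 1, 5),
                       substr(at$atom_name, 1, 5), at$atom_id %% 100000L,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]), con)
  }
  invisible(path)
}

# --- PDB via bio3d (Angstrom -> nm) ---------------------------------------

read_pdb_file <- function(path, dt = 1) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) hs_stop("failed to parse PDB '%s': %s",
                                              "hs_io_error", path, conditionMessage(e)))
  at <- pdb$atom
  nat <- nrow(at)
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(!nzchar(trimws(el)))) {
    el <- element_from_name(at$elety)
  } else {
    el <- toupper(trimws(el))
    el[!nzchar(el) | is.na(el)] <- element_from_name(at$elety[!nzchar(el) | is.na(el)])
  }
  atoms_df <- data.frame(
    atom_id = seq_len(nat), atom_name = trimws(at$elety), element = el,
    residue_id = at$resno, residue_name = trimws(at$resid),
    stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  coords <- array(0, c(nat, 3, nf))
  for (f in seq_len(nf)) coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) * 0.1
  box <- read_cryst1(path)
  bonds <- read_conect(path)
  top <- topology(atoms_df, bonds = bonds, infer = !is.null(bonds))
  if (is.null(bonds)) top <- infer_bonds(top, coords[, , 1], box = box)
  trajectory(top, coords, box, (seq_len(nf) - 1) * dt)
}

# CRYST1 record: a, b, c (Angstrom) and angles; nm on return.
read_cryst1 <- function(path) {
  ln <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (!length(ln)) return(NULL)
  ln <- ln[1]
  abc <- suppressWarnings(as.numeric(c(substr(ln, 7, 15), substr(ln, 16, 24),
                                       substr(ln, 25, 33))))
  ang <- suppressWarnings(as.numeric(c(substr(ln, 34, 40), substr(ln, 41, 47),
                                       substr(ln, 48, 54))))
  if (anyNA(abc) || any(abc <= 0)) return(NULL)
  if (!anyNA(ang) && any(abs(ang - 90) > 1e-6)) {
    hs_stop("only orthorhombic boxes are supported (CRYST1 angles != 90)", "hs_box_error")
  }
  abc * 0.1
}

# CONECT records: serial numbers, columns of width 5 after the tag.
read_conect <- function(path) {
  lines <- grep("^CONECT", readLines(path, warn = FALSE), value = TRUE)
  if (!length(lines)) return(NULL)
  pairs <- list()
  for (ln in lines) {
    flds <- suppressWarnings(as.integer(substring(ln, seq(7, 27, 5), seq(11, 31, 5))))
    flds <- flds[!is.na(flds)]
    if (length(flds) >= 2) {
      pairs[[length(pairs) + 1L]] <- cbind(flds[1], flds[-1])
    }
  }
  if (!length(pairs)) return(NULL)
  b <- do.call(rbind, pairs)
  b <- t(apply(b, 1, sort))
  unique(b)
}

# --- DCD via bio3d --------------------------------------------------------

read_dcd_file <- function(path, dt = 1, fallback_box = NULL) {
  xyz <- tryCatch(suppressWarnings(bio3d::read.dcd(path, verbose = FALSE)),
                  error = function(e) hs_stop("failed to read DCD '%s': %s",
                                              "hs_io_error", path, conditionMessage(e)))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz); nat <- ncol(xyz) / 3
  coords <- array(0, c(nat, 3, nf))
  for (f in seq_len(nf)) coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) * 0.1
  top <- topology(data.frame(atom_id = seq_len(nat), atom_name = "X", element = "C",
                             residue_id = seq_len(nat), residue_name = "UNK",
                             stringsAsFactors = FALSE))
  trajectory(top, coords, fallback_box, (seq_len(nf) - 1) * dt)
}

# --- Tabular output -------------------------------------------------------

#' Write a named-column table with a metadata header
#'
#' Writes CSV/TSV (with `#`-prefixed metadata lines: package version plus
#' any caller-supplied key/value pairs) or JSON. Values survive a write/read
#' round trip to full double precision.
#'
#' @param table data.frame (or list of equal-length columns).
#' @param path output file.
#' @param format one of `"csv"`, `"tsv"`, `"json"`.
#' @param meta optional named character/numeric vector recorded in the
#'   header (e.g. parameters, seed, config hash).
#' @return Invisibly, `path`.
#' @export
write_series <- function(table, path, format = c("csv", "tsv", "json"), meta = NULL) {
  format <- match.arg(format)
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (nrow(table) && length(unique(vapply(table, length, 1L))) != 1L) {
    hs_stop("columns must have equal length", "hs_parameter_error")
  }
  meta_all <- c(tool = paste0("hydrashell ", as.character(utils::packageVersion("hydrashell"))),
                meta)
  ok <- tryCatch(suppressWarnings({
    if (format == "json") {
      jsonlite::write_json(list(meta = as.list(meta_all), data = table), path,
                           digits = NA, auto_unbox = TRUE, pretty = TRUE)
    } else {
      sep <- if (format == "csv") "," else "\t"
      con <- file(path, "w")
      on.exit(close(con), add = TRUE)
      writeLines(sprintf("# %s: %s", names(meta_all), as.character(meta_all)), con)
      fmt <- as.data.frame(lapply(table, function(col) {
        if (is.double(col)) sprintf("%.17g", col) else as.character(col)
      }), stringsAsFactors = FALSE, check.names = FALSE)
      names(fmt) <- names(table)
      utils::write.table(fmt, con, sep = sep, row.names = FALSE, quote = FALSE)
    }
    TRUE
  }), error = function(e) e)
  if (!isTRUE(ok)) hs_stop("cannot write '%s': %s", "hs_io_error", path,
                           conditionMessage(ok))
  invisible(path)
}

#' Read a table written by [write_series()]
#'
#' @param path file written by [write_series()].
#' @param format format; inferred from the extension when `NULL`.
#' @return data.frame (metadata available as attribute `"meta"`).
#' @export
read_series <- function(path, format = NULL) {
  if (!file.exists(path)) hs_stop("cannot read '%s'", "hs_io_error", path)
  format <- format %||% tolower(tools::file_ext(path))
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    out <- as.data.frame(obj$data, stringsAsFactors = FALSE)
    attr(out, "meta") <- obj$meta
    return(out)
  }
  sep <- if (format == "tsv") "\t" else ","
  lines <- readLines(path, warn = FALSE)
  meta <- sub("^# ", "", grep("^#", lines, value = TRUE))
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  out <- utils::read.table(text = body, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  attr(out, "meta") <- meta
  out
}
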