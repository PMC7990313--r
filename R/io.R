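#' Read a structure file into an `md_system`
#'
#' Reads PDB (via bio3d) or GROMACS GRO files. PDB coordinates (Angstrom) are
#' converted to nm; GRO is natively nm. Chain species are inferred by exact
#' sequence match against the built-in Abeta42/Abeta40/SST14/AVP sequences;
#' anything else is classified `OTHER`. Alternate locations other than
#' blank/'A' are dropped.
#'
#' @param path Path to the file.
#' @param format `"pdb"` or `"gro"`; guessed from the file extension when
#'   omitted.
#' @return An [md_system].
#' @export
read_structure <- function(path, format = NULL) {
  format <- format %||% guess_format(path)
  switch(format,
    pdb = read_pdb_system(path),
    gro = read_gro_system(path),
    abort(sprintf("unsupported structure format '%s'", format))
  )
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) "pdb"
  else if (ext == "gro") "gro"
  else if (ext == "xtc") "xtc"
  else if (ext == "dcd") "dcd"
  else abort(sprintf("cannot guess format from extension '.%s'", ext))
}

## Validate coordinate fields of ATOM/HETATM records so a malformed file
## fails with the offending line number rather than deep inside the parser.
validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) abort(sprintf("'%s' is empty", path))
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) abort(sprintf("'%s' contains no ATOM/HETATM records", path))
  for (i in which(rec)) {
    xyz <- suppressWarnings(as.numeric(c(
      substr(lines[i], 31, 38), substr(lines[i], 39, 46),
      substr(lines[i], 47, 54)
    )))
    if (anyNA(xyz)) {
      abort(sprintf("malformed coordinate fields at line %d of '%s'", i, path))
    }
  }
  invisible(lines)
}

## Element from PDB atom name by the standard convention: strip leading
## digits, first character is the element (peptide atoms only ever need
## one-letter elements here).
element_from_name <- function(name) {
  toupper(substr(gsub("^[0-9]+", "", trimws(name)), 1, 1))
}

read_pdb_system <- function(path) {
  validate_pdb_lines(path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  elem <- trimws(at$elesy %||% "")
  if (length(elem) == 0) elem <- rep("", nrow(at))
  elem[is.na(elem) | elem == ""] <-
    element_from_name(at$elety[is.na(elem) | elem == ""])
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  atoms <- tibble::tibble(
    name = trimws(at$elety), element = toupper(elem),
    resid = at$resno, resname = trimws(at$resid), chain = chain
  )
  atoms <- renumber_residues(atoms)
  md_system(atoms, cbind(at$x, at$y, at$z) / 10)
}

## Residue numbering within a chain made contiguous from 1, preserving order
renumber_residues <- function(atoms) {
  for (lab in unique(atoms$chain)) {
    sel <- atoms$chain == lab
    r <- atoms$resid[sel]
    atoms$resid[sel] <- cumsum(c(TRUE, diff(r) != 0))
  }
  atoms
}

read_gro_system <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) abort(sprintf("'%s' is not a valid GRO file", path))
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) abort(sprintf("malformed atom count at line 2 of '%s'", path))
  if (length(lines) < 2 + n + 1) {
    abort(sprintf("'%s' truncated: expected %d atom lines", path, n))
  }
  al <- lines[3:(2 + n)]
  resno <- suppressWarnings(as.integer(substr(al, 1, 5)))
  resnm <- trimws(substr(al, 6, 10))
  atnm <- trimws(substr(al, 11, 15))
  x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
  bad <- which(is.na(resno) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad)) {
    abort(sprintf("malformed GRO record at line %d of '%s'", bad[1] + 2, path))
  }
  ## GRO has no chain labels: start a new chain whenever the residue number
  ## decreases or jumps backwards
  newchain <- c(TRUE, diff(resno) < 0)
  chain_id <- cumsum(newchain)
  chain <- LETTERS[(chain_id - 1) %% 26 + 1]
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[2 + n + 1]),
                                              "\\s+")[[1]][1:3]))
  if (anyNA(box) || all(box == 0)) box <- NULL
  atoms <- tibble::tibble(
    name = atnm, element = element_from_name(atnm),
    resid = resno, resname = resnm, chain = chain
  )
  atoms <- renumber_residues(atoms)
  md_system(atoms, cbind(x, y, z), box = box)
}

#' Write a system or trajectory as PDB
#'
#' Writes fixed-width PDB; multi-frame input produces MODEL/ENDMDL blocks.
#' Coordinates are converted from nm to Angstrom.
#'
#' @param x An [md_system] or [md_trajectory].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "md_trajectory")) {
    system <- x$system
    frames <- lapply(seq_len(n_frames(x)), function(t) frame_xyz(x, t))
  } else {
    system <- x
    frames <- list(system$xyz)
  }
  a <- system$atoms
  name4 <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
  name4 <- formatC(name4, width = -4)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1
  for (t in seq_along(frames)) {
    xyz <- frames[[t]] * 10
    if (multi) writeLines(sprintf("MODEL     %4d", t), con)
    writeLines(sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)) %% 100000, name4, a$resname, a$chain, a$resid,
      xyz[, 1], xyz[, 2], xyz[, 3], 1.0, 0.0, a$element
    ), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Trajectory container
#'
#' Time-ordered coordinate frames bound to an [md_system]. Frames are stored
#' as a T x 3N matrix (row = frame, columns x1,y1,z1,x2,...) in nm, the
#' layout the covariance analysis consumes directly.
#'
#' @param system An [md_system].
#' @param coords T x 3N matrix of frame coordinates in nm, or a list of
#'   N x 3 matrices.
#' @param dt Inter-frame spacing in ps.
#' @param t0 Time of the first frame in ps.
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(system, coords, dt = 1, t0 = 0) {
  if (is.list(coords)) {
    coords <- do.call(rbind, lapply(coords, function(m) as.numeric(t(m))))
  }
  coords <- as.matrix(coords)
  if (ncol(coords) != 3 * n_atoms(system)) {
    abort(sprintf("coords has %d columns; system has %d atoms (need %d)",
                  ncol(coords), n_atoms(system), 3 * n_atoms(system)))
  }
  if (nrow(coords) < 1) abort("a trajectory needs at least one frame")
  structure(list(system = system, coords = coords, dt = dt, t0 = t0),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d frames x %d atoms, dt = %g ps (%g-%g ps)\n",
              n_frames(x), n_atoms(x$system), x$dt, x$t0,
              x$t0 + (n_frames(x) - 1) * x$dt))
  invisible(x)
}

#' @rdname md_trajectory
#' @param traj An `md_trajectory`.
#' @export
n_frames <- function(traj) nrow(traj$coords)

#' @rdname md_trajectory
#' @export
frame_times <- function(traj) traj$t0 + (seq_len(n_frames(traj)) - 1) * traj$dt

#' @rdname md_trajectory
#' @param i Frame index (1-based).
#' @return `frame_xyz()`: the N x 3 coordinate matrix of frame `i` in nm.
#' @export
frame_xyz <- function(traj, i) {
  matrix(traj$coords[i, ], ncol = 3, byrow = TRUE)
}

## System with coordinates replaced by frame i
frame_system <- function(traj, i) {
  s <- traj$system
  s$xyz <- frame_xyz(traj, i)
  s
}

#' Read a coordinate trajectory
#'
#' Multi-model PDB is parsed natively; DCD via bio3d; XTC through a thin
#' adapter that shells out to the `mdtraj` Python library (coordinates are
#' exchanged as a plain-text table, so the adapter needs `python` with
#' `mdtraj` on the PATH).
#'
#' @param path Trajectory file.
#' @param system The [md_system] the frames belong to (atom counts must
#'   match).
#' @param format `"pdb"`, `"dcd"` or `"xtc"`; guessed from the extension when
#'   omitted.
#' @param dt Frame spacing in ps; overrides any file metadata.
#' @return An [md_trajectory].
#' @export
read_trajectory <- function(path, system, format = NULL, dt = NULL) {
  format <- format %||% guess_format(path)
  res <- switch(format,
    pdb = read_multimodel_pdb(path),
    dcd = {
      xyz <- bio3d::read.dcd(path, verbose = FALSE)
      list(coords = unclass(xyz) / 10, dt = NULL)
    },
    xtc = read_xtc_adapter(path, system),
    abort(sprintf("unsupported trajectory format '%s'", format))
  )
  found <- ncol(res$coords) / 3
  if (found != n_atoms(system)) {
    abort(sprintf("atom count mismatch: system has %d atoms, file has %g",
                  n_atoms(system), found))
  }
  md_trajectory(system, res$coords, dt = dt %||% res$dt %||% 1)
}

read_multimodel_pdb <- function(path) {
  lines <- validate_pdb_lines(path)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0) model_starts <- 1
  ends <- c(model_starts[-1] - 1, length(lines))
  frames <- lapply(seq_along(model_starts), function(k) {
    blk <- lines[model_starts[k]:ends[k]]
    at <- blk[grepl("^(ATOM  |HETATM)", blk)]
    cbind(as.numeric(substr(at, 31, 38)), as.numeric(substr(at, 39, 46)),
          as.numeric(substr(at, 47, 54))) / 10
  })
  nats <- vapply(frames, nrow, integer(1))
  if (length(unique(nats)) != 1) {
    abort(sprintf("models differ in atom count (%s)",
                  paste(unique(nats), collapse = ", ")))
  }
  list(coords = do.call(rbind, lapply(frames, function(m) as.numeric(t(m)))),
       dt = NULL)
}

read_xtc_adapter <- function(path, system) {
  if (Sys.which("python") == "") {
    abort("XTC support needs 'python' with mdtraj on the PATH")
  }
  top <- tempfile(fileext = ".pdb")
  write_pdb(system, top)
  out <- tempfile(fileext = ".tsv")
  script <- sprintf(paste0(
    "import mdtraj, numpy as np\n",
    "t = mdtraj.load('%s', top='%s')\n",
    "m = t.xyz.reshape(t.n_frames, -1)\n",
    "dt = t.timestep if t.n_frames > 1 else 1.0\n",
    "np.savetxt('%s', m, header=str(dt), comments='#')\n"),
    path, top, out)
  status <- system2("python", c("-c", shQuote(script)))
  if (status != 0) abort(sprintf("mdtraj adapter failed reading '%s'", path))
  hdr <- readLines(out, n = 1)
  dt <- as.numeric(sub("^#\\s*", "", hdr))
  coords <- as.matrix(utils::read.table(out))
  dimnames(coords) <- NULL
  list(coords = coords, dt = dt)
}

#' @rdname write_pdb
#' @export
write_trajectory <- function(x, path) write_pdb(x, path)
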