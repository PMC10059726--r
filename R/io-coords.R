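#' Trajectory container
#'
#' An ordered list of coordinate frames (n_atoms x 3 matrices, Angstrom)
#' with a constant atom count and optional frame times in ps.
#'
#' @param frames list of n x 3 numeric matrices
#' @param times optional numeric vector of time stamps, ps
#' @param atom_names optional atom-name vector carried for format checks
#' @return list of class `"trajectory"`
#' @export
trajectory <- function(frames, times = NULL, atom_names = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1)
  n <- nrow(frames[[1]])
  for (f in seq_along(frames)) {
    m <- frames[[f]]
    if (!is.matrix(m) || ncol(m) != 3 || nrow(m) != n)
      stop(sprintf("trajectory: frame %d does not have %d x 3 coordinates",
                   f, n))
    if (any(!is.finite(m)))
      stop(sprintf("trajectory: non-finite coordinate in frame %d", f))
  }
  if (!is.null(times)) stopifnot(length(times) == length(frames))
  structure(list(frames = frames, times = times, atom_names = atom_names),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms\n",
              length(x$frames), nrow(x$frames[[1]])))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$frames)

trajectory_frames <- function(traj) {
  if (inherits(traj, "trajectory")) traj$frames
  else if (is.list(traj)) traj
  else list(as.matrix(traj))
}

#' Read multi-frame coordinates (multi-model PDB or concatenated XYZ)
#'
#' PDB frames are delimited by MODEL/ENDMDL records (a file without MODEL
#' records is a single frame); coordinates are parsed by fixed columns from
#' ATOM/HETATM records, ignoring occupancy and B-factor. XYZ files are
#' concatenated `n / comment / n atom lines` blocks. Atom order is the
#' contract with the topology: the atom count (and names, when a topology
#' is supplied) must match, and no reordering is performed.
#'
#' @param path input file
#' @param format `"pdb"` or `"xyz"`; guessed from the extension by default
#' @param topo optional [topology()] to validate atom count and names
#' @return a [trajectory()]
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "xyz"),
                            topo = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  traj <- if (format == "pdb") read_pdb_frames(path) else read_xyz_frames(path)
  if (!is.null(topo)) {
    if (nrow(traj$frames[[1]]) != n_atoms(topo))
      stop(sprintf("read_trajectory: %d atoms per frame but topology has %d",
                   nrow(traj$frames[[1]]), n_atoms(topo)))
    if (!is.null(traj$atom_names) &&
        !all(trimws(traj$atom_names) == trimws(topo$atoms$name)))
      stop("read_trajectory: atom names do not match topology order")
  }
  traj
}

read_pdb_frames <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- which(trimws(rec) == "MODEL")
  frames <- list(); names_first <- NULL
  parse_block <- function(ln, fidx) {
    xyz <- cbind(as.numeric(substr(ln, 31, 38)),
                 as.numeric(substr(ln, 39, 46)),
                 as.numeric(substr(ln, 47, 54)))
    if (any(!is.finite(xyz)))
      stop(sprintf("read_trajectory: unreadable coordinates in frame %d", fidx))
    list(xyz = xyz, names = trimws(substr(ln, 13, 16)))
  }
  if (!length(model_starts)) {
    if (!any(is_atom)) stop("read_trajectory: no ATOM/HETATM records in ", path)
    b <- parse_block(lines[is_atom], 1)
    return(trajectory(list(b$xyz), atom_names = b$names))
  }
  ends <- c(model_starts[-1] - 1, length(lines))
  n0 <- NULL
  for (f in seq_along(model_starts)) {
    sel <- seq(model_starts[f], ends[f])
    ln <- lines[sel][is_atom[sel]]
    if (!length(ln)) stop(sprintf("read_trajectory: frame %d has no atoms", f))
    b <- parse_block(ln, f)
    if (is.null(n0)) { n0 <- nrow(b$xyz); names_first <- b$names }
    if (nrow(b$xyz) != n0)
      stop(sprintf("read_trajectory: frame %d has %d atoms, expected %d",
                   f, nrow(b$xyz), n0))
    frames[[f]] <- b$xyz
  }
  trajectory(frames, atom_names = names_first)
}

read_xyz_frames <- function(path) {
  lines <- readLines(path)
  frames <- list(); i <- 1; f <- 0; names_first <- NULL; n0 <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("read_trajectory: malformed XYZ atom-count line ", i)
    f <- f + 1
    if (i + 1 + n > length(lines))
      stop(sprintf("read_trajectory: frame %d truncated", f))
    body <- lines[(i + 2):(i + 1 + n)]
    tok <- strsplit(trimws(body), "[[:space:]]+")
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    if (any(!is.finite(xyz)))
      stop(sprintf("read_trajectory: unreadable coordinates in frame %d", f))
    nm <- vapply(tok, `[`, character(1), 1)
    if (is.null(n0)) { n0 <- n; names_first <- nm }
    if (n != n0)
      stop(sprintf("read_trajectory: frame %d has %d atoms, expected %d",
                   f, n, n0))
    frames[[f]] <- xyz
    i <- i + 2 + n
  }
  if (!length(frames)) stop("read_trajectory: empty XYZ file")
  trajectory(frames, atom_names = names_first)
}

#' Write a trajectory as multi-model PDB or XYZ
#'
#' XYZ output keeps 9 decimal places and round-trips through
#' [read_trajectory()] to well below 1e-6 Angstrom; PDB output follows the
#' fixed-column format (3 decimals).
#'
#' @param traj a [trajectory()] or list of frames
#' @param path output file
#' @param format `"pdb"` or `"xyz"`
#' @param atom_names atom names (defaults to names stored in `traj`)
#' @return invisibly, `path`
#' @export
write_trajectory <- function(traj, path, format = c("pdb", "xyz"),
                             atom_names = NULL) {
  format <- match.arg(format)
  frames <- trajectory_frames(traj)
  n <- nrow(frames[[1]])
  nm <- atom_names %||%
    (if (inherits(traj, "trajectory")) traj$atom_names else NULL) %||%
    sprintf("X%d", seq_len(n))
  con <- file(path, "w"); on.exit(close(con))
  if (format == "xyz") {
    for (f in seq_along(frames)) {
      writeLines(c(as.character(n), sprintf("frame %d", f)), con)
      writeLines(sprintf("%-4s %15.9f %15.9f %15.9f", nm,
                         frames[[f]][, 1], frames[[f]][, 2],
                         frames[[f]][, 3]), con)
    }
  } else {
    for (f in seq_along(frames)) {
      writeLines(sprintf("MODEL     %4d", f), con)
      writeLines(sprintf("ATOM  %5d %-4s MOL A   1    %8.3f%8.3f%8.3f  1.00  0.00",
                         seq_len(n), substr(nm, 1, 4),
                         frames[[f]][, 1], frames[[f]][, 2],
                         frames[[f]][, 3]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  invisible(path)
}
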