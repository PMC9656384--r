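# The trajectory container and trajectory readers/writers.

#' Construct a study trajectory
#'
#' Container for frames of one protein plus M polymer oligomers on a uniform
#' time grid, with a phase label per frame separating the restraint-ON and
#' restraint-OFF windows.
#'
#' @param times_ps numeric vector of frame times in ps, strictly increasing.
#' @param protein_xyz array `[n_frames, n_protein_atoms, 3]` (nm), or a
#'   single `[n_atoms, 3]` matrix for a static protein (replicated
#'   logically, stored once).
#' @param oligomer_xyz list of arrays `[n_frames, n_beads, 3]` (nm), one per
#'   oligomer.
#' @param phase character vector per frame, `"ON"` or `"OFF"`; must form one
#'   ON block followed by one OFF block (either may be empty).
#' @param protein_masses,oligomer_masses atom/bead masses in Da;
#'   `oligomer_masses` is a list parallel to `oligomer_xyz`.
#' @param box optional periodic box lengths, numeric length-3 (nm).
#' @return an object of class `study_trajectory`.
#' @export
study_trajectory <- function(times_ps, protein_xyz, oligomer_xyz, phase,
                             protein_masses, oligomer_masses, box = NULL) {
  n <- length(times_ps)
  if (n < 1L) stop("trajectory must have at least one frame", call. = FALSE)
  if (any(diff(times_ps) <= 0)) stop("frame times must be strictly increasing", call. = FALSE)
  if (length(phase) != n) stop("`phase` must have one label per frame", call. = FALSE)
  if (!all(phase %in% c("ON", "OFF")))
    stop('phase labels must be "ON" or "OFF"', call. = FALSE)
  r <- rle(phase)
  if (length(r$values) > 2L || (length(r$values) == 2L && !identical(r$values, c("ON", "OFF"))))
    stop("phase labels must form one ON block followed by one OFF block", call. = FALSE)

  static_protein <- is.matrix(protein_xyz)
  if (static_protein) {
    stopifnot(ncol(protein_xyz) == 3L)
    n_prot <- nrow(protein_xyz)
  } else {
    stopifnot(length(dim(protein_xyz)) == 3L, dim(protein_xyz)[1] == n,
              dim(protein_xyz)[3] == 3L)
    n_prot <- dim(protein_xyz)[2]
  }
  if (length(protein_masses) != n_prot)
    stop("`protein_masses` length must match protein atom count", call. = FALSE)
  if (length(oligomer_xyz) < 1L) stop("at least one oligomer required", call. = FALSE)
  if (length(oligomer_masses) != length(oligomer_xyz))
    stop("`oligomer_masses` must parallel `oligomer_xyz`", call. = FALSE)
  for (i in seq_along(oligomer_xyz)) {
    d <- dim(oligomer_xyz[[i]])
    if (length(d) != 3L || d[1] != n || d[3] != 3L)
      stop("oligomer ", i, " coordinates must be [n_frames, n_beads, 3]", call. = FALSE)
    if (length(oligomer_masses[[i]]) != d[2])
      stop("oligomer ", i, " mass vector must match bead count", call. = FALSE)
  }
  if (!is.null(box)) stopifnot(is.numeric(box), length(box) == 3L, all(box > 0))

  structure(
    list(times_ps = times_ps, protein_xyz = protein_xyz,
         oligomer_xyz = oligomer_xyz, phase = phase,
         protein_masses = protein_masses, oligomer_masses = oligomer_masses,
         box = box, static_protein = static_protein),
    class = "study_trajectory"
  )
}

#' @export
print.study_trajectory <- function(x, ...) {
  cat("<study_trajectory> ", length(x$times_ps), " frames (",
      sum(x$phase == "ON"), " ON / ", sum(x$phase == "OFF"), " OFF), ",
      length(x$oligomer_xyz), " oligomers\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `study_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$times_ps)

# Protein coordinates of frame f as an [n_atoms, 3] matrix.
protein_frame <- function(traj, f) {
  if (traj$static_protein) return(traj$protein_xyz)
  m <- traj$protein_xyz[f, , , drop = FALSE]
  dim(m) <- dim(m)[2:3]
  m
}

oligomer_frame <- function(traj, i, f) {
  m <- traj$oligomer_xyz[[i]][f, , , drop = FALSE]
  dim(m) <- dim(m)[2:3]
  m
}

#' Write a multi-frame point set in the plain-text XYZ dialect
#'
#' A whitespace format used for synthetic trajectories: per frame one header
#' line `natoms time_ps` followed by `element x y z` rows (nm). Coordinates
#' are printed with fixed precision so identical inputs give byte-identical
#' files.
#'
#' @param path output path.
#' @param xyz array `[n_frames, n_atoms, 3]` in nm.
#' @param times_ps frame times.
#' @param elements per-atom element symbols.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(path, xyz, times_ps, elements) {
  stopifnot(length(dim(xyz)) == 3L, dim(xyz)[1] == length(times_ps),
            dim(xyz)[2] == length(elements))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(times_ps)) {
    writeLines(sprintf("%d %.4f", length(elements), times_ps[f]), con)
    m <- xyz[f, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = 3)
    writeLines(sprintf("%s %.6f %.6f %.6f", elements, m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Read the plain-text XYZ dialect written by [write_xyz_trajectory()]
#'
#' @param path file path.
#' @return list with `xyz` (array `[n_frames, n_atoms, 3]`, nm), `times_ps`
#'   and `elements`.
#' @export
read_xyz_trajectory <- function(path) {
  lines <- readLines(path)
  pos <- 1L
  frames <- list(); times <- numeric(0); elements <- NULL
  while (pos <= length(lines)) {
    hdr <- strsplit(trimws(lines[pos]), "\\s+")[[1]]
    if (length(hdr) != 2L)
      stop("XYZ format error at line ", pos, ": expected 'natoms time_ps'", call. = FALSE)
    na <- as.integer(hdr[1]); t <- as.numeric(hdr[2])
    if (is.na(na) || is.na(t))
      stop("XYZ format error at line ", pos, ": ", lines[pos], call. = FALSE)
    if (pos + na > length(lines)) stop("XYZ file truncated at frame starting line ", pos, call. = FALSE)
    rows <- strsplit(trimws(lines[(pos + 1):(pos + na)]), "\\s+")
    bad <- which(vapply(rows, length, 1L) != 4L)
    if (length(bad))
      stop("XYZ format error at line ", pos + bad[1], call. = FALSE)
    el <- vapply(rows, `[[`, "", 1L)
    m <- matrix(as.numeric(unlist(lapply(rows, `[`, 2:4))), ncol = 3, byrow = TRUE)
    if (is.null(elements)) elements <- el
    else if (!identical(elements, el))
      stop("atom list changed between frames at line ", pos, call. = FALSE)
    frames[[length(frames) + 1L]] <- m
    times <- c(times, t)
    pos <- pos + na + 1L
  }
  n <- length(frames); na <- length(elements)
  xyz <- array(0, c(n, na, 3))
  for (f in seq_len(n)) xyz[f, , ] <- frames[[f]]
  list(xyz = xyz, times_ps = times, elements = elements)
}

#' Read raw trajectory coordinates (DCD, multi-model PDB, XYZ dialect)
#'
#' Returns per-frame coordinates for all atoms in the file; splitting into
#' protein/oligomer selections and attaching phase labels is done by the
#' caller via [study_trajectory()]. XTC is not supported (no available
#' reader); convert to DCD or multi-model PDB upstream.
#'
#' @param path file path.
#' @param format `"auto"`, `"dcd"`, `"pdb"` (multi-model) or `"xyz"`.
#' @param dt_ps frame spacing used to synthesize times for formats that do
#'   not store them (DCD, PDB). Default 10 ps.
#' @return list with `xyz` array `[n_frames, n_atoms, 3]` in nm and
#'   `times_ps`.
#' @export
read_trajectory <- function(path, format = c("auto", "dcd", "pdb", "xyz", "xtc"),
                            dt_ps = 10) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, dcd = "dcd", pdb = "pdb", xyz = "xyz", xtc = "xtc",
                     stop("cannot infer trajectory format from extension: .", ext,
                          call. = FALSE))
  }
  if (format == "xtc")
    stop("XTC reading is not supported; convert to DCD or multi-model PDB ",
         "(e.g. `mdconvert` or `gmx trjconv`) or use the XYZ dialect",
         call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "xyz") {
    tr <- read_xyz_trajectory(path)
    return(list(xyz = tr$xyz, times_ps = tr$times_ps))
  }
  if (format == "dcd") {
    m <- bio3d::read.dcd(path, verbose = FALSE)  # frames x 3N, Angstrom
    n <- nrow(m); na <- ncol(m) / 3L
    xyz <- array(0, c(n, na, 3))
    for (f in seq_len(n)) xyz[f, , ] <- matrix(m[f, ], ncol = 3, byrow = TRUE) / 10
    return(list(xyz = xyz, times_ps = seq_len(n) * dt_ps))
  }
  # multi-model PDB
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  m <- pdb$xyz
  n <- nrow(m); na <- ncol(m) / 3L
  xyz <- array(0, c(n, na, 3))
  for (f in seq_len(n)) xyz[f, , ] <- matrix(m[f, ], ncol = 3, byrow = TRUE) / 10
  list(xyz = xyz, times_ps = seq_len(n) * dt_ps)
}

# Frame indices belonging to a window specification: either a phase name
# ("ON"/"OFF"/"ALL") or an integer vector of frame indices.
resolve_window <- function(traj_or_phase, window) {
  phase <- if (is.character(traj_or_phase)) traj_or_phase else traj_or_phase$phase
  if (is.character(window) && length(window) == 1L) {
    idx <- switch(window,
                  ON = which(phase == "ON"),
                  OFF = which(phase == "OFF"),
                  ALL = seq_along(phase),
                  stop('window must be "ON", "OFF", "ALL" or frame indices',
                       call. = FALSE))
  } else {
    idx <- as.integer(window)
    if (any(idx < 1L) || any(idx > length(phase)))
      stop("window frame indices out of range", call. = FALSE)
  }
  if (length(idx) == 0L) stop("empty analysis window", call. = FALSE)
  idx
}
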