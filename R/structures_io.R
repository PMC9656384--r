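# Structure and trajectory I/O plus sequence-level bookkeeping.
#
# Internal conventions: coordinates are stored in nanometers everywhere;
# Angstrom values (PDB files, SASA, contact cutoffs) are converted at the
# I/O boundary. van der Waals radii are kept in Angstrom because they are
# only consumed by the SASA quadrature, which works in Angstrom.

#' Construct a protein model
#'
#' Builds the package's protein container from a per-atom table. Most users
#' get one from [read_structure()] or [synth_protein()]; the constructor is
#' exported for programmatic model building and enforces the container's
#' invariants (unique residues within a chain, finite coordinates, positive
#' radii).
#'
#' @param atoms data frame with one row per atom and columns `elety` (atom
#'   name), `element`, `resid` (integer), `resname` (3-letter code), `chain`,
#'   `x`, `y`, `z` (nm), and optionally `mass` (Da) and `radius` (Angstrom);
#'   missing masses/radii are filled from the element tables.
#' @param source optional character tag recording provenance.
#' @param radii named radius table as from [vdw_radii()].
#' @return an object of class `protein_model`: a list with `atoms` (per-atom
#'   table including `residue_uid`, `mass`, `radius`, `backbone`), `residues`
#'   (one row per residue: `residue_uid`, `resid`, `resname`, `chain`) and
#'   `xyz_ref` (reference coordinates, nm, one row per atom).
#' @export
protein_model <- function(atoms, source = "constructed", radii = vdw_radii()) {
  needed <- c("elety", "element", "resid", "resname", "chain", "x", "y", "z")
  if (!all(needed %in% names(atoms)))
    stop("`atoms` must have columns ", paste(needed, collapse = ", "), call. = FALSE)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  atoms$resid <- as.integer(atoms$resid)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in atom table", call. = FALSE)

  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  if (is.null(atoms$radius)) atoms$radius <- element_radius(atoms$element, radii)
  if (any(atoms$radius <= 0)) stop("van der Waals radii must be positive", call. = FALSE)
  if (any(atoms$mass <= 0)) stop("atom masses must be positive", call. = FALSE)

  # Residues in file order; a residue is a (chain, resid) pair and must not
  # recur after an intervening residue (duplicate id within a chain).
  key <- paste(atoms$chain, atoms$resid, sep = "|")
  runs <- rle(key)$values
  if (anyDuplicated(runs)) {
    dup <- runs[duplicated(runs)][1]
    stop("duplicate residue id within a chain: ", sub("\\|", " ", dup), call. = FALSE)
  }
  atoms$residue_uid <- match(key, runs)
  first <- !duplicated(key)
  residues <- data.frame(
    residue_uid = atoms$residue_uid[first],
    resid = atoms$resid[first],
    resname = atoms$resname[first],
    chain = atoms$chain[first],
    stringsAsFactors = FALSE
  )
  # one resname per residue
  same <- tapply(atoms$resname, atoms$residue_uid, function(v) length(unique(v)) == 1L)
  if (!all(same)) stop("a residue has atoms with differing residue names", call. = FALSE)

  atoms$backbone <- atoms$elety %in% c("N", "CA", "C", "O")
  structure(
    list(atoms = atoms, residues = residues, xyz_ref = xyz, source = source),
    class = "protein_model"
  )
}

#' @export
print.protein_model <- function(x, ...) {
  cat("<protein_model> ", nrow(x$residues), " residues, ", nrow(x$atoms),
      " atoms (", x$source, ")\n", sep = "")
  invisible(x)
}

#' Number of residues / atoms in a model
#' @param model a `protein_model`.
#' @return integer count.
#' @export
n_residues <- function(model) nrow(model$residues)

#' Representative (C-alpha) coordinates per residue
#'
#' Coordinates (nm) of one representative atom per residue, preferring the
#' CA atom, as an `[n_residues, 3]` matrix in residue order.
#'
#' @param model a `protein_model`.
#' @param xyz optional replacement full-atom coordinate matrix (nm).
#' @return `[n_residues, 3]` numeric matrix.
#' @export
calpha_coords <- function(model, xyz = NULL) {
  at <- model$atoms
  if (is.null(xyz)) xyz <- as.matrix(at[, c("x", "y", "z")])
  idx <- integer(nrow(model$residues))
  for (u in model$residues$residue_uid) {
    rows <- which(at$residue_uid == u)
    ca <- rows[at$elety[rows] == "CA"]
    idx[u] <- if (length(ca)) ca[1] else rows[1]
  }
  xyz[idx, , drop = FALSE]
}

#' Read a protein structure (PDB or GRO)
#'
#' Parses a structure file into a [protein_model]. PDB parsing is delegated
#' to \pkg{bio3d}; GRO files are parsed directly (fixed-width GROMACS
#' format, coordinates already in nm). Coordinates from PDB are converted
#' from Angstrom to nm. Only ATOM records of the first model are used for
#' PDB input; waters and monoatomic ions are dropped.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`.
#' @param radii radius table, see [vdw_radii()].
#' @return a `protein_model`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro"),
                           radii = vdw_radii()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", gro = "gro",
                     stop("cannot infer structure format from extension: .", ext,
                          call. = FALSE))
  }
  if (format == "pdb") {
    pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                    error = function(e) stop("failed to parse PDB file ", path,
                                             ": ", conditionMessage(e), call. = FALSE))
    at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
    if (nrow(at) == 0L) stop("no ATOM records in ", path, call. = FALSE)
    at <- at[!at$resid %in% c("HOH", "WAT"), , drop = FALSE]
    element <- at$elesy
    missing_el <- is.na(element) | !nzchar(trimws(element))
    element[missing_el] <- guess_element(at$elety[missing_el])
    chain <- ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain)
    atoms <- data.frame(
      elety = at$elety, element = toupper(trimws(element)),
      resid = at$resno, resname = at$resid, chain = chain,
      x = at$x / 10, y = at$y / 10, z = at$z / 10,
      stringsAsFactors = FALSE
    )
    return(protein_model(atoms, source = paste0("pdb:", basename(path)), radii = radii))
  }
  # GRO: fixed-width; line 1 title, line 2 atom count, then one row per atom:
  # resid(5) resname(5) atomname(5) atomnum(5) x y z (nm, %8.3f)
  lines <- readLines(path)
  if (length(lines) < 3L) stop("not a valid GRO file (too short): ", path, call. = FALSE)
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms)) stop("GRO format error at line 2 (atom count): ",
                          lines[2], call. = FALSE)
  if (length(lines) < 2L + natoms)
    stop("GRO file truncated: expected ", natoms, " atom lines", call. = FALSE)
  rows <- lines[3:(2 + natoms)]
  resid <- suppressWarnings(as.integer(substr(rows, 1, 5)))
  resname <- trimws(substr(rows, 6, 10))
  aname <- trimws(substr(rows, 11, 15))
  x <- suppressWarnings(as.numeric(substr(rows, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(rows, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(rows, 37, 44)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("GRO format error at line ", 2 + bad[1], ": ", rows[bad[1]], call. = FALSE)
  atoms <- data.frame(
    elety = aname, element = guess_element(aname),
    resid = resid, resname = resname, chain = "A",
    x = x, y = y, z = z, stringsAsFactors = FALSE
  )
  protein_model(atoms, source = paste0("gro:", basename(path)), radii = radii)
}

#' Write a protein model to PDB
#'
#' Writes the model (coordinates converted nm to Angstrom) through
#' \pkg{bio3d}. Optional per-residue values can be written into the B-factor
#' or occupancy columns, the usual channel for coloring structures by a
#' scalar (e.g. percent occupancy of a binding interface).
#'
#' @param model a `protein_model`.
#' @param path output file path.
#' @param bfactor optional numeric vector, one value per residue, written to
#'   the B-factor column of all atoms of that residue.
#' @param occupancy optional numeric vector, one value per residue, written
#'   to the occupancy column.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path, bfactor = NULL, occupancy = NULL) {
  at <- model$atoms
  expand <- function(v, what) {
    if (is.null(v)) return(NULL)
    if (length(v) != nrow(model$residues))
      stop("`", what, "` must have one value per residue", call. = FALSE)
    v[at$residue_uid]
  }
  b <- expand(bfactor, "bfactor") %||% rep(0, nrow(at))
  o <- expand(occupancy, "occupancy") %||% rep(1, nrow(at))
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")]) * 10))
  bio3d::write.pdb(file = path, xyz = xyz, resno = at$resid, resid = at$resname,
                   eleno = seq_len(nrow(at)), elety = at$elety, chain = at$chain,
                   o = o, b = b, elesy = at$element)
  invisible(path)
}

#' Fetch a structure from the RCSB PDB
#'
#' Downloads `<id>.pdb` from the RCSB file server. Requires network access;
#' offline environments get an informative error.
#'
#' @param id 4-character PDB accession, e.g. `"5FQL"`.
#' @param dest destination file path (default: tempfile).
#' @return the destination path of the downloaded file.
#' @export
fetch_rcsb <- function(id, dest = tempfile(fileext = ".pdb")) {
  stopifnot(is.character(id), nchar(id) == 4L)
  url <- paste0("https://files.rcsb.org/download/", toupper(id), ".pdb")
  ok <- tryCatch(utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
                 error = function(e) -1L, warning = function(w) -1L)
  if (!identical(ok, 0L) || !file.exists(dest) || file.size(dest) == 0)
    stop("could not download ", url,
         " (no network access or accession unavailable)", call. = FALSE)
  dest
}

#' Assign amino-acid group labels to residues
#'
#' Labels every residue with its primary physiochemical group and aromatic
#' flag. Non-standard residue names are an error rather than silently
#' defaulted, so modified residues must be mapped by the caller first.
#'
#' @param model a `protein_model`, or a character vector of 3-letter codes.
#' @param grouping grouping table from [aa_grouping()].
#' @return data frame with columns `residue_uid` (absent for character
#'   input), `resid`, `resname`, `group`, `aromatic`.
#' @export
#' @examples
#' assign_groups(c("ASP", "LYS", "SER", "LEU", "PHE"))
assign_groups <- function(model, grouping = aa_grouping()) {
  if (is.character(model)) {
    res <- data.frame(resid = seq_along(model), resname = model,
                      stringsAsFactors = FALSE)
  } else {
    res <- model$residues
  }
  m <- match(res$resname, grouping$resname)
  if (anyNA(m))
    stop("residue name(s) not in grouping table: ",
         paste(unique(res$resname[is.na(m)]), collapse = ", "), call. = FALSE)
  res$group <- grouping$group[m]
  res$aromatic <- grouping$aromatic[m]
  res
}

#' Sequence-derived formal charge and counterion count
#'
#' Formal charge at neutral pH from side chains only: +1 per LYS/ARG, -1 per
#' ASP/GLU; HIS neutral; termini ignored (appropriate for loop-modeled,
#' tail-truncated constructs; set `termini` to add the zwitterionic +1/-1
#' pair, which cancels for a single chain). The counterion count is the
#' number of monovalent ions needed to neutralize the system, with species
#' chosen by the sign of the charge.
#'
#' @param model a `protein_model` or character vector of 3-letter codes.
#' @param termini if `TRUE`, include one +1 N-terminus and one -1 C-terminus
#'   per chain.
#' @return list with `charge` (integer), `counterions` (integer count) and
#'   `counterion_species` (`"NA+"`, `"CL-"` or `NA` if neutral).
#' @export
#' @examples
#' formal_charge(c("GLU"))            # -1, one sodium
#' formal_charge(c("LYS", "ASP"))     # neutral
formal_charge <- function(model, termini = FALSE) {
  if (is.character(model)) {
    resname <- model
    n_chains <- 1L
  } else {
    resname <- model$residues$resname
    n_chains <- length(unique(model$residues$chain))
  }
  labels <- assign_groups(resname)  # validates names
  charge <- sum(resname %in% c("LYS", "ARG")) - sum(resname %in% c("ASP", "GLU"))
  if (termini) charge <- charge + 0L * n_chains  # +1 N-term and -1 C-term cancel
  charge <- as.integer(charge)
  list(
    charge = charge,
    counterions = abs(charge),
    counterion_species = if (charge < 0) "NA+" else if (charge > 0) "CL-" else NA_character_
  )
}
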