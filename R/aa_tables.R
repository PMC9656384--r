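# Amino-acid classification tables, physiochemical descriptor table, and
# element property tables. All are shipped as plain TSV resources under
# inst/extdata and can be overridden by passing a replacement file or
# data frame, so alternative groupings or descriptor scales slot in without
# code changes.

.pb_cache <- new.env(parent = emptyenv())

read_resource_tsv <- function(name) {
  path <- system.file("extdata", name, package = "patchbind")
  if (!nzchar(path)) stop("bundled resource not found: ", name, call. = FALSE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

cached_resource <- function(name) {
  if (is.null(.pb_cache[[name]])) .pb_cache[[name]] <- read_resource_tsv(name)
  .pb_cache[[name]]
}

#' Amino-acid group membership
#'
#' Classification of the 20 standard residues into one primary category
#' (negative, positive, polar, hydrophobic) plus an aromatic flag. Aromatic
#' residues (PHE, TRP, TYR) are counted inside the hydrophobic group as well,
#' so the four primary fractions always partition unity while the aromatic
#' fraction overlaps the hydrophobic one. HIS is treated as neutral/polar at
#' pH 7, consistent with formal-charge bookkeeping that counts only
#' ASP/GLU/LYS/ARG.
#'
#' @param file optional path to a replacement TSV with columns
#'   `resname`, `group`, `aromatic`.
#' @return data frame with columns `resname` (3-letter code), `group`
#'   (one of `"negative"`, `"positive"`, `"polar"`, `"hydrophobic"`) and
#'   `aromatic` (logical).
#' @export
#' @examples
#' g <- aa_grouping()
#' g[g$resname == "PHE", ]
aa_grouping <- function(file = NULL) {
  g <- if (is.null(file)) cached_resource("aa_grouping.tsv")
       else utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  g$aromatic <- as.logical(g$aromatic)
  bad <- !g$group %in% c("negative", "positive", "polar", "hydrophobic")
  if (any(bad))
    stop("invalid primary group(s): ", paste(unique(g$group[bad]), collapse = ", "),
         call. = FALSE)
  if (any(g$aromatic & g$group != "hydrophobic"))
    stop("aromatic residues must belong to the hydrophobic primary group",
         call. = FALSE)
  if (anyDuplicated(g$resname)) stop("duplicate residue names in grouping", call. = FALSE)
  g
}

#' Physiochemical side-chain descriptor table
#'
#' The four per-residue descriptors used to characterize surface patches and
#' binding interfaces: hydrophobicity (HB, water-octanol partition scale),
#' polarizability (PB), graph shape index (GSI) and normalized van der Waals
#' volume (nVdW), from the experimentally derived side-chain scale of
#' Fauchere and co-workers.
#'
#' @param file optional path to a replacement TSV with columns
#'   `resname`, `HB`, `PB`, `GSI`, `nVdW`.
#' @return data frame with exactly 20 rows and the four descriptor columns.
#' @export
descriptor_table <- function(file = NULL) {
  d <- if (is.null(file)) cached_resource("fauchere_descriptors.tsv")
       else utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("resname", "HB", "PB", "GSI", "nVdW")
  if (!all(needed %in% names(d)))
    stop("descriptor table must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (nrow(d) != 20L) stop("descriptor table must have exactly 20 entries", call. = FALSE)
  if (anyNA(d[needed])) stop("descriptor table has missing values", call. = FALSE)
  d
}

#' van der Waals radii by element
#'
#' Bondi-set van der Waals radii in Angstrom, used for Shrake-Rupley solvent
#' accessibility. Replaceable via `file` for alternative radius sets.
#'
#' @param file optional path to a replacement TSV with columns `element`,
#'   `radius_A`.
#' @return named numeric vector of radii in Angstrom, names are element
#'   symbols (upper case).
#' @export
vdw_radii <- function(file = NULL) {
  r <- if (is.null(file)) cached_resource("vdw_radii.tsv")
       else utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  stats::setNames(r$radius_A, toupper(r$element))
}

# Standard atomic masses (Da) for the elements this package encounters.
atomic_masses <- function() {
  c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
    F = 18.998, CL = 35.45, BR = 79.904, I = 126.904, NA. = 22.990,
    MG = 24.305, K = 39.098, CA = 40.078, ZN = 65.38, FE = 55.845,
    SE = 78.971)
}

element_mass <- function(element) {
  m <- atomic_masses()
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  out <- m[key]
  if (anyNA(out))
    stop("unknown element(s): ", paste(unique(element[is.na(out)]), collapse = ", "),
         call. = FALSE)
  unname(out)
}

element_radius <- function(element, radii = vdw_radii()) {
  out <- radii[toupper(element)]
  if (anyNA(out))
    stop("no van der Waals radius for element(s): ",
         paste(unique(element[is.na(out)]), collapse = ", "), call. = FALSE)
  unname(out)
}

# Infer an element symbol from a PDB/GRO atom name: strip digits/primes,
# take a leading two-letter symbol if it is a known element, else the first
# letter. Handles the common biomolecular set; unknown names error upstream.
guess_element <- function(atom_name) {
  nm <- toupper(gsub("[0-9'\"]", "", trimws(atom_name)))
  two <- substr(nm, 1, 2)
  one <- substr(nm, 1, 1)
  known2 <- c("CL", "BR", "NA", "MG", "ZN", "FE", "SE")
  ifelse(two %in% known2, two, one)
}
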