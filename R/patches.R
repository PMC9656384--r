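# Surface-patch methodology: neighbor-search calibration, solvent vectors,
# patch generation under an angular cutoff, physiochemical descriptors,
# decile ranking of interfaces, and percent patch overlap.

#' Calibrate the C-alpha neighbor-search radius
#'
#' Fixed-radius neighbor searches return varying counts; this scans radii on
#' a grid and returns the radius at which the largest fraction of surface
#' residues has exactly `target_count` neighbors, together with the full
#' count histogram at that radius. Used to reproduce the construction in
#' which most surface residues have 10 nearest neighbors with the remainder
#' at 11-12.
#'
#' @param calphas `[n, 3]` C-alpha coordinates of surface residues, nm.
#' @param target_count desired neighbor count (default 10).
#' @param radii_A candidate radii in Angstrom (default 8-16 by 0.1).
#' @return list with `radius_A` (best radius), `fraction` (share of
#'   residues at exactly `target_count` there), `counts` (per-residue
#'   neighbor counts at the best radius), `histogram` (table of counts) and
#'   `mode` (modal neighbor count).
#' @export
calibrate_neighbor_radius <- function(calphas, target_count = 10,
                                      radii_A = seq(8, 16, by = 0.1)) {
  n <- nrow(calphas)
  if (n < target_count + 1L)
    stop("need at least target_count + 1 surface residues", call. = FALSE)
  d2 <- cross_dist2(calphas, calphas) * 100  # nm^2 -> A^2
  best <- NULL
  for (r in radii_A) {
    counts <- rowSums(d2 <= r * r) - 1L
    frac <- mean(counts == target_count)
    if (is.null(best) || frac > best$fraction)
      best <- list(radius_A = r, fraction = frac, counts = counts)
  }
  best$histogram <- table(best$counts)
  best$mode <- int_mode(best$counts)
  best
}

#' Solvent vector of one surface residue
#'
#' The outward unit vector at a surface residue: the negative of the
#' normalized vector from its C-alpha to the COM of its neighboring surface
#' C-alpha atoms. Residues whose neighbors are symmetric about them (COM
#' coincident with the center) are degenerate and excluded from patch
#' generation.
#'
#' @param center length-3 C-alpha position (nm).
#' @param neighbor_calphas `[k, 3]` neighbor C-alpha positions (nm).
#' @return unit length-3 vector pointing toward solvent.
#' @export
solvent_vector <- function(center, neighbor_calphas) {
  neighbor_calphas <- rbind(neighbor_calphas)
  if (nrow(neighbor_calphas) < 1L) stop("no neighbors for solvent vector", call. = FALSE)
  com <- colMeans(neighbor_calphas)
  v <- com - center
  nv <- sqrt(sum(v * v))
  if (nv < 1e-6)
    stop("degenerate residue: neighbor COM coincides with the center", call. = FALSE)
  -v / nv
}

#' Solvent vectors for all surface residues
#'
#' Computes [solvent_vector()] for every surface residue using neighbors
#' within `radius_A` (typically the calibrated radius). Residues with no
#' neighbors in range or with degenerate geometry get `NA` rows and a
#' single summary warning; they are skipped by patch generation.
#'
#' @param calphas `[n, 3]` surface C-alpha coordinates (nm), rows parallel
#'   to `uids`.
#' @param uids residue uids parallel to `calphas`.
#' @param radius_A neighbor-search radius in Angstrom.
#' @return `[n, 3]` matrix of unit vectors (rows `NA` where degenerate),
#'   with `uids` as rownames.
#' @export
surface_solvent_vectors <- function(calphas, uids, radius_A) {
  n <- nrow(calphas)
  d2 <- cross_dist2(calphas, calphas) * 100
  r2 <- radius_A^2
  out <- matrix(NA_real_, n, 3, dimnames = list(uids, c("x", "y", "z")))
  n_bad <- 0L
  for (i in seq_len(n)) {
    js <- which(d2[i, ] <= r2)
    js <- js[js != i]
    if (length(js) == 0L) { n_bad <- n_bad + 1L; next }
    v <- tryCatch(solvent_vector(calphas[i, ], calphas[js, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(v)) { n_bad <- n_bad + 1L; next }
    out[i, ] <- v
  }
  if (n_bad > 0L)
    warning(n_bad, " surface residue(s) with degenerate solvent vectors; ",
            "excluded from patch generation", call. = FALSE)
  out
}

#' Generate overlapping contiguous surface patches
#'
#' One patch per surface residue (the center): a neighboring surface
#' residue within `search_radius_A` joins the patch iff the angle between
#' its solvent vector and the center's is strictly less than `theta_cut`
#' degrees. The angular test removes residues on the opposite face or on
#' rings around concavities that a pure distance search would include.
#'
#' @param calphas `[n, 3]` surface C-alpha coordinates (nm).
#' @param uids residue uids parallel to `calphas`.
#' @param resnames residue names parallel to `calphas`.
#' @param vectors solvent vectors from [surface_solvent_vectors()].
#' @param search_radius_A residue neighbor-search radius, Angstrom
#'   (default 13).
#' @param theta_cut angular cutoff in degrees (default 125).
#' @param table descriptor table from [descriptor_table()] used to attach
#'   patch descriptors.
#' @return object of class `patch_set`: list with `patches` (list of
#'   per-patch lists: `center_uid`, `members`, `vsol`, `n_res`) and
#'   `summary` (data frame: `center_uid`, `n_res`, `HB`, `PB`, `GSI`,
#'   `nVdW`).
#' @export
generate_patches <- function(calphas, uids, resnames, vectors,
                             search_radius_A = 13, theta_cut = 125,
                             table = descriptor_table()) {
  n <- nrow(calphas)
  stopifnot(length(uids) == n, length(resnames) == n, nrow(vectors) == n)
  d2 <- cross_dist2(calphas, calphas) * 100
  r2 <- search_radius_A^2
  cos_cut <- cos(theta_cut * pi / 180)
  valid <- !is.na(vectors[, 1])
  patches <- list()
  for (i in which(valid)) {
    js <- which(d2[i, ] <= r2 & valid)
    js <- js[js != i]
    if (length(js)) {
      # angle < theta_cut  <=>  cos(angle) > cos(theta_cut); dot clamped.
      dots <- pmin(1, pmax(-1, as.vector(vectors[js, , drop = FALSE] %*% vectors[i, ])))
      js <- js[dots > cos_cut]
    }
    members <- sort(c(uids[i], uids[js]))
    patches[[length(patches) + 1L]] <- list(
      center_uid = uids[i], members = members,
      vsol = vectors[i, ], n_res = length(members)
    )
  }
  desc <- t(vapply(patches, function(p)
    patch_descriptors(resnames[match(p$members, uids)], table), numeric(4)))
  summary <- data.frame(
    center_uid = vapply(patches, `[[`, uids[1], "center_uid"),
    n_res = vapply(patches, `[[`, 1L, "n_res"),
    HB = desc[, 1], PB = desc[, 2], GSI = desc[, 3], nVdW = desc[, 4]
  )
  structure(list(patches = patches, summary = summary,
                 search_radius_A = search_radius_A, theta_cut = theta_cut),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat("<patch_set> ", length(x$patches), " patches, modal size ",
      int_mode(x$summary$n_res), " residues (theta_cut ", x$theta_cut,
      " deg, search ", x$search_radius_A, " A)\n", sep = "")
  invisible(x)
}

#' Physiochemical descriptors of a residue set
#'
#' Arithmetic means of the four per-residue descriptor values
#' (hydrophobicity, polarizability, graph shape index, normalized van der
#' Waals volume) over the members of a patch or interface.
#'
#' @param resnames 3-letter codes of the member residues.
#' @param table descriptor table from [descriptor_table()].
#' @return named numeric vector `HB`, `PB`, `GSI`, `nVdW`.
#' @export
patch_descriptors <- function(resnames, table = descriptor_table()) {
  m <- match(resnames, table$resname)
  if (anyNA(m))
    stop("no descriptor entry for residue(s): ",
         paste(unique(resnames[is.na(m)]), collapse = ", "), call. = FALSE)
  c(HB = mean(table$HB[m]), PB = mean(table$PB[m]),
    GSI = mean(table$GSI[m]), nVdW = mean(table$nVdW[m]))
}

#' Decile rank of an interface descriptor against the patch population
#'
#' Rank 1 means the value sits in the highest 10% of the patch descriptor
#' distribution; rank 10 the lowest 10%. The rank is
#' `10 - floor(10 * F)` clamped to `[1, 10]`, where `F` is the fraction of
#' patch values strictly below the interface value, so boundary values
#' promote to the better (lower) rank.
#'
#' @param interface_value descriptor value of the interface.
#' @param patch_values descriptor values of all patches (>= 10 values).
#' @return integer rank in 1..10.
#' @export
rank_interface <- function(interface_value, patch_values) {
  if (length(patch_values) < 10L)
    stop("need at least 10 patch values to rank into deciles", call. = FALSE)
  F <- mean(patch_values < interface_value)
  max(1L, min(10L, 10L - as.integer(floor(10 * F))))
}

#' Percent overlap of a patch with an interface
#'
#' `100 * |patch members in the interface| / N_interface`, the share of the
#' interface captured by one contiguous patch. The patch whose overlap is
#' maximal localizes the binding hotspot.
#'
#' @param patch a per-patch list from a `patch_set` (needs `members`), or a
#'   vector of member residue uids.
#' @param interface a `collapsed_interface` (or data frame with
#'   `residue_uid`).
#' @return percentage in `[0, 100]`.
#' @export
patch_overlap <- function(patch, interface) {
  members <- if (is.list(patch) && !is.null(patch$members)) patch$members else patch
  n_int <- nrow(interface)
  if (is.null(n_int) || n_int == 0L) stop("empty interface", call. = FALSE)
  100 * length(intersect(members, interface$residue_uid)) / n_int
}

#' Overlap of every patch with an interface
#'
#' @param patch_set a `patch_set`.
#' @param interface a `collapsed_interface`.
#' @return data frame `center_uid`, `n_res`, `overlap_pct`, sorted as in the
#'   patch set; attribute `max_overlap_uids` lists all co-maximal centers.
#' @export
patch_overlap_profile <- function(patch_set, interface) {
  ov <- vapply(patch_set$patches, patch_overlap, numeric(1), interface = interface)
  out <- data.frame(center_uid = patch_set$summary$center_uid,
                    n_res = patch_set$summary$n_res, overlap_pct = ov)
  mx <- max(ov)
  structure(out,
            max_overlap_pct = mx,
            max_overlap_uids = out$center_uid[ov == mx])
}
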