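# Geometric primitives: center of mass and radius of gyration, superposed
# backbone RMSD, Shrake-Rupley solvent accessibility, surface-residue
# selection, ellipsoid shape approximation and neighbor searches.

#' Center of mass and radius of gyration
#'
#' @param xyz `[n, 3]` coordinate matrix (nm).
#' @param masses per-point masses in Da (default: equal weights).
#' @return list with `com` (length-3, nm) and `rg` (nm), where
#'   `rg = sqrt(sum(m_i |r_i - com|^2) / sum(m_i))`.
#' @export
#' @examples
#' com_and_rg(rbind(c(0, 0, 0), c(1, 0, 0)))$rg  # 0.5
com_and_rg <- function(xyz, masses = NULL) {
  xyz <- rbind(xyz)  # promote a single point
  n <- nrow(xyz)
  if (n < 1L) stop("empty selection: no points for COM/Rg", call. = FALSE)
  if (is.null(masses)) masses <- rep(1, n)
  if (length(masses) != n) stop("`masses` must match the number of points", call. = FALSE)
  if (any(masses <= 0)) stop("masses must be positive", call. = FALSE)
  w <- masses / sum(masses)
  com <- colSums(xyz * w)
  d <- sweep(xyz, 2, com)
  rg <- sqrt(sum(w * rowSums(d * d)))
  list(com = com, rg = rg)
}

# Kabsch least-squares rotation aligning P onto Q (both centered by caller).
kabsch_rotation <- function(P, Q) {
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(tcrossprod(s$u, s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Backbone RMSD against a reference structure
#'
#' Root-mean-square deviation `sqrt(sum(delta_i^2)/N)` over backbone heavy
#' atoms, where `delta_i` is the distance of atom i from its reference
#' position. By default a least-squares rigid superposition (Kabsch) is
#' applied first, so rigid-body motion does not register as deviation.
#'
#' @param xyz `[N, 3]` frame coordinates (nm), backbone atoms only, in the
#'   same order as `ref`.
#' @param ref `[N, 3]` reference coordinates (nm).
#' @param superpose apply Kabsch superposition first (default `TRUE`).
#' @return RMSD in nm.
#' @export
backbone_rmsd <- function(xyz, ref, superpose = TRUE) {
  xyz <- rbind(xyz); ref <- rbind(ref)
  if (!all(dim(xyz) == dim(ref)))
    stop("frame and reference atom counts differ", call. = FALSE)
  if (superpose) {
    cx <- colMeans(xyz); cr <- colMeans(ref)
    P <- sweep(xyz, 2, cx); Q <- sweep(ref, 2, cr)
    R <- kabsch_rotation(P, Q)
    d <- P %*% R - Q
  } else {
    d <- xyz - ref
  }
  sqrt(sum(d * d) / nrow(xyz))
}

# Extract backbone heavy-atom coordinates of a model (reference) or of a
# supplied full-atom coordinate matrix.
backbone_xyz <- function(model, xyz = NULL) {
  if (is.null(xyz)) xyz <- model$xyz_ref
  xyz[model$atoms$backbone, , drop = FALSE]
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numerical SASA: each atom is expanded by the probe radius and sampled
#' with a deterministic golden-spiral quadrature; a sample point is
#' accessible if it lies outside every neighboring expanded sphere. Per-atom
#' areas are accumulated per residue.
#'
#' @param model a `protein_model` (coordinates nm, radii Angstrom).
#' @param probe_radius probe radius in Angstrom (default 1.4, a water
#'   molecule).
#' @param n_points quadrature points per atom (default 960).
#' @param xyz optional replacement coordinates (nm) to evaluate SASA on a
#'   frame other than the reference structure.
#' @return object of class `sasa_profile`: data frame with one row per
#'   residue (`residue_uid`, `resid`, `chain`, `resname`, `sasa` in
#'   Angstrom^2) and attributes `probe_radius`, `n_points`, `total`
#'   (total protein SASA, Angstrom^2) and `atom_sasa`.
#' @export
shrake_rupley_sasa <- function(model, probe_radius = 1.4, n_points = 960,
                               xyz = NULL) {
  if (probe_radius <= 0) stop("probe radius must be positive", call. = FALSE)
  if (n_points < 100) stop("need at least 100 quadrature points", call. = FALSE)
  coords <- 10 * (if (is.null(xyz)) model$xyz_ref else xyz)  # Angstrom
  radii <- model$atoms$radius + probe_radius
  n <- nrow(coords)
  sphere <- unit_sphere_points(n_points)
  atom_sasa <- numeric(n)
  # Neighbor lists from the full pairwise distance matrix; fine for the
  # few thousand atoms this package handles.
  d2 <- cross_dist2(coords, coords)
  rsum <- outer(radii, radii, "+")
  nb <- d2 < rsum * rsum
  diag(nb) <- FALSE
  for (i in seq_len(n)) {
    ri <- radii[i]
    pts <- sweep(sphere * ri, 2, coords[i, ], "+")
    js <- which(nb[i, ])
    if (length(js) == 0L) {
      acc <- n_points
    } else {
      buried <- rep(FALSE, n_points)
      for (j in js) {
        if (all(buried)) break
        keep <- !buried
        buried[keep] <- dist2_point(coords[j, ], pts[keep, , drop = FALSE]) <
          radii[j]^2
      }
      acc <- sum(!buried)
    }
    atom_sasa[i] <- 4 * pi * ri * ri * acc / n_points
  }
  res_sasa <- as.numeric(rowsum(atom_sasa, model$atoms$residue_uid,
                                reorder = TRUE))
  out <- model$residues
  out$sasa <- res_sasa
  structure(out, class = c("sasa_profile", "data.frame"),
            probe_radius = probe_radius, n_points = n_points,
            total = sum(atom_sasa), atom_sasa = atom_sasa)
}

#' Select surface residues by SASA threshold
#'
#' Residues with SASA strictly greater than the threshold, in residue order.
#' The default 1 Angstrom^2 keeps residues a water molecule (radius ~1.4
#' Angstrom) can plausibly touch.
#'
#' @param sasa a `sasa_profile`.
#' @param threshold Angstrom^2, non-negative.
#' @return integer vector of `residue_uid`s.
#' @export
select_surface_residues <- function(sasa, threshold = 1) {
  if (threshold < 0) stop("threshold must be non-negative", call. = FALSE)
  sasa$residue_uid[sasa$sasa > threshold]
}

#' Ellipsoid approximation of a protein's shape
#'
#' Principal axes from the covariance of surface-residue C-alpha positions
#' about the protein's center of mass; each semi-axis length is the maximum
#' absolute projection of the COM-to-C-alpha vectors onto that axis. This is
#' the construction behind distance-cutoff choices of the form "largest
#' semi-axis plus oligomer reach".
#'
#' @param model a `protein_model`.
#' @param surface integer vector of surface `residue_uid`s (e.g. from
#'   [select_surface_residues()]).
#' @return object of class `ellipsoid_fit`: list with `semi_axes` (sorted
#'   decreasing, nm), `axes` (3x3 orthonormal columns), `com` (nm).
#' @export
ellipsoid_axes <- function(model, surface) {
  ca <- calpha_coords(model)[surface, , drop = FALSE]
  if (nrow(ca) < 4L) stop("need at least 4 surface residues", call. = FALSE)
  com <- com_and_rg(model$xyz_ref, model$atoms$mass)$com
  centered <- sweep(ca, 2, com)
  cv <- crossprod(centered) / nrow(centered)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[3] < 1e-12 * eg$values[1])
    stop("degenerate (coplanar) surface residue geometry", call. = FALSE)
  proj <- abs(centered %*% eg$vectors)   # |projection| onto each axis
  semi <- apply(proj, 2, max)
  ord <- order(semi, decreasing = TRUE)
  structure(list(semi_axes = semi[ord],
                 axes = eg$vectors[, ord, drop = FALSE],
                 com = com),
            class = "ellipsoid_fit")
}

#' @export
print.ellipsoid_fit <- function(x, ...) {
  cat(sprintf("<ellipsoid_fit> semi-axes a=%.2f b=%.2f c=%.2f nm\n",
              x$semi_axes[1], x$semi_axes[2], x$semi_axes[3]))
  invisible(x)
}

#' Labels of points within a radius of a center point
#'
#' Fixed-radius neighbor search over a labeled point set; the center label
#' itself is excluded and results are returned in label order, so the output
#' is deterministic.
#'
#' @param points `[n, 3]` coordinate matrix.
#' @param labels vector of unique labels parallel to `points`.
#' @param center the label of the search center.
#' @param radius search radius, same units as `points`.
#' @return labels within `radius` of the center point, sorted.
#' @export
nearest_neighbors <- function(points, labels, center, radius) {
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  idx <- match(center, labels)
  if (is.na(idx)) stop("unknown center label: ", center, call. = FALSE)
  d2 <- dist2_point(points[idx, ], points)
  hits <- labels[d2 <= radius * radius]
  sort(hits[hits != center])
}
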