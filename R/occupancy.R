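# Per-residue percent occupancy, collapsed interfaces, occupancy filtering,
# amino-acid group fractions, and contact surface area.

#' Per-residue percent occupancy of polymer contact
#'
#' For each residue, the percentage of window frames in which any atom of
#' any (or one selected) oligomer lies within `cutoff` Angstrom of any atom
#' of the residue. A residue counts at most once per frame regardless of how
#' many atoms are in contact. The denominator is the analyzed window's frame
#' count, so occupancies are per restraint phase when a phase window is
#' used.
#'
#' @param traj a `study_trajectory`.
#' @param model the `protein_model` the trajectory's protein selection
#'   corresponds to (atom order must match).
#' @param window `"ON"`, `"OFF"`, `"ALL"` or integer frame indices.
#' @param cutoff contact cutoff in Angstrom (default 4).
#' @param oligomer `"any"` (default) to pool all oligomers, or one oligomer
#'   index for a per-oligomer map.
#' @param surface optional vector of surface `residue_uid`s; if supplied,
#'   non-zero occupancy at a non-surface residue raises a warning (possible
#'   burial or SASA-threshold artifact).
#' @param trial optional trial identifier stored in the result.
#' @return object of class `occupancy_map`: data frame with one row per
#'   residue (`residue_uid`, `resid`, `chain`, `resname`, `occupancy_pct`)
#'   and attributes `cutoff_A`, `window`, `n_window_frames`, `oligomer`,
#'   `trial`.
#' @export
residue_occupancy <- function(traj, model, window = "ALL", cutoff = 4,
                              oligomer = "any", surface = NULL, trial = NA) {
  if (cutoff <= 0) stop("contact cutoff must be positive", call. = FALSE)
  idx <- resolve_window(traj, window)
  olig_set <- if (identical(oligomer, "any")) seq_along(traj$oligomer_xyz)
              else as.integer(oligomer)
  if (any(olig_set < 1L) || any(olig_set > length(traj$oligomer_xyz)))
    stop("oligomer index out of range", call. = FALSE)
  cut_nm2 <- (cutoff / 10)^2
  uid <- model$atoms$residue_uid
  n_res <- nrow(model$residues)
  counts <- integer(n_res)
  for (f in idx) {
    prot <- protein_frame(traj, f)
    # per-protein-atom squared distance to the nearest selected bead
    amin <- rep(Inf, nrow(prot))
    for (i in olig_set) {
      d2 <- cross_dist2(oligomer_frame(traj, i, f), prot)
      m <- d2[1, ]
      if (nrow(d2) > 1L) for (b in 2:nrow(d2)) m <- pmin(m, d2[b, ])
      amin <- pmin(amin, m)
    }
    hit <- rowsum(as.integer(amin <= cut_nm2), uid, reorder = TRUE) > 0
    counts <- counts + as.integer(hit)
  }
  out <- model$residues
  out$occupancy_pct <- 100 * counts / length(idx)
  if (!is.null(surface)) {
    stray <- out$residue_uid[out$occupancy_pct > 0 &
                               !out$residue_uid %in% surface]
    if (length(stray))
      warning("non-zero occupancy at ", length(stray),
              " non-surface residue(s); possible burial or SASA-threshold artifact",
              call. = FALSE)
  }
  structure(out, class = c("occupancy_map", "data.frame"),
            cutoff_A = cutoff,
            window = if (is.character(window)) window else "custom",
            n_window_frames = length(idx),
            oligomer = if (identical(oligomer, "any")) "any" else olig_set,
            trial = trial,
            model_signature = model_signature(model))
}

# Cheap identity check that two occupancy maps came from the same protein.
model_signature <- function(model) {
  paste(nrow(model$residues), paste(range(model$residues$resid), collapse = "-"),
        paste(utils::head(model$residues$resname, 5), collapse = ""))
}

#' Collapse per-trial occupancy maps into one interface
#'
#' Union of residues with non-zero occupancy in at least one trial; the
#' stored value for a residue is the mean of its non-zero occupancies
#' across trials (repeating residues are averaged, non-repeating ones are
#' kept as-is). Set `average_zeros = TRUE` to average over all trials
#' including zeros instead.
#'
#' @param maps list of `occupancy_map`s sharing a protein model and window.
#' @param average_zeros include zero occupancies in the per-residue mean.
#' @return object of class `collapsed_interface`: data frame with columns
#'   `residue_uid`, `resid`, `chain`, `resname`, `occupancy_pct`, plus
#'   attributes `n_trials`, `filter_pct` (0 on construction), `window`.
#' @export
collapse_interfaces <- function(maps, average_zeros = FALSE) {
  if (length(maps) == 0L) stop("no occupancy maps supplied", call. = FALSE)
  sigs <- vapply(maps, function(m) attr(m, "model_signature"), "")
  if (length(unique(sigs)) != 1L)
    stop("occupancy maps come from different protein models", call. = FALSE)
  wins <- vapply(maps, function(m) attr(m, "window"), "")
  if (length(unique(wins)) != 1L)
    stop("occupancy maps analyzed different windows", call. = FALSE)
  occ <- vapply(maps, function(m) m$occupancy_pct, numeric(nrow(maps[[1]])))
  occ <- matrix(occ, nrow = nrow(maps[[1]]))
  nz <- occ > 0
  keep <- rowSums(nz) > 0
  value <- numeric(nrow(occ))
  if (average_zeros) {
    value <- rowMeans(occ)
  } else {
    value[keep] <- rowSums(occ * nz)[keep] / rowSums(nz)[keep]
  }
  out <- maps[[1]][keep, c("residue_uid", "resid", "chain", "resname")]
  out$occupancy_pct <- value[keep]
  rownames(out) <- NULL
  structure(out, class = c("collapsed_interface", "data.frame"),
            n_trials = length(maps), filter_pct = 0,
            window = wins[1], model_signature = sigs[1],
            average_zeros = average_zeros)
}

#' Filter a collapsed interface by occupancy
#'
#' Keeps residues with occupancy strictly greater than `cutoff_percent`.
#' Cutoffs around 50% select residues with favorable (possibly reversible)
#' binding; around 90% they isolate irreversible binding.
#'
#' @param interface a `collapsed_interface`.
#' @param cutoff_percent value in `[0, 100)`.
#' @return a `collapsed_interface` restricted to the surviving residues,
#'   with `filter_pct` recorded.
#' @export
filter_by_occupancy <- function(interface, cutoff_percent) {
  if (cutoff_percent < 0 || cutoff_percent >= 100)
    stop("occupancy cutoff must be in [0, 100)", call. = FALSE)
  keep <- interface$occupancy_pct > cutoff_percent
  out <- interface[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes_to_keep <- attributes(interface)
  structure(out, class = class(interface),
            n_trials = attributes_to_keep$n_trials,
            filter_pct = cutoff_percent,
            window = attributes_to_keep$window,
            model_signature = attributes_to_keep$model_signature,
            average_zeros = attributes_to_keep$average_zeros)
}

#' Amino-acid group fractions of an interface
#'
#' For each of the five categories, the fraction of interface residues that
#' belong to it. The four primary groups (negative, positive, polar,
#' hydrophobic) partition unity; the aromatic fraction is counted inside
#' the hydrophobic group as well, so it never exceeds it.
#'
#' @param interface a `collapsed_interface` (or any data frame with a
#'   `resname` column).
#' @param grouping grouping table from [aa_grouping()].
#' @return named numeric vector with elements `negative`, `positive`,
#'   `polar`, `hydrophobic`, `aromatic`.
#' @export
aa_group_fractions <- function(interface, grouping = aa_grouping()) {
  if (nrow(interface) == 0L) stop("empty interface", call. = FALSE)
  lab <- assign_groups(interface$resname, grouping)
  n <- nrow(interface)
  out <- c(negative = sum(lab$group == "negative") / n,
           positive = sum(lab$group == "positive") / n,
           polar = sum(lab$group == "polar") / n,
           hydrophobic = sum(lab$group == "hydrophobic") / n,
           aromatic = sum(lab$aromatic) / n)
  out
}

#' Contact surface area of an interface
#'
#' Sum of the reference-structure SASA values of the interface members:
#' `CSA = sum(SASA_i)` over the `N_interface` residues. An interface
#' member without a SASA value is an error.
#'
#' @param interface a `collapsed_interface` or `occupancy_map` restricted to
#'   interface residues (any data frame with `residue_uid`).
#' @param sasa a `sasa_profile` for the same model.
#' @return CSA in Angstrom^2 (0 for an empty interface).
#' @export
contact_surface_area <- function(interface, sasa) {
  if (nrow(interface) == 0L) return(0)
  m <- match(interface$residue_uid, sasa$residue_uid)
  if (anyNA(m))
    stop("no SASA value for residue uid(s): ",
         paste(interface$residue_uid[is.na(m)], collapse = ", "), call. = FALSE)
  sum(sasa$sasa[m])
}

#' Summarize a collapsed interface
#'
#' Size, contact surface area and share of the protein surface for a
#' (possibly filtered) collapsed interface.
#'
#' @param interface a `collapsed_interface`.
#' @param sasa a `sasa_profile`.
#' @return list with `n_interface`, `asa_int` (Angstrom^2),
#'   `pct_surface_area` (ASA_int as % of total protein SASA), `filter_pct`.
#' @export
interface_summary <- function(interface, sasa) {
  asa <- contact_surface_area(interface, sasa)
  list(n_interface = nrow(interface),
       asa_int = asa,
       pct_surface_area = 100 * asa / attr(sasa, "total"),
       filter_pct = attr(interface, "filter_pct") %||% NA_real_)
}
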