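# Plain-text exports: CSVs for timelines, occupancy maps, interfaces and
# patches; JSON with provenance for TF records; PDB copies with occupancy
# painted into the B-factor column for visualization.

#' Export an interaction timeline as CSV
#'
#' Columns: frame, time_ps, phase, oligomer, d_prot_nm, min_pair_nm, class.
#'
#' @param timeline an `interaction_timeline`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_timeline_csv <- function(timeline, path) {
  df <- as.data.frame(timeline)
  names(df)[names(df) == "d_prot"] <- "d_prot_nm"
  names(df)[names(df) == "min_pair"] <- "min_pair_nm"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export an occupancy map or collapsed interface as CSV
#'
#' Columns: residue_uid, resid, chain, resname, group, occupancy_pct and,
#' when a SASA profile is given, sasa_A2.
#'
#' @param x an `occupancy_map` or `collapsed_interface`.
#' @param path output path.
#' @param sasa optional `sasa_profile` to append per-residue SASA.
#' @param grouping grouping table for the `group` column.
#' @return `path`, invisibly.
#' @export
export_interface_csv <- function(x, path, sasa = NULL,
                                 grouping = aa_grouping()) {
  df <- as.data.frame(x)
  lab <- assign_groups(df$resname, grouping)
  df$group <- lab$group
  if (!is.null(sasa))
    df$sasa_A2 <- sasa$sasa[match(df$residue_uid, sasa$residue_uid)]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a TF record as JSON with provenance
#'
#' @param record a `tf_record`.
#' @param path output path.
#' @param provenance named list recorded alongside the values (cutoffs,
#'   window, seeds).
#' @return `path`, invisibly.
#' @export
export_tf_json <- function(record, path, provenance = list()) {
  payload <- list(
    tf_avg = as.data.frame(record$tf_avg),
    tf_avg_poly = as.list(record$tf_avg_poly),
    n_olig = record$n_olig, n_trials = record$n_trials,
    provenance = provenance
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a structure colored by occupancy
#'
#' Writes a PDB copy of the model with per-residue percent occupancy in the
#' B-factor column (max occupancy renders hottest in standard viewers);
#' residues outside the interface get 0.
#'
#' @param model a `protein_model`.
#' @param interface an `occupancy_map` or `collapsed_interface`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_occupancy_pdb <- function(model, interface, path) {
  b <- numeric(nrow(model$residues))
  m <- match(interface$residue_uid, model$residues$residue_uid)
  b[m] <- interface$occupancy_pct
  write_structure_pdb(model, path, bfactor = b)
}

#' Write a structure highlighting one patch
#'
#' Occupancy column flags: 2 for the patch center, 1 for members, 0
#' elsewhere — the center/member color semantics used for max-overlap patch
#' figures.
#'
#' @param model a `protein_model`.
#' @param patch a per-patch list (from a `patch_set`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_patch_pdb <- function(model, patch, path) {
  o <- numeric(nrow(model$residues))
  o[match(patch$members, model$residues$residue_uid)] <- 1
  o[match(patch$center_uid, model$residues$residue_uid)] <- 2
  write_structure_pdb(model, path, occupancy = o)
}

#' Export a patch set as CSV
#'
#' Columns: center_uid, n_res, HB, PB, GSI, nVdW, member_uids
#' (semicolon-separated), vsol_x/y/z.
#'
#' @param patch_set a `patch_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_patches_csv <- function(patch_set, path) {
  df <- patch_set$summary
  df$member_uids <- vapply(patch_set$patches, function(p)
    paste(p$members, collapse = ";"), "")
  vs <- t(vapply(patch_set$patches, `[[`, numeric(3), "vsol"))
  df$vsol_x <- vs[, 1]; df$vsol_y <- vs[, 2]; df$vsol_z <- vs[, 3]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export ground truth as JSON
#'
#' Sidecar for synthetic trajectories: per-frame class labels and contacted
#' residues, plus the scenario bookkeeping (margins, noise, seed, restraint
#' constant).
#'
#' @param gt a `ground_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_ground_truth_json <- function(gt, path) {
  sc <- gt$scenario
  payload <- list(
    class = apply(gt$class, 2, identity, simplify = FALSE),
    contacts = gt$contacts,
    scenario = list(n_frames = sc$n_frames, split_frame = sc$split_frame,
                    rg_on = sc$rg_on, off_mode = sc$off_mode,
                    margin_nm = sc$margin_nm, noise_sd_nm = sc$noise_sd_nm,
                    k = sc$k, seed = sc$seed)
  )
  jsonlite::write_json(payload, path, digits = NA)
  invisible(path)
}
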