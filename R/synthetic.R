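# Synthetic proteins and scripted oligomer trajectories with exact ground
# truth. The generator is a geometry scripter, not a simulator: it places
# bead chains so that center-of-mass distances and residue contacts satisfy
# the scripted interaction modes with explicit geometric margins, verifies
# the construction frame by frame, and only then adds bounded noise smaller
# than the margins. Ground-truth labels are therefore exact by construction.

#' Oligomer bead-chain specification
#'
#' Bead-per-monomer description of a polymer oligomer. Defaults reproduce
#' the study geometry: all three polymer types have nearly the same contour
#' length (~10.4-10.5 nm) so one set of radius-of-gyration targets spans
#' the same range of extension for each chemistry.
#'
#' @param type `"PLGA"` (20 monomers, 10.5 nm), `"PEG"` (33, 10.4 nm) or
#'   `"PLGA-PEG"` (25, 10.4 nm; diblock of 12 LGA + 13 EG units).
#' @param n_mon,lc_nm override monomer count / contour length.
#' @return object of class `oligomer_spec`: list with `type`, `n_mon`,
#'   `lc_nm`, `spacing_nm` (bead spacing `lc/(n_mon-1)`), `masses` (Da per
#'   bead; LGA ~65, EG ~44) and `elements` (all `"C"`).
#' @export
oligomer_spec <- function(type = c("PLGA", "PEG", "PLGA-PEG"),
                          n_mon = NULL, lc_nm = NULL) {
  type <- match.arg(type)
  defaults <- list(
    PLGA = list(n_mon = 20L, lc_nm = 10.5),
    PEG = list(n_mon = 33L, lc_nm = 10.4),
    `PLGA-PEG` = list(n_mon = 25L, lc_nm = 10.4)
  )[[type]]
  n_mon <- as.integer(n_mon %||% defaults$n_mon)
  lc_nm <- lc_nm %||% defaults$lc_nm
  if (n_mon < 2L) stop("oligomer needs at least 2 beads", call. = FALSE)
  masses <- switch(type,
    PLGA = rep(65, n_mon),
    PEG = rep(44, n_mon),
    `PLGA-PEG` = {
      n_lga <- round(n_mon * 12 / 25)
      c(rep(65, n_lga), rep(44, n_mon - n_lga))
    })
  structure(list(type = type, n_mon = n_mon, lc_nm = lc_nm,
                 spacing_nm = lc_nm / (n_mon - 1), masses = masses,
                 elements = rep("C", n_mon)),
            class = "oligomer_spec")
}

# Group -> residue names drawn by the synthetic protein, weighted by
# natural (Swiss-Prot) relative abundances so the surface chemistry is
# protein-like (e.g. TRP stays rare, aromatics ~9% of all residues rather
# than a third of the hydrophobic draw). GLY is excluded because the
# generator represents each residue as C-alpha plus one side-group bead.
SYNTH_DRAW <- list(
  negative = c(ASP = 5.46, GLU = 6.72),
  positive = c(LYS = 5.80, ARG = 5.53),
  polar = c(SER = 6.63, THR = 5.35, ASN = 4.06, GLN = 3.93, CYS = 1.38,
            HIS = 2.27),
  hydrophobic = c(ALA = 8.25, VAL = 6.86, LEU = 9.65, ILE = 5.91, MET = 2.41,
                  PRO = 4.74, PHE = 3.86, TRP = 1.10, TYR = 2.92)
)

#' Synthetic spherical-shell protein
#'
#' A stand-in protein surface: `n_residues` residues on a Fibonacci lattice
#' over a sphere, each with a C-alpha bead at the shell radius and one
#' side-group bead 0.2 nm further out, so every residue is solvent exposed.
#' Residue names are drawn to match the requested group composition exactly
#' (largest-remainder apportionment). The defaults emulate the scale of a
#' ~500-residue globular protein: ~300 surface residues on a 3.4 nm shell
#' gives ~48 Angstrom^2 of shell per residue and the characteristic ~10
#' C-alpha neighbors within 13 Angstrom.
#'
#' @param n_residues number of residues (>= 20).
#' @param composition named fractions over
#'   `negative`/`positive`/`polar`/`hydrophobic`; any residual up to 1 is
#'   assigned to `polar`. Default 12/9/30/48 percent (+1 residual to polar).
#' @param radius_nm shell radius.
#' @param seed RNG seed (name draw and lattice orientation).
#' @return a `protein_model` whose source is tagged `"synthetic"`.
#' @export
synth_protein <- function(n_residues = 300,
                          composition = c(negative = 0.12, positive = 0.09,
                                          polar = 0.30, hydrophobic = 0.48),
                          radius_nm = 3.4, seed = 1) {
  if (n_residues < 20L) stop("need at least 20 residues", call. = FALSE)
  groups <- names(SYNTH_DRAW)
  comp <- stats::setNames(rep(0, 4), groups)
  if (is.null(names(composition)) || !all(names(composition) %in% groups))
    stop("composition names must be among ", paste(groups, collapse = ", "),
         call. = FALSE)
  comp[names(composition)] <- composition
  total <- sum(comp)
  if (total > 1 + 1e-9) stop("composition fractions exceed 1", call. = FALSE)
  comp["polar"] <- comp["polar"] + (1 - total)  # residual to polar
  counts <- largest_remainder(n_residues, comp)
  with_seed(seed, {
    resnames <- unlist(lapply(seq_along(groups), function(g) {
      pool <- SYNTH_DRAW[[groups[g]]]
      sample(names(pool), counts[g], replace = TRUE, prob = pool)
    }))
    resnames <- sample(resnames)  # shuffle positions on the shell
    ca <- unit_sphere_points(n_residues) * radius_nm
    cb <- unit_sphere_points(n_residues) * (radius_nm + 0.2)
    atoms <- data.frame(
      elety = rep(c("CA", "CB"), n_residues),
      element = "C",
      resid = rep(seq_len(n_residues), each = 2),
      resname = rep(resnames, each = 2),
      chain = "A",
      x = as.vector(rbind(ca[, 1], cb[, 1])),
      y = as.vector(rbind(ca[, 2], cb[, 2])),
      z = as.vector(rbind(ca[, 3], cb[, 3])),
      stringsAsFactors = FALSE
    )
    protein_model(atoms, source = sprintf("synthetic sphere r=%.2fnm seed=%d",
                                          radius_nm, as.integer(seed)))
  })
}

#' One segment of an oligomer script
#'
#' @param mode `"FREE"`, `"BIND"`, `"AGGREGATE"` or `"BOTH"`.
#' @param frames segment duration in frames.
#' @param targets residue uids contacted while bound (BIND/BOTH).
#' @param partner index of the aggregation partner (AGGREGATE/BOTH).
#' @return list describing the segment.
#' @export
scenario_segment <- function(mode = c("FREE", "BIND", "AGGREGATE", "BOTH"),
                             frames, targets = NULL, partner = NA_integer_) {
  mode <- match.arg(mode)
  frames <- as.integer(frames)
  if (frames < 0L) stop("segment duration must be non-negative", call. = FALSE)
  if (mode %in% c("BIND", "BOTH") && length(targets) == 0L)
    stop(mode, " segment needs target residues", call. = FALSE)
  if (mode %in% c("AGGREGATE", "BOTH") && is.na(partner))
    stop(mode, " segment needs a partner oligomer", call. = FALSE)
  list(mode = mode, frames = frames, targets = as.integer(targets),
       partner = as.integer(partner))
}

#' Scripted scenario for a synthetic trajectory
#'
#' Per-oligomer ordered segments plus the restraint bookkeeping: the Rg
#' target applied during the ON phase, the relaxation behavior after
#' release, the geometric margin kept between scripted placements and every
#' decision cutoff, and the noise level (which must stay well below the
#' margin for ground truth to be exact; the generator truncates bead noise
#' at 3 standard deviations).
#'
#' @param scripts list with one element per oligomer, each an ordered list
#'   of [scenario_segment()]s; durations must sum to `n_frames`.
#' @param n_frames total frames.
#' @param split_frame last ON-phase frame (default `n_frames %/% 2`).
#' @param rg_on restrained-phase Rg target(s) in nm (recycled over
#'   oligomers).
#' @param off_mode `"collapse"` (poor solvent) or `"expand"` (good solvent)
#'   relaxation after release.
#' @param margin_nm geometric margin from all cutoffs (default 0.2).
#' @param noise_sd_nm bead jitter standard deviation (default 0.05).
#' @param k restraint force constant in kJ/mol, carried as metadata only
#'   (default 140).
#' @param seed RNG seed.
#' @return object of class `synth_scenario`.
#' @export
synth_scenario <- function(scripts, n_frames, split_frame = n_frames %/% 2,
                           rg_on = 2.0, off_mode = c("collapse", "expand"),
                           margin_nm = 0.2, noise_sd_nm = 0.05, k = 140,
                           seed = 1) {
  off_mode <- match.arg(off_mode)
  if (margin_nm <= 0) stop("margin must be positive", call. = FALSE)
  if (n_frames < 1L) stop("need at least one frame", call. = FALSE)
  for (i in seq_along(scripts)) {
    tot <- sum(vapply(scripts[[i]], `[[`, 1L, "frames"))
    if (tot != n_frames)
      stop("oligomer ", i, " segment durations sum to ", tot,
           ", expected ", n_frames, call. = FALSE)
  }
  rg_on <- rep(rg_on, length.out = length(scripts))
  structure(list(scripts = scripts, n_frames = as.integer(n_frames),
                 split_frame = as.integer(split_frame), rg_on = rg_on,
                 off_mode = off_mode, margin_nm = margin_nm,
                 noise_sd_nm = noise_sd_nm, k = k, seed = seed),
            class = "synth_scenario")
}

# Random-walk chain centered on its mass-weighted COM and rescaled to an
# exact mass-weighted radius of gyration (the quantity the classification
# and restraint bookkeeping use; diblock chains have non-uniform bead
# masses). Bond lengths are distorted by the rescale; the generator scripts
# geometry, it does not preserve a force field.
chain_blob <- function(n_beads, spacing, rg, masses = rep(1, n_beads)) {
  steps <- matrix(stats::rnorm(3 * (n_beads - 1)), ncol = 3)
  steps <- steps / row_norms(steps) * spacing
  pos <- rbind(0, apply(steps, 2, cumsum))
  w <- masses / sum(masses)
  pos <- sweep(pos, 2, colSums(pos * w))
  cur <- sqrt(sum(w * rowSums(pos * pos)))
  pos * (rg / cur)
}

# Mass-weighted Rg of a centered chain.
chain_rg <- function(pos, masses) {
  w <- masses / sum(masses)
  sqrt(sum(w * rowSums(pos * pos)))
}

# Mode geometry for one oligomer at one frame (pre-noise). Returns bead
# coordinates. `shell_out` is the outermost protein atom radial distance.
place_free <- function(blob, u, prot_cut, margin, shell_out, contact_cut) {
  extent <- max(row_norms(blob))
  R <- max(prot_cut + margin + 0.5, shell_out + contact_cut + margin + extent + 0.1)
  sweep(blob, 2, u * R, "+")
}

place_bound <- function(n_beads, targets, side_xyz, margin, contact_cut,
                        lateral = 0.1) {
  # contact beads hover (contact_cut - margin)*0.75 above each target's
  # side-group bead; remaining beads sit contact_cut + margin + 0.15 above
  # the target zone so only scripted residues register contact.
  n_c <- max(length(targets), n_beads %/% 2L)
  tpos <- side_xyz[targets, , drop = FALSE]
  rhat <- tpos / row_norms(tpos)
  h_c <- (contact_cut - margin) * 0.75
  assign <- rep(seq_along(targets), length.out = n_c)
  contact <- tpos[assign, , drop = FALSE] + rhat[assign, , drop = FALSE] * h_c
  n_f <- n_beads - n_c
  if (n_f > 0) {
    czone <- colMeans(tpos)
    czhat <- czone / sqrt(sum(czone^2))
    h_f <- contact_cut + margin + 0.15
    spread <- matrix(stats::rnorm(3 * n_f, sd = lateral), ncol = 3)
    spread <- spread - tcrossprod(spread %*% czhat, czhat)  # tangential only
    far <- sweep(spread, 2, czone + czhat * h_f, "+")
    out <- rbind(contact, far)
  } else out <- contact
  out
}

place_aggregate <- function(blob_i, blob_j, u_i, u_j, prot_cut, pair_cut,
                            margin, shell_out, contact_cut) {
  extent <- max(max(row_norms(blob_i)), max(row_norms(blob_j)))
  half_sep <- (pair_cut - margin) / 2 - 0.05
  u_mid <- u_i + u_j
  u_mid <- u_mid / sqrt(sum(u_mid^2))
  # lateral direction perpendicular to u_mid
  w <- c(-u_mid[2], u_mid[1], 0)
  if (sum(w^2) < 1e-8) w <- c(1, 0, 0)
  w <- w / sqrt(sum(w^2))
  R <- max(sqrt(max(0, (prot_cut + margin + 0.2)^2 - half_sep^2)),
           shell_out + contact_cut + margin + extent + 0.1)
  C <- u_mid * (R + extent)
  list(i = sweep(blob_i, 2, C + w * half_sep, "+"),
       j = sweep(blob_j, 2, C - w * half_sep, "+"))
}

# Scheduled Rg for frame f: restrained at rg_on during ON, exponential
# relaxation toward the collapse (<1.2 nm) or expansion plateau during OFF.
rg_schedule <- function(f, split_frame, rg_on, off_mode, dt_ps,
                        relax_tau_ps = 15000) {
  if (f <= split_frame) return(rg_on)
  plateau <- if (off_mode == "collapse") 1.0 else 1.9
  dt_off <- (f - split_frame) * dt_ps
  plateau + (rg_on - plateau) * exp(-dt_off / relax_tau_ps)
}

#' Generate a scripted trajectory with ground truth
#'
#' Builds a [study_trajectory()] in which each oligomer follows its
#' scripted segments: `FREE` keeps all COM distances outside the cutoffs
#' plus margin; `BIND` places beads in contact (within the contact cutoff
#' minus margin) with each scripted target residue while keeping the
#' protein-oligomer COM distance inside its cutoff minus margin;
#' `AGGREGATE` brings a pair of oligomers within the pair cutoff minus
#' margin (away from the protein); `BOTH` combines binding with
#' aggregation. Every frame is verified against the cutoffs before
#' truncated Gaussian noise (clipped at 3 sd, below the margin) is added,
#' so the returned ground truth is exact.
#'
#' @param protein a `protein_model` (typically [synth_protein()]).
#' @param oligomers list of [oligomer_spec()]s.
#' @param scenario a [synth_scenario()]; its scripts must cover `n_frames`.
#' @param n_frames number of frames (defaults to the scenario's).
#' @param dt_ps frame spacing in ps (default 10).
#' @param prot_cut,pair_cut,contact_cut_A decision cutoffs the script is
#'   built against (defaults 4.3 nm, 2.3 nm, 4 Angstrom).
#' @return list with `trajectory` (a `study_trajectory`) and `ground_truth`
#'   (class `ground_truth`: per-frame class matrix, per-frame contacted
#'   residues per oligomer, and the scenario).
#' @export
synth_trajectory <- function(protein, oligomers, scenario,
                             n_frames = scenario$n_frames, dt_ps = 10,
                             prot_cut = 4.3, pair_cut = 2.3, contact_cut_A = 4) {
  stopifnot(inherits(scenario, "synth_scenario"))
  if (n_frames != scenario$n_frames)
    stop("scenario covers ", scenario$n_frames, " frames, requested ", n_frames,
         call. = FALSE)
  M <- length(scenario$scripts)
  if (length(oligomers) != M)
    stop("need one oligomer spec per script", call. = FALSE)
  margin <- scenario$margin_nm
  contact_cut <- contact_cut_A / 10
  if (margin >= contact_cut || margin >= pair_cut / 2)
    stop("infeasible script: margin ", margin,
         " nm too large for the decision cutoffs", call. = FALSE)

  prot_xyz <- protein$xyz_ref
  shell_out <- max(row_norms(prot_xyz))
  atom_groups <- split(seq_len(nrow(prot_xyz)), protein$atoms$residue_uid)
  side_idx <- vapply(protein$residues$residue_uid, function(u) {
    rows <- which(protein$atoms$residue_uid == u)
    cb <- rows[protein$atoms$elety[rows] != "CA"]
    if (length(cb)) cb[1] else rows[1]
  }, 1L)
  side_xyz <- prot_xyz[side_idx, , drop = FALSE]

  # home directions, maximally separated on the equator
  ang <- 2 * pi * (seq_len(M) - 1) / max(M, 1)
  homes <- cbind(cos(ang), sin(ang), 0)

  # expand scripts to a per-frame mode table
  mode_tab <- vector("list", M)
  for (i in seq_len(M)) {
    segs <- scenario$scripts[[i]]
    mode_tab[[i]] <- do.call(rbind, lapply(segs, function(s)
      if (s$frames > 0)
        data.frame(mode = rep(s$mode, s$frames),
                   partner = rep(s$partner, s$frames),
                   seg = rep(TRUE, s$frames), stringsAsFactors = FALSE)
      else NULL))
    mode_tab[[i]]$targets <- rep(lapply(segs, `[[`, "targets"),
                                 times = vapply(segs, `[[`, 1L, "frames"))
  }

  with_seed(scenario$seed, {
    olig_xyz <- lapply(seq_len(M), function(i)
      array(0, c(n_frames, oligomers[[i]]$n_mon, 3)))
    gt_class <- matrix("", n_frames, M)
    gt_contacts <- lapply(seq_len(M), function(i) vector("list", n_frames))

    # per-oligomer blob templates are refreshed at segment boundaries
    blobs <- vector("list", M)
    for (f in seq_len(n_frames)) {
      placed <- vector("list", M)
      for (i in seq_len(M)) {
        mi <- mode_tab[[i]]$mode[f]
        rg_f <- rg_schedule(f, scenario$split_frame, scenario$rg_on[i],
                            scenario$off_mode, dt_ps)
        if (mi %in% c("FREE", "AGGREGATE")) {
          if (is.null(blobs[[i]]) || f == 1L ||
              mode_tab[[i]]$mode[max(1, f - 1)] != mi)
            blobs[[i]] <- chain_blob(oligomers[[i]]$n_mon,
                                     oligomers[[i]]$spacing_nm, 1,
                                     oligomers[[i]]$masses)
          blob <- blobs[[i]] * rg_f  # templates are normalized to Rg = 1
        }
        if (mi == "FREE") {
          placed[[i]] <- place_free(blob, homes[i, ], prot_cut, margin,
                                    shell_out, contact_cut)
        } else if (mi %in% c("BIND", "BOTH")) {
          placed[[i]] <- place_bound(oligomers[[i]]$n_mon,
                                     mode_tab[[i]]$targets[[f]],
                                     side_xyz, margin, contact_cut)
        } else if (mi == "AGGREGATE") {
          j <- mode_tab[[i]]$partner[f]
          if (is.na(j) || mode_tab[[j]]$mode[f] != "AGGREGATE" ||
              mode_tab[[j]]$partner[f] != i)
            stop("infeasible script: AGGREGATE partners of oligomers ", i,
                 " and ", j, " are not mutual at frame ", f, call. = FALSE)
          if (j < i) { placed[[i]] <- attr(placed[[j]], "partner_xyz"); next }
          if (is.null(blobs[[j]]) ||
              mode_tab[[j]]$mode[max(1, f - 1)] != "AGGREGATE")
            blobs[[j]] <- chain_blob(oligomers[[j]]$n_mon,
                                     oligomers[[j]]$spacing_nm, 1,
                                     oligomers[[j]]$masses)
          blob_j <- blobs[[j]] * rg_f
          pr <- place_aggregate(blob, blob_j, homes[i, ], homes[j, ],
                                prot_cut, pair_cut, margin, shell_out,
                                contact_cut)
          placed[[i]] <- pr$i
          attr(placed[[i]], "partner_xyz") <- pr$j
        }
      }

      # --- verification (pre-noise): classes and contacts from geometry ---
      pm <- protein$atoms$mass
      pcom <- colSums(prot_xyz * pm / sum(pm))
      ocoms <- t(vapply(seq_len(M), function(i) {
        w <- oligomers[[i]]$masses / sum(oligomers[[i]]$masses)
        colSums(placed[[i]] * w)
      }, numeric(3)))
      d_prot <- row_norms(sweep(ocoms, 2, pcom))
      d_pair <- as.matrix(stats::dist(ocoms))
      in_band <- function(d, cut) abs(d - cut) < margin - 1e-9
      if (any(in_band(d_prot, prot_cut)) ||
          any(in_band(d_pair[upper.tri(d_pair)], pair_cut)))
        stop("infeasible script: a COM distance falls inside the guard band ",
             "at frame ", f, " (d_prot = ",
             paste(round(d_prot, 3), collapse = ", "), "; d_pair = ",
             paste(round(d_pair[upper.tri(d_pair)], 3), collapse = ", "), ")",
             call. = FALSE)
      geom_class <- unname(as.character(classify_frame(d_prot, d_pair,
                                                       prot_cut, pair_cut)))
      want <- vapply(seq_len(M), function(i)
        switch(mode_tab[[i]]$mode[f], FREE = "FREE", BIND = "PROT_POLY",
               AGGREGATE = "POLY_POLY", BOTH = "BOTH"), "")
      if (!identical(geom_class, want))
        stop("infeasible script: scripted mode and geometric class disagree ",
             "at frame ", f, " (", paste(want, collapse = ","), " vs ",
             paste(geom_class, collapse = ","), ")", call. = FALSE)
      gt_class[f, ] <- geom_class
      for (i in seq_len(M)) {
        d2 <- cross_dist2(placed[[i]], prot_xyz)
        mn <- d2[1, ]
        if (nrow(d2) > 1) for (b in 2:nrow(d2)) mn <- pmin(mn, d2[b, ])
        # per-residue minimum bead distance
        res_min <- vapply(atom_groups, function(ix) sqrt(min(mn[ix])),
                          numeric(1))
        if (any(abs(res_min - contact_cut) < margin - 1e-9))
          stop("infeasible script: a bead-residue distance falls inside the ",
               "contact guard band at frame ", f, call. = FALSE)
        touched <- as.integer(names(res_min))[res_min < contact_cut]
        tg <- mode_tab[[i]]$targets[[f]]
        if (mode_tab[[i]]$mode[f] %in% c("BIND", "BOTH")) {
          if (!all(tg %in% touched))
            stop("infeasible script: scripted target not contacted at frame ",
                 f, call. = FALSE)
        } else if (length(touched))
          stop("infeasible script: unscripted residue contact at frame ", f,
               call. = FALSE)
        gt_contacts[[i]][[f]] <- sort(touched)
      }

      # --- truncated noise, below the margin by construction ---
      for (i in seq_len(M)) {
        nz <- matrix(stats::rnorm(length(placed[[i]]), sd = scenario$noise_sd_nm),
                     ncol = 3)
        nrm <- row_norms(nz)
        cap <- 3 * scenario$noise_sd_nm
        scale <- ifelse(nrm > cap, cap / nrm, 1)
        olig_xyz[[i]][f, , ] <- placed[[i]] + nz * scale
      }
    }

    times <- seq_len(n_frames) * dt_ps
    phase <- ifelse(seq_len(n_frames) <= scenario$split_frame, "ON", "OFF")
    if (scenario$split_frame <= 0) phase[] <- "OFF"
    traj <- study_trajectory(
      times_ps = times, protein_xyz = prot_xyz, oligomer_xyz = olig_xyz,
      phase = phase, protein_masses = protein$atoms$mass,
      oligomer_masses = lapply(oligomers, `[[`, "masses"), box = NULL
    )
    gt <- structure(list(class = gt_class, contacts = gt_contacts,
                         scenario = scenario),
                    class = "ground_truth")
    list(trajectory = traj, ground_truth = gt)
  })
}

#' Ground-truth contact fractions over a window
#'
#' @param gt a `ground_truth` from [synth_trajectory()].
#' @param model the protein model.
#' @param window frame indices (or `"ON"`/`"OFF"`/`"ALL"` resolved against
#'   the scenario's phase split).
#' @param oligomer `"any"` or an oligomer index.
#' @return numeric vector, percent of window frames each residue is
#'   contacted, named by `residue_uid`.
#' @export
gt_contact_fraction <- function(gt, model, window = "ALL", oligomer = "any") {
  n <- gt$scenario$n_frames
  phase <- ifelse(seq_len(n) <= gt$scenario$split_frame, "ON", "OFF")
  idx <- resolve_window(phase, window)
  olig_set <- if (identical(oligomer, "any")) seq_along(gt$contacts)
              else as.integer(oligomer)
  counts <- stats::setNames(numeric(nrow(model$residues)),
                            model$residues$residue_uid)
  for (f in idx) {
    touched <- unique(unlist(lapply(olig_set, function(i) gt$contacts[[i]][[f]])))
    if (length(touched)) counts[as.character(touched)] <-
        counts[as.character(touched)] + 1
  }
  100 * counts / length(idx)
}

#' Restrained / released chain trajectory
#'
#' A chain whose per-frame radius of gyration tracks the restrained target
#' during the ON phase (within a +/-2.5% resampling band, well inside the
#' +/-5% restraint tolerance) and relaxes exponentially after release:
#' collapse toward a plateau below 1.2 nm (poor solvent) or expansion
#' toward ~1.9 nm (good solvent).
#'
#' @param spec an [oligomer_spec()].
#' @param rg_target restrained Rg target in nm; must not exceed the rigid
#'   rod bound `Lc/sqrt(12)`.
#' @param n_frames total frames.
#' @param seed RNG seed.
#' @param dt_ps frame spacing (default 10 ps).
#' @param split_frame last ON frame (default `n_frames %/% 2`; 0 = all OFF).
#' @param off_mode `"collapse"` or `"expand"`.
#' @param relax_tau_ps relaxation time constant (default 15000 ps, i.e.
#'   collapse essentially complete within ~50 ns).
#' @return list with `xyz` (`[n_frames, n_beads, 3]`, nm), `rg` (per-frame,
#'   exact), `times_ps`, `phase`, `schedule` (noise-free target series).
#' @export
synth_restrained_chain <- function(spec, rg_target, n_frames, seed = 1,
                                   dt_ps = 10, split_frame = n_frames %/% 2,
                                   off_mode = c("collapse", "expand"),
                                   relax_tau_ps = 15000) {
  off_mode <- match.arg(off_mode)
  rod_bound <- spec$lc_nm / sqrt(12)
  if (rg_target > rod_bound)
    stop(sprintf("Rg target %.2f nm exceeds the rod bound Lc/sqrt(12) = %.2f nm",
                 rg_target, rod_bound), call. = FALSE)
  if (rg_target <= 0) stop("Rg target must be positive", call. = FALSE)
  with_seed(seed, {
    xyz <- array(0, c(n_frames, spec$n_mon, 3))
    rg <- numeric(n_frames)
    schedule <- numeric(n_frames)
    w <- spec$masses / sum(spec$masses)
    base <- chain_blob(spec$n_mon, spec$spacing_nm, rg_target, spec$masses)
    for (f in seq_len(n_frames)) {
      target <- rg_schedule(f, split_frame, rg_target, off_mode, dt_ps,
                            relax_tau_ps)
      schedule[f] <- target
      # jitter then rescale: conformations vary, Rg follows the schedule
      base <- base + matrix(stats::rnorm(length(base), sd = 0.03), ncol = 3)
      base <- sweep(base, 2, colSums(base * w))
      rg_f <- if (f <= split_frame)
        target * (1 + stats::runif(1, -0.025, 0.025)) else target
      base <- base * (rg_f / chain_rg(base, spec$masses))
      xyz[f, , ] <- base
      rg[f] <- rg_f
    }
    list(xyz = xyz, rg = rg, times_ps = seq_len(n_frames) * dt_ps,
         phase = ifelse(seq_len(n_frames) <= split_frame, "ON", "OFF"),
         schedule = schedule)
  })
}

#' Pick a cluster of adjacent surface residues
#'
#' Utility for scripting binding targets: the `k` surface residues nearest
#' to a direction from the protein center (or nearest to a given residue),
#' by C-alpha distance. Clustered targets keep scripted binding zones
#' compact, which the patch-overlap analysis then recovers.
#'
#' @param model a `protein_model`.
#' @param direction length-3 vector from the protein center, or a single
#'   residue uid to cluster around.
#' @param k cluster size.
#' @param surface optional restriction to surface residue uids.
#' @return integer vector of `k` residue uids.
#' @export
nearby_residues <- function(model, direction, k = 5, surface = NULL) {
  ca <- calpha_coords(model)
  uids <- model$residues$residue_uid
  if (!is.null(surface)) {
    keep <- uids %in% surface
    ca <- ca[keep, , drop = FALSE]
    uids <- uids[keep]
  }
  if (length(direction) == 1L) {
    idx <- match(direction, uids)
    if (is.na(idx)) stop("unknown residue uid: ", direction, call. = FALSE)
    anchor <- ca[idx, ]
  } else {
    u <- direction / sqrt(sum(direction^2))
    anchor <- u * max(row_norms(ca))
  }
  d2 <- dist2_point(anchor, ca)
  sort(uids[order(d2)[seq_len(min(k, length(uids)))]])
}
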