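# Study orchestration: per-trial analysis bundles, cross-trial aggregation
# into a study report, and radius-of-gyration densities.

#' Analysis configuration
#'
#' All tunable cutoffs of the pipeline in one validated object. The
#' defaults are the study conditions: COM cutoffs 4.3 / 2.3 nm, 4 Angstrom
#' contact rule, 1 Angstrom^2 surface threshold, 1.4 Angstrom probe,
#' occupancy filters at 50 and 90 percent, patch angle 125 degrees with a
#' 13 Angstrom residue search, phase flip at 100 ns, and a 100-frame
#' (1 ns at 10 ps/frame) moving-average window.
#'
#' @param prot_cut_nm,pair_cut_nm COM classification cutoffs (nm).
#' @param contact_cut_A occupancy contact cutoff (Angstrom).
#' @param sasa_threshold_A2 surface-residue SASA threshold (Angstrom^2).
#' @param probe_radius_A SASA probe radius (Angstrom).
#' @param sasa_points SASA quadrature points per atom.
#' @param occupancy_filters occupancy cutoffs (%) applied to collapsed
#'   interfaces.
#' @param theta_cut_deg patch solvent-vector angle cutoff (degrees).
#' @param patch_radius_A patch residue-search radius (Angstrom).
#' @param phase_split_ps restraint release time (ps).
#' @param ma_window_frames moving-average window for Rg smoothing.
#' @param rg_bin_nm histogram bin width for Rg densities (nm).
#' @param seed master seed recorded with every report.
#' @return object of class `analysis_config` (a validated list).
#' @export
analysis_config <- function(prot_cut_nm = 4.3, pair_cut_nm = 2.3,
                            contact_cut_A = 4, sasa_threshold_A2 = 1,
                            probe_radius_A = 1.4, sasa_points = 960,
                            occupancy_filters = c(50, 90),
                            theta_cut_deg = 125, patch_radius_A = 13,
                            phase_split_ps = 100000, ma_window_frames = 100,
                            rg_bin_nm = 0.05, seed = 1) {
  cfg <- list(prot_cut_nm = prot_cut_nm, pair_cut_nm = pair_cut_nm,
              contact_cut_A = contact_cut_A,
              sasa_threshold_A2 = sasa_threshold_A2,
              probe_radius_A = probe_radius_A, sasa_points = sasa_points,
              occupancy_filters = occupancy_filters,
              theta_cut_deg = theta_cut_deg, patch_radius_A = patch_radius_A,
              phase_split_ps = phase_split_ps,
              ma_window_frames = ma_window_frames, rg_bin_nm = rg_bin_nm,
              seed = seed)
  pos <- c("prot_cut_nm", "pair_cut_nm", "contact_cut_A", "probe_radius_A",
           "theta_cut_deg", "patch_radius_A", "rg_bin_nm")
  for (p in pos) if (cfg[[p]] <= 0) stop(p, " must be positive", call. = FALSE)
  if (any(occupancy_filters < 0 | occupancy_filters >= 100))
    stop("occupancy filters must be in [0, 100)", call. = FALSE)
  structure(cfg, class = "analysis_config")
}

#' Analyze one simulation trial
#'
#' Runs the per-trial pipeline: COM distances, interaction classification,
#' per-phase time frequencies, per-phase occupancy maps (pooled and per
#' oligomer), per-phase Rg series with moving-average smoothing and
#' probability densities.
#'
#' @param traj a `study_trajectory`.
#' @param model the matching `protein_model`.
#' @param config an [analysis_config()].
#' @param label optional named list of trial labels (`polymer`, `extension`,
#'   `trial`) carried into aggregation.
#' @return object of class `trial_bundle`: list with `timeline`, and per
#'   phase (`ON`, `OFF`, skipping empty phases): `tf`, `occupancy`
#'   (pooled map), `occupancy_per_oligomer`, `interface` (non-zero-occupancy
#'   residues); plus `rg` (per-oligomer series, smoothed series, densities)
#'   and `label`.
#' @export
run_trial <- function(traj, model, config = analysis_config(), label = list()) {
  dists <- com_distance_series(traj)
  tl <- classify_timeline(dists, config$prot_cut_nm, config$pair_cut_nm)
  phases <- intersect(c("ON", "OFF"), unique(traj$phase))
  per_phase <- list()
  for (ph in phases) {
    occ <- residue_occupancy(traj, model, window = ph,
                             cutoff = config$contact_cut_A,
                             trial = label$trial %||% NA)
    occ_per <- lapply(seq_along(traj$oligomer_xyz), function(i)
      residue_occupancy(traj, model, window = ph,
                        cutoff = config$contact_cut_A, oligomer = i,
                        trial = label$trial %||% NA))
    per_phase[[ph]] <- list(
      tf = time_frequencies(tl, ph),
      occupancy = occ,
      occupancy_per_oligomer = occ_per,
      interface = occ[occ$occupancy_pct > 0, , drop = FALSE]
    )
  }
  # Rg series per oligomer with smoothing and per-phase densities
  M <- length(traj$oligomer_xyz)
  rg <- matrix(0, n_frames(traj), M)
  for (i in seq_len(M)) {
    w <- traj$oligomer_masses[[i]]
    for (f in seq_len(n_frames(traj)))
      rg[f, i] <- com_and_rg(oligomer_frame(traj, i, f), w)$rg
  }
  rg_smooth <- apply(rg, 2, moving_average, w = config$ma_window_frames)
  dens <- compare_rg_densities(rg, traj$phase, bin_nm = config$rg_bin_nm)
  structure(list(timeline = tl, phases = per_phase,
                 rg = list(series = rg, smoothed = rg_smooth,
                           densities = dens, times_ps = traj$times_ps),
                 label = label, config = config),
            class = "trial_bundle")
}

#' Per-phase probability densities of the radius of gyration
#'
#' Histogram densities on a fixed bin grid (default width 0.05 nm), pooled
#' over oligomers, normalized to integrate to one within each phase.
#'
#' @param rg_series numeric matrix `[n_frames, n_oligomers]` (or vector).
#' @param phase per-frame phase labels (`"ON"`/`"OFF"`).
#' @param bin_nm bin width (nm).
#' @return named list per phase present: data frame `mid` (bin midpoint,
#'   nm), `density` (1/nm); each integrates to 1.
#' @export
compare_rg_densities <- function(rg_series, phase, bin_nm = 0.05) {
  rg_series <- cbind(rg_series)
  out <- list()
  for (ph in intersect(c("ON", "OFF"), unique(phase))) {
    idx <- which(phase == ph)
    if (length(idx) < 2L) stop("phase ", ph, " has fewer than 2 frames", call. = FALSE)
    v <- as.vector(rg_series[idx, ])
    lo <- floor(min(v) / bin_nm) * bin_nm
    breaks <- seq(lo, max(v) + bin_nm, by = bin_nm)
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    out[[ph]] <- data.frame(mid = h$mids, density = h$density)
  }
  out
}

# Per-trial CSA for one phase of a bundle.
bundle_csa <- function(bundle, phase, sasa)
  contact_surface_area(bundle$phases[[phase]]$interface, sasa)

#' Aggregate trial bundles into a study report
#'
#' Cross-trial aggregation within each (polymer, extension) group and
#' phase: oligomer- then trial-averaged time frequencies; collapsed
#' interfaces at each occupancy filter with size, contact surface area and
#' share of the protein surface; per-trial CSA mean and standard error;
#' amino-acid group fractions of the filtered interface; and, when a patch
#' set is supplied, descriptor decile ranks of each trial interface and the
#' patch-overlap profile of the filtered collapsed interface (all
#' co-maximal patches reported on ties). Extension levels within a polymer
#' are compared pairwise on per-trial CSA with the Wilcoxon signed-rank
#' test, paired by trial index; raw and Holm-adjusted p-values are both
#' reported, and all-zero difference sets are flagged as NA.
#'
#' @param bundles list of `trial_bundle`s with `label` entries.
#' @param sasa a `sasa_profile` of the reference structure.
#' @param patch_set optional `patch_set` for ranks and overlaps.
#' @param grouping grouping table.
#' @param config an [analysis_config()].
#' @return object of class `study_report`: list with `groups` (per
#'   polymer/extension/phase summaries), `csa_tests` (Wilcoxon table),
#'   `provenance`.
#' @export
aggregate_study <- function(bundles, sasa, patch_set = NULL,
                            grouping = aa_grouping(),
                            config = analysis_config()) {
  if (length(bundles) == 0L) stop("no trial bundles", call. = FALSE)
  labs <- lapply(bundles, function(b) b$label)
  key <- vapply(labs, function(l)
    paste(l$polymer %||% "poly", l$extension %||% "ext", sep = "|"), "")
  phases <- names(bundles[[1]]$phases)
  same_phases <- all(vapply(bundles, function(b)
    identical(names(b$phases), phases), TRUE))
  if (!same_phases) stop("bundles have ragged phase structure", call. = FALSE)

  groups <- list()
  csa_rows <- list()
  for (g in unique(key)) {
    gb <- bundles[key == g]
    pol <- gb[[1]]$label$polymer %||% "poly"
    ext <- gb[[1]]$label$extension %||% "ext"
    for (ph in phases) {
      tfrec <- aggregate_tf(lapply(gb, function(b) b$phases[[ph]]$tf))
      maps <- lapply(gb, function(b) b$phases[[ph]]$occupancy)
      collapsed <- collapse_interfaces(maps)
      filters <- sort(unique(c(0, config$occupancy_filters)))
      ifaces <- lapply(filters, function(fc)
        if (fc == 0) collapsed else filter_by_occupancy(collapsed, fc))
      names(ifaces) <- paste0("gt", filters)
      iface_sum <- lapply(ifaces, interface_summary, sasa = sasa)
      csa <- vapply(gb, bundle_csa, numeric(1), phase = ph, sasa = sasa)
      main_filter <- paste0("gt", max(0, min(config$occupancy_filters)))
      frac <- if (nrow(ifaces[[main_filter]]) > 0)
        aa_group_fractions(ifaces[[main_filter]], grouping) else NULL
      ranks <- overlap <- NULL
      if (!is.null(patch_set)) {
        trial_ranks <- lapply(gb, function(b) {
          iface <- b$phases[[ph]]$interface
          if (nrow(iface) == 0L) return(rep(NA_integer_, 4))
          dv <- patch_descriptors(iface$resname)
          vapply(c("HB", "PB", "GSI", "nVdW"), function(d)
            rank_interface(dv[[d]], patch_set$summary[[d]]), 1L)
        })
        ranks <- do.call(rbind, trial_ranks)
        colnames(ranks) <- c("HB", "PB", "GSI", "nVdW")
        fi <- ifaces[[main_filter]]
        if (nrow(fi) > 0) overlap <- patch_overlap_profile(patch_set, fi)
      }
      groups[[paste(g, ph, sep = "|")]] <- list(
        polymer = pol, extension = ext, phase = ph,
        tf = tfrec, interfaces = ifaces, interface_summaries = iface_sum,
        csa_per_trial = csa, csa_mean = mean(csa),
        csa_se = if (length(csa) > 1) stats::sd(csa) / sqrt(length(csa)) else 0,
        group_fractions = frac, ranks = ranks, overlap = overlap
      )
      for (i in seq_along(gb))
        csa_rows[[length(csa_rows) + 1L]] <- data.frame(
          polymer = pol, extension = ext, phase = ph,
          trial = gb[[i]]$label$trial %||% i, csa = csa[i],
          stringsAsFactors = FALSE)
    }
  }
  csa_df <- do.call(rbind, csa_rows)

  # pairwise extension comparisons within polymer and phase, paired by trial
  tests <- list()
  for (pol in unique(csa_df$polymer)) for (ph in unique(csa_df$phase)) {
    sub <- csa_df[csa_df$polymer == pol & csa_df$phase == ph, ]
    exts <- unique(sub$extension)
    if (length(exts) < 2L) next
    for (a in seq_along(exts)) for (b in seq_along(exts)) {
      if (a >= b) next
      xa <- sub$csa[sub$extension == exts[a]][order(sub$trial[sub$extension == exts[a]])]
      xb <- sub$csa[sub$extension == exts[b]][order(sub$trial[sub$extension == exts[b]])]
      if (length(xa) != length(xb)) stop("unpaired trials across extensions",
                                         call. = FALSE)
      d <- xa - xb
      p <- if (all(d == 0)) NA_real_ else
        suppressWarnings(stats::wilcox.test(xa, xb, paired = TRUE)$p.value)
      tests[[length(tests) + 1L]] <- data.frame(
        polymer = pol, phase = ph, ext_a = exts[a], ext_b = exts[b],
        n_pairs = length(d), p_value = p, degenerate = all(d == 0),
        stringsAsFactors = FALSE)
    }
  }
  csa_tests <- if (length(tests)) do.call(rbind, tests) else NULL
  if (!is.null(csa_tests))
    csa_tests$p_holm <- stats::p.adjust(csa_tests$p_value, method = "holm")

  structure(list(groups = groups, csa = csa_df, csa_tests = csa_tests,
                 provenance = list(
                   config = unclass(config), n_trials = length(bundles),
                   phases = phases, generated = "aggregate_study")),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> ", length(x$groups), " group-phase summaries, ",
      x$provenance$n_trials, " trials\n", sep = "")
  invisible(x)
}

# Scripted-binding intensity by polymer and extension level: fraction of
# ON-phase frames spent bound, whether binding persists after release, the
# aggregation fraction, and how many residues the bound chain contacts
# (more extended chains wrap more surface). These encode the qualitative
# study-level behavior the synthetic study emulates; see the methods
# vignette for the rationale.
SYNTH_BEHAVIOR <- list(
  PLGA = list(bind = c(high = 0.55, medium = 0.40, low = 0.30),
              agg = c(high = 0.35, medium = 0.50, low = 0.40), persist = 1.0),
  PEG = list(bind = c(high = 0.25, medium = 0.45, low = 0.20),
             agg = c(high = 0.10, medium = 0.10, low = 0.10), persist = 0.5),
  `PLGA-PEG` = list(bind = c(high = 0.60, medium = 0.45, low = 0.25),
                    agg = c(high = 0.15, medium = 0.20, low = 0.20), persist = 1.0)
)

#' Standard scripted scenario for one design row
#'
#' Builds the scenario a design row implies: oligomer 1 binds a hotspot
#' cluster near its approach direction for a polymer- and
#' extension-dependent fraction of the ON phase (and, for polymers with
#' persistent binding, of the OFF phase); oligomers 2 and 3 aggregate with
#' each other for a polymer-dependent fraction and are otherwise free. The
#' number of hotspot residues grows with the extension level, reflecting
#' the larger footprint of an extended chain.
#'
#' @param polymer polymer type (`"PLGA"`, `"PEG"`, `"PLGA-PEG"`).
#' @param extension `"high"`, `"medium"` or `"low"`.
#' @param rg_target_nm restrained Rg target.
#' @param protein the `protein_model` binding targets are drawn from.
#' @param surface surface residue uids.
#' @param n_frames total frames; `split_frame` defaults to half.
#' @param seed per-trial seed (vary targets and script durations).
#' @param n_olig number of oligomers (default 3).
#' @return a [synth_scenario()].
#' @export
standard_study_scenario <- function(polymer, extension, rg_target_nm, protein,
                                    surface, n_frames, seed, n_olig = 3) {
  beh <- SYNTH_BEHAVIOR[[polymer]]
  if (is.null(beh)) stop("unknown polymer type: ", polymer, call. = FALSE)
  bind_frac <- beh$bind[[extension]]
  agg_frac <- beh$agg[[extension]]
  n_on <- n_frames %/% 2
  n_off <- n_frames - n_on
  n_targets <- round(3 + 6 * (rg_target_nm - 1.1) / 0.9)
  with_seed(seed, {
    jitter_frac <- stats::runif(1, -0.15, 0.15)
    clamp <- function(x, lo, hi) max(lo, min(hi, x))
    b_on <- clamp(round(n_on * (bind_frac + jitter_frac)), 1L, n_on)
    b_off <- clamp(round(n_off * (bind_frac * beh$persist + jitter_frac)),
                   0L, n_off)
    a_on <- clamp(round(n_on * agg_frac), 0L, n_on)
    # hotspot in a per-trial random direction within oligomer 1's approach
    # cone (kept >30 degrees away from the other oligomers' home directions)
    az <- stats::runif(1, -70, 70) * pi / 180
    el <- stats::runif(1, -50, 50) * pi / 180
    dir <- c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
    hotspot <- nearby_residues(protein, dir, k = n_targets,
                               surface = surface)
    s1 <- list(scenario_segment("BIND", b_on, targets = hotspot),
               scenario_segment("FREE", n_on - b_on))
    s1 <- c(s1, if (b_off > 0) list(scenario_segment("BIND", b_off,
                                                     targets = hotspot)))
    s1 <- c(s1, list(scenario_segment("FREE", n_off - b_off)))
    s23 <- function(me, partner) {
      segs <- list()
      if (a_on > 0)
        segs <- list(scenario_segment("AGGREGATE", a_on, partner = partner))
      c(segs, list(scenario_segment("FREE", n_frames - a_on)))
    }
    scripts <- c(list(s1), lapply(seq_len(n_olig - 1), function(i) {
      idx <- i + 1L
      partner <- if (idx == 2L) 3L else 2L
      if (n_olig >= 3L) s23(idx, partner)
      else list(scenario_segment("FREE", n_frames))
    }))
    synth_scenario(scripts, n_frames = n_frames, split_frame = n_on,
                   rg_on = rg_target_nm,
                   off_mode = if (polymer == "PEG") "expand" else "collapse",
                   seed = seed)
  })
}

#' Run a full synthetic study from a design table
#'
#' Generates and analyzes one scripted trial per design row and aggregates
#' the bundles into a study report. This is the library-level entry point
#' the worked examples and the acceptance script drive.
#'
#' @param design a design table from [enumerate_design()] (or a subset).
#' @param protein a `protein_model` (default: [synth_protein()]).
#' @param n_frames frames per trial (choose to taste; analysis is
#'   frame-count agnostic).
#' @param config an [analysis_config()].
#' @return list with `report` (a `study_report`), `sasa`, `surface`,
#'   `patch_set`, `bundles`.
#' @export
run_study <- function(design, protein = synth_protein(),
                      n_frames = 200, config = analysis_config()) {
  sasa <- shrake_rupley_sasa(protein, config$probe_radius_A, config$sasa_points)
  surface <- select_surface_residues(sasa, config$sasa_threshold_A2)
  ca <- calpha_coords(protein)[surface, , drop = FALSE]
  calib <- calibrate_neighbor_radius(ca)
  vecs <- surface_solvent_vectors(ca, surface, calib$radius_A)
  resnames <- protein$residues$resname[match(surface,
                                             protein$residues$residue_uid)]
  patches <- generate_patches(ca, surface, resnames, vecs,
                              search_radius_A = config$patch_radius_A,
                              theta_cut = config$theta_cut_deg)
  bundles <- vector("list", nrow(design))
  for (r in seq_len(nrow(design))) {
    row <- design[r, ]
    scen <- standard_study_scenario(row$polymer, row$extension,
                                    row$rg_target_nm, protein, surface,
                                    n_frames, seed = row$seed)
    olig <- replicate(3, oligomer_spec(row$polymer), simplify = FALSE)
    st <- synth_trajectory(protein, olig, scen,
                           prot_cut = config$prot_cut_nm,
                           pair_cut = config$pair_cut_nm,
                           contact_cut_A = config$contact_cut_A)
    bundles[[r]] <- run_trial(st$trajectory, protein, config,
                              label = list(polymer = row$polymer,
                                           extension = row$extension,
                                           trial = row$trial))
  }
  report <- aggregate_study(bundles, sasa, patch_set = patches,
                            config = config)
  list(report = report, sasa = sasa, surface = surface, calibration = calib,
       patch_set = patches, bundles = bundles)
}
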