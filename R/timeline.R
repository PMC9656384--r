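# Interaction-class timelines: COM distance series, four-class
# classification, time frequencies and their two-level aggregation, and
# study-design enumeration.

INTERACTION_CLASSES <- c("PROT_POLY", "POLY_POLY", "BOTH", "FREE")

#' Center-of-mass distance series
#'
#' Per frame: the mass-weighted COM distance between the protein and each
#' oligomer (`d_prot`), and the full symmetric oligomer-oligomer COM
#' distance matrix (`d_pair`). Minimum-image displacements are used when the
#' trajectory carries a periodic box.
#'
#' @param traj a `study_trajectory`.
#' @return object of class `com_distances`: list with `d_prot`
#'   (`[n_frames, M]`, nm), `d_pair` (`[M, M, n_frames]`, nm, zero
#'   diagonal), `times_ps`, `phase`.
#' @export
com_distance_series <- function(traj) {
  n <- n_frames(traj)
  M <- length(traj$oligomer_xyz)
  if (M < 1L) stop("empty oligomer selection", call. = FALSE)
  d_prot <- matrix(0, n, M)
  d_pair <- array(0, c(M, M, n))
  pw <- traj$protein_masses / sum(traj$protein_masses)
  ow <- lapply(traj$oligomer_masses, function(m) m / sum(m))
  static_pcom <- if (traj$static_protein) colSums(traj$protein_xyz * pw) else NULL
  for (f in seq_len(n)) {
    pcom <- static_pcom %||% colSums(protein_frame(traj, f) * pw)
    ocom <- t(vapply(seq_len(M), function(i)
      colSums(oligomer_frame(traj, i, f) * ow[[i]]), numeric(3)))
    dp <- min_image(sweep(ocom, 2, pcom), traj$box)
    d_prot[f, ] <- row_norms(dp)
    for (i in seq_len(M)) {
      dd <- min_image(sweep(ocom, 2, ocom[i, ]), traj$box)
      d_pair[i, , f] <- row_norms(dd)
    }
  }
  structure(list(d_prot = d_prot, d_pair = d_pair,
                 times_ps = traj$times_ps, phase = traj$phase),
            class = "com_distances")
}

# Pure classification rule: vector of protein distances (length M) and an
# M x M pair-distance matrix -> factor of classes. Comparisons inclusive.
classify_frame <- function(d_prot, d_pair, prot_cut, pair_cut) {
  M <- length(d_prot)
  near_prot <- d_prot <= prot_cut
  pp <- d_pair <= pair_cut
  diag(pp) <- FALSE
  near_pair <- rowSums(pp) > 0
  ifelse(near_prot & near_pair, "BOTH",
         ifelse(near_prot, "PROT_POLY",
                ifelse(near_pair, "POLY_POLY", "FREE")))
}

#' Classify every (frame, oligomer) into an interaction class
#'
#' Four mutually exclusive classes from COM distances, with inclusive
#' cutoffs: `PROT_POLY` if the oligomer is within `prot_cut` of the protein
#' and no other oligomer is within `pair_cut`; `POLY_POLY` if at least one
#' other oligomer is within `pair_cut` but the protein is not within
#' `prot_cut`; `BOTH` if both conditions hold; `FREE` otherwise. The default
#' cutoffs (4.3 nm protein, 2.3 nm pair) suit a globular protein with a
#' largest ellipsoid semi-axis of ~3.5 nm and oligomers of ~10.5 nm contour
#' length.
#'
#' @param distances a `com_distances` object.
#' @param prot_cut protein-oligomer COM cutoff, nm.
#' @param pair_cut oligomer-oligomer COM cutoff, nm.
#' @return object of class `interaction_timeline`: data frame with columns
#'   `frame`, `time_ps`, `phase`, `oligomer`, `d_prot`, `min_pair`, `class`,
#'   with the distance series and cutoffs attached as attributes so every
#'   label is recomputable.
#' @export
classify_timeline <- function(distances, prot_cut = 4.3, pair_cut = 2.3) {
  stopifnot(inherits(distances, "com_distances"))
  if (prot_cut <= 0 || pair_cut <= 0) stop("cutoffs must be positive", call. = FALSE)
  n <- nrow(distances$d_prot)
  M <- ncol(distances$d_prot)
  cls <- matrix("", n, M)
  min_pair <- matrix(NA_real_, n, M)
  for (f in seq_len(n)) {
    dp <- distances$d_pair[, , f, drop = FALSE][, , 1]
    if (M == 1L) dp <- matrix(0, 1, 1)
    cls[f, ] <- classify_frame(distances$d_prot[f, ], dp, prot_cut, pair_cut)
    if (M > 1L) {
      dp2 <- dp; diag(dp2) <- Inf
      min_pair[f, ] <- apply(dp2, 1, min)
    }
  }
  out <- data.frame(
    frame = rep(seq_len(n), times = M),
    time_ps = rep(distances$times_ps, times = M),
    phase = rep(distances$phase, times = M),
    oligomer = rep(seq_len(M), each = n),
    d_prot = as.vector(distances$d_prot),
    min_pair = as.vector(min_pair),
    class = factor(as.vector(cls), levels = INTERACTION_CLASSES),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("interaction_timeline", "data.frame"),
            prot_cut = prot_cut, pair_cut = pair_cut,
            distances = distances, n_olig = M, n_frames = n)
}

#' Class time frequencies per oligomer
#'
#' `TF_i` = fraction of window frames oligomer i spends in each class; the
#' four classes partition unity for every oligomer.
#'
#' @param timeline an `interaction_timeline`.
#' @param window `"ON"`, `"OFF"`, `"ALL"` or an integer vector of frame
#'   indices.
#' @return numeric matrix `[n_olig, 4]` with class columns; attribute
#'   `window_frames` records the frames analyzed.
#' @export
time_frequencies <- function(timeline, window = "ALL") {
  idx <- resolve_window(attr(timeline, "distances")$phase, window)
  sub <- timeline[timeline$frame %in% idx, ]
  M <- attr(timeline, "n_olig")
  tf <- matrix(0, M, length(INTERACTION_CLASSES),
               dimnames = list(NULL, INTERACTION_CLASSES))
  for (i in seq_len(M)) {
    tab <- table(sub$class[sub$oligomer == i])
    tf[i, names(tab)] <- as.numeric(tab) / length(idx)
  }
  structure(tf, window_frames = idx)
}

#' Aggregate time frequencies over oligomers and trials
#'
#' Two-level averaging with fixed order: within each trial, `TF_avg` is the
#' mean of `TF_i` over oligomers; across trials, `TF_avg_poly` is the mean
#' of the trial `TF_avg` values. With equal oligomer counts per trial the
#' result equals a flat average, but the order is kept explicit because it
#' defines the reported statistic.
#'
#' @param per_trial list of per-oligomer TF matrices (from
#'   [time_frequencies()]), one per trial, all with the same oligomer count.
#' @return object of class `tf_record`: list with `tf_avg`
#'   (`[n_trials, 4]`), `tf_avg_poly` (length-4), `n_olig`, `n_trials`.
#' @export
aggregate_tf <- function(per_trial) {
  if (length(per_trial) == 0L) stop("no trials supplied", call. = FALSE)
  n_olig <- unique(vapply(per_trial, nrow, 1L))
  if (length(n_olig) != 1L)
    stop("all trials must have the same oligomer count", call. = FALSE)
  cls <- lapply(per_trial, colnames)
  if (!all(vapply(cls, identical, TRUE, y = INTERACTION_CLASSES)))
    stop("all trials must carry the same class set", call. = FALSE)
  tf_avg <- t(vapply(per_trial, colMeans, numeric(length(INTERACTION_CLASSES))))
  structure(list(tf_avg = tf_avg, tf_avg_poly = colMeans(tf_avg),
                 n_olig = n_olig, n_trials = length(per_trial)),
            class = "tf_record")
}

#' @export
print.tf_record <- function(x, ...) {
  cat("<tf_record> ", x$n_trials, " trials x ", x$n_olig, " oligomers\n", sep = "")
  print(round(x$tf_avg_poly, 4))
  invisible(x)
}

#' Enumerate the study design
#'
#' Full factorial of polymer types, extension levels (radius-of-gyration
#' targets) and trials, with a deterministic per-row seed derived from
#' `base_seed`. The default factors are 3 polymers x 3 extensions x 7 trials
#' = 63 experiments with Rg targets of 2.0 (high), 1.5 (medium) and 1.1 nm
#' (low).
#'
#' @param polymers character vector of polymer types.
#' @param extensions named numeric vector of Rg targets (nm).
#' @param n_trials trials per cell.
#' @param base_seed integer master seed expanded per row.
#' @return data frame with one row per experiment: `polymer`, `extension`,
#'   `rg_target_nm`, `trial`, `seed`.
#' @export
#' @examples
#' nrow(enumerate_design())  # 63
enumerate_design <- function(polymers = c("PLGA", "PEG", "PLGA-PEG"),
                             extensions = c(high = 2.0, medium = 1.5, low = 1.1),
                             n_trials = 7, base_seed = 1) {
  if (length(polymers) == 0L || length(extensions) == 0L || n_trials < 1L)
    stop("design factors must be non-empty", call. = FALSE)
  if (is.null(names(extensions)) || any(!nzchar(names(extensions))))
    stop("`extensions` must be a named vector of Rg targets", call. = FALSE)
  grid <- expand.grid(trial = seq_len(n_trials),
                      extension = names(extensions),
                      polymer = polymers,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("polymer", "extension", "trial")]
  grid$rg_target_nm <- unname(extensions[grid$extension])
  # Counter-based seed expansion keeps rows independent and reproducible.
  grid$seed <- as.integer((as.numeric(base_seed) * 7919 +
                             seq_len(nrow(grid)) * 104729) %% 2147483647)
  grid[, c("polymer", "extension", "rg_target_nm", "trial", "seed")]
}
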