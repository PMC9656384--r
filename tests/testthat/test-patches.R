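# Neighbor-radius calibration, solvent vectors, patch generation and
# descriptors, decile ranking, and patch overlap.

test_that("neighbor calibration finds a constant-count radius on a ring", {
  # 24 equally spaced points on a ring, 0.5 nm arc spacing: every point is
  # equivalent, so the calibrated radius gives a single-spike histogram
  th <- 2 * pi * (0:23) / 24
  r_ring <- 0.5 / (2 * sin(pi / 24))
  pts <- cbind(r_ring * cos(th), r_ring * sin(th), 0)
  cal <- calibrate_neighbor_radius(pts, target_count = 4)
  expect_equal(cal$fraction, 1)
  expect_equal(length(cal$histogram), 1L)
  expect_equal(cal$mode, 4)
  expect_error(calibrate_neighbor_radius(pts[1:3, ], target_count = 4),
               "at least")
})

test_that("neighbor counts at the calibrated radius match a brute-force scan", {
  set.seed(17)
  pts <- matrix(stats::runif(600, 0, 4), ncol = 3)
  cal <- calibrate_neighbor_radius(pts, target_count = 10)
  r_nm <- cal$radius_A / 10
  want <- vapply(seq_len(200), function(i)
    sum(sqrt(colSums((t(pts) - pts[i, ])^2)) <= r_nm) - 1L, 1L)
  expect_equal(unname(cal$counts), want)
})

test_that("solvent vectors invert the normalized neighbor-COM vector", {
  expect_equal(solvent_vector(c(0, 0, 0), matrix(c(1, 0, 0), 1)),
               c(-1, 0, 0))
  # symmetric neighbors -> degenerate
  sym <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  expect_error(solvent_vector(c(0, 0, 0), sym), "degenerate")
  # random neighbors vs direct recomputation
  set.seed(23)
  for (i in 1:10) {
    ctr <- stats::rnorm(3)
    nb <- matrix(stats::rnorm(30), ncol = 3)
    v <- colMeans(nb) - ctr
    expect_equal(solvent_vector(ctr, nb), -v / sqrt(sum(v^2)),
                 tolerance = 1e-12)
  }
})

test_that("patch membership follows the strict angular cutoff", {
  # center and one neighbor 0.5 nm apart with controlled vector angles
  ca <- rbind(c(0, 0, 0), c(0.5, 0, 0))
  mk_vec <- function(deg) {
    rad <- deg * pi / 180
    rbind(c(0, 0, 1), c(sin(rad), 0, cos(rad)))
  }
  run <- function(deg) {
    ps <- generate_patches(ca, uids = 1:2, resnames = c("ALA", "GLY"),
                           vectors = mk_vec(deg), search_radius_A = 13,
                           theta_cut = 125)
    ps$patches[[1]]$members
  }
  expect_equal(run(0), c(1L, 2L))      # identical vectors join
  expect_equal(run(120), c(1L, 2L))    # inside the cutoff
  expect_equal(run(125), 1L)           # boundary excluded (strict <)
  expect_equal(run(130), 1L)           # outside
  # isolated residue: singleton patch
  far <- rbind(c(0, 0, 0), c(5, 0, 0))
  ps <- generate_patches(far, 1:2, c("ALA", "GLY"), mk_vec(0))
  expect_equal(ps$patches[[1]]$n_res, 1L)
})

test_that("patch generation covers all valid centers; membership is mutual", {
  p <- test_protein()
  sasa <- test_sasa()
  surf <- select_surface_residues(sasa)
  ca <- calpha_coords(p)[surf, , drop = FALSE]
  vecs <- surface_solvent_vectors(ca, surf, 13)
  ps <- generate_patches(ca, surf, p$residues$resname[surf], vecs)
  n_valid <- sum(!is.na(vecs[, 1]))
  expect_equal(length(ps$patches), n_valid)
  centers <- vapply(ps$patches, `[[`, surf[1], "center_uid")
  for (pp in ps$patches) expect_true(pp$center_uid %in% pp$members)
  # the fixed-radius + angle rule is symmetric: b in patch(a) iff a in
  # patch(b) (for valid centers)
  member_map <- stats::setNames(lapply(ps$patches, `[[`, "members"), centers)
  for (k in seq(1, length(centers), by = 7)) {
    a <- as.character(centers[k])
    for (b in setdiff(member_map[[a]], centers[k]))
      expect_true(centers[k] %in% member_map[[as.character(b)]])
  }
})

test_that("patch descriptors are member means of the bundled table", {
  tab <- descriptor_table()
  one <- patch_descriptors("TRP", tab)
  row <- tab[tab$resname == "TRP", ]
  expect_equal(unname(one), unlist(row[, c("HB", "PB", "GSI", "nVdW")]),
               ignore_attr = TRUE)
  two <- patch_descriptors(c("TRP", "ALA"), tab)
  rows <- tab[match(c("TRP", "ALA"), tab$resname), ]
  expect_equal(unname(two["HB"]), mean(rows$HB))
  set.seed(4)
  nine <- sample(tab$resname, 9, TRUE)
  got <- patch_descriptors(nine, tab)
  m <- match(nine, tab$resname)
  expect_equal(unname(got),
               c(mean(tab$HB[m]), mean(tab$PB[m]), mean(tab$GSI[m]),
                 mean(tab$nVdW[m])), tolerance = 1e-12)
  expect_error(patch_descriptors("XXX", tab), "XXX")
})

test_that("decile ranking maps extremes, the median, and self-ranks uniformly", {
  set.seed(6)
  vals <- stats::rnorm(1000)
  expect_equal(rank_interface(max(vals) + 1, vals), 1L)
  expect_equal(rank_interface(min(vals) - 1, vals), 10L)
  med_rank <- rank_interface(stats::median(vals), vals)
  expect_true(med_rank %in% c(5L, 6L))
  expect_error(rank_interface(0, stats::rnorm(5)), "at least 10")
  # ranking each member of a population against itself fills each decile
  # with 10% +/- 1 of the population
  pop <- stats::rnorm(100)
  ranks <- vapply(pop, rank_interface, 1L, patch_values = pop)
  tab <- table(factor(ranks, levels = 1:10))
  expect_true(all(abs(as.numeric(tab) - 10) <= 1))
  # cross-check F against a direct percentile computation
  for (v in sample(pop, 10)) {
    F <- mean(pop < v)
    expect_equal(rank_interface(v, pop),
                 max(1L, min(10L, 10L - as.integer(floor(10 * F)))))
  }
})

test_that("patch overlap hits its bounds and is monotone under shrinking", {
  iface <- function(uids) data.frame(residue_uid = uids)
  patch <- list(members = 1:9)
  expect_equal(patch_overlap(patch, iface(101:110)), 0)
  expect_equal(patch_overlap(patch, iface(2:4)), 100)
  expect_equal(patch_overlap(patch, iface(c(1:3, 101:107))), 30)
  expect_error(patch_overlap(patch, iface(integer(0))), "empty")
  # shrinking the interface toward a subset of the patch never lowers overlap
  full <- c(1:5, 201:205)
  prev <- patch_overlap(patch, iface(full))
  for (k in c(8, 6, 5)) {
    cur <- patch_overlap(patch, iface(full[seq_len(k)]))
    expect_gte(cur, prev - 1e-12)
    prev <- cur
  }
  expect_true(all(vapply(list(1:9, 5:13, 100:120), function(m)
    patch_overlap(list(members = m), iface(4:13)), 1) >= 0))
})
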