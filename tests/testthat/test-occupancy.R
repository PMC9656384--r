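# Percent occupancy, interface collapsing and filtering, group fractions,
# and contact surface area.

# random small system used by the brute-force occupancy oracle
random_contact_system <- function(nf = 20, n_res = 10, n_olig = 2, n_beads = 3,
                                  seed = 13) {
  set.seed(seed)
  prot_xyz <- matrix(stats::runif(2 * n_res * 3, 0, 2), ncol = 3)
  model <- protein_model(data.frame(
    elety = rep(c("CA", "CB"), n_res), element = "C",
    resid = rep(seq_len(n_res), each = 2),
    resname = sample(aa_grouping()$resname, n_res, TRUE)[rep(seq_len(n_res), each = 2)],
    chain = "A", x = prot_xyz[, 1], y = prot_xyz[, 2], z = prot_xyz[, 3],
    stringsAsFactors = FALSE
  ))
  oxyz <- lapply(seq_len(n_olig), function(i)
    array(stats::runif(nf * n_beads * 3, 0, 2.3), c(nf, n_beads, 3)))
  traj <- study_trajectory(seq_len(nf) * 10, model$xyz_ref, oxyz,
                           rep(c("ON", "OFF"), each = nf / 2),
                           model$atoms$mass,
                           rep(list(rep(1, n_beads)), n_olig))
  list(model = model, traj = traj, oxyz = oxyz)
}

test_that("occupancy equals an all-pairs brute-force scan per frame", {
  sys <- random_contact_system()
  occ <- residue_occupancy(sys$traj, sys$model, window = "ALL", cutoff = 4)
  # oracle: triple loop over frames, residues, (oligomer, bead, atom)
  nf <- 20
  counts <- numeric(10)
  for (f in seq_len(nf)) for (r in seq_len(10)) {
    atoms <- which(sys$model$atoms$residue_uid == r)
    hit <- FALSE
    for (i in 1:2) for (b in 1:3) for (a in atoms) {
      dd <- sqrt(sum((sys$oxyz[[i]][f, b, ] -
                        unlist(sys$model$atoms[a, c("x", "y", "z")]))^2))
      if (dd <= 0.4) hit <- TRUE
    }
    counts[r] <- counts[r] + hit
  }
  expect_equal(occ$occupancy_pct, 100 * counts / nf, tolerance = 1e-12)
  # per-oligomer maps never exceed the pooled map
  occ1 <- residue_occupancy(sys$traj, sys$model, "ALL", oligomer = 1)
  expect_true(all(occ1$occupancy_pct <= occ$occupancy_pct + 1e-12))
})

test_that("occupancy windows scale by the window frame count", {
  # contact in exactly the first 2 of 20 frames
  nf <- 20
  pos <- matrix(rep(c(10, 0, 0), each = nf), ncol = 3)
  pos[1:2, ] <- matrix(rep(c(0.03, 0, 0), each = 2), ncol = 3)
  tr <- point_trajectory(list(pos), phase = rep(c("ON", "OFF"), each = 10))
  prot <- toy_model("ALA", xyz = matrix(0, 1, 3))
  expect_equal(residue_occupancy(tr, prot, "ALL")$occupancy_pct, 10)
  expect_equal(residue_occupancy(tr, prot, "ON")$occupancy_pct, 20)
  expect_equal(residue_occupancy(tr, prot, "OFF")$occupancy_pct, 0)
  # glued all frames -> 100%
  glued <- point_trajectory(list(matrix(rep(c(0.03, 0, 0), each = nf),
                                        ncol = 3)))
  expect_equal(residue_occupancy(glued, prot, "ALL")$occupancy_pct, 100)
})

test_that("non-surface contacts raise a warning when a surface is supplied", {
  sys <- random_contact_system()
  touched <- residue_occupancy(sys$traj, sys$model, "ALL")
  hot <- touched$residue_uid[touched$occupancy_pct > 0][1]
  expect_warning(
    residue_occupancy(sys$traj, sys$model, "ALL",
                      surface = setdiff(1:10, hot)),
    "non-surface"
  )
})

mk_map <- function(occ, model) {
  out <- model$residues
  out$occupancy_pct <- occ
  structure(out, class = c("occupancy_map", "data.frame"),
            cutoff_A = 4, window = "ON", n_window_frames = 100,
            oligomer = "any", trial = NA,
            model_signature = patchbind:::model_signature(model))
}

test_that("collapsing unions residues and averages non-zero occupancies", {
  model <- toy_model(c("ASP", "LYS", "SER", "LEU", "PHE"))
  # single map: identity restricted to non-zero residues
  m1 <- mk_map(c(0, 60, 0, 30, 0), model)
  c1 <- collapse_interfaces(list(m1))
  expect_equal(c1$residue_uid, c(2L, 4L))
  expect_equal(c1$occupancy_pct, c(60, 30))
  # residue at 60% once, absent in six others -> stays 60%
  zeros <- mk_map(rep(0, 5), model)
  c7 <- collapse_interfaces(c(list(m1), rep(list(zeros), 6)))
  expect_equal(c7$occupancy_pct[c7$residue_uid == 2], 60)
  # averaging over all trials including zeros, behind the flag
  c7z <- collapse_interfaces(c(list(m1), rep(list(zeros), 6)),
                             average_zeros = TRUE)
  expect_equal(c7z$occupancy_pct[c7z$residue_uid == 2], 60 / 7)
  # 7 random maps vs an independent dictionary-merge oracle
  set.seed(31)
  maps <- lapply(1:7, function(i)
    mk_map(sample(c(0, 0, 25, 50, 75, 100), 5, TRUE), model))
  got <- collapse_interfaces(maps)
  dict <- new.env()
  for (mp in maps) for (r in seq_len(5)) {
    v <- mp$occupancy_pct[r]
    if (v > 0) assign(as.character(r), c(get0(as.character(r), dict), v), dict)
  }
  want_uids <- sort(as.integer(ls(dict)))
  expect_equal(got$residue_uid, want_uids)
  for (u in want_uids)
    expect_equal(got$occupancy_pct[got$residue_uid == u],
                 mean(get(as.character(u), dict)))
  # mismatched protein models error
  other <- toy_model(c("GLY", "GLY", "GLY"))
  expect_error(collapse_interfaces(list(m1, mk_map(c(1, 1, 1), other))),
               "different protein models")
})

test_that("occupancy filtering is strict and nested", {
  model <- toy_model(c("ALA", "GLY", "SER", "THR"))
  ci <- collapse_interfaces(list(mk_map(c(40, 50, 51, 95), model)))
  f50 <- filter_by_occupancy(ci, 50)
  expect_equal(f50$occupancy_pct, c(51, 95))  # strict >
  f0 <- filter_by_occupancy(ci, 0)
  expect_equal(nrow(f0), 4L)
  f90 <- filter_by_occupancy(ci, 90)
  expect_true(all(f90$residue_uid %in% f50$residue_uid))
  expect_equal(attr(f90, "filter_pct"), 90)
  expect_error(filter_by_occupancy(ci, 100), "\\[0, 100\\)")
})

test_that("group fractions partition unity with aromatic inside hydrophobic", {
  model <- toy_model(c("ASP", "LYS", "SER", "LEU", "PHE"))
  ci <- collapse_interfaces(list(mk_map(rep(60, 5), model)))
  fr <- aa_group_fractions(ci)
  expect_equal(unname(fr), c(0.2, 0.2, 0.2, 0.4, 0.2))
  all_ser <- collapse_interfaces(list(mk_map(rep(60, 3),
                                             toy_model(rep("SER", 3)))))
  fr2 <- aa_group_fractions(all_ser)
  expect_equal(unname(fr2["polar"]), 1)
  expect_equal(sum(fr2[c("negative", "positive", "polar", "hydrophobic")]), 1)
  # property over random interfaces
  set.seed(8)
  for (i in 1:20) {
    rn <- sample(aa_grouping()$resname, sample(3:15, 1), TRUE)
    fr3 <- aa_group_fractions(data.frame(resname = rn))
    expect_equal(sum(fr3[c("negative", "positive", "polar", "hydrophobic")]),
                 1, tolerance = 1e-12)
    expect_lte(fr3[["aromatic"]], fr3[["hydrophobic"]])
  }
  expect_error(aa_group_fractions(data.frame(resname = character(0))), "empty")
})

test_that("contact surface area is the member-SASA sum and is additive", {
  sasa <- structure(data.frame(residue_uid = 1:5, resid = 1:5, chain = "A",
                               resname = "ALA", sasa = c(50, 30, 20, 10, 5)),
                    class = c("sasa_profile", "data.frame"), total = 115)
  iface <- data.frame(residue_uid = c(1L, 2L))
  expect_equal(contact_surface_area(iface, sasa), 80)
  expect_equal(contact_surface_area(iface[0, , drop = FALSE], sasa), 0)
  expect_error(contact_surface_area(data.frame(residue_uid = 9L), sasa),
               "no SASA value")
  # 30-residue random interface vs independent summation; additivity
  big <- structure(data.frame(residue_uid = 1:40, resid = 1:40, chain = "A",
                              resname = "ALA",
                              sasa = stats::runif(40, 0, 120)),
                   class = c("sasa_profile", "data.frame"))
  set.seed(2)
  uids <- sample(40, 30)
  whole <- contact_surface_area(data.frame(residue_uid = uids), big)
  expect_equal(whole, sum(big$sasa[uids]))
  part <- contact_surface_area(data.frame(residue_uid = uids[1:12]), big) +
    contact_surface_area(data.frame(residue_uid = uids[13:30]), big)
  expect_equal(whole, part, tolerance = 1e-12)
})
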