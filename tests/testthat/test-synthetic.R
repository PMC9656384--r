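# The synthetic generators: determinism, composition accounting, scripted
# trajectories vs ground truth, and restrained-chain Rg behavior.

test_that("synthetic proteins are deterministic and composition-exact", {
  a <- synth_protein(n_residues = 60, seed = 9)
  b <- synth_protein(n_residues = 60, seed = 9)
  expect_identical(a$atoms, b$atoms)
  expect_false(identical(a$atoms$resname,
                         synth_protein(n_residues = 60, seed = 10)$atoms$resname))
  # largest-remainder counts: composition matched exactly
  comp <- c(negative = 0.12, positive = 0.09, polar = 0.30, hydrophobic = 0.48)
  p <- synth_protein(n_residues = 300, composition = comp, seed = 2)
  lab <- assign_groups(p)
  counts <- table(factor(lab$group, levels = c("negative", "positive",
                                               "polar", "hydrophobic")))
  expect_equal(as.numeric(counts), c(36, 27, 93, 144))  # residual 1% -> polar
  # all-polar corner
  tiny <- synth_protein(20, composition = c(polar = 1), seed = 1)
  expect_true(all(assign_groups(tiny)$group == "polar"))
  expect_error(synth_protein(300, composition = c(polar = 1.2)), "exceed")
})

test_that("synthetic trajectories are byte-identical under a fixed seed", {
  p <- synth_protein(40, radius_nm = 2.0, seed = 5)
  hot <- nearby_residues(p, c(1, 0, 0), k = 3)
  scen <- function() synth_scenario(
    scripts = list(list(scenario_segment("BIND", 6, targets = hot),
                        scenario_segment("FREE", 6))),
    n_frames = 12, split_frame = 6, seed = 77)
  run <- function() synth_trajectory(p, list(oligomer_spec("PEG")), scen())
  t1 <- run(); t2 <- run()
  f1 <- tempfile(); f2 <- tempfile()
  write_xyz_trajectory(f1, t1$trajectory$oligomer_xyz[[1]],
                       t1$trajectory$times_ps, rep("C", 33))
  write_xyz_trajectory(f2, t2$trajectory$oligomer_xyz[[1]],
                       t2$trajectory$times_ps, rep("C", 33))
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(t1$ground_truth$class, t2$ground_truth$class)
})

test_that("a four-mode script reproduces its ground truth exactly", {
  p <- synth_protein(150, radius_nm = 2.6, seed = 3)
  sasa <- shrake_rupley_sasa(p, n_points = 240)
  surf <- select_surface_residues(sasa)
  hot1 <- nearby_residues(p, c(1, 0, 0), k = 4, surface = surf)
  hot2 <- nearby_residues(p, c(cos(0.3), sin(0.3), 0), k = 4, surface = surf)
  scen <- synth_scenario(
    scripts = list(
      list(scenario_segment("BIND", 20, targets = hot1),
           scenario_segment("FREE", 10),
           scenario_segment("BOTH", 10, targets = hot1, partner = 2)),
      list(scenario_segment("FREE", 10),
           scenario_segment("AGGREGATE", 20, partner = 3),
           scenario_segment("BOTH", 10, targets = hot2, partner = 1)),
      list(scenario_segment("FREE", 10),
           scenario_segment("AGGREGATE", 20, partner = 2),
           scenario_segment("FREE", 10))),
    n_frames = 40, split_frame = 20, rg_on = 1.5, margin_nm = 0.2, seed = 19)
  olig <- replicate(3, oligomer_spec("PLGA"), simplify = FALSE)
  st <- synth_trajectory(p, olig, scen)
  tl <- classify_timeline(com_distance_series(st$trajectory))
  got <- matrix(as.character(tl$class), 40, 3)
  expect_identical(got, st$ground_truth$class)
  # scripted occupancy recovered exactly: BIND 20 + BOTH 10 of 40 frames
  occ <- residue_occupancy(st$trajectory, p, window = "ALL")
  expect_equal(occ$occupancy_pct[hot1], rep(75, 4))
  gt <- gt_contact_fraction(st$ground_truth, p, window = "ALL")
  expect_equal(occ$occupancy_pct, unname(gt), tolerance = 1e-12)
})

test_that("infeasible scripts are rejected", {
  p <- synth_protein(40, radius_nm = 2.0, seed = 5)
  hot <- nearby_residues(p, c(1, 0, 0), k = 3)
  # margin too large for the contact cutoff
  expect_error(synth_trajectory(
    p, list(oligomer_spec("PEG")),
    synth_scenario(list(list(scenario_segment("FREE", 4))), n_frames = 4,
                   margin_nm = 0.5, seed = 1)), "infeasible")
  # AGGREGATE partners must be mutual
  scen <- synth_scenario(
    scripts = list(
      list(scenario_segment("AGGREGATE", 4, partner = 2)),
      list(scenario_segment("FREE", 4))),
    n_frames = 4, seed = 1)
  expect_error(synth_trajectory(p, replicate(2, oligomer_spec("PEG"),
                                             simplify = FALSE), scen),
               "not mutual")
  # durations must cover the trajectory
  expect_error(synth_scenario(list(list(scenario_segment("FREE", 3))),
                              n_frames = 5), "sum to 3")
})

test_that("restrained chains hold their Rg target and relax on release", {
  spec <- oligomer_spec("PLGA-PEG")
  # rod bound: Lc/sqrt(12) ~ 3.0 nm, so 2.0 nm is feasible and 3.5 is not
  expect_error(synth_restrained_chain(spec, 3.5, 10), "rod bound")
  ch <- synth_restrained_chain(spec, 1.5, n_frames = 120, seed = 4,
                               split_frame = 60, off_mode = "collapse",
                               relax_tau_ps = 150)
  on_rg <- ch$rg[1:60]
  expect_true(all(abs(on_rg - 1.5) / 1.5 <= 0.05))
  expect_true(mean(on_rg) > 1.425 && mean(on_rg) < 1.575)
  # per-frame Rg equals the recomputed mass-weighted Rg of the coordinates
  for (f in c(1, 30, 90))
    expect_equal(com_and_rg(ch$xyz[f, , ], spec$masses)$rg, ch$rg[f],
                 tolerance = 1e-9)
  # OFF phase: smoothed monotone decay to the collapsed plateau < 1.2 nm
  off_rg <- patchbind:::moving_average(ch$rg[61:120], 10)
  expect_true(all(diff(off_rg) <= 1e-9))
  expect_lt(off_rg[length(off_rg)], 1.2)
  # expansion mode rises instead
  ex <- synth_restrained_chain(spec, 1.1, n_frames = 60, seed = 4,
                               split_frame = 30, off_mode = "expand",
                               relax_tau_ps = 100)
  expect_gt(mean(ex$rg[55:60]), 1.7)
})

test_that("oligomer specs reproduce the study chain geometry", {
  plga <- oligomer_spec("PLGA")
  peg <- oligomer_spec("PEG")
  co <- oligomer_spec("PLGA-PEG")
  expect_equal(c(plga$n_mon, peg$n_mon, co$n_mon), c(20L, 33L, 25L))
  expect_equal(c(plga$lc_nm, peg$lc_nm, co$lc_nm), c(10.5, 10.4, 10.4))
  # contour length ~ (n-1) * spacing by construction
  expect_equal(plga$spacing_nm * 19, 10.5)
  # diblock mass split: 12 LGA + 13 EG beads
  expect_equal(sum(co$masses == 65), 12L)
  expect_equal(sum(co$masses == 44), 13L)
})
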