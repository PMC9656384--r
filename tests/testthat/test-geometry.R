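# Geometric primitives: COM/Rg, superposed RMSD, Shrake-Rupley SASA,
# surface selection, ellipsoid fit, neighbor search.

random_rotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3)))
}

test_that("COM and Rg match definitions and a pairwise-distance oracle", {
  one <- com_and_rg(matrix(c(1, 2, 3), 1))
  expect_equal(one$com, c(1, 2, 3), ignore_attr = TRUE)
  expect_equal(one$rg, 0)
  two <- com_and_rg(rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(two$rg, 0.5)
  # mass-weighted 20-bead chain vs the independent pairwise identity
  # Rg^2 = sum_ij m_i m_j r_ij^2 / (2 M^2)
  set.seed(7)
  xyz <- matrix(stats::rnorm(60), ncol = 3)
  m <- stats::runif(20, 0.5, 2)
  got <- com_and_rg(xyz, m)$rg
  M <- sum(m)
  acc <- 0
  for (i in 1:20) for (j in 1:20)
    acc <- acc + m[i] * m[j] * sum((xyz[i, ] - xyz[j, ])^2)
  expect_equal(got, sqrt(acc / (2 * M^2)), tolerance = 1e-12)
  expect_error(com_and_rg(xyz[0, , drop = FALSE]), "empty")
  expect_error(com_and_rg(xyz, rep(-1, 20)), "positive")
})

test_that("backbone RMSD is zero on identity and rigid motion, exact on a shift", {
  set.seed(1)
  ref <- matrix(stats::rnorm(30), ncol = 3)
  expect_equal(backbone_rmsd(ref, ref), 0)
  R <- random_rotation()
  moved <- sweep(ref %*% R, 2, c(1, -2, 0.5), "+")
  expect_lt(backbone_rmsd(moved, ref, superpose = TRUE), 1e-6)
  expect_gt(backbone_rmsd(moved, ref, superpose = FALSE), 0.1)
  # closed form: +0.1 nm on one of N=10 atoms, no superposition
  shifted <- ref
  shifted[1, 1] <- shifted[1, 1] + 0.1
  expect_equal(backbone_rmsd(shifted, ref, superpose = FALSE),
               0.1 / sqrt(10), tolerance = 1e-12)
  expect_error(backbone_rmsd(ref[1:5, ], ref), "differ")
})

test_that("SASA of an isolated atom matches the analytic sphere within 1%", {
  m <- protein_model(data.frame(
    elety = "SE", element = "SE", resid = 1L, resname = "MET", chain = "A",
    x = 0, y = 0, z = 0, stringsAsFactors = FALSE
  ))  # Se radius 1.9 A
  s <- shrake_rupley_sasa(m, probe_radius = 1.4, n_points = 960)
  analytic <- 4 * pi * 3.3^2
  expect_equal(s$sasa, analytic, tolerance = 0.01)
  expect_equal(attr(s, "total"), s$sasa)
})

test_that("an atom enclosed by a tight shell has (near) zero SASA", {
  dirs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  atoms <- data.frame(
    elety = "C", element = "C", resid = c(1L, rep(2L, nrow(dirs))),
    resname = c("ALA", rep("GLY", nrow(dirs))), chain = "A",
    x = c(0, dirs[, 1] / 10), y = c(0, dirs[, 2] / 10),
    z = c(0, dirs[, 3] / 10), stringsAsFactors = FALSE
  )
  s <- shrake_rupley_sasa(protein_model(atoms), n_points = 960)
  expect_equal(s$sasa[1], 0, tolerance = 1e-6)
})

test_that("SASA matches an independent Monte-Carlo quadrature on a cluster", {
  set.seed(11)
  n <- 5
  xyz <- matrix(stats::rnorm(3 * n, sd = 0.15), ncol = 3)  # nm, overlapping
  m <- protein_model(data.frame(
    elety = "C", element = "C", resid = seq_len(n), resname = "ALA",
    chain = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  ))
  got <- attr(shrake_rupley_sasa(m, n_points = 960), "total")
  # oracle: random-direction quadrature at 1e4 points per atom
  coords <- xyz * 10
  radii <- m$atoms$radius + 1.4
  pts <- matrix(stats::rnorm(3e4), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2))
  oracle <- 0
  for (i in seq_len(n)) {
    p <- sweep(pts * radii[i], 2, coords[i, ], "+")
    free <- rep(TRUE, nrow(p))
    for (j in seq_len(n)[-i]) {
      d2 <- (p[, 1] - coords[j, 1])^2 + (p[, 2] - coords[j, 2])^2 +
        (p[, 3] - coords[j, 3])^2
      free <- free & d2 >= radii[j]^2
    }
    oracle <- oracle + 4 * pi * radii[i]^2 * mean(free)
  }
  expect_equal(got, oracle, tolerance = 0.02)
})

test_that("SASA is conserved across residues and monotone under crowding", {
  s <- test_sasa()
  expect_equal(sum(s$sasa), attr(s, "total"), tolerance = 1e-9)
  expect_true(all(s$sasa >= 0))
  # adding atoms around a fixed atom never increases its SASA
  base <- data.frame(elety = "C", element = "C", resid = 1L, resname = "ALA",
                     chain = "A", x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  prev <- Inf
  for (k in 1:4) {
    extra <- data.frame(elety = "C", element = "C", resid = 2L,
                        resname = "GLY", chain = "A",
                        x = 0.25 * cos(2 * pi * seq_len(k) / 4),
                        y = 0.25 * sin(2 * pi * seq_len(k) / 4), z = 0,
                        stringsAsFactors = FALSE)
    s_k <- shrake_rupley_sasa(protein_model(rbind(base, extra)), n_points = 480)
    expect_lte(s_k$sasa[1], prev)
    prev <- s_k$sasa[1]
  }
})

test_that("surface selection uses a strict threshold", {
  fake <- structure(data.frame(residue_uid = 1:3, resid = 1:3, resname = "ALA",
                               chain = "A", sasa = c(0.5, 1.0, 1.1)),
                    class = c("sasa_profile", "data.frame"))
  expect_equal(select_surface_residues(fake, 1), 3L)
  fake$sasa <- c(0, 0, 0)
  expect_length(select_surface_residues(fake, 1), 0L)
  # construction guarantees exposure on a spherical shell
  expect_length(select_surface_residues(test_sasa(), 1),
                n_residues(test_protein()))
})

test_that("ellipsoid axes recover spheres and anisotropic shapes", {
  sph <- toy_model(rep("ALA", 80), xyz = patchbind:::unit_sphere_points(80) * 2)
  fit <- ellipsoid_axes(sph, 1:80)
  expect_equal(fit$semi_axes, rep(2, 3), tolerance = 0.05)
  expect_equal(crossprod(fit$axes), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  # axis-aligned ellipsoid (2, 3, 1) nm
  pts <- patchbind:::unit_sphere_points(200)
  ell <- sweep(pts, 2, c(2, 3, 1), "*")
  me <- toy_model(rep("ALA", 200), xyz = ell)
  fit2 <- ellipsoid_axes(me, 1:200)
  expect_equal(fit2$semi_axes, c(3, 2, 1), tolerance = 0.05)
  # rigid-body invariance of the semi-axis lengths
  R <- random_rotation()
  moved <- sweep(ell %*% R, 2, c(5, -1, 2), "+")
  fit3 <- ellipsoid_axes(toy_model(rep("ALA", 200), xyz = moved), 1:200)
  expect_equal(fit3$semi_axes, fit2$semi_axes, tolerance = 1e-9)
  # coplanar input errors
  flat <- cbind(stats::rnorm(10), stats::rnorm(10), 0)
  expect_error(ellipsoid_axes(toy_model(rep("ALA", 10), xyz = flat), 1:10),
               "degenerate|coplanar")
})

test_that("fixed-radius neighbor search equals a brute-force scan", {
  set.seed(5)
  for (rep in 1:10) {
    pts <- matrix(stats::runif(150, 0, 3), ncol = 3)
    labs <- sample(1000, 50)
    center <- sample(labs, 1)
    r <- stats::runif(1, 0.3, 1.5)
    got <- nearest_neighbors(pts, labs, center, r)
    ci <- match(center, labs)
    want <- sort(labs[which(sqrt(colSums((t(pts) - pts[ci, ])^2)) <= r)])
    want <- want[want != center]
    expect_identical(got, want)
  }
  pts <- matrix(0, 4, 3)
  expect_setequal(nearest_neighbors(pts, 1:4, 2, 1), c(1, 3, 4))
  far <- rbind(c(0, 0, 0), c(5, 5, 5))
  expect_length(nearest_neighbors(far, 1:2, 1, 1), 0L)
  expect_error(nearest_neighbors(far, 1:2, 99, 1), "unknown center")
})
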