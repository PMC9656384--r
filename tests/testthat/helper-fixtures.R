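# Fixtures built in code: toy structures, random models, and tiny
# single-bead trajectory builders used across the suite.

# A 3-residue toy PDB (ALA-GLY-SER) written to a tempfile.
write_toy_pdb <- function(path = tempfile(fileext = ".pdb")) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.988  -0.773  -1.199  1.00  0.00           C",
    "ATOM      6  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      7  CA  GLY A   2       3.985   2.835   0.000  1.00  0.00           C",
    "ATOM      8  C   GLY A   2       5.498   2.705   0.000  1.00  0.00           C",
    "ATOM      9  O   GLY A   2       6.062   1.610   0.000  1.00  0.00           O",
    "ATOM     10  N   SER A   3       6.168   3.852   0.000  1.00  0.00           N",
    "ATOM     11  CA  SER A   3       7.621   3.854   0.000  1.00  0.00           C",
    "ATOM     12  C   SER A   3       8.176   5.270   0.000  1.00  0.00           C",
    "ATOM     13  O   SER A   3       7.425   6.253   0.000  1.00  0.00           O",
    "ATOM     14  CB  SER A   3       8.146   3.091   1.221  1.00  0.00           C",
    "ATOM     15  OG  SER A   3       7.657   1.760   1.221  1.00  0.00           O",
    "END"
  )
  writeLines(lines, path)
  path
}

# Minimal protein model from explicit atom rows.
toy_model <- function(resnames = c("ALA", "GLY", "SER"),
                      xyz = NULL, elety = NULL, chain = "A") {
  n <- length(resnames)
  if (is.null(xyz)) xyz <- matrix(seq_len(3 * n) / 10, ncol = 3)
  if (is.null(elety)) elety <- rep("CA", n)
  protein_model(data.frame(
    elety = elety, element = "C", resid = seq_len(n), resname = resnames,
    chain = chain, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  ))
}

# A study trajectory of single-bead oligomers at scripted positions.
# `positions` is a list per oligomer of [n_frames, 3] COM coordinate
# matrices (nm); the protein is a single atom at the origin.
point_trajectory <- function(positions, phase = NULL, dt = 10) {
  nf <- nrow(positions[[1]])
  prot <- toy_model("ALA", xyz = matrix(0, 1, 3))
  if (is.null(phase)) phase <- rep("ON", nf)
  study_trajectory(
    times_ps = seq_len(nf) * dt,
    protein_xyz = prot$xyz_ref,
    oligomer_xyz = lapply(positions, function(m) {
      a <- array(0, c(nf, 1, 3)); a[, 1, ] <- m; a
    }),
    phase = phase,
    protein_masses = prot$atoms$mass,
    oligomer_masses = rep(list(1), length(positions))
  )
}

# Small shared synthetic protein for surface/patch tests (cached per run).
test_protein <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synth_protein(n_residues = 150,
                                                radius_nm = 2.6, seed = 3)
    cache
  }
})

test_sasa <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- shrake_rupley_sasa(test_protein(),
                                                     n_points = 240)
    cache
  }
})
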