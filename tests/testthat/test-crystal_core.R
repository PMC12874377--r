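test_that("cell volume matches the vector triple product", {
  expect_equal(cell_volume(unit_cell(1, 1, 1)), 1.0)
  expect_equal(cell_volume(unit_cell(2, 3, 4)), 24.0)
  ## hexagonal worked cell against |a . (b x c)| from explicit vectors
  cellh <- unit_cell(13.905, 13.905, 8.515, 90, 90, 120)
  M <- cell_matrix(cellh)
  vtriple <- abs(sum(M[1, ] * c(
    M[2, 2] * M[3, 3] - M[2, 3] * M[3, 2],
    M[2, 3] * M[3, 1] - M[2, 1] * M[3, 3],
    M[2, 1] * M[3, 2] - M[2, 2] * M[3, 1])))
  expect_equal(cell_volume(cellh), vtriple, tolerance = 1e-12)
  ## property: 400 random valid cells
  set.seed(42)
  for (i in 1:400) {
    cl <- random_cell()
    M <- cell_matrix(cl)
    expect_equal(cell_volume(cl), abs(det(M)), tolerance = 1e-10)
  }
})

test_that("degenerate cells are rejected", {
  expect_error(unit_cell(-1, 1, 1), "lengths")
  expect_error(unit_cell(1, 1, 1, 0, 90, 90), "angles")
  expect_error(unit_cell(1, 1, 1, 10, 10, 170), "degenerate")
})

test_that("densities reproduce the printed crystallographic values", {
  M_tcne <- 128.09
  ## cubic experimental cell
  expect_equal(compute_density(unit_cell(9.736, 9.736, 9.736), M_tcne,
                               Z = 6), 1.383, tolerance = 1e-3)
  ## monoclinic predicted cell
  expect_equal(compute_density(unit_cell(7.830, 6.128, 6.522, 90, 81.2,
                                         90), M_tcne, Z = 2),
               1.376, tolerance = 1e-3)
  ## hexagonal predicted cell, Z inferred from the 2x2x4 supercell of
  ## 144 molecules
  expect_equal(compute_density(unit_cell(13.905, 13.905, 8.515, 90, 90,
                                         120), M_tcne, Z = 9),
               1.343, tolerance = 1e-3)
  expect_error(compute_density(unit_cell(5, 5, 5), 0, Z = 1),
               "molar_mass")
  expect_error(compute_density(unit_cell(5, 5, 5), 100, Z = 0), "Z")
  ## M -> 0 limit drives density to 0
  expect_lt(compute_density(unit_cell(5, 5, 5), 1e-8, Z = 1), 1e-8)
})

test_that("supercells replicate counts and preserve density", {
  st <- toy_dimer_crystal()
  mass <- sum(st$molecules[[1]]$mass)
  sup <- build_supercell(st, c(2, 3, 4))
  expect_equal(sup$Z, 2 * 2 * 3 * 4)
  expect_equal(compute_density(sup, mass), compute_density(st, mass),
               tolerance = 1e-12)
  id <- build_supercell(st, c(1, 1, 1))
  expect_equal(id$Z, st$Z)
  expect_equal(id$centroids, st$centroids)
  ## replication factors of the reported simulation boxes
  expect_equal(9 * 2 * 2 * 4, 144)    # hexagonal candidate
  expect_equal(2 * 4 * 5 * 5, 200)    # monoclinic-like candidates
  expect_error(build_supercell(st, c(0, 1, 1)), "replication")
  expect_error(build_supercell(st, c(1.5, 1, 1)), "replication")
  ## property: density invariant for random replications
  set.seed(3)
  for (i in 1:5) {
    r <- sample(1:3, 3, replace = TRUE)
    expect_equal(compute_density(build_supercell(st, r), mass),
                 compute_density(st, mass), tolerance = 1e-12)
  }
})

test_that("automatic supercell sizing uses the strict-exceedance rule", {
  cellh <- unit_cell(13.905, 13.905, 8.515, 90, 90, 120)
  expect_identical(auto_supercell_size(cellh, 30), 4L)   # 30/8.515 = 3.52
  expect_identical(auto_supercell_size(cellh, 0), 1L)
  ## exact ratio: "exceeding" is strict
  expect_identical(auto_supercell_size(unit_cell(5, 7, 9), 5), 2L)
  expect_identical(auto_supercell_size(unit_cell(5, 7, 9), 10), 3L)
  ## exhaustive small-ratio table
  for (r in seq(0.1, 4.9, by = 0.2)) {
    expect_identical(auto_supercell_size(unit_cell(1, 2, 3), r),
                     as.integer(floor(r) + 1))
  }
  ## monotone in cutoff, anti-monotone in min length
  cuts <- seq(0, 40, by = 2.5)
  ns <- vapply(cuts, function(ct) auto_supercell_size(cellh, ct), 1L)
  expect_true(all(diff(ns) >= 0))
  lens <- seq(3, 12, by = 1)
  ns2 <- vapply(lens, function(l)
    auto_supercell_size(unit_cell(l, 20, 20), 15), 1L)
  expect_true(all(diff(ns2) <= 0))
})

test_that("packing-shell RMSD recognises identity, isometry and mismatch", {
  st <- toy_dimer_crystal()
  r0 <- packing_shell_rmsd(st, st, N = 8)
  expect_equal(r0$rmsd, 0, tolerance = 1e-8)
  expect_true(r0$match)

  ## a genuine isometry: a cubic crystal translated and rotated 90
  ## degrees about z (cart (x,y,z) -> (-y,x,z); frac likewise for a
  ## cubic cell)
  m1 <- st$molecules[[1]]; m2 <- st$molecules[[2]]
  stc <- crystal_structure(unit_cell(7, 7, 7), list(m1, m2),
                           rbind(c(0.15, 0.22, 0.31),
                                 c(0.63, 0.71, 0.44)))
  R90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  fr <- stc$centroids %*% t(R90)
  st2 <- crystal_structure(stc$cell, list(m1, m2), (fr + 0.21) %% 1,
                           rotations = lapply(stc$rotations,
                                              function(r) R90 %*% r))
  r1 <- packing_shell_rmsd(stc, st2, N = 8)
  expect_equal(r1$rmsd, 0, tolerance = 1e-6)
  expect_true(r1$match)

  ## symmetry of the score
  r1b <- packing_shell_rmsd(st2, stc, N = 8)
  expect_equal(r1$rmsd, r1b$rmsd, tolerance = 1e-8)

  ## superposition-destroying molecular rotations: every atom ends at
  ## least ~1 A from any compatible pairing, so RMSD must exceed 0.5
  st3 <- st
  flip <- matrix(c(1, 0, 0, 0, -1, 0, 0, 0, -1), 3, 3)
  st3$rotations <- lapply(st$rotations, function(r) flip %*% r)
  r2 <- packing_shell_rmsd(st, st3, N = 8)
  expect_gt(r2$rmsd, 0.50)
  expect_false(r2$match)

  ## formula mismatch gives a no-match result, not an error
  other <- crystal_structure(
    st$cell, list(rigid_molecule("O", matrix(0, 1, 3)),
                  rigid_molecule("O", matrix(0, 1, 3))),
    st$centroids)
  r3 <- packing_shell_rmsd(st, other, N = 4)
  expect_false(r3$match)
})

test_that("CIF and XYZ round-trips preserve geometry", {
  st <- toy_dimer_crystal()
  f <- tempfile(fileext = ".cif")
  write_cif(st, f)
  st2 <- read_cif(f, molecule_size = 2)
  expect_equal(st2$cell$a, st$cell$a, tolerance = 1e-7)
  expect_equal(st2$Z, st$Z)
  at1 <- polystab:::atom_table(st)
  at2 <- polystab:::atom_table(st2)
  expect_equal(at2$xyz, at1$xyz, tolerance = 1e-6)
  expect_equal(at2$element, at1$element)

  fx <- tempfile(fileext = ".xyz")
  write_xyz(st, fx)
  st3 <- read_xyz(fx, molecule_size = 2)
  expect_equal(polystab:::atom_table(st3)$xyz, at1$xyz,
               tolerance = 1e-6)

  ## unknown loops are skipped with a warning
  extra <- c(readLines(f), "loop_", "_symmetry_equiv_pos_as_xyz",
             "x,y,z")
  writeLines(extra, f)
  expect_warning(read_cif(f, molecule_size = 2), "ignoring")
})

test_that("force-field files round-trip and carry line-numbered errors", {
  ff <- toy_dimer_ff()
  f <- tempfile()
  write_forcefield(ff, f)
  ff2 <- read_forcefield(f)
  expect_equal(ff2$charges[["C"]], 0.3)
  expect_equal(ff2$cutoff_rd, ff$cutoff_rd)
  p <- polystab:::pair_params(ff2, "N", "C")
  expect_equal(unname(p["A"]), 25000)
  ## symmetric lookup
  expect_equal(polystab:::pair_params(ff2, "C", "N"), p)

  bad <- tempfile()
  writeLines(c("cutoff_rd 10", "pair C C A 1 B -2 C 3"), bad)
  expect_error(read_forcefield(bad), ":2:")
  writeLines(c("frobnicate 1"), bad)
  expect_error(read_forcefield(bad), "unknown directive")
})

test_that("charges come from the force field and must stay neutral", {
  st <- toy_dimer_crystal(q = 0)
  ff <- toy_dimer_ff(q = 0.25)
  st2 <- apply_charges(st, ff)
  expect_equal(st2$molecules[[1]]$charge, c(0.25, -0.25))
  ffbad <- force_field(charges = c(C = 0.3, N = 0.1), cutoff_rd = 5)
  expect_error(apply_charges(st, ffbad), "non-neutral")
})
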