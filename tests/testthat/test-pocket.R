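one_atom_topo <- function() {
  data.frame(serial = 1L, atom_name = "C5", residue_name = "LIG",
             residue_number = 1L, chain_id = "A", element = "C",
             b_factor = 0, stringsAsFactors = FALSE)
}

with_occluder <- function(occ_xyz, occ_elem = "C") {
  topo <- rbind(one_atom_topo(),
                data.frame(serial = 2L, atom_name = "CX",
                           residue_name = "ALA", residue_number = 10L,
                           chain_id = "A", element = occ_elem, b_factor = 0))
  list(topo = topo, xyz = rbind(c(0, 0, 0), occ_xyz))
}

test_that("the atom-free spherical region converges to the analytic
           volume", {
  region <- function(h) pocket_region(atom_spec(1, "C5"), radius = 6,
                                      grid_spacing = h)
  analytic <- 4 / 3 * pi * 6^3
  v <- vapply(c(1, 0.5, 0.25), function(h)
    pocket_volume(matrix(0, 1, 3), one_atom_topo(), region(h)), 0)
  expect_lt(abs(v[2] - analytic) / analytic, 0.05)
  err <- abs(v - analytic) / analytic
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.02)
})

test_that("a central occluder removes its analytic excluded sphere", {
  # carbon occluder: excluded radius 1.70 (vdW) + 1.40 (probe) = 3.1 A
  sys <- with_occluder(c(0, 0, 0))
  region <- pocket_region(atom_spec(1, "C5"), radius = 6, grid_spacing = 0.5)
  v <- pocket_volume(sys$xyz, sys$topo, region)
  analytic <- 4 / 3 * pi * (6^3 - 3.1^3)
  expect_lt(abs(v - analytic) / analytic, 0.05)
})

test_that("occluders beyond reach are ignored and extra occluders only
           shrink the volume", {
  region <- pocket_region(atom_spec(1, "C5"), radius = 6, grid_spacing = 0.5)
  v_free <- pocket_volume(matrix(0, 1, 3), one_atom_topo(), region)

  far <- with_occluder(c(6 + 1.7 + 1.4 + 0.2, 0, 0))
  expect_equal(pocket_volume(far$xyz, far$topo, region), v_free)

  near <- with_occluder(c(3, 0, 0))
  v1 <- pocket_volume(near$xyz, near$topo, region)
  expect_lt(v1, v_free)
  topo3 <- rbind(near$topo,
                 data.frame(serial = 3L, atom_name = "CY",
                            residue_name = "ALA", residue_number = 11L,
                            chain_id = "A", element = "C", b_factor = 0))
  xyz3 <- rbind(near$xyz, c(-3, 1, 0))
  expect_lte(pocket_volume(xyz3, topo3, region), v1)
})

test_that("the grid follows the center atom: translation leaves the
           volume unchanged", {
  sys <- with_occluder(c(2.5, 1, -1))
  region <- pocket_region(atom_spec(1, "C5"), radius = 6, grid_spacing = 0.5)
  v0 <- pocket_volume(sys$xyz, sys$topo, region)
  shift <- matrix(c(13.7, -8.1, 4.4), 2, 3, byrow = TRUE)
  expect_equal(pocket_volume(sys$xyz + shift, sys$topo, region), v0)
})

test_that("per-frame volume series distinguishes kinked from open
           geometries", {
  # two-frame toy: occluders closer to the center in frame 1 (kinked)
  topo <- rbind(one_atom_topo(),
                data.frame(serial = 2:4, atom_name = c("N1", "O1", "C2"),
                           residue_name = "GLN", residue_number = 147L,
                           chain_id = "A", element = c("N", "O", "C"),
                           b_factor = 0))
  kinked <- rbind(c(0, 0, 0), c(2.5, 0, 0), c(0, 2.5, 0), c(0, 0, 2.5))
  open <- rbind(c(0, 0, 0), c(5.0, 0, 0), c(0, 5.0, 0), c(0, 0, 5.0))
  coords <- array(c(kinked, open), c(4, 3, 2))
  traj <- trajectory(topo, coords, "toy")
  region <- pocket_region(atom_spec(1, "C5"), radius = 6, grid_spacing = 0.5)
  vs <- volume_series(traj, region)
  expect_equal(nrow(vs), 2)
  expect_lt(vs$volume_A3[1], vs$volume_A3[2])
  expect_true(all(vs$volume_A3 <= 4 / 3 * pi * 6^3))

  # rigid trajectory gives a constant series
  rigid <- trajectory(topo, array(rep(kinked, 3), c(4, 3, 3)), "rigid")
  expect_equal(length(unique(volume_series(rigid, region)$volume_A3)), 1L)
})

test_that("ligand atoms are not occluders under the protein default, and
           region parameters are validated", {
  sys <- with_occluder(c(0, 0, 0))
  sys$topo$residue_name[2] <- "LIG" # occluder becomes a ligand atom
  region <- pocket_region(atom_spec(1, "C5"), radius = 6, grid_spacing = 0.5)
  v <- pocket_volume(sys$xyz, sys$topo, region)
  expect_equal(v, pocket_volume(matrix(0, 1, 3), one_atom_topo(), region))
  all_region <- pocket_region(atom_spec(1, "C5"), radius = 6,
                              grid_spacing = 0.5, occluders = "all")
  expect_lt(pocket_volume(sys$xyz, sys$topo, all_region), v)
  expect_error(pocket_region(atom_spec(1, "C5"), grid_spacing = 7),
               "exceed")
})
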