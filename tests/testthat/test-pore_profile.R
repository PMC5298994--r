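test_that("PDB loading assigns Bondi radii and honors atom filters", {
  path <- toy_mixed_pdb()
  atoms <- load_structure(path)
  expect_s3_class(atoms, "atom_set")
  expect_equal(nrow(atoms), 3L)  # ATOM records only, no LIG, no HOH
  expect_equal(atoms$vdw[atoms$element == "C"], 1.70)
  expect_equal(atoms$vdw[atoms$element == "N"], 1.55)
  expect_equal(atoms$vdw[atoms$element == "O"], 1.52)
  # hetero flag adds the ligand but never the water
  with_het <- load_structure(path, include_hetero = TRUE)
  expect_equal(nrow(with_het), 4L)
  expect_false("HOH" %in% with_het$resid)
  # water-only file leaves nothing
  hoh <- write_toy_pdb(data.frame(
    record = "HETATM", name = "O", resid = "HOH", chain = "A", resno = 1L,
    x = 0, y = 0, z = 0, element = "O", stringsAsFactors = FALSE))
  expect_error(load_structure(hoh), "no atoms")
  expect_error(load_structure("/nonexistent.pdb"), "not found")
})

test_that("unknown elements get the default radius with a warning", {
  path <- write_toy_pdb(data.frame(
    record = "ATOM", name = "X1", resid = "UNK", chain = "A", resno = 1L,
    x = 0, y = 0, z = 0, element = "Q", stringsAsFactors = FALSE))
  expect_warning(atoms <- load_structure(path), "unknown element")
  expect_equal(atoms$vdw, 1.70)
})

test_that("ring geometries reproduce the analytic radius to 1e-9", {
  rings <- data.frame(z = c(-10, 5, 20),
                      ring_radius = c(12, 10, 6),
                      n_atoms = c(16, 12, 20),
                      vdw = c(1.7, 1.7, 1.5))
  geom <- gen_pore_geometry(rings)
  prof <- compute_profile(geom$atoms, pore_params("hc"))
  for (i in seq_len(nrow(rings))) {
    got <- prof$radius[abs(prof$z - rings$z[i]) < 1e-9]
    expect_equal(got, geom$oracle$radius[i], tolerance = 1e-9)
  }
  # z grid invariants
  expect_equal(unique(round(diff(prof$z), 9)), 0.5)
  expect_true(all(prof$radius >= 0 & prof$radius <= 16))
  # far from all rings the cap value is reported
  expect_equal(prof$radius[prof$z == -60], 16)
})

test_that("profiles are invariant under rigid motion and monotone under added atoms", {
  rings <- data.frame(z = c(0, 10), ring_radius = c(8, 5),
                      n_atoms = c(12, 12), vdw = c(1.7, 1.7))
  geom <- gen_pore_geometry(rings)
  prof0 <- compute_profile(geom$atoms, pore_params("hc"))
  # rotate atoms and axis together by a rotation about x, plus a shift
  th <- 0.7
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  shift <- c(3, -2, 7)
  xyz <- as.matrix(geom$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  rot_atoms <- atom_set(xyz[, 1], xyz[, 2], xyz[, 3],
                        vdw = geom$atoms$vdw)
  rot_params <- pore_params("hc",
                            origin = as.numeric(R %*% c(0, 0, 0) + shift),
                            direction = as.numeric(R %*% c(0, 0, 1)))
  prof1 <- compute_profile(rot_atoms, rot_params)
  expect_equal(prof1$radius, prof0$radius, tolerance = 1e-9)
  # adding an atom can only decrease or preserve the radius everywhere
  plus <- rbind(geom$atoms,
                data.frame(element = "C", x = 2, y = 0, z = 5, vdw = 1.7,
                           chain = "A", resno = NA_integer_, resid = "UNK"))
  class(plus) <- class(geom$atoms)
  prof2 <- compute_profile(plus, pore_params("hc"))
  expect_true(all(prof2$radius <= prof0$radius + 1e-12))
})

test_that("extrema are located with smallest-z tie-breaking and windowing", {
  rings <- data.frame(z = c(-20, 0, 25), ring_radius = c(7.7, 4.7, 7.7),
                      n_atoms = 12, vdw = 1.7)
  geom <- gen_pore_geometry(rings)
  prof <- compute_profile(geom$atoms, pore_params("hc"))
  ext <- locate_extrema(prof)
  expect_equal(unname(ext$min["z"]), 0)
  expect_equal(unname(ext$min["r"]), 3.0, tolerance = 1e-9)
  expect_equal(unname(ext$max["r"]), 16)  # cap far from the rings
  # windowed search around the two 6-Angstrom rings
  ext_w <- locate_extrema(prof, z_window = c(-25, -15))
  expect_equal(unname(ext_w$min["z"]), -20)
  expect_equal(unname(ext_w$min["r"]), 6.0, tolerance = 1e-9)
  expect_error(locate_extrema(prof, z_window = c(500, 600)), "empty z window")
  # monotone synthetic profile: min at last z, max at first
  mono <- structure(data.frame(z = 0:10, radius = 10:0),
                    params = pore_params("hc"),
                    class = c("pore_profile", "data.frame"))
  em <- locate_extrema(mono)
  expect_equal(unname(em$min["z"]), 10)
  expect_equal(unname(em$max["z"]), 0)
})

test_that("default axis passes through the centroid and is shift-equivariant", {
  rings <- data.frame(z = c(0, 10), ring_radius = c(8, 5),
                      n_atoms = c(12, 12), vdw = c(1.7, 1.7))
  geom <- gen_pore_geometry(rings)
  ax <- default_axis(geom$atoms)
  expect_equal(ax$origin[1:2], c(0, 0), tolerance = 1e-12)
  expect_equal(ax$origin[3], 5)
  expect_equal(ax$direction, c(0, 0, 1))
  shifted <- geom$atoms
  shifted$x <- shifted$x + 4; shifted$y <- shifted$y - 1; shifted$z <- shifted$z + 9
  ax2 <- default_axis(shifted)
  expect_equal(ax2$origin, ax$origin + c(4, -1, 9), tolerance = 1e-12)
  # single atom: axis through that atom
  one <- atom_set(1, 2, 3, vdw = 1.7)
  ax3 <- default_axis(one)
  expect_equal(ax3$origin, c(1, 2, 3))
})

test_that("written geometries reload with PDB-precision coordinates", {
  rings <- data.frame(z = c(0, 6), ring_radius = c(9.123456, 5.5),
                      n_atoms = c(12, 8), vdw = c(1.7, 1.7))
  path <- tempfile(fileext = ".pdb")
  geom <- gen_pore_geometry(rings, pdb_path = path)
  back <- load_structure(path)
  expect_equal(nrow(back), nrow(geom$atoms))
  expect_lt(max(abs(as.matrix(back[, c("x", "y", "z")]) -
                      as.matrix(geom$atoms[, c("x", "y", "z")]))), 1e-3)
})
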