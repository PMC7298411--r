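test_that("grid construction follows the bounding-box arithmetic", {
  atom <- single_atom("C", c(0, 0, 0))
  g <- build_grid(list(atom), margin = 4, spacing = 2)
  expect_equal(g$origin, c(-4, -4, -4))
  expect_equal(g$dims, rep(5L, 3))
  expect_equal(prod(g$dims), 125)
  pts <- grid_points(g)
  expect_equal(range(pts), c(-4, 4))

  g06 <- build_grid(list(atom), margin = 4, spacing = 0.6)
  expect_equal(g06$dims, rep(ceiling(8 / 0.6) + 1L, 3))  # 15 per axis

  expect_error(build_grid(list(), 4, 2), "no molecules")
  expect_error(build_grid(list(atom), -1, 2), "> 0")
})

test_that("Lennard-Jones field matches its analytic landmarks", {
  probe <- list(vdw = 1.70, eps = 0.107)
  mol <- single_atom("C")
  rmin <- 1.70 + probe$vdw
  eps_pair <- sqrt(0.107 * probe$eps)

  # zero crossing at rmin * 2^(-1/6)
  e0 <- lennard_jones_field(mol, point_grid(c(rmin * 2^(-1 / 6), 0, 0)), probe)
  expect_equal(e0, 0, tolerance = 1e-9)
  # well depth -eps at rmin
  emin <- lennard_jones_field(mol, point_grid(c(rmin, 0, 0)), probe)
  expect_equal(emin, -eps_pair, tolerance = 1e-9)
  # clamped at the nucleus
  expect_equal(lennard_jones_field(mol, point_grid(c(0, 0, 0)), probe), 30)
  # decays to zero far away
  far <- lennard_jones_field(mol, point_grid(c(50, 0, 0)), probe)
  expect_lt(abs(far), 1e-6)
})

test_that("Coulomb field uses k = 332 with distance-dependent dielectric", {
  plus <- single_atom("C", c(0, 0, 0), charge = 1)
  e <- coulomb_field(plus, point_grid(c(1, 0, 0)), probe_charge = 1)
  expect_equal(e, 332.0, tolerance = 1e-9)
  # D(r) = r means 1/r^2 decay
  e2 <- coulomb_field(plus, point_grid(c(2, 0, 0)), probe_charge = 1)
  expect_equal(e2, 332.0 / 4, tolerance = 1e-9)

  none <- single_atom("C", c(0, 0, 0), charge = 0)
  expect_equal(coulomb_field(none, point_grid(c(1, 0, 0))), 0)

  # superposition over atoms
  pair <- molecule("pair", c("C", "C"), rbind(c(0, 0, 0), c(0, 2, 0)),
                   charges = c(0.5, -0.3), charge_source = "file")
  g <- point_grid(c(1.1, 0.4, 0.2))
  single_sum <- coulomb_field(single_atom("C", c(0, 0, 0), 0.5), g) +
    coulomb_field(single_atom("C", c(0, 2, 0), -0.3), g)
  expect_equal(coulomb_field(pair, g), single_sum, tolerance = 1e-12)
})

test_that("CoMSIA indices are Gaussian-attenuated and bounded", {
  atom <- single_atom("C", c(0, 0, 0))  # steric weight vdw^3
  w <- 1.70^3
  at_atom <- comsia_field(atom, point_grid(c(0, 0, 0)), "steric", alpha = 0.3)
  expect_equal(at_atom, -w, tolerance = 1e-12)
  at_1A <- comsia_field(atom, point_grid(c(1, 0, 0)), "steric", alpha = 0.3)
  expect_equal(at_1A, -w * exp(-0.3), tolerance = 1e-9)

  # no atoms carry the donor property here
  expect_equal(comsia_field(methane(), point_grid(c(0, 0, 0)), "donor"), 0)
  expect_error(comsia_field(atom, point_grid(c(0, 0, 0)), "magnetic"),
               "unknown field_kind")

  # |A(q)| <= sum |w| everywhere, on a real molecule and full grid
  mols <- small_series(6, seed = 31)
  g <- build_grid(mols[1], margin = 3, spacing = 1.5)
  for (kind in c("steric", "electrostatic", "hydrophobic", "donor", "acceptor")) {
    v <- comsia_field(mols[[1]], g, kind)
    wk <- switch(kind, steric = mols[[1]]$atoms$vdw^3,
                 electrostatic = mols[[1]]$atoms$charge,
                 hydrophobic = mols[[1]]$atoms$hydro,
                 donor = as.numeric(mols[[1]]$atoms$hbd),
                 acceptor = as.numeric(mols[[1]]$atoms$hba))
    expect_lte(max(abs(v)), sum(abs(wk)) + 1e-12)
  }
})

test_that("descriptor assembly has the right shape and determinism", {
  mols <- small_series(6, seed = 13)[1:2]
  g <- build_grid(mols, margin = 3, spacing = 2)
  blocks <- assemble_descriptor_matrix(mols, g, method = "comfa")
  expect_named(blocks, c("steric", "electrostatic"))
  for (b in blocks) {
    expect_equal(nrow(b$values), 2)
    expect_equal(ncol(b$values), prod(g$dims))
  }
  # duplicated compound gives an identical row
  dup <- assemble_descriptor_matrix(list(mols[[1]], mols[[1]]), g,
                                    method = "comsia")
  for (b in dup) expect_equal(b$values[1, ], b$values[2, ])

  blocks2 <- assemble_descriptor_matrix(mols, g, method = "comfa")
  expect_identical(blocks, blocks2)
})

test_that("fields are invariant under rigid motion of molecules plus grid", {
  mols <- small_series(6, seed = 17)[1:2]
  g <- build_grid(mols, margin = 3, spacing = 2)
  ref <- assemble_descriptor_matrix(mols, g, method = "comfa")

  # translation of everything by a fixed vector: values identical
  shift <- c(3.2, -1.7, 0.9)
  mols_t <- lapply(mols, function(m)
    set_coords(m, sweep(coords_of(m), 2, -shift)))
  g_t <- structure(list(origin = g$origin + shift, spacing = g$spacing,
                        dims = g$dims), class = "qsar_grid")
  tr <- assemble_descriptor_matrix(mols_t, g_t, method = "comfa")
  for (k in names(ref))
    expect_equal(tr[[k]]$values, ref[[k]]$values, tolerance = 1e-9)

  # 90-degree rotation about z keeps the grid axis-aligned; the value
  # multiset per compound is preserved exactly
  R <- rot_z(pi / 2)
  mols_r <- lapply(mols, function(m) set_coords(m, coords_of(m) %*% t(R)))
  corners <- grid_points(g)[c(1, prod(g$dims)), ] %*% t(R)
  g_r <- structure(list(origin = pmin(corners[1, ], corners[2, ]),
                        spacing = g$spacing,
                        dims = g$dims[c(2, 1, 3)]), class = "qsar_grid")
  rot <- assemble_descriptor_matrix(mols_r, g_r, method = "comfa")
  for (k in names(ref))
    for (i in 1:2)
      expect_equal(sort(rot[[k]]$values[i, ]), sort(ref[[k]]$values[i, ]),
                   tolerance = 1e-9)
})

test_that("cube export writes a parseable grid with the right values", {
  atom <- single_atom("C")
  g <- build_grid(list(atom), margin = 2, spacing = 2)
  v <- lennard_jones_field(atom, g)
  f <- tempfile(fileext = ".cube")
  write_cube(v, g, f)
  lines <- readLines(f)
  hdr <- as.numeric(strsplit(trimws(lines[3]), "\\s+")[[1]])
  expect_equal(hdr[1], 1)
  expect_equal(hdr[2:4], g$origin / 0.529177210903, tolerance = 1e-5)
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:7)]), "\\s+")))
  expect_equal(length(vals), prod(g$dims))
  expect_equal(sort(vals), sort(v), tolerance = 1e-4)
})
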