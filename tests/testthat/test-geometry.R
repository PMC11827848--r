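test_that("dihedral and bond angles reproduce analytic cases", {
  # planar cis and trans arrangements
  expect_equal(dihedral_angle(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0),
                              c(2, 1, 0)), 0)
  expect_equal(abs(dihedral_angle(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0),
                                  c(2, -1, 0))), 180)
  # right-hand sign convention
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                              c(1, 1, 1)), -90)
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(3, 1, 0)), "collinear")

  expect_equal(bond_angle(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0)), 180)
  expect_equal(bond_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  # ideal tetrahedral angle, arccos(-1/3)
  tet <- rbind(c(1, 1, 1), c(0, 0, 0), c(1, -1, -1))
  expect_equal(bond_angle(tet[1, ], tet[2, ], tet[3, ]),
               acos(-1 / 3) * 180 / pi, tolerance = 1e-9)
  expect_error(bond_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "zero-length")
})

test_that("chain geometry recovers the generator's dihedrals", {
  for (ps in list(c(-57, -47), c(-120, 130), c(-75, 145))) {
    h <- build_helix(15, phi = ps[1], psi = ps[2])
    g <- chain_geometry(h, "A")
    expect_true(all(abs(g$phi[-1] - ps[1]) < 0.5))
    expect_true(all(abs(g$psi[-15] - ps[2]) < 0.5))
    expect_true(all(abs(abs(g$omega[-15]) - 180) < 0.5))
  }
  g <- chain_geometry(build_helix(15), "A")
  expect_true(is.na(g$phi[1]))       # no preceding residue
  expect_true(is.na(g$psi[15]))      # no following residue
  expect_equal(g$rama[2:14], rep("alpha", 13))
  gb <- chain_geometry(build_helix(15, phi = -120, psi = 130), "A")
  expect_equal(gb$rama[2:14], rep("beta", 13))
})

test_that("missing backbone atoms yield absent values, not fabricated ones", {
  h <- build_helix(10)
  drop <- h$atoms$name == "CA" & h$atoms$resseq == 5
  h$atoms <- h$atoms[!drop, ]
  g <- chain_geometry(h, "A")
  expect_true(is.na(g$phi[5]))
  expect_true(is.na(g$psi[5]))
  expect_true(is.na(g$ang_n_ca_c[5]))
  # neighbours that depend on residue 5 atoms other than CA are unaffected
  expect_false(is.na(g$psi[4]))
})

test_that("geometry is invariant under rigid motion", {
  h <- build_helix(12, phi = -60, psi = -45)
  g0 <- chain_geometry(h, "A")
  for (seed in c(3, 14, 27)) {
    mot <- random_rigid_motion(seed)
    g1 <- chain_geometry(transform_model(h, mot$rotation, mot$translation),
                         "A")
    expect_equal(g1$phi, g0$phi, tolerance = 1e-6)
    expect_equal(g1$psi, g0$psi, tolerance = 1e-6)
    expect_equal(g1$ang_n_ca_c, g0$ang_n_ca_c, tolerance = 1e-6)
  }
})

test_that("wrapped angular differences never exceed 180 in magnitude", {
  expect_equal(abs(wrap_angle(179 - (-179))), 2)
  set.seed(5)
  a <- runif(500, -180, 180)
  b <- runif(500, -180, 180)
  d <- wrap_angle(b - a)
  expect_true(all(abs(d) <= 180))
  # wrapped difference reconstructs b from a on the circle
  expect_equal(wrap_angle(a + d - b), rep(0, 500), tolerance = 1e-9)
})

test_that("geometry_diff of a structure with itself is identically zero", {
  g <- chain_geometry(wt_complex, "T")
  p <- pair_residues(wt_complex, wt_complex, chain_a = "T", chain_b = "T")
  gd <- geometry_diff(g, g, p)
  expect_equal(nrow(attr(gd, "flagged")), 0)
  dcols <- grep("^d_", names(gd), value = TRUE)
  expect_true(all(abs(as.matrix(gd[, dcols])) < 1e-9, na.rm = TRUE))
})

test_that("z-scores standardise per quantity and flag the engineered outlier", {
  h <- build_helix(30, phi = -57, psi = -47)
  # perturb one residue's psi by rebuilding with a modified dihedral: rotate
  # everything after residue 15's CA-C bond about that bond by 40 degrees
  h2 <- h
  ca <- as.numeric(h$atoms[h$atoms$resseq == 15 & h$atoms$name == "CA",
                           c("x", "y", "z")])
  cc <- as.numeric(h$atoms[h$atoms$resseq == 15 & h$atoms$name == "C",
                           c("x", "y", "z")])
  axis <- cc - ca
  R <- rotation_about_axis(axis, 40)
  after <- which(h2$atoms$resseq > 15 |
                   (h2$atoms$resseq == 15 & h2$atoms$name == "O"))
  xyz <- atom_coords(h2, after)
  h2$atoms[after, c("x", "y", "z")] <-
    sweep(sweep(xyz, 2, cc) %*% t(R), 2, cc, `+`)
  ga <- chain_geometry(h, "A")
  gb <- chain_geometry(h2, "A")
  p <- pair_residues(h, h2, chain_a = "A", chain_b = "A")
  gd <- geometry_diff(ga, gb, p, z_threshold = 2)
  expect_equal(abs(round(wrap_angle(gb$psi[15] - ga$psi[15]))), 40)
  fl <- attr(gd, "flagged")
  expect_equal(fl$resseq_a, 15)
  # z-scores have mean 0 and sd 1 over defined residues
  z <- gd$z_psi[!is.na(gd$z_psi)]
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
})

test_that("omega planarity summarises deviation from trans", {
  g <- chain_geometry(build_helix(15), "A")
  expect_lt(omega_planarity(g), 0.5)
})
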