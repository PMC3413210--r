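test_that("ideal fixtures score exactly zero on all geometry statistics", {
  m <- build_ideal_peptide("ASTVLINDQEKMGRC", phi = -57, psi = -47)
  g <- geometry_summary(m)
  expect_equal(g$bond_rmsd, 0, tolerance = 1e-9)
  expect_equal(g$angle_rmsd, 0, tolerance = 1e-9)
  expect_equal(g$planarity_rmsd, 0, tolerance = 1e-9)
  expect_equal(g$omega_sd, 0, tolerance = 1e-9)
  expect_gt(g$n_bonds, 0)
  expect_gt(g$n_angles, 0)
})

test_that("a single stretched bond yields exactly one deviation", {
  m <- build_ideal_peptide("AAA")
  a <- m$atoms
  ca <- which(a$resseq == 2 & a$name == "CA")
  cb <- which(a$resseq == 2 & a$name == "CB")
  u <- (coords(m)[cb, ] - coords(m)[ca, ])
  u <- u / clashaudit:::vec_norm(u)
  m$atoms[cb, c("x", "y", "z")] <-
    as.list(coords(m)[cb, ] + 0.020 * u)
  dev <- bond_angle_deviations(m)
  delta <- dev$bonds$observed - dev$bonds$ideal
  expect_identical(sum(abs(delta) > 1e-9), 1L)
  expect_equal(max(abs(delta)), 0.020, tolerance = 1e-9)
})

test_that("rmsd and rms_z definitions", {
  expect_equal(rmsd(c(0.02)), 0.02)
  expect_equal(rmsd(c(3, 4)), sqrt((9 + 16) / 2))
  d <- data.frame(observed = c(1.52, 1.47), ideal = c(1.50, 1.45),
                  sigma = c(0.02, 0.02))
  expect_equal(rms_z(d), 1.0, tolerance = 1e-12)
  expect_true(is.na(rmsd(numeric(0))))
  expect_true(is.na(rms_z(numeric(0))))
})

test_that("planarity: SVD oracle, exact zeros and isometry invariance", {
  # 4 coplanar atoms -> 0
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(clashaudit:::fit_plane(sq)$rmsd, 0, tolerance = 1e-12)
  # hexagon with one atom displaced: compare to a direct SVD computed here
  hex <- t(vapply(0:5, function(k)
    c(cos(k * pi / 3), sin(k * pi / 3), 0), numeric(3)))
  hex[1, 3] <- 0.05
  ctr <- colMeans(hex)
  sv <- svd(sweep(hex, 2, ctr))
  oracle <- sqrt(mean((sweep(hex, 2, ctr) %*% sv$v[, 3])^2))
  expect_equal(clashaudit:::fit_plane(hex)$rmsd, oracle, tolerance = 1e-12)
  # rotation invariance
  R <- clashaudit:::rotation_about(c(2, -1, 1), 37)
  expect_equal(clashaudit:::fit_plane(hex %*% t(R))$rmsd, oracle,
               tolerance = 1e-9)
  # model-level: groups need >= 4 atoms; Phe ring group present
  m <- build_ideal_peptide("AFA")
  pl <- sidechain_planarity(m)
  expect_identical(nrow(pl$groups), 1L)
  expect_equal(pl$planarity_rmsd, 0, tolerance = 1e-9)
})

test_that("omega statistics: ideals, wrap, cis assignment, mirror", {
  m <- build_ideal_peptide("AAAAAA", omega = 180)
  expect_equal(omega_stats(m)$omega_sd, 0, tolerance = 1e-9)
  m2 <- build_ideal_peptide("AAA", omega = c(180, 175, 185))
  expect_equal(omega_stats(m2)$omega_sd, 5.0, tolerance = 1e-6)
  # circular wrap: -178 deviates by 2
  m3 <- build_ideal_peptide("AA", omega = c(180, -178))
  expect_equal(omega_stats(m3)$omega_sd, 2.0, tolerance = 1e-6)
  # cis peptide assigned to ideal 0
  m4 <- build_ideal_peptide("AAA", omega = c(180, 5, 180))
  s4 <- omega_stats(m4)
  expect_equal(s4$cis_fraction, 0.5)
  expect_equal(s4$omega_sd, sqrt(mean(c(5, 0)^2)), tolerance = 1e-6)
  # mirror (negate x): |deviation| preserved
  m5 <- build_ideal_peptide("AAAA", omega = c(180, 174, 186, 180))
  s5a <- omega_stats(m5)$omega_sd
  m5$atoms$x <- -m5$atoms$x
  expect_equal(omega_stats(m5)$omega_sd, s5a, tolerance = 1e-9)
  # single residue: no omega
  expect_identical(omega_stats(build_ideal_peptide("G"))$n_omega, 0L)
})

test_that("deterministic k-sigma perturbation recovers RMS Z = k exactly", {
  base <- build_ideal_peptide("ASTVLNQEK")
  for (k in c(0.5, 1, 2)) {
    m <- perturb_geometry(base, k, deterministic = TRUE)
    dev <- bond_angle_deviations(m)
    expect_equal(rms_z(dev$bonds), k, tolerance = 1e-6)
    nonlink <- !grepl("C-N", dev$angles$label)
    expect_equal(rms_z(dev$angles[nonlink, ]), k, tolerance = 1e-6)
  }
})

test_that("Gaussian noise at k sigma recovers bond RMS Z near k", {
  base <- build_ideal_peptide(strrep("ASTVLINDQEKMRG", 5))
  m1 <- perturb_geometry(base, 1, seed = 11)
  dev1 <- bond_angle_deviations(m1)
  expect_gte(nrow(dev1$bonds), 500)
  expect_lt(abs(rms_z(dev1$bonds) - 1), 0.1)
  # linearity under a fixed seed
  m2 <- perturb_geometry(base, 2, seed = 11)
  expect_equal(rms_z(bond_angle_deviations(m2)$bonds),
               2 * rms_z(dev1$bonds), tolerance = 1e-6)
  # k = 0 reproduces the base model exactly
  m0 <- perturb_geometry(base, 0)
  expect_equal(coords(m0), coords(base), tolerance = 1e-12)
})

test_that("geometry summary is invariant to chain order", {
  m1 <- build_ideal_peptide("ASTN", chain = "A")
  m2 <- build_ideal_peptide("GLVK", chain = "B")
  m2$atoms$x <- m2$atoms$x + 40
  g12 <- geometry_summary(clashaudit:::merge_models(m1, m2))
  g21 <- geometry_summary(clashaudit:::merge_models(m2, m1))
  expect_equal(g12$bond_rmsd, g21$bond_rmsd, tolerance = 1e-12)
  expect_equal(g12$angle_rmsd, g21$angle_rmsd, tolerance = 1e-12)
  expect_identical(g12$n_bonds, g21$n_bonds)
})

test_that("hydrogens never enter geometry statistics", {
  m <- build_ideal_peptide("ASTN")
  g0 <- geometry_summary(m)
  g1 <- geometry_summary(add_hydrogens(m))
  expect_identical(g0$n_bonds, g1$n_bonds)
  expect_identical(g0$n_angles, g1$n_angles)
  expect_equal(g0$bond_rmsd, g1$bond_rmsd, tolerance = 1e-12)
})
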