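test_that("van der Waals radii match the two dialects", {
  prim <- vdw_table("primary")
  rich <- vdw_table("richardson")
  expect_equal(vdw_radius("H", prim), 1.10)
  expect_equal(vdw_radius("O", prim), 1.58)
  expect_equal(vdw_radius("O", rich), 1.40)
  expect_equal(vdw_radius("H", rich, polar_aromatic_h = TRUE), 1.00)
  expect_equal(vdw_radius("H", rich, polar_aromatic_h = FALSE), 1.17)
  expect_warning(r <- vdw_radius("P", prim), "Bondi")
  expect_equal(r, 1.80)
  expect_error(vdw_radius("XX", prim), "no van der Waals radius")
  ov <- vdw_table("primary", override = c(C = 2.0))
  expect_equal(vdw_radius("C", ov), 2.0)
})

test_that("classification thresholds sit exactly at the printed boundaries", {
  # primary H-H: clash boundary 1.76 A (= 0.8 x 2.2), severe 1.54
  expect_identical(classify_contact(1.76, 1.1, 1.1)$clash_class, "clash")
  expect_identical(classify_contact(1.7601, 1.1, 1.1)$clash_class, "none")
  expect_identical(classify_contact(1.54, 1.1, 1.1)$clash_class, "severe")
  expect_identical(classify_contact(1.5401, 1.1, 1.1)$clash_class, "clash")
  # primary O-O boundary 2.53
  expect_identical(classify_contact(2.528, 1.58, 1.58)$clash_class, "clash")
  expect_identical(classify_contact(2.529, 1.58, 1.58)$clash_class, "none")
  # richardson: nonpolar H-H 1.94, polar 1.60, O-O 2.40
  expect_identical(classify_contact(1.94, 1.17, 1.17, "richardson")$clash_class,
                   "clash")
  expect_identical(classify_contact(1.941, 1.17, 1.17, "richardson")$clash_class,
                   "none")
  expect_identical(classify_contact(1.60, 1.00, 1.00, "richardson")$clash_class,
                   "clash")
  expect_identical(classify_contact(2.40, 1.40, 1.40, "richardson")$clash_class,
                   "clash")
})

test_that("classification is monotone in distance and classes are disjoint", {
  d <- seq(1.2, 2.2, by = 0.005)
  cls <- classify_contact(d, 1.1, 1.1)$clash_class
  rank <- c(severe = 1, clash = 2, none = 3)[cls]
  expect_true(all(diff(rank) >= 0))
  expect_identical(sum(cls == "severe") + sum(cls == "clash"),
                   sum(d / 2.2 <= 0.8))
})

test_that("cell-list contact search matches the all-pairs oracle", {
  set.seed(99)
  for (trial in 1:12) {
    n <- sample(30:600, 1)
    cutoff <- runif(1, 2, 6)
    m <- random_cloud(n, box = runif(1, 8, 40))
    p <- find_contacts(m, cutoff)
    bf <- brute_force_pairs(m, cutoff)
    expect_identical(pair_key(p), pair_key(bf))
    expect_identical(anyDuplicated(pair_key(p)), 0L)
  }
  # degenerate cases
  m2 <- random_cloud(2)
  m2$atoms$x <- c(0, 10); m2$atoms$y <- 0; m2$atoms$z <- 0
  expect_identical(nrow(find_contacts(m2, 4)), 0L)
})

test_that("exclusion rules remove bonded paths, hbond pairs, flip groups", {
  m <- helical_allatom("ASNTLK")
  roles <- hbond_roles(m)
  pairs <- find_contacts(m, 4.5)
  ex <- apply_exclusions(pairs, m)
  a <- m$atoms
  # geminal H-H (2 bonds) excluded
  hb2 <- which(a$name == "HB2" & a$resname == "ASN")
  hb3 <- which(a$name == "HB3" & a$resname == "ASN")
  expect_false(any(ex$pairs[, 1] == min(hb2, hb3) &
                     ex$pairs[, 2] == max(hb2, hb3)))
  expect_gt(ex$tally[["bonded_path"]], 0)
  # backbone donor-acceptor pairs excluded by role alone: helical O(i)..N(i+4)
  # and O(i)..H-N pairs must never appear among retained pairs
  keyO <- which(a$name == "O"); keyN <- which(a$name == "N")
  bad <- (ex$pairs[, 1] %in% keyO & ex$pairs[, 2] %in% keyN) |
    (ex$pairs[, 1] %in% keyN & ex$pairs[, 2] %in% keyO)
  expect_false(any(bad))
  expect_gt(ex$tally[["donor_acceptor"]], 0)
  # donor-H vs acceptor excluded
  expect_gte(ex$tally[["donor_h_acceptor"]], 0)
})

test_that("apolar H-H contacts between residues are retained", {
  # Leu HD vs Met HE at 1.6 A in different chains: no exclusion rule applies
  m1 <- helical_allatom("GLG")
  m2 <- helical_allatom("GMG")
  mm <- clashaudit:::merge_models(m1, m2)
  nb <- mm$atoms$serial > nrow(m1$atoms)
  mm$atoms$chain[nb] <- "B"
  a <- mm$atoms
  hd <- which(a$chain == "A" & a$name == "HD11")
  he <- which(a$chain == "B" & a$name == "HE1")
  shift <- (coords(mm)[hd, ] + c(1.6, 0, 0)) - coords(mm)[he, ]
  mm$atoms$x[nb] <- mm$atoms$x[nb] + shift[1]
  mm$atoms$y[nb] <- mm$atoms$y[nb] + shift[2]
  mm$atoms$z[nb] <- mm$atoms$z[nb] + shift[3]
  mm <- build_covalent_graph(mm)
  pairs <- find_contacts(mm, 4.5)
  ex <- apply_exclusions(pairs, mm)
  keys <- pair_key(ex$pairs)
  expect_true(paste(min(hd, he), max(hd, he), sep = "-") %in% keys)
})

test_that("detect_clashes on engineered fixtures reports exact counts", {
  m <- clash_fixture(50, c(0.75, 0.65))
  r <- detect_clashes(m)
  expect_identical(r$n_clashes, 1L)
  expect_identical(r$n_severe, 1L)
  expect_identical(r$residue_count, 52L)
  expect_equal(r$clashes_per_100, round(100 * 1 / 52, 1))
  expect_equal(r$severe_per_100, round(100 * 1 / 52, 1))
  # determinism: identical report when run twice
  r2 <- detect_clashes(m)
  expect_identical(r$findings, r2$findings)
  # above threshold: no findings
  r3 <- detect_clashes(clash_fixture(20, 0.81))
  expect_identical(r3$n_clashes + r3$n_severe, 0L)
})

test_that("ideal helical and strand fixtures are clash free (brute force)", {
  for (tors in list(c(-57, -47), c(-120, 130))) {
    m <- add_hydrogens(build_ideal_peptide("ASTVLINDQEKM",
                                           phi = tors[1], psi = tors[2]))
    r <- detect_clashes(m)
    expect_identical(r$n_clashes + r$n_severe, 0L)
    # brute-force verification of the candidate set underneath
    p <- find_contacts(m, 4.5)
    expect_identical(pair_key(p), pair_key(brute_force_pairs(m, 4.5)))
  }
})

test_that("clash report is invariant under rigid motion", {
  m <- clash_fixture(30, c(0.72))
  r0 <- detect_clashes(m)
  R <- clashaudit:::rotation_about(c(1, 2, 3), 71)
  xyz <- coords(m) %*% t(R)
  xyz <- sweep(xyz, 2, c(5, -3, 11), FUN = "+")
  m$atoms$x <- xyz[, 1]; m$atoms$y <- xyz[, 2]; m$atoms$z <- xyz[, 3]
  r1 <- detect_clashes(m)
  expect_identical(r1$n_clashes, r0$n_clashes)
  expect_identical(r1$n_severe, r0$n_severe)
  expect_equal(r1$findings$distance, r0$findings$distance, tolerance = 1e-9)
})

test_that("water contacts are reported separately from headline counts", {
  m <- build_ideal_peptide(strrep("A", 10), phi = -120, psi = 130)
  cb <- which(m$atoms$resseq == 5 & m$atoms$name == "CB")
  ca <- which(m$atoms$resseq == 5 & m$atoms$name == "CA")
  d <- coords(m)[cb, ] - coords(m)[ca, ]
  d <- d / clashaudit:::vec_norm(d)
  w <- clashaudit:::single_water(coords(m)[cb, ] + 2.2 * d)  # 0.657 ratio C-O
  mm <- clashaudit:::merge_models(m, w)
  r <- detect_clashes(mm)
  expect_identical(r$n_clashes + r$n_severe, 0L)
  expect_identical(nrow(r$water), 1L)
})

test_that("per-100 frequencies follow the sum/sum printing convention", {
  expect_equal(per_100(52, 3543), 1.5)
  expect_equal(per_100(21, 3543), 0.6)
  expect_equal(per_100(0, 123), 0.0)
  expect_error(per_100(1, 0), "positive")
})
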