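test_that("hydrogen sites are classified riding vs rotatable", {
  m <- build_ideal_peptide("ASYC")
  sites <- classify_hydrogen_sites(m)
  a <- m$atoms
  info <- do.call(rbind, lapply(sites, function(s) data.frame(
    resname = a$resname[s$parent], parent = a$name[s$parent],
    class = s$site_class, kind = s$rotatable_kind,
    stringsAsFactors = FALSE)))
  # Ala CA carries one riding HA
  expect_true(any(info$resname == "ALA" & info$parent == "CA" &
                    info$class == "riding"))
  # Ser OG: rotatable hydroxyl with CB-OG axis
  ser <- sites[[which(info$parent == "OG")]]
  expect_identical(ser$site_class, "rotatable")
  expect_identical(ser$rotatable_kind, "hydroxyl")
  expect_identical(a$name[ser$torsion_axis], c("OG", "CB"))
  # Tyr OH: phenolic; Cys SG: sulfhydryl
  expect_identical(info$kind[info$parent == "OH"], "phenolic")
  expect_identical(info$kind[info$parent == "SG"], "sulfhydryl")
  # every H name appears in exactly one site
  all_h <- unlist(lapply(sites, function(s)
    paste(a$resseq[s$parent], s$h_names)))
  expect_identical(anyDuplicated(all_h), 0L)
})

test_that("riding H geometry: lengths, planarity, symmetry", {
  m0 <- build_ideal_peptide("GAVN", phi = -57, psi = -47)
  m <- place_riding_hydrogens(m0)
  a <- m$atoms; xyz <- coords(m)
  adj <- clashaudit:::adjacency_list(m)
  # X-H bond lengths match templates to 1e-6
  for (i in which(a$is_h)) {
    p <- adj[[i]][1]
    expected <- clashaudit:::.XH_LENGTHS[[a$element[p]]]
    expect_equal(clashaudit:::vec_norm(xyz[i, ] - xyz[p, ]), expected,
                 tolerance = 1e-6)
  }
  # amide H lies in the C(i-1)-N-CA plane
  h <- which(a$resseq == 2 & a$name == "H")
  n <- which(a$resseq == 2 & a$name == "N")
  cprev <- which(a$resseq == 1 & a$name == "C")
  ca <- which(a$resseq == 2 & a$name == "CA")
  nrm <- clashaudit:::vec_cross(xyz[cprev, ] - xyz[n, ], xyz[ca, ] - xyz[n, ])
  nrm <- nrm / clashaudit:::vec_norm(nrm)
  expect_lt(abs(sum((xyz[h, ] - xyz[n, ]) * nrm)), 1e-9)
  # Gly HA2/HA3 mirror-symmetric about the N-CA-C plane
  g <- which(a$resseq == 1)
  ha <- g[a$name[g] %in% c("HA2", "HA3")]
  nn <- g[a$name[g] == "N"]; cc <- g[a$name[g] == "C"]
  caa <- g[a$name[g] == "CA"]
  pn <- clashaudit:::vec_cross(xyz[nn, ] - xyz[caa, ], xyz[cc, ] - xyz[caa, ])
  pn <- pn / clashaudit:::vec_norm(pn)
  d1 <- sum((xyz[ha[1], ] - xyz[caa, ]) * pn)
  d2 <- sum((xyz[ha[2], ] - xyz[caa, ]) * pn)
  expect_equal(d1, -d2, tolerance = 1e-9)
  # methyl H-H distances all equal (tetrahedral construction)
  v <- which(a$resseq == 3)
  hg1 <- v[grepl("^HG1", a$name[v])]
  dists <- as.numeric(dist(xyz[hg1, ]))
  expect_equal(max(dists) - min(dists), 0, tolerance = 1e-6)
})

test_that("placement is idempotent and never moves heavy atoms", {
  m0 <- build_ideal_peptide("ASNQ")
  heavy0 <- coords(m0)
  m1 <- add_hydrogens(m0)
  m2 <- add_hydrogens(m1)
  expect_identical(nrow(m1$atoms), nrow(m2$atoms))
  expect_equal(coords(m1), coords(m2), tolerance = 1e-12)
  keep <- !m1$atoms$is_h
  expect_equal(coords(m1)[keep, ], heavy0, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("deposited H are trusted by default and rebuilt on request", {
  m <- helical_allatom("AS")
  # nudge one H; default placement keeps it, rebuild restores geometry
  hi <- which(m$atoms$name == "HA")[1]
  m$atoms$x[hi] <- m$atoms$x[hi] + 0.2
  kept <- add_hydrogens(m)
  expect_equal(kept$atoms$x[kept$atoms$name == "HA"][1],
               m$atoms$x[hi], tolerance = 1e-12)
  rebuilt <- add_hydrogens(m, rebuild = TRUE)
  adj <- clashaudit:::adjacency_list(rebuilt)
  hi2 <- which(rebuilt$atoms$name == "HA")[1]
  p <- adj[[hi2]][1]
  expect_equal(clashaudit:::vec_norm(coords(rebuilt)[hi2, ] -
                                       coords(rebuilt)[p, ]),
               1.090, tolerance = 1e-6)
})
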