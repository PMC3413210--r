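test_that("PDB and mmCIF round trips preserve atoms to format precision", {
  m <- helical_allatom("ASTW")
  for (fmt in c("pdb", "mmcif")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_structure(m, f, fmt)
    m2 <- read_structure(f)
    expect_identical(nrow(m2$atoms), nrow(m$atoms))
    expect_identical(m2$atoms$name, m$atoms$name)
    expect_identical(m2$atoms$element, m$atoms$element)
    expect_lt(max(abs(coords(m2) - coords(m))), 1e-3)
  }
})

test_that("PDB and mmCIF renderings of one peptide load identically", {
  m <- build_ideal_peptide("SNA")
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".cif")
  write_structure(m, f1, "pdb")
  write_structure(m, f2, "mmcif")
  a <- read_structure(f1); b <- read_structure(f2)
  expect_identical(nrow(a$atoms), nrow(b$atoms))
  expect_equal(coords(a), coords(b), tolerance = 1e-9)
})

test_that("single-atom file and multi-model files parse per the rules", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1      11.000  12.000  13.000  1.00  5.00           C",
    "END"), f)
  m <- read_structure(f)
  expect_identical(nrow(m$atoms), 1L)
  expect_identical(residue_count(m), 1L)
  expect_identical(length(unique(residue_keys(m))), 1L)

  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  GLY A   1      11.000  12.000  13.000  1.00  5.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  GLY A   1      12.000  12.000  13.000  1.00  5.00           C",
    "ATOM      2  CA  GLY A   2      15.000  12.000  13.000  1.00  5.00           C",
    "ENDMDL",
    "END"), f2)
  expect_warning(m2 <- read_structure(f2), "first MODEL")
  expect_identical(nrow(m2$atoms), 1L)
  expect_equal(m2$atoms$x, 11)
})

test_that("zero atoms and unparseable input raise errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", f)
  expect_error(read_structure(f), "no atoms")
  f2 <- withr::local_tempfile(fileext = ".cif")
  writeLines("data_x", f2)
  expect_error(read_structure(f2, format = "mmcif"), "atom_site")
})

test_that("altloc selection keeps the higher-occupancy conformer", {
  m <- build_ideal_peptide("GSA")
  a <- m$atoms[, setdiff(names(m$atoms), c("is_h", "polar_aromatic_h"))]
  og <- which(a$name == "OG")
  a$altloc[og] <- "A"; a$occ[og] <- 0.6
  dup <- a[og, ]; dup$altloc <- "B"; dup$occ <- 0.4; dup$x <- dup$x + 0.5
  am <- structure_model(rbind(a, dup))
  sel <- select_primary_altlocs(am)
  kept <- sel$atoms[sel$atoms$name == "OG", ]
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$altloc, "A")
  # ties broken by file order: first-listed conformer survives
  a2 <- rbind(a, dup)
  a2$occ[a2$name == "OG"] <- 0.5
  sel2 <- select_primary_altlocs(structure_model(a2))
  expect_identical(sel2$atoms$altloc[sel2$atoms$name == "OG"], "A")
  # idempotent, never increases atoms, no-op without altlocs
  expect_identical(select_primary_altlocs(sel)$atoms, sel$atoms)
  expect_lte(nrow(sel$atoms), nrow(am$atoms))
  expect_identical(select_primary_altlocs(m)$atoms, m$atoms)
})

test_that("covalent graph: peptide bonds, disulfides, distance fallback", {
  m <- build_ideal_peptide("GA")
  a <- m$atoms
  gC <- which(a$resseq == 1 & a$name == "C")
  aN <- which(a$resseq == 2 & a$name == "N")
  expect_true(any(m$bonds[, 1] == min(gC, aN) & m$bonds[, 2] == max(gC, aN)))

  # disulfide: two Cys chains with SG atoms 2.03 A apart
  m1 <- build_ideal_peptide("C", chain = "A")
  m2 <- build_ideal_peptide("C", chain = "B")
  sg1 <- coords(m1)[m1$atoms$name == "SG", ]
  sg2 <- coords(m2)[m2$atoms$name == "SG", ]
  shift <- (sg1 + c(2.03, 0, 0)) - sg2
  m2$atoms$x <- m2$atoms$x + shift[1]
  m2$atoms$y <- m2$atoms$y + shift[2]
  m2$atoms$z <- m2$atoms$z + shift[3]
  mm <- clashaudit:::merge_models(m1, m2)
  sgs <- which(mm$atoms$name == "SG")
  expect_true(any(mm$bonds[, 1] == min(sgs) & mm$bonds[, 2] == max(sgs)))
  # and no free S-H site on a disulfide cysteine
  sites <- classify_hydrogen_sites(mm)
  expect_false(any(vapply(sites, function(s)
    s$rotatable_kind == "sulfhydryl", logical(1))))

  # distance fallback bonds a C-C ligand pair at 1.53 A (2.12 A ceiling)
  a <- clashaudit:::empty_atoms(2)
  a$serial <- 1:2; a$name <- c("C1", "C2"); a$altloc <- ""
  a$resname <- "LIG"; a$chain <- "X"; a$resseq <- 1L; a$icode <- ""
  a$x <- c(0, 1.53); a$y <- 0; a$z <- 0; a$occ <- 1; a$b <- 0
  a$element <- "C"; a$het <- TRUE
  lig <- build_covalent_graph(structure_model(a))
  expect_identical(nrow(lig$bonds), 1L)
})

test_that("residue_count counts polymer residues only", {
  m <- build_ideal_peptide(strrep("A", 12))
  expect_identical(residue_count(m), 12L)
  # waters do not count
  w <- clashaudit:::single_water(c(50, 50, 50))
  mm <- clashaudit:::merge_models(m, w)
  expect_identical(residue_count(mm), 12L)
  # two chains add up
  m2 <- build_ideal_peptide(strrep("G", 5), chain = "B")
  m2$atoms$x <- m2$atoms$x + 100
  expect_identical(residue_count(clashaudit:::merge_models(m, m2)), 17L)
  # empty model
  expect_identical(residue_count(structure_model(clashaudit:::empty_atoms(0))), 0L)
})

test_that("every hydrogen has covalent degree exactly 1", {
  m <- helical_allatom("GSNTAYKEW")
  adj <- clashaudit:::adjacency_list(m)
  hs <- which(m$atoms$is_h)
  expect_true(all(vapply(adj[hs], length, integer(1)) == 1L))
})

test_that("PDB writer rejects long atom names and supports hybrid-36", {
  m <- build_ideal_peptide("A")
  m$atoms$name[1] <- "ABCDE"
  f <- withr::local_tempfile(fileext = ".pdb")
  expect_error(write_structure(m, f, "pdb"), "4 characters")
  expect_identical(clashaudit:::hy36_encode(99999), "99999")
  expect_identical(clashaudit:::hy36_encode(100000), "A0000")
})
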