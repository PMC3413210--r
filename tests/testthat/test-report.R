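test_that("run_audit presets follow the two auditing protocols", {
  m <- build_ideal_peptide("GSNTAYKE", phi = -57, psi = -47)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f, "pdb")
  # united-atom + deposited-h: no H added, audit as-is
  r1 <- run_audit(f, preset = "deposited-h")
  expect_false(any(r1$model$atoms$is_h))
  # build-h: hydrogens added and network optimized before the audit
  r2 <- run_audit(f, preset = "build-h", mode = "both", seed = 3)
  expect_true(any(r2$model$atoms$is_h))
  expect_s3_class(r2$clash$richardson, "clash_report")
  expect_false(is.null(r2$optimization))
  # deterministic JSON (byte-identical for same input and seed)
  j1 <- withr::local_tempfile(fileext = ".json")
  j2 <- withr::local_tempfile(fileext = ".json")
  write_audit_json(r2, j1)
  write_audit_json(run_audit(f, preset = "build-h", mode = "both",
                             seed = 3), j2)
  expect_identical(readLines(j1), readLines(j2))
})

test_that("audit errors: parse failure and zero polymer residues", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", f)
  expect_error(run_audit(f), "no atoms")
  w <- clashaudit:::single_water(c(0, 0, 0))
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(w, f2, "pdb")
  expect_error(run_audit(f2), "no polymer")
})

test_that("batch pooling uses sum/sum and means for geometry", {
  m1 <- clash_fixture(49, 0.75)   # 50 residues incl. probe, 1 clash
  m2 <- clash_fixture(47, c(0.75, 0.74, 0.72))  # 50 residues, 3 clashes
  b <- batch_audit(list(m1, m2), preset = "deposited-h")
  expect_identical(nrow(b$table), 2L)
  expect_identical(b$cohort$clashes, 4L)
  expect_equal(b$cohort$clashes_per_100, 4.0)
  expect_equal(b$cohort$bond_rmsd, mean(b$table$bond_rmsd))
  # single structure: cohort equals its own row on pooled columns
  b1 <- batch_audit(list(m1), preset = "deposited-h")
  expect_equal(b1$cohort$clashes_per_100, b1$table$clashes_per_100[1])
  # individual failures are logged and skipped
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", f)
  g <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m1, g, "pdb")
  b2 <- batch_audit(c(f, g), preset = "deposited-h")
  expect_identical(length(b2$failures), 1L)
  expect_identical(nrow(b2$table), 1L)
})

test_that("clash findings export as TSV", {
  m <- clash_fixture(20, 0.75)
  r <- detect_clashes(m)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_clash_tsv(r, f)
  tab <- read.delim(f)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$clash_class, "clash")
})
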