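test_that("variable species are found per the defined inventory", {
  toy <- build_network_toy("ser_water_chain")
  kinds <- vapply(find_variable_species(toy$model), function(s) s$kind,
                  character(1))
  expect_identical(sort(kinds), c("hydroxyl", "water"))
  # His: 6 states (3 protonation x 2 flip); Asn: 2 states
  his <- helical_allatom("GHG")
  sp <- find_variable_species(his)
  sp <- lapply(sp, enumerate_states, model = his)
  expect_identical(length(sp), 1L)
  expect_identical(length(sp[[1]]$states), 6L)
  expect_setequal(
    vapply(sp[[1]]$states, function(s) s$protonation, character(1)),
    c("HIE", "HID", "HIP"))
  asn <- helical_allatom("GNG")
  spn <- lapply(find_variable_species(asn), enumerate_states, model = asn)
  expect_identical(length(spn[[1]]$states), 2L)
  expect_identical(vapply(spn[[1]]$states, function(s) s$label,
                          character(1)), c("asis", "flip"))
  # Asp/Glu: deprotonated + 2x2 protonated
  asp <- helical_allatom("GDG")
  spd <- lapply(find_variable_species(asp), enumerate_states, model = asp)
  expect_identical(length(spd[[1]]$states), 5L)
})

test_that("state enumeration: aimed states, defaults, degenerate cases", {
  toy <- build_network_toy("ser_water_chain")
  sp <- toy$clusters[[1]]
  hyd <- sp[[which(vapply(sp, function(s) s$kind, character(1)) ==
                     "hydroxyl")]]
  # >= 3 staggered defaults plus at least one aimed state survive merging
  expect_gte(length(hyd$states), 3L)
  # aimed state must bring H closer to the water O than any pure default
  m <- toy$model
  wo <- which(m$atoms$resname == "HOH" & m$atoms$element == "O")
  dists <- vapply(hyd$states, function(st)
    clashaudit:::vec_norm(st$h[[1]] - coords(m)[wo, ]), numeric(1))
  sol <- toy$known_optimum[[1]]
  expect_lt(min(dists), 2.0)  # an aimed state points right at the acceptor
  # isolated water: defaults only, still >= 1 state
  w <- clashaudit:::single_water(c(0, 0, 0))
  attr(w, "hbond_roles") <- hbond_roles(w)
  spw <- lapply(find_variable_species(w), enumerate_states, model = w)
  expect_gte(length(spw[[1]]$states), 1L)
})

test_that("clusters are connected components under the coupling cutoff", {
  m1 <- build_ideal_peptide("GSG", chain = "A")
  m2 <- build_ideal_peptide("GSG", chain = "B")
  m2$atoms$x <- m2$atoms$x + 25
  mm <- add_hydrogens(clashaudit:::merge_models(m1, m2))
  sp <- find_variable_species(mm)
  cl <- build_clusters(sp, mm, 4.0)
  expect_identical(length(cl), 2L)
  expect_true(all(vapply(cl, length, integer(1)) == 1L))
  # chain Ser-water-(Asn) within range merges into one cluster
  toy <- build_network_toy("ser_water_chain")
  expect_identical(length(toy$clusters), 1L)
  expect_identical(length(toy$clusters[[1]]), 2L)
  # invariant to species order
  cl2 <- build_clusters(rev(sp), mm, 4.0)
  expect_identical(length(cl2), 2L)
})

test_that("scoring: empty cluster zero; clash dominates hydrogen bonds", {
  empty <- score_solution(list(), integer(0), NULL)
  expect_identical(empty$score, 0)
  # a hydroxyl H forced at 1.6 A from another H scores negative
  m1 <- helical_allatom("GSG")
  m2 <- helical_allatom("GAG")
  mm <- clashaudit:::merge_models(m1, m2)
  nb <- mm$atoms$serial > nrow(m1$atoms)
  mm$atoms$chain[nb] <- "B"
  a <- mm$atoms
  hg <- which(a$chain == "A" & a$name == "HG")
  og <- which(a$chain == "A" & a$name == "OG")
  hb1 <- which(a$chain == "B" & a$name == "HB1")
  # park the Ala methyl H directly beyond the hydroxyl H
  dirv <- coords(mm)[hg, ] - coords(mm)[og, ]
  dirv <- dirv / clashaudit:::vec_norm(dirv)
  shift <- (coords(mm)[hg, ] + 1.6 * dirv) - coords(mm)[hb1, ]
  mm$atoms$x[nb] <- mm$atoms$x[nb] + shift[1]
  mm$atoms$y[nb] <- mm$atoms$y[nb] + shift[2]
  mm$atoms$z[nb] <- mm$atoms$z[nb] + shift[3]
  mm <- build_covalent_graph(mm)
  attr(mm, "hbond_roles") <- hbond_roles(mm)
  sp <- find_variable_species(mm)
  sp <- lapply(sp, enumerate_states, model = mm)
  ser <- sp[[which(vapply(sp, function(s) s$kind, character(1)) ==
                     "hydroxyl")]]
  cl <- list(ser)
  # the state matching the deposited HG torsion clashes with HB1
  xyz_hg <- coords(mm)[which(mm$atoms$name == "HG"), ]
  dmin <- vapply(ser$states, function(st)
    clashaudit:::vec_norm(st$h[[1]] - xyz_hg), numeric(1))
  bad <- which.min(dmin)
  sol <- score_solution(cl, bad, mm)
  expect_lt(sol$score, 0)
  expect_gt(sol$n_clashes + sol$n_severe, 0)
})

test_that("optimizer equals the exhaustive oracle on every toy", {
  for (kind in c("ser_water_chain", "asn_flip", "his_tautomer", "mixed")) {
    toy <- build_network_toy(kind)
    for (ci in seq_along(toy$clusters)) {
      sol <- optimize_cluster(toy$clusters[[ci]], toy$model, seed = 5)
      expect_identical(sol$score, toy$known_optimum[[ci]]$score,
                       info = kind)
      # forced stochastic path reaches the same optimum
      solS <- optimize_cluster(toy$clusters[[ci]], toy$model, seed = 17,
                               params = network_params(
                                 force_stochastic = TRUE))
      expect_identical(solS$score, toy$known_optimum[[ci]]$score,
                       info = paste(kind, "stochastic"))
    }
  }
})

test_that("the asn flip toy flips and the ser-water chain bonds fully", {
  toy <- build_network_toy("asn_flip")
  cl <- toy$clusters[[1]]
  sol <- optimize_cluster(cl, toy$model, seed = 1)
  expect_identical(cl[[1]]$states[[sol$assignment[1]]]$label, "flip")
  expect_identical(sol$n_hbonds, 2L)
  toy2 <- build_network_toy("ser_water_chain")
  sol2 <- toy2$known_optimum[[1]]
  expect_gte(sol2$n_hbonds, 2L)
  expect_identical(sol2$n_clashes + sol2$n_severe, 0L)
})

test_that("optimization is deterministic and idempotent in score", {
  toy <- build_network_toy("mixed")
  o1 <- optimize_network(toy$model, seed = 9)
  o2 <- optimize_network(toy$model, seed = 9)
  expect_identical(o1$report, o2$report)
  # re-optimizing the optimized model cannot change total score
  o3 <- optimize_network(o1$model, seed = 9)
  expect_equal(sum(o3$report$score), sum(o1$report$score), tolerance = 1e-9)
  # monotonicity: final score is >= any single random start's converged score
  cl <- toy$clusters[[1]]
  tables <- clashaudit:::cluster_tables(cl, toy$model)
  set.seed(4)
  for (r in 1:5) {
    st <- vapply(cl, function(s) sample.int(length(s$states), 1),
                 integer(1))
    conv <- clashaudit:::best_response(tables, st)
    expect_gte(toy$known_optimum[[1]]$score,
               clashaudit:::score_from_tables(tables, conv))
  }
})

test_that("models with zero variable species pass through unchanged", {
  m <- helical_allatom("GAGVLG")
  o <- optimize_network(m, seed = 1)
  expect_identical(nrow(o$report), 0L)
  expect_equal(coords(o$model), coords(m), tolerance = 1e-12)
})

test_that("applying the winning states yields a clash-free audited model", {
  for (kind in c("ser_water_chain", "asn_flip", "his_tautomer")) {
    toy <- build_network_toy(kind)
    o <- optimize_network(toy$model, seed = 2)
    r <- detect_clashes(o$model)
    expect_identical(r$n_clashes + r$n_severe, 0L, info = kind)
  }
})
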