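# Deterministic synthetic-structure generator. Peptides are built in
# internal coordinates (NeRF) directly from the geometry target tables, so
# every constructed bond/angle sits exactly on its reference value and the
# zero-deviation oracles of the geometry module are exact by construction
# (ring-closing bonds of His/Phe/Tyr/Trp/Pro excepted; see vignette).

lookup_bond <- function(targets, rn, a1, a2) {
  t <- bond_target(targets, rn, a1, a2)
  if (is.null(t)) stop("no bond target for ", rn, " ", a1, "-", a2)
  t
}

lookup_angle <- function(targets, rn, a1, a2, a3) {
  t <- angle_target(targets, rn, a1, a2, a3)
  if (is.null(t)) stop("no angle target for ", rn, " ", a1, "-", a2, "-", a3)
  t
}

#' Build an ideal-geometry peptide
#'
#' Constructs a single-chain peptide whose every bond and angle equals its
#' reference target exactly (acyclic residues), at the given backbone
#' torsions. Optionally applies Gaussian internal-coordinate noise scaled in
#' units of the per-target sigma: with `noise_k > 0`, each constructed bond
#' is displaced by `noise_k * sigma * z` (z standard normal, drawn under
#' `seed`), so the recovered RMS Z score has expectation `noise_k`. The same
#' seed always yields the same z draws regardless of `noise_k`, making RMS Z
#' exactly linear in `noise_k` for a fixed seed. `shift_k` instead applies
#' the deterministic displacement `shift_k * sigma` to every bond and angle
#' (RMS Z exactly `shift_k`).
#'
#' @param sequence one-letter amino-acid string (standard residues)
#' @param phi,psi,omega backbone torsions in degrees, recycled per residue
#' @param chain chain identifier
#' @param oxt add a C-terminal OXT
#' @param noise_k,angle_noise_k Gaussian noise scale for bonds / angles
#' @param shift_k deterministic sigma-shift applied to bonds and angles
#' @param seed integer seed for the noise draws
#' @param targets a [geometry_targets()]
#' @return heavy-atom structure_model with covalent graph built
#' @export
build_ideal_peptide <- function(sequence, phi = -120, psi = 130,
                                omega = 180, chain = "A", oxt = TRUE,
                                noise_k = 0, angle_noise_k = noise_k,
                                shift_k = 0, seed = 1L,
                                targets = geometry_targets()) {
  seq3 <- .AA1TO3[strsplit(toupper(sequence), "")[[1]]]
  if (anyNA(seq3)) stop("unknown residue letter in sequence")
  n <- length(seq3)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n); omega <- rep_len(omega, n)
  rng <- local({
    set.seed(as.integer(seed) %% .Machine$integer.max)
    function() stats::rnorm(1)
  })
  bval <- function(rn, a1, a2) {
    t <- lookup_bond(targets, rn, a1, a2)
    v <- t$ideal + shift_k * t$sigma
    if (noise_k != 0 || shift_k == 0) {
      z <- if (noise_k != 0) rng() else 0
      v <- t$ideal + noise_k * t$sigma * z + shift_k * t$sigma
    }
    v
  }
  aval <- function(rn, a1, a2, a3) {
    t <- lookup_angle(targets, rn, a1, a2, a3)
    z <- if (angle_noise_k != 0) rng() else 0
    t$ideal + angle_noise_k * t$sigma * z + shift_k * t$sigma
  }
  res_atoms <- vector("list", n)
  push <- function(name, resseq, xyz, element = substr(name, 1, 1)) {
    res_atoms[[resseq]][[length(res_atoms[[resseq]]) + 1]] <<- data.frame(
      serial = 0L, name = name, altloc = "",
      resname = seq3[resseq], chain = chain, resseq = resseq, icode = "",
      x = xyz[1], y = xyz[2], z = xyz[3], occ = 1, b = 0,
      element = element, het = FALSE, stringsAsFactors = FALSE)
    xyz
  }
  prevN <- prevCA <- prevC <- NULL
  for (i in seq_len(n)) {
    rn <- seq3[i]
    if (i == 1) {
      N <- push("N", i, c(0, 0, 0), "N")
      CA <- push("CA", i, c(bval(rn, "N", "CA"), 0, 0), "C")
      ang <- deg2rad(aval(rn, "N", "CA", "C"))
      C <- push("C", i,
                CA + bval(rn, "CA", "C") * c(-cos(ang), sin(ang), 0), "C")
    } else {
      N <- push("N", i, nerf_place(prevN, prevCA, prevC,
                                   bval(seq3[i - 1], "C", "N"),
                                   aval(seq3[i - 1], "CA", "C", "N"),
                                   psi[i - 1]), "N")
      CA <- push("CA", i, nerf_place(prevCA, prevC, N,
                                     bval(rn, "N", "CA"),
                                     aval(rn, "C", "N", "CA"),
                                     omega[i]), "C")
      C <- push("C", i, nerf_place(prevC, N, CA,
                                   bval(rn, "CA", "C"),
                                   aval(rn, "N", "CA", "C"),
                                   phi[i]), "C")
      # O of the previous residue lies in its peptide plane
      O <- nerf_place(prevN, prevCA, prevC, bval(seq3[i - 1], "C", "O"),
                      aval(seq3[i - 1], "CA", "C", "O"), psi[i - 1] + 180)
      push("O", i - 1L, O, "O")
    }
    # sidechain
    pos <- list(N = N, CA = CA, C = C)
    if (rn != "GLY") {
      CB <- nerf_place(C, N, CA, bval(rn, "CA", "CB"),
                       aval(rn, "N", "CA", "CB"), .CB_IMPROPER)
      push("CB", i, CB, "C")
      pos$CB <- CB
      zm <- .SIDE_ZMAT[[rn]]
      if (!is.null(zm)) {
        for (row in zm) {
          nm <- row[1]; r1 <- row[2]; r2 <- row[3]; r3 <- row[4]
          tors <- as.numeric(row[5])
          xyz <- nerf_place(pos[[r3]], pos[[r2]], pos[[r1]],
                            bval(rn, r1, nm), aval(rn, r2, r1, nm), tors)
          el <- substr(nm, 1, 1)
          push(nm, i, xyz, if (el %in% c("O", "N", "S")) el else "C")
          pos[[nm]] <- xyz
        }
      }
    }
    if (i == n) {
      O <- nerf_place(N, CA, C, bval(rn, "C", "O"),
                      aval(rn, "CA", "C", "O"), psi[n] + 180)
      push("O", i, O, "O")
      if (oxt) {
        OXT <- nerf_place(N, CA, C, bval(rn, "C", "OXT"),
                          aval(rn, "CA", "C", "OXT"), psi[n])
        push("OXT", i, OXT, "O")
      }
    }
    prevN <- N; prevCA <- CA; prevC <- C
  }
  a <- do.call(rbind, unlist(res_atoms, recursive = FALSE))
  bb_first <- match(a$name, c("N", "CA", "C", "O"))
  bb_first[is.na(bb_first)] <- 5L
  a <- a[order(a$resseq, bb_first), , drop = FALSE]
  a$serial <- seq_len(nrow(a))
  m <- structure_model(a, NULL, NA_real_, "built")
  m <- build_covalent_graph(m)
  attr(m, "fixture_spec") <- list(sequence = sequence, phi = phi, psi = psi,
                                  omega = omega, chain = chain, oxt = oxt,
                                  seed = seed)
  m
}

#' Re-build a generated peptide with internal-coordinate noise
#'
#' Rebuilds the fixture recorded in the model's construction spec with
#' Gaussian bond/angle noise of `k` reference sigmas (see
#' [build_ideal_peptide()]); `k = 0` reproduces the model exactly.
#'
#' @param model a model produced by [build_ideal_peptide()]
#' @param k noise scale in sigma units
#' @param seed seed for the draws (defaults to the spec's seed)
#' @param deterministic if TRUE, shift every bond/angle by exactly
#'   `k * sigma` instead of sampling
#' @export
perturb_geometry <- function(model, k, seed = NULL, deterministic = FALSE) {
  spec <- attr(model, "fixture_spec")
  if (is.null(spec))
    stop("perturb_geometry requires a model built by build_ideal_peptide")
  if (is.null(seed)) seed <- spec$seed
  if (deterministic) {
    build_ideal_peptide(spec$sequence, spec$phi, spec$psi, spec$omega,
                        spec$chain, spec$oxt, noise_k = 0, shift_k = k,
                        seed = seed)
  } else {
    build_ideal_peptide(spec$sequence, spec$phi, spec$psi, spec$omega,
                        spec$chain, spec$oxt, noise_k = k, seed = seed)
  }
}

resolve_selector <- function(model, sel) {
  a <- model$atoms
  if (is.character(sel) && length(sel) == 1) {
    parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
    if (length(parts) != 3) stop("selector must be 'chain:resseq:name'")
    sel <- list(chain = parts[1], resseq = as.integer(parts[2]),
                name = parts[3])
  }
  hit <- which(a$chain == sel$chain & a$resseq == sel$resseq &
                 a$name == sel$name)
  if (length(hit) != 1)
    stop("selector does not resolve to exactly one atom: ",
         paste(unlist(sel), collapse = ":"))
  hit
}

#' Engineer a contact at an exact distance ratio
#'
#' Rigidly translates the residue containing atom B so that the
#' center-to-center distance d(A,B) equals `ratio x (r_A + r_B)` under the
#' given radius table, then verifies that no unintended contact at ratio
#' <= 0.8 was created (error otherwise).
#'
#' @param model structure_model with graph built
#' @param selector_a,selector_b `"chain:resseq:name"` strings or lists with
#'   `chain`, `resseq`, `name`
#' @param ratio target distance ratio (> 0)
#' @param table a [vdw_table()]
#' @return modified structure_model
#' @export
inject_contact <- function(model, selector_a, selector_b, ratio,
                           table = vdw_table("primary")) {
  stopifnot(ratio > 0)
  ia <- resolve_selector(model, selector_a)
  ib <- resolve_selector(model, selector_b)
  a <- model$atoms
  before <- finding_keys(detect_clashes(model, mode = table$mode,
                                        table = table))
  ra <- vdw_radius(a$element[ia], table, a$polar_aromatic_h[ia])
  rb <- vdw_radius(a$element[ib], table, a$polar_aromatic_h[ib])
  dir <- coords(model)[ib, ] - coords(model)[ia, ]
  if (vec_norm(dir) < 1e-9) stop("selected atoms coincide")
  target <- ratio * (ra + rb)
  newB <- coords(model)[ia, ] + target * vec_unit(dir)
  shift <- newB - coords(model)[ib, ]
  key <- residue_keys(model)
  move <- key == key[ib]
  model$atoms$x[move] <- model$atoms$x[move] + shift[1]
  model$atoms$y[move] <- model$atoms$y[move] + shift[2]
  model$atoms$z[move] <- model$atoms$z[move] + shift[3]
  after <- detect_clashes(model, mode = table$mode, table = table)
  intended <- paste(sort(c(ia, ib)), collapse = "-")
  new_keys <- setdiff(finding_keys(after), c(before, intended))
  if (length(new_keys))
    stop("inject_contact created unintended contact(s): ",
         paste(new_keys, collapse = ", "))
  model
}

finding_keys <- function(report) {
  f <- report$findings
  if (!nrow(f)) return(character(0))
  paste(pmin(f$atom_a, f$atom_b), pmax(f$atom_a, f$atom_b), sep = "-")
}

# ------------------------------------------------------------- network ----

rigid_transform_to <- function(model, anchor_sel, target, direction) {
  # translate + rotate a whole model so that `anchor_sel` lands on `target`
  # with the anchor->CA axis along `direction`
  ia <- resolve_selector(model, anchor_sel)
  xyz <- coords(model)
  key <- residue_keys(model)
  ca <- which(key == key[ia] & model$atoms$name == "CA")[1]
  u <- vec_unit(xyz[ca, ] - xyz[ia, ])
  v <- vec_unit(direction)
  axis <- vec_cross(u, v)
  if (vec_norm(axis) < 1e-9) {
    R <- diag(3) * ifelse(sum(u * v) > 0, 1, -1)
    if (sum(u * v) < 0) {
      perp <- vec_cross(u, c(1, 0, 0))
      if (vec_norm(perp) < 1e-6) perp <- vec_cross(u, c(0, 1, 0))
      R <- rotation_about(perp, 180)
    }
  } else {
    ang <- rad2deg(acos(max(-1, min(1, sum(u * v)))))
    R <- rotation_about(axis, ang)
  }
  newxyz <- sweep(xyz, 2, xyz[ia, ]) %*% t(R)
  newxyz <- sweep(newxyz, 2, target, FUN = "+")
  model$atoms$x <- newxyz[, 1]
  model$atoms$y <- newxyz[, 2]
  model$atoms$z <- newxyz[, 3]
  model
}

merge_models <- function(...) {
  models <- list(...)
  atoms <- do.call(rbind, lapply(models, function(m) m$atoms[
    , setdiff(names(m$atoms), c("is_h", "polar_aromatic_h"))]))
  atoms$serial <- seq_len(nrow(atoms))
  build_covalent_graph(structure_model(atoms, NULL, NA_real_, "built"))
}

single_water <- function(center, chain = "W", resseq = 1L) {
  a <- empty_atoms(1)
  a$serial <- 1L; a$name <- "O"; a$altloc <- ""; a$resname <- "HOH"
  a$chain <- chain; a$resseq <- resseq; a$icode <- ""
  a$x <- center[1]; a$y <- center[2]; a$z <- center[3]
  a$occ <- 1; a$b <- 0; a$element <- "O"; a$het <- TRUE
  structure_model(a, NULL, NA_real_, "built")
}

acceptor_fragment <- function(target, away_from, chain) {
  # a single Ala whose backbone O sits at `target`, body pointing away
  frag <- build_ideal_peptide("A", chain = chain, oxt = FALSE)
  rigid_transform_to(frag, paste0(chain, ":1:O"), target,
                     vec_unit(target - away_from))
}

#' Build a small hydrogen-bond network toy with known optimum
#'
#' Constructs a tiny model containing one interaction cluster whose
#' exhaustive optimum is computed by full enumeration (independent of the
#' stochastic search) and returned alongside the model.
#'
#' @param kind `"ser_water_chain"`, `"asn_flip"`, `"his_tautomer"` or
#'   `"mixed"`
#' @param seed integer seed used for enumeration bookkeeping
#' @param params a [network_params()]
#' @return list: `model` (all-atom, graph built), `clusters`,
#'   `known_optimum` (list per cluster: assignment + score by brute force)
#' @export
build_network_toy <- function(kind = c("ser_water_chain", "asn_flip",
                                       "his_tautomer", "mixed"),
                              seed = 1L, params = network_params()) {
  kind <- match.arg(kind)
  host <- switch(kind,
    ser_water_chain = build_ideal_peptide("GSG", chain = "A"),
    asn_flip = build_ideal_peptide("GNG", chain = "A"),
    his_tautomer = build_ideal_peptide("GHG", chain = "A"),
    mixed = build_ideal_peptide("GSNG", chain = "A"))
  host <- add_hydrogens(host)
  a <- host$atoms
  xyz <- coords(host)
  at <- function(nm, resseq = 2L) {
    which(a$chain == "A" & a$resseq == resseq & a$name == nm)[1]
  }
  parts <- list(host)
  if (kind == "ser_water_chain") {
    og <- at("OG"); hg <- at("HG")
    # along the deposited hydroxyl H direction, so an aimed torsion state
    # can hydrogen-bond Ser-OH -> water -> acceptor in a chain
    wdir <- vec_unit(xyz[hg, ] - xyz[og, ])
    wpos <- xyz[og, ] + 2.8 * wdir
    parts[[2]] <- single_water(wpos)
    acc <- wpos + 2.8 * wdir
    parts[[3]] <- acceptor_fragment(acc, wpos, "B")
  } else if (kind == "asn_flip") {
    od1 <- at("OD1"); nd2 <- at("ND2"); cg <- at("CG"); cb <- at("CB")
    # swing the amide plane away from the backbone (rotation about CB-CG
    # preserves all bonded geometry), then re-derive positions
    grp <- c(od1, nd2, at("HD21"), at("HD22"))
    grp <- grp[!is.na(grp)]
    R <- rotation_about(xyz[cg, ] - xyz[cb, ], -90)
    rel <- sweep(xyz[grp, , drop = FALSE], 2, xyz[cg, ]) %*% t(R)
    host$atoms[grp, c("x", "y", "z")] <- sweep(rel, 2, xyz[cg, ], FUN = "+")
    xyz <- coords(host)
    parts[[1]] <- host
    # the flipped amide N sits on the old OD1 position; dock one acceptor
    # along each of its two in-plane N-H directions
    for (chi in c(0, 180)) {
      h <- nerf_place(xyz[cb, ], xyz[cg, ], xyz[od1, ], 1.01, 120, chi)
      acc <- xyz[od1, ] + 2.9 * vec_unit(h - xyz[od1, ])
      parts[[length(parts) + 1]] <-
        acceptor_fragment(acc, xyz[od1, ], if (chi == 0) "B" else "C")
    }
  } else if (kind == "his_tautomer") {
    nd1 <- at("ND1"); cg <- at("CG"); ce1 <- at("CE1")
    d <- vec_unit(-(vec_unit(xyz[cg, ] - xyz[nd1, ]) +
                      vec_unit(xyz[ce1, ] - xyz[nd1, ])))
    acc <- xyz[nd1, ] + 2.9 * d
    parts[[2]] <- acceptor_fragment(acc, xyz[nd1, ], "B")
  } else {
    og <- at("OG"); hg <- at("HG")
    wdir <- vec_unit(xyz[hg, ] - xyz[og, ])
    wpos <- xyz[og, ] + 2.8 * wdir
    parts[[2]] <- single_water(wpos)
  }
  model <- do.call(merge_models, parts)
  attr(model, "hbond_roles") <- hbond_roles(model)
  species <- find_variable_species(model)
  species <- lapply(species, enumerate_states, model = model,
                    params = params)
  clusters <- build_clusters(species, model, params$coupling_cutoff)
  known <- lapply(clusters, function(cl) {
    nstates <- vapply(cl, function(s) length(s$states), integer(1))
    grid <- as.matrix(expand.grid(lapply(nstates, seq_len)))
    best <- NULL
    for (r in seq_len(nrow(grid))) {
      sol <- score_solution(cl, as.integer(grid[r, ]), model, params)
      if (is.null(best) || sol$score > best$score) best <- sol
    }
    best
  })
  list(model = model, clusters = clusters, known_optimum = known)
}

#' Fixture with engineered clashes at exact ratios
#'
#' Builds an extended host peptide and, for each requested contact, docks a
#' single-alanine probe chain along the outward CB normal of a host residue
#' so that the probe CB meets the host CB at exactly the requested distance
#' ratio. Only the intended pair comes close; [inject_contact()] verifies
#' this and errors otherwise.
#'
#' @param n_residues host length (alanines)
#' @param ratios numeric vector of target ratios, one probe per entry
#' @param host_res host residue indices to target (default: spread out)
#' @param table radius table
#' @return structure_model with `n_residues + length(ratios)` residues
#' @export
clash_fixture <- function(n_residues = 50, ratios = numeric(0),
                          host_res = NULL,
                          table = vdw_table("primary")) {
  host <- build_ideal_peptide(strrep("A", n_residues), phi = -120,
                              psi = 130)
  if (!length(ratios)) return(host)
  if (is.null(host_res)) {
    k <- length(ratios)
    host_res <- seq(5, n_residues - 4, length.out = k + 2)[seq_len(k) + 1]
  }
  host_res <- as.integer(round(host_res))
  stopifnot(length(host_res) == length(ratios))
  parts <- list(host)
  xyz <- coords(host)
  a <- host$atoms
  for (t in seq_along(ratios)) {
    rs <- host_res[t]
    cb <- which(a$resseq == rs & a$name == "CB")
    ca <- which(a$resseq == rs & a$name == "CA")
    d <- vec_unit(xyz[cb, ] - xyz[ca, ])
    probe <- build_ideal_peptide("A", chain = LETTERS[t + 1], oxt = FALSE)
    # put the probe CB on the outward normal, pointing away from the host
    start <- xyz[cb, ] + 6.0 * d
    probe <- rigid_transform_to(probe, paste0(LETTERS[t + 1], ":1:CB"),
                                start, d)
    parts[[t + 1]] <- probe
  }
  m <- do.call(merge_models, parts)
  for (t in seq_along(ratios)) {
    m <- inject_contact(m, list(chain = "A", resseq = host_res[t],
                                name = "CB"),
                        list(chain = LETTERS[t + 1], resseq = 1L,
                             name = "CB"),
                        ratios[t], table)
  }
  m
}
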