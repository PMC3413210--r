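# Rule-based hydrogen-bond network optimization.
#
# The variable species are (i) alcoholic, (ii) sulfhydryl and (iii) phenolic
# H torsions, (iv) Asp/Glu charge state, (v) His charge/tautomer/flip,
# (vi) Asn/Gln flip, (vii) water orientation. States are enumerated
# discretely (aimed at nearby acceptors, anti to nearby donors, staggered
# defaults); species are grouped into clusters that could be hydrogen-bond
# connected, and each cluster is solved for the assignment maximizing the
# hydrogen-bond count while avoiding clashes. Small clusters are solved
# exhaustively; larger ones by multistart best-response, recombination and
# simulated annealing. The scoring decomposes exactly into per-species and
# pairwise terms, which the search exploits.

#' Network-optimization parameters
#'
#' @param coupling_cutoff Å between polar atoms linking two species into one
#'   cluster (default 4.0: the 3.5 Å hydrogen-bond ceiling plus slack)
#' @param hb_da_max,hb_ha_max,hb_angle_min hydrogen-bond criteria:
#'   donor-acceptor <= 3.5 Å, H...A <= 2.5 Å, D-H...A >= 120 deg
#' @param w_hb,w_clash,w_severe scoring weights (+1 per hydrogen bond, -10
#'   per clash, -100 per severe clash: any clash outweighs any plausible
#'   hydrogen-bond gain)
#' @param prior_charge prior (default -0.5) added for a neutral Asp/Glu or a
#'   charged His, disfavouring gratuitous (de)protonation
#' @param n_starts,n_offspring,sa_steps_per_species,t_start,t_end stochastic
#'   search controls
#' @param exhaustive_limit clusters with at most this many state
#'   combinations are solved by enumeration (default 1e4)
#' @param merge_tol torsion dedup tolerance in degrees
#' @param force_stochastic skip the exhaustive path (testing hook)
#' @export
network_params <- function(coupling_cutoff = 4.0, hb_da_max = 3.5,
                           hb_ha_max = 2.5, hb_angle_min = 120,
                           w_hb = 1, w_clash = 10, w_severe = 100,
                           prior_charge = -0.5, n_starts = 10,
                           n_offspring = 20, sa_steps_per_species = 200,
                           t_start = 1.0, t_end = 0.01,
                           exhaustive_limit = 1e4, merge_tol = 15,
                           force_stochastic = FALSE) {
  as.list(environment())
}

.H_OH_ANGLE <- c(O = 109.47, S = 96, N = 109.47)

# ------------------------------------------------------------- species ----

#' Find the variable hydrogen-bond species of a model
#'
#' @param model all-atom structure_model (riding H placed, graph built)
#' @return list of `variable_species`
#' @export
find_variable_species <- function(model) {
  a <- model$atoms
  key <- residue_keys(model)
  adj <- adjacency_list(model)
  species <- list()
  add <- function(kind, idx, parent, polar, owned_h, axis = NULL) {
    species[[length(species) + 1]] <<- structure(list(
      id = length(species) + 1L, kind = kind, res_key = key[idx[1]],
      resname = toupper(a$resname[idx[1]]), parent_idx = parent,
      polar_idx = polar, owned_h = owned_h, torsion_axis = axis,
      states = NULL), class = "variable_species")
  }
  for (k in unique(key)) {
    idx <- which(key == k)
    rn <- toupper(a$resname[idx[1]])
    at <- function(nm) { h <- idx[a$name[idx] == nm]; if (length(h)) h[1] else NA_integer_ }
    if (is_water_res(rn)) {
      o <- idx[a$element[idx] == "O"][1]
      if (!is.na(o)) add("water", idx, o, o,
                         a$name[idx[a$is_h[idx]]])
      next
    }
    if (!is_standard_aa(rn)) next
    if (rn %in% c("SER", "THR", "TYR", "CYS")) {
      rot <- .ROTATABLE_SITES[[rn]]
      p <- at(rot$parent)
      if (is.na(p)) next
      if (rn == "CYS" &&
          any(!a$is_h[adj[[p]]] & a$name[adj[[p]]] == "SG")) next
      hn <- residue_bond_names(rn)
      hn <- hn[hn[, 1] == rot$parent & grepl("^H", hn[, 2]), 2]
      add(rot$kind, idx, p, p, hn, axis = c(p, at(rot$axis)))
    } else if (rn %in% c("ASP", "GLU")) {
      o1 <- at(if (rn == "ASP") "OD1" else "OE1")
      o2 <- at(if (rn == "ASP") "OD2" else "OE2")
      if (is.na(o1) || is.na(o2)) next
      add("asp_glu_state", idx, c(o1, o2), c(o1, o2),
          if (rn == "ASP") c("HD1", "HD2") else c("HE1", "HE2"))
    } else if (rn == "HIS") {
      nd1 <- at("ND1"); ne2 <- at("NE2"); ce1 <- at("CE1"); cd2 <- at("CD2")
      cg <- at("CG")
      if (any(is.na(c(nd1, ne2, ce1, cd2, cg)))) next
      add("his_state", idx, c(nd1, ne2, ce1, cd2, cg), c(nd1, ne2),
          c("HD1", "HE2", "HD2", "HE1"))
    } else if (rn %in% c("ASN", "GLN")) {
      o <- at(if (rn == "ASN") "OD1" else "OE1")
      nn <- at(if (rn == "ASN") "ND2" else "NE2")
      cc <- at(if (rn == "ASN") "CG" else "CD")
      if (any(is.na(c(o, nn, cc)))) next
      add("asn_gln_flip", idx, c(o, nn, cc), c(o, nn),
          if (rn == "ASN") c("HD21", "HD22") else c("HE21", "HE22"))
    }
  }
  species
}

# neighbour polar atoms of the fixed environment near a point
.near_rows <- function(xyz, pt, radius) {
  d2 <- (xyz[, 1] - pt[1])^2 + (xyz[, 2] - pt[2])^2 + (xyz[, 3] - pt[3])^2
  which(d2 <= radius^2)
}

#' Enumerate the discrete states of one species
#'
#' Hydroxyl/sulfhydryl/phenolic: one torsion aimed at each acceptor within
#' 3.5 Å of the parent heavy atom, one anti to each nearby donor, plus three
#' staggered defaults; duplicates within `merge_tol` degrees merged. Water:
#' orientations pairing the two H directions with up to two nearby
#' acceptors, plus defaults. Asp/Glu: deprotonated plus syn/anti protonation
#' of either oxygen. His: 3 protonation states x 2 flips. Asn/Gln: flip or
#' not.
#'
#' @param species a `variable_species`
#' @param model the model
#' @param params a [network_params()]
#' @return the species with `$states` filled
#' @export
enumerate_states <- function(species, model, params = network_params()) {
  a <- model$atoms
  xyz <- coords(model)
  adj <- adjacency_list(model)
  roles <- attr(model, "hbond_roles")
  if (is.null(roles)) roles <- hbond_roles(model)
  kind <- species$kind
  sts <- list()
  mk <- function(label, h = list(), swap = list(), protonation = "",
                 prior = 0) {
    list(label = label, h = h, swap = swap, protonation = protonation,
         prior = prior)
  }
  if (kind %in% c("hydroxyl", "sulfhydryl", "phenolic", "amine")) {
    p <- species$parent_idx[1]
    q <- species$torsion_axis[2]
    refs <- setdiff(heavy_neighbors(model, adj, q), p)
    ref <- if (length(refs)) refs[1] else setdiff(sort(adj[[q]]), p)[1]
    el <- a$element[p]
    L <- .XH_LENGTHS[[el]]
    theta <- .H_OH_ANGLE[[el]]
    excl <- c(graph_neighborhood(adj, p, 3), p)
    near <- setdiff(.near_rows(xyz, xyz[p, ], params$hb_da_max), excl)
    accs <- near[roles$acceptor[near]]
    dons <- near[roles$donor[near]]
    chis <- c(60, 180, 300)
    for (ac in accs)
      chis <- c(chis, torsion_angle(xyz[ref, ], xyz[q, ], xyz[p, ], xyz[ac, ]))
    for (dn in dons)
      chis <- c(chis, torsion_angle(xyz[ref, ], xyz[q, ], xyz[p, ], xyz[dn, ]) + 180)
    chis <- chis %% 360
    kept <- numeric(0)
    for (chi in chis) {
      if (any(abs(wrap180(chi - kept)) < params$merge_tol)) next
      kept <- c(kept, chi)
    }
    nH <- length(species$owned_h)
    for (chi in kept) {
      h <- list()
      for (t in seq_len(nH)) {
        h[[species$owned_h[t]]] <-
          nerf_place(xyz[ref, ], xyz[q, ], xyz[p, ], L, theta,
                     chi + (t - 1) * 360 / nH)
      }
      sts[[length(sts) + 1]] <- mk(sprintf("chi%.0f", chi), h = h)
    }
  } else if (kind == "water") {
    o <- species$parent_idx[1]
    O <- xyz[o, ]
    L <- .XH_LENGTHS[["O"]]
    hoh <- 104.5
    near <- setdiff(.near_rows(xyz, O, params$hb_da_max), o)
    near <- near[!a$is_h[near]]
    accs <- near[roles$acceptor[near] | roles$donor[near]]
    dirs <- lapply(accs, function(i) vec_unit(xyz[i, ] - O))
    # default frame
    e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
    if (length(dirs)) {
      e1 <- dirs[[1]]
      ortho <- vec_cross(e1, if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
      e2 <- vec_unit(vec_cross(ortho, e1))
    }
    second_h <- function(d1, target) {
      # H2 on the 104.5 deg cone about d1, azimuth closest to `target`
      axis <- vec_unit(d1)
      perp <- target - sum(target * axis) * axis
      if (vec_norm(perp) < 1e-6) {
        perp <- vec_cross(axis, if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
      }
      perp <- vec_unit(perp)
      vec_unit(cos(deg2rad(hoh)) * axis + sin(deg2rad(hoh)) * perp)
    }
    cand <- list()
    if (length(dirs) == 0) {
      cand[[1]] <- list(e1, second_h(e1, e2))
    } else {
      for (i in seq_along(dirs)) {
        others <- setdiff(seq_along(dirs), i)
        if (length(others)) {
          for (j in others) cand[[length(cand) + 1]] <-
              list(dirs[[i]], second_h(dirs[[i]], xyz[accs[j], ] - O))
        }
        # defaults: two arbitrary azimuths for the second H
        base <- second_h(dirs[[i]], e2)
        cand[[length(cand) + 1]] <- list(dirs[[i]], base)
        rot <- rotation_about(dirs[[i]], 120)
        cand[[length(cand) + 1]] <- list(dirs[[i]], as.numeric(rot %*% base))
      }
    }
    hn <- species$owned_h
    if (length(hn) < 2) hn <- c("H1", "H2")
    seen <- list()
    for (cd in cand) {
      h1 <- O + L * cd[[1]]; h2 <- O + L * cd[[2]]
      dup <- any(vapply(seen, function(s)
        (vec_norm(s[[1]] - h1) < 0.3 && vec_norm(s[[2]] - h2) < 0.3) ||
        (vec_norm(s[[1]] - h2) < 0.3 && vec_norm(s[[2]] - h1) < 0.3),
        logical(1)))
      if (dup) next
      seen[[length(seen) + 1]] <- list(h1, h2)
      sts[[length(sts) + 1]] <- mk(sprintf("w%d", length(sts) + 1),
                                   h = stats::setNames(list(h1, h2), hn))
    }
  } else if (kind == "asp_glu_state") {
    o1 <- species$parent_idx[1]; o2 <- species$parent_idx[2]
    cg <- intersect(heavy_neighbors(model, adj, o1),
                    heavy_neighbors(model, adj, o2))[1]
    cb <- setdiff(heavy_neighbors(model, adj, cg), c(o1, o2))[1]
    hn <- species$owned_h  # e.g. HD1 (on OD1), HD2 (on OD2)
    sts[[1]] <- mk("deprotonated", prior = 0, protonation = "charged")
    for (which_o in 1:2) {
      o <- c(o1, o2)[which_o]
      for (chi in c(0, 180)) {
        h <- list()
        h[[hn[which_o]]] <- nerf_place(xyz[cb, ], xyz[cg, ], xyz[o, ],
                                       .XH_LENGTHS[["O"]], 110, chi)
        sts[[length(sts) + 1]] <- mk(
          sprintf("%s-%s", c("O1", "O2")[which_o],
                  if (chi == 0) "syn" else "anti"),
          h = h, prior = params$prior_charge, protonation = "neutral")
      }
    }
  } else if (kind == "his_state") {
    nd1 <- species$parent_idx[1]; ne2 <- species$parent_idx[2]
    ce1 <- species$parent_idx[3]; cd2 <- species$parent_idx[4]
    cg <- species$parent_idx[5]
    ring_h <- function(center, n1, n2, L) {
      d <- vec_unit(-(vec_unit(n1 - center) + vec_unit(n2 - center)))
      center + L * d
    }
    pos <- function(swap) {
      p <- list(ND1 = xyz[nd1, ], NE2 = xyz[ne2, ],
                CE1 = xyz[ce1, ], CD2 = xyz[cd2, ], CG = xyz[cg, ])
      if (swap) {
        p[c("ND1", "CD2")] <- p[c("CD2", "ND1")]
        p[c("CE1", "NE2")] <- p[c("NE2", "CE1")]
      }
      p
    }
    for (flip in c(FALSE, TRUE)) {
      p <- pos(flip)
      swap <- if (flip) list(c(nd1, cd2), c(ce1, ne2)) else list()
      hd2 <- ring_h(p$CD2, p$CG, p$NE2, .XH_LENGTHS[["C"]])
      he1 <- ring_h(p$CE1, p$ND1, p$NE2, .XH_LENGTHS[["C"]])
      hd1 <- ring_h(p$ND1, p$CG, p$CE1, .XH_LENGTHS[["N"]])
      he2 <- ring_h(p$NE2, p$CE1, p$CD2, .XH_LENGTHS[["N"]])
      base <- list(HD2 = hd2, HE1 = he1)
      lab <- if (flip) "flip" else "asis"
      sts[[length(sts) + 1]] <- mk(paste0("HIE-", lab),
                                   h = c(base, list(HE2 = he2)),
                                   swap = swap, protonation = "HIE")
      sts[[length(sts) + 1]] <- mk(paste0("HID-", lab),
                                   h = c(base, list(HD1 = hd1)),
                                   swap = swap, protonation = "HID")
      sts[[length(sts) + 1]] <- mk(paste0("HIP-", lab),
                                   h = c(base, list(HD1 = hd1, HE2 = he2)),
                                   swap = swap, protonation = "HIP",
                                   prior = params$prior_charge)
    }
  } else if (kind == "asn_gln_flip") {
    o <- species$parent_idx[1]; nn <- species$parent_idx[2]
    cc <- species$parent_idx[3]
    ref <- setdiff(heavy_neighbors(model, adj, cc), c(o, nn))[1]
    amide_h <- function(Np, Cp, Rp, hn) {
      stats::setNames(
        list(nerf_place(Rp, Cp, Np, .XH_LENGTHS[["N"]], 120, 0),
             nerf_place(Rp, Cp, Np, .XH_LENGTHS[["N"]], 120, 180)), hn)
    }
    sts[[1]] <- mk("asis",
                   h = amide_h(xyz[nn, ], xyz[cc, ], xyz[ref, ],
                               species$owned_h))
    sts[[2]] <- mk("flip",
                   h = amide_h(xyz[o, ], xyz[cc, ], xyz[ref, ],
                               species$owned_h),
                   swap = list(c(o, nn)))
  } else stop("unknown species kind: ", kind)
  species$states <- sts
  species
}

# ------------------------------------------------------------ clusters ----

#' Group species into interaction clusters
#'
#' Connected components of the graph linking species whose polar atoms lie
#' within `coupling_cutoff` of each other.
#'
#' @param species list of species (states enumerated or not)
#' @param model the model
#' @param coupling_cutoff Å (default 4.0)
#' @return list of clusters (each a list of species)
#' @export
build_clusters <- function(species, model,
                           coupling_cutoff = 4.0) {
  n <- length(species)
  if (n == 0) return(list())
  xyz <- coords(model)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pi_ <- xyz[species[[i]]$polar_idx, , drop = FALSE]
    pj <- xyz[species[[j]]$polar_idx, , drop = FALSE]
    dmin <- min(apply(pi_, 1, function(p)
      min(sqrt(rowSums(sweep(pj, 2, p)^2)))))
    if (dmin <= coupling_cutoff) parent[find(i)] <- find(j)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(unique(roots), function(r) species[roots == r])
}

# --------------------------------------------------------------- scoring --

# Scoring-geometry of one species state: variable atoms with roles.
state_geometry <- function(species, state, model, xyz) {
  a <- model$atoms
  adj <- adjacency_list(model)
  heavy <- list()
  for (sw in state$swap) {
    heavy[[as.character(sw[1])]] <- xyz[sw[2], ]
    heavy[[as.character(sw[2])]] <- xyz[sw[1], ]
  }
  hpos <- function(i) {
    ci <- as.character(i)
    if (!is.null(heavy[[ci]])) heavy[[ci]] else xyz[i, ]
  }
  rows <- list()
  addrow <- function(name, el, p, parent_row, own_row, donor, acceptor,
                     donor_h, d_xyz = NULL) {
    rows[[length(rows) + 1]] <<- list(name = name, element = el, xyz = p,
      parent_row = parent_row, own_row = own_row, donor = donor,
      acceptor = acceptor, donor_h = donor_h, d_xyz = d_xyz)
  }
  key <- residue_keys(model)
  res_rows <- which(key == species$res_key)
  h_parent <- function(hname) {
    # heavy atom carrying this H, by template bond list (or water O)
    if (species$kind == "water") return(species$parent_idx[1])
    tpl <- rbind(residue_bond_names(species$resname),
                 optional_bond_names(species$resname))
    pr <- tpl[tpl[, 2] == hname, 1]
    if (!length(pr)) return(NA_integer_)
    hit <- res_rows[a$name[res_rows] == pr[1]]
    if (length(hit)) hit[1] else NA_integer_
  }
  # variable hydrogens of this state
  for (hn in names(state$h)) {
    p <- h_parent(hn)
    own <- res_rows[a$name[res_rows] == hn]
    addrow(hn, "H", state$h[[hn]], p,
           if (length(own)) own[1] else NA_integer_,
           donor = FALSE, acceptor = FALSE, donor_h = TRUE,
           d_xyz = hpos(p))
  }
  # movable heavy atoms (flips): roles depend on protonation
  has_state_h_on <- function(row) {
    # is one of the state's H atoms attached to this heavy atom?
    any(vapply(names(state$h), function(hn) {
      p <- h_parent(hn); !is.na(p) && p == row
    }, logical(1)))
  }
  for (sw in state$swap) for (i in sw) {
    el <- a$element[i]
    don <- el %in% c("N", "O", "S") && has_state_h_on(i)
    acc <- el == "O" || (el == "N" && species$kind == "his_state" &&
                           !has_state_h_on(i))
    addrow(a$name[i], el, hpos(i), i, i, donor = don, acceptor = acc,
           donor_h = FALSE)
  }
  # immovable polar atoms whose ROLE depends on the state (Asp/Glu O,
  # hydroxyl O, water O): they are part of the species for h-bonding
  if (species$kind == "asp_glu_state") {
    for (t in 1:2) {
      i <- species$parent_idx[t]
      don <- has_state_h_on(i)
      addrow(a$name[i], a$element[i], xyz[i, ], i, i, donor = don,
             acceptor = TRUE, donor_h = FALSE)
    }
  } else if (species$kind %in% c("hydroxyl", "phenolic", "sulfhydryl",
                                 "water")) {
    i <- species$parent_idx[1]
    addrow(a$name[i], a$element[i], xyz[i, ], i, i, donor = TRUE,
           acceptor = a$element[i] != "N", donor_h = FALSE)
  } else if (species$kind == "his_state" && length(state$swap) == 0) {
    for (i in species$parent_idx[1:2]) {
      don <- has_state_h_on(i)
      addrow(a$name[i], a$element[i], xyz[i, ], i, i, donor = don,
             acceptor = !don, donor_h = FALSE)
    }
  } else if (species$kind == "asn_gln_flip" && length(state$swap) == 0) {
    o <- species$parent_idx[1]; nn <- species$parent_idx[2]
    addrow(a$name[o], "O", xyz[o, ], o, o, donor = FALSE, acceptor = TRUE,
           donor_h = FALSE)
    addrow(a$name[nn], "N", xyz[nn, ], nn, nn, donor = TRUE,
           acceptor = FALSE, donor_h = FALSE)
  }
  rows
}

graph_sep_le <- function(adj, i, j, depth) {
  if (is.na(i) || is.na(j)) return(FALSE)
  if (i == j) return(TRUE)
  j %in% graph_neighborhood(adj, i, depth)
}

# hydrogen-bond test
.hb_ok <- function(d_xyz, h_xyz, a_xyz, params) {
  vec_norm(d_xyz - a_xyz) <= params$hb_da_max &&
    vec_norm(h_xyz - a_xyz) <= params$hb_ha_max &&
    bond_angle(d_xyz, h_xyz, a_xyz) >= params$hb_angle_min
}

# contact classification between a variable atom record and another atom
# record (variable or environment); returns "none"/"clash"/"severe"
.pair_clash <- function(va, vb, adj, table, params) {
  # bonded-path exclusion: effective separation via owner/parent rows
  ra <- if (!is.na(va$own_row)) va$own_row else va$parent_row
  rb <- if (!is.na(vb$own_row)) vb$own_row else vb$parent_row
  pen <- (is.na(va$own_row)) + (is.na(vb$own_row))
  if (graph_sep_le(adj, ra, rb, max(0, 3 - pen))) return("none")
  # hydrogen-bond exclusions
  if ((va$donor && vb$acceptor) || (vb$donor && va$acceptor)) return("none")
  if ((va$donor_h && vb$acceptor) || (vb$donor_h && va$acceptor))
    return("none")
  d <- vec_norm(va$xyz - vb$xyz)
  r1 <- vdw_radius(va$element, table, TRUE)  # variable H are all polar
  r2 <- vdw_radius(vb$element, table, isTRUE(vb$polar_aromatic))
  ratio <- d / (r1 + r2)
  if (ratio <= .SEVERE_RATIO) "severe" else
    if (ratio <= .CLASH_RATIO) "clash" else "none"
}

# environment atom records near a cluster (fixed atoms only)
env_records <- function(model, cluster, params, table) {
  a <- model$atoms
  xyz <- coords(model)
  roles <- attr(model, "hbond_roles")
  if (is.null(roles)) roles <- hbond_roles(model)
  adj <- adjacency_list(model)
  var_rows <- unlist(lapply(cluster, function(s) {
    key <- residue_keys(model)
    res_rows <- which(key == s$res_key)
    hrows <- res_rows[a$name[res_rows] %in% s$owned_h]
    c(hrows, if (s$kind %in% c("asn_gln_flip", "his_state"))
        s$parent_idx else integer(0))
  }))
  centers <- do.call(rbind, lapply(cluster, function(s)
    xyz[s$polar_idx, , drop = FALSE]))
  near <- unique(unlist(apply(centers, 1, function(p)
    .near_rows(xyz, p, 6.0), simplify = FALSE)))
  near <- setdiff(near, var_rows)
  lapply(near, function(i) {
    dxyz <- NULL
    if (a$is_h[i]) {
      nb <- adj[[i]]
      hv <- nb[!a$is_h[nb]]
      if (length(hv)) dxyz <- xyz[hv[1], ]
    }
    list(name = a$name[i], element = a$element[i], xyz = xyz[i, ],
         parent_row = i, own_row = i,
         donor = roles$donor[i], acceptor = roles$acceptor[i],
         donor_h = i %in% roles$donor_h, d_xyz = dxyz,
         polar_aromatic = isTRUE(a$polar_aromatic_h[i]))
  })
}

# score contributions of one species-state against the environment
single_terms <- function(geom, env, adj, table, params) {
  n_hb <- 0L; n_cl <- 0L; n_sv <- 0L
  for (va in geom) {
    for (ve in env) {
      if (va$donor_h && ve$acceptor && !is.null(va$d_xyz)) {
        if (.hb_ok(va$d_xyz, va$xyz, ve$xyz, params)) n_hb <- n_hb + 1L
      }
      if (va$acceptor && ve$donor_h && !is.null(ve$d_xyz)) {
        if (.hb_ok(ve$d_xyz, ve$xyz, va$xyz, params)) n_hb <- n_hb + 1L
      }
      cl <- .pair_clash(va, ve, adj, table, params)
      if (cl == "clash") n_cl <- n_cl + 1L
      if (cl == "severe") n_sv <- n_sv + 1L
    }
  }
  c(hb = n_hb, clash = n_cl, severe = n_sv)
}

pair_terms <- function(geomA, geomB, adj, table, params) {
  n_hb <- 0L; n_cl <- 0L; n_sv <- 0L
  for (va in geomA) for (vb in geomB) {
    if (va$donor_h && vb$acceptor && !is.null(va$d_xyz) &&
        .hb_ok(va$d_xyz, va$xyz, vb$xyz, params)) n_hb <- n_hb + 1L
    if (vb$donor_h && va$acceptor && !is.null(vb$d_xyz) &&
        .hb_ok(vb$d_xyz, vb$xyz, va$xyz, params)) n_hb <- n_hb + 1L
    cl <- .pair_clash(va, vb, adj, table, params)
    if (cl == "clash") n_cl <- n_cl + 1L
    if (cl == "severe") n_sv <- n_sv + 1L
  }
  c(hb = n_hb, clash = n_cl, severe = n_sv)
}

# Precompute the score tables of a cluster: $single[[s]][st, c(hb,cl,sv)]
# and $pair[[s1]][[s2]] array [st1, st2, 3].
cluster_tables <- function(cluster, model, params = network_params(),
                           table = vdw_table("primary")) {
  adj <- adjacency_list(model)
  xyz <- coords(model)
  env <- env_records(model, cluster, params, table)
  ns <- length(cluster)
  geoms <- lapply(cluster, function(s)
    lapply(s$states, function(st) state_geometry(s, st, model, xyz)))
  single <- lapply(seq_len(ns), function(si) {
    t(vapply(seq_along(cluster[[si]]$states), function(st)
      single_terms(geoms[[si]][[st]], env, adj, table, params),
      numeric(3)))
  })
  pair <- vector("list", ns)
  for (i in seq_len(ns)) {
    pair[[i]] <- vector("list", ns)
    for (j in seq_len(ns)) {
      if (j <= i) next
      ni <- length(cluster[[i]]$states)
      nj <- length(cluster[[j]]$states)
      arr <- array(0, dim = c(ni, nj, 3))
      for (si in seq_len(ni)) for (sj in seq_len(nj)) {
        arr[si, sj, ] <- pair_terms(geoms[[i]][[si]], geoms[[j]][[sj]],
                                    adj, table, params)
      }
      pair[[i]][[j]] <- arr
    }
  }
  priors <- lapply(cluster, function(s)
    vapply(s$states, function(st) st$prior, numeric(1)))
  list(cluster = cluster, single = single, pair = pair, priors = priors,
       params = params)
}

assignment_counts <- function(tables, assignment) {
  ns <- length(tables$cluster)
  tot <- c(hb = 0, clash = 0, severe = 0)
  prior <- 0
  for (i in seq_len(ns)) {
    tot <- tot + tables$single[[i]][assignment[i], ]
    prior <- prior + tables$priors[[i]][assignment[i]]
    for (j in seq_len(ns)) {
      if (j <= i) next
      tot <- tot + tables$pair[[i]][[j]][assignment[i], assignment[j], ]
    }
  }
  list(counts = tot, prior = prior)
}

#' Score one assignment of states to a cluster
#'
#' @param cluster list of species with states enumerated (or precomputed
#'   tables from the internal path)
#' @param assignment integer state index per species
#' @param model the model
#' @param params a [network_params()]
#' @return `network_solution`: `assignment`, `score`, `n_hbonds`,
#'   `n_clashes`, `n_severe`
#' @export
score_solution <- function(cluster, assignment, model,
                           params = network_params()) {
  if (length(cluster) == 0)
    return(structure(list(assignment = integer(0), score = 0,
                          n_hbonds = 0L, n_clashes = 0L, n_severe = 0L),
                     class = "network_solution"))
  tables <- if (!is.null(attr(cluster, "tables"))) attr(cluster, "tables")
            else cluster_tables(cluster, model, params)
  ac <- assignment_counts(tables, assignment)
  score <- params$w_hb * ac$counts[["hb"]] -
    params$w_clash * ac$counts[["clash"]] -
    params$w_severe * ac$counts[["severe"]] + ac$prior
  structure(list(assignment = assignment, score = score,
                 n_hbonds = as.integer(ac$counts[["hb"]]),
                 n_clashes = as.integer(ac$counts[["clash"]]),
                 n_severe = as.integer(ac$counts[["severe"]])),
            class = "network_solution")
}

score_from_tables <- function(tables, assignment) {
  ac <- assignment_counts(tables, assignment)
  p <- tables$params
  p$w_hb * ac$counts[["hb"]] - p$w_clash * ac$counts[["clash"]] -
    p$w_severe * ac$counts[["severe"]] + ac$prior
}

# best-response sweep to convergence
best_response <- function(tables, assignment) {
  ns <- length(tables$cluster)
  nstates <- vapply(tables$cluster, function(s) length(s$states), integer(1))
  repeat {
    changed <- FALSE
    for (i in seq_len(ns)) {
      scores <- vapply(seq_len(nstates[i]), function(st) {
        assignment[i] <- st
        score_from_tables(tables, assignment)
      }, numeric(1))
      best <- which.max(scores)
      if (best != assignment[i]) { assignment[i] <- best; changed <- TRUE }
    }
    if (!changed) break
  }
  assignment
}

#' Optimize one cluster
#'
#' Clusters whose full state space has at most `params$exhaustive_limit`
#' combinations are solved exactly by enumeration. Larger clusters run
#' `n_starts` random best-response descents, uniform-crossover
#' recombination of the top solutions, and simulated annealing (Metropolis
#' single-species moves, geometric cooling) from the best solution found.
#'
#' @param cluster list of species with states enumerated
#' @param model the model
#' @param seed integer RNG seed (determinism)
#' @param params a [network_params()]
#' @return a `network_solution`
#' @export
optimize_cluster <- function(cluster, model, seed = 1L,
                             params = network_params()) {
  if (!length(cluster))
    return(score_solution(cluster, integer(0), model, params))
  tables <- cluster_tables(cluster, model, params)
  nstates <- vapply(cluster, function(s) length(s$states), integer(1))
  total <- prod(nstates)
  attr(cluster, "tables") <- tables
  if (total <= params$exhaustive_limit && !params$force_stochastic) {
    grid <- as.matrix(expand.grid(lapply(nstates, seq_len)))
    scores <- apply(grid, 1, function(asn) score_from_tables(tables, asn))
    best <- which.max(scores)
    return(score_solution(cluster, as.integer(grid[best, ]), model, params))
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  ns <- length(cluster)
  rand_assign <- function() vapply(nstates, function(k)
    sample.int(k, 1), integer(1))
  starts <- lapply(seq_len(params$n_starts), function(i)
    best_response(tables, rand_assign()))
  scores <- vapply(starts, function(a) score_from_tables(tables, a),
                   numeric(1))
  ord <- order(scores, decreasing = TRUE)
  pool <- starts[ord]
  best_a <- pool[[1]]; best_s <- max(scores)
  # recombination
  if (length(pool) >= 2) {
    for (k in seq_len(params$n_offspring)) {
      pa <- sample(seq_len(min(5, length(pool))), 2)
      mask <- stats::runif(ns) < 0.5
      child <- ifelse(mask, pool[[pa[1]]], pool[[pa[2]]])
      child <- best_response(tables, child)
      s <- score_from_tables(tables, child)
      if (s > best_s) { best_s <- s; best_a <- child }
    }
  }
  # simulated annealing
  steps <- params$sa_steps_per_species * ns
  cool <- (params$t_end / params$t_start)^(1 / max(1, steps - 1))
  temp <- params$t_start
  cur <- best_a; cur_s <- best_s
  for (st in seq_len(steps)) {
    i <- sample.int(ns, 1)
    prop <- cur
    prop[i] <- sample.int(nstates[i], 1)
    s <- score_from_tables(tables, prop)
    if (s >= cur_s || stats::runif(1) < exp((s - cur_s) / temp)) {
      cur <- prop; cur_s <- s
      if (s > best_s) { best_s <- s; best_a <- cur }
    }
    temp <- temp * cool
  }
  best_a <- best_response(tables, best_a)
  score_solution(cluster, best_a, model, params)
}

# ------------------------------------------------------------- applying ---

apply_state <- function(model, species, state) {
  a <- model$atoms
  key <- residue_keys(model)
  res_rows <- which(key == species$res_key)
  xyz <- coords(model)
  for (sw in state$swap) {
    tmp <- xyz[sw[1], ]
    model$atoms[sw[1], c("x", "y", "z")] <- xyz[sw[2], ]
    model$atoms[sw[2], c("x", "y", "z")] <- tmp
  }
  # drop owned H not in this state; set/add the ones that are
  drop_rows <- res_rows[a$name[res_rows] %in% species$owned_h &
                          !(a$name[res_rows] %in% names(state$h))]
  for (hn in names(state$h)) {
    row <- res_rows[a$name[res_rows] == hn]
    p <- state$h[[hn]]
    if (length(row)) {
      model$atoms[row[1], c("x", "y", "z")] <- as.list(p)
    } else {
      tmplrow <- res_rows[1]
      model$atoms <- rbind(model$atoms, within(a[tmplrow, ], {
        name <- hn; element <- "H"; x <- p[1]; y <- p[2]; z <- p[3]
        serial <- nrow(a) + 1L
      }))
    }
  }
  if (length(drop_rows)) {
    mask <- !(seq_len(nrow(model$atoms)) %in% drop_rows)
    model <- subset_model(model, mask)
  }
  model$atoms$is_h <- toupper(model$atoms$element) %in% c("H", "D")
  model
}

#' Optimize the whole hydrogen-bond network of a model
#'
#' Finds variable species, enumerates their states, decomposes the model
#' into clusters, optimizes each independently and applies the winning
#' states (H coordinates set, flip heavy-atom pairs swapped, protonation
#' recorded).
#'
#' @param model all-atom structure_model (graph built)
#' @param seed integer seed (per-cluster seeds are derived from it)
#' @param params a [network_params()]
#' @return list: `model` (optimized, graph rebuilt), `report` (data.frame
#'   per cluster: sizes, scores, hydrogen bonds), `solutions`
#' @export
optimize_network <- function(model, seed = 1L, params = network_params()) {
  attr(model, "hbond_roles") <- hbond_roles(model)
  species <- find_variable_species(model)
  if (!length(species))
    return(list(model = model,
                report = data.frame(cluster = integer(0)),
                solutions = list()))
  species <- lapply(species, enumerate_states, model = model,
                    params = params)
  clusters <- build_clusters(species, model, params$coupling_cutoff)
  solutions <- list()
  rows <- list()
  ord <- order(vapply(clusters, function(cl)
    min(vapply(cl, function(s) s$id, integer(1))), integer(1)))
  clusters <- clusters[ord]
  out <- model
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    sol <- optimize_cluster(cl, model, seed = seed + ci, params = params)
    solutions[[ci]] <- sol
    for (t in seq_along(cl)) {
      out <- apply_state(out, cl[[t]], cl[[t]]$states[[sol$assignment[t]]])
    }
    rows[[ci]] <- data.frame(
      cluster = ci, n_species = length(cl),
      kinds = paste(vapply(cl, function(s) s$kind, character(1)),
                    collapse = "+"),
      states = paste(vapply(seq_along(cl), function(t)
        cl[[t]]$states[[sol$assignment[t]]]$label, character(1)),
        collapse = ","),
      score = sol$score, n_hbonds = sol$n_hbonds,
      n_clashes = sol$n_clashes + sol$n_severe,
      stringsAsFactors = FALSE)
  }
  out <- build_covalent_graph(out)
  list(model = out, report = do.call(rbind, rows), solutions = solutions)
}
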