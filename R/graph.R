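# Covalent-graph construction. Bonds come from per-residue templates for the
# 20 standard amino acids (plus waters), peptide links C(i)-N(i+1),
# disulfides (S-S <= 2.5 A), and a distance fallback for residues without a
# template: d <= 0.6 x (r1 + r2) of the primary van der Waals radii.

.PEPTIDE_MAX <- 2.5   # A, C-N / S-S bonded-distance ceiling
.FALLBACK_FACTOR <- 0.6

altloc_compatible <- function(a1, a2) a1 == "" | a2 == "" | a1 == a2

#' Build the covalent graph of a model
#'
#' Adds template bonds (including hydrogens when present), inter-residue
#' peptide bonds, disulfide bridges and distance-fallback bonds for
#' non-template residues. Alternate-conformer atoms are only bonded when
#' their altloc labels are compatible (equal, or one blank). Also annotates
#' each hydrogen with its polar/aromatic flag (bonded to N/O/S, or to an
#' aromatic ring atom) used by the Richardson radius dialect.
#'
#' @param model a structure_model (altlocs ideally resolved first)
#' @return the model with `bonds` populated
#' @export
build_covalent_graph <- function(model) {
  a <- model$atoms
  n <- nrow(a)
  if (n == 0) return(model)
  key <- residue_keys(model)
  ukeys <- unique(key)
  xyz <- coords(model)
  pairs <- list()
  add_pair <- function(i, j) pairs[[length(pairs) + 1]] <<- c(i, j)

  bond_by_names <- function(idx, nm_pairs) {
    for (r in seq_len(nrow(nm_pairs))) {
      ii <- idx[a$name[idx] == nm_pairs[r, 1]]
      jj <- idx[a$name[idx] == nm_pairs[r, 2]]
      for (i in ii) for (j in jj) {
        if (altloc_compatible(a$altloc[i], a$altloc[j])) add_pair(i, j)
      }
    }
  }

  no_template <- integer(0)
  for (k in ukeys) {
    idx <- which(key == k)
    rn <- toupper(a$resname[idx[1]])
    if (is_standard_aa(rn)) {
      tpl <- residue_bond_names(rn)
      present <- tpl[, 1] %in% a$name[idx] & tpl[, 2] %in% a$name[idx]
      bond_by_names(idx, tpl[present, , drop = FALSE])
      opt <- optional_bond_names(rn)
      present <- opt[, 1] %in% a$name[idx] & opt[, 2] %in% a$name[idx]
      bond_by_names(idx, opt[present, , drop = FALSE])
    } else if (is_water_res(rn)) {
      wt <- rbind(c("O", "H1"), c("O", "H2"), c("O", "H"),
                  c("O", "D1"), c("O", "D2"))
      present <- wt[, 1] %in% a$name[idx] & wt[, 2] %in% a$name[idx]
      bond_by_names(idx, wt[present, , drop = FALSE])
    } else {
      no_template <- c(no_template, idx)
    }
  }

  # peptide bonds between consecutive polymer residues of the same chain
  poly <- polymer_flags(model)
  res_order <- ukeys[vapply(ukeys, function(k) any(poly[key == k]), TRUE)]
  if (length(res_order) > 1) {
    for (t in seq_len(length(res_order) - 1)) {
      i1 <- which(key == res_order[t])
      i2 <- which(key == res_order[t + 1])
      if (a$chain[i1[1]] != a$chain[i2[1]]) next
      ci <- i1[a$name[i1] == "C"]
      nj <- i2[a$name[i2] == "N"]
      for (i in ci) for (j in nj) {
        if (!altloc_compatible(a$altloc[i], a$altloc[j])) next
        if (vec_norm(xyz[i, ] - xyz[j, ]) <= .PEPTIDE_MAX) add_pair(i, j)
      }
    }
  }

  # disulfides
  sg <- which(a$name == "SG" & toupper(a$resname) == "CYS")
  if (length(sg) > 1) {
    for (u in seq_along(sg)) for (v in seq_along(sg)) {
      if (u >= v) next
      if (vec_norm(xyz[sg[u], ] - xyz[sg[v], ]) <= .PEPTIDE_MAX)
        add_pair(sg[u], sg[v])
    }
  }

  # distance fallback for non-template residues: against all atoms nearby
  if (length(no_template)) {
    tbl <- vdw_table("primary")
    rad <- vdw_radius(a$element, tbl)
    for (i in no_template) {
      d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
      cand <- which(d > 1e-6 & d <= .FALLBACK_FACTOR * (rad[i] + rad))
      cand <- cand[altloc_compatible(a$altloc[i], a$altloc[cand])]
      if (a$is_h[i]) {
        cand <- cand[!a$is_h[cand]]
        if (length(cand)) cand <- cand[which.min(d[cand])]
      }
      for (j in cand) if (!(a$is_h[j] && !a$is_h[i])) add_pair(i, j)
    }
  }

  bonds <- if (length(pairs)) do.call(rbind, pairs) else
    matrix(integer(0), ncol = 2)
  model$bonds <- normalize_bonds(bonds)
  model$atoms <- annotate_h_polarity(model)
  model
}

#' Flag H atoms bonded to N/O/S or to an aromatic ring atom
#' @noRd
annotate_h_polarity <- function(model) {
  a <- model$atoms
  a$polar_aromatic_h <- FALSE
  if (!nrow(model$bonds)) return(a)
  adj <- adjacency_list(model)
  hs <- which(a$is_h)
  for (i in hs) {
    nb <- adj[[i]]
    if (!length(nb)) next
    par <- nb[1]
    el <- a$element[par]
    arom <- a$name[par] %in% .AROMATIC_ATOMS[[toupper(a$resname[par])]]
    a$polar_aromatic_h[i] <- el %in% c("N", "O", "S") || isTRUE(arom)
  }
  a
}

#' Adjacency list of the covalent graph
#' @noRd
adjacency_list <- function(model) {
  n <- nrow(model$atoms)
  adj <- vector("list", n)
  b <- model$bonds
  if (nrow(b)) {
    for (r in seq_len(nrow(b))) {
      adj[[b[r, 1]]] <- c(adj[[b[r, 1]]], b[r, 2])
      adj[[b[r, 2]]] <- c(adj[[b[r, 2]]], b[r, 1])
    }
  }
  adj
}

#' Atoms within `depth` bonds of atom i (excluding i itself)
#' @noRd
graph_neighborhood <- function(adj, i, depth = 3) {
  seen <- i
  frontier <- i
  for (d in seq_len(depth)) {
    frontier <- unique(unlist(adj[frontier]))
    frontier <- setdiff(frontier, seen)
    if (!length(frontier)) break
    seen <- c(seen, frontier)
  }
  setdiff(seen, i)
}
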