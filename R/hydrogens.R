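# Riding-hydrogen placement from ideal geometry.
#
# A riding H position is fully determined by the non-H atoms; rotatable
# sites (Ser/Thr hydroxyls, Cys sulfhydryl, Tyr phenolic OH, Lys ammonium,
# waters) have a free torsion and receive a deterministic default here; the
# hydrogen-bond network module owns their final orientation.
#
# X-H bond lengths are nuclear (C-H 1.090, N-H 1.010, O-H 0.960,
# S-H 1.340 A), configurable via `xh_lengths`.

.TETRA <- 109.471

#' Classify hydrogen sites of a model
#'
#' Every hydrogen implied by standard protonation at pH 7 is assigned to
#' exactly one site on its parent heavy atom. Ser/Thr/Tyr hydroxyls, Cys
#' sulfhydryls (when not in a disulfide), Lys ammonium groups and waters are
#' rotatable; everything else rides.
#'
#' @param model a structure_model with covalent graph built
#' @return list of sites: `parent` (atom row), `h_names`, `site_class`
#'   (`"riding"`/`"rotatable"`), `rotatable_kind`
#'   (`hydroxyl|sulfhydryl|phenolic|amine|water|none`), `torsion_axis`
#'   (parent/axis atom rows, rotatable only)
#' @export
classify_hydrogen_sites <- function(model) {
  a <- model$atoms
  adj <- adjacency_list(model)
  key <- residue_keys(model)
  sites <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    rn <- toupper(a$resname[idx[1]])
    if (is_water_res(rn)) {
      o <- idx[a$element[idx] == "O"]
      if (length(o) != 1) next
      sites[[length(sites) + 1]] <- list(
        parent = o, h_names = c("H1", "H2"), site_class = "rotatable",
        rotatable_kind = "water", torsion_axis = NULL)
      next
    }
    if (!is_standard_aa(rn)) next
    tpl <- residue_bond_names(rn)
    hrow <- grepl("^H", tpl[, 2]) | grepl("^H", tpl[, 1])
    tpl <- tpl[hrow, , drop = FALSE]
    parents <- unique(tpl[, 1])
    # N-terminal residues: replace amide H with an ammonium/amine group
    nterm <- {
      ni <- idx[a$name[idx] == "N"]
      length(ni) >= 1 &&
        !any(!a$is_h[adj[[ni[1]]]] & a$name[adj[[ni[1]]]] == "C" &
               key[adj[[ni[1]]]] != k)
    }
    rot <- .ROTATABLE_SITES[[rn]]
    for (p in parents) {
      pi_ <- idx[a$name[idx] == p & a$altloc[idx] == ""]
      if (!length(pi_)) pi_ <- idx[a$name[idx] == p]
      if (!length(pi_)) next
      h_names <- tpl[tpl[, 1] == p, 2]
      cls <- "riding"; kind <- "none"; axis <- NULL
      if (p == "N" && nterm) {
        h_names <- if (rn == "PRO") c("H2", "H3") else c("H1", "H2", "H3")
        cls <- "rotatable"; kind <- "amine"
        ca <- idx[a$name[idx] == "CA"]
        axis <- c(pi_[1], ca[1])
      } else if (!is.null(rot) && p == rot$parent) {
        # a Cys SG in a disulfide has no H site at all
        if (rn == "CYS" &&
            any(a$name[adj[[pi_[1]]]] == "SG" & !a$is_h[adj[[pi_[1]]]]))
          next
        cls <- "rotatable"; kind <- rot$kind
        ax <- idx[a$name[idx] == rot$axis]
        axis <- c(pi_[1], ax[1])
      }
      for (pp in pi_) {
        sites[[length(sites) + 1]] <- list(
          parent = pp, h_names = h_names, site_class = cls,
          rotatable_kind = kind,
          torsion_axis = if (is.null(axis)) NULL else c(pp, axis[2]))
      }
    }
  }
  sites
}

heavy_neighbors <- function(model, adj, i) {
  nb <- adj[[i]]
  sort(nb[!model$atoms$is_h[nb]])
}

#' Construct hydrogen coordinates for one site given current heavy atoms.
#' Returns a named list h_name -> coordinate, or NULL when frame atoms are
#' missing. `torsion` overrides the free torsion of rotatable sites.
#' @noRd
h_site_coords <- function(model, site, xh_lengths = .XH_LENGTHS,
                          torsion = NULL) {
  a <- model$atoms
  adj <- adjacency_list(model)
  xyz <- coords(model)
  p <- site$parent
  el <- a$element[p]
  L <- xh_lengths[[el]]
  if (is.null(L)) return(NULL)
  hv <- heavy_neighbors(model, adj, p)
  nH <- length(site$h_names)
  P <- xyz[p, ]
  rn <- toupper(a$resname[p])
  sp2 <- (a$name[p] %in% .SP2_ATOMS[[rn]]) ||
    (a$name[p] == "N" && length(hv) == 2)
  out <- list()
  if (length(hv) == 0 && nH == 2) {
    # isolated water: canonical deterministic orientation
    ang <- deg2rad(104.5)
    out[[site$h_names[1]]] <- P + L * c(1, 0, 0)
    out[[site$h_names[2]]] <- P + L * c(cos(ang), sin(ang), 0)
    return(out)
  }
  if (length(hv) == 0) return(NULL)
  u <- lapply(hv, function(j) vec_unit(xyz[j, ] - P))
  if (length(hv) >= 3 && nH == 1) {
    d <- -(u[[1]] + u[[2]] + u[[3]])
    out[[site$h_names[1]]] <- P + L * vec_unit(d)
    return(out)
  }
  if (length(hv) == 2 && nH == 1) {
    # in-plane bisector (amide H, aromatic CH) or tetrahedral CH on a
    # 2-neighbour sp3 carbon with one H (none standard) -- same construction
    d <- -(u[[1]] + u[[2]])
    out[[site$h_names[1]]] <- P + L * vec_unit(d)
    return(out)
  }
  if (length(hv) == 2 && nH == 2) {
    b <- vec_unit(-(u[[1]] + u[[2]]))
    pp <- vec_unit(vec_cross(u[[1]], u[[2]]))
    alpha <- deg2rad(.TETRA / 2)
    out[[site$h_names[1]]] <- P + L * (cos(alpha) * b + sin(alpha) * pp)
    out[[site$h_names[2]]] <- P + L * (cos(alpha) * b - sin(alpha) * pp)
    return(out)
  }
  # single heavy neighbour: torsion-defined placement
  q <- hv[1]
  ref <- setdiff(heavy_neighbors(model, adj, q), p)
  if (!length(ref)) {
    nb2 <- setdiff(sort(adj[[q]]), p)
    if (!length(nb2)) return(NULL)
    ref <- nb2
  }
  A <- xyz[ref[1], ]; B <- xyz[q, ]
  theta <- if (sp2) 120 else if (el == "S") 96 else .TETRA
  base <- if (is.null(torsion)) 180 else torsion
  chis <- if (nH == 3) base + c(0, 120, 240) else
    if (nH == 2) base + c(0, 180) else base
  if (sp2 && nH == 2) chis <- c(0, 180)  # planar amide NH2
  for (t in seq_len(nH)) {
    out[[site$h_names[t]]] <- nerf_place(A, B, P, L, theta, chis[t])
  }
  out
}

#' Place riding hydrogens at ideal geometry
#'
#' Adds missing riding H atoms; deposited H atoms are kept unless
#' `rebuild = TRUE`. Heavy-atom coordinates are never modified. With
#' `include_rotatable = TRUE` rotatable sites also receive a deterministic
#' default orientation (anti torsion) so that a complete all-atom model is
#' produced; the network optimizer may replace those positions later.
#'
#' @param model structure_model with covalent graph built
#' @param rebuild drop and re-place existing H atoms
#' @param include_rotatable also place rotatable-site hydrogens at defaults
#' @param xh_lengths named X-H bond lengths in Å
#' @return structure_model with hydrogens added and graph rebuilt
#' @export
place_riding_hydrogens <- function(model, rebuild = FALSE,
                                   include_rotatable = FALSE,
                                   xh_lengths = .XH_LENGTHS) {
  if (rebuild && any(model$atoms$is_h)) {
    model <- subset_model(model, !model$atoms$is_h)
    model <- build_covalent_graph(model)
  }
  sites <- classify_hydrogen_sites(model)
  a <- model$atoms
  key <- residue_keys(model)
  new_rows <- list()
  for (site in sites) {
    if (site$site_class == "rotatable" && !include_rotatable) next
    p <- site$parent
    have <- a$name[key == key[p] & a$altloc %in% c("", a$altloc[p])]
    missing_h <- setdiff(site$h_names, have)
    if (!length(missing_h)) next
    hc <- tryCatch(h_site_coords(model, site, xh_lengths),
                   error = function(e) NULL)
    if (is.null(hc)) {
      warning("cannot place H on ", a$resname[p], " ", a$resseq[p], " ",
              a$name[p], ": incomplete frame")
      next
    }
    for (nm in missing_h) {
      if (is.null(hc[[nm]])) next
      new_rows[[length(new_rows) + 1]] <- data.frame(
        serial = 0L, name = nm, altloc = a$altloc[p],
        resname = a$resname[p], chain = a$chain[p], resseq = a$resseq[p],
        icode = a$icode[p], x = hc[[nm]][1], y = hc[[nm]][2],
        z = hc[[nm]][3], occ = a$occ[p], b = a$b[p], element = "H",
        het = a$het[p], stringsAsFactors = FALSE)
    }
  }
  if (!length(new_rows)) return(model)
  add <- do.call(rbind, new_rows)
  # insert H atoms after their residues to keep residue blocks contiguous
  a$is_h <- NULL
  if ("polar_aromatic_h" %in% names(a)) a$polar_aromatic_h <- NULL
  merged <- rbind(a, add)
  res_order <- match(paste(merged$chain, merged$resseq, merged$icode),
                     unique(paste(a$chain, a$resseq, a$icode)))
  merged <- merged[order(res_order), , drop = FALSE]
  merged$serial <- seq_len(nrow(merged))
  out <- structure_model(merged, NULL, model$resolution,
                         model$source_format)
  build_covalent_graph(out)
}

#' Add all hydrogens (riding + rotatable defaults)
#'
#' Convenience wrapper producing a complete all-atom model: riding H at
#' ideal geometry, rotatable sites at deterministic default torsions.
#' @inheritParams place_riding_hydrogens
#' @export
add_hydrogens <- function(model, rebuild = FALSE,
                          xh_lengths = .XH_LENGTHS) {
  place_riding_hydrogens(model, rebuild = rebuild,
                         include_rotatable = TRUE,
                         xh_lengths = xh_lengths)
}
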