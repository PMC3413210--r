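# Summary molecular-geometry statistics: bond-length and bond-angle r.m.s.d.
# and r.m.s. Z scores against the reference restraint targets, least-squares
# side-chain planarity r.m.s.d., and the omega peptide-torsion deviation.
# Hydrogens never enter these statistics.

#' Bond and angle deviations against the reference targets
#'
#' Enumerates every covalent heavy-atom bond and every angle with a target
#' entry in polymer residues (including the peptide-link bond and angles),
#' and returns observed/ideal/sigma triples. Residues without a template are
#' skipped and tallied.
#'
#' @param model structure_model with graph built
#' @param targets a [geometry_targets()]
#' @return list with data.frames `bonds` and `angles` (columns `observed`,
#'   `ideal`, `sigma`, `resname`, `label`) and `skipped_residues`
#' @export
bond_angle_deviations <- function(model, targets = geometry_targets()) {
  a <- model$atoms
  xyz <- coords(model)
  key <- residue_keys(model)
  poly <- polymer_flags(model)
  adj <- adjacency_list(model)
  bonds_out <- list(); angles_out <- list(); skipped <- character(0)

  ukeys <- unique(key[poly])
  find_atom <- function(idx, nm) {
    hit <- idx[a$name[idx] == nm & !a$is_h[idx]]
    if (length(hit)) hit[1] else NA_integer_
  }
  res_idx <- lapply(ukeys, function(k) which(key == k))
  names(res_idx) <- ukeys
  rn_of <- vapply(res_idx, function(idx) toupper(a$resname[idx[1]]),
                  character(1))

  for (t in seq_along(ukeys)) {
    idx <- res_idx[[t]]
    rn <- rn_of[t]
    if (!is_standard_aa(rn)) { skipped <- c(skipped, ukeys[t]); next }
    tg_b <- targets$bonds
    rows <- which((tg_b$resname == rn | tg_b$resname == "*") & tg_b$link == 0)
    seen <- character(0)
    for (r in rows) {
      pk <- paste(pmin(tg_b$atom1[r], tg_b$atom2[r]),
                  pmax(tg_b$atom1[r], tg_b$atom2[r]))
      if (pk %in% seen) next
      # residue-specific rows shadow "*" rows (file lists them later; the
      # bond_target() lookup gives precedence properly)
      tgt <- bond_target(targets, rn, tg_b$atom1[r], tg_b$atom2[r])
      i <- find_atom(idx, tg_b$atom1[r]); j <- find_atom(idx, tg_b$atom2[r])
      if (is.na(i) || is.na(j)) next
      if (!any((model$bonds[, 1] == min(i, j)) &
                 (model$bonds[, 2] == max(i, j)))) next
      seen <- c(seen, pk)
      bonds_out[[length(bonds_out) + 1]] <- data.frame(
        observed = vec_norm(xyz[i, ] - xyz[j, ]), ideal = tgt$ideal,
        sigma = tgt$sigma, resname = rn,
        label = paste0(ukeys[t], ":", tg_b$atom1[r], "-", tg_b$atom2[r]),
        stringsAsFactors = FALSE)
    }
    tg_a <- targets$angles
    rows <- which((tg_a$resname == rn | tg_a$resname == "*") & tg_a$link == 0)
    seen <- character(0)
    for (r in rows) {
      ak <- paste(tg_a$atom1[r], tg_a$atom2[r], tg_a$atom3[r])
      if (ak %in% seen) next
      tgt <- angle_target(targets, rn, tg_a$atom1[r], tg_a$atom2[r],
                          tg_a$atom3[r])
      i <- find_atom(idx, tg_a$atom1[r])
      j <- find_atom(idx, tg_a$atom2[r])
      l <- find_atom(idx, tg_a$atom3[r])
      if (is.na(i) || is.na(j) || is.na(l)) next
      seen <- c(seen, ak)
      angles_out[[length(angles_out) + 1]] <- data.frame(
        observed = bond_angle(xyz[i, ], xyz[j, ], xyz[l, ]),
        ideal = tgt$ideal, sigma = tgt$sigma, resname = rn,
        label = paste0(ukeys[t], ":", ak), stringsAsFactors = FALSE)
    }
  }

  # peptide links: C(i)-N(i+1) bond plus CA-C-N, O-C-N, C-N-CA(+ C-N-CD)
  for (t in seq_len(length(ukeys) - 1)) {
    if (!length(ukeys)) break
    i1 <- res_idx[[t]]; i2 <- res_idx[[t + 1]]
    if (!is_standard_aa(rn_of[t]) || !is_standard_aa(rn_of[t + 1])) next
    if (a$chain[i1[1]] != a$chain[i2[1]]) next
    ci <- find_atom(i1, "C"); nj <- find_atom(i2, "N")
    if (is.na(ci) || is.na(nj)) next
    if (!any((model$bonds[, 1] == min(ci, nj)) &
               (model$bonds[, 2] == max(ci, nj)))) next
    tgt <- bond_target(targets, rn_of[t], "C", "N")
    bonds_out[[length(bonds_out) + 1]] <- data.frame(
      observed = vec_norm(xyz[ci, ] - xyz[nj, ]), ideal = tgt$ideal,
      sigma = tgt$sigma, resname = rn_of[t],
      label = paste0(ukeys[t], ":C-N+"), stringsAsFactors = FALSE)
    link_angle <- function(p, q, s, rn, lab) {
      tgt <- angle_target(targets, rn, lab[1], lab[2], lab[3])
      if (is.null(tgt) || any(is.na(c(p, q, s)))) return()
      angles_out[[length(angles_out) + 1]] <<- data.frame(
        observed = bond_angle(xyz[p, ], xyz[q, ], xyz[s, ]),
        ideal = tgt$ideal, sigma = tgt$sigma, resname = rn,
        label = paste0(lab, collapse = "-"), stringsAsFactors = FALSE)
    }
    cai <- find_atom(i1, "CA"); oi <- find_atom(i1, "O")
    caj <- find_atom(i2, "CA")
    link_angle(cai, ci, nj, rn_of[t], c("CA", "C", "N"))
    link_angle(oi, ci, nj, rn_of[t], c("O", "C", "N"))
    link_angle(ci, nj, caj, rn_of[t + 1], c("C", "N", "CA"))
    if (rn_of[t + 1] == "PRO") {
      cdj <- find_atom(i2, "CD")
      link_angle(ci, nj, cdj, "PRO", c("C", "N", "CD"))
    }
  }

  empty <- data.frame(observed = numeric(0), ideal = numeric(0),
                      sigma = numeric(0), resname = character(0),
                      label = character(0), stringsAsFactors = FALSE)
  list(bonds = if (length(bonds_out)) do.call(rbind, bonds_out) else empty,
       angles = if (length(angles_out)) do.call(rbind, angles_out) else empty,
       skipped_residues = skipped)
}

#' Root-mean-square deviation of observed values from ideals
#' @param deviations data.frame with `observed` and `ideal` (or a numeric
#'   vector of differences)
#' @return RMSD, or NA for empty input
#' @export
rmsd <- function(deviations) {
  d <- if (is.data.frame(deviations)) deviations$observed - deviations$ideal
       else deviations
  if (!length(d)) return(NA_real_)
  sqrt(mean(d^2))
}

#' RMS Z score: deviations in units of the reference sigma
#' @param deviations data.frame with `observed`, `ideal`, `sigma` (or a
#'   numeric vector of already-normalised Z values)
#' @return RMS Z, or NA for empty input
#' @export
rms_z <- function(deviations) {
  z <- if (is.data.frame(deviations))
    (deviations$observed - deviations$ideal) / deviations$sigma
  else deviations
  if (!length(z)) return(NA_real_)
  sqrt(mean(z^2))
}

#' Side-chain planarity r.m.s.d.
#'
#' For each planar group (Arg guanidinium, Asn/Gln amides, Asp/Glu
#' carboxylates, His/Phe/Tyr/Trp rings with first substituents) with at
#' least 4 member atoms present, fits the least-squares plane and takes the
#' RMSD of members from it; the summary is the mean over groups.
#'
#' @param model structure_model
#' @return list: `planarity_rmsd` (mean), `groups` data.frame
#' @export
sidechain_planarity <- function(model) {
  a <- model$atoms
  xyz <- coords(model)
  key <- residue_keys(model)
  out <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    rn <- toupper(a$resname[idx[1]])
    groups <- .PLANAR_GROUPS[[rn]]
    if (is.null(groups)) next
    for (g in groups) {
      rows <- idx[match(g, a$name[idx])]
      rows <- rows[!is.na(rows)]
      if (length(rows) < 4) next
      fit <- fit_plane(xyz[rows, , drop = FALSE])
      out[[length(out) + 1]] <- data.frame(
        residue = k, resname = rn, n_atoms = length(rows),
        rmsd = fit$rmsd, stringsAsFactors = FALSE)
    }
  }
  groups_df <- if (length(out)) do.call(rbind, out) else
    data.frame(residue = character(0), resname = character(0),
               n_atoms = integer(0), rmsd = numeric(0))
  list(planarity_rmsd = if (nrow(groups_df)) mean(groups_df$rmsd) else
         NA_real_,
       groups = groups_df)
}

#' Omega peptide-torsion statistics
#'
#' omega = CA(i)-C(i)-N(i+1)-CA(i+1) over consecutive bonded residues
#' (C-N distance <= 2.5 Å). Each peptide is assigned trans (ideal 180) or
#' cis (ideal 0) by proximity; the reported value is the RMS circular
#' deviation from the assigned ideal. `about = "mean"` instead measures
#' about the circular mean of the trans (and cis) populations.
#'
#' @param model structure_model
#' @param about `"ideal"` (default) or `"mean"`
#' @return list: `omega_sd` (deg), `n_omega`, `cis_fraction`, `omegas`
#' @export
omega_stats <- function(model, about = c("ideal", "mean")) {
  about <- match.arg(about)
  a <- model$atoms
  xyz <- coords(model)
  key <- residue_keys(model)
  poly <- polymer_flags(model)
  ukeys <- unique(key[poly])
  omegas <- numeric(0)
  for (t in seq_len(max(0, length(ukeys) - 1))) {
    i1 <- which(key == ukeys[t]); i2 <- which(key == ukeys[t + 1])
    if (a$chain[i1[1]] != a$chain[i2[1]]) next
    g <- function(idx, nm) {
      h <- idx[a$name[idx] == nm & !a$is_h[idx]]
      if (length(h)) h[1] else NA_integer_
    }
    ca1 <- g(i1, "CA"); c1 <- g(i1, "C"); n2 <- g(i2, "N"); ca2 <- g(i2, "CA")
    if (any(is.na(c(ca1, c1, n2, ca2)))) next
    if (vec_norm(xyz[c1, ] - xyz[n2, ]) > 2.5) next  # chain break
    omegas <- c(omegas, torsion_angle(xyz[ca1, ], xyz[c1, ], xyz[n2, ],
                                      xyz[ca2, ]))
  }
  if (!length(omegas))
    return(list(omega_sd = NA_real_, n_omega = 0L, cis_fraction = NA_real_,
                omegas = omegas))
  is_cis <- abs(wrap180(omegas)) < 90
  ideal <- ifelse(is_cis, 0, 180)
  if (about == "mean") {
    for (grp in unique(is_cis)) {
      sel <- is_cis == grp
      m <- rad2deg(atan2(mean(sin(deg2rad(omegas[sel]))),
                         mean(cos(deg2rad(omegas[sel])))))
      ideal[sel] <- m
    }
  }
  dev <- wrap180(omegas - ideal)
  list(omega_sd = sqrt(mean(dev^2)), n_omega = length(omegas),
       cis_fraction = mean(is_cis), omegas = omegas)
}

#' Full geometry summary of a model
#'
#' @param model structure_model with graph built
#' @param targets a [geometry_targets()]
#' @return object of class `geometry_summary`: bond/angle RMSD and RMS Z,
#'   planarity RMSD, omega SD plus the underlying counts
#' @export
geometry_summary <- function(model, targets = geometry_targets()) {
  dev <- bond_angle_deviations(model, targets)
  pl <- sidechain_planarity(model)
  om <- omega_stats(model)
  structure(list(
    bond_rmsd = rmsd(dev$bonds), angle_rmsd = rmsd(dev$angles),
    bond_rmsz = rms_z(dev$bonds), angle_rmsz = rms_z(dev$angles),
    planarity_rmsd = pl$planarity_rmsd, omega_sd = om$omega_sd,
    n_bonds = nrow(dev$bonds), n_angles = nrow(dev$angles),
    n_planar_groups = nrow(pl$groups), n_omega = om$n_omega,
    cis_fraction = om$cis_fraction,
    skipped_residues = dev$skipped_residues
  ), class = "geometry_summary")
}

#' @export
print.geometry_summary <- function(x, ...) {
  cat("<geometry_summary>\n")
  cat(sprintf("  bond rmsd  %.4f A (rms Z %.2f, n=%d)\n",
              x$bond_rmsd, x$bond_rmsz, x$n_bonds))
  cat(sprintf("  angle rmsd %.2f deg (rms Z %.2f, n=%d)\n",
              x$angle_rmsd, x$angle_rmsz, x$n_angles))
  cat(sprintf("  planarity rmsd %.4f A (n=%d groups)\n",
              x$planarity_rmsd, x$n_planar_groups))
  cat(sprintf("  omega sd %.1f deg (n=%d, cis %.1f%%)\n",
              x$omega_sd, x$n_omega, 100 * x$cis_fraction))
  invisible(x)
}
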