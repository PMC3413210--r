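# Nonbonded close-contact detection and classification.
#
# Primary mode: clash when d <= 0.8 x (r_a + r_b), severe when
# d <= 0.7 x (boundaries inclusive, severe takes precedence).
# Richardson comparison mode: clash when the van der Waals overlap
# (r_a + r_b) - d >= 0.4 A, with polarity-split H radii.
#
# Exclusions, applied in order and tallied: (a) pairs within 3 covalent
# bonds; (b) heavy donor / heavy acceptor pairs -- any pair that could
# potentially hydrogen bond is removed even without an H between them;
# (c) donor-attached H against an acceptor; (d) pairs inside one residue's
# flip-ambiguous group. Contacts involving waters are reported separately
# from the headline protein-protein counts.

.CLASH_RATIO <- 0.8
.SEVERE_RATIO <- 0.7
.RICHARDSON_OVERLAP <- 0.4

#' All atom pairs within a distance cutoff (cell-list search)
#'
#' Spatial-partition neighbour search: atoms are binned into cubic cells of
#' edge `cutoff` and only the 27-cell neighbourhoods are scanned. Each
#' unordered pair is returned once.
#'
#' @param model structure_model
#' @param cutoff distance cutoff in Å
#' @return two-column integer matrix of atom row indices (i < j) plus a
#'   `dist` attribute with the distances
#' @export
find_contacts <- function(model, cutoff) {
  xyz <- coords(model)
  n <- nrow(xyz)
  if (n < 2) {
    out <- matrix(integer(0), ncol = 2)
    attr(out, "dist") <- numeric(0)
    return(out)
  }
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cutoff)
  nx <- max(cell[, 1]) + 1; ny <- max(cell[, 2]) + 1
  cid <- cell[, 1] + nx * (cell[, 2] + ny * cell[, 3])
  by_cell <- split(seq_len(n), cid)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  pairs_i <- integer(0); pairs_j <- integer(0)
  for (key in names(by_cell)) {
    idx <- by_cell[[key]]
    base <- as.numeric(key)
    cz <- base %/% (nx * ny); rem <- base %% (nx * ny)
    cy <- rem %/% nx; cx <- rem %% nx
    neigh_ids <- (cx + offsets[, 1]) +
      nx * ((cy + offsets[, 2]) + ny * (cz + offsets[, 3]))
    valid <- (cx + offsets[, 1]) >= 0 & (cy + offsets[, 2]) >= 0 &
      (cz + offsets[, 3]) >= 0
    cand <- unlist(by_cell[as.character(neigh_ids[valid])], use.names = FALSE)
    cand <- cand[!is.na(cand)]
    for (i in idx) {
      js <- cand[cand > i]
      if (!length(js)) next
      d2 <- (xyz[js, 1] - xyz[i, 1])^2 + (xyz[js, 2] - xyz[i, 2])^2 +
        (xyz[js, 3] - xyz[i, 3])^2
      hit <- js[d2 <= cutoff^2]
      pairs_i <- c(pairs_i, rep(i, length(hit)))
      pairs_j <- c(pairs_j, hit)
    }
  }
  out <- cbind(pairs_i, pairs_j)
  colnames(out) <- NULL
  d <- sqrt(rowSums((xyz[out[, 1], , drop = FALSE] -
                       xyz[out[, 2], , drop = FALSE])^2))
  ord <- order(out[, 1], out[, 2])
  out <- out[ord, , drop = FALSE]
  attr(out, "dist") <- d[ord]
  out
}

#' Classify one atom pair
#'
#' @param distance center-to-center distance in Å (or atom rows via
#'   `model`); vectors allowed
#' @param r_a,r_b van der Waals radii of the two atoms
#' @param mode `"primary"` or `"richardson"`
#' @return data.frame with `distance`, `sum_radii`, `ratio` (primary),
#'   `overlap` (richardson) and `clash_class`
#'   (`"severe"`/`"clash"`/`"none"`)
#' @export
classify_contact <- function(distance, r_a, r_b,
                             mode = c("primary", "richardson")) {
  mode <- match.arg(mode)
  s <- r_a + r_b
  eps <- 1e-9  # boundaries are inclusive; guard against FP rounding
  if (mode == "primary") {
    ratio <- distance / s
    cls <- ifelse(ratio <= .SEVERE_RATIO + eps, "severe",
                  ifelse(ratio <= .CLASH_RATIO + eps, "clash", "none"))
    data.frame(distance = distance, sum_radii = s, ratio = ratio,
               overlap = s - distance, clash_class = cls,
               stringsAsFactors = FALSE)
  } else {
    ov <- s - distance
    cls <- ifelse(ov >= .RICHARDSON_OVERLAP - eps, "clash", "none")
    data.frame(distance = distance, sum_radii = s, ratio = distance / s,
               overlap = ov, clash_class = cls, stringsAsFactors = FALSE)
  }
}

#' Hydrogen-bond donor / acceptor role assignment
#'
#' Donors are N/O/S atoms carrying at least one bonded H, or atoms whose
#' names are canonical donors (so united-atom models are treated
#' conservatively). Acceptors: carbonyl/carboxylate/amide O, hydroxyl O,
#' water O, His ring N without H, Met SD, Cys SG.
#'
#' @param model structure_model with graph built
#' @return list with logical vectors `donor`, `acceptor` and integer vector
#'   `donor_h` (rows of H atoms attached to a donor)
#' @export
hbond_roles <- function(model) {
  a <- model$atoms
  adj <- adjacency_list(model)
  n <- nrow(a)
  has_h <- vapply(seq_len(n), function(i)
    any(a$is_h[adj[[i]]]), logical(1))
  donor <- acceptor <- logical(n)
  for (i in seq_len(n)) {
    if (a$is_h[i]) next
    el <- a$element[i]
    rn <- toupper(a$resname[i])
    nm <- a$name[i]
    if (is_water_res(rn) && el == "O") {
      donor[i] <- TRUE; acceptor[i] <- TRUE; next
    }
    if (el %in% c("N", "O", "S")) {
      named_donor <- nm %in% role_names(.DONOR_NAMES, rn)
      if (rn == "PRO" && nm == "N") named_donor <- FALSE
      donor[i] <- has_h[i] || named_donor
      if (nm %in% role_names(.ACCEPTOR_NAMES, rn)) {
        acceptor[i] <- TRUE
        # a protonated His ring N is a donor, not an acceptor
        if (rn == "HIS" && nm %in% c("ND1", "NE2") && has_h[i])
          acceptor[i] <- FALSE
      }
    }
  }
  donor_h <- which(a$is_h & vapply(seq_len(n), function(i) {
    nb <- adj[[i]]
    length(nb) > 0 && any(donor[nb])
  }, logical(1)))
  list(donor = donor, acceptor = acceptor, donor_h = donor_h)
}

#' Apply the hydrogen-bond and bonded-path exclusion rules
#'
#' @param pairs pair matrix from [find_contacts()]
#' @param model structure_model with graph built
#' @param roles output of [hbond_roles()] (computed if NULL)
#' @param bond_depth pairs separated by <= this many covalent bonds are
#'   excluded (default 3: 1-2, 1-3 and 1-4 pairs)
#' @return list: `pairs` (retained), `dist`, `tally` (named exclusion
#'   counts), `excluded` (data.frame pair/reason)
#' @export
apply_exclusions <- function(pairs, model, roles = NULL, bond_depth = 3) {
  if (is.null(roles)) roles <- hbond_roles(model)
  a <- model$atoms
  adj <- adjacency_list(model)
  d <- attr(pairs, "dist")
  n <- nrow(pairs)
  reason <- character(n)
  key <- residue_keys(model)
  flip_atoms <- function(i) {
    fg <- .FLIP_GROUPS[[toupper(a$resname[i])]]
    !is.null(fg) && a$name[i] %in% fg$atoms
  }
  donor_h <- logical(nrow(a)); donor_h[roles$donor_h] <- TRUE
  for (r in seq_len(n)) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (j %in% graph_neighborhood(adj, i, bond_depth)) {
      reason[r] <- "bonded_path"
    } else if ((roles$donor[i] && roles$acceptor[j]) ||
               (roles$donor[j] && roles$acceptor[i])) {
      reason[r] <- "donor_acceptor"
    } else if ((donor_h[i] && roles$acceptor[j]) ||
               (donor_h[j] && roles$acceptor[i])) {
      reason[r] <- "donor_h_acceptor"
    } else if (key[i] == key[j] && flip_atoms(i) && flip_atoms(j)) {
      reason[r] <- "flip_group"
    }
  }
  keep <- reason == ""
  kept <- pairs[keep, , drop = FALSE]
  attr(kept, "dist") <- d[keep]
  tally <- table(factor(reason[!keep],
                        levels = c("bonded_path", "donor_acceptor",
                                   "donor_h_acceptor", "flip_group")))
  list(pairs = kept, dist = d[keep],
       tally = stats::setNames(as.integer(tally), names(tally)),
       excluded = data.frame(atom_a = pairs[!keep, 1],
                             atom_b = pairs[!keep, 2],
                             reason = reason[!keep],
                             stringsAsFactors = FALSE))
}

#' Detect and classify nonbonded clashes
#'
#' Full audit pipeline: candidate contacts by cell-list search, exclusion
#' rules, classification against the radius table. Contacts involving water
#' are tallied separately and do not enter the headline counts; symmetry
#' mates are never generated (deposited coordinates only).
#'
#' @param model all-atom structure_model, altlocs resolved, graph built
#' @param mode `"primary"` or `"richardson"`
#' @param table radius table (defaults to the mode's standard table)
#' @param bond_depth see [apply_exclusions()]
#' @return object of class `clash_report`: `findings` data.frame (atom
#'   indices, names, distance, sum_radii, ratio, overlap, class),
#'   `n_clashes`, `n_severe`, `residue_count`, `clashes_per_100`,
#'   `severe_per_100`, `excluded_tally`, `water` (separate water-involving
#'   findings), `mode`
#' @export
detect_clashes <- function(model, mode = c("primary", "richardson"),
                           table = NULL, bond_depth = 3) {
  mode <- match.arg(mode)
  if (is.null(table)) table <- vdw_table(mode)
  stopifnot(table$mode == mode)
  a <- model$atoms
  if (is.null(a$polar_aromatic_h)) {
    model$atoms <- annotate_h_polarity(model)
    a <- model$atoms
  }
  rad <- vdw_radius(a$element, table, a$polar_aromatic_h)
  cutoff <- max(.CLASH_RATIO * 2 * max(rad),
                if (mode == "richardson") 2 * max(rad) else 0)
  pairs <- find_contacts(model, cutoff)
  ex <- apply_exclusions(pairs, model, bond_depth = bond_depth)
  p <- ex$pairs
  cls <- classify_contact(ex$dist, rad[p[, 1]], rad[p[, 2]], mode)
  keep <- cls$clash_class != "none"
  f <- cbind(data.frame(atom_a = p[keep, 1], atom_b = p[keep, 2]),
             cls[keep, , drop = FALSE])
  lab <- function(i) {
    if (!length(i)) return(character(0))
    paste0(a$chain[i], a$resseq[i], a$resname[i], "/", a$name[i])
  }
  f$label_a <- lab(f$atom_a); f$label_b <- lab(f$atom_b)
  rownames(f) <- NULL
  wat <- is_water_res(a$resname)
  water_involved <- wat[f$atom_a] | wat[f$atom_b]
  water_f <- f[water_involved, , drop = FALSE]
  f <- f[!water_involved, , drop = FALSE]
  nres <- residue_count(model)
  n_clash <- sum(f$clash_class == "clash")
  n_severe <- sum(f$clash_class == "severe")
  if (mode == "richardson") {
    n_clash <- sum(f$clash_class == "clash")
    n_severe <- 0L
  }
  structure(list(
    findings = f, water = water_f,
    n_clashes = n_clash, n_severe = n_severe,
    residue_count = nres,
    clashes_per_100 = if (nres > 0) per_100(n_clash, nres) else NA_real_,
    severe_per_100 = if (nres > 0) per_100(n_severe, nres) else NA_real_,
    excluded_tally = ex$tally, mode = mode
  ), class = "clash_report")
}

#' Frequency per 100 residues
#'
#' The cohort convention is sum/sum pooling: totals over all structures
#' divided by total residues (so 52 clashes over 3543 residues prints 1.5).
#'
#' @param count number of findings
#' @param residue_count number of polymer residues (> 0)
#' @param digits decimals for reporting (default 1, as printed)
#' @export
per_100 <- function(count, residue_count, digits = 1) {
  if (residue_count <= 0) stop("residue_count must be positive")
  round(100 * count / residue_count, digits)
}

#' @export
print.clash_report <- function(x, ...) {
  cat(sprintf("<clash_report> mode=%s: %d clashes, %d severe over %d residues\n",
              x$mode, x$n_clashes, x$n_severe, x$residue_count))
  if (!is.na(x$clashes_per_100))
    cat(sprintf("  per 100 residues: %.1f clashes, %.1f severe\n",
                x$clashes_per_100, x$severe_per_100))
  cat("  excluded:", paste(names(x$excluded_tally), x$excluded_tally,
                           collapse = ", "), "\n")
  if (nrow(x$findings)) {
    cat(sprintf("  %-22s %-22s %6s %6s %6s %s\n", "atom_a", "atom_b",
                "dist", "ratio", "ovl", "class"))
    for (r in seq_len(min(nrow(x$findings), 20))) {
      f <- x$findings[r, ]
      cat(sprintf("  %-22s %-22s %6.2f %6.3f %6.2f %s\n", f$label_a,
                  f$label_b, f$distance, f$ratio, f$overlap, f$clash_class))
    }
  }
  invisible(x)
}

#' Export clash findings as TSV
#' @param report a clash_report
#' @param path output file
#' @export
write_clash_tsv <- function(report, path) {
  f <- report$findings
  cols <- c("label_a", "label_b", "distance", "sum_radii", "ratio",
            "overlap", "clash_class")
  utils::write.table(f[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
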