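# StructureModel: a flat atom table plus a covalent-bond index matrix.
# This mirrors the atom-record layout of the PDB coordinate section; all
# higher modules address atoms by row index into `atoms`.

#' Construct a structure model
#'
#' @param atoms data.frame with columns `serial`, `name`, `altloc`,
#'   `resname`, `chain`, `resseq`, `icode`, `x`, `y`, `z`, `occ`, `b`,
#'   `element`, `het`.
#' @param bonds two-column integer matrix of row indices into `atoms`
#'   (unordered pairs, stored with first index < second).
#' @param resolution resolution in Å, or `NA`.
#' @param source_format `"pdb"`, `"mmcif"` or `"built"`.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, bonds = NULL, resolution = NA_real_,
                            source_format = "built") {
  req <- c("serial", "name", "altloc", "resname", "chain", "resseq",
           "icode", "x", "y", "z", "occ", "b", "element", "het")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) && !all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  if (nrow(atoms) && any(atoms$element == ""))
    stop("empty element symbols")
  if (nrow(atoms) &&
      any(atoms$occ < 0 | atoms$occ > 1, na.rm = TRUE))
    stop("occupancies must lie in [0, 1]")
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  bonds <- normalize_bonds(bonds)
  if (nrow(bonds) && max(bonds) > nrow(atoms))
    stop("bond references an atom not present in the model")
  rownames(atoms) <- NULL
  atoms$is_h <- toupper(atoms$element) %in% c("H", "D")
  structure(list(atoms = atoms, bonds = bonds,
                 resolution = resolution, source_format = source_format),
            class = "structure_model")
}

normalize_bonds <- function(bonds) {
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds)) {
    bonds <- t(apply(bonds, 1, sort))
    bonds <- unique(bonds)
  }
  bonds
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<structure_model> %d atoms (%d H), %d residues, %d bonds\n",
              nrow(a), sum(a$is_h), length(unique(residue_keys(x))),
              nrow(x$bonds)))
  if (!is.na(x$resolution))
    cat(sprintf("  resolution: %.2f A\n", x$resolution))
  invisible(x)
}

#' Per-atom residue keys (chain / seq number / insertion code)
#' @param model a structure_model
#' @return character vector, one entry per atom
#' @export
residue_keys <- function(model) {
  a <- model$atoms
  paste(a$chain, a$resseq, a$icode, sep = "|")
}

#' Coordinate matrix (n x 3)
#' @param model a structure_model
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' Is each atom part of a polymer amino-acid residue?
#'
#' A residue is polymer if it is a standard amino acid, or a non-water
#' residue that carries the backbone atoms N, CA and C (modified residues).
#' @noRd
polymer_flags <- function(model) {
  a <- model$atoms
  key <- residue_keys(model)
  std <- is_standard_aa(a$resname)
  wat <- is_water_res(a$resname)
  res_poly <- tapply(seq_len(nrow(a)), key, function(idx) {
    if (any(std[idx])) return(TRUE)
    if (any(wat[idx])) return(FALSE)
    all(c("N", "CA", "C") %in% a$name[idx])
  })
  as.logical(res_poly[key])
}

#' Count polymer amino-acid residues
#'
#' Waters and non-polymer heteroatoms are excluded; modified amino acids
#' carrying an N/CA/C backbone count as polymer.
#' @param model a structure_model
#' @return integer count
#' @export
residue_count <- function(model) {
  if (nrow(model$atoms) == 0L) return(0L)
  key <- residue_keys(model)
  length(unique(key[polymer_flags(model)]))
}

#' Keep only the highest-occupancy alternate conformer
#'
#' For each residue with alternate-conformer labels, the label with the
#' highest summed occupancy is retained (ties broken by file order);
#' blank-altloc atoms are always kept. Idempotent.
#'
#' @param model a structure_model
#' @return filtered structure_model
#' @export
select_primary_altlocs <- function(model) {
  a <- model$atoms
  if (!nrow(a) || all(a$altloc == "")) return(model)
  key <- residue_keys(model)
  keep <- rep(TRUE, nrow(a))
  for (k in unique(key[a$altloc != ""])) {
    idx <- which(key == k & a$altloc != "")
    labs <- a$altloc[idx]
    occ_by <- vapply(unique(labs), function(l) sum(a$occ[idx[labs == l]]),
                     numeric(1))
    best <- unique(labs)[which.max(occ_by)]  # which.max -> first on ties
    keep[idx[labs != best]] <- FALSE
  }
  subset_model(model, keep)
}

#' Subset a model by an atom mask, remapping bonds
#' @noRd
subset_model <- function(model, mask) {
  idx_map <- integer(nrow(model$atoms))
  idx_map[mask] <- seq_len(sum(mask))
  bonds <- model$bonds
  if (nrow(bonds)) {
    ok <- mask[bonds[, 1]] & mask[bonds[, 2]]
    bonds <- matrix(idx_map[bonds[ok, , drop = FALSE]], ncol = 2)
  }
  structure_model(model$atoms[mask, , drop = FALSE], bonds,
                  model$resolution, model$source_format)
}

empty_atoms <- function(n = 0) {
  data.frame(serial = integer(n), name = character(n), altloc = character(n),
             resname = character(n), chain = character(n),
             resseq = integer(n), icode = character(n),
             x = numeric(n), y = numeric(n), z = numeric(n),
             occ = numeric(n), b = numeric(n), element = character(n),
             het = logical(n), stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------- reading --

#' Read a protein structure from PDB or mmCIF
#'
#' Only the first MODEL of a multi-model file is loaded (with a warning).
#' Element symbols are taken from the element columns when present and
#' inferred from atom names otherwise. Resolution is captured from
#' REMARK 2 / `_refine.ls_d_res_high` when available.
#'
#' @param path file path.
#' @param format `"auto"` (by extension/content), `"pdb"` or `"mmcif"`.
#' @return a [structure_model()] (bonds not yet built; see
#'   [build_covalent_graph()]).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE) ||
                  any(startsWith(lines, "_atom_site."))) "mmcif" else "pdb"
  }
  model <- if (format == "pdb") parse_pdb(lines) else parse_mmcif(lines)
  if (nrow(model$atoms) == 0L) stop("no atoms found in ", path)
  model
}

infer_element <- function(name, resname) {
  nm <- gsub("[^A-Za-z]", "", name)
  if (nchar(nm) == 0) return("X")
  first <- toupper(substr(nm, 1, 1))
  if (is_standard_aa(resname) || is_water_res(resname)) {
    if (first %in% c("H", "C", "N", "O", "S", "P", "D")) {
      return(if (first == "D") "H" else first)
    }
  }
  two <- toupper(substr(nm, 1, 2))
  if (two %in% names(.BONDI_RADII)) return(two)
  first
}

parse_pdb <- function(lines) {
  n_models <- sum(startsWith(lines, "MODEL "))
  if (n_models > 1) {
    warning("multi-model file: using the first MODEL only")
    first_end <- which(startsWith(lines, "ENDMDL"))[1]
    if (!is.na(first_end)) lines <- lines[seq_len(first_end)]
  }
  rec <- lines[startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")]
  a <- empty_atoms(length(rec))
  if (length(rec)) {
    fx <- function(from, to) trimws(substr(rec, from, to))
    a$serial <- seq_along(rec)  # re-serialised; originals may be hybrid-36
    a$name <- fx(13, 16)
    a$altloc <- substr(rec, 17, 17)
    a$altloc[a$altloc == " "] <- ""
    a$resname <- fx(18, 20)
    a$chain <- substr(rec, 22, 22)
    a$resseq <- suppressWarnings(as.integer(fx(23, 26)))
    a$icode <- trimws(substr(rec, 27, 27))
    a$x <- as.numeric(fx(31, 38))
    a$y <- as.numeric(fx(39, 46))
    a$z <- as.numeric(fx(47, 54))
    occ <- suppressWarnings(as.numeric(fx(55, 60)))
    a$occ <- ifelse(is.na(occ), 1, occ)
    bf <- suppressWarnings(as.numeric(fx(61, 66)))
    a$b <- ifelse(is.na(bf), 0, bf)
    el <- toupper(fx(77, 78))
    fixme <- el == "" | is.na(el)
    if (any(fixme))
      el[fixme] <- mapply(infer_element, a$name[fixme], a$resname[fixme])
    el[el == "D"] <- "H"
    a$element <- el
    a$het <- startsWith(rec, "HETATM")
    if (anyNA(a$x) || anyNA(a$y) || anyNA(a$z) || anyNA(a$resseq))
      stop("malformed ATOM/HETATM record(s): cannot parse coordinates")
  }
  res <- NA_real_
  rem2 <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rem2)) {
    m <- regmatches(rem2[1], regexpr("[0-9]+\\.[0-9]+", rem2[1]))
    if (length(m)) res <- as.numeric(m)
  }
  structure_model(a, NULL, res, "pdb")
}

# Minimal mmCIF tokenizer for one loop_ category: handles quoted strings and
# `.`/`?` null markers, not multi-line semicolon text (never used in
# atom_site values we read).
cif_tokens <- function(line) {
  out <- character(0)
  i <- 1; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1; next }
    if (ch %in% c("'", '"')) {
      j <- i + 1
      while (j <= n && substr(line, j, j) != ch) j <- j + 1
      out <- c(out, substr(line, i + 1, j - 1))
      i <- j + 1
    } else {
      j <- i
      while (j <= n && !substr(line, j, j) %in% c(" ", "\t")) j <- j + 1
      out <- c(out, substr(line, i, j - 1))
      i <- j
    }
  }
  out
}

parse_mmcif <- function(lines) {
  # locate the atom_site loop
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (!length(hdr_idx)) stop("no _atom_site loop found in mmCIF input")
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  body_start <- max(hdr_idx) + 1
  rows <- list()
  i <- body_start
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
        startsWith(ln, "loop_") || startsWith(ln, "data_")) break
    rows[[length(rows) + 1]] <- cif_tokens(lines[i])
    i <- i + 1
  }
  if (!length(rows)) stop("empty _atom_site loop")
  bad <- vapply(rows, length, integer(1)) != length(fields)
  if (any(bad)) stop("mmCIF atom_site rows do not match the field list")
  m <- do.call(rbind, rows)
  colnames(m) <- fields
  get <- function(nm, default = NA_character_) {
    if (nm %in% fields) m[, nm] else rep(default, nrow(m))
  }
  nullify <- function(x) ifelse(x %in% c(".", "?"), "", x)
  grp <- get("group_PDB", "ATOM")
  models <- get("pdbx_PDB_model_num", "1")
  first_model <- models[1]
  keep <- models == first_model
  if (!all(keep)) warning("multi-model file: using the first model only")
  a <- empty_atoms(sum(keep))
  a$serial <- seq_len(sum(keep))
  a$name <- nullify(get("auth_atom_id", get("label_atom_id")))[keep]
  a$altloc <- nullify(get("label_alt_id"))[keep]
  a$resname <- nullify(get("auth_comp_id", get("label_comp_id")))[keep]
  a$chain <- nullify(get("auth_asym_id", get("label_asym_id")))[keep]
  seqv <- nullify(get("auth_seq_id", get("label_seq_id")))[keep]
  a$resseq <- suppressWarnings(as.integer(seqv))
  a$icode <- nullify(get("pdbx_PDB_ins_code"))[keep]
  a$x <- as.numeric(get("Cartn_x")[keep])
  a$y <- as.numeric(get("Cartn_y")[keep])
  a$z <- as.numeric(get("Cartn_z")[keep])
  occ <- suppressWarnings(as.numeric(nullify(get("occupancy", "1"))[keep]))
  a$occ <- ifelse(is.na(occ), 1, occ)
  bf <- suppressWarnings(as.numeric(
    nullify(get("B_iso_or_equiv", "0"))[keep]))
  a$b <- ifelse(is.na(bf), 0, bf)
  el <- toupper(nullify(get("type_symbol"))[keep])
  fixme <- el == "" | is.na(el)
  if (any(fixme))
    el[fixme] <- mapply(infer_element, a$name[fixme], a$resname[fixme])
  el[el == "D"] <- "H"
  a$element <- el
  a$het <- grp[keep] == "HETATM"
  if (anyNA(a$resseq)) a$resseq[is.na(a$resseq)] <- 0L
  res <- NA_real_
  rln <- grep("^_(refine\\.ls_d_res_high|reflns\\.d_resolution_high)", lines,
              value = TRUE)
  if (length(rln)) {
    tok <- cif_tokens(rln[1])
    if (length(tok) >= 2) res <- suppressWarnings(as.numeric(tok[2]))
  }
  structure_model(a, NULL, res, "mmcif")
}

# ---------------------------------------------------------------- writing --

hy36_encode <- function(serial) {
  if (serial <= 99999) return(sprintf("%5d", serial))
  digits <- c(0:9, LETTERS)
  enc <- function(v, width) {
    out <- character(width)
    for (k in width:1) { out[k] <- digits[v %% 36 + 1]; v <- v %/% 36 }
    paste(out, collapse = "")
  }
  v <- serial - 99999 - 1 + 10 * 36^4
  if (v < 26 * 36^4) return(enc(v, 5))
  stop("atom serial out of hybrid-36 range")
}

#' Write a structure to PDB or mmCIF
#'
#' The PDB dialect uses fixed 8.3 coordinate fields, so a read-write-read
#' round trip preserves coordinates to 1e-3 Å. Serial numbers above 99999
#' are written in hybrid-36 or raise an error, per `overflow`.
#'
#' @param model a structure_model
#' @param path output path
#' @param format `"pdb"` or `"mmcif"`
#' @param overflow `"hybrid36"` or `"error"`: behaviour for >99999 atoms in
#'   the PDB dialect
#' @return `path`, invisibly
#' @export
write_structure <- function(model, path, format = c("pdb", "mmcif"),
                            overflow = c("hybrid36", "error")) {
  format <- match.arg(format)
  overflow <- match.arg(overflow)
  a <- model$atoms
  if (format == "pdb") {
    if (any(nchar(a$name) > 4))
      stop("atom name longer than 4 characters cannot be written as PDB")
    lines <- character(0)
    if (!is.na(model$resolution))
      lines <- sprintf(
        "REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", model$resolution)
    fmt_name <- function(name, element) {
      # element symbol occupies columns 13-14 for 2-char elements
      if (nchar(name) >= 4) return(substr(paste0(name, "   "), 1, 4))
      if (nchar(element) == 2 || nchar(name) == 4)
        return(sprintf("%-4s", name))
      sprintf(" %-3s", name)
    }
    recs <- vapply(seq_len(nrow(a)), function(i) {
      serial <- if (i <= 99999) sprintf("%5d", i) else {
        if (overflow == "error") stop("more than 99999 atoms in PDB dialect")
        hy36_encode(i)
      }
      sprintf("%-6s%s %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
              if (a$het[i]) "HETATM" else "ATOM",
              serial, fmt_name(a$name[i], a$element[i]),
              ifelse(a$altloc[i] == "", " ", a$altloc[i]),
              a$resname[i], a$chain[i], a$resseq[i],
              ifelse(a$icode[i] == "", " ", a$icode[i]),
              a$x[i], a$y[i], a$z[i], a$occ[i], a$b[i], a$element[i])
    }, character(1))
    writeLines(c(lines, recs, "END"), path)
  } else {
    hdr <- c("data_model", "#", "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_seq_id", "pdbx_PDB_ins_code", "Cartn_x",
                      "Cartn_y", "Cartn_z", "occupancy", "B_iso_or_equiv",
                      "auth_seq_id", "auth_comp_id", "auth_asym_id",
                      "auth_atom_id", "pdbx_PDB_model_num")))
    q <- function(x, blank = ".") ifelse(x == "", blank, x)
    recs <- sprintf(
      "%-6s %d %s %s %s %s %s %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
      ifelse(a$het, "HETATM", "ATOM"), seq_len(nrow(a)), a$element,
      q(a$name), q(a$altloc), q(a$resname), q(a$chain), a$resseq,
      q(a$icode, "?"), a$x, a$y, a$z, a$occ, a$b,
      a$resseq, q(a$resname), q(a$chain), q(a$name))
    reslns <- if (!is.na(model$resolution))
      sprintf("_refine.ls_d_res_high %.2f", model$resolution) else character(0)
    writeLines(c(hdr, recs, reslns, "#"), path)
  }
  invisible(path)
}
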