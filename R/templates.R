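# Residue chemistry templates for the 20 standard amino acids.
#
# Bond lists use PDB v3 atom naming and include hydrogens at the standard
# pH 7 protonation defaults: Asp/Glu deprotonated, Lys/Arg protonated, His
# neutral NE2 tautomer. Variable protonation (Asp/Glu/His) is handled by the
# hydrogen-bond network module, which owns those optional hydrogens.

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

.AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

.WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

# Sidechain bonds (heavy + H); backbone bonds are added generically.
.SIDE_BONDS <- list(
  ALA = c("CA CB", "CB HB1", "CB HB2", "CB HB3"),
  ARG = c("CA CB", "CB CG", "CG CD", "CD NE", "NE CZ", "CZ NH1", "CZ NH2",
          "CB HB2", "CB HB3", "CG HG2", "CG HG3", "CD HD2", "CD HD3",
          "NE HE", "NH1 HH11", "NH1 HH12", "NH2 HH21", "NH2 HH22"),
  ASN = c("CA CB", "CB CG", "CG OD1", "CG ND2",
          "CB HB2", "CB HB3", "ND2 HD21", "ND2 HD22"),
  ASP = c("CA CB", "CB CG", "CG OD1", "CG OD2", "CB HB2", "CB HB3"),
  CYS = c("CA CB", "CB SG", "CB HB2", "CB HB3", "SG HG"),
  GLN = c("CA CB", "CB CG", "CG CD", "CD OE1", "CD NE2",
          "CB HB2", "CB HB3", "CG HG2", "CG HG3", "NE2 HE21", "NE2 HE22"),
  GLU = c("CA CB", "CB CG", "CG CD", "CD OE1", "CD OE2",
          "CB HB2", "CB HB3", "CG HG2", "CG HG3"),
  GLY = character(0),
  HIS = c("CA CB", "CB CG", "CG ND1", "CG CD2", "ND1 CE1", "CE1 NE2",
          "NE2 CD2", "CB HB2", "CB HB3", "CD2 HD2", "CE1 HE1", "NE2 HE2"),
  ILE = c("CA CB", "CB CG1", "CB CG2", "CG1 CD1",
          "CB HB", "CG1 HG12", "CG1 HG13",
          "CG2 HG21", "CG2 HG22", "CG2 HG23",
          "CD1 HD11", "CD1 HD12", "CD1 HD13"),
  LEU = c("CA CB", "CB CG", "CG CD1", "CG CD2",
          "CB HB2", "CB HB3", "CG HG",
          "CD1 HD11", "CD1 HD12", "CD1 HD13",
          "CD2 HD21", "CD2 HD22", "CD2 HD23"),
  LYS = c("CA CB", "CB CG", "CG CD", "CD CE", "CE NZ",
          "CB HB2", "CB HB3", "CG HG2", "CG HG3", "CD HD2", "CD HD3",
          "CE HE2", "CE HE3", "NZ HZ1", "NZ HZ2", "NZ HZ3"),
  MET = c("CA CB", "CB CG", "CG SD", "SD CE",
          "CB HB2", "CB HB3", "CG HG2", "CG HG3",
          "CE HE1", "CE HE2", "CE HE3"),
  PHE = c("CA CB", "CB CG", "CG CD1", "CG CD2", "CD1 CE1", "CD2 CE2",
          "CE1 CZ", "CE2 CZ",
          "CB HB2", "CB HB3", "CD1 HD1", "CD2 HD2",
          "CE1 HE1", "CE2 HE2", "CZ HZ"),
  PRO = c("CA CB", "CB CG", "CG CD", "CD N",
          "CB HB2", "CB HB3", "CG HG2", "CG HG3", "CD HD2", "CD HD3"),
  SER = c("CA CB", "CB OG", "CB HB2", "CB HB3", "OG HG"),
  THR = c("CA CB", "CB OG1", "CB CG2",
          "CB HB", "OG1 HG1", "CG2 HG21", "CG2 HG22", "CG2 HG23"),
  TRP = c("CA CB", "CB CG", "CG CD1", "CG CD2", "CD1 NE1", "NE1 CE2",
          "CE2 CD2", "CD2 CE3", "CE3 CZ3", "CZ3 CH2", "CH2 CZ2", "CZ2 CE2",
          "CB HB2", "CB HB3", "CD1 HD1", "NE1 HE1",
          "CE3 HE3", "CZ3 HZ3", "CH2 HH2", "CZ2 HZ2"),
  TYR = c("CA CB", "CB CG", "CG CD1", "CG CD2", "CD1 CE1", "CD2 CE2",
          "CE1 CZ", "CE2 CZ", "CZ OH",
          "CB HB2", "CB HB3", "CD1 HD1", "CD2 HD2",
          "CE1 HE1", "CE2 HE2", "OH HH"),
  VAL = c("CA CB", "CB CG1", "CB CG2",
          "CB HB", "CG1 HG11", "CG1 HG12", "CG1 HG13",
          "CG2 HG21", "CG2 HG22", "CG2 HG23")
)

# sp2-hybridised heavy atoms (planar H frames); backbone N and C are sp2 in
# every residue and are handled generically.
.SP2_ATOMS <- list(
  ARG = c("NE", "CZ", "NH1", "NH2"),
  ASN = c("CG", "OD1", "ND2"),
  ASP = c("CG", "OD1", "OD2"),
  GLN = c("CD", "OE1", "NE2"),
  GLU = c("CD", "OE1", "OE2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ3", "CH2", "CZ2"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
)

# Aromatic ring atoms: an H riding on one of these counts as "aromatic" in
# the Richardson radius system.
.AROMATIC_ATOMS <- list(
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ3", "CH2", "CZ2"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
)

# Flip groups: terminal heavy-atom pair swapped by a 180 deg reorientation,
# plus all atoms belonging to the flip-ambiguous moiety.
.FLIP_GROUPS <- list(
  ASN = list(swap = list(c("OD1", "ND2")),
             atoms = c("CG", "OD1", "ND2", "HD21", "HD22")),
  GLN = list(swap = list(c("OE1", "NE2")),
             atoms = c("CD", "OE1", "NE2", "HE21", "HE22")),
  HIS = list(swap = list(c("ND1", "CD2"), c("CE1", "NE2")),
             atoms = c("CG", "ND1", "CD2", "CE1", "NE2",
                       "HD1", "HD2", "HE1", "HE2"))
)

# Hydrogen-bond roles by atom name (applied to polymer residues); donors are
# additionally recognised structurally as any N/O/S carrying a bonded H.
.DONOR_NAMES <- list(
  "*"   = "N",
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
  TRP = "NE1", TYR = "OH", CYS = "SG"
)

.ACCEPTOR_NAMES <- list(
  "*" = c("O", "OXT"),
  ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1", GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"), MET = "SD", CYS = "SG",
  SER = "OG", THR = "OG1", TYR = "OH"
)

# Rotatable-hydrogen sites (torsional freedom not determined by heavy atoms).
# columns: parent atom, kind, torsion axis (bonded heavy neighbour defining
# the rotation bond together with the parent).
.ROTATABLE_SITES <- list(
  SER = list(parent = "OG",  kind = "hydroxyl",   axis = "CB"),
  THR = list(parent = "OG1", kind = "hydroxyl",   axis = "CB"),
  TYR = list(parent = "OH",  kind = "phenolic",   axis = "CZ"),
  CYS = list(parent = "SG",  kind = "sulfhydryl", axis = "CB"),
  LYS = list(parent = "NZ",  kind = "amine",      axis = "CE")
)

# Planar side-chain groups (ring/plane plus first substituent atoms) whose
# least-squares-plane r.m.s.d. enters the planarity statistic.
.PLANAR_GROUPS <- list(
  ARG = list(c("CD", "NE", "CZ", "NH1", "NH2")),
  ASN = list(c("CB", "CG", "OD1", "ND2")),
  ASP = list(c("CB", "CG", "OD1", "OD2")),
  GLN = list(c("CG", "CD", "OE1", "NE2")),
  GLU = list(c("CG", "CD", "OE1", "OE2")),
  HIS = list(c("CB", "CG", "ND1", "CD2", "CE1", "NE2")),
  PHE = list(c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ3",
               "CH2", "CZ2")),
  TYR = list(c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"))
)

# X-H template bond lengths (nuclear positions, A); configurable through
# options in hydrogen placement.
.XH_LENGTHS <- c(C = 1.090, N = 1.010, O = 0.960, S = 1.340)

#' Is a residue name a standard amino acid?
#' @noRd
is_standard_aa <- function(resname) toupper(resname) %in% .AA3

#' Is a residue name water?
#' @noRd
is_water_res <- function(resname) toupper(resname) %in% .WATER_NAMES

#' Full bond-name table for one residue (backbone + sidechain), as a
#' two-column character matrix. `n_h` toggles the backbone amide H (absent
#' for Pro).
#' @noRd
residue_bond_names <- function(resname) {
  resname <- toupper(resname)
  if (!is_standard_aa(resname)) return(NULL)
  bb <- c("N CA", "CA C", "C O")
  if (resname == "GLY") {
    bb <- c(bb, "CA HA2", "CA HA3")
  } else {
    bb <- c(bb, "CA HA")
  }
  if (resname != "PRO") bb <- c(bb, "N H")
  all <- c(bb, .SIDE_BONDS[[resname]])
  do.call(rbind, strsplit(all, " ", fixed = TRUE))
}

#' Optional-atom bonds recognised when present (termini, variable protons)
#' @noRd
optional_bond_names <- function(resname) {
  resname <- toupper(resname)
  ext <- c("C OXT", "N H1", "N H2", "N H3", "N H")
  ext <- switch(resname,
    ASP = c(ext, "OD2 HD2", "OD1 HD1"),
    GLU = c(ext, "OE2 HE2", "OE1 HE1"),
    HIS = c(ext, "ND1 HD1"),
    ext)
  do.call(rbind, strsplit(ext, " ", fixed = TRUE))
}

#' Atom-name based role lookups
#' @noRd
role_names <- function(table, resname) {
  resname <- toupper(resname)
  c(table[["*"]], table[[resname]])
}
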