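# Reference geometry targets (Engh & Huber-style restraint library) and the
# internal-coordinate construction table used by the fixture generator.
#
# Lookup precedence: residue-specific row, then the generic "*" row. The
# angle list deliberately contains exactly the angles the builder sets
# (plus planar complements that are exact by construction), so an ideal
# fixture scores zero deviation against these targets by construction.

.targets_cache <- new.env(parent = emptyenv())

#' Load the geometry target tables
#'
#' @param bonds_file,angles_file optional CSV overrides with columns
#'   `resname, atom1, atom2[, atom3], ideal, sigma, link` (`link = 1` marks
#'   entries spanning the peptide bond).
#' @return object of class `geometry_targets` with `$bonds` and `$angles`
#' @export
geometry_targets <- function(bonds_file = NULL, angles_file = NULL) {
  default <- is.null(bonds_file) && is.null(angles_file)
  if (default && !is.null(.targets_cache$default))
    return(.targets_cache$default)
  if (is.null(bonds_file))
    bonds_file <- system.file("extdata", "eh_bonds.csv", package = "clashaudit")
  if (is.null(angles_file))
    angles_file <- system.file("extdata", "eh_angles.csv", package = "clashaudit")
  bonds <- utils::read.csv(bonds_file, stringsAsFactors = FALSE)
  angles <- utils::read.csv(angles_file, stringsAsFactors = FALSE)
  stopifnot(all(bonds$sigma > 0), all(angles$sigma > 0))
  bonds$key <- paste(bonds$resname,
                     pmin(bonds$atom1, bonds$atom2),
                     pmax(bonds$atom1, bonds$atom2))
  angles$key <- paste(angles$resname, angles$atom1, angles$atom2,
                      angles$atom3)
  angles$rkey <- paste(angles$resname, angles$atom3, angles$atom2,
                       angles$atom1)
  out <- structure(list(bonds = bonds, angles = angles),
                   class = "geometry_targets")
  if (default) .targets_cache$default <- out
  out
}

#' Look up a bond target (ideal, sigma) or NULL
#' @noRd
bond_target <- function(targets, resname, a1, a2) {
  b <- targets$bonds
  key <- paste(c(toupper(resname), "*"),
               pmin(a1, a2), pmax(a1, a2))
  hit <- match(key, b$key)
  hit <- hit[!is.na(hit)][1]
  if (is.na(hit)) return(NULL)
  list(ideal = b$ideal[hit], sigma = b$sigma[hit], link = b$link[hit] == 1)
}

#' Look up an angle target (vertex = a2) or NULL
#' @noRd
angle_target <- function(targets, resname, a1, a2, a3) {
  an <- targets$angles
  keys <- c(paste(toupper(resname), a1, a2, a3),
            paste("*", a1, a2, a3))
  hit <- match(keys, an$key)
  if (all(is.na(hit))) hit <- match(keys, an$rkey)
  hit <- hit[!is.na(hit)][1]
  if (is.na(hit)) return(NULL)
  list(ideal = an$ideal[hit], sigma = an$sigma[hit], link = an$link[hit] == 1)
}

# -------------------------------------------------------- construction ----
# Sidechain internal-coordinate entries: each atom placed via NeRF from
# (ref1 = bonded parent, ref2, ref3) with bond (atom, ref1) and angle
# (ref2, ref1, atom) taken from the target tables and the listed default
# torsion ref3-ref2-ref1-atom in degrees. CB is placed generically with an
# improper torsion chosen for L-configuration.
.SIDE_ZMAT <- list(
  ALA = NULL,
  SER = list(c("OG",  "CB", "CA", "N",  "180")),
  CYS = list(c("SG",  "CB", "CA", "N",  "180")),
  THR = list(c("OG1", "CB", "CA", "N",  "60"),
             c("CG2", "CB", "CA", "N",  "-60")),
  VAL = list(c("CG1", "CB", "CA", "N",  "180"),
             c("CG2", "CB", "CA", "N",  "-60")),
  # Ile in the common mt rotamer; the 3S branch puts CG2 at chi1 - 120
  ILE = list(c("CG1", "CB", "CA", "N",  "-60"),
             c("CG2", "CB", "CA", "N",  "180"),
             c("CD1", "CG1", "CB", "CA", "170")),
  LEU = list(c("CG",  "CB", "CA", "N",  "180"),
             c("CD1", "CG", "CB", "CA", "60"),
             c("CD2", "CG", "CB", "CA", "180")),
  MET = list(c("CG",  "CB", "CA", "N",  "180"),
             c("SD",  "CG", "CB", "CA", "180"),
             c("CE",  "SD", "CG", "CB", "180")),
  LYS = list(c("CG",  "CB", "CA", "N",  "180"),
             c("CD",  "CG", "CB", "CA", "180"),
             c("CE",  "CD", "CG", "CB", "180"),
             c("NZ",  "CE", "CD", "CG", "180")),
  ARG = list(c("CG",  "CB", "CA", "N",  "180"),
             c("CD",  "CG", "CB", "CA", "180"),
             c("NE",  "CD", "CG", "CB", "180"),
             c("CZ",  "NE", "CD", "CG", "180"),
             c("NH1", "CZ", "NE", "CD", "0"),
             c("NH2", "CZ", "NE", "CD", "180")),
  ASP = list(c("CG",  "CB", "CA", "N",  "180"),
             c("OD1", "CG", "CB", "CA", "0"),
             c("OD2", "CG", "CB", "CA", "180")),
  ASN = list(c("CG",  "CB", "CA", "N",  "180"),
             c("OD1", "CG", "CB", "CA", "0"),
             c("ND2", "CG", "CB", "CA", "180")),
  GLU = list(c("CG",  "CB", "CA", "N",  "180"),
             c("CD",  "CG", "CB", "CA", "180"),
             c("OE1", "CD", "CG", "CB", "0"),
             c("OE2", "CD", "CG", "CB", "180")),
  GLN = list(c("CG",  "CB", "CA", "N",  "180"),
             c("CD",  "CG", "CB", "CA", "180"),
             c("OE1", "CD", "CG", "CB", "0"),
             c("NE2", "CD", "CG", "CB", "180")),
  HIS = list(c("CG",  "CB", "CA", "N",  "180"),
             c("ND1", "CG", "CB", "CA", "90"),
             c("CE1", "ND1", "CG", "CB", "180"),
             c("NE2", "CE1", "ND1", "CG", "0"),
             c("CD2", "NE2", "CE1", "ND1", "0")),
  PHE = list(c("CG",  "CB", "CA", "N",  "180"),
             c("CD1", "CG", "CB", "CA", "90"),
             c("CE1", "CD1", "CG", "CB", "180"),
             c("CZ",  "CE1", "CD1", "CG", "0"),
             c("CE2", "CZ", "CE1", "CD1", "0"),
             c("CD2", "CE2", "CZ", "CE1", "0")),
  TYR = list(c("CG",  "CB", "CA", "N",  "180"),
             c("CD1", "CG", "CB", "CA", "90"),
             c("CE1", "CD1", "CG", "CB", "180"),
             c("CZ",  "CE1", "CD1", "CG", "0"),
             c("CE2", "CZ", "CE1", "CD1", "0"),
             c("CD2", "CE2", "CZ", "CE1", "0"),
             c("OH",  "CZ", "CE1", "CD1", "180")),
  TRP = list(c("CG",  "CB", "CA", "N",  "180"),
             c("CD1", "CG", "CB", "CA", "90"),
             c("NE1", "CD1", "CG", "CB", "180"),
             c("CE2", "NE1", "CD1", "CG", "0"),
             c("CD2", "CE2", "NE1", "CD1", "0"),
             c("CE3", "CD2", "CE2", "NE1", "180"),
             c("CZ3", "CE3", "CD2", "CE2", "0"),
             c("CH2", "CZ3", "CE3", "CD2", "0"),
             c("CZ2", "CH2", "CZ3", "CE3", "0")),
  # proline ring torsions solved so that the closing N-CD bond and the
  # CA-N-CD angle both land exactly on their targets
  PRO = list(c("CG",  "CB", "CA", "N",  "28.7217"),
             c("CD",  "CG", "CB", "CA", "-32.8139")),
  GLY = NULL
)

# Improper torsion C(i)-N(i)-CA(i)-CB giving the L configuration
# (reference components place CB at -120 about the N-CA axis from C).
.CB_IMPROPER <- -122.6
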