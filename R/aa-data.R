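# Amino-acid tables: codes, heavy-atom side-chain topology (internal
# coordinates), intra-residue bond lists and chi-angle definitions.
# Geometry uses ideal bond lengths/angles; side chains are rebuilt from these
# tables, so the values here define the package's "ideal internal geometry".

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
names(AA1) <- AA3
AA3_FROM_1 <- stats::setNames(AA3, AA1)

#' Convert between one- and three-letter amino-acid codes
#'
#' @param x character vector of codes.
#' @return character vector of converted codes.
#' @export
aa123 <- function(x) {
  out <- AA3_FROM_1[toupper(x)]
  if (anyNA(out)) stop("unknown one-letter amino-acid code: ",
                       paste(x[is.na(out)], collapse = ", "))
  unname(out)
}

#' @rdname aa123
#' @export
aa321 <- function(x) {
  out <- AA1[toupper(x)]
  if (anyNA(out)) stop("unknown three-letter amino-acid code: ",
                       paste(x[is.na(out)], collapse = ", "))
  unname(out)
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# Side-chain topology. Each row places one atom by NeRF from
# (parent, angle_ref, dih_ref) with bond length (A), bond angle (deg) and a
# dihedral that is either absolute (abs) or chi_k + offset (deg).
# CB is placed from (CA, N, C) with an improper torsion fixing chirality.
.sc_row <- function(name, el, parent, aref, dref, b, ang, chi = NA, dih = NA) {
  list(name = name, el = el, parent = parent, aref = aref, dref = dref,
       b = b, ang = ang, chi = chi, dih = dih)
}

.CB <- .sc_row("CB", "C", "CA", "N", "C", 1.53, 110.4, NA, -122.6)

SIDECHAIN_TOPOLOGY <- list(
  ALA = list(.CB),
  ARG = list(.CB,
    .sc_row("CG",  "C", "CB", "CA", "N",  1.52, 112, 1, 0),
    .sc_row("CD",  "C", "CG", "CB", "CA", 1.52, 112, 2, 0),
    .sc_row("NE",  "N", "CD", "CG", "CB", 1.46, 112, 3, 0),
    .sc_row("CZ",  "C", "NE", "CD", "CG", 1.33, 124, 4, 0),
    .sc_row("NH1", "N", "CZ", "NE", "CD", 1.33, 120, NA, 0),
    .sc_row("NH2", "N", "CZ", "NE", "CD", 1.33, 120, NA, 180)),
  ASN = list(.CB,
    .sc_row("CG",  "C", "CB", "CA", "N",  1.52, 112, 1, 0),
    .sc_row("OD1", "O", "CG", "CB", "CA", 1.23, 120, 2, 0),
    .sc_row("ND2", "N", "CG", "CB", "CA", 1.33, 116, 2, 180)),
  ASP = list(.CB,
    .sc_row("CG",  "C", "CB", "CA", "N",  1.52, 112, 1, 0),
    .sc_row("OD1", "O", "CG", "CB", "CA", 1.25, 118, 2, 0),
    .sc_row("OD2", "O", "CG", "CB", "CA", 1.25, 118, 2, 180)),
  CYS = list(.CB,
    .sc_row("SG", "S", "CB", "CA", "N", 1.81, 114, 1, 0)),
  GLN = list(.CB,
    .sc_row("CG",  "C", "CB", "CA", "N",  1.52, 112, 1, 0),
    .sc_row("CD",  "C", "CG", "CB", "CA", 1.52, 112, 2, 0),
    .sc_row("OE1", "O", "CD", "CG", "CB", 1.23, 120, 3, 0),
    .sc_row("NE2", "N", "CD", "CG", "CB", 1.33, 116, 3, 180)),
  GLU = list(.CB,
    .sc_row("CG",  "C", "CB", "CA", "N",  1.52, 112, 1, 0),
    .sc_row("CD",  "C", "CG", "CB", "CA", 1.52, 112, 2, 0),
    .sc_row("OE1", "O", "CD", "CG", "CB", 1.25, 118, 3, 0),
    .sc_row("OE2", "O", "CD", "CG", "CB", 1.25, 118, 3, 180)),
  GLY = list(),
  HIS = list(.CB,
    .sc_row("CG",  "C", "CB", "CA", "N",  1.50, 113, 1, 0),
    .sc_row("ND1", "N", "CG", "CB", "CA", 1.38, 122, 2, 0),
    .sc_row("CD2", "C", "CG", "CB", "CA", 1.36, 129, 2, 180),
    .sc_row("CE1", "C", "ND1", "CG", "CB", 1.32, 109, NA, 180),
    .sc_row("NE2", "N", "CD2", "CG", "CB", 1.37, 107, NA, 180)),
  ILE = list(.CB,
    .sc_row("CG1", "C", "CB", "CA", "N",  1.53, 110.5, 1, 0),
    .sc_row("CG2", "C", "CB", "CA", "N",  1.53, 110.5, 1, -122),
    .sc_row("CD1", "C", "CG1", "CB", "CA", 1.52, 113, 2, 0)),
  LEU = list(.CB,
    .sc_row("CG",  "C", "CB", "CA", "N",  1.53, 116, 1, 0),
    .sc_row("CD1", "C", "CG", "CB", "CA", 1.52, 110, 2, 0),
    .sc_row("CD2", "C", "CG", "CB", "CA", 1.52, 110, 2, 122)),
  LYS = list(.CB,
    .sc_row("CG", "C", "CB", "CA", "N",  1.52, 112, 1, 0),
    .sc_row("CD", "C", "CG", "CB", "CA", 1.52, 112, 2, 0),
    .sc_row("CE", "C", "CD", "CG", "CB", 1.52, 112, 3, 0),
    .sc_row("NZ", "N", "CE", "CD", "CG", 1.47, 111, 4, 0)),
  MET = list(.CB,
    .sc_row("CG", "C", "CB", "CA", "N",  1.52, 112, 1, 0),
    .sc_row("SD", "S", "CG", "CB", "CA", 1.80, 112, 2, 0),
    .sc_row("CE", "C", "SD", "CG", "CB", 1.79, 100, 3, 0)),
  PHE = list(.CB,
    .sc_row("CG",  "C", "CB", "CA", "N",  1.50, 114, 1, 0),
    .sc_row("CD1", "C", "CG", "CB", "CA", 1.39, 120, 2, 0),
    .sc_row("CD2", "C", "CG", "CB", "CA", 1.39, 120, 2, 180),
    .sc_row("CE1", "C", "CD1", "CG", "CB", 1.39, 120, NA, 180),
    .sc_row("CE2", "C", "CD2", "CG", "CB", 1.39, 120, NA, 180),
    .sc_row("CZ",  "C", "CE1", "CD1", "CG", 1.39, 120, NA, 0)),
  PRO = list(.CB,
    .sc_row("CG", "C", "CB", "CA", "N",  1.50, 104, 1, 0),
    .sc_row("CD", "C", "CG", "CB", "CA", 1.50, 106, 2, 0)),
  SER = list(.CB,
    .sc_row("OG", "O", "CB", "CA", "N", 1.42, 111, 1, 0)),
  THR = list(.CB,
    .sc_row("OG1", "O", "CB", "CA", "N", 1.43, 109.5, 1, 0),
    .sc_row("CG2", "C", "CB", "CA", "N", 1.52, 110.5, 1, -122)),
  TRP = list(.CB,
    .sc_row("CG",  "C", "CB", "CA", "N",  1.50, 114, 1, 0),
    .sc_row("CD1", "C", "CG", "CB", "CA", 1.37, 127, 2, 0),
    .sc_row("CD2", "C", "CG", "CB", "CA", 1.43, 127, 2, 180),
    .sc_row("NE1", "N", "CD1", "CG", "CB", 1.38, 110, NA, 180),
    .sc_row("CE2", "C", "CD2", "CG", "CB", 1.41, 107, NA, 180),
    .sc_row("CE3", "C", "CD2", "CG", "CB", 1.40, 133, NA, 0),
    .sc_row("CZ2", "C", "CE2", "CD2", "CG", 1.40, 122, NA, 180),
    .sc_row("CZ3", "C", "CE3", "CD2", "CG", 1.39, 118, NA, 180),
    .sc_row("CH2", "C", "CZ2", "CE2", "CD2", 1.37, 117, NA, 0)),
  TYR = list(.CB,
    .sc_row("CG",  "C", "CB", "CA", "N",  1.50, 114, 1, 0),
    .sc_row("CD1", "C", "CG", "CB", "CA", 1.39, 120, 2, 0),
    .sc_row("CD2", "C", "CG", "CB", "CA", 1.39, 120, 2, 180),
    .sc_row("CE1", "C", "CD1", "CG", "CB", 1.39, 120, NA, 180),
    .sc_row("CE2", "C", "CD2", "CG", "CB", 1.39, 120, NA, 180),
    .sc_row("CZ",  "C", "CE1", "CD1", "CG", 1.39, 120, NA, 0),
    .sc_row("OH",  "O", "CZ", "CE1", "CD1", 1.38, 120, NA, 180)),
  VAL = list(.CB,
    .sc_row("CG1", "C", "CB", "CA", "N", 1.53, 110.5, 1, 0),
    .sc_row("CG2", "C", "CB", "CA", "N", 1.53, 110.5, 1, 122))
)

# Ring-closing (and proline N-CD) bonds that the parent relation misses.
RING_BONDS <- list(
  HIS = list(c("CE1", "NE2")),
  PHE = list(c("CZ", "CE2")),
  TYR = list(c("CZ", "CE2")),
  TRP = list(c("NE1", "CE2"), c("CZ3", "CH2")),
  PRO = list(c("CD", "N"))
)

# Number of chi angles per residue (PRO's two are ring pseudo-chis; the
# rotamer library pins them near ring-compatible values).
N_CHI <- c(ALA = 0L, ARG = 4L, ASN = 2L, ASP = 2L, CYS = 1L, GLN = 3L,
           GLU = 3L, GLY = 0L, HIS = 2L, ILE = 2L, LEU = 2L, LYS = 4L,
           MET = 3L, PHE = 2L, PRO = 2L, SER = 1L, THR = 1L, TRP = 2L,
           TYR = 2L, VAL = 1L)

# Intra-residue heavy-atom bond list (pairs of atom names).
residue_bonds <- function(aa) {
  stopifnot(aa %in% AA3)
  bonds <- list(c("N", "CA"), c("CA", "C"), c("C", "O"))
  for (row in SIDECHAIN_TOPOLOGY[[aa]]) {
    bonds[[length(bonds) + 1L]] <- c(row$parent, row$name)
  }
  for (b in RING_BONDS[[aa]]) bonds[[length(bonds) + 1L]] <- b
  bonds
}

# Default per-element radii used for clash scoring and as GB radii fallback.
ELEMENT_RADII <- c(C = 1.90, N = 1.70, O = 1.50, S = 1.90)

# Expected heavy side-chain atom names for each residue type.
sidechain_atom_names <- function(aa) {
  vapply(SIDECHAIN_TOPOLOGY[[aa]], `[[`, character(1), "name")
}
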