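# Amino-acid reference data: codes, volumes, size classes, covalent templates.

#' @keywords internal
AA_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN", E = "GLU",
  G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS", M = "MET", F = "PHE",
  P = "PRO", S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)

AA_ONE <- stats::setNames(names(AA_THREE), AA_THREE)

#' Standard one-letter amino-acid alphabet
#'
#' The 20 standard amino acids as one-letter codes, alphabetically sorted.
#' This is the default insertion alphabet for mutant enumeration.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' standard_aa()
standard_aa <- function() sort(unname(names(AA_THREE)))

# Mean residue volumes (A^3); used only to order residue pairs from
# smallest (GG) to largest (WW) and to bin into size classes.
AA_VOLUME <- c(
  G = 60.1, A = 88.6, S = 89.0,
  C = 108.5, D = 111.1, P = 112.7, N = 114.1, T = 116.1,
  E = 138.4, V = 140.0, Q = 143.8, H = 153.2,
  M = 162.9, I = 166.7, L = 166.7, K = 168.6, R = 173.4,
  F = 189.9, Y = 193.6, W = 227.8
)

# Volume size classes: VS/S/M/L/VL partition the 20 standard residues.
SIZE_CLASS_DEF <- list(
  VS = list(members = c("G", "A", "S"), volume_range = c(60, 89)),
  S  = list(members = c("C", "D", "P", "N", "T"), volume_range = c(108, 116)),
  M  = list(members = c("E", "V", "Q", "H"), volume_range = c(138, 153)),
  L  = list(members = c("M", "I", "L", "K", "R"), volume_range = c(162, 173)),
  VL = list(members = c("F", "Y", "W"), volume_range = c(189, 227))
)

SIZE_ORDER <- c("VS", "S", "M", "L", "VL")

AA_SIZE_CLASS <- local({
  out <- character(0)
  for (cls in SIZE_ORDER) {
    m <- SIZE_CLASS_DEF[[cls]]$members
    out[m] <- cls
  }
  out
})

#' Amino-acid volume size-class table
#'
#' Residue volume classes used to group inserted residues: very small (VS),
#' small (S), medium (M), large (L) and very large (VL), with the volume range
#' in cubic Angstroms each class spans.
#'
#' @return A data frame with columns `aa`, `volume`, `class`, `vol_low`,
#'   `vol_high`, one row per standard amino acid, ordered by volume.
#' @export
#' @examples
#' size_class_table()
size_class_table <- function() {
  aa <- names(sort(AA_VOLUME))
  cls <- AA_SIZE_CLASS[aa]
  rng <- t(vapply(cls, function(k) SIZE_CLASS_DEF[[k]]$volume_range,
                  numeric(2)))
  data.frame(aa = aa, volume = unname(AA_VOLUME[aa]), class = unname(cls),
             vol_low = rng[, 1], vol_high = rng[, 2], row.names = NULL)
}

# ---------------------------------------------------------------------------
# Residue covalent templates.
#
# For every standard residue: heavy-atom side-chain bonds with a locked flag
# (TRUE for peptide/double/partial-double/ring bonds, which merge their atoms
# into one rigid body; FALSE for rotatable single bonds, modelled as 5-bar
# hinges), plus hydrogen-bond donor and acceptor atom names. Backbone bonds
# (N-CA, CA-C rotatable; C-O, C-OXT locked; CA-CB rotatable) are shared and
# added programmatically.
# ---------------------------------------------------------------------------

.bond <- function(a, b, locked = FALSE) list(a = a, b = b, locked = locked)

RESIDUE_TEMPLATES <- list(
  GLY = list(bonds = list(), donors = character(0), acceptors = character(0)),
  ALA = list(bonds = list(), donors = character(0), acceptors = character(0)),
  SER = list(bonds = list(.bond("CB", "OG")),
             donors = "OG", acceptors = "OG"),
  CYS = list(bonds = list(.bond("CB", "SG")),
             donors = "SG", acceptors = "SG"),
  THR = list(bonds = list(.bond("CB", "OG1"), .bond("CB", "CG2")),
             donors = "OG1", acceptors = "OG1"),
  VAL = list(bonds = list(.bond("CB", "CG1"), .bond("CB", "CG2")),
             donors = character(0), acceptors = character(0)),
  LEU = list(bonds = list(.bond("CB", "CG"), .bond("CG", "CD1"),
                          .bond("CG", "CD2")),
             donors = character(0), acceptors = character(0)),
  ILE = list(bonds = list(.bond("CB", "CG1"), .bond("CB", "CG2"),
                          .bond("CG1", "CD1")),
             donors = character(0), acceptors = character(0)),
  MET = list(bonds = list(.bond("CB", "CG"), .bond("CG", "SD"),
                          .bond("SD", "CE")),
             donors = character(0), acceptors = "SD"),
  PRO = list(bonds = list(.bond("CB", "CG", TRUE), .bond("CG", "CD", TRUE),
                          .bond("CD", "N", TRUE), .bond("N", "CA", TRUE),
                          .bond("CA", "CB", TRUE)),
             donors = character(0), acceptors = character(0)),
  PHE = list(bonds = list(.bond("CB", "CG"),
                          .bond("CG", "CD1", TRUE), .bond("CD1", "CE1", TRUE),
                          .bond("CE1", "CZ", TRUE), .bond("CZ", "CE2", TRUE),
                          .bond("CE2", "CD2", TRUE), .bond("CD2", "CG", TRUE)),
             donors = character(0), acceptors = character(0)),
  TYR = list(bonds = list(.bond("CB", "CG"),
                          .bond("CG", "CD1", TRUE), .bond("CD1", "CE1", TRUE),
                          .bond("CE1", "CZ", TRUE), .bond("CZ", "CE2", TRUE),
                          .bond("CE2", "CD2", TRUE), .bond("CD2", "CG", TRUE),
                          .bond("CZ", "OH")),
             donors = "OH", acceptors = "OH"),
  TRP = list(bonds = list(.bond("CB", "CG"),
                          .bond("CG", "CD1", TRUE), .bond("CD1", "NE1", TRUE),
                          .bond("NE1", "CE2", TRUE), .bond("CE2", "CD2", TRUE),
                          .bond("CD2", "CG", TRUE), .bond("CE2", "CZ2", TRUE),
                          .bond("CZ2", "CH2", TRUE), .bond("CH2", "CZ3", TRUE),
                          .bond("CZ3", "CE3", TRUE), .bond("CE3", "CD2", TRUE)),
             donors = "NE1", acceptors = character(0)),
  ASP = list(bonds = list(.bond("CB", "CG"),
                          .bond("CG", "OD1", TRUE), .bond("CG", "OD2", TRUE)),
             donors = character(0), acceptors = c("OD1", "OD2")),
  GLU = list(bonds = list(.bond("CB", "CG"), .bond("CG", "CD"),
                          .bond("CD", "OE1", TRUE), .bond("CD", "OE2", TRUE)),
             donors = character(0), acceptors = c("OE1", "OE2")),
  ASN = list(bonds = list(.bond("CB", "CG"),
                          .bond("CG", "OD1", TRUE), .bond("CG", "ND2", TRUE)),
             donors = "ND2", acceptors = "OD1"),
  GLN = list(bonds = list(.bond("CB", "CG"), .bond("CG", "CD"),
                          .bond("CD", "OE1", TRUE), .bond("CD", "NE2", TRUE)),
             donors = "NE2", acceptors = "OE1"),
  LYS = list(bonds = list(.bond("CB", "CG"), .bond("CG", "CD"),
                          .bond("CD", "CE"), .bond("CE", "NZ")),
             donors = "NZ", acceptors = character(0)),
  ARG = list(bonds = list(.bond("CB", "CG"), .bond("CG", "CD"),
                          .bond("CD", "NE"),
                          .bond("NE", "CZ", TRUE), .bond("CZ", "NH1", TRUE),
                          .bond("CZ", "NH2", TRUE)),
             donors = c("NE", "NH1", "NH2"), acceptors = character(0)),
  HIS = list(bonds = list(.bond("CB", "CG"),
                          .bond("CG", "ND1", TRUE), .bond("ND1", "CE1", TRUE),
                          .bond("CE1", "NE2", TRUE), .bond("NE2", "CD2", TRUE),
                          .bond("CD2", "CG", TRUE)),
             donors = c("ND1", "NE2"), acceptors = c("ND1", "NE2"))
)
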