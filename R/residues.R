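#' @keywords internal
"_PACKAGE"

#' Ionizable residue types
#'
#' Three-letter codes of the amino acids with titratable side chains:
#' Asp, Glu, His, Cys, Tyr, Lys, Arg.
#'
#' @format Character vector of length 7.
#' @export
IONIZABLE_RESIDUES <- c("ASP", "GLU", "HIS", "CYS", "TYR", "LYS", "ARG")

# Reference (model) pKa values of the isolated amino acids in solution,
# used by the built-in deterministic engine. External engines report their
# own model values, which are parsed from their output, never taken from here.
MOCK_MODEL_PKA <- c(
  ASP = 3.80, GLU = 4.50, HIS = 6.50, CYS = 9.00,
  TYR = 10.00, LYS = 10.50, ARG = 12.50
)

# Protonation-state variant names (AMBER/CHARMM conventions) mapped to the
# canonical names that single-structure pKa engines accept.
RESNAME_CONVERSION <- c(
  ASH = "ASP", GLH = "GLU",
  HID = "HIS", HIE = "HIS", HIP = "HIS",
  HSD = "HIS", HSE = "HIS", HSP = "HIS",
  CYX = "CYS", CYM = "CYS",
  LYN = "LYS", ARN = "ARG", TYM = "TYR"
)

CANONICAL_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

# Terminal caps passed through untouched.
CAP_RESIDUES <- c("ACE", "NME", "NMA")

AA_1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

# Side-chain heavy atoms of each residue type, in PDB naming. Backbone
# atoms (N, CA, C, O, OXT) are implicit.
SIDECHAIN_ATOMS <- list(
  ALA = "CB",
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

# Atoms retained when a residue is truncated to alanine: the alanine heavy
# atoms plus backbone/beta hydrogens and the terminal carboxyl oxygen.
ALANINE_KEEP_ATOMS <- c(
  "N", "CA", "C", "O", "CB", "OXT",
  "H", "HN", "HA", "H1", "H2", "H3",
  "HB", "HB1", "HB2", "HB3"
)

#' Build a residue label
#'
#' Residues are identified throughout the package by the label
#' `"RESNAME RESID CHAIN"` (for example `"ASP 52 A"`), which is also the
#' column naming scheme of the wide pKa/buried CSV files.
#'
#' @param resname Three-letter residue type.
#' @param resid Integer residue number.
#' @param chain Single-character chain identifier.
#' @return Character vector of labels.
#' @export
#' @examples
#' res_label("ASP", 52, "A")
res_label <- function(resname, resid, chain) {
  paste(resname, resid, chain)
}

#' Parse residue labels
#'
#' Inverse of [res_label()]: splits `"RESNAME RESID CHAIN"` strings into a
#' tibble with one row per label.
#'
#' @param labels Character vector of `"RESNAME RESID CHAIN"` labels.
#' @return A tibble with columns `resname`, `resid`, `chain`, `label`.
#' @export
parse_res_label <- function(labels) {
  parts <- strsplit(trimws(labels), "\\s+")
  bad <- lengths(parts) != 3L
  if (any(bad)) {
    rlang::abort(
      paste0("Malformed residue label(s): ",
             paste(labels[bad], collapse = ", "),
             " (expected \"RESNAME RESID CHAIN\")"),
      class = "trajpka_value_error"
    )
  }
  tibble::tibble(
    resname = vapply(parts, `[`, "", 1L),
    resid = as.integer(vapply(parts, `[`, "", 2L)),
    chain = vapply(parts, `[`, "", 3L),
    label = labels
  )
}

element_from_name <- function(atom_name) {
  first <- substr(gsub("^[0-9]+", "", atom_name), 1L, 1L)
  ifelse(first %in% c("C", "N", "O", "S", "H", "P"), first, "C")
}

is_heavy_atom <- function(atom_name) {
  element_from_name(atom_name) != "H"
}
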