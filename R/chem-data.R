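# Element property tables used by geometry validity checks and interaction
# detection. Radii in Angstrom.

# single-bond covalent radii (Cordero et al. consensus values)
COVALENT_RADII <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
  F = 0.57, Cl = 1.02, Br = 1.20, I = 1.39, B = 0.84, Se = 1.20,
  Na = 1.66, K = 2.03, Mg = 1.41, Ca = 1.76, Zn = 1.22, Fe = 1.32,
  Mn = 1.39, Cu = 1.32, Ni = 1.24, Co = 1.26
)

# Bondi van der Waals radii; elements Bondi did not tabulate fall back to
# the commonly used 2.0 default for transition metals / 2.27+ alkali values
VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98, B = 1.92, Se = 1.90,
  Na = 2.27, K = 2.75, Mg = 1.73, Ca = 2.31, Zn = 1.39, Fe = 2.00,
  Mn = 2.00, Cu = 1.40, Ni = 1.63, Co = 2.00
)

METAL_ELEMENTS <- c("Na", "K", "Mg", "Ca", "Zn", "Fe", "Mn", "Cu", "Ni", "Co")

# scale factors applied to the covalent-radius sum to obtain a reference
# bond length for higher bond orders (aromatic treated as order 1.5)
BOND_ORDER_SCALE <- c(`1` = 1.00, `1.5` = 0.93, `2` = 0.87, `3` = 0.78)

# heavy-atom valence ceilings used by the sanitization check; a positive
# formal charge raises the ceiling for N by one, a negative charge lowers
# the expected bonding electron count for O by one
MAX_VALENCE <- c(C = 4, N = 3, O = 2, S = 6, P = 5, F = 1, Cl = 1, Br = 1,
                 I = 1, B = 3, Se = 2, H = 1)

vdw_radius <- function(element) {
  r <- VDW_RADII[element]
  r[is.na(r)] <- 2.0
  unname(r)
}

covalent_radius <- function(element) {
  r <- COVALENT_RADII[element]
  if (anyNA(r)) stop("unknown element(s): ",
                     paste(unique(element[is.na(r)]), collapse = ", "),
                     call. = FALSE)
  unname(r)
}

is_metal <- function(element) element %in% METAL_ELEMENTS

reference_bond_length <- function(el1, el2, order) {
  key <- as.character(order)
  sc <- BOND_ORDER_SCALE[key]
  sc[is.na(sc)] <- 1
  (covalent_radius(el1) + covalent_radius(el2)) * unname(sc)
}

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")
AA1 <- setNames(names(AA3), AA3)

aa_one_letter <- function(residue_name) {
  out <- AA1[residue_name]
  out[is.na(out)] <- "X"
  unname(out)
}

# --- protein-side interaction chemistry, keyed on (residue, atom name) ----

# hydrogen-bond donor heavy atoms (carry at least one H in the standard
# protonation state); backbone N of every residue is a donor
PROTEIN_DONORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", TRP = "NE1",
  ASN = "ND2", GLN = "NE2", LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2")
)

# hydrogen-bond acceptor heavy atoms; backbone O of every residue accepts
PROTEIN_ACCEPTORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = "OD1", GLN = "OE1", HIS = c("ND1", "NE2"), MET = "SD"
)

# formally charged side-chain groups: the atoms whose mean position is the
# charge center used by ionic / cation-pi rules
PROTEIN_CATIONS <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ"
)
PROTEIN_ANIONS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")
)

# aromatic side-chain ring atoms (rings used for pi-stacking rules)
PROTEIN_RINGS <- list(
  PHE = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
  TYR = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
  HIS = list(c("CG", "ND1", "CE1", "NE2", "CD2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CE2", "CD2", "CE3", "CZ3", "CH2", "CZ2"))
)

backbone_atom <- function(atom_name) atom_name %in% c("N", "CA", "C", "O", "OXT")
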