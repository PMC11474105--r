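#' Idealized residue geometry tables
#'
#' Static per-residue templates of idealized bond lengths, bond angles and
#' chi-axis definitions used for all-atom reconstruction, for the structural
#' violation loss, and for building synthetic fixtures. Values are idealized
#' protein stereochemistry rounded from standard crystallographic restraint
#' dictionaries (Engh & Huber-style targets); they are a package asset, and
#' aromatic rings use exactly regular geometry so that ring closure is exact.
#' All angles in the tables are degrees; all lengths Angstrom.
#'
#' @name chem_tables
#' @keywords internal
NULL

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

#' @rdname chem_tables
#' @param code one-letter amino-acid code(s).
#' @export
aa_three <- function(code) {
  out <- AA3[code]
  if (anyNA(out)) stop("unknown residue code(s): ",
                       paste(unique(code[is.na(out)]), collapse = ", "))
  unname(out)
}

#' @rdname chem_tables
#' @param three three-letter code(s).
#' @export
aa_one <- function(three) {
  m <- names(AA3)[match(toupper(three), AA3)]
  m[is.na(m)] <- "X"
  m
}

# Backbone ideal constants (Angstrom / degrees)
backbone_ideal <- function() {
  list(n_ca = 1.458, ca_c = 1.525, c_o = 1.231, c_n = 1.329,
       ang_n_ca_c = 111.0, ang_ca_c_o = 120.8, ang_ca_c_n = 116.2,
       ang_c_n_ca = 121.7, omega = 180)
}

# Canonical local backbone coordinates in the residue frame
# (x along CA->C, y toward N; see frames_from_backbone).
backbone_local_coords <- function() {
  bi <- backbone_ideal()
  a <- bi$ang_n_ca_c * pi / 180
  rbind(N  = c(bi$n_ca * cos(a), bi$n_ca * sin(a), 0),
        CA = c(0, 0, 0),
        C  = c(bi$ca_c, 0, 0))
}

# Side-chain internal-coordinate templates. Each row places atom `atom` by
# NERF from reference atoms a-b-c at the stated bond length (c-atom), bond
# angle (b-c-atom, degrees) and torsion a-b-c-atom. chi = 0 means the torsion
# is the fixed `offset` (degrees); chi = k means torsion = chi_k + offset.
# The CB row is shared by all non-glycine residues (placed from C, N, CA).
sc_row <- function(atom, a, b, c, bond, angle, chi, offset) {
  data.frame(atom = atom, a = a, b = b, c = c, bond = bond,
             angle = angle, chi = chi, offset = offset,
             stringsAsFactors = FALSE)
}

CB_ROW <- sc_row("CB", "C", "N", "CA", 1.530, 110.5, 0L, 122.6)

SIDECHAIN_TEMPLATES <- local({
  t <- list()
  t$G <- sc_row(character(), character(), character(), character(),
                numeric(), numeric(), integer(), numeric())
  t$A <- CB_ROW
  t$S <- rbind(CB_ROW, sc_row("OG", "N", "CA", "CB", 1.417, 110.8, 1L, 0))
  t$C <- rbind(CB_ROW, sc_row("SG", "N", "CA", "CB", 1.808, 113.8, 1L, 0))
  t$T <- rbind(CB_ROW,
               sc_row("OG1", "N", "CA", "CB", 1.433, 109.6, 1L, 0),
               sc_row("CG2", "N", "CA", "CB", 1.521, 110.5, 1L, -120))
  t$V <- rbind(CB_ROW,
               sc_row("CG1", "N", "CA", "CB", 1.527, 110.5, 1L, 0),
               sc_row("CG2", "N", "CA", "CB", 1.527, 110.5, 1L, 120))
  t$L <- rbind(CB_ROW,
               sc_row("CG", "N", "CA", "CB", 1.530, 116.3, 1L, 0),
               sc_row("CD1", "CA", "CB", "CG", 1.521, 110.7, 2L, 0),
               sc_row("CD2", "CA", "CB", "CG", 1.521, 110.7, 2L, 120))
  t$I <- rbind(CB_ROW,
               sc_row("CG1", "N", "CA", "CB", 1.530, 110.4, 1L, 0),
               sc_row("CG2", "N", "CA", "CB", 1.521, 110.5, 1L, -120),
               sc_row("CD1", "CA", "CB", "CG1", 1.513, 113.9, 2L, 0))
  t$M <- rbind(CB_ROW,
               sc_row("CG", "N", "CA", "CB", 1.520, 114.1, 1L, 0),
               sc_row("SD", "CA", "CB", "CG", 1.803, 112.7, 2L, 0),
               sc_row("CE", "CB", "CG", "SD", 1.791, 100.9, 3L, 0))
  t$P <- rbind(CB_ROW,
               sc_row("CG", "N", "CA", "CB", 1.492, 104.5, 1L, 0),
               sc_row("CD", "CA", "CB", "CG", 1.503, 106.1, 2L, 0))
  ring6 <- function(pre, bonds) {
    rbind(sc_row(paste0(pre, "D1"), "CA", "CB", paste0(pre, "G"), bonds, 120, 2L, 0),
          sc_row(paste0(pre, "D2"), "CA", "CB", paste0(pre, "G"), bonds, 120, 2L, 180),
          sc_row(paste0(pre, "E1"), "CB", paste0(pre, "G"), paste0(pre, "D1"), bonds, 120, 0L, 180),
          sc_row(paste0(pre, "E2"), "CB", paste0(pre, "G"), paste0(pre, "D2"), bonds, 120, 0L, 180),
          sc_row(paste0(pre, "Z"), paste0(pre, "G"), paste0(pre, "D1"), paste0(pre, "E1"), bonds, 120, 0L, 0))
  }
  t$F <- rbind(CB_ROW,
               sc_row("CG", "N", "CA", "CB", 1.502, 113.8, 1L, 0),
               ring6("C", 1.39))
  t$Y <- rbind(CB_ROW,
               sc_row("CG", "N", "CA", "CB", 1.512, 113.9, 1L, 0),
               ring6("C", 1.39),
               sc_row("OH", "CD1", "CE1", "CZ", 1.376, 120, 0L, 180))
  t$W <- rbind(CB_ROW,
               sc_row("CG", "N", "CA", "CB", 1.498, 113.6, 1L, 0),
               sc_row("CD1", "CA", "CB", "CG", 1.363, 126.9, 2L, 0),
               sc_row("CD2", "CA", "CB", "CG", 1.433, 126.8, 2L, 180),
               sc_row("NE1", "CB", "CG", "CD1", 1.375, 110.2, 0L, 180),
               sc_row("CE2", "CB", "CG", "CD2", 1.409, 107.2, 0L, 180),
               sc_row("CE3", "CB", "CG", "CD2", 1.400, 133.9, 0L, 0),
               sc_row("CZ2", "CG", "CD2", "CE2", 1.400, 122.4, 0L, 180),
               sc_row("CZ3", "CG", "CD2", "CE3", 1.400, 118.7, 0L, 180),
               sc_row("CH2", "CD2", "CE2", "CZ2", 1.400, 117.5, 0L, 0))
  t$D <- rbind(CB_ROW,
               sc_row("CG", "N", "CA", "CB", 1.516, 112.6, 1L, 0),
               sc_row("OD1", "CA", "CB", "CG", 1.249, 118.4, 2L, 0),
               sc_row("OD2", "CA", "CB", "CG", 1.249, 118.4, 2L, 180))
  t$N <- rbind(CB_ROW,
               sc_row("CG", "N", "CA", "CB", 1.516, 112.6, 1L, 0),
               sc_row("OD1", "CA", "CB", "CG", 1.231, 120.8, 2L, 0),
               sc_row("ND2", "CA", "CB", "CG", 1.328, 116.4, 2L, 180))
  t$E <- rbind(CB_ROW,
               sc_row("CG", "N", "CA", "CB", 1.520, 114.1, 1L, 0),
               sc_row("CD", "CA", "CB", "CG", 1.516, 112.6, 2L, 0),
               sc_row("OE1", "CB", "CG", "CD", 1.249, 118.4, 3L, 0),
               sc_row("OE2", "CB", "CG", "CD", 1.249, 118.4, 3L, 180))
  t$Q <- rbind(CB_ROW,
               sc_row("CG", "N", "CA", "CB", 1.520, 114.1, 1L, 0),
               sc_row("CD", "CA", "CB", "CG", 1.516, 112.6, 2L, 0),
               sc_row("OE1", "CB", "CG", "CD", 1.231, 120.8, 3L, 0),
               sc_row("NE2", "CB", "CG", "CD", 1.328, 116.4, 3L, 180))
  t$K <- rbind(CB_ROW,
               sc_row("CG", "N", "CA", "CB", 1.520, 114.1, 1L, 0),
               sc_row("CD", "CA", "CB", "CG", 1.520, 111.3, 2L, 0),
               sc_row("CE", "CB", "CG", "CD", 1.508, 111.3, 3L, 0),
               sc_row("NZ", "CG", "CD", "CE", 1.489, 111.5, 4L, 0))
  t$R <- rbind(CB_ROW,
               sc_row("CG", "N", "CA", "CB", 1.520, 114.1, 1L, 0),
               sc_row("CD", "CA", "CB", "CG", 1.520, 111.3, 2L, 0),
               sc_row("NE", "CB", "CG", "CD", 1.461, 112.0, 3L, 0),
               sc_row("CZ", "CG", "CD", "NE", 1.329, 124.2, 4L, 0),
               sc_row("NH1", "CD", "NE", "CZ", 1.326, 120.0, 0L, 0),
               sc_row("NH2", "CD", "NE", "CZ", 1.326, 120.0, 0L, 180))
  t$H <- rbind(CB_ROW,
               sc_row("CG", "N", "CA", "CB", 1.497, 113.8, 1L, 0),
               sc_row("ND1", "CA", "CB", "CG", 1.371, 122.7, 2L, 0),
               sc_row("CD2", "CA", "CB", "CG", 1.356, 131.2, 2L, 180),
               sc_row("CE1", "CB", "CG", "ND1", 1.319, 109.0, 0L, 180),
               sc_row("NE2", "CB", "CG", "CD2", 1.374, 107.2, 0L, 180))
  t
})

#' @rdname chem_tables
#' @export
sidechain_template <- function(code) {
  tpl <- SIDECHAIN_TEMPLATES[[code]]
  if (is.null(tpl)) stop("unknown residue type: '", code, "'")
  tpl
}

# chi dihedral definitions: list of atom quadruples per residue type
CHI_ATOMS <- local({
  g <- function(...) list(...)
  chi1 <- function(x) c("N", "CA", "CB", x)
  list(
    G = g(), A = g(),
    S = g(chi1("OG")), C = g(chi1("SG")), T = g(chi1("OG1")),
    V = g(chi1("CG1")),
    L = g(chi1("CG"), c("CA", "CB", "CG", "CD1")),
    I = g(chi1("CG1"), c("CA", "CB", "CG1", "CD1")),
    M = g(chi1("CG"), c("CA", "CB", "CG", "SD"), c("CB", "CG", "SD", "CE")),
    P = g(chi1("CG"), c("CA", "CB", "CG", "CD")),
    F = g(chi1("CG"), c("CA", "CB", "CG", "CD1")),
    Y = g(chi1("CG"), c("CA", "CB", "CG", "CD1")),
    W = g(chi1("CG"), c("CA", "CB", "CG", "CD1")),
    D = g(chi1("CG"), c("CA", "CB", "CG", "OD1")),
    N = g(chi1("CG"), c("CA", "CB", "CG", "OD1")),
    H = g(chi1("CG"), c("CA", "CB", "CG", "ND1")),
    E = g(chi1("CG"), c("CA", "CB", "CG", "CD"), c("CB", "CG", "CD", "OE1")),
    Q = g(chi1("CG"), c("CA", "CB", "CG", "CD"), c("CB", "CG", "CD", "OE1")),
    K = g(chi1("CG"), c("CA", "CB", "CG", "CD"), c("CB", "CG", "CD", "CE"),
          c("CG", "CD", "CE", "NZ")),
    R = g(chi1("CG"), c("CA", "CB", "CG", "CD"), c("CB", "CG", "CD", "NE"),
          c("CG", "CD", "NE", "CZ"))
  )
})

#' @rdname chem_tables
#' @export
chi_atoms <- function(code) {
  out <- CHI_ATOMS[[code]]
  if (is.null(out)) stop("unknown residue type: '", code, "'")
  out
}

#' @rdname chem_tables
#' @export
n_chi <- function(code) lengths(CHI_ATOMS[code])

# chis whose terminal group is 180-degree symmetric: measuring the rebuilt
# side chain can return chi or chi + pi; the torsion loss accepts either branch
CHI_PI_SYMMETRIC <- list(D = c(FALSE, TRUE), E = c(FALSE, FALSE, TRUE),
                         F = c(FALSE, TRUE), Y = c(FALSE, TRUE))

#' @rdname chem_tables
#' @export
chi_symmetric <- function(code) {
  out <- CHI_PI_SYMMETRIC[[code]]
  if (is.null(out)) out <- rep(FALSE, n_chi(code))
  out
}

# van der Waals radii by element (Angstrom), for the clash term
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

atom_element <- function(atom) substr(atom, 1, 1)

atom_radius <- function(atom) {
  r <- VDW_RADII[atom_element(atom)]
  r[is.na(r)] <- 1.70
  unname(r)
}
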