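#' Antibody Fv structure records
#'
#' An `fv_structure` holds one paired heavy/light variable domain: per-residue
#' chain id (`"H"` or `"L"`), one-letter sequence, IMGT number plus insertion
#' code, region label (one of the eight CDR/framework regions), and a long
#' atom table with coordinates in Angstrom. Presence of an atom row is the
#' atom mask: an absent atom simply has no row.
#'
#' @param chain character vector of `"H"`/`"L"` per residue, heavy block first.
#' @param sequence character vector of one-letter amino-acid codes per residue.
#' @param imgt integer IMGT number per residue.
#' @param imgt_ins insertion code per residue (`""` if none).
#' @param region per-residue region label; if `NULL`, derived from `imgt` and
#'   `chain` via [assign_imgt_regions()].
#' @param atoms a data frame with columns `res` (residue index), `atom`
#'   (PDB atom name, e.g. `"CA"`), `x`, `y`, `z` and optionally `b` (B-factor).
#' @return an object of class `fv_structure`.
#' @export
fv_structure <- function(chain, sequence, imgt, imgt_ins = NULL, region = NULL,
                         atoms) {
  n <- length(chain)
  if (is.null(imgt_ins)) imgt_ins <- rep("", n)
  stopifnot(length(sequence) == n, length(imgt) == n, length(imgt_ins) == n)
  if (!all(chain %in% c("H", "L"))) {
    stop("chain ids must be 'H' or 'L' (single paired Fv)")
  }
  if (!all(c("H", "L") %in% chain)) {
    stop("a paired Fv requires both an H and an L chain")
  }
  if (any(diff(match(chain, c("H", "L"))) < 0)) {
    stop("residues must be ordered heavy chain first, then light chain")
  }
  if (is.null(region)) {
    region <- imgt_region_of(imgt, chain)
  }
  region <- as.character(region)
  bad <- setdiff(unique(region), region_levels())
  if (length(bad)) stop("unknown region label(s): ", paste(bad, collapse = ", "))
  atoms <- as.data.frame(atoms)
  stopifnot(all(c("res", "atom", "x", "y", "z") %in% names(atoms)))
  if (!"b" %in% names(atoms)) atoms$b <- 0
  if (nrow(atoms) && (max(atoms$res) > n || min(atoms$res) < 1)) {
    stop("atom table refers to residues outside 1..", n)
  }
  # backbone completeness: a residue with any backbone atom must carry N, CA, C
  bb <- atoms[atoms$atom %in% c("N", "CA", "C"), ]
  if (nrow(bb)) {
    cnt <- table(factor(bb$res, levels = seq_len(n)), factor(bb$atom, levels = c("N", "CA", "C")))
    partial <- rowSums(cnt > 0)
    if (any(partial > 0 & partial < 3)) {
      stop("residue(s) with incomplete backbone (need N, CA, C): ",
           paste(which(partial > 0 & partial < 3), collapse = ", "))
    }
  }
  structure(list(chain = as.character(chain), sequence = as.character(sequence),
                 imgt = as.integer(imgt), imgt_ins = as.character(imgt_ins),
                 region = region, atoms = atoms),
            class = "fv_structure")
}

#' @export
length.fv_structure <- function(x) length(x$chain)

#' @export
print.fv_structure <- function(x, ...) {
  cat("<fv_structure> ", length(x), " residues (H: ", sum(x$chain == "H"),
      ", L: ", sum(x$chain == "L"), "), ", nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' The eight variable-domain region labels
#'
#' CDR1-3 and the framework of each chain, matching the columns of a standard
#' per-region accuracy report.
#' @return character vector of the eight labels.
#' @export
region_levels <- function() {
  c("CDRH1", "CDRH2", "CDRH3", "FWH", "CDRL1", "CDRL2", "CDRL3", "FWL")
}

#' Extract per-residue coordinates of one atom type
#'
#' @param record an `fv_structure`.
#' @param atom atom name, e.g. `"CA"`.
#' @return an `n x 3` matrix with `NA` rows where the atom is absent.
#' @export
atom_coords <- function(record, atom = "CA") {
  n <- length(record)
  out <- matrix(NA_real_, n, 3)
  sel <- record$atoms[record$atoms$atom == atom, ]
  out[sel$res, ] <- as.matrix(sel[, c("x", "y", "z")])
  out
}

#' @rdname atom_coords
#' @param atoms_wanted which backbone atoms to stack (in residue-major order).
#' @return `backbone_coords`: a matrix of stacked backbone atom coordinates
#'   with attributes `res` (residue index per row) and `atom` (name per row);
#'   rows are ordered residue-by-residue. Residues missing any requested atom
#'   are dropped from the stack.
#' @export
backbone_coords <- function(record, atoms_wanted = c("N", "CA", "C")) {
  sel <- record$atoms[record$atoms$atom %in% atoms_wanted, ]
  sel <- sel[order(sel$res, match(sel$atom, atoms_wanted)), ]
  keep <- stats::ave(seq_len(nrow(sel)), sel$res, FUN = length) == length(atoms_wanted)
  sel <- sel[keep, ]
  out <- as.matrix(sel[, c("x", "y", "z")])
  attr(out, "res") <- sel$res
  attr(out, "atom") <- sel$atom
  out
}

#' Apply a global rigid transform to a structure
#'
#' @param record an `fv_structure`.
#' @param transform a single-frame `rigid`.
#' @return the transformed `fv_structure`.
#' @export
transform_structure <- function(record, transform) {
  stopifnot(length(transform) == 1L)
  xyz <- as.matrix(record$atoms[, c("x", "y", "z")])
  xyz <- rigid_apply(transform, xyz)
  record$atoms$x <- xyz[, 1]; record$atoms$y <- xyz[, 2]; record$atoms$z <- xyz[, 3]
  record
}

#' Set per-residue B-factors (e.g. pLDDT) on all atoms of each residue
#'
#' @param record an `fv_structure`.
#' @param values numeric vector, one per residue.
#' @return the updated record.
#' @export
set_bfactor <- function(record, values) {
  stopifnot(length(values) == length(record))
  record$atoms$b <- values[record$atoms$res]
  record
}
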