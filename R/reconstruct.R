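#' Per-residue chi-angle sets
#'
#' A `torsion_set` stores side-chain chi angles chi1..chi4 per residue as an
#' `n x 4` matrix in radians, masked by residue type: entries beyond the
#' canonical chi count of a residue are `NA` and the logical `mask` matrix
#' marks which angles exist. Angles are reported in (-pi, pi].
#'
#' @param chi `n x 4` numeric matrix of chi angles (radians), `NA` where absent.
#' @param mask `n x 4` logical matrix; must match the `NA` pattern of `chi`.
#' @return an object of class `torsion_set`.
#' @export
torsion_set <- function(chi, mask = !is.na(chi)) {
  chi <- as.matrix(chi); mask <- as.matrix(mask)
  stopifnot(ncol(chi) == 4L, all(dim(chi) == dim(mask)))
  if (any(is.na(chi) & mask)) stop("masked-present chi angles must not be NA")
  ok <- chi[mask]
  if (length(ok) && (any(ok <= -pi - 1e-12) || any(ok > pi + 1e-12))) {
    stop("chi angles must lie in (-pi, pi]")
  }
  structure(list(chi = chi, mask = mask), class = "torsion_set")
}

#' @rdname torsion_set
#' @param sequence one-letter codes; used to validate the mask against the
#'   canonical chi count per residue type.
#' @export
validate_torsion_mask <- function(x, sequence) {
  expected <- n_chi(sequence)
  got <- rowSums(x$mask)
  if (any(got != expected)) {
    stop("chi mask inconsistent with residue types at residue(s): ",
         paste(which(got != expected), collapse = ", "))
  }
  invisible(x)
}

wrap_angle <- function(a) {
  a <- atan2(sin(a), cos(a))
  ifelse(a <= -pi, pi, a)
}

#' Measure side-chain chi angles on a structure
#'
#' @param record an `fv_structure` with side-chain atoms.
#' @return a `torsion_set`; angles are `NA` where the defining atoms are
#'   missing or the residue type carries no such chi.
#' @export
measure_torsions <- function(record) {
  n <- length(record)
  chi <- matrix(NA_real_, n, 4)
  mask <- matrix(FALSE, n, 4)
  coords <- split(record$atoms, record$atoms$res)
  for (i in seq_len(n)) {
    defs <- CHI_ATOMS[[record$sequence[i]]]
    if (is.null(defs) || !length(defs)) next
    at <- coords[[as.character(i)]]
    if (is.null(at)) next
    pos <- function(nm) {
      row <- at[at$atom == nm, , drop = FALSE]
      if (!nrow(row)) return(NULL)
      as.numeric(row[1, c("x", "y", "z")])
    }
    for (k in seq_along(defs)) {
      ps <- lapply(defs[[k]], pos)
      if (any(vapply(ps, is.null, logical(1)))) next
      chi[i, k] <- dihedral(ps[[1]], ps[[2]], ps[[3]], ps[[4]])
      mask[i, k] <- TRUE
    }
  }
  torsion_set(chi, mask)
}

#' Rebuild all side-chain atoms from backbone + chi angles
#'
#' Places CB and every side-chain atom by rotating idealized rigid groups
#' about the chi axes (NERF placement from the idealized template tables).
#' Bond lengths and angles internal to each rigid group match the template
#' exactly, and re-measuring chi on the output recovers the input torsions.
#' Existing non-backbone atoms are discarded and rebuilt.
#'
#' @param record an `fv_structure` with backbone atoms (N, CA, C; O kept
#'   if present).
#' @param torsions a `torsion_set` with masks consistent with the sequence
#'   (see [validate_torsion_mask()]).
#' @return an `fv_structure` with full side chains.
#' @export
reconstruct_all_atom <- function(record, torsions) {
  validate_torsion_mask(torsions, record$sequence)
  n <- length(record)
  keep <- record$atoms[record$atoms$atom %in% c("N", "CA", "C", "O"), ]
  new_rows <- vector("list", n)
  for (i in seq_len(n)) {
    code <- record$sequence[i]
    tpl <- sidechain_template(code)  # errors on unknown residue type
    if (!nrow(tpl)) next
    at <- keep[keep$res == i, ]
    placed <- stats::setNames(
      lapply(seq_len(nrow(at)), function(r) as.numeric(at[r, c("x", "y", "z")])),
      at$atom)
    for (r in seq_len(nrow(tpl))) {
      row <- tpl[r, ]
      tors <- row$offset * pi / 180
      if (row$chi > 0) {
        if (!torsions$mask[i, row$chi]) {
          stop("residue ", i, " (", code, ") needs chi", row$chi,
               " but the torsion set masks it absent")
        }
        tors <- tors + torsions$chi[i, row$chi]
      }
      placed[[row$atom]] <- nerf_place(placed[[row$a]], placed[[row$b]],
                                       placed[[row$c]], row$bond,
                                       row$angle * pi / 180, tors)
    }
    sc <- tpl$atom
    new_rows[[i]] <- data.frame(res = i, atom = sc,
                                x = vapply(placed[sc], `[`, 0, 1),
                                y = vapply(placed[sc], `[`, 0, 2),
                                z = vapply(placed[sc], `[`, 0, 3),
                                b = 0, stringsAsFactors = FALSE)
  }
  atoms <- rbind(keep, do.call(rbind, new_rows))
  atoms <- atoms[order(atoms$res), ]
  rownames(atoms) <- NULL
  fv_structure(record$chain, record$sequence, record$imgt, record$imgt_ins,
               record$region, atoms)
}
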