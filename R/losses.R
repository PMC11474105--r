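#' Region-dependent FAPE clamp matrix
#'
#' The FAPE loss is clamped at 30 Angstrom for residue pairs where exactly one
#' residue lies in a CDR and the other in framework, and at 10 Angstrom
#' otherwise (CDR-CDR and framework-framework): long-range CDR/framework
#' geometry is allowed a wider error band before the loss saturates.
#'
#' @param regions per-residue region labels (see [region_levels()]).
#' @param cdr_fw_clamp,other_clamp clamp values in Angstrom.
#' @param Z normalisation scale in Angstrom (a single documented scale,
#'   independent of the clamp).
#' @return a list of class `clamp_spec` with the `n x n` clamp matrix and `Z`.
#' @export
build_clamp_matrix <- function(regions, cdr_fw_clamp = 30, other_clamp = 10,
                               Z = 10) {
  is_cdr <- grepl("^CDR", regions)
  mixed <- outer(is_cdr, is_cdr, "!=")
  clamp <- ifelse(mixed, cdr_fw_clamp, other_clamp)
  structure(list(clamp = clamp, Z = Z), class = "clamp_spec")
}

#' Frame-aligned point error
#'
#' Mean over (frame i, point j) of `min(||x_ij_pred - x_ij_true||, clamp_ij) / Z`
#' where `x_ij` is point `j` expressed in residue `i`'s local frame. Zero iff
#' the prediction equals the truth up to a global rigid transform applied to
#' frames and points jointly; invariant under independent global transforms of
#' prediction and truth.
#'
#' @param pred_frames,true_frames `rigid` objects with one frame per residue.
#' @param pred_points,true_points `m x 3` point matrices (Angstrom).
#' @param clamp a `clamp_spec` from [build_clamp_matrix()], a numeric clamp
#'   (recycled), or `NULL` for unclamped.
#' @param point_res optional residue index per point row, used to pick the
#'   clamp entry for (frame residue, point residue) pairs; defaults to
#'   identifying point `j` with residue `j`.
#' @param Z normalisation scale (Angstrom); ignored when `clamp` is a
#'   `clamp_spec` (which carries its own `Z`).
#' @param eps numerical floor inside the square root.
#' @return non-negative scalar (dimensionless).
#' @export
fape <- function(pred_frames, pred_points, true_frames, true_points,
                 clamp = NULL, point_res = NULL, Z = 10, eps = 1e-12) {
  check_rigid(pred_frames); check_rigid(true_frames)
  n <- length(pred_frames)
  if (length(true_frames) != n) stop("frame counts differ")
  pred_points <- as.matrix(pred_points); true_points <- as.matrix(true_points)
  if (!all(dim(pred_points) == dim(true_points))) stop("point counts differ")
  m <- nrow(pred_points)
  if (is.null(point_res)) point_res <- seq_len(m)
  local_mat <- function(frames, points) {
    # D[i, j] = || R_i^T (p_j - t_i) || components; build n x m per coordinate
    inv <- rigid_invert(frames)
    lx <- matrix(0, n, m); ly <- lx; lz <- lx
    for (i in seq_len(n)) {
      p <- points %*% t(inv$R[, , i])
      p <- sweep(p, 2, inv$t[i, ], "+")
      lx[i, ] <- p[, 1]; ly[i, ] <- p[, 2]; lz[i, ] <- p[, 3]
    }
    list(x = lx, y = ly, z = lz)
  }
  P <- local_mat(pred_frames, pred_points)
  T <- local_mat(true_frames, true_points)
  d <- sqrt((P$x - T$x)^2 + (P$y - T$y)^2 + (P$z - T$z)^2 + eps)
  if (inherits(clamp, "clamp_spec")) {
    Z <- clamp$Z
    cmat <- clamp$clamp[, point_res, drop = FALSE]
    d <- pmin(d, cmat)
  } else if (!is.null(clamp)) {
    d <- pmin(d, clamp)
  }
  mean(d) / Z
}

#' Trajectory FAPE: per-block backbone term plus final all-atom term
#'
#' The training FAPE is the sum of (a) the average, over update blocks, of the
#' backbone FAPE of each block's frames against the truth, and (b) the
#' all-atom FAPE of the final reconstructed structure. Backbone points per
#' block are the N, CA, C atoms implied by that block's frames (canonical
#' local coordinates pushed through the frames).
#'
#' @param traj a list of `rigid` frame sets, one per block (a `trajectory`'s
#'   `frames` element).
#' @param final_record the final all-atom `fv_structure` prediction.
#' @param truth the reference `fv_structure`.
#' @param clamp a `clamp_spec` over residues (see [build_clamp_matrix()]).
#' @return list with `backbone_fape` and `final_fape`.
#' @export
total_fape <- function(traj, final_record, truth, clamp) {
  if (!length(traj)) stop("empty trajectory")
  true_frames <- frames_from_backbone(truth)
  n <- length(true_frames)
  bl <- backbone_local_coords()
  true_bb <- backbone_coords(truth, c("N", "CA", "C"))
  bb_res <- attr(true_bb, "res")
  per_block <- vapply(traj, function(frames) {
    pred_bb <- do.call(rbind, lapply(seq_len(n), function(i) {
      rigid_apply(frames[i], bl)
    }))
    fape(frames, pred_bb, true_frames, true_bb, clamp = clamp,
         point_res = rep(seq_len(n), each = 3))
  }, 0)
  # final all-atom term: atoms present in both structures, frames from the
  # final backbone
  key_p <- paste(final_record$atoms$res, final_record$atoms$atom)
  key_t <- paste(truth$atoms$res, truth$atoms$atom)
  common <- intersect(key_p, key_t)
  ap <- final_record$atoms[match(common, key_p), ]
  at <- truth$atoms[match(common, key_t), ]
  final <- fape(frames_from_backbone(final_record),
                as.matrix(ap[, c("x", "y", "z")]),
                true_frames, as.matrix(at[, c("x", "y", "z")]),
                clamp = clamp, point_res = ap$res)
  list(backbone_fape = mean(per_block), final_fape = final)
}

#' Side-chain torsion loss
#'
#' Per valid chi angle, the minimum over the true angle and its alternate
#' (pi-flipped for 180-degree-symmetric terminal groups) of the Euclidean
#' distance between unit (sin, cos) vectors, averaged over valid angles, plus
#' a norm regulariser pulling the raw (sin, cos) outputs toward unit norm.
#' Invariant under 2 pi shifts of the true angles.
#'
#' @param pred_sincos `n x 4 x 2` array of raw (sin, cos) network outputs.
#' @param true,alt_true `torsion_set`s with identical masks; `alt_true`
#'   defaults to `true`.
#' @param norm_weight weight of the norm regulariser (default 0.02).
#' @return non-negative scalar.
#' @export
torsion_angle_loss <- function(pred_sincos, true, alt_true = NULL,
                               norm_weight = 0.02) {
  if (is.null(alt_true)) alt_true <- true
  if (!identical(dim(true$mask), dim(alt_true$mask)) ||
      any(true$mask != alt_true$mask)) stop("mask mismatch")
  mask <- true$mask
  if (!any(mask)) return(0)
  s <- pred_sincos[, , 1]; cs <- pred_sincos[, , 2]
  norm <- sqrt(s^2 + cs^2 + 1e-12)
  us <- s / norm; uc <- cs / norm
  d2 <- function(ang) (us - sin(ang))^2 + (uc - cos(ang))^2
  angle_term <- pmin(d2(true$chi), d2(alt_true$chi))
  mean_angle <- mean(sqrt(angle_term[mask] + 1e-12))
  mean_norm <- mean(abs(norm[mask] - 1))
  mean_angle + norm_weight * mean_norm
}

#' Structural violation loss
#'
#' Flat-bottom penalties on (a) bond lengths deviating from the idealized
#' template beyond a tolerance, for intra-residue template bonds and peptide
#' bonds, (b) bond angles likewise, and (c) non-bonded interatomic clashes
#' when the distance falls below the sum of van der Waals radii minus a
#' tolerance. Exactly zero on template-built geometry.
#'
#' @param record an all-atom (or backbone) `fv_structure`.
#' @param bond_tol_sd tolerance in standard deviations of literature bond
#'   statistics (default 12; sigma = 0.016 Angstrom for bonds, 1.6 degrees
#'   for angles).
#' @param clash_tol clash tolerance in Angstrom (default 1.5).
#' @param per_component return the three components separately.
#' @return non-negative scalar, or a named list when `per_component`.
#' @export
violation_loss <- function(record, bond_tol_sd = 12, clash_tol = 1.5,
                           per_component = FALSE) {
  sigma_bond <- 0.016; sigma_angle <- 1.6 * pi / 180
  tol_b <- bond_tol_sd * sigma_bond
  tol_a <- bond_tol_sd * sigma_angle
  bi <- backbone_ideal()
  n <- length(record)
  at <- record$atoms
  pos <- function(i, nm) {
    row <- at[at$res == i & at$atom == nm, , drop = FALSE]
    if (!nrow(row)) return(NULL)
    as.numeric(row[1, c("x", "y", "z")])
  }
  has_bb <- vapply(seq_len(n), function(i) {
    !is.null(pos(i, "N")) && !is.null(pos(i, "CA")) && !is.null(pos(i, "C"))
  }, TRUE)
  if (!all(has_bb)) stop("missing backbone atoms at residue(s): ",
                         paste(which(!has_bb), collapse = ", "))
  bond_excess <- 0; angle_excess <- 0
  add_bond <- function(p, q, ideal) {
    d <- sqrt(sum((p - q)^2))
    max(0, abs(d - ideal) - tol_b)
  }
  ang_of <- function(p, q, r) {
    u <- p - q; v <- r - q
    acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
  }
  add_angle <- function(p, q, r, ideal_deg) {
    max(0, abs(ang_of(p, q, r) - ideal_deg * pi / 180) - tol_a)
  }
  for (i in seq_len(n)) {
    Np <- pos(i, "N"); CAp <- pos(i, "CA"); Cp <- pos(i, "C"); Op <- pos(i, "O")
    bond_excess <- bond_excess + add_bond(Np, CAp, bi$n_ca) +
      add_bond(CAp, Cp, bi$ca_c)
    angle_excess <- angle_excess + add_angle(Np, CAp, Cp, bi$ang_n_ca_c)
    if (!is.null(Op)) {
      bond_excess <- bond_excess + add_bond(Cp, Op, bi$c_o)
      angle_excess <- angle_excess + add_angle(CAp, Cp, Op, bi$ang_ca_c_o)
    }
    # template side-chain bonds/angles for atoms actually present
    tpl <- SIDECHAIN_TEMPLATES[[record$sequence[i]]]
    if (!is.null(tpl) && nrow(tpl)) {
      for (r in seq_len(nrow(tpl))) {
        dq <- pos(i, tpl$atom[r])
        if (is.null(dq)) next
        cq <- pos(i, tpl$c[r]); bq <- pos(i, tpl$b[r])
        if (is.null(cq) || is.null(bq)) next
        bond_excess <- bond_excess + add_bond(cq, dq, tpl$bond[r])
        angle_excess <- angle_excess + add_angle(bq, cq, dq, tpl$angle[r])
      }
    }
    # peptide bond to the next residue of the same chain
    if (i < n && record$chain[i + 1] == record$chain[i]) {
      Nn <- pos(i + 1, "N"); CAn <- pos(i + 1, "CA")
      bond_excess <- bond_excess + add_bond(Cp, Nn, bi$c_n)
      angle_excess <- angle_excess + add_angle(CAp, Cp, Nn, bi$ang_ca_c_n) +
        add_angle(Cp, Nn, CAn, bi$ang_c_n_ca)
    }
  }
  # non-bonded clashes: atoms of different residues, excluding the peptide
  # C(i)-N(i+1) pair
  xyz <- as.matrix(at[, c("x", "y", "z")])
  radii <- atom_radius(at$atom)
  dm <- as.matrix(stats::dist(xyz))
  lim <- outer(radii, radii, "+") - clash_tol
  same_res <- outer(at$res, at$res, "==")
  pept <- outer(at$res, at$res, function(a, b) abs(a - b) == 1) &
    ((outer(at$atom == "C", at$atom == "N") & outer(at$res, at$res, "<")) |
       (outer(at$atom == "N", at$atom == "C") & outer(at$res, at$res, ">")))
  viol <- pmax(lim - dm, 0)
  viol[same_res | pept] <- 0
  diag(viol) <- 0
  clash_excess <- sum(viol) / 2
  if (per_component) {
    list(bond = bond_excess, angle = angle_excess, clash = clash_excess)
  } else {
    bond_excess + angle_excess + clash_excess
  }
}

#' pLDDT cross-entropy loss
#'
#' Cross-entropy between the predicted bin distribution and the one-hot bin
#' containing the true per-residue lDDT, averaged over residues. Bin edges are
#' equal-width on `[0, 1]`, left-closed, with the last bin right-closed: the
#' bin index of lDDT `l` with `K` bins is `floor(l K)` capped at `K - 1`.
#'
#' @param pred an `n x K` bin-probability matrix (`bin_distribution`).
#' @param true_lddt numeric vector in `[0, 1]` per residue.
#' @return non-negative scalar.
#' @export
plddt_loss <- function(pred, true_lddt) {
  pred <- unclass_bins(pred)
  if (any(true_lddt < 0 | true_lddt > 1)) stop("lDDT values must lie in [0, 1]")
  if (length(true_lddt) != nrow(pred)) stop("length mismatch")
  K <- ncol(pred)
  idx <- pmin(floor(true_lddt * K), K - 1) + 1
  -mean(log(pred[cbind(seq_len(nrow(pred)), idx)] + 1e-300))
}

#' Loss weights and stage combination
#'
#' Stage 1 optimises the FAPE and torsion terms (plus the pLDDT cross-entropy
#' at weight 0.01); stage 2 adds the structural violation term and is run at a
#' fixed learning rate. Weights are exposed so either scheme can be adjusted.
#'
#' @param backbone_fape,final_fape,torsion,violation,plddt_ce component weights.
#' @return a named numeric vector of weights.
#' @export
loss_weights <- function(backbone_fape = 1, final_fape = 1, torsion = 1,
                         violation = 1, plddt_ce = 0.01) {
  c(backbone_fape = backbone_fape, final_fape = final_fape, torsion = torsion,
    violation = violation, plddt_ce = plddt_ce)
}

#' @rdname loss_weights
#' @param parts named list/vector with components `backbone_fape`,
#'   `final_fape`, `torsion`, `violation`, `plddt_ce`.
#' @param stage 1 or 2; the violation term only enters in stage 2.
#' @param weights from [loss_weights()].
#' @return the combined scalar total.
#' @export
combine_losses <- function(parts, stage = 1, weights = loss_weights()) {
  stopifnot(stage %in% c(1, 2))
  p <- function(nm) if (is.null(parts[[nm]])) 0 else parts[[nm]]
  total <- weights["backbone_fape"] * p("backbone_fape") +
    weights["final_fape"] * p("final_fape") +
    weights["torsion"] * p("torsion") +
    weights["plddt_ce"] * p("plddt_ce")
  if (stage == 2) total <- total + weights["violation"] * p("violation")
  unname(total)
}
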