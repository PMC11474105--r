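#' lDDT-CA configuration
#'
#' Defaults follow the standard per-residue lDDT definition: a 15 Angstrom
#' inclusion radius measured on the TRUE structure, preserved-distance
#' thresholds 0.5/1/2/4 Angstrom, CA atoms only, strict inequalities at both
#' the radius and the thresholds. Cross-chain pairs count by default (the Fv
#' is one assembly); set `within_chain_only` to restrict.
#'
#' @param inclusion_radius Angstrom (default 15).
#' @param thresholds ascending positive Angstrom vector (default 0.5, 1, 2, 4).
#' @param within_chain_only logical.
#' @return a list of class `lddt_config`.
#' @export
lddt_config <- function(inclusion_radius = 15, thresholds = c(0.5, 1, 2, 4),
                        within_chain_only = FALSE) {
  stopifnot(inclusion_radius > 0, all(thresholds > 0),
            !is.unsorted(thresholds, strictly = TRUE))
  structure(list(inclusion_radius = inclusion_radius, thresholds = thresholds,
                 within_chain_only = within_chain_only), class = "lddt_config")
}

#' Per-residue lDDT-CA
#'
#' Superposition-free local accuracy: for residue `i`, over all pairs `(i, j)`
#' with `j != i` whose TRUE CA-CA distance is below the inclusion radius, the
#' fraction of pairs whose predicted distance deviates by less than each
#' threshold, averaged over the thresholds. Invariant to rigid transforms of
#' either structure. Residues with no in-radius partner return `NA`.
#'
#' @param pred,true `fv_structure` objects over the same residue set, or
#'   `n x 3` CA coordinate matrices.
#' @param cfg an [lddt_config()].
#' @return numeric vector in `[0, 1]` per residue.
#' @export
lddt_ca <- function(pred, true, cfg = lddt_config()) {
  chain <- NULL
  if (inherits(pred, "fv_structure")) {
    if (length(pred) != length(true)) stop("mismatched residue sets")
    chain <- true$chain
    pred <- atom_coords(pred, "CA"); true <- atom_coords(true, "CA")
  }
  if (anyNA(pred) || anyNA(true)) stop("missing CA coordinates")
  if (!all(dim(pred) == dim(true))) stop("mismatched residue sets")
  n <- nrow(true)
  dt <- as.matrix(stats::dist(true))
  dp <- as.matrix(stats::dist(pred))
  include <- dt < cfg$inclusion_radius
  diag(include) <- FALSE
  if (cfg$within_chain_only && !is.null(chain)) {
    include <- include & outer(chain, chain, "==")
  }
  dev <- abs(dp - dt)
  out <- numeric(n)
  for (i in seq_len(n)) {
    js <- which(include[i, ])
    if (!length(js)) { out[i] <- NA_real_; next }
    out[i] <- mean(vapply(cfg$thresholds,
                          function(th) mean(dev[i, js] < th), 0))
  }
  out
}

#' Chain-aligned per-region backbone RMSD
#'
#' The evaluation protocol for antibody models: superpose the heavy and light
#' chains separately onto the reference (Kabsch on all backbone atoms of the
#' chain), then report the RMSD of backbone atoms over the residues of each
#' CDR and framework region under its chain's alignment.
#'
#' @param pred,true `fv_structure` objects with matching residue sets
#'   (correspondence by position; IMGT numbers are checked when present).
#' @param backbone_atoms atom set used both for alignment and scoring
#'   (default N, CA, C, O; O inclusion is a documented choice).
#' @return a tibble with columns `region`, `n_res`, `rmsd` (absent regions
#'   carry `NA`), plus attribute `transforms` (per-chain rigid).
#' @export
region_rmsd <- function(pred, true, backbone_atoms = c("N", "CA", "C", "O")) {
  if (length(pred) != length(true)) stop("mismatched residue sets")
  if (!all(pred$chain == true$chain)) stop("chain layout differs")
  if (!all(pred$imgt == true$imgt & pred$imgt_ins == true$imgt_ins)) {
    stop("IMGT numbering mismatch between prediction and reference")
  }
  sq <- list()
  transforms <- list()
  aligned_pred <- pred
  for (ch in c("H", "L")) {
    res_ids <- which(true$chain == ch)
    if (!length(res_ids)) stop("empty chain ", ch)
    pb <- backbone_coords_of(pred, res_ids, backbone_atoms)
    tb <- backbone_coords_of(true, res_ids, backbone_atoms)
    fit <- kabsch_superpose(pb$xyz, tb$xyz)
    transforms[[ch]] <- fit$transform
    moved <- rigid_apply(fit$transform, pb$xyz)
    sq[[ch]] <- data.frame(res = pb$res,
                           d2 = rowSums((moved - tb$xyz)^2))
  }
  sq <- rbind(sq$H, sq$L)
  out <- lapply(region_levels(), function(rg) {
    rows <- sq[true$region[sq$res] == rg, ]
    tibble::tibble(region = rg,
                   n_res = length(unique(rows$res)),
                   rmsd = if (nrow(rows)) sqrt(mean(rows$d2)) else NA_real_)
  })
  out <- do.call(rbind, out)
  attr(out, "transforms") <- transforms
  out
}

backbone_coords_of <- function(record, res_ids, atoms_wanted) {
  sel <- record$atoms[record$atoms$res %in% res_ids &
                        record$atoms$atom %in% atoms_wanted, ]
  sel <- sel[order(sel$res, match(sel$atom, atoms_wanted)), ]
  list(xyz = as.matrix(sel[, c("x", "y", "z")]), res = sel$res)
}

#' Expected pLDDT from a bin distribution
#'
#' The per-residue confidence: `100 * sum_k p_k * center_k`, where `center_k`
#' is the midpoint of bin `k` on the lDDT scale `[0, 1]`.
#'
#' @param bins an `n x K` matrix of per-residue bin probabilities (a
#'   `bin_distribution`).
#' @return numeric vector in `[0, 100]`.
#' @export
expected_plddt <- function(bins) {
  bins <- unclass_bins(bins)
  K <- ncol(bins)
  centers <- (seq_len(K) - 0.5) / K
  as.numeric(100 * bins %*% centers)
}

#' Aggregate per-residue pLDDT over a scope
#'
#' Unweighted mean of per-residue scores over the full domain or one region.
#'
#' @param per_res numeric per-residue scores.
#' @param regions per-residue region labels.
#' @param scope `"full"` or one of [region_levels()].
#' @return a single mean, or `NA` for an empty scope.
#' @export
aggregate_plddt <- function(per_res, regions = NULL, scope = "full") {
  if (scope == "full") return(mean(per_res))
  stopifnot(!is.null(regions), length(regions) == length(per_res))
  sel <- regions == scope
  if (!any(sel)) return(NA_real_)
  mean(per_res[sel])
}

#' Confidence calibration correlations
#'
#' Pearson and Spearman correlation between per-structure (or per-region)
#' confidence scores and the corresponding accuracy values (e.g. RMSD).
#' Constant input makes the correlation undefined; this is signalled with a
#' warning and `NA` rather than silently returned.
#'
#' @param scores,rmsds paired numeric vectors, length >= 3, finite.
#' @return a list with `pearson` and `spearman`.
#' @export
calibration <- function(scores, rmsds) {
  if (length(scores) != length(rmsds)) stop("length mismatch")
  if (length(scores) < 3) stop("need at least 3 paired values")
  if (!all(is.finite(scores)) || !all(is.finite(rmsds))) stop("non-finite input")
  if (stats::sd(scores) == 0 || stats::sd(rmsds) == 0) {
    warning("correlation undefined: an input is constant")
    return(list(pearson = NA_real_, spearman = NA_real_))
  }
  list(pearson = stats::cor(scores, rmsds, method = "pearson"),
       spearman = stats::cor(scores, rmsds, method = "spearman"))
}

#' Confidence-thresholded retention
#'
#' Retains structures with pLDDT strictly above `plddt_threshold` and reports
#' the retained fraction together with the fraction of retained structures
#' whose RMSD lies strictly below `rmsd_cutoff` (the screening guideline:
#' thresholding at pLDDT 85 retains ~32% of structures with >80% of those
#' under 2 Angstrom CDRH3 RMSD, on the published test set).
#'
#' @param plddt,rmsd paired numeric vectors.
#' @param plddt_threshold retention threshold (default 85).
#' @param rmsd_cutoff Angstrom (default 2).
#' @return list with `fraction_retained` and `fraction_below_cutoff` (the
#'   latter `NA` when nothing is retained).
#' @export
retention_curve <- function(plddt, rmsd, plddt_threshold = 85, rmsd_cutoff = 2) {
  if (length(plddt) != length(rmsd)) stop("length mismatch")
  if (!all(is.finite(plddt)) || !all(is.finite(rmsd))) stop("non-finite input")
  keep <- plddt > plddt_threshold
  frac <- mean(keep)
  below <- if (any(keep)) mean(rmsd[keep] < rmsd_cutoff) else NA_real_
  list(fraction_retained = frac, fraction_below_cutoff = below)
}
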