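#' Structure-module configuration
#'
#' Hyperparameters of the structure module: eight sequential update blocks
#' with independent weights by default, each applying invariant point
#' attention (IPA) followed by a quaternion backbone update, plus the torsion
#' (chi) head and the 50-bin pLDDT confidence head. The IPA channel counts
#' follow the published AlphaFold2-style defaults since the architecture
#' specifies the layer only by name.
#'
#' @param num_blocks number of update blocks (default 8).
#' @param node_width single-representation width.
#' @param edge_width projected edge-feature width.
#' @param heads attention heads.
#' @param scalar_qk scalar query/key/value channels per head.
#' @param point_qk,point_v query/key and value 3-D points per head.
#' @param plddt_bins confidence bins (default 50).
#' @param torsion_angles chi angles per residue (default 4).
#' @param clip relative-position clip for edge features.
#' @param trans_scale scale factor (Angstrom) applied to the raw translation
#'   outputs of the backbone update, so the network works in O(1) units
#'   while residues move tens of Angstrom (default 10).
#' @param stop_rotation_grad detach rotations between blocks during training
#'   (the lineage's stabilisation trick; on by default).
#' @param weight_init_seed seed for [init_weights()].
#' @return a list of class `model_config`.
#' @export
model_config <- function(num_blocks = 8L, node_width = 128L, edge_width = 16L,
                         heads = 8L, scalar_qk = 16L, point_qk = 4L,
                         point_v = 8L, plddt_bins = 50L, torsion_angles = 4L,
                         clip = 32L, trans_scale = 10, stop_rotation_grad = TRUE,
                         weight_init_seed = 1L) {
  stopifnot(num_blocks >= 1, plddt_bins >= 2, node_width >= 1, edge_width >= 1,
            heads >= 1, scalar_qk >= 1, point_qk >= 1, point_v >= 1)
  structure(list(num_blocks = as.integer(num_blocks),
                 node_width = as.integer(node_width),
                 edge_width = as.integer(edge_width),
                 heads = as.integer(heads), scalar_qk = as.integer(scalar_qk),
                 point_qk = as.integer(point_qk), point_v = as.integer(point_v),
                 plddt_bins = as.integer(plddt_bins),
                 torsion_angles = as.integer(torsion_angles),
                 clip = as.integer(clip),
                 trans_scale = trans_scale,
                 stop_rotation_grad = stop_rotation_grad,
                 weight_init_seed = as.integer(weight_init_seed)),
            class = "model_config")
}

#' @rdname model_config
#' @description `desk_config()` is the small profile used for desk-scale
#'   training and the test suite.
#' @param ... overrides passed to [model_config()].
#' @export
desk_config <- function(...) {
  args <- utils::modifyList(
    list(num_blocks = 2L, node_width = 24L, edge_width = 4L, heads = 2L,
         scalar_qk = 4L, point_qk = 2L, point_v = 2L, clip = 8L), list(...))
  do.call(model_config, args)
}

#' Initialise model weights
#'
#' Seeded scaled-Gaussian initialisation (1/sqrt(fan-in)); the final
#' backbone-update projection of every block is zero-initialised so an
#' untrained model starts from identity frames at the origin, and all biases
#' start at zero.
#'
#' @param config a [model_config()].
#' @param input_width width of the input per-residue embedding.
#' @param seed integer; defaults to the config's `weight_init_seed`.
#' @return a nested list of numeric matrices/vectors of class `model_weights`.
#' @export
init_weights <- function(config, input_width,
                         seed = config$weight_init_seed) {
  edge_raw <- 2L * config$clip + 2L
  with_seed(seed, {
    lin <- function(ni, no) matrix(stats::rnorm(ni * no, sd = 1 / sqrt(ni)), ni, no)
    blk <- function() {
      c <- config$node_width; h <- config$heads
      list(wq = lin(c, h * config$scalar_qk),
           wk = lin(c, h * config$scalar_qk),
           wv = lin(c, h * config$scalar_qk),
           wqp = lin(c, h * config$point_qk * 3L),
           wkp = lin(c, h * config$point_qk * 3L),
           wvp = lin(c, h * config$point_v * 3L),
           wb = lin(config$edge_width, h),
           head_gamma = rep(0.541, h),  # softplus^-1(1)
           wo = lin(h * (config$scalar_qk + config$edge_width +
                           4L * config$point_v), c),
           bo = rep(0, c),
           ln1_g = rep(1, c), ln1_b = rep(0, c),
           tw1 = lin(c, c), tb1 = rep(0, c),
           tw2 = lin(c, c), tb2 = rep(0, c),
           ln2_g = rep(1, c), ln2_b = rep(0, c),
           update_w = matrix(0, c, 6L), update_b = rep(0, 6L))
    }
    c <- config$node_width
    structure(list(
      input_w = lin(input_width, c), input_b = rep(0, c),
      edge_w = lin(edge_raw, config$edge_width), edge_b = rep(0, config$edge_width),
      blocks = lapply(seq_len(config$num_blocks), function(i) blk()),
      torsion_w1 = lin(c, c), torsion_b1 = rep(0, c),
      torsion_w2 = lin(c, 2L * config$torsion_angles),
      torsion_b2 = rep(0, 2L * config$torsion_angles),
      plddt_w1 = lin(c, c), plddt_b1 = rep(0, c),
      plddt_w2 = lin(c, config$plddt_bins), plddt_b2 = rep(0, config$plddt_bins)
    ), class = "model_weights")
  })
}

# ---- vectorised frames for the differentiable path ------------------------
# rotations held as nine n-vectors (row-major R11..R33), translations as
# three n-vectors; entries may be ag nodes or plain numerics.

af_identity <- function(n) {
  z <- rep(0, n); o <- rep(1, n)
  list(R = list(o, z, z, z, o, z, z, z, o), t = list(z, z, z))
}

af_from_rigid <- function(r) {
  list(R = list(r$R[1, 1, ], r$R[1, 2, ], r$R[1, 3, ],
                r$R[2, 1, ], r$R[2, 2, ], r$R[2, 3, ],
                r$R[3, 1, ], r$R[3, 2, ], r$R[3, 3, ]),
       t = list(r$t[, 1], r$t[, 2], r$t[, 3]))
}

af_to_rigid <- function(f) {
  R9 <- lapply(f$R, ag_value); t3 <- lapply(f$t, ag_value)
  n <- length(R9[[1]])
  R <- array(0, c(3, 3, n))
  R[1, 1, ] <- R9[[1]]; R[1, 2, ] <- R9[[2]]; R[1, 3, ] <- R9[[3]]
  R[2, 1, ] <- R9[[4]]; R[2, 2, ] <- R9[[5]]; R[2, 3, ] <- R9[[6]]
  R[3, 1, ] <- R9[[7]]; R[3, 2, ] <- R9[[8]]; R[3, 3, ] <- R9[[9]]
  structure(list(R = R, t = cbind(t3[[1]], t3[[2]], t3[[3]])), class = "rigid")
}

af_detach <- function(f) {
  list(R = lapply(f$R, ag_value), t = f$t)
}

# new = old o delta (delta applied in the local frame)
af_compose <- function(old, delta) {
  Ro <- old$R; Rd <- delta$R
  idx <- function(i, j) (i - 1L) * 3L + j
  R <- vector("list", 9L)
  for (i in 1:3) for (j in 1:3) {
    acc <- ag_mul(Ro[[idx(i, 1)]], Rd[[idx(1, j)]])
    acc <- ag_add(acc, ag_mul(Ro[[idx(i, 2)]], Rd[[idx(2, j)]]))
    acc <- ag_add(acc, ag_mul(Ro[[idx(i, 3)]], Rd[[idx(3, j)]]))
    R[[idx(i, j)]] <- acc
  }
  t <- vector("list", 3L)
  for (i in 1:3) {
    acc <- ag_mul(Ro[[idx(i, 1)]], delta$t[[1]])
    acc <- ag_add(acc, ag_mul(Ro[[idx(i, 2)]], delta$t[[2]]))
    acc <- ag_add(acc, ag_mul(Ro[[idx(i, 3)]], delta$t[[3]]))
    t[[i]] <- ag_add(acc, old$t[[i]])
  }
  list(R = R, t = t)
}

# global = R local + t, all per-residue n-vectors
af_apply <- function(f, lx, ly, lz) {
  R <- f$R
  list(
    x = ag_add(ag_add(ag_mul(R[[1]], lx), ag_add(ag_mul(R[[2]], ly), ag_mul(R[[3]], lz))), f$t[[1]]),
    y = ag_add(ag_add(ag_mul(R[[4]], lx), ag_add(ag_mul(R[[5]], ly), ag_mul(R[[6]], lz))), f$t[[2]]),
    z = ag_add(ag_add(ag_mul(R[[7]], lx), ag_add(ag_mul(R[[8]], ly), ag_mul(R[[9]], lz))), f$t[[3]]))
}

# local = R^T (global - t)
af_apply_inv <- function(f, gx, gy, gz) {
  R <- f$R
  dx <- ag_sub(gx, f$t[[1]]); dy <- ag_sub(gy, f$t[[2]]); dz <- ag_sub(gz, f$t[[3]])
  list(
    x = ag_add(ag_mul(R[[1]], dx), ag_add(ag_mul(R[[4]], dy), ag_mul(R[[7]], dz))),
    y = ag_add(ag_mul(R[[2]], dx), ag_add(ag_mul(R[[5]], dy), ag_mul(R[[8]], dz))),
    z = ag_add(ag_mul(R[[3]], dx), ag_add(ag_mul(R[[6]], dy), ag_mul(R[[9]], dz))))
}

# x_ij = R_i^T (p_j - t_i) for all frames i and points j: n x m matrices
af_pairwise_local <- function(f, px, py, pz) {
  n <- length(ag_value(f$t[[1]])); m <- length(ag_value(px))
  rv <- function(v) ag_rowvec_mat(v, n)
  cv <- function(v) ag_colvec_mat(v, m)
  dx <- ag_sub(rv(px), cv(f$t[[1]]))
  dy <- ag_sub(rv(py), cv(f$t[[2]]))
  dz <- ag_sub(rv(pz), cv(f$t[[3]]))
  R <- lapply(f$R, cv)
  list(
    x = ag_add(ag_mul(R[[1]], dx), ag_add(ag_mul(R[[4]], dy), ag_mul(R[[7]], dz))),
    y = ag_add(ag_mul(R[[2]], dx), ag_add(ag_mul(R[[5]], dy), ag_mul(R[[8]], dz))),
    z = ag_add(ag_mul(R[[3]], dx), ag_add(ag_mul(R[[6]], dy), ag_mul(R[[9]], dz))))
}

# quaternion (1, b, c, d) -> frame, vectorised over residues
af_from_bcd <- function(b, c, d, tx, ty, tz) {
  s <- ag_add(1, ag_add(ag_mul(b, b), ag_add(ag_mul(c, c), ag_mul(d, d))))
  e <- function(x) ag_div(x, s)
  two <- function(x, y) ag_mul(2, ag_mul(x, y))
  bb <- ag_mul(b, b); cc <- ag_mul(c, c); dd <- ag_mul(d, d)
  list(R = list(
    e(ag_sub(ag_add(1, bb), ag_add(cc, dd))),
    e(ag_sub(two(b, c), ag_mul(2, d))),
    e(ag_add(two(b, d), ag_mul(2, c))),
    e(ag_add(two(b, c), ag_mul(2, d))),
    e(ag_add(ag_sub(1, bb), ag_sub(cc, dd))),
    e(ag_sub(two(c, d), ag_mul(2, b))),
    e(ag_sub(two(b, d), ag_mul(2, c))),
    e(ag_add(two(c, d), ag_mul(2, b))),
    e(ag_add(ag_sub(1, bb), ag_sub(dd, cc)))),
    t = list(tx, ty, tz))
}

layer_norm <- function(x, g, b, eps = 1e-6) {
  nc <- ncol(ag_value(x)); nr <- nrow(ag_value(x))
  mu <- ag_rowmeans(x)
  xc <- ag_sub(x, ag_colvec_mat(mu, nc))
  v <- ag_rowmeans(ag_mul(xc, xc))
  xn <- ag_div(xc, ag_colvec_mat(ag_sqrt(ag_add(v, eps)), nc))
  ag_add(ag_mul(xn, ag_rowvec_mat(g, nr)), ag_rowvec_mat(b, nr))
}

# flatten an n x n x w edge array into (n^2) x w, column-major pair index
flatten_edges <- function(edges) {
  d <- dim(edges)
  matrix(edges, d[1] * d[2], d[3])
}

#' Invariant point attention layer
#'
#' Updates the per-residue node features by attending over residue pairs with
#' three logit contributions: scalar query-key products, learned edge biases
#' from the relative-position features, and distances between query/key
#' points expressed in global coordinates through the residue frames. Because
#' point contributions depend only on inter-point distances and outputs are
#' mapped back into local frames, the layer's output is invariant under any
#' global rigid transform applied jointly to all frames.
#'
#' @param nodes `n x node_width` matrix (numeric or `ag`).
#' @param edge_flat `(n^2) x (2 clip + 2)` flattened edge features (see
#'   [relative_position_encoding()]).
#' @param frames per-residue frames in vectorised form (internal) or a
#'   `rigid` object.
#' @param wts one element of `weights$blocks`, plus the shared edge
#'   projection in `edge_proj`.
#' @param config a [model_config()].
#' @param edge_proj list with the shared `w`, `b` edge projection.
#' @return the IPA output (`n x node_width`), before residual/normalisation.
#' @export
ipa_layer <- function(nodes, edge_flat, frames, wts, config, edge_proj) {
  if (inherits(frames, "rigid")) frames <- af_from_rigid(frames)
  n <- nrow(ag_value(nodes))
  if (nrow(ag_value(edge_flat)) != n * n) stop("edge/node shape mismatch")
  h <- config$heads; sq <- config$scalar_qk
  pq <- config$point_qk; pv <- config$point_v; ew <- config$edge_width
  eproj <- ag_add(ag_matmul(edge_flat, edge_proj$w),
                  ag_rowvec_mat(edge_proj$b, n * n))
  q_all <- ag_matmul(nodes, wts$wq); k_all <- ag_matmul(nodes, wts$wk)
  v_all <- ag_matmul(nodes, wts$wv)
  qp_all <- ag_matmul(nodes, wts$wqp); kp_all <- ag_matmul(nodes, wts$wkp)
  vp_all <- ag_matmul(nodes, wts$wvp)
  gamma <- ag_softplus(wts$head_gamma)
  wC <- sqrt(2 / (9 * pq))
  wL <- 1 / sqrt(3)
  outs <- list()
  for (hh in seq_len(h)) {
    qc <- (hh - 1L) * sq + seq_len(sq)
    q <- ag_cols(q_all, qc); k <- ag_cols(k_all, qc); v <- ag_cols(v_all, qc)
    logits <- ag_mul(ag_tcrossprod(q, k), wL / sqrt(sq))
    bias <- ag_reshape(ag_matmul(eproj, ag_cols_of_vecmat(wts$wb, hh)), c(n, n))
    logits <- ag_add(logits, ag_mul(bias, wL))
    # point distances in global coordinates
    ptsum <- NULL
    for (p in seq_len(pq)) {
      base <- (hh - 1L) * pq * 3L + (p - 1L) * 3L
      ql <- lapply(1:3, function(a) vec_of(ag_cols(qp_all, base + a)))
      kl <- lapply(1:3, function(a) vec_of(ag_cols(kp_all, base + a)))
      qg <- af_apply(frames, ql[[1]], ql[[2]], ql[[3]])
      kg <- af_apply(frames, kl[[1]], kl[[2]], kl[[3]])
      for (a in c("x", "y", "z")) {
        d <- ag_sub(ag_colvec_mat(qg[[a]], n), ag_rowvec_mat(kg[[a]], n))
        term <- ag_mul(d, d)
        ptsum <- if (is.null(ptsum)) term else ag_add(ptsum, term)
      }
    }
    gh <- ag_cols_scalar(gamma, hh)
    logits <- ag_sub(logits, ag_mul(ag_mul(gh, wL * wC / 2), ptsum))
    A <- ag_softmax_rows(logits)
    o_scalar <- ag_matmul(A, v)
    o_pair <- lapply(seq_len(ew), function(kk) {
      Mk <- ag_reshape(ag_cols(eproj, kk), c(n, n))
      mat_of(ag_rowsums(ag_mul(A, Mk)))
    })
    o_pts <- list()
    for (p in seq_len(pv)) {
      base <- (hh - 1L) * pv * 3L + (p - 1L) * 3L
      vl <- lapply(1:3, function(a) vec_of(ag_cols(vp_all, base + a)))
      vg <- af_apply(frames, vl[[1]], vl[[2]], vl[[3]])
      og <- lapply(vg, function(comp) vec_of(ag_matmul(A, mat_of(comp))))
      ol <- af_apply_inv(frames, og$x, og$y, og$z)
      nrm <- ag_sqrt(ag_add(ag_add(ag_mul(ol$x, ol$x), ag_mul(ol$y, ol$y)),
                            ag_add(ag_mul(ol$z, ol$z), 1e-8)))
      o_pts[[p]] <- lapply(list(ol$x, ol$y, ol$z, nrm), mat_of)
    }
    outs[[hh]] <- do.call(ag_cbind, c(list(o_scalar), o_pair,
                                      unlist(o_pts, recursive = FALSE)))
  }
  ag_add(ag_matmul(do.call(ag_cbind, outs), wts$wo),
         ag_rowvec_mat(wts$bo, n))
}

# column hh of a small plain matrix as a plain column vector matrix
ag_cols_of_vecmat <- function(m, hh) {
  if (is_ag(m)) ag_cols(m, hh) else m[, hh, drop = FALSE]
}

ag_cols_scalar <- function(v, i) {
  if (is_ag(v)) {
    vec_of(ag_cols(ag_reshape(v, c(1L, length(ag_value(v)))), i))
  } else v[i]
}

vec_of <- function(m) if (is_ag(m)) ag_reshape(m, length(ag_value(m))) else as.numeric(m)

mat_of <- function(v) {
  if (is_ag(v)) ag_reshape(v, c(length(ag_value(v)), 1L)) else matrix(v, ncol = 1)
}

#' Backbone update layer
#'
#' Projects the node features to six numbers per residue: an unconstrained
#' quaternion tail `(b, c, d)` mapped through the fixed-first-component
#' quaternion parametrisation (so a zero projection is the identity rotation)
#' and a local-frame translation in Angstrom.
#'
#' @param nodes `n x node_width` matrix.
#' @param wts block weights (`update_w`, `update_b`).
#' @return a per-residue frame delta (vectorised form; convert with
#'   `af_to_rigid` or compose via the forward pass).
#' @export
backbone_update <- function(nodes, wts, trans_scale = 10) {
  n <- nrow(ag_value(nodes))
  u <- ag_add(ag_matmul(nodes, wts$update_w), ag_rowvec_mat(wts$update_b, n))
  cols <- lapply(1:6, function(k) vec_of(ag_cols(u, k)))
  af_from_bcd(cols[[1]], cols[[2]], cols[[3]],
              ag_mul(cols[[4]], trans_scale), ag_mul(cols[[5]], trans_scale),
              ag_mul(cols[[6]], trans_scale))
}

transition_mlp <- function(x, wts) {
  n <- nrow(ag_value(x))
  h <- ag_relu(ag_add(ag_matmul(x, wts$tw1), ag_rowvec_mat(wts$tb1, n)))
  ag_add(ag_matmul(h, wts$tw2), ag_rowvec_mat(wts$tb2, n))
}

# core differentiable forward pass; weights may contain ag nodes
sm_forward <- function(emb, edge_flat, config, weights, init_frames = NULL) {
  n <- nrow(ag_value(emb))
  nodes <- ag_add(ag_matmul(emb, weights$input_w),
                  ag_rowvec_mat(weights$input_b, n))
  frames <- if (is.null(init_frames)) af_identity(n) else init_frames
  if (inherits(frames, "rigid")) frames <- af_from_rigid(frames)
  edge_proj <- list(w = weights$edge_w, b = weights$edge_b)
  traj <- vector("list", config$num_blocks)
  for (blk in seq_len(config$num_blocks)) {
    wts <- weights$blocks[[blk]]
    nodes <- layer_norm(ag_add(nodes, ipa_layer(nodes, edge_flat, frames,
                                                wts, config, edge_proj)),
                        wts$ln1_g, wts$ln1_b)
    nodes <- layer_norm(ag_add(nodes, transition_mlp(nodes, wts)),
                        wts$ln2_g, wts$ln2_b)
    delta <- backbone_update(nodes, wts, config$trans_scale)
    frames <- af_compose(frames, delta)
    traj[[blk]] <- frames
    if (config$stop_rotation_grad && blk < config$num_blocks) {
      frames <- af_detach(frames)
    }
  }
  list(frames = traj, nodes = nodes)
}

#' Run the structure module
#'
#' Starting from identity frames at the origin (residue gas), each of the
#' `num_blocks` blocks applies invariant point attention and a backbone
#' update with block-specific weights; every block's frames are retained so
#' the trajectory-averaged backbone FAPE can be computed.
#'
#' @param embeddings per-residue embedding matrix (heavy then light rows).
#' @param edges `n x n x w` relative-position edge array from
#'   [relative_position_encoding()].
#' @param config a [model_config()].
#' @param weights from [init_weights()] (or trained).
#' @param init_frames optional initial `rigid` frames (default identity at
#'   the origin).
#' @return an object of class `trajectory`: list of per-block `rigid` frame
#'   sets (`frames`, length `num_blocks`) and the final node matrix
#'   (`nodes`).
#' @export
structure_module_forward <- function(embeddings, edges, config, weights,
                                     init_frames = NULL) {
  if (dim(edges)[1] != nrow(embeddings)) stop("embedding/edge residue counts differ")
  out <- sm_forward(embeddings, flatten_edges(edges), config, weights,
                    init_frames)
  structure(list(frames = lapply(out$frames, af_to_rigid),
                 nodes = ag_value(out$nodes)),
            class = "trajectory")
}

#' @export
length.trajectory <- function(x) length(x$frames)

#' Per-residue bin distributions
#'
#' An `n x K` matrix of categorical probabilities over equal-width lDDT bins
#' on `[0, 1]`; rows must sum to 1 within 1e-6.
#'
#' @param p probability matrix.
#' @return the validated matrix with class `bin_distribution`.
#' @export
bin_distribution <- function(p) {
  p <- as.matrix(p)
  if (any(p < -1e-12)) stop("negative bin probabilities")
  if (max(abs(rowSums(p) - 1)) > 1e-6) stop("bin rows must sum to 1")
  structure(p, class = c("bin_distribution", "matrix"))
}

unclass_bins <- function(p) {
  if (inherits(p, "bin_distribution")) unclass(p) else as.matrix(p)
}

#' Torsion (chi) head
#'
#' A two-layer MLP over the final node representation emits raw (sin, cos)
#' pairs for chi1..chi4 per residue; angles are extracted after unit-norm
#' normalisation (epsilon-guarded so a zero raw output still yields a finite
#' angle) and masked by the canonical chi count of each residue type.
#'
#' @param final_nodes final-block node matrix.
#' @param sequence per-residue one-letter codes (heavy then light).
#' @param weights,config model weights and config.
#' @return list with `raw` (`n x 4 x 2` sin/cos array) and `torsions`
#'   (a [torsion_set()]).
#' @export
torsion_head <- function(final_nodes, sequence, weights, config) {
  raw <- torsion_head_raw(final_nodes, weights)
  rawv <- ag_value(raw)
  n <- nrow(rawv)
  arr <- array(0, c(n, config$torsion_angles, 2))
  arr[, , 1] <- rawv[, seq(1, by = 2, length.out = config$torsion_angles)]
  arr[, , 2] <- rawv[, seq(2, by = 2, length.out = config$torsion_angles)]
  norm <- sqrt(arr[, , 1]^2 + arr[, , 2]^2 + 1e-12)
  ang <- atan2(arr[, , 1] / norm, arr[, , 2] / norm)
  mask <- matrix(FALSE, n, 4)
  nch <- n_chi(sequence)
  for (i in seq_len(n)) mask[i, seq_len(nch[i])] <- TRUE
  ang[!mask] <- NA_real_
  list(raw = arr, torsions = torsion_set(wrap_angle_mat(ang), mask))
}

wrap_angle_mat <- function(a) {
  out <- a
  ok <- !is.na(a)
  out[ok] <- wrap_angle(a[ok])
  out
}

torsion_head_raw <- function(final_nodes, weights) {
  n <- nrow(ag_value(final_nodes))
  hdn <- ag_relu(ag_add(ag_matmul(final_nodes, weights$torsion_w1),
                        ag_rowvec_mat(weights$torsion_b1, n)))
  ag_add(ag_matmul(hdn, weights$torsion_w2),
         ag_rowvec_mat(weights$torsion_b2, n))
}

#' pLDDT confidence head
#'
#' A multilayer perceptron with softmax activation over the final single
#' representation, projecting the local confidence into `plddt_bins` bins
#' (50 by default).
#'
#' @param final_nodes final-block node matrix.
#' @param weights,config model weights and config.
#' @return a [bin_distribution()].
#' @export
plddt_head <- function(final_nodes, weights, config) {
  bin_distribution(ag_value(plddt_head_raw(final_nodes, weights)))
}

plddt_head_raw <- function(final_nodes, weights) {
  n <- nrow(ag_value(final_nodes))
  hdn <- ag_relu(ag_add(ag_matmul(final_nodes, weights$plddt_w1),
                        ag_rowvec_mat(weights$plddt_b1, n)))
  ag_softmax_rows(ag_add(ag_matmul(hdn, weights$plddt_w2),
                         ag_rowvec_mat(weights$plddt_b2, n)))
}

# backbone N, CA, C (and O) coordinates implied by per-residue frames
frames_to_backbone <- function(frames, psi_anti = TRUE) {
  bl <- backbone_local_coords()
  n <- length(frames)
  Nm <- rigid_apply(frames, matrix(bl["N", ], n, 3, byrow = TRUE))
  CAm <- rigid_apply(frames, matrix(bl["CA", ], n, 3, byrow = TRUE))
  Cm <- rigid_apply(frames, matrix(bl["C", ], n, 3, byrow = TRUE))
  bi <- backbone_ideal()
  Om <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    psi <- if (i < n) {
      dihedral(Nm[i, ], CAm[i, ], Cm[i, ], Nm[i + 1, ])
    } else pi * 130 / 180
    Om[i, ] <- nerf_place(Nm[i, ], CAm[i, ], Cm[i, ], bi$c_o,
                          bi$ang_ca_c_o * pi / 180, psi + pi)
  }
  list(N = Nm, CA = CAm, C = Cm, O = Om)
}

#' End-to-end prediction
#'
#' Runs the full pipeline: structure-module forward pass, chi prediction,
#' idealized all-atom reconstruction, and per-residue pLDDT (the expectation
#' of the 50-bin confidence distribution, written into the structure's
#' B-factor column on a 0-100 scale). Deterministic given weights and inputs.
#'
#' @param pair a [sequence_pair()].
#' @param config a [model_config()].
#' @param weights model weights.
#' @param embeddings optional precomputed per-residue embedding matrix
#'   (default: [one_hot_encode()]).
#' @return list of class `fv_prediction`: `structure` (all-atom
#'   `fv_structure` with pLDDT B-factors), `plddt` (per-residue 0-100),
#'   `bins` (a `bin_distribution`), `trajectory`.
#' @export
fv_predict <- function(pair, config, weights, embeddings = NULL) {
  if (is.null(embeddings)) embeddings <- one_hot_encode(pair)
  n <- length(pair)
  if (nrow(embeddings) != n) {
    stop("embedding rows (", nrow(embeddings), ") != residue count (", n, ")")
  }
  edges <- relative_position_encoding(pair, config$clip)
  traj <- structure_module_forward(embeddings, edges, config, weights)
  final <- traj$frames[[config$num_blocks]]
  bb <- frames_to_backbone(final)
  seqs <- pair_sequence(pair)
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(res = i, atom = c("N", "CA", "C", "O"),
               x = c(bb$N[i, 1], bb$CA[i, 1], bb$C[i, 1], bb$O[i, 1]),
               y = c(bb$N[i, 2], bb$CA[i, 2], bb$C[i, 2], bb$O[i, 2]),
               z = c(bb$N[i, 3], bb$CA[i, 3], bb$C[i, 3], bb$O[i, 3]))
  }))
  record <- fv_structure(pair_chain(pair), seqs,
                         c(pair$imgt$H, pair$imgt$L),
                         c(pair$ins$H, pair$ins$L),
                         pair$region, atoms)
  th <- torsion_head(traj$nodes, seqs, weights, config)
  record <- reconstruct_all_atom(record, th$torsions)
  bins <- plddt_head(traj$nodes, weights, config)
  plddt <- expected_plddt(bins)
  record <- set_bfactor(record, plddt)
  structure(list(structure = record, plddt = plddt, bins = bins,
                 trajectory = traj, torsions = th$torsions),
            class = "fv_prediction")
}
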