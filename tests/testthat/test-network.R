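cfg0 <- desk_config(weight_init_seed = 7)

setup_net <- function(seed = 1L) {
  rec <- small_fv(seed)
  pair <- pair_of(rec)
  emb <- one_hot_encode(pair)
  list(rec = rec, pair = pair, emb = emb,
       edges = relative_position_encoding(pair, cfg0$clip),
       w = init_weights(cfg0, ncol(emb)))
}

test_that("IPA output is invariant under global rigid transforms of the frames", {
  s <- setup_net()
  n <- length(s$pair)
  frames <- rigid_compose(random_rigid(seed = 2),
                          frames_from_backbone(s$rec))
  nodes <- s$emb %*% s$w$input_w
  ef <- fvforge:::flatten_edges(s$edges)
  ep <- list(w = s$w$edge_w, b = s$w$edge_b)
  base <- ipa_layer(nodes, ef, frames, s$w$blocks[[1]], cfg0, ep)
  for (k in 1:5) {
    Tg <- random_rigid(seed = 10 + k)
    out <- ipa_layer(nodes, ef, rigid_compose(Tg, frames),
                     s$w$blocks[[1]], cfg0, ep)
    expect_lt(max(abs(out - base)), 1e-8)
  }
  expect_error(ipa_layer(nodes, ef[1:4, ], frames, s$w$blocks[[1]], cfg0, ep),
               "shape mismatch")
})

test_that("permuting residues and permuting back reproduces IPA outputs", {
  s <- setup_net()
  n <- length(s$pair)
  frames <- frames_from_backbone(s$rec)
  nodes <- s$emb %*% s$w$input_w
  ep <- list(w = s$w$edge_w, b = s$w$edge_b)
  base <- ipa_layer(nodes, fvforge:::flatten_edges(s$edges), frames,
                    s$w$blocks[[1]], cfg0, ep)
  set.seed(77)
  perm <- sample.int(n)
  out_p <- ipa_layer(nodes[perm, ],
                     fvforge:::flatten_edges(s$edges[perm, perm, ]),
                     frames[perm], s$w$blocks[[1]], cfg0, ep)
  expect_lt(max(abs(out_p[order(perm), ] - base)), 1e-6)
})

test_that("zero-initialised updates leave the trajectory at the origin", {
  s <- setup_net()
  w0 <- s$w
  w0$blocks <- lapply(w0$blocks, function(b) {
    b$update_w[] <- 0; b$update_b[] <- 0; b
  })
  traj <- structure_module_forward(s$emb, s$edges, cfg0, w0)
  expect_length(traj, cfg0$num_blocks)
  for (fr in traj$frames) {
    expect_lt(max(abs(fr$t)), 1e-12)
    expect_lt(max(abs(fr$R - array(diag(3), dim(fr$R)))), 1e-12)
  }
})

test_that("the forward pass is equivariant and has the configured depth", {
  s <- setup_net()
  traj <- structure_module_forward(s$emb, s$edges, cfg0, s$w)
  expect_length(traj, 2L)
  cfg8 <- desk_config(num_blocks = 8L, weight_init_seed = 7)
  w8 <- init_weights(cfg8, ncol(s$emb))
  expect_length(structure_module_forward(s$emb, s$edges, cfg8, w8), 8L)
  # equivariance from a nonzero initial frame set
  init <- frames_from_backbone(s$rec)
  Tg <- random_rigid(seed = 5)
  trA <- structure_module_forward(s$emb, s$edges, cfg0, s$w, init_frames = init)
  trB <- structure_module_forward(s$emb, s$edges, cfg0, s$w,
                                  init_frames = rigid_compose(Tg, init))
  for (b in seq_len(2)) {
    want <- rigid_compose(Tg, trA$frames[[b]])
    expect_lt(max(abs(want$R - trB$frames[[b]]$R)), 1e-8)
    expect_lt(max(abs(want$t - trB$frames[[b]]$t)), 1e-8)
  }
})

test_that("blocks have independent weights", {
  s <- setup_net()
  w1 <- s$w
  set.seed(88)
  for (b in 1:2) {  # nonzero updates so frames leave the origin
    w1$blocks[[b]]$update_w <- matrix(rnorm(length(w1$blocks[[b]]$update_w),
                                            sd = 0.05),
                                      nrow(w1$blocks[[b]]$update_w), 6)
  }
  w2 <- w1
  w2$blocks[[2]]$wq <- w2$blocks[[2]]$wq +
    matrix(rnorm(length(w2$blocks[[2]]$wq), sd = 0.1),
           nrow(w2$blocks[[2]]$wq), ncol(w2$blocks[[2]]$wq))
  t1 <- structure_module_forward(s$emb, s$edges, cfg0, w1)
  t2 <- structure_module_forward(s$emb, s$edges, cfg0, w2)
  # block 1 frames identical, block 2 output changed
  expect_identical(t1$frames[[1]]$t, t2$frames[[1]]$t)
  expect_identical(t1$frames[[1]]$R, t2$frames[[1]]$R)
  expect_gt(max(abs(t1$frames[[2]]$t - t2$frames[[2]]$t)), 1e-8)
})

test_that("the torsion head normalises raw sin/cos pairs and masks by type", {
  s <- setup_net()
  w <- s$w
  w$torsion_w1[] <- 0; w$torsion_b1[] <- 0; w$torsion_w2[] <- 0
  w$torsion_b2 <- c(0.3, 0.4, rep(0, 6))  # raw (sin, cos) = (0.3, 0.4) for chi1
  nodes <- matrix(rnorm(nrow(s$emb) * cfg0$node_width),
                  nrow(s$emb), cfg0$node_width)
  th <- torsion_head(nodes, pair_sequence(s$pair), w, cfg0)
  has_chi1 <- n_chi(pair_sequence(s$pair)) >= 1
  expect_equal(unname(th$torsions$chi[which(has_chi1)[1], 1]),
               atan2(0.6, 0.8), tolerance = 1e-9)
  gly <- which(pair_sequence(s$pair) == "G")
  if (length(gly)) expect_false(any(th$torsions$mask[gly, ]))
  # degenerate raw (0, 0) still yields a finite angle
  w$torsion_b2 <- rep(0, 8)
  th0 <- torsion_head(nodes, pair_sequence(s$pair), w, cfg0)
  expect_true(all(is.finite(th0$torsions$chi[th0$torsions$mask])))
})

test_that("the pLDDT head emits valid 50-bin distributions", {
  s <- setup_net()
  nodes <- matrix(rnorm(nrow(s$emb) * cfg0$node_width),
                  nrow(s$emb), cfg0$node_width)
  bins <- plddt_head(nodes, s$w, cfg0)
  expect_s3_class(bins, "bin_distribution")
  expect_equal(ncol(bins), 50L)
  expect_equal(unname(rowSums(bins)), rep(1, nrow(bins)), tolerance = 1e-6)
  expect_true(all(bins >= 0))
  # softmax shift invariance: shifting all logits leaves the head unchanged
  w2 <- s$w; w2$plddt_b2 <- w2$plddt_b2 + 3.7
  expect_equal(unclass(plddt_head(nodes, w2, cfg0)), unclass(bins),
               tolerance = 1e-9)
})

test_that("prediction is deterministic and satisfies the output contracts", {
  s <- setup_net()
  p1 <- fv_predict(s$pair, cfg0, s$w)
  p2 <- fv_predict(s$pair, cfg0, s$w)
  expect_identical(p1$structure$atoms, p2$structure$atoms)
  expect_s3_class(p1$structure, "fv_structure")
  expect_true(all(p1$plddt >= 0 & p1$plddt <= 100))
  expect_equal(p1$structure$atoms$b[match(1:length(s$pair),
                                          p1$structure$atoms$res)],
               p1$plddt, tolerance = 1e-9)
  expect_error(fv_predict(s$pair, cfg0, s$w,
                          embeddings = one_hot_encode(s$pair)[-1, ]),
               "residue count")
})
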