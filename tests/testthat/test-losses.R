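test_that("clamp matrix applies 30 A only across CDR/framework pairs", {
  rec <- small_fv()
  cs <- build_clamp_matrix(rec$region)
  is_cdr <- grepl("^CDR", rec$region)
  for (i in seq_along(is_cdr)) for (j in seq_along(is_cdr)) {
    expected <- if (xor(is_cdr[i], is_cdr[j])) 30 else 10
    expect_identical(cs$clamp[i, j], expected)
  }
  expect_identical(cs$clamp, t(cs$clamp))
  expect_equal(cs$Z, 10)
})

test_that("FAPE is zero at equality, clamps by the hand-computed value, and is rigid-invariant", {
  fr <- rigid_identity(1)
  expect_equal(fape(fr, matrix(0, 1, 3), fr, matrix(0, 1, 3), clamp = 10),
               0, tolerance = 1e-6)
  # single identity frame, one point displaced 40 A, clamp 10, Z = 10 -> 1.0
  expect_equal(fape(fr, matrix(c(40, 0, 0), 1, 3), fr, matrix(0, 1, 3),
                    clamp = 10, Z = 10), 1.0, tolerance = 1e-9)
  set.seed(41)
  for (k in 1:100) {
    n <- 6
    pf <- random_rigid(n); tf <- random_rigid(n)
    pp <- random_points(n); tp <- random_points(n)
    base <- fape(pf, pp, tf, tp, clamp = 10)
    Tp <- random_rigid(); Tt <- random_rigid()
    moved <- fape(rigid_compose(Tp, pf), rigid_apply(Tp, pp),
                  rigid_compose(Tt, tf), rigid_apply(Tt, tp), clamp = 10)
    expect_lt(abs(base - moved), 1e-9)
  }
})

test_that("raising clamps never lowers FAPE and infinite clamp equals mean/Z", {
  set.seed(42)
  n <- 8
  pf <- random_rigid(n); tf <- random_rigid(n)
  pp <- random_points(n); tp <- random_points(n)
  l10 <- fape(pf, pp, tf, tp, clamp = 10)
  l30 <- fape(pf, pp, tf, tp, clamp = 30)
  linf <- fape(pf, pp, tf, tp, clamp = NULL)
  expect_gte(l30, l10)
  expect_gte(linf, l30)
})

test_that("trajectory FAPE averages blocks and reacts to per-block error", {
  rec <- small_fv()
  clamp <- build_clamp_matrix(rec$region)
  fr <- frames_from_backbone(rec)
  tors <- measure_torsions(rec)
  perfect <- list(fr, fr, fr)
  tf <- total_fape(perfect, rec, rec, clamp)
  expect_lt(tf$backbone_fape, 1e-6)
  expect_lt(tf$final_fape, 1e-6)
  # corrupting one block strictly increases the backbone term, final unchanged
  off <- fr
  off$t[3, ] <- off$t[3, ] + 5
  worse <- total_fape(list(fr, off, fr), rec, rec, clamp)
  expect_gt(worse$backbone_fape, tf$backbone_fape)
  expect_equal(worse$final_fape, tf$final_fape)
  # the backbone term is the mean of per-block values
  one <- total_fape(list(off), rec, rec, clamp)$backbone_fape
  expect_equal(worse$backbone_fape, (2 * tf$backbone_fape / 3) + one / 3,
               tolerance = 1e-9)
})

test_that("torsion loss respects periodicity and the alternate branch", {
  chi <- matrix(NA_real_, 1, 4); chi[1, 1:2] <- c(0.5, -2.0)
  ts <- torsion_set(chi)
  raw <- array(0, c(1, 4, 2))
  raw[1, , 1] <- sin(c(0.5, -2.0, 0, 0)); raw[1, , 2] <- cos(c(0.5, -2.0, 0, 0))
  expect_equal(torsion_angle_loss(raw, ts, ts), 0, tolerance = 1e-5)
  # 2 pi shifts of the target leave the loss unchanged (wrapped at input)
  chi_shift <- chi; chi_shift[1, 1] <- fvforge:::wrap_angle(0.5 + 2 * pi)
  expect_equal(torsion_angle_loss(raw, torsion_set(chi_shift), ts),
               torsion_angle_loss(raw, ts, ts), tolerance = 1e-12)
  # pi-flipped prediction is rescued by the alternate target
  raw_flip <- raw
  raw_flip[1, 1, 1] <- sin(0.5 + pi); raw_flip[1, 1, 2] <- cos(0.5 + pi)
  alt <- chi; alt[1, 1] <- fvforge:::wrap_angle(0.5 + pi)
  loss_no_alt <- torsion_angle_loss(raw_flip, ts, ts)
  loss_alt <- torsion_angle_loss(raw_flip, ts, torsion_set(alt))
  expect_gt(loss_no_alt, 0.5)
  expect_lt(loss_alt, 1e-5)
  # non-unit raw outputs are penalised through the norm regulariser
  raw2 <- raw; raw2[1, , ] <- raw2[1, , ] * 3
  expect_gt(torsion_angle_loss(raw2, ts, ts), 0.02)
})

test_that("violation loss is zero on templates and isolates single violations", {
  rec <- small_fv()
  expect_equal(violation_loss(rec), 0)
  # all-atom reconstructions from the idealized templates carry no violations
  for (code in c("S", "K", "F", "W")) {
    nchi <- unname(n_chi(code))
    chi <- matrix(NA_real_, 2, 4); chi[1, seq_len(nchi)] <- -1.1
    full <- reconstruct_all_atom(scaffold(code), torsion_set(chi))
    expect_equal(violation_loss(full), 0)
  }
  # stretch one peptide bond by 0.5 A: bond term only
  stretched <- rec
  i <- 5L
  cpos <- as.numeric(rec$atoms[rec$atoms$res == i & rec$atoms$atom == "C", c("x", "y", "z")])
  npos <- as.numeric(rec$atoms[rec$atoms$res == i + 1 & rec$atoms$atom == "N", c("x", "y", "z")])
  dir <- (npos - cpos) / sqrt(sum((npos - cpos)^2))
  later <- stretched$atoms$res > i & stretched$atoms$res <= sum(rec$chain == "H")
  stretched$atoms[later, c("x", "y", "z")] <-
    sweep(as.matrix(stretched$atoms[later, c("x", "y", "z")]), 2, 0.5 * dir, "+")
  parts <- violation_loss(stretched, per_component = TRUE)
  expect_gt(parts$bond, 0)
  expect_equal(parts$bond, 0.5 - 12 * 0.016, tolerance = 1e-9)
  expect_equal(parts$angle, 0)
  expect_equal(parts$clash, 0)
  # two atoms forced to 50% of their radius sum: clash term appears
  clashy <- rec
  h1 <- as.numeric(rec$atoms[1, c("x", "y", "z")])
  lsel <- which(clashy$atoms$res == length(rec))[1]
  target_d <- 0.5 * (fvforge:::atom_radius(clashy$atoms$atom[lsel]) +
                       fvforge:::atom_radius(rec$atoms$atom[1]))
  clashy$atoms[lsel, c("x", "y", "z")] <- as.list(h1 + c(target_d, 0, 0))
  parts2 <- violation_loss(clashy, per_component = TRUE)
  expect_gt(parts2$clash, 0)
})

test_that("pLDDT cross-entropy matches closed forms and bins boundaries", {
  K <- 50
  onehot <- matrix(0, 3, K)
  truth <- c(0.31, 0.999, 1.0)
  idx <- pmin(floor(truth * K), K - 1) + 1
  onehot[cbind(1:3, idx)] <- 1
  expect_equal(plddt_loss(bin_distribution(onehot), truth), 0, tolerance = 1e-9)
  unif <- bin_distribution(matrix(1 / K, 4, K))
  expect_equal(plddt_loss(unif, rep(0.5, 4)), log(K), tolerance = 1e-9)
  # lDDT of exactly 1.0 falls in the top (right-closed) bin
  expect_equal(idx[3], K)
  expect_error(plddt_loss(unif, c(0.5, 0.5, 0.5, 1.2)), "\\[0, 1\\]")
})

test_that("stage combination applies the published weights", {
  parts <- list(backbone_fape = 1, final_fape = 2, torsion = 3,
                violation = 7, plddt_ce = 2)
  s1 <- combine_losses(parts, stage = 1)
  expect_equal(s1, 1 + 2 + 3 + 0.02)
  # stage 1 ignores the violation term entirely
  parts2 <- parts; parts2$violation <- 1e6
  expect_equal(combine_losses(parts2, stage = 1), s1)
  expect_equal(combine_losses(parts, stage = 2), s1 + 7)
  zero <- list(backbone_fape = 0, final_fape = 0, torsion = 0,
               violation = 0, plddt_ce = 0)
  expect_equal(combine_losses(zero, stage = 2), 0)
})
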