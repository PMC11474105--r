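test_that("backbone frames sit on CA and are equivariant", {
  rec <- small_fv()
  fr <- frames_from_backbone(rec)
  expect_equal(fr$t, atom_coords(rec, "CA"), ignore_attr = TRUE)
  set.seed(11)
  for (k in 1:100) {
    Tg <- random_rigid()
    fr2 <- frames_from_backbone(transform_structure(rec, Tg))
    comp <- rigid_compose(Tg, fr)
    expect_lt(max(abs(fr2$R - comp$R)), 1e-9)
    expect_lt(max(abs(fr2$t - comp$t)), 1e-9)
  }
})

test_that("frame-local backbone coordinates are canonical across residues", {
  rec <- small_fv()
  fr <- frames_from_backbone(rec)
  Nm <- atom_coords(rec, "N"); CAm <- atom_coords(rec, "CA")
  Cm <- atom_coords(rec, "C")
  locals <- sapply(seq_len(length(rec)), function(i) {
    inv <- rigid_invert(fr[i])
    c(rigid_apply(inv, Nm[i, ]), rigid_apply(inv, CAm[i, ]),
      rigid_apply(inv, Cm[i, ]))
  })
  # identical local coordinates for every residue, matching the ideal template
  expect_lt(max(abs(locals - locals[, 1])), 1e-6)
  bl <- fvforge:::backbone_local_coords()
  expect_equal(as.numeric(locals[, 1]), as.numeric(t(bl)), tolerance = 1e-6)
})

test_that("collinear backbone triggers a degenerate-geometry error", {
  rec <- small_fv()
  bad <- rec
  ca <- atom_coords(rec, "CA")[1, ]; cc <- atom_coords(rec, "C")[1, ]
  sel <- bad$atoms$res == 1 & bad$atoms$atom == "N"
  bad$atoms[sel, c("x", "y", "z")] <- as.list(2 * ca - cc)  # N on the CA-C line
  expect_error(frames_from_backbone(bad), "collinear|degenerate")
})

test_that("Kabsch superposition recovers rigid transforms and is optimal", {
  set.seed(21)
  # exact recovery
  for (k in 1:10) {
    mob <- random_points(8)
    Tg <- random_rigid()
    fit <- kabsch_superpose(mob, rigid_apply(Tg, mob))
    expect_lt(fit$rmsd, 1e-9)
  }
  fit0 <- kabsch_superpose(random_points(6, seed = 1), random_points(6, seed = 1))
  expect_lt(max(abs(fit0$transform$R[, , 1] - diag(3))), 1e-9)
  expect_lt(fit0$rmsd, 1e-12)
  # agreement with an established superposition routine on noisy pairs
  mob <- random_points(20, seed = 8)
  tgt <- rigid_apply(random_rigid(), mob) + matrix(rnorm(60, sd = 0.3), 20, 3)
  fit <- kabsch_superpose(mob, tgt)
  b3d <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(tgt)), mobile = as.numeric(t(mob))))
  rms_b3d <- sqrt(mean(rowSums((matrix(b3d, ncol = 3, byrow = TRUE) - tgt)^2)))
  expect_equal(fit$rmsd, rms_b3d, tolerance = 1e-6)
  # weighted case: zero-weight points are ignored
  w <- c(rep(1, 15), rep(0, 5))
  tgt2 <- tgt; tgt2[16:20, ] <- tgt2[16:20, ] + 100
  fitw <- kabsch_superpose(mob, tgt2, weights = w)
  expect_equal(fitw$rmsd, kabsch_superpose(mob[1:15, ], tgt2[1:15, ])$rmsd,
               tolerance = 1e-9)
  expect_error(kabsch_superpose(mob[1:2, ], tgt[1:2, ]), "3 points")
  expect_error(kabsch_superpose(mob, tgt, weights = rep(0, 20)), "zero")
})

test_that("dihedral follows the standard convention and mirror antisymmetry", {
  p2 <- c(1, 0, 0); p3 <- c(0, 0, 0)
  expect_equal(dihedral(c(1, 1, 0), p2, p3, c(-1, -1, 0)), pi)
  expect_equal(dihedral(c(1, 1, 0), p2, p3, c(-1, 1, 0)), 0)
  set.seed(31)
  for (k in 1:100) {
    ps <- lapply(1:4, function(i) rnorm(3))
    a1 <- dihedral(ps[[1]], ps[[2]], ps[[3]], ps[[4]])
    # independent construction: project end points onto the plane normal to
    # the central bond and measure the signed angle there
    b <- ps[[3]] - ps[[2]]; b <- b / sqrt(sum(b^2))
    u <- ps[[1]] - ps[[2]]; u <- u - sum(u * b) * b
    v <- ps[[4]] - ps[[3]]; v <- v - sum(v * b) * b
    cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    # IUPAC: viewed along the central bond, clockwise is positive
    a2 <- atan2(-sum(cr * b), sum(u * v))
    expect_equal(a1, if (a2 <= -pi + 1e-15) pi else a2, tolerance = 1e-9)
    # mirror: negating z negates the angle (up to the pi branch)
    mz <- function(p) p * c(1, 1, -1)
    a3 <- dihedral(mz(ps[[1]]), mz(ps[[2]]), mz(ps[[3]]), mz(ps[[4]]))
    expect_equal(abs(a3), abs(a1), tolerance = 1e-9)
    if (abs(abs(a1) - pi) > 1e-9 && abs(a1) > 1e-9) {
      expect_equal(a3, -a1, tolerance = 1e-9)
    }
  }
  expect_error(dihedral(p2, p2, p3, c(0, 1, 0)), "degenerate")
})
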