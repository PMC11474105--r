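test_that("lDDT-CA matches the hand-counted two-residue case and perfection", {
  rec <- small_fv()
  expect_equal(lddt_ca(rec, rec), rep(1, length(rec)))
  # true distance 10, predicted 10.6: preserved at 1/2/4, broken at 0.5
  true_ca <- rbind(c(0, 0, 0), c(10, 0, 0))
  pred_ca <- rbind(c(0, 0, 0), c(10.6, 0, 0))
  expect_equal(lddt_ca(pred_ca, true_ca), c(0.75, 0.75))
})

test_that("lDDT-CA equals the brute-force oracle and is superposition-free", {
  set.seed(51)
  for (k in 1:25) {
    n <- sample(5:20, 1)
    true_ca <- random_points(n, sd = 6)
    pred_ca <- true_ca + matrix(rnorm(3 * n, sd = 0.8), n, 3)
    got <- lddt_ca(pred_ca, true_ca)
    expect_equal(got, lddt_oracle(pred_ca, true_ca), tolerance = 1e-12)
    # invariant to independent rigid motions of either structure
    got2 <- lddt_ca(rigid_apply(random_rigid(), pred_ca),
                    rigid_apply(random_rigid(), true_ca))
    expect_equal(got2, got, tolerance = 1e-9)
  }
})

test_that("region RMSD is zero for rigid copies and localises perturbations", {
  rec <- small_fv()
  moved <- transform_structure(rec, random_rigid(seed = 3))
  rr <- region_rmsd(moved, rec)
  expect_equal(nrow(rr), 8L)
  expect_lt(max(rr$rmsd), 1e-9)
  expect_lt(max(region_rmsd(rec, rec)$rmsd), 1e-12)
  # perturbing only CDRH3 makes it the worst heavy-chain region
  pert <- perturb(rec, noise_sd = 1.5, regions = "CDRH3", seed = 9)
  rp <- region_rmsd(pert, rec)
  h3 <- rp$rmsd[rp$region == "CDRH3"]
  expect_gt(h3, max(rp$rmsd[rp$region %in% c("CDRH1", "CDRH2", "FWH")]))
  # independent align-then-measure oracle
  for (ch in c("H", "L")) {
    res_ids <- which(rec$chain == ch)
    sel <- function(r) {
      at <- r$atoms[r$atoms$res %in% res_ids &
                      r$atoms$atom %in% c("N", "CA", "C", "O"), ]
      at[order(at$res, match(at$atom, c("N", "CA", "C", "O"))), ]
    }
    ap <- sel(pert); at <- sel(rec)
    fit <- kabsch_superpose(as.matrix(ap[, c("x", "y", "z")]),
                            as.matrix(at[, c("x", "y", "z")]))
    moved <- rigid_apply(fit$transform, as.matrix(ap[, c("x", "y", "z")]))
    d2 <- rowSums((moved - as.matrix(at[, c("x", "y", "z")]))^2)
    for (rg in unique(rec$region[res_ids])) {
      oracle <- sqrt(mean(d2[rec$region[ap$res] == rg]))
      expect_equal(rp$rmsd[rp$region == rg], oracle, tolerance = 1e-9)
    }
  }
})

test_that("expected pLDDT is the bin-midpoint expectation on a 0-100 scale", {
  K <- 50
  onehot <- matrix(0, 3, K); onehot[cbind(1:3, c(1, 25, 50))] <- 1
  expect_equal(expected_plddt(bin_distribution(onehot)),
               100 * (c(1, 25, 50) - 0.5) / K)
  unif <- bin_distribution(matrix(1 / K, 2, K))
  expect_equal(expected_plddt(unif), c(50, 50))
  set.seed(52)
  p <- matrix(rexp(10 * K), 10, K); p <- p / rowSums(p)
  ep <- expected_plddt(bin_distribution(p))
  expect_true(all(ep >= 1 & ep <= 99))
})

test_that("pLDDT aggregation means over scopes and respects empty scopes", {
  regions <- c("CDRH3", "CDRH3", "CDRH3", "FWH")
  expect_equal(aggregate_plddt(c(60, 70, 80, 10), regions, "CDRH3"), 70)
  expect_equal(aggregate_plddt(rep(42, 4), regions, "full"), 42)
  expect_true(is.na(aggregate_plddt(c(1, 2, 3, 4), regions, "CDRL1")))
  # full mean equals the residue-count-weighted mean of region means
  set.seed(53)
  rec <- small_fv()
  v <- runif(length(rec), 30, 95)
  per_region <- vapply(region_levels(), function(rg)
    aggregate_plddt(v, rec$region, rg), 0)
  counts <- table(factor(rec$region, levels = region_levels()))
  expect_equal(aggregate_plddt(v, rec$region, "full"),
               sum(per_region * as.numeric(counts)) / sum(counts))
})

test_that("calibration matches textbook formulas and flags degenerate input", {
  set.seed(54)
  x <- rnorm(30); y <- 2 * x + rnorm(30, sd = 0.5)
  cal <- calibration(x, y)
  mx <- mean(x); my <- mean(y)
  pearson_direct <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  expect_equal(cal$pearson, pearson_direct, tolerance = 1e-12)
  expect_equal(calibration(x, -x)$pearson, -1)
  # rank-preserving monotone transform leaves spearman unchanged
  expect_equal(calibration(x, exp(y))$spearman, cal$spearman)
  expect_warning(out <- calibration(rep(1, 5), rnorm(5)), "constant")
  expect_true(is.na(out$pearson))
  expect_error(calibration(1:2, 1:2), "at least 3")
})

test_that("retention thresholds strictly and handles boundary thresholds", {
  cal <- make_calibration_set(n = 100, n_above = 32, n_accurate = 26, seed = 7)
  rc <- retention_curve(cal$plddt, cal$rmsd, 85, 2)
  expect_equal(rc$fraction_retained, 0.32)
  expect_equal(rc$fraction_below_cutoff, 26 / 32)
  low <- retention_curve(cal$plddt, cal$rmsd, min(cal$plddt) - 1, 2)
  expect_equal(low$fraction_retained, 1)
  expect_equal(low$fraction_below_cutoff, mean(cal$rmsd < 2))
  high <- retention_curve(cal$plddt, cal$rmsd, max(cal$plddt) + 1, 2)
  expect_equal(high$fraction_retained, 0)
  expect_true(is.na(high$fraction_below_cutoff))
})
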