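test_that("mini-Fv fixtures are valid, seeded and violation-free", {
  rec <- make_mini_fv(fixture_spec(seed = 3))
  expect_s3_class(rec, "fv_structure")
  expect_equal(violation_loss(rec), 0)
  expect_setequal(unique(rec$region), region_levels())
  rec2 <- make_mini_fv(fixture_spec(seed = 3))
  expect_identical(rec$atoms, rec2$atoms)
  rec3 <- make_mini_fv(fixture_spec(seed = 4))
  expect_false(identical(rec$sequence, rec3$sequence))
  # stored labels agree with the shipped region table applied to the numbering
  pair <- pair_of(rec)
  expect_identical(assign_imgt_regions(pair), rec$region)
  # region lengths beyond the numbering capacity are rejected
  expect_error(make_mini_fv(fixture_spec(cdr_lengths = c(20L, 4L, 6L, 4L, 4L, 4L))),
               "capacity")
})

test_that("perturbation scopes regions, is identity at zero, and scales correctly", {
  rec <- small_fv()
  expect_identical(perturb(rec, 0), rec)
  p <- perturb(rec, 1.0, regions = "CDRH3", seed = 4)
  moved <- p$atoms$x != rec$atoms$x
  in_h3 <- rec$region[rec$atoms$res] == "CDRH3"
  expect_true(all(moved[in_h3]))
  expect_identical(p$atoms[!in_h3, ], rec$atoms[!in_h3, ])
  expect_error(perturb(rec, 1, regions = "CDRH4"), "unknown region")
  # RMS displacement over ~1e4 atom draws approaches noise_sd * sqrt(3)
  sd0 <- 0.8
  d2 <- unlist(lapply(1:95, function(s) {
    q <- perturb(rec, sd0, seed = s)
    rowSums((as.matrix(q$atoms[, c("x", "y", "z")]) -
               as.matrix(rec$atoms[, c("x", "y", "z")]))^2)
  }))
  expect_gt(length(d2), 1e4)
  expect_equal(sqrt(mean(d2)), sd0 * sqrt(3), tolerance = 0.1)
})

test_that("curation fixtures carry correct oracle labels", {
  plants <- list(nanobody = 2, resolution = 3, orientation = 2,
                 cdrh3_length = 2, species = 16)
  tab <- make_curation_table(n = 80, plants = plants, n_val = 5, n_test = 4,
                             n_legacy = 2, n_dedup = 3, seed = 8)
  expect_equal(nrow(tab), 80)
  expect_equal(tab$cdrh3_length, nchar(tab$cdrh3))
  expect_equal(sum(tab$planted_fail == "nanobody", na.rm = TRUE), 2)
  expect_true(all(!tab$has_light_chain[which(tab$planted_fail == "nanobody")]))
  expect_true(all(tab$resolution[which(tab$planted_fail == "resolution")] > 3.5))
  expect_true(all(tab$cdrh3_length[which(tab$planted_fail == "cdrh3_length")] > 30))
  # oracle labels agree with single-filter outcomes
  out <- filter_nanobody(tab)
  expect_setequal(attr(out, "removed")$entry_id,
                  tab$entry_id[which(tab$planted_fail == "nanobody")])
  out <- filter_cdrh3_length(tab, 30)
  expect_setequal(attr(out, "removed")$entry_id,
                  tab$entry_id[which(tab$planted_fail == "cdrh3_length")])
  # inconsistent species plants are refused
  expect_error(make_curation_table(n = 80, plants = utils::modifyList(
    plants, list(species = 10)), seed = 1), "inconsistent plants")
  # zero plants: only split allocation removes entries
  tab0 <- make_curation_table(n = 60, plants = list(nanobody = 0, resolution = 0,
                                                    orientation = 0,
                                                    cdrh3_length = 0, species = 0),
                              n_val = 4, n_test = 3, n_legacy = 1, n_dedup = 0,
                              seed = 9)
  legacy <- tab0$entry_id[tab0$eval_role == "legacy"]
  res <- run_curation(tab0, curation_config(n_val = 4, n_test = 3,
                                            legacy_test_ids = legacy))
  st <- res$report$stages
  expect_equal(sum(st$n_removed[st$stage != "split"]), 0)
})

test_that("calibration plants produce the planted counts and rank patterns", {
  cal <- make_calibration_set(n = 100, n_above = 32, n_accurate = 26,
                              threshold = 85, cutoff = 2, seed = 3)
  expect_equal(sum(cal$plddt > 85), 32)
  expect_equal(sum(cal$rmsd[cal$plddt > 85] < 2), 26)
  anti <- make_calibration_set(n = 50, pattern = "antimonotone")
  expect_equal(calibration(anti$plddt, anti$rmsd)$spearman, -1)
  expect_warning(calibration(rep(50, 3), c(1, 2, 3)), "constant")
})
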