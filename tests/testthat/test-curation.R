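base_table <- function(n = 40, seed = 2) {
  make_curation_table(n = n, plants = list(nanobody = 0, resolution = 0,
                                           orientation = 0, cdrh3_length = 0,
                                           species = 0),
                      n_val = 4, n_test = 3, n_legacy = 1, n_dedup = 0,
                      seed = seed)
}

test_that("resolution filter reads 'above' strictly and flags missing values", {
  tab <- base_table()
  tab$resolution[1] <- 3.6; tab$resolution[2] <- 3.5; tab$resolution[3] <- NA
  out <- filter_resolution(tab, 3.5)
  removed <- attr(out, "removed")$entry_id
  expect_setequal(removed, tab$entry_id[c(1, 3)])
  expect_true(tab$entry_id[2] %in% out$entry_id)
  empty <- filter_resolution(tab[0, ], 3.5)
  expect_equal(nrow(empty), 0)
})

test_that("nanobody filter removes exactly the unpaired entries", {
  tab <- base_table()
  tab$has_light_chain[c(4, 9, 17)] <- FALSE
  out <- filter_nanobody(tab)
  expect_equal(nrow(out), nrow(tab) - 3)
  expect_setequal(attr(out, "removed")$entry_id, tab$entry_id[c(4, 9, 17)])
})

test_that("orientation filter uses one-pass statistics with a strict boundary", {
  tab <- base_table(n = 60)
  # plant an outlier at mean + 4 SD of the resulting column
  v <- tab$os1
  mu <- mean(v); s <- sd(v)
  out <- filter_orientation_outliers(tab, 3.5,
                                     center = list(os1 = mu, os2 = 0, os3 = 0,
                                                   os4 = 0, os5 = 0, os6 = 0),
                                     scale = list(os1 = s, os2 = 1, os3 = 1,
                                                  os4 = 1, os5 = 1, os6 = 1))
  expect_equal(nrow(out), nrow(tab))  # baseline draws are within 2.5 SD
  tab2 <- tab
  tab2$os1[5] <- mu + 4 * s
  out2 <- filter_orientation_outliers(tab2, 3.5,
                                      center = list(os1 = mu, os2 = 0, os3 = 0,
                                                    os4 = 0, os5 = 0, os6 = 0),
                                      scale = list(os1 = s, os2 = 1, os3 = 1,
                                                   os4 = 1, os5 = 1, os6 = 1))
  expect_equal(attr(out2, "removed")$entry_id, tab2$entry_id[5])
  # exactly 3.5 SD is kept (strict >)
  tab3 <- tab
  tab3$os1[5] <- mu + 3.5 * s
  out3 <- filter_orientation_outliers(tab3, 3.5,
                                      center = list(os1 = mu, os2 = 0, os3 = 0,
                                                    os4 = 0, os5 = 0, os6 = 0),
                                      scale = list(os1 = s, os2 = 1, os3 = 1,
                                                   os4 = 1, os5 = 1, os6 = 1))
  expect_equal(nrow(out3), nrow(tab3))
  # zero-spread statistics are excluded rather than dividing by zero
  tab4 <- tab; tab4$os2 <- 1
  expect_message(out4 <- filter_orientation_outliers(tab4, 3.5), "zero spread")
  expect_equal(nrow(out4), nrow(tab4))
})

test_that("CDRH3 length filter reads 'over 30' strictly", {
  tab <- base_table()
  long31 <- paste(rep("A", 31), collapse = "")
  long30 <- paste(rep("A", 30), collapse = "")
  tab$cdrh3[1] <- long31; tab$cdrh3_length[1] <- 31L
  tab$cdrh3[2] <- long30; tab$cdrh3_length[2] <- 30L
  out <- filter_cdrh3_length(tab, 30)
  expect_equal(attr(out, "removed")$entry_id, tab$entry_id[1])
  expect_true(tab$entry_id[2] %in% out$entry_id)
})

test_that("species filter supports both the literal and the rare reading", {
  tab <- base_table(n = 40)
  tab$species[1:20] <- "mus_synthetic"
  lit <- filter_species_frequency(tab, 15, mode = "common")
  expect_equal(sum(attr(lit, "removed")$entry_id %in% tab$entry_id[1:20]), 20)
  # under the rare reading the 20-strong species survives and singletons go
  rare <- filter_species_frequency(tab, 15, mode = "rare")
  expect_true(all(tab$entry_id[1:20] %in% rare$entry_id))
  expect_equal(nrow(rare), 20)
  # single-species input below threshold is untouched under the literal mode
  tab2 <- base_table(n = 10); tab2$species <- "homo_sapiens"
  expect_equal(nrow(filter_species_frequency(tab2, 15, "common")), 10)
})

test_that("validation/test selection enforces eligibility and determinism", {
  tab <- make_curation_table(n = 60, plants = list(nanobody = 0, resolution = 0,
                                                   orientation = 0,
                                                   cdrh3_length = 0, species = 0),
                             n_val = 6, n_test = 5, n_legacy = 2, n_dedup = 0,
                             seed = 4)
  legacy <- tab$entry_id[tab$eval_role == "legacy"]
  sel <- select_validation_test(tab, n_val = 6, n_test = 5,
                                legacy_test_ids = legacy, seed = 1)
  # with exactly 6 eligible entries, all are selected, deterministically
  expect_setequal(sel$val$entry_id, tab$entry_id[tab$eval_role == "val"])
  sel2 <- select_validation_test(tab, n_val = 6, n_test = 5,
                                 legacy_test_ids = legacy, seed = 1)
  expect_identical(sel$val$entry_id, sel2$val$entry_id)
  expect_identical(sel$test$entry_id, sel2$test$entry_id)
  expect_length(intersect(sel$val$entry_id, sel$test$entry_id), 0)
  expect_true(all(legacy %in% sel$test$entry_id))
  # validation candidates must be human with resolution < 2.5 and CDRH3 > 22
  expect_true(all(sel$val$human_annotated))
  expect_true(all(sel$val$resolution < 2.5))
  expect_true(all(sel$val$cdrh3_length > 22))
  # shortfall errors are explicit
  expect_error(select_validation_test(tab, n_val = 50, n_test = 5,
                                      legacy_test_ids = legacy, seed = 1),
               "insufficient validation-eligible")
})

test_that("deduplication removes any same-region CDR collision", {
  tab <- base_table(n = 30)
  eval_set <- tab[1:5, ]
  train <- tab[6:30, ]
  train$cdrl2[3] <- eval_set$cdrl2[2]          # single-region collision
  train$cdrh1[7] <- tolower(eval_set$cdrh1[1]) # case-normalised match
  out <- dedup_train_against_eval(train, list(eval_set))
  expect_setequal(attr(out, "removed")$entry_id, train$entry_id[c(3, 7)])
  # a cross-region match (H1 string appearing as L1) is not a collision
  train2 <- tab[6:30, ]
  train2$cdrl1[1] <- eval_set$cdrh1[1]
  expect_equal(nrow(dedup_train_against_eval(train2, list(eval_set))), 25)
})

test_that("the full pipeline accounts for every entry and is leakage-safe", {
  plants <- list(nanobody = 5, resolution = 5, orientation = 3,
                 cdrh3_length = 4, species = 20)
  tab <- make_curation_table(n = 200, plants = plants, n_val = 10, n_test = 8,
                             n_legacy = 3, n_dedup = 7, seed = 6)
  legacy <- tab$entry_id[tab$eval_role == "legacy"]
  cfg <- curation_config(n_val = 10, n_test = 8, legacy_test_ids = legacy,
                         seed = 2)
  res <- run_curation(tab, cfg)
  st <- res$report$stages
  expect_equal(st$n_in - st$n_removed, st$n_retained)
  expect_equal(st$n_in[-1], st$n_retained[-nrow(st)])
  got <- stats::setNames(st$n_removed, st$stage)
  expect_equal(got[["nanobody"]], plants$nanobody)
  expect_equal(got[["resolution"]], plants$resolution)
  expect_equal(got[["orientation"]], plants$orientation)
  expect_equal(got[["cdrh3_length"]], plants$cdrh3_length)
  expect_equal(got[["species"]], plants$species)
  expect_equal(got[["dedup"]], 7)
  # exhaustive leakage check
  ev <- rbind(res$val, res$test)
  for (col in fvforge:::cdr_columns()) {
    expect_length(intersect(toupper(res$train[[col]]), toupper(ev[[col]])), 0)
  }
  # filter stages are idempotent on their own output with frozen statistics
  s <- res$train
  frozen_mu <- as.list(colMeans(tab[paste0("os", 1:6)]))
  frozen_sd <- lapply(tab[paste0("os", 1:6)], sd)
  for (f in list(function(x) filter_nanobody(x),
                 function(x) filter_resolution(x, 3.5),
                 function(x) filter_orientation_outliers(x, 3.5, frozen_mu,
                                                         frozen_sd),
                 function(x) filter_cdrh3_length(x, 30),
                 function(x) filter_species_frequency(x, 15, "common"))) {
    s2 <- f(s)
    expect_equal(nrow(s2), nrow(s))
    s <- s2
  }
  # empty input flows through with zero counts
  res0 <- tryCatch(run_curation(tab[0, ], cfg), error = function(e) e)
  expect_s3_class(res0, "error")  # split is impossible on an empty table
  expect_match(conditionMessage(res0), "insufficient|legacy")
})
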