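#' Curation configuration
#'
#' All thresholds of the dataset-construction pipeline, defaulting to the
#' published values: nanobody removal, resolution <= 3.5 Angstrom ("above 3.5"
#' removed, boundary kept), orientation outliers at |z| > 3.5 on any of the
#' six VH/VL orientation statistics, CDRH3 length <= 30 ("over 30" removed),
#' species occurring more than 15 times removed (literal reading; the rare
#' reading is available as a mode since the printed rule conflicts with its
#' stated outlier-removal intent), validation restricted to human entries
#' with resolution below 2.5 Angstrom and CDRH3 length > 22 (direction
#' configurable for the same reason), 150 validation / 100 test structures
#' with a reserved legacy test subset.
#'
#' @param max_resolution,orientation_sd,max_cdrh3,species_threshold filter
#'   thresholds.
#' @param species_mode `"common"` removes species occurring more than
#'   `species_threshold` times (literal); `"rare"` removes species occurring
#'   fewer than `species_threshold` times.
#' @param n_val,n_test split sizes; `legacy_test_ids` are reserved test ids.
#' @param val_max_res,val_cdrh3_len,val_cdrh3_direction validation
#'   eligibility rules.
#' @param seed seed for the (deterministic) sampling among eligible entries.
#' @return a list of class `curation_config`.
#' @export
curation_config <- function(max_resolution = 3.5, orientation_sd = 3.5,
                            max_cdrh3 = 30L, species_threshold = 15L,
                            species_mode = c("common", "rare"),
                            n_val = 150L, n_test = 100L,
                            legacy_test_ids = character(),
                            val_max_res = 2.5, val_cdrh3_len = 22L,
                            val_cdrh3_direction = c("greater", "less"),
                            seed = 1L) {
  structure(list(max_resolution = max_resolution,
                 orientation_sd = orientation_sd,
                 max_cdrh3 = as.integer(max_cdrh3),
                 species_threshold = as.integer(species_threshold),
                 species_mode = match.arg(species_mode),
                 n_val = as.integer(n_val), n_test = as.integer(n_test),
                 legacy_test_ids = legacy_test_ids,
                 val_max_res = val_max_res,
                 val_cdrh3_len = as.integer(val_cdrh3_len),
                 val_cdrh3_direction = match.arg(val_cdrh3_direction),
                 seed = as.integer(seed)), class = "curation_config")
}

cdr_columns <- function() c("cdrh1", "cdrh2", "cdrh3", "cdrl1", "cdrl2", "cdrl3")

check_entries <- function(entries) {
  entries <- tibble::as_tibble(entries)
  need <- c("entry_id", "species", "resolution", "has_light_chain",
            paste0("os", 1:6), cdr_columns(), "cdrh3_length", "human_annotated")
  miss <- setdiff(need, names(entries))
  if (length(miss)) stop("entry table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(entries$cdrh3_length != nchar(entries$cdrh3))
  if (length(bad)) stop("cdrh3_length inconsistent with cdrh3 at row(s): ",
                        paste(utils::head(bad, 5), collapse = ", "))
  entries
}

mark_removed <- function(entries, removed_mask, filter_name) {
  kept <- entries[!removed_mask, , drop = FALSE]
  removed <- entries[removed_mask, , drop = FALSE]
  attr(kept, "removed") <- tibble::tibble(
    entry_id = removed$entry_id,
    filter = if (nrow(removed)) filter_name else character())
  kept
}

#' Curation filters
#'
#' Each filter takes and returns an entry tibble; the removed rows are
#' recorded in the `removed` attribute (entry id + filter name) so the
#' pipeline report can account for every entry. See [curation_config()] for
#' the boundary conventions ("above"/"over"/">" are read strictly).
#'
#' @param entries a curation entry tibble (see [make_curation_table()] for
#'   the column contract).
#' @param max_res resolution cut (keep iff resolution <= max_res); entries
#'   with missing resolution are removed and flagged, never silently kept.
#' @return the retained entries with a `removed` attribute.
#' @export
filter_resolution <- function(entries, max_res = 3.5) {
  entries <- check_entries(entries)
  bad <- is.na(entries$resolution) | entries$resolution > max_res
  mark_removed(entries, bad, "resolution")
}

#' @rdname filter_resolution
#' @export
filter_nanobody <- function(entries) {
  entries <- check_entries(entries)
  mark_removed(entries, !entries$has_light_chain, "nanobody")
}

#' @rdname filter_resolution
#' @param n_sd z-score threshold (strict: exactly `n_sd` is kept).
#' @param center,scale optional frozen per-statistic means and standard
#'   deviations (named by `os1`..`os6`); by default both are computed once on
#'   the input set (no iteration).
#' @export
filter_orientation_outliers <- function(entries, n_sd = 3.5, center = NULL,
                                        scale = NULL) {
  entries <- check_entries(entries)
  stats_cols <- paste0("os", 1:6)
  n <- nrow(entries)
  if (!n) return(mark_removed(entries, logical(0), "orientation"))
  out <- rep(FALSE, n)
  for (col in stats_cols) {
    v <- entries[[col]]
    m <- if (is.null(center)) mean(v) else center[[col]]
    s <- if (is.null(scale)) stats::sd(v) else scale[[col]]
    if (!is.finite(s) || s == 0) {
      message("orientation statistic ", col,
              " has zero spread; excluded from the outlier test")
      next
    }
    out <- out | abs(v - m) / s > n_sd
  }
  mark_removed(entries, out, "orientation")
}

#' @rdname filter_resolution
#' @param max_len CDRH3 length cap (keep iff length <= max_len).
#' @export
filter_cdrh3_length <- function(entries, max_len = 30L) {
  entries <- check_entries(entries)
  mark_removed(entries, entries$cdrh3_length > max_len, "cdrh3_length")
}

#' @rdname filter_resolution
#' @param threshold species occurrence threshold.
#' @param mode `"common"` (literal rule: species occurring more than
#'   `threshold` times are removed) or `"rare"` (species occurring fewer than
#'   `threshold` times are removed).
#' @export
filter_species_frequency <- function(entries, threshold = 15L,
                                     mode = c("common", "rare")) {
  mode <- match.arg(mode)
  entries <- check_entries(entries)
  sp <- tolower(entries$species)
  # a missing species label is treated as a singleton species per entry
  missing <- is.na(sp) | sp == ""
  sp[missing] <- paste0(".missing_", seq_len(nrow(entries))[missing])
  counts <- table(sp)
  k <- as.integer(counts[sp])
  bad <- if (mode == "common") k > threshold else k < threshold
  mark_removed(entries, bad, "species")
}

#' Validation/test selection
#'
#' Validation entries are drawn only from human-annotated entries with
#' resolution strictly below `val_max_res` that satisfy the CDRH3-length rule
#' (`> val_cdrh3_len` under the default literal direction). The test set is
#' the reserved legacy ids plus additional human entries sampled up to
#' `n_test`. Selection is seeded and deterministic; validation and test are
#' disjoint.
#'
#' @param entries post-filter entry tibble.
#' @param n_val,n_test set sizes.
#' @param legacy_test_ids reserved test entry ids (kept in test regardless of
#'   eligibility rules).
#' @param val_max_res,val_cdrh3_len,val_cdrh3_direction eligibility rules.
#' @param seed integer seed.
#' @return list with tibbles `val`, `test`, `rest`.
#' @export
select_validation_test <- function(entries, n_val = 150L, n_test = 100L,
                                   legacy_test_ids = character(),
                                   val_max_res = 2.5, val_cdrh3_len = 22L,
                                   val_cdrh3_direction = c("greater", "less"),
                                   seed = 1L) {
  val_cdrh3_direction <- match.arg(val_cdrh3_direction)
  entries <- check_entries(entries)
  legacy <- entries$entry_id %in% legacy_test_ids
  if (sum(legacy) < length(legacy_test_ids)) {
    missing <- setdiff(legacy_test_ids, entries$entry_id)
    stop("legacy test id(s) absent from the entries: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  len_ok <- if (val_cdrh3_direction == "greater") {
    entries$cdrh3_length > val_cdrh3_len
  } else {
    entries$cdrh3_length < val_cdrh3_len
  }
  val_eligible <- !legacy & entries$human_annotated &
    entries$resolution < val_max_res & len_ok
  if (sum(val_eligible) < n_val) {
    stop("insufficient validation-eligible entries: need ", n_val,
         ", have ", sum(val_eligible))
  }
  with_seed(seed, {
    val_idx <- sort(sample(which(val_eligible), n_val))
    n_extra <- n_test - sum(legacy)
    test_eligible <- !legacy & entries$human_annotated
    test_eligible[val_idx] <- FALSE
    if (sum(test_eligible) < n_extra) {
      stop("insufficient test-eligible entries: need ", n_extra,
           " beyond ", sum(legacy), " legacy, have ", sum(test_eligible))
    }
    test_idx <- sort(c(which(legacy), sample(which(test_eligible), n_extra)))
    list(val = entries[val_idx, ],
         test = entries[test_idx, ],
         rest = entries[-c(val_idx, test_idx), ])
  })
}

#' Remove training entries sharing any CDR with the evaluation sets
#'
#' A training entry is removed iff any one of its six CDR sequences exactly
#' matches the same-region CDR of any validation/test entry (exact string
#' match after case normalisation).
#'
#' @param train training entry tibble.
#' @param eval_sets a tibble or list of tibbles (validation, test).
#' @return the deduplicated training tibble with a `removed` attribute.
#' @export
dedup_train_against_eval <- function(train, eval_sets) {
  train <- check_entries(train)
  if (!is.data.frame(eval_sets)) eval_sets <- do.call(rbind, eval_sets)
  hit <- rep(FALSE, nrow(train))
  for (col in cdr_columns()) {
    hit <- hit | toupper(train[[col]]) %in% toupper(eval_sets[[col]])
  }
  mark_removed(train, hit, "dedup")
}

#' Run the full curation pipeline
#'
#' Stage order as published: nanobody and resolution filtering, orientation
#' outlier removal (statistics computed once on the post-resolution set),
#' CDRH3-length filter, species-frequency filter, validation/test selection,
#' and training-set deduplication against the evaluation sets. The report
#' accounts for every entry exactly once per stage (removed + retained =
#' stage input).
#'
#' @param entries a curation entry tibble.
#' @param config a [curation_config()].
#' @return list with `train`, `val`, `test` tibbles and `report` (stage
#'   counts, ordered removals, config echo).
#' @export
run_curation <- function(entries, config = curation_config()) {
  entries <- check_entries(entries)
  removals <- list()
  stages <- list()
  log_stage <- function(name, before, after) {
    stages[[length(stages) + 1]] <<- tibble::tibble(
      stage = name, n_in = nrow(before),
      n_removed = nrow(before) - nrow(after), n_retained = nrow(after))
    removals[[length(removals) + 1]] <<- attr(after, "removed")
  }
  s0 <- entries
  s1 <- filter_nanobody(s0);                         log_stage("nanobody", s0, s1)
  s2 <- filter_resolution(s1, config$max_resolution); log_stage("resolution", s1, s2)
  s3 <- filter_orientation_outliers(s2, config$orientation_sd)
  log_stage("orientation", s2, s3)
  s4 <- filter_cdrh3_length(s3, config$max_cdrh3);   log_stage("cdrh3_length", s3, s4)
  s5 <- filter_species_frequency(s4, config$species_threshold,
                                 config$species_mode)
  log_stage("species", s4, s5)
  split <- select_validation_test(
    s5, n_val = config$n_val, n_test = config$n_test,
    legacy_test_ids = config$legacy_test_ids,
    val_max_res = config$val_max_res, val_cdrh3_len = config$val_cdrh3_len,
    val_cdrh3_direction = config$val_cdrh3_direction, seed = config$seed)
  stages[[length(stages) + 1]] <- tibble::tibble(
    stage = "split", n_in = nrow(s5),
    n_removed = nrow(split$val) + nrow(split$test),
    n_retained = nrow(split$rest))
  train <- dedup_train_against_eval(split$rest,
                                    list(split$val, split$test))
  log_stage("dedup", split$rest, train)
  report <- list(stages = do.call(rbind, stages),
                 removals = do.call(rbind, removals),
                 seed = config$seed,
                 config = config)
  list(train = train, val = split$val, test = split$test, report = report)
}
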