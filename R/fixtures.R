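#' Fixture specifications for synthetic mini-Fv structures
#'
#' The fixture generator emulates the paired-Fv layout the models consume:
#' two chains of idealized backbone geometry (template peptide bond lengths
#' and angles, extended-strand framework with compact helical CDR loops),
#' synthetic IMGT numbering covering all eight regions, and seeded sequences.
#' It makes every module testable without downloads; it does not attempt a
#' realistic immunoglobulin fold.
#'
#' @param n_heavy,n_light residues per chain.
#' @param cdr_lengths integer vector of 6 CDR lengths
#'   (H1, H2, H3, L1, L2, L3).
#' @param noise_sd isotropic coordinate noise in Angstrom applied after
#'   building (0 = ideal geometry).
#' @param seed integer; fixes all randomness bitwise.
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_heavy = 24L, n_light = 24L,
                         cdr_lengths = c(4L, 4L, 6L, 4L, 4L, 4L),
                         noise_sd = 0, seed = 1L) {
  stopifnot(n_heavy >= 1, n_light >= 1, length(cdr_lengths) == 6,
            all(cdr_lengths >= 1), noise_sd >= 0)
  structure(list(n_heavy = as.integer(n_heavy), n_light = as.integer(n_light),
                 cdr_lengths = as.integer(cdr_lengths), noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "fixture_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# IMGT numbering for one chain: framework residues ending at/starting from the
# CDR boundaries, CDRs at 27.., 56.., 105..
chain_numbering <- function(n, cdr) {
  tb <- imgt_region_table()
  cap <- tb$to - tb$from + 1L
  if (any(cdr > cap)) {
    stop("CDR length(s) exceed numbering capacity (max ",
         paste(cap, collapse = "/"), " without insertion codes)")
  }
  n_fw <- n - sum(cdr)
  if (n_fw < 4) stop("chain too short for 4 framework segments")
  fw <- rep(n_fw %/% 4, 4)
  fw[seq_len(n_fw %% 4)] <- fw[seq_len(n_fw %% 4)] + 1L
  caps_fw <- c(26L, tb$from[2] - tb$to[1] - 1L, tb$from[3] - tb$to[2] - 1L, 128L - tb$to[3])
  if (any(fw > caps_fw)) stop("framework segment(s) exceed numbering capacity")
  c(seq(27L - fw[1], 26L),
    seq(27L, length.out = cdr[1]),
    seq(39L, length.out = fw[2]),
    seq(56L, length.out = cdr[2]),
    seq(105L - fw[3], 104L),
    seq(105L, length.out = cdr[3]),
    seq(118L, length.out = fw[4]))
}

build_chain_backbone <- function(n, phi, psi, omega = pi) {
  bi <- backbone_ideal()
  d2r <- pi / 180
  N <- matrix(0, n, 3); CA <- N; C <- N; O <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(bi$n_ca, 0, 0)
  a <- bi$ang_n_ca_c * d2r
  C[1, ] <- CA[1, ] + bi$ca_c * c(-cos(a), sin(a), 0)
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], bi$c_n,
                             bi$ang_ca_c_n * d2r, psi[i])
    CA[i + 1, ] <- nerf_place(CA[i, ], C[i, ], N[i + 1, ], bi$n_ca,
                              bi$ang_c_n_ca * d2r, omega)
    C[i + 1, ] <- nerf_place(C[i, ], N[i + 1, ], CA[i + 1, ], bi$ca_c,
                             bi$ang_n_ca_c * d2r, phi[i + 1])
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], bi$c_o,
                         bi$ang_ca_c_o * d2r, psi[i] + pi)
  }
  O[n, ] <- nerf_place(N[n, ], CA[n, ], C[n, ], bi$c_o,
                       bi$ang_ca_c_o * d2r, psi[n] + pi)
  list(N = N, CA = CA, C = C, O = O)
}

#' Build a synthetic mini-Fv structure
#'
#' @param spec a [fixture_spec()].
#' @return an `fv_structure` with N, CA, C, O backbone atoms, deterministic
#'   per seed, passing all structure invariants, with zero structural
#'   violation at `noise_sd = 0`.
#' @export
make_mini_fv <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    imgt_h <- chain_numbering(spec$n_heavy, spec$cdr_lengths[1:3])
    imgt_l <- chain_numbering(spec$n_light, spec$cdr_lengths[4:6])
    d2r <- pi / 180
    build <- function(n, imgt, chain_lab) {
      region <- imgt_region_of(imgt, rep(chain_lab, n))
      in_cdr <- grepl("^CDR", region)
      phi <- ifelse(in_cdr, -60, -120) * d2r
      psi <- ifelse(in_cdr, -45, 130) * d2r
      bb <- build_chain_backbone(n, phi, psi)
      list(bb = bb, region = region)
    }
    h <- build(spec$n_heavy, imgt_h, "H")
    l <- build(spec$n_light, imgt_l, "L")
    # place the light chain parallel to the heavy chain, well separated
    shift <- c(0, 25, 0)
    for (nm in c("N", "CA", "C", "O")) {
      l$bb[[nm]] <- sweep(l$bb[[nm]], 2, shift, "+")
    }
    n_tot <- spec$n_heavy + spec$n_light
    seqs <- sample(AA1, n_tot, replace = TRUE)
    mk_atoms <- function(bb, res0) {
      do.call(rbind, lapply(seq_len(nrow(bb$N)), function(i) {
        data.frame(res = res0 + i,
                   atom = c("N", "CA", "C", "O"),
                   x = c(bb$N[i, 1], bb$CA[i, 1], bb$C[i, 1], bb$O[i, 1]),
                   y = c(bb$N[i, 2], bb$CA[i, 2], bb$C[i, 2], bb$O[i, 2]),
                   z = c(bb$N[i, 3], bb$CA[i, 3], bb$C[i, 3], bb$O[i, 3]))
      }))
    }
    atoms <- rbind(mk_atoms(h$bb, 0L), mk_atoms(l$bb, spec$n_heavy))
    rec <- fv_structure(chain = rep(c("H", "L"), c(spec$n_heavy, spec$n_light)),
                        sequence = seqs,
                        imgt = c(imgt_h, imgt_l),
                        region = c(h$region, l$region),
                        atoms = atoms)
    if (spec$noise_sd > 0) {
      rec <- perturb(rec, spec$noise_sd, seed = spec$seed + 1L)
    }
    rec
  })
}

#' Perturb a structure with seeded isotropic noise
#'
#' Adds independent Gaussian displacement (`noise_sd` per coordinate, so the
#' expected per-atom displacement norm is `noise_sd * sqrt(3)` in RMS) to the
#' atoms of the selected regions only; other coordinates are untouched.
#'
#' @param record an `fv_structure`.
#' @param noise_sd Angstrom; 0 is the identity.
#' @param regions optional subset of [region_levels()] (default: all).
#' @param seed integer seed.
#' @return the perturbed `fv_structure`.
#' @export
perturb <- function(record, noise_sd, regions = NULL, seed = 1L) {
  stopifnot(noise_sd >= 0)
  if (noise_sd == 0) return(record)
  if (is.null(regions)) regions <- region_levels()
  bad <- setdiff(regions, region_levels())
  if (length(bad)) stop("unknown region name(s): ", paste(bad, collapse = ", "))
  sel <- record$region[record$atoms$res] %in% regions
  m <- sum(sel)
  with_seed(seed, {
    noise <- matrix(stats::rnorm(3 * m, sd = noise_sd), m, 3)
    record$atoms$x[sel] <- record$atoms$x[sel] + noise[, 1]
    record$atoms$y[sel] <- record$atoms$y[sel] + noise[, 2]
    record$atoms$z[sel] <- record$atoms$z[sel] + noise[, 3]
  })
  record
}

random_cdr <- function(len) {
  paste(sample(AA1, len, replace = TRUE), collapse = "")
}

#' Synthetic curation table with planted filter outcomes
#'
#' Builds a SAbDab-like entry table in which every deviation from the filter
#' rules is planted deliberately: each planted entry fails exactly one stage
#' of the curation pipeline, and the oracle label of the expected outcome is
#' carried in the `planted_fail` column (`NA` for compliant entries). Entries
#' destined for the validation/test split carry `eval_role` oracle labels;
#' exactly `n_val` entries are validation-eligible and exactly `n_test`
#' (legacy reserved plus additional human) are test-eligible, so the seeded
#' split is fully determined. `n_dedup` training entries copy one CDR from an
#' eval entry and must be removed by deduplication.
#'
#' @param n total number of entries.
#' @param plants named list of planted violation counts: `nanobody`,
#'   `resolution`, `orientation`, `cdrh3_length`, `species` (the species count
#'   must exceed the species-frequency threshold or be 0).
#' @param n_val,n_test,n_legacy,n_dedup split-plant sizes.
#' @param species_threshold the frequency threshold the species plant must
#'   exceed.
#' @param seed integer seed.
#' @return a tibble of curation entries with oracle columns `planted_fail`
#'   and `eval_role`.
#' @export
make_curation_table <- function(n = 200L,
                                plants = list(nanobody = 5L, resolution = 5L,
                                              orientation = 3L,
                                              cdrh3_length = 4L, species = 20L),
                                n_val = 10L, n_test = 8L, n_legacy = 3L,
                                n_dedup = 7L, species_threshold = 15L,
                                seed = 1L) {
  for (nm in c("nanobody", "resolution", "orientation", "cdrh3_length", "species")) {
    if (is.null(plants[[nm]])) plants[[nm]] <- 0L
  }
  if (plants$species > 0 && plants$species <= species_threshold) {
    stop("inconsistent plants: a species plant of ", plants$species,
         " does not exceed the frequency threshold ", species_threshold)
  }
  n_planted <- sum(unlist(plants))
  if (n_planted + n_val + n_test + n_dedup > n) stop("inconsistent plants: exceed n")
  with_seed(seed, {
    mk_entry <- function(i, cdrh3_len = sample(8:14, 1)) {
      cdrs <- c(random_cdr(sample(6:9, 1)), random_cdr(sample(6:9, 1)),
                random_cdr(cdrh3_len), random_cdr(sample(6:9, 1)),
                random_cdr(sample(6:9, 1)), random_cdr(sample(6:9, 1)))
      os <- pmin(2.5, pmax(-2.5, stats::rnorm(6)))
      tibble::tibble(entry_id = sprintf("syn%04d", i),
                     species = paste0("synthetic_species_", i),
                     resolution = stats::runif(1, 1.5, 3.4),
                     has_light_chain = TRUE,
                     os1 = os[1], os2 = os[2], os3 = os[3],
                     os4 = os[4], os5 = os[5], os6 = os[6],
                     heavy_seq = random_cdr(30), light_seq = random_cdr(30),
                     cdrh1 = cdrs[1], cdrh2 = cdrs[2], cdrh3 = cdrs[3],
                     cdrl1 = cdrs[4], cdrl2 = cdrs[5], cdrl3 = cdrs[6],
                     cdrh3_length = nchar(cdrs[3]),
                     human_annotated = FALSE,
                     planted_fail = NA_character_,
                     eval_role = "train")
    }
    entries <- do.call(rbind, lapply(seq_len(n), mk_entry))
    i <- 1L
    take <- function(k) { idx <- seq(i, length.out = k); i <<- i + k; idx }
    # validation-eligible plants: human, high resolution, long CDRH3
    idx <- take(n_val)
    entries$human_annotated[idx] <- TRUE
    entries$resolution[idx] <- stats::runif(n_val, 1.6, 2.4)
    for (j in idx) {
      entries$cdrh3[j] <- random_cdr(sample(23:28, 1))
      entries$cdrh3_length[j] <- nchar(entries$cdrh3[j])
    }
    entries$eval_role[idx] <- "val"
    # legacy test ids (reserved) + additional human test entries
    idx <- take(n_legacy); entries$eval_role[idx] <- "legacy"
    idx <- take(n_test - n_legacy)
    entries$human_annotated[idx] <- TRUE
    entries$eval_role[idx] <- "test"
    # dedup plants: copy one CDR (cycling over the six regions) from an eval
    # entry into a training entry
    eval_idx <- which(entries$eval_role != "train")
    cdr_cols <- c("cdrh1", "cdrh2", "cdrh3", "cdrl1", "cdrl2", "cdrl3")
    idx <- take(n_dedup)
    for (k in seq_along(idx)) {
      col <- cdr_cols[(k - 1L) %% 6L + 1L]
      src <- eval_idx[(k - 1L) %% length(eval_idx) + 1L]
      entries[[col]][idx[k]] <- entries[[col]][src]
      if (col == "cdrh3") {
        entries$cdrh3_length[idx[k]] <- nchar(entries$cdrh3[idx[k]])
      }
      entries$planted_fail[idx[k]] <- "dedup"
    }
    # filter plants
    idx <- take(plants$nanobody)
    entries$has_light_chain[idx] <- FALSE
    entries$planted_fail[idx] <- "nanobody"
    idx <- take(plants$resolution)
    entries$resolution[idx] <- stats::runif(plants$resolution, 3.6, 4.5)
    entries$planted_fail[idx] <- "resolution"
    idx <- take(plants$orientation)
    for (k in seq_along(idx)) {
      entries[[paste0("os", (k - 1L) %% 6L + 1L)]][idx[k]] <- 8
    }
    entries$planted_fail[idx] <- "orientation"
    idx <- take(plants$cdrh3_length)
    for (j in idx) {
      entries$cdrh3[j] <- random_cdr(sample(31:35, 1))
      entries$cdrh3_length[j] <- nchar(entries$cdrh3[j])
    }
    entries$planted_fail[idx] <- "cdrh3_length"
    idx <- take(plants$species)
    entries$species[idx] <- "synthetic_common_species"
    entries$planted_fail[idx] <- "species"
    entries
  })
}

#' Planted calibration sets for retention and correlation checks
#'
#' @param n number of structures.
#' @param n_above how many pLDDT values are planted strictly above the
#'   threshold.
#' @param n_accurate how many of the above-threshold structures get an RMSD
#'   strictly below the cutoff.
#' @param threshold,cutoff the retention threshold and RMSD cutoff the plant
#'   is built against.
#' @param pattern `"planted"` for the counting plant, `"antimonotone"` for an
#'   exactly rank-inverted pair (Spearman -1).
#' @param seed integer seed.
#' @return list with numeric vectors `plddt` and `rmsd`.
#' @export
make_calibration_set <- function(n = 100L, n_above = 32L, n_accurate = 26L,
                                 threshold = 85, cutoff = 2,
                                 pattern = c("planted", "antimonotone"),
                                 seed = 1L) {
  pattern <- match.arg(pattern)
  if (pattern == "antimonotone") {
    return(list(plddt = seq(99, 40, length.out = n),
                rmsd = seq(0.5, 6, length.out = n)))
  }
  stopifnot(n_above <= n, n_accurate <= n_above)
  with_seed(seed, {
    plddt <- c(stats::runif(n_above, threshold + 0.5, 99),
               stats::runif(n - n_above, 40, threshold - 0.5))
    rmsd <- c(stats::runif(n_accurate, 0.4, cutoff - 0.1),
              stats::runif(n_above - n_accurate, cutoff + 0.2, 6),
              stats::runif(n - n_above, 0.4, 6))
    ord <- sample.int(n)
    list(plddt = plddt[ord], rmsd = rmsd[ord])
  })
}
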