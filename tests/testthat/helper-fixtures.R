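# shared small fixtures, built once per test run

small_spec <- function(seed = 1L) {
  fixture_spec(n_heavy = 14L, n_light = 14L,
               cdr_lengths = c(3L, 3L, 4L, 3L, 3L, 3L), seed = seed)
}

small_fv <- local({
  cache <- new.env()
  function(seed = 1L) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) cache[[key]] <- make_mini_fv(small_spec(seed))
    cache[[key]]
  }
})

pair_of <- function(record) {
  sequence_pair(paste(record$sequence[record$chain == "H"], collapse = ""),
                paste(record$sequence[record$chain == "L"], collapse = ""),
                imgt_h = record$imgt[record$chain == "H"],
                imgt_l = record$imgt[record$chain == "L"])
}

random_rigid <- function(n = 1L, seed = NULL, trans_sd = 5) {
  if (!is.null(seed)) set.seed(seed)
  q <- matrix(rnorm(3 * n), n, 3)
  r <- quaternion_from_bcd(q[, 1], q[, 2], q[, 3])
  r$t <- matrix(rnorm(3 * n, sd = trans_sd), n, 3)
  r
}

random_points <- function(m, seed = NULL, sd = 8) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(3 * m, sd = sd), m, 3)
}

# brute-force per-residue lDDT-CA oracle: explicit double loop
lddt_oracle <- function(pred_ca, true_ca, radius = 15,
                        thresholds = c(0.5, 1, 2, 4)) {
  n <- nrow(true_ca)
  out <- numeric(n)
  for (i in seq_len(n)) {
    hits <- 0; cnt <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      dt <- sqrt(sum((true_ca[i, ] - true_ca[j, ])^2))
      if (dt >= radius) next
      dp <- sqrt(sum((pred_ca[i, ] - pred_ca[j, ])^2))
      for (th in thresholds) hits <- hits + (abs(dp - dt) < th)
      cnt <- cnt + length(thresholds)
    }
    out[i] <- if (cnt == 0) NA_real_ else hits / cnt
  }
  out
}

desk_weights <- function(config, pair, seed = 2L) {
  init_weights(config, ncol(one_hot_encode(pair)), seed = seed)
}

# two-residue scaffold with residue 1 of the requested type
scaffold <- function(code) {
  bl <- fvforge:::backbone_local_coords()
  atoms <- data.frame(res = rep(1:2, each = 3), atom = rep(c("N", "CA", "C"), 2),
                      x = c(bl[, 1], bl[, 1] + 20),
                      y = c(bl[, 2], bl[, 2]), z = c(bl[, 3], bl[, 3]))
  fv_structure(c("H", "L"), c(code, "G"), c(1L, 1L), atoms = atoms)
}

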