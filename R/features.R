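#' IMGT region definitions
#'
#' The shipped default region table follows the IMGT unique numbering: CDR1 is
#' positions 27-38, CDR2 is 56-65, CDR3 is 105-117 (all inclusive); everything
#' else is framework of its chain. Insertion codes (e.g. 111A in long CDRH3
#' loops) inherit the region of their integer position. The table is a config
#' asset (also shipped as `extdata/imgt_regions.csv`) so alternative schemes
#' can be swapped in.
#'
#' @return a data frame with columns `cdr`, `from`, `to`.
#' @export
imgt_region_table <- function() {
  data.frame(cdr = 1:3, from = c(27L, 56L, 105L), to = c(38L, 65L, 117L))
}

# vectorised region lookup used by constructors
imgt_region_of <- function(imgt, chain, table = imgt_region_table()) {
  cdr <- rep(0L, length(imgt))
  for (r in seq_len(nrow(table))) {
    cdr[imgt >= table$from[r] & imgt <= table$to[r]] <- table$cdr[r]
  }
  ifelse(cdr == 0L, ifelse(chain == "H", "FWH", "FWL"),
         paste0("CDR", chain, cdr))
}

#' Paired heavy/light variable-region sequences
#'
#' @param heavy,light amino-acid strings (one-letter codes; the 20 canonical
#'   letters plus `X`). Both chains are required (paired Fv).
#' @param imgt_h,imgt_l integer IMGT numbers per residue; default contiguous
#'   1..n numbering.
#' @param ins_h,ins_l insertion codes per residue (`""` if none).
#' @return an object of class `sequence_pair` with per-residue region labels.
#' @export
sequence_pair <- function(heavy, light, imgt_h = NULL, imgt_l = NULL,
                          ins_h = NULL, ins_l = NULL) {
  check_seq <- function(s, what) {
    if (!nzchar(s)) stop("empty ", what, " chain: a paired Fv requires both chains")
    letters <- strsplit(s, "")[[1]]
    bad <- which(!letters %in% c(AA1, "X"))
    if (length(bad)) {
      stop("unknown amino-acid letter '", letters[bad[1]], "' at ", what,
           " position ", bad[1])
    }
    letters
  }
  h <- check_seq(heavy, "heavy"); l <- check_seq(light, "light")
  if (is.null(imgt_h)) imgt_h <- seq_along(h)
  if (is.null(imgt_l)) imgt_l <- seq_along(l)
  if (is.null(ins_h)) ins_h <- rep("", length(h))
  if (is.null(ins_l)) ins_l <- rep("", length(l))
  stopifnot(length(imgt_h) == length(h), length(imgt_l) == length(l))
  structure(list(
    heavy = h, light = l,
    imgt = list(H = as.integer(imgt_h), L = as.integer(imgt_l)),
    ins = list(H = ins_h, L = ins_l),
    region = c(imgt_region_of(imgt_h, rep("H", length(h))),
               imgt_region_of(imgt_l, rep("L", length(l))))
  ), class = "sequence_pair")
}

#' @export
length.sequence_pair <- function(x) length(x$heavy) + length(x$light)

#' @export
print.sequence_pair <- function(x, ...) {
  cat("<sequence_pair> H:", paste(x$heavy, collapse = ""),
      " L:", paste(x$light, collapse = ""), "\n")
  invisible(x)
}

pair_chain <- function(pair) {
  c(rep("H", length(pair$heavy)), rep("L", length(pair$light)))
}

pair_sequence <- function(pair) c(pair$heavy, pair$light)

#' Assign IMGT regions to a sequence pair
#'
#' @param pair a `sequence_pair`.
#' @param table region boundary table, see [imgt_region_table()].
#' @return character vector of region labels, heavy residues first.
#' @export
assign_imgt_regions <- function(pair, table = imgt_region_table()) {
  if (is.null(pair$imgt)) stop("missing IMGT numbering")
  c(imgt_region_of(pair$imgt$H, rep("H", length(pair$heavy)), table),
    imgt_region_of(pair$imgt$L, rep("L", length(pair$light)), table))
}

#' One-hot sequence encoding
#'
#' Encodes each residue as a one-hot vector over the 20 canonical amino acids
#' plus `X`, concatenated with a two-column chain-indicator block (H, L).
#' Rows are ordered heavy chain first, then light.
#'
#' @param pair a `sequence_pair`.
#' @return an embedding matrix with `length(pair)` rows.
#' @export
one_hot_encode <- function(pair) {
  letters <- pair_sequence(pair)
  alphabet <- c(AA1, "X")
  idx <- match(letters, alphabet)
  n <- length(letters)
  out <- matrix(0, n, length(alphabet) + 2,
                dimnames = list(NULL, c(alphabet, "chainH", "chainL")))
  out[cbind(seq_len(n), idx)] <- 1
  out[, "chainH"] <- as.numeric(pair_chain(pair) == "H")
  out[, "chainL"] <- as.numeric(pair_chain(pair) == "L")
  out
}

#' Concatenate separately computed chain embeddings
#'
#' Chains are embedded separately (e.g. by a single-chain protein language
#' model) and their residue representations stacked heavy-first to give one
#' per-residue embedding of the full variable region.
#'
#' @param heavy_emb,light_emb per-residue embedding matrices of equal width.
#' @return the row-wise stack.
#' @export
concat_chain_embeddings <- function(heavy_emb, light_emb) {
  if (ncol(heavy_emb) != ncol(light_emb)) {
    stop("embedding widths differ: ", ncol(heavy_emb), " vs ", ncol(light_emb))
  }
  rbind(heavy_emb, light_emb)
}

# stable 32-bit string hash (polynomial rolling hash), platform-independent
str_hash <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 131 + x) %% 2147483647
  h
}

# small deterministic LCG uniform stream in [-1, 1]
lcg_stream <- function(seed, n) {
  out <- numeric(n)
  state <- seed %% 2147483647
  if (state == 0) state <- 1
  for (i in seq_len(n)) {
    state <- (state * 48271) %% 2147483647
    out[i] <- 2 * state / 2147483647 - 1
  }
  out
}

#' Deterministic mock per-residue embedder
#'
#' A stand-in for an external protein language model with the properties the
#' pipeline relies on: rows are a pure function of `(local sequence context,
#' width, seed)`, so identical residues in identical 5-mer contexts receive
#' identical rows, and no download or model inference is needed. Each chain is
#' embedded separately and the rows concatenated heavy-first.
#'
#' @param pair a `sequence_pair`.
#' @param width embedding width (default 1024, the width of the documented
#'   external embedder; fully configurable).
#' @param seed integer seed.
#' @return a `length(pair) x width` matrix.
#' @export
mock_embedder <- function(pair, width = 1024L, seed = 0L) {
  stopifnot(width >= 1)
  embed_chain <- function(letters) {
    s <- paste(letters, collapse = "")
    padded <- paste0("--", s, "--")
    t(vapply(seq_along(letters), function(i) {
      ctx <- substr(padded, i, i + 4)
      lcg_stream(str_hash(paste0(ctx, ":", width, ":", seed)), width)
    }, numeric(width)))
  }
  rbind(embed_chain(pair$heavy), embed_chain(pair$light))
}

#' Relative positional edge features
#'
#' For each ordered residue pair, a one-hot bucket over the within-chain
#' sequence offset clipped to `[-clip, clip]`, plus a dedicated final bucket
#' for cross-chain pairs (which carry no meaningful sequence offset). The
#' result is an `n x n x (2 clip + 2)` array.
#'
#' @param pair a `sequence_pair`.
#' @param clip maximum absolute offset before saturation (default 32).
#' @return a 3-d array of edge features.
#' @export
relative_position_encoding <- function(pair, clip = 32L) {
  stopifnot(clip >= 1)
  chain <- pair_chain(pair)
  n <- length(chain)
  width <- 2L * clip + 2L
  pos <- c(seq_along(pair$heavy), seq_along(pair$light))
  out <- array(0, c(n, n, width))
  off <- outer(pos, pos, "-")            # offset of j relative to i: pos_j - pos_i
  same <- outer(chain, chain, "==")
  bucket <- pmin(pmax(off, -clip), clip) + clip + 1L
  bucket[!same] <- width
  for (k in seq_len(width)) out[, , k][bucket == k] <- 1
  out
}
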