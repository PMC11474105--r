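#' Structure file input/output
#'
#' PDB files are read and written through bio3d with standard atom naming;
#' per-residue pLDDT values are written into the B-factor column on a 0-100
#' scale. mmCIF files are read through bio3d and written with a minimal
#' `atom_site` loop writer. Chains other than H and L are rejected (the
#' package models a single paired Fv).
#'
#' @param record an `fv_structure`.
#' @param path file path.
#' @return `read_structure` returns an `fv_structure`.
#' @name structure_io
NULL

#' @rdname structure_io
#' @export
write_structure_pdb <- function(record, path) {
  at <- record$atoms
  at <- at[order(at$res, match(at$atom, c("N", "CA", "C", "O"))), ]
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    resno = record$imgt[at$res],
    resid = aa_three(record$sequence[at$res]),
    insert = ifelse(record$imgt_ins[at$res] == "", "", record$imgt_ins[at$res]),
    chain = record$chain[at$res],
    elety = at$atom,
    o = rep(1, nrow(at)),
    b = round(at$b, 2))
  invisible(path)
}

#' @rdname structure_io
#' @export
write_structure_cif <- function(record, path) {
  at <- record$atoms
  at <- at[order(at$res, match(at$atom, c("N", "CA", "C", "O"))), ]
  resid <- aa_three(record$sequence[at$res])
  chain <- record$chain[at$res]
  resno <- record$imgt[at$res]
  ins <- ifelse(record$imgt_ins[at$res] == "", "?", record$imgt_ins[at$res])
  lines <- c("data_fvforge", "#", "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                      "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                      "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                      "auth_comp_id", "auth_asym_id", "auth_atom_id",
                      "pdbx_PDB_model_num")),
             sprintf(paste("ATOM %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f",
                           "1.00 %.2f ? %d %s %s %s 1"),
                     seq_len(nrow(at)), atom_element(at$atom), at$atom,
                     resid, chain, resno, ins, at$x, at$y, at$z, at$b,
                     resno, resid, chain, at$atom),
             "#")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname structure_io
#' @export
read_structure <- function(path) {
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path)
  } else {
    bio3d::read.pdb(path)
  }
  at <- pdb$atom
  at <- at[at$type == "ATOM", ]
  if (!all(at$chain %in% c("H", "L"))) {
    stop("expected chains H and L only, found: ",
         paste(setdiff(unique(at$chain), c("H", "L")), collapse = ", "))
  }
  at$insert[is.na(at$insert)] <- ""
  # first-conformer selection: drop alternate locations beyond the first
  if (!is.null(at$alt)) {
    at$alt[is.na(at$alt)] <- ""
    at <- at[at$alt %in% c("", "A"), ]
  }
  key <- paste(at$chain, at$resno, at$insert)
  at$res_key <- factor(key, levels = unique(key[order(match(at$chain, c("H", "L")))]))
  res_tab <- at[!duplicated(at$res_key), ]
  ord <- order(match(res_tab$chain, c("H", "L")))
  res_tab <- res_tab[ord, ]
  res_index <- match(at$res_key, res_tab$res_key)
  atoms <- data.frame(res = res_index, atom = at$elety,
                      x = at$x, y = at$y, z = at$z, b = at$b)
  fv_structure(chain = res_tab$chain,
               sequence = aa_one(res_tab$resid),
               imgt = res_tab$resno,
               imgt_ins = res_tab$insert,
               atoms = atoms[order(atoms$res), ])
}

#' Paired-FASTA input/output
#'
#' A paired entry is two records whose headers end in a `|H` / `|L` chain
#' tag (e.g. `>myab|H`). Reading returns a [sequence_pair()] with default
#' contiguous numbering unless a numbering CSV is supplied.
#'
#' @param path FASTA path.
#' @param numbering_csv optional CSV with columns `chain`, `imgt`, `ins`
#'   giving per-residue IMGT numbers in order (heavy rows first).
#' @return a `sequence_pair`.
#' @export
read_fasta_pair <- function(path, numbering_csv = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  tags <- toupper(sub(".*[|_ ]", "", names(seqs)))
  if (!all(c("H", "L") %in% tags)) {
    stop("FASTA must contain records tagged H and L (e.g. '>name|H')")
  }
  heavy <- as.character(seqs[[which(tags == "H")[1]]])
  light <- as.character(seqs[[which(tags == "L")[1]]])
  if (is.null(numbering_csv)) return(sequence_pair(heavy, light))
  num <- utils::read.csv(numbering_csv, stringsAsFactors = FALSE)
  if (is.null(num$ins)) num$ins <- ""
  num$ins[is.na(num$ins)] <- ""
  h <- num[toupper(num$chain) == "H", ]
  l <- num[toupper(num$chain) == "L", ]
  sequence_pair(heavy, light, imgt_h = h$imgt, imgt_l = l$imgt,
                ins_h = h$ins, ins_l = l$ins)
}

#' @rdname read_fasta_pair
#' @param pair a `sequence_pair`.
#' @param name entry name used in the headers.
#' @export
write_fasta_pair <- function(pair, path, name = "fv") {
  x <- Biostrings::AAStringSet(c(paste(pair$heavy, collapse = ""),
                                 paste(pair$light, collapse = "")))
  names(x) <- paste0(name, "|", c("H", "L"))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Embedding matrix import
#'
#' Reads a precomputed per-residue embedding from a delimited text file:
#' one row per residue (heavy chain rows first, then light), one column per
#' embedding dimension, no header.
#'
#' @param path file path (whitespace- or comma-delimited).
#' @return a numeric matrix.
#' @export
read_embedding_matrix <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  storage.mode(m) <- "double"
  if (!all(is.finite(m))) stop("embedding matrix contains non-finite values")
  unname(m)
}

#' Curation table input/output
#'
#' @param path CSV path.
#' @param entries a curation entry tibble.
#' @return `read_curation_csv` returns a tibble validated against the entry
#'   column contract.
#' @export
read_curation_csv <- function(path) {
  check_entries(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_curation_csv
#' @export
write_curation_csv <- function(entries, path) {
  utils::write.csv(entries, path, row.names = FALSE)
  invisible(path)
}

#' Model checkpoints
#'
#' A checkpoint is a single-file container holding the model weights, the
#' model configuration and the seed, sufficient for exact resumption.
#'
#' @param weights,config,seed checkpoint content.
#' @param path file path (`.rds`).
#' @export
save_checkpoint <- function(weights, config, path, seed = NA_integer_) {
  saveRDS(list(weights = weights, config = config, seed = seed,
               package_version = tryCatch(
                 as.character(utils::packageVersion("fvforge")),
                 error = function(e) NA_character_)),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns the stored list.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(is.list(ck), !is.null(ck$weights), !is.null(ck$config))
  ck
}
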