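# Domain containers. Lightweight S3: a protein_record is a list, a cohort is
# a list of records; per-residue tracks are stored 0-based-free as plain R
# vectors (files use 1-based positions, memory uses ordinary R indexing).

#' Construct a protein record
#'
#' One protein with its sequence and optional per-residue signal tracks.
#' All tracks, when present, must match the sequence length. pLDDT is stored
#' on \[0, 1\] throughout the package; scaling from the PDB 0-100 convention
#' happens once, at ingestion ([read_pdb_complex()]).
#'
#' @param id Protein identifier.
#' @param sequence Amino-acid string over the 20-letter alphabet (plus `X`).
#' @param gene_class `"denovo"` or `"duplicate"`.
#' @param branch Origination branch, one of `br1..br9`.
#' @param disorder_track Optional per-residue disorder signal in \[0, 1\]
#'   (probabilities or binary).
#' @param morf_track Optional per-residue binary MoRF indicator.
#' @param plddt_track Optional per-residue pLDDT in \[0, 1\].
#' @param ss_string Optional secondary-structure string over the STRIDE
#'   alphabet `H G I E B T C` (lowercase bridge `b` is normalised to `B`).
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence,
                           gene_class = c("denovo", "duplicate"),
                           branch = "br1",
                           disorder_track = NULL, morf_track = NULL,
                           plddt_track = NULL, ss_string = NULL) {
  gene_class <- match.arg(gene_class)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop_ds("protein id must be a nonempty string")
  check_sequence(sequence)
  if (!branch %in% BRANCH_IDS) stop_ds("unknown branch '%s'", branch)
  n <- nchar(sequence)
  check_track <- function(track, name, binary = FALSE) {
    if (is.null(track)) return(NULL)
    if (length(track) != n)
      stop_ds("%s: %s length %d != sequence length %d", id, name,
              length(track), n)
    check_probability_vector(track, name)
    if (binary && !all(track %in% c(0, 1)))
      stop_ds("%s: %s must be binary", id, name)
    track
  }
  if (!is.null(ss_string)) {
    ss_string <- normalize_ss(ss_string)
    if (nchar(ss_string) != n)
      stop_ds("%s: ss_string length %d != sequence length %d", id,
              nchar(ss_string), n)
  }
  structure(list(
    id = id, gene_class = gene_class, branch = branch, sequence = sequence,
    disorder_track = check_track(disorder_track, "disorder_track"),
    morf_track = check_track(morf_track, "morf_track", binary = TRUE),
    plddt_track = check_track(plddt_track, "plddt_track"),
    ss_string = ss_string
  ), class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  tracks <- c("disorder_track", "morf_track", "plddt_track", "ss_string")
  have <- tracks[!vapply(x[tracks], is.null, logical(1))]
  cat(sprintf("<protein_record> %s [%s, %s], %d aa%s\n", x$id, x$gene_class,
              x$branch, nchar(x$sequence),
              if (length(have)) paste0("; tracks: ", paste(have, collapse = ", "))
              else ""))
  invisible(x)
}

STRIDE_ALPHABET <- c("H", "G", "I", "E", "B", "T", "C")

normalize_ss <- function(ss_string) {
  ss_string <- chartr("b", "B", ss_string)
  bad <- setdiff(unique(strsplit(ss_string, "", fixed = TRUE)[[1]]),
                 STRIDE_ALPHABET)
  if (length(bad))
    stop_ds("unknown secondary-structure code(s): %s",
            paste(sQuote(bad), collapse = ", "))
  ss_string
}

#' Construct a two-chain complex model
#'
#' @param chains A list of exactly two chains. Each chain is a `data.frame`
#'   of heavy atoms with columns `resno` (residue sequence number), `resid`
#'   (three-letter residue code), `x`, `y`, `z` (Angstrom) and `plddt`
#'   (per-residue confidence on \[0, 1\]).
#' @param id Complex identifier.
#' @return An object of class `complex_model`.
#' @export
complex_model <- function(chains, id = "complex") {
  if (!is.list(chains) || length(chains) != 2L)
    stop_ds("a complex model has exactly 2 chains (got %d)", length(chains))
  cols <- c("resno", "resid", "x", "y", "z", "plddt")
  for (k in 1:2) {
    ch <- chains[[k]]
    if (!is.data.frame(ch) || !all(cols %in% names(ch)))
      stop_ds("chain %d must have columns %s", k, paste(cols, collapse = ", "))
    if (nrow(ch) == 0L) stop_ds("chain %d has no atoms", k)
    if (!all(is.finite(as.matrix(ch[, c("x", "y", "z")]))))
      stop_ds("chain %d has non-finite coordinates", k)
    chains[[k]] <- ch[order(ch$resno), , drop = FALSE]
  }
  if (is.null(names(chains))) names(chains) <- c("A", "B")
  structure(list(id = id, chains = chains), class = "complex_model")
}

chain_lengths <- function(model) {
  vapply(model$chains, function(ch) length(unique(ch$resno)), integer(1))
}

#' @export
print.complex_model <- function(x, ...) {
  n <- chain_lengths(x)
  cat(sprintf("<complex_model> %s: chains %s (%d res, %d atoms) / %s (%d res, %d atoms)\n",
              x$id, names(x$chains)[1], n[1], nrow(x$chains[[1]]),
              names(x$chains)[2], n[2], nrow(x$chains[[2]])))
  invisible(x)
}
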