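# Readers and writers for every external format the pipeline touches.
# Downstream modules only consume the domain containers built here.
# File positions are 1-based; in-memory tracks use ordinary R vectors.

#' Read protein sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] with alphabet policy:
#' in `strict` mode (default) any character outside the 20-letter amino-acid
#' alphabet (plus `X`) is an error naming the offending residue; in
#' `lenient` mode such characters are masked to `X` (and are later excluded
#' from composition denominators, see [aa_composition()]).
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"strict"` or `"lenient"`.
#' @return A `data.frame` with columns `id` and `sequence`, in file order.
#'   An empty file yields zero rows.
#' @export
read_fasta <- function(path, alphabet = c("strict", "lenient")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop_ds("FASTA file not found: %s", path)
  if (file.size(path) == 0L)
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  # alphabet policy is applied on the raw text BEFORE parsing: the parser
  # silently discards letters outside its alphabet, which would defeat
  # both the strict error and the lenient X-masking
  lines <- readLines(path)
  ok_chars <- c(AA_LETTERS, "X")
  is_header <- startsWith(lines, ">")
  current <- "(no header)"
  for (i in seq_along(lines)) {
    if (is_header[i]) { current <- sub("^>\\s*", "", lines[i]); next }
    chars <- unique(strsplit(toupper(lines[i]), "", fixed = TRUE)[[1]])
    bad <- setdiff(chars, ok_chars)
    if (length(bad)) {
      if (alphabet == "strict")
        stop_ds("record '%s': invalid residue(s) %s", current,
                paste(sQuote(bad), collapse = ", "))
      lines[i] <- chartr(paste(bad, collapse = ""),
                         strrep("X", length(bad)), toupper(lines[i]))
    }
  }
  src <- path
  if (alphabet == "lenient") {
    src <- tempfile(fileext = ".fasta")
    on.exit(unlink(src), add = TRUE)
    writeLines(lines, src)
  }
  set <- tryCatch(Biostrings::readAAStringSet(src),
                  error = function(e) stop_ds("FASTA parse error in %s: %s",
                                              path, conditionMessage(e)))
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(ids))) stop_ds("FASTA record with empty id in %s", path)
  if (any(!nzchar(seqs))) stop_ds("FASTA record with empty sequence in %s", path)
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write protein sequences to FASTA
#'
#' @param records A `data.frame` with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read per-residue tracks from a long-format TSV
#'
#' Carrier format for external per-residue predictions (disorder
#' probabilities, binary MoRF calls, pLDDT). Columns: `id`, `position`
#' (1-based, contiguous within each id), `value`.
#'
#' @param path Path to the TSV.
#' @param range_check If `TRUE` (default) values must lie in \[0, 1\];
#'   disable for tracks on other scales.
#' @return A named list, one numeric vector per id, in position order.
#' @export
read_track_tsv <- function(path, range_check = TRUE) {
  if (!file.exists(path)) stop_ds("track file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "position", "value")
  if (!all(need %in% names(tab)))
    stop_ds("track TSV needs columns %s", paste(need, collapse = ", "))
  if (range_check) check_probability_vector(tab$value, "value")
  out <- lapply(split(tab, tab$id), function(d) {
    d <- d[order(d$position), , drop = FALSE]
    if (!identical(as.integer(d$position), seq_len(nrow(d)))) {
      missing <- setdiff(seq_len(max(d$position)), d$position)
      stop_ds("track '%s': position %d missing (positions must be 1-based and contiguous)",
              d$id[1], if (length(missing)) missing[1] else NA_integer_)
    }
    d$value
  })
  out[unique(tab$id)]  # preserve first-appearance order
}

#' Write per-residue tracks to long-format TSV
#'
#' Inverse of [read_track_tsv()]; write-then-read is the identity.
#'
#' @param tracks A named list of numeric vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(tracks, path) {
  tab <- do.call(rbind, lapply(names(tracks), function(id) {
    data.frame(id = id, position = seq_along(tracks[[id]]),
               value = tracks[[id]], stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read secondary-structure assignments from STRIDE output
#'
#' Parses the per-residue `ASG` lines of STRIDE detailed output and
#' concatenates the one-letter code column into one string per chain.
#' Lowercase `b` (isolated bridge) is normalised to `B`. Codes outside the
#' STRIDE alphabet `H G I E B T C` are an error naming the code.
#'
#' @param path Path to a STRIDE output file.
#' @return A named list of secondary-structure strings, keyed by chain id.
#' @export
read_stride <- function(path) {
  if (!file.exists(path)) stop_ds("STRIDE file not found: %s", path)
  lines <- readLines(path)
  asg <- lines[startsWith(lines, "ASG")]
  if (!length(asg)) return(list())
  fields <- strsplit(trimws(asg), "\\s+")
  chains <- vapply(fields, `[[`, character(1), 3L)
  codes <- vapply(fields, `[[`, character(1), 6L)
  out <- lapply(split(codes, chains), function(cc)
    normalize_ss(paste(cc, collapse = "")))
  out[unique(chains)]
}

# -- PDB complexes -----------------------------------------------------------

#' Read a two-chain complex from a PDB file
#'
#' Reads `ATOM` records via [bio3d::read.pdb()], drops hydrogens, and
#' requires exactly two chain identifiers. The B-factor column is taken to
#' hold pLDDT on the conventional 0-100 scale; each residue's pLDDT is the
#' B-factor of its first atom divided by 100 (the only place in the package
#' where that scaling happens).
#'
#' @param path Path to a PDB file.
#' @return A [complex_model()].
#' @export
read_pdb_complex <- function(path) {
  if (!file.exists(path)) stop_ds("PDB file not found: %s", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  atoms <- atoms[!(atoms$elesy %in% c("H", "D")), , drop = FALSE]
  if (anyNA(atoms[, c("x", "y", "z")]))
    stop_ds("%s: missing atom coordinates", path)
  chains <- unique(atoms$chain)
  if (length(chains) != 2L)
    stop_ds("%s: expected exactly 2 chains, found %d (%s)", path,
            length(chains), paste(chains, collapse = ", "))
  built <- lapply(chains, function(cid) {
    a <- atoms[atoms$chain == cid, , drop = FALSE]
    a <- a[order(a$resno, a$eleno), , drop = FALSE]
    first <- !duplicated(a$resno)
    plddt_by_res <- stats::setNames(a$b[first] / 100, a$resno[first])
    data.frame(resno = a$resno, resid = a$resid,
               x = a$x, y = a$y, z = a$z,
               plddt = unname(plddt_by_res[as.character(a$resno)]),
               stringsAsFactors = FALSE)
  })
  names(built) <- chains
  complex_model(built, id = sub("\\.pdb$", "", basename(path)))
}

#' Write a two-chain complex to a PDB file
#'
#' Inverse of [read_pdb_complex()]: pLDDT is written to the B-factor column
#' on the 0-100 scale; coordinates survive a round trip to 3 decimals (the
#' fixed-width PDB contract). All atoms are written as carbon `CB` unless a
#' `name` column is present on the chains.
#'
#' @param model A [complex_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_complex <- function(model, path) {
  stopifnot(inherits(model, "complex_model"))
  rows <- do.call(rbind, lapply(seq_along(model$chains), function(k) {
    ch <- model$chains[[k]]
    data.frame(chain = names(model$chains)[k], resno = ch$resno,
               resid = ch$resid, x = ch$x, y = ch$y, z = ch$z,
               b = round(ch$plddt * 100, 2),
               name = if ("name" %in% names(ch)) ch$name else "CB",
               stringsAsFactors = FALSE)
  }))
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(rows[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(rows)),
                   resno = rows$resno, resid = rows$resid,
                   chain = rows$chain, elety = rows$name,
                   b = rows$b, o = rep(1, nrow(rows)))
  invisible(path)
}

# -- Tables ------------------------------------------------------------------

#' Read a TPM expression matrix from TSV
#'
#' Genes in rows (first column `gene_id`), samples in columns. All cells
#' must be present and non-negative.
#'
#' @param path Path to the TSV.
#' @return A numeric matrix, genes x samples, with gene ids as rownames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop_ds("expression matrix not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "gene_id")
    stop_ds("expression TSV must start with a 'gene_id' column")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene_id
  if (anyNA(m)) stop_ds("expression matrix has missing cells")
  if (any(m < 0)) stop_ds("TPM values must be >= 0")
  m
}

#' Write a TPM expression matrix to TSV
#' @param matrix Numeric genes x samples matrix with rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(matrix, path) {
  tab <- data.frame(gene_id = rownames(matrix), matrix,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a descriptor (or any flat) table as TSV
#'
#' @param table A `data.frame`.
#' @param path File path.
#' @return The table (read) or `path` invisibly (write).
#' @export
write_descriptor_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_descriptor_table
#' @export
read_descriptor_table <- function(path) {
  if (!file.exists(path)) stop_ds("table not found: %s", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
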