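# Protein-complex interface analysis: residue-residue (RR) contacts across
# the two chains, raw and length-normalised contact statistics, the
# Gibbs-free-energy / dissociation-constant identity, affinity
# classification and docking-partner selection.

GAS_CONSTANT_KCAL <- 1.987e-3  # kcal / (mol K)

#' Enumerate residue-residue contacts across a two-chain interface
#'
#' A residue pair (one residue from each chain) is a contact iff any pair
#' of their heavy atoms lies within `cutoff` Angstrom (inclusive; the
#' conventional 5.5 A all-heavy-atom contact definition). Each contacting
#' pair appears once, annotated with its minimum atom-atom distance.
#'
#' @param model A [complex_model()].
#' @param cutoff Distance cutoff in Angstrom (default 5.5).
#' @return A `data.frame` with columns `res_a`, `res_b` (residue sequence
#'   numbers) and `min_dist`; `attr(, "chain_lengths")` carries the two
#'   chain lengths.
#' @export
interface_contacts <- function(model, cutoff = 5.5) {
  stopifnot(inherits(model, "complex_model"))
  check_scalar_number(cutoff, "cutoff", positive = TRUE)
  a <- model$chains[[1]]; b <- model$chains[[2]]
  xa <- as.matrix(a[, c("x", "y", "z")])
  xb <- as.matrix(b[, c("x", "y", "z")])
  # all-atom cross-distance matrix, then min-aggregate to residue pairs
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * (xa %*% t(xb))
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  key <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  pair <- paste(a$resno[key$i], b$resno[key$j], sep = "\r")
  min_d <- tapply(as.vector(d), pair, min)
  hit <- min_d <= cutoff
  ids <- strsplit(names(min_d)[hit], "\r", fixed = TRUE)
  out <- data.frame(
    res_a = as.integer(vapply(ids, `[[`, character(1), 1L)),
    res_b = as.integer(vapply(ids, `[[`, character(1), 2L)),
    min_dist = unname(min_d[hit]))
  out <- out[order(out$res_a, out$res_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "chain_lengths") <- chain_lengths(model)
  attr(out, "cutoff") <- cutoff
  out
}

#' Raw and length-normalised RR contact statistics
#'
#' `raw_count` is the number of distinct contacting residue pairs.
#' `nonredundant_ratio` adjusts for complex size: by default the number of
#' distinct residue pairs divided by the total residue length of the
#' complex; `mode = "residues"` instead counts distinct interface residues
#' (union over both chains) over the total length.
#'
#' @param contacts Output of [interface_contacts()].
#' @param mode `"pairs"` (default) or `"residues"`.
#' @return A list with `raw_count` and `nonredundant_ratio`.
#' @export
rr_statistics <- function(contacts, mode = c("pairs", "residues")) {
  mode <- match.arg(mode)
  lens <- attr(contacts, "chain_lengths")
  if (is.null(lens)) stop_ds("contacts lack chain_lengths attribute")
  total <- sum(lens)
  raw <- nrow(unique(contacts[, c("res_a", "res_b")]))
  numer <- if (mode == "pairs") raw
           else length(unique(contacts$res_a)) + length(unique(contacts$res_b))
  list(raw_count = raw, nonredundant_ratio = numer / total)
}

#' Convert between binding free energy and dissociation constant
#'
#' `delta_g = R * T * ln(kd)` with `R = 1.987e-3` kcal/(mol K); the two
#' functions are exact inverses. The default temperature is 273.15 K, the
#' choice under which the conventional high-affinity cutoff pair
#' (-10 kcal/mol, Kd = 1e-8 M) is numerically consistent; 298.15 K gives
#' -10.9 kcal/mol for the same Kd. The temperature used is always an
#' explicit argument so either convention can be carried through.
#'
#' @param kd Dissociation constant in molar, `> 0`.
#' @param delta_g Binding free energy in kcal/mol.
#' @param temperature Temperature in K (default 273.15).
#' @return Free energy in kcal/mol, or Kd in molar.
#' @examples
#' delta_g_from_kd(1e-8)          # about -10 kcal/mol
#' kd_from_delta_g(-10, 298.15)
#' @export
delta_g_from_kd <- function(kd, temperature = 273.15) {
  if (any(kd <= 0)) stop_ds("kd must be > 0")
  check_scalar_number(temperature, "temperature", positive = TRUE)
  GAS_CONSTANT_KCAL * temperature * log(kd)
}

#' @rdname delta_g_from_kd
#' @export
kd_from_delta_g <- function(delta_g, temperature = 273.15) {
  check_scalar_number(temperature, "temperature", positive = TRUE)
  exp(delta_g / (GAS_CONSTANT_KCAL * temperature))
}

#' Classify a complex as high affinity
#'
#' @param delta_g Binding free energy in kcal/mol.
#' @param cutoff High-affinity cutoff (default -10 kcal/mol, inclusive).
#' @return Logical: `delta_g <= cutoff`.
#' @export
classify_affinity <- function(delta_g, cutoff = -10) {
  if (any(!is.finite(delta_g))) stop_ds("delta_g must be finite")
  delta_g <= cutoff
}

#' Filter candidate docking partners
#'
#' Keeps candidates that satisfy all four partner-selection criteria:
#' (i) ordered sequence, disorder fraction below 0.05; (ii) strong
#' coexpression with the target, correlation above 0.8; (iii) length between 200 and
#' 500 residues (inclusive); (iv) an old gene, branch `br6..br9`.
#'
#' @param candidates `data.frame` with columns `gene_id`, `isd_ratio`,
#'   `coexpr_r`, `length`, `branch`.
#' @return The passing rows; `attr(, "filter_report")` counts failures per
#'   criterion (a candidate can fail several).
#' @export
partner_filter <- function(candidates) {
  need <- c("gene_id", "isd_ratio", "coexpr_r", "length", "branch")
  for (col in need) {
    if (!col %in% names(candidates))
      stop_ds("candidates lack column '%s'", col)
    if (anyNA(candidates[[col]]))
      stop_ds("gene '%s': missing field '%s'",
              candidates$gene_id[which(is.na(candidates[[col]]))[1]], col)
  }
  ok_isd <- candidates$isd_ratio < 0.05
  ok_r <- candidates$coexpr_r > 0.8
  ok_len <- candidates$length >= 200 & candidates$length <= 500
  ok_age <- candidates$branch %in% paste0("br", 6:9)
  keep <- ok_isd & ok_r & ok_len & ok_age
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_report") <- c(
    fail_disorder = sum(!ok_isd), fail_coexpression = sum(!ok_r),
    fail_length = sum(!ok_len), fail_age = sum(!ok_age))
  out
}
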