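# Per-protein descriptors: disorder fraction, secondary-structure
# proportions, composition, molecular weight, charge/pI, hydrophobicity,
# MoRF fraction, pLDDT folding-confidence class, TM-score fold class.

#' Binarize a disorder probability track
#'
#' @param probabilities Per-residue probabilities in \[0, 1\].
#' @param threshold Values `>= threshold` are called disordered (default
#'   0.5, the usual consensus-predictor convention).
#' @return An integer 0/1 vector of the same length.
#' @export
binarize_disorder <- function(probabilities, threshold = 0.5) {
  check_probability_vector(probabilities, "probabilities")
  as.integer(probabilities >= threshold)
}

#' Fraction of positive residues in a binary track
#'
#' The ISD ratio of a protein is `track_fraction` of its binarized disorder
#' track: the fraction of residues inside disordered segments out of the
#' full length. The same statistic gives MoRF fractions from MoRF tracks.
#'
#' @param track A nonempty binary (0/1) vector.
#' @return `sum(track) / length(track)`.
#' @export
track_fraction <- function(track) {
  if (length(track) == 0L) stop_ds("empty track")
  if (!all(track %in% c(0, 1))) stop_ds("track must be binary 0/1")
  sum(track) / length(track)
}

#' Classify a protein as fully disordered
#'
#' A protein counts as a full-ISD protein iff 100% of its residues are in
#' disordered states, i.e. the ISD ratio is exactly 1.
#'
#' @param isd_ratio Number in \[0, 1\].
#' @return `TRUE` iff `isd_ratio == 1`.
#' @export
classify_full_isd <- function(isd_ratio) {
  check_probability_vector(isd_ratio, "isd_ratio")
  isd_ratio == 1
}

# Default mapping of STRIDE letters to reported classes. Turns (T) count as
# coil: unstructured, consistent with coil medians of 40-47% in real data.
DEFAULT_SS_PARTITION <- c(H = "helix", I = "helix", G = "p310helix",
                          E = "strand", B = "bridge", C = "coil", T = "coil")

SS_CLASSES <- c("coil", "helix", "p310helix", "strand", "bridge")

#' Secondary-structure class proportions
#'
#' For each class i, `P_i = l_i / l_total`: the cumulative length of
#' residues assigned to that class over the protein length. Proportions sum
#' to 1 under any partition that maps every STRIDE letter to exactly one
#' class.
#'
#' @param ss_string Secondary-structure string over `H G I E B T C`
#'   (lowercase `b` accepted, normalised to `B`).
#' @param partition Named character vector mapping each STRIDE letter to a
#'   class in `coil, helix, p310helix, strand, bridge`.
#' @return Named numeric vector `p_coil, p_helix, p_310helix, p_strand,
#'   p_bridge`.
#' @examples
#' ss_proportions("CCCCHHHHHHEEEE")
#' @export
ss_proportions <- function(ss_string, partition = DEFAULT_SS_PARTITION) {
  ss_string <- normalize_ss(ss_string)
  if (nchar(ss_string) == 0L) stop_ds("empty secondary-structure string")
  letters <- strsplit(ss_string, "", fixed = TRUE)[[1]]
  miss <- setdiff(unique(letters), names(partition))
  if (length(miss))
    stop_ds("letter(s) absent from partition: %s", paste(miss, collapse = ", "))
  cls <- partition[letters]
  counts <- vapply(SS_CLASSES, function(k) sum(cls == k), numeric(1))
  props <- counts / length(letters)
  stats::setNames(props, c("p_coil", "p_helix", "p_310helix", "p_strand",
                           "p_bridge"))
}

#' Amino-acid composition
#'
#' Fractions of the 20 standard residues; `X` (masked/unknown) is excluded
#' from both numerator and denominator.
#'
#' @param sequence Amino-acid string.
#' @return Named numeric vector of 20 fractions summing to 1.
#' @export
aa_composition <- function(sequence) {
  chars <- check_sequence(sequence)
  chars <- chars[chars != "X"]
  if (length(chars) == 0L) stop_ds("sequence is all-X; composition undefined")
  counts <- vapply(AA_LETTERS, function(a) sum(chars == a), numeric(1))
  counts / length(chars)
}

# Average residue (water-free) masses, Da.
AA_RESIDUE_MASS <- c(
  A = 71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167, Q = 128.1307, R = 156.1875,
  S = 87.0782, T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760)

WATER_MASS <- 18.0153

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water (18.0153 Da). `X` residues
#' are not allowed (mass undefined).
#'
#' @param sequence Amino-acid string.
#' @return Molecular weight in Da.
#' @examples
#' molecular_weight("G")  # 75.07
#' @export
molecular_weight <- function(sequence) {
  chars <- check_sequence(sequence, allow_x = FALSE)
  sum(AA_RESIDUE_MASS[chars]) + WATER_MASS
}

# EMBOSS pKa values; the pI tool the original analysis used keeps its set
# proprietary, so the open EMBOSS set is the default and is recorded in
# every output row.
PKA_EMBOSS <- list(
  nterm = 8.6, cterm = 3.6,
  acidic = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1),
  basic = c(H = 6.5, K = 10.8, R = 12.5))

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the ionizable groups (N-terminus,
#' C-terminus, side chains of D, E, C, Y, H, K, R): each basic group
#' contributes `+1 / (1 + 10^(pH - pKa))`, each acidic group
#' `-1 / (1 + 10^(pKa - pH))`.
#'
#' @param sequence Amino-acid string.
#' @param pH pH in \[0, 14\].
#' @param pka_set A list with elements `nterm`, `cterm` (scalars) and
#'   `acidic`, `basic` (named vectors); default EMBOSS values.
#' @return Net charge in elementary charges.
#' @export
net_charge <- function(sequence, pH, pka_set = PKA_EMBOSS) {
  chars <- check_sequence(sequence)
  check_scalar_number(pH, "pH")
  if (pH < 0 || pH > 14) stop_ds("pH must lie in [0, 14]")
  pos <- function(pka) 1 / (1 + 10^(pH - pka))
  neg <- function(pka) -1 / (1 + 10^(pka - pH))
  q <- pos(pka_set$nterm) + neg(pka_set$cterm)
  for (aa in names(pka_set$acidic))
    q <- q + sum(chars == aa) * neg(pka_set$acidic[[aa]])
  for (aa in names(pka_set$basic))
    q <- q + sum(chars == aa) * pos(pka_set$basic[[aa]])
  q
}

#' Isoelectric point by bisection
#'
#' The pH at which [net_charge()] crosses zero. Net charge is strictly
#' decreasing in pH, so the root is unique; bisection on \[0, 14\] runs to
#' `|charge| < tol`.
#'
#' @param sequence Amino-acid string.
#' @param pka_set See [net_charge()].
#' @param tol Convergence tolerance on the charge (default 1e-4).
#' @return pI in pH units.
#' @export
isoelectric_point <- function(sequence, pka_set = PKA_EMBOSS, tol = 1e-4) {
  lo <- 0; hi <- 14
  q_lo <- net_charge(sequence, lo, pka_set)
  q_hi <- net_charge(sequence, hi, pka_set)
  if (q_lo < 0 || q_hi > 0)
    stop_ds("net charge does not change sign on [0, 14]; check the pKa set")
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(sequence, mid, pka_set)
    if ((abs(q) < tol && hi - lo < 1e-6) || hi - lo < 1e-12) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

# Kyte-Doolittle hydropathy index.
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Mean hydrophobicity of a protein
#'
#' Mean per-residue value under a hydropathy scale (default
#' Kyte-Doolittle). The scale name travels with descriptor output for
#' provenance; any complete named scale can be substituted.
#'
#' @param sequence Amino-acid string (no `X`).
#' @param scale Named numeric vector with a value for every residue present.
#' @return Mean scale value per residue.
#' @export
hydrophobicity_score <- function(sequence, scale = KYTE_DOOLITTLE) {
  chars <- check_sequence(sequence, allow_x = FALSE)
  miss <- setdiff(unique(chars), names(scale))
  if (length(miss))
    stop_ds("residue(s) missing from hydrophobicity scale: %s",
            paste(miss, collapse = ", "))
  mean(scale[chars])
}

#' pLDDT folding-confidence class
#'
#' `high` if the track has at least one contiguous run of `min_len`
#' residues each with pLDDT `>= hi`; else `medium` if such a run exists at
#' `>= mid`; else `low`. "An element over ten amino acids" is read as a run
#' of at least 11 residues, each individually over the threshold.
#'
#' @param plddt_track Per-residue pLDDT in \[0, 1\].
#' @param hi,mid Thresholds (defaults 0.9 and 0.7).
#' @param min_len Minimum run length (default 11).
#' @return `"high"`, `"medium"` or `"low"`.
#' @export
folding_confidence <- function(plddt_track, hi = 0.9, mid = 0.7,
                               min_len = 11) {
  check_probability_vector(plddt_track, "plddt_track")
  has_run <- function(threshold) {
    r <- rle(plddt_track >= threshold)
    any(r$values & r$lengths >= min_len)
  }
  if (has_run(hi)) "high" else if (has_run(mid)) "medium" else "low"
}

#' Fold-similarity class from pairwise TM scores
#'
#' Median TM score above 0.5 indicates a consistently similar fold across
#' models; below 0.17 structural likeness is near random; in between is
#' intermediate.
#'
#' @param tm_scores Numeric vector of TM scores in \[0, 1\].
#' @param similar,random Class thresholds (defaults 0.5 and 0.17).
#' @return `"similar"`, `"intermediate"` or `"random"`.
#' @export
fold_similarity_class <- function(tm_scores, similar = 0.5, random = 0.17) {
  check_probability_vector(tm_scores, "tm_scores")
  m <- stats::median(tm_scores)
  if (m > similar) "similar" else if (m < random) "random" else "intermediate"
}

#' Compute the full descriptor row for one protein
#'
#' Bundles every per-protein metric into one row, with provenance columns
#' recording the scale, pKa set and thresholds used.
#'
#' @param record A [protein_record()].
#' @param disorder_threshold Binarization threshold for probability
#'   disorder tracks (ignored for already-binary tracks).
#' @param partition Secondary-structure partition (see [ss_proportions()]).
#' @param scale Hydrophobicity scale; `scale_name` is recorded.
#' @param scale_name,pka_name Provenance labels.
#' @param pka_set pKa set for charge and pI.
#' @return A one-row `data.frame`.
#' @export
describe_protein <- function(record, disorder_threshold = 0.5,
                             partition = DEFAULT_SS_PARTITION,
                             scale = KYTE_DOOLITTLE,
                             scale_name = "kyte-doolittle",
                             pka_set = PKA_EMBOSS, pka_name = "emboss") {
  stopifnot(inherits(record, "protein_record"))
  isd <- NA_real_
  if (!is.null(record$disorder_track)) {
    bin <- if (all(record$disorder_track %in% c(0, 1))) record$disorder_track
           else binarize_disorder(record$disorder_track, disorder_threshold)
    isd <- track_fraction(bin)
  }
  ss <- if (!is.null(record$ss_string))
    ss_proportions(record$ss_string, partition)
  else stats::setNames(rep(NA_real_, 5),
                       c("p_coil", "p_helix", "p_310helix", "p_strand",
                         "p_bridge"))
  seq_for_chem <- gsub("X", "", record$sequence, fixed = TRUE)
  data.frame(
    id = record$id, gene_class = record$gene_class, branch = record$branch,
    length = nchar(record$sequence),
    isd_ratio = isd,
    is_full_isd = if (is.na(isd)) NA else classify_full_isd(isd),
    t(ss),
    mol_weight = if (nzchar(seq_for_chem)) molecular_weight(seq_for_chem)
                 else NA_real_,
    pI = if (nzchar(seq_for_chem)) isoelectric_point(seq_for_chem, pka_set)
         else NA_real_,
    net_charge_pH7 = if (nzchar(seq_for_chem))
      net_charge(seq_for_chem, 7, pka_set) else NA_real_,
    hydrophobicity = if (nzchar(seq_for_chem))
      hydrophobicity_score(seq_for_chem, scale) else NA_real_,
    morf_fraction = if (!is.null(record$morf_track))
      track_fraction(record$morf_track) else NA_real_,
    folding_class = if (!is.null(record$plddt_track))
      folding_confidence(record$plddt_track) else NA_character_,
    hydro_scale = scale_name, pka_set = pka_name,
    disorder_threshold = disorder_threshold,
    stringsAsFactors = FALSE
  )
}

#' Descriptor table for a cohort of proteins
#'
#' @param records List of [protein_record()] objects.
#' @param ... Passed to [describe_protein()].
#' @return A `data.frame`, one row per protein.
#' @export
describe_cohort <- function(records, ...) {
  rows <- lapply(records, describe_protein, ...)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
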