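# Synthetic cohorts with planted, known ground truth. Each generator is a
# pure function of (spec, seed): same spec and seed, same output. Planted
# metric laws are linear in divergence time, median-targeted: per-protein
# noise on proportions is drawn on the logit scale around the law value, so
# the population median at every branch equals the law exactly and branch
# medians converge to the planted line as n grows.

#' Specification of a synthetic cohort
#'
#' A cohort is a set of branches (with divergence times), a per-branch
#' sample size, and a planted linear law `metric = intercept + slope * t`
#' with per-protein noise `sigma`. For `kind = "proportion"` the law must
#' stay inside (0, 1) at every branch time (inside \[0, 1\] when
#' `sigma = 0`) and noise is logit-normal; for `kind = "metric"` the law is
#' unconstrained and noise is Gaussian.
#'
#' @param branches Branch ids (subset of `br1..br9`).
#' @param n_per_branch Proteins per branch.
#' @param intercept,slope The planted law, per My.
#' @param sigma Per-protein noise (logit units for proportions, metric
#'   units otherwise).
#' @param kind `"proportion"` or `"metric"`.
#' @param branch_table Branch-time table.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(branches, n_per_branch, intercept, slope,
                        sigma = 0.5, kind = c("proportion", "metric"),
                        branch_table = default_branch_table()) {
  kind <- match.arg(kind)
  validate_branch_table(branch_table)
  times <- branch_time(branches, branch_table)
  check_scalar_number(sigma, "sigma")
  if (sigma < 0) stop_ds("sigma must be >= 0")
  law <- intercept + slope * times
  if (kind == "proportion") {
    lo <- if (sigma > 0) 1e-6 else 0
    if (any(law < lo | law > 1 - lo))
      stop_ds("planted law leaves [0, 1] at branch time(s) %s",
              paste(times[law < lo | law > 1 - lo], collapse = ", "))
  }
  structure(list(branches = branches, times = times,
                 n_per_branch = as.integer(n_per_branch),
                 intercept = intercept, slope = slope, sigma = sigma,
                 kind = kind, branch_table = branch_table),
            class = "cohort_spec")
}

law_values <- function(spec) spec$intercept + spec$slope * spec$times

draw_proportions <- function(spec) {
  unlist(lapply(seq_along(spec$branches), function(bi) {
    law <- law_values(spec)[bi]
    if (spec$sigma == 0) rep(law, spec$n_per_branch)
    else stats::plogis(stats::rnorm(spec$n_per_branch,
                                    stats::qlogis(law), spec$sigma))
  }))
}

random_sequence <- function(n) {
  paste(sample(AA_LETTERS, n, replace = TRUE), collapse = "")
}

#' Generate a disorder cohort with a planted median trend
#'
#' Each protein gets a binary disorder track whose fraction of disordered
#' residues is drawn around the branch's law value (one contiguous
#' disordered segment at a random offset). Optionally, the first
#' `n_full_isd` proteins per cohort are planted as fully disordered
#' (all-ones tracks); all other tracks are capped below 1, so full-ISD
#' bookkeeping is exact.
#'
#' @param spec A proportion [cohort_spec()].
#' @param seed Integer seed; generation is a pure function of
#'   (spec, seed).
#' @param track_length Residues per protein (default 150).
#' @param n_full_isd Number of proteins (across the whole cohort, taken
#'   from the start) planted with ISD ratio exactly 1.
#' @param gene_class `"denovo"` or `"duplicate"` label for the records.
#' @param morf If `TRUE`, the binary track is attached as the MoRF track
#'   instead of the disorder track.
#' @return A list with `records` (list of [protein_record()]) and `truth`
#'   (`data.frame`: `id`, `branch`, `time_mya`, `target_fraction`,
#'   `realized_fraction`, `full_isd`).
#' @export
gen_disorder_cohort <- function(spec, seed, track_length = 150,
                                n_full_isd = 0,
                                gene_class = c("denovo", "duplicate"),
                                morf = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"), spec$kind == "proportion")
  gene_class <- match.arg(gene_class)
  set.seed(seed)
  p <- draw_proportions(spec)
  n_total <- length(p)
  if (n_full_isd > n_total) stop_ds("n_full_isd exceeds cohort size")
  branch <- rep(spec$branches, each = spec$n_per_branch)
  k <- pmin(round(p * track_length), track_length - 1L)  # never full by noise
  full <- seq_len(n_total) <= n_full_isd
  k[full] <- track_length
  ids <- sprintf("%s_%s_%04d", gene_class, branch, seq_len(n_total))
  records <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    track <- integer(track_length)
    if (k[i] > 0) {
      start <- if (k[i] == track_length) 1L
               else sample.int(track_length - k[i] + 1L, 1L)
      track[start:(start + k[i] - 1L)] <- 1L
    }
    records[[i]] <- protein_record(
      id = ids[i], sequence = random_sequence(track_length),
      gene_class = gene_class, branch = branch[i],
      disorder_track = if (!morf) track else NULL,
      morf_track = if (morf) track else NULL)
  }
  truth <- data.frame(
    id = ids, branch = branch,
    time_mya = rep(spec$times, each = spec$n_per_branch),
    target_fraction = p, realized_fraction = k / track_length,
    full_isd = full, stringsAsFactors = FALSE)
  list(records = records, truth = truth, spec = spec)
}

#' Generate per-protein metric values with a planted median trend
#'
#' For descriptors that are not proportions (hydrophobicity score in scale
#' units, for instance): per-protein values are Gaussian around the
#' branch's law value, so the branch median converges to the law.
#'
#' @param spec A metric [cohort_spec()].
#' @param seed Integer seed.
#' @return A list with `values` (`data.frame`: `id`, `branch`, `time_mya`,
#'   `value`) and the `spec`.
#' @export
gen_metric_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"), spec$kind == "metric")
  set.seed(seed)
  branch <- rep(spec$branches, each = spec$n_per_branch)
  law <- rep(law_values(spec), each = spec$n_per_branch)
  value <- law + stats::rnorm(length(law), 0, spec$sigma)
  values <- data.frame(
    id = sprintf("m_%s_%04d", branch, seq_along(law)),
    branch = branch, time_mya = rep(spec$times, each = spec$n_per_branch),
    value = value, stringsAsFactors = FALSE)
  list(values = values, spec = spec)
}

SS_CLASS_LETTER <- c(coil = "C", helix = "H", p310helix = "G",
                     strand = "E", bridge = "B")

#' Specification of a secondary-structure cohort
#'
#' One linear law per structure class; at every branch time the class
#' proportions must be non-negative and sum to 1.
#'
#' @param branches,n_per_branch,branch_table As in [cohort_spec()].
#' @param laws A `data.frame` with columns `class` (covering exactly
#'   `coil, helix, p310helix, strand, bridge`), `intercept`, `slope`.
#' @param string_length Residues per protein (default 300).
#' @return An `ss_cohort_spec` object.
#' @export
ss_cohort_spec <- function(branches, n_per_branch, laws,
                           string_length = 300,
                           branch_table = default_branch_table()) {
  validate_branch_table(branch_table)
  if (!setequal(laws$class, SS_CLASSES))
    stop_ds("laws must cover exactly the classes: %s",
            paste(SS_CLASSES, collapse = ", "))
  laws <- laws[match(SS_CLASSES, laws$class), , drop = FALSE]
  times <- branch_time(branches, branch_table)
  for (t in times) {
    p <- laws$intercept + laws$slope * t
    if (any(p < 0)) stop_ds("class proportion negative at t = %g", t)
    if (abs(sum(p) - 1) > 1e-9)
      stop_ds("class proportions sum to %.6f != 1 at t = %g", sum(p), t)
  }
  structure(list(branches = branches, times = times,
                 n_per_branch = as.integer(n_per_branch), laws = laws,
                 string_length = as.integer(string_length),
                 branch_table = branch_table),
            class = "ss_cohort_spec")
}

#' Generate a secondary-structure cohort with planted class trends
#'
#' For every protein, the letters of its secondary-structure string are
#' drawn multinomially at the branch's target class proportions and
#' shuffled into a string; [ss_proportions()] recovers the targets within
#' multinomial sampling error, and branch medians follow the planted laws.
#'
#' @param spec An [ss_cohort_spec()].
#' @param seed Integer seed.
#' @return A list with `records` (list of [protein_record()]) and `truth`
#'   (`data.frame` of per-branch class targets).
#' @export
gen_ss_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "ss_cohort_spec"))
  set.seed(seed)
  letters_by_class <- SS_CLASS_LETTER[spec$laws$class]
  records <- list()
  truth <- list()
  idx <- 0L
  for (bi in seq_along(spec$branches)) {
    p <- spec$laws$intercept + spec$laws$slope * spec$times[bi]
    counts <- stats::rmultinom(spec$n_per_branch, spec$string_length, p)
    truth[[bi]] <- data.frame(
      branch = spec$branches[bi], time_mya = spec$times[bi],
      class = spec$laws$class, target = p, stringsAsFactors = FALSE)
    for (j in seq_len(spec$n_per_branch)) {
      idx <- idx + 1L
      letters <- rep(letters_by_class, counts[, j])
      ss <- paste(letters[sample.int(length(letters))], collapse = "")
      records[[idx]] <- protein_record(
        id = sprintf("ss_%s_%04d", spec$branches[bi], idx),
        sequence = random_sequence(spec$string_length),
        gene_class = "denovo", branch = spec$branches[bi],
        ss_string = ss)
    }
  }
  list(records = records, truth = do.call(rbind, truth), spec = spec)
}

#' Generate a sequence cohort with planted amino-acid composition trends
#'
#' Residues are drawn from a branch-specific composition
#' `base + trend * t` (clipped at a small floor and renormalised), so
#' per-amino-acid age correlations recover the planted signs. The default
#' plant mirrors the qualitative real-data finding: glycine and alanine
#' decline with age while tyrosine, phenylalanine, lysine and leucine rise.
#'
#' @param branches,n_per_branch As in [cohort_spec()].
#' @param seed Integer seed.
#' @param seq_length Residues per protein (default 300).
#' @param base Named base composition over the 20 residues (defaults to a
#'   mildly non-uniform composition).
#' @param trends Named per-My composition slopes for a subset of residues.
#' @param branch_table Branch-time table.
#' @return A list with `records`, `truth` (per-branch target
#'   compositions), and the planted `trends`.
#' @export
gen_sequence_cohort <- function(branches, n_per_branch, seed,
                                seq_length = 300, base = NULL,
                                trends = c(G = -0.010, A = -0.008,
                                           Y = 0.004, F = 0.005,
                                           K = 0.006, L = 0.008),
                                branch_table = default_branch_table()) {
  if (is.null(base)) {
    base <- stats::setNames(rep(0.05, 20), AA_LETTERS)
    base[c("G", "A", "L", "S")] <- 0.07
    base[c("W", "C", "H", "M")] <- 0.02
    base <- base / sum(base)
  }
  if (any(!names(trends) %in% AA_LETTERS)) stop_ds("unknown residue in trends")
  if (any(base < 0)) stop_ds("negative composition")
  set.seed(seed)
  times <- branch_time(branches, branch_table)
  records <- list(); truth <- list(); idx <- 0L
  for (bi in seq_along(branches)) {
    comp <- base
    comp[names(trends)] <- comp[names(trends)] + trends * times[bi]
    comp <- pmax(comp, 1e-4)
    comp <- comp / sum(comp)
    truth[[bi]] <- data.frame(branch = branches[bi], time_mya = times[bi],
                              aa = names(comp), target = unname(comp),
                              stringsAsFactors = FALSE)
    for (j in seq_len(n_per_branch)) {
      idx <- idx + 1L
      seqn <- paste(sample(AA_LETTERS, seq_length, replace = TRUE,
                           prob = comp), collapse = "")
      records[[idx]] <- protein_record(
        id = sprintf("aa_%s_%04d", branches[bi], idx), sequence = seqn,
        gene_class = "denovo", branch = branches[bi])
    }
  }
  list(records = records, truth = do.call(rbind, truth), trends = trends)
}
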