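# Geometric, genomic and expression fixtures with planted ground truth.

#' Generate a toy two-chain complex with a planted contact set
#'
#' Chain B residues are single atoms spread far apart along a line; chain A
#' residues get a distant base atom plus, for every planted contact (i, j),
#' an extra heavy atom placed within the cutoff of B residue j. Exactly the
#' k planted residue pairs lie within the cutoff and every other cross-chain
#' atom pair is farther than `cutoff + 1` Angstrom, so the planted list is
#' the exact truth for [interface_contacts()].
#'
#' @param len_a,len_b Residues per chain.
#' @param k_contacts Number of residue pairs to plant
#'   (`0 <= k <= len_a * len_b`).
#' @param cutoff Contact cutoff in Angstrom (default 5.5).
#' @param seed Integer seed.
#' @return A list with `model` (a [complex_model()]) and `truth`
#'   (`data.frame` with `res_a`, `res_b`, sorted).
#' @export
gen_toy_complex <- function(len_a, len_b, k_contacts, cutoff = 5.5,
                            seed = 1) {
  if (k_contacts < 0 || k_contacts > len_a * len_b)
    stop_ds("k_contacts must lie in [0, len_a * len_b]")
  set.seed(seed)
  spacing <- 2 * (cutoff + 2)
  # chain B: one atom per residue along y at x = 0
  b <- data.frame(resno = seq_len(len_b), resid = "GLY",
                  x = 0, y = seq_len(len_b) * spacing, z = 0,
                  plddt = round(stats::runif(len_b, 0.5, 0.95), 2))
  # chain A: base atoms far away in x
  a_base <- data.frame(resno = seq_len(len_a), resid = "ALA",
                       x = 1000 + seq_len(len_a) * spacing, y = 0, z = 0,
                       plddt = round(stats::runif(len_a, 0.5, 0.95), 2))
  planted <- if (k_contacts > 0) {
    pick <- sample.int(len_a * len_b, k_contacts)
    data.frame(res_a = ((pick - 1L) %% len_a) + 1L,
               res_b = ((pick - 1L) %/% len_a) + 1L)
  } else data.frame(res_a = integer(), res_b = integer())
  contact_atoms <- if (nrow(planted)) {
    d <- round(stats::runif(nrow(planted), 0.5 * cutoff, cutoff - 0.5), 3)
    data.frame(resno = planted$res_a, resid = "ALA",
               x = d, y = b$y[planted$res_b], z = 0,
               plddt = a_base$plddt[planted$res_a])
  } else NULL
  a <- rbind(a_base, contact_atoms)
  a <- a[order(a$resno), , drop = FALSE]
  a[, c("x", "y", "z")] <- round(a[, c("x", "y", "z")], 3)
  b[, c("x", "y", "z")] <- round(b[, c("x", "y", "z")], 3)
  truth <- planted[order(planted$res_a, planted$res_b), , drop = FALSE]
  rownames(truth) <- NULL
  list(model = complex_model(list(A = a, B = b), id = "toy_complex"),
       truth = truth)
}

#' Generate a synteny fixture with genes planted at known branches
#'
#' Builds a focal genome of conserved backbone genes with test genes
#' inserted between them, plus one genome per outgroup branch
#' (`br2..br9`). The backbone is shared by all genomes (conserved
#' neighbourhoods); a test gene planted at branch `br_k` has an ortholog in
#' every outgroup that diverged at or after its origination, i.e. outgroups
#' `br2..br_k`, and is absent from older outgroups — so [date_genes()]
#' recovers the planted branch. Genes planted at `br1` are focal-specific.
#' Similarity tables carry high scores for ortholog pairs and a sprinkling
#' of weak spurious hits.
#'
#' @param planted Named character vector: test gene id -> branch
#'   (`br1..br9`).
#' @param seed Integer seed.
#' @param n_backbone Conserved backbone genes (default
#'   `4 * length(planted) + 20`).
#' @return A list with `focal_order`, `outgroups` (named list of
#'   `hits_ab`, `hits_ba`, `order` per outgroup branch) and `truth`.
#' @export
gen_synteny_fixture <- function(planted, seed = 1, n_backbone = NULL) {
  if (any(!planted %in% BRANCH_IDS)) stop_ds("planted branches must be br1..br9")
  set.seed(seed)
  n_test <- length(planted)
  if (is.null(n_backbone)) n_backbone <- 4 * n_test + 20
  backbone <- sprintf("bb%04d", seq_len(n_backbone))
  # interleave: one test gene after every 4th backbone gene
  slots <- round(seq(4, n_backbone - 1, length.out = n_test))
  focal_ids <- character(0)
  j <- 1L
  for (i in seq_len(n_backbone)) {
    focal_ids <- c(focal_ids, backbone[i])
    if (j <= n_test && i == slots[j]) {
      focal_ids <- c(focal_ids, names(planted)[j])
      j <- j + 1L
    }
  }
  focal_order <- data.frame(chromosome = "chr1",
                            rank = seq_along(focal_ids),
                            gene_id = focal_ids, stringsAsFactors = FALSE)
  outgroups <- list()
  for (k in 2:9) {
    og_branch <- BRANCH_IDS[k]
    gene_branch_idx <- match(planted[focal_ids], BRANCH_IDS)
    keep <- focal_ids %in% backbone |
      (!is.na(gene_branch_idx) & gene_branch_idx >= k)
    og_ids <- paste0(og_branch, "_", focal_ids[keep])
    order_b <- data.frame(chromosome = "chr1", rank = seq_along(og_ids),
                          gene_id = og_ids, stringsAsFactors = FALSE)
    pairs <- data.frame(a = focal_ids[keep], b = og_ids,
                        stringsAsFactors = FALSE)
    score <- round(100 + stats::runif(nrow(pairs), 0, 10), 2)
    hits_ab <- data.frame(query_id = pairs$a, subject_id = pairs$b,
                          score = score, stringsAsFactors = FALSE)
    hits_ba <- data.frame(query_id = pairs$b, subject_id = pairs$a,
                          score = score, stringsAsFactors = FALSE)
    # weak spurious cross-hits: never outrank the true ortholog
    n_noise <- max(3L, nrow(pairs) %/% 10L)
    noise <- data.frame(
      query_id = sample(pairs$a, n_noise, replace = TRUE),
      subject_id = sample(og_ids, n_noise, replace = TRUE),
      score = round(stats::runif(n_noise, 20, 40), 2),
      stringsAsFactors = FALSE)
    hits_ab <- rbind(hits_ab, noise)
    outgroups[[og_branch]] <- list(hits_ab = hits_ab, hits_ba = hits_ba,
                                   order = order_b)
  }
  truth <- data.frame(gene_id = names(planted), branch = unname(planted),
                      stringsAsFactors = FALSE)
  list(focal_order = focal_order, outgroups = outgroups, truth = truth)
}

#' Generate a TPM expression matrix with planted coexpression partners
#'
#' The target gene's profile is lognormal across samples; each planted
#' partner is the target plus Gaussian noise with standard deviation
#' calibrated so the expected Pearson correlation is about `r_target`
#' (`tau = sd(target) * sqrt(1 / r_target^2 - 1)`); remaining genes are
#' independent lognormal noise. Values are truncated at zero (TPM scale).
#'
#' @param n_genes Total genes including target and partners.
#' @param n_samples Samples (columns).
#' @param n_partners Number of planted partners.
#' @param r_target Planted correlation, in (0, 1).
#' @param seed Integer seed.
#' @return A list with `matrix` (genes x samples, rownames set; target is
#'   `"target"`, partners `"partner_01"...`) and `truth` (partner ids).
#' @export
gen_expression_matrix <- function(n_genes, n_samples, n_partners,
                                  r_target = 0.95, seed = 1) {
  if (r_target <= 0 || r_target >= 1) stop_ds("r_target must lie in (0, 1)")
  if (n_partners + 1 > n_genes) stop_ds("n_partners + target exceed n_genes")
  set.seed(seed)
  target <- stats::rlnorm(n_samples, meanlog = 3, sdlog = 0.8)
  tau <- stats::sd(target) * sqrt(1 / r_target^2 - 1)
  partners <- t(vapply(seq_len(n_partners), function(i)
    pmax(target + stats::rnorm(n_samples, 0, tau), 0),
    numeric(n_samples)))
  n_noise <- n_genes - n_partners - 1L
  noise <- matrix(stats::rlnorm(n_noise * n_samples, 3, 0.8),
                  nrow = n_noise)
  m <- rbind(matrix(target, nrow = 1), partners, noise)
  rownames(m) <- c("target", sprintf("partner_%02d", seq_len(n_partners)),
                   sprintf("noise_%04d", seq_len(n_noise)))
  colnames(m) <- sprintf("sample_%03d", seq_len(n_samples))
  list(matrix = m, truth = sprintf("partner_%02d", seq_len(n_partners)))
}
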