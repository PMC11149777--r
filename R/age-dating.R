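# Synteny-based gene age dating: reciprocal best hits between the focal
# genome and each outgroup, chaining of anchors into synteny blocks with a
# bounded gene-rank gap, and branch assignment by the oldest outgroup with
# conserved syntenic presence. De novo gene ages are consumed as
# annotations, not recomputed.

#' Reciprocal best hits between two protein sets
#'
#' A pair (a, b) is returned iff `b` is the unique top-scoring subject of
#' `a` in the A-to-B table and `a` is the unique top-scoring subject of `b`
#' in the B-to-A table. A tie for the top score disqualifies the query
#' (conservative: an ambiguous best hit is no best hit).
#'
#' @param hits_ab,hits_ba `data.frame`s with columns `query_id`,
#'   `subject_id`, `score` (higher is better), one row per directed pair.
#' @return A `data.frame` with columns `a_id`, `b_id`. Swapping the inputs
#'   swaps the pair order only.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba) {
  best <- function(hits) {
    if (nrow(hits) == 0L)
      return(data.frame(query = character(), subject = character()))
    picks <- lapply(split(hits, hits$query_id), function(d) {
      top <- d[d$score == max(d$score), , drop = FALSE]
      if (nrow(top) != 1L) return(NULL)  # tied top score: excluded
      data.frame(query = top$query_id, subject = top$subject_id,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, picks)
  }
  ab <- best(hits_ab)
  ba <- best(hits_ba)
  if (is.null(ab) || is.null(ba) || nrow(ab) == 0L || nrow(ba) == 0L)
    return(data.frame(a_id = character(), b_id = character(),
                      stringsAsFactors = FALSE))
  key_ab <- paste(ab$query, ab$subject, sep = "\r")
  key_ba <- paste(ba$subject, ba$query, sep = "\r")
  keep <- ab[key_ab %in% key_ba, , drop = FALSE]
  out <- data.frame(a_id = keep$query, b_id = keep$subject,
                    stringsAsFactors = FALSE)
  out[order(out$a_id), , drop = FALSE]
}

gene_rank <- function(order_tbl, ids) {
  idx <- match(ids, order_tbl$gene_id)
  if (anyNA(idx))
    stop_ds("gene id(s) absent from gene order: %s",
            paste(unique(ids[is.na(idx)]), collapse = ", "))
  list(chromosome = order_tbl$chromosome[idx], rank = order_tbl$rank[idx])
}

#' Chain reciprocal-best-hit anchors into synteny blocks
#'
#' Anchors on the same chromosome pair are sorted by rank in genome A and
#' chained into one block while the gene-rank gap to the previous anchor is
#' at most `max_gap` on *both* genomes (at most `max_gap` intervening
#' genes). Blocks are maximal.
#'
#' @param rbh_pairs Output of [reciprocal_best_hits()].
#' @param order_a,order_b Gene-order `data.frame`s with columns
#'   `chromosome`, `rank` (1-based within chromosome), `gene_id`.
#' @param max_gap Maximum intervening-gene gap (default 5).
#' @return A `data.frame`, one row per anchor, with columns `block_id`,
#'   `a_id`, `b_id`, `chr_a`, `chr_b`, `rank_a`, `rank_b`, plus an
#'   `attr(, "blocks")` summary (anchor counts and rank spans per block).
#' @export
build_synteny_blocks <- function(rbh_pairs, order_a, order_b, max_gap = 5) {
  if (nrow(rbh_pairs) == 0L) {
    out <- data.frame(block_id = integer(), a_id = character(),
                      b_id = character(), chr_a = character(),
                      chr_b = character(), rank_a = integer(),
                      rank_b = integer(), stringsAsFactors = FALSE)
    attr(out, "blocks") <- data.frame(block_id = integer(),
                                      n_anchors = integer())
    return(out)
  }
  ra <- gene_rank(order_a, rbh_pairs$a_id)
  rb <- gene_rank(order_b, rbh_pairs$b_id)
  anchors <- data.frame(a_id = rbh_pairs$a_id, b_id = rbh_pairs$b_id,
                        chr_a = ra$chromosome, chr_b = rb$chromosome,
                        rank_a = ra$rank, rank_b = rb$rank,
                        stringsAsFactors = FALSE)
  anchors <- anchors[order(anchors$chr_a, anchors$chr_b, anchors$rank_a), ,
                     drop = FALSE]
  grp <- paste(anchors$chr_a, anchors$chr_b, sep = "\r")
  block <- integer(nrow(anchors))
  next_id <- 0L
  for (g in unique(grp)) {
    i <- which(grp == g)
    gap_a <- c(Inf, diff(anchors$rank_a[i]) - 1L)
    gap_b <- c(Inf, abs(diff(anchors$rank_b[i])) - 1L)
    new_block <- gap_a > max_gap | gap_b > max_gap
    block[i] <- next_id + cumsum(new_block)
    next_id <- max(block[i])
  }
  anchors$block_id <- block
  anchors <- anchors[, c("block_id", "a_id", "b_id", "chr_a", "chr_b",
                         "rank_a", "rank_b")]
  summ <- do.call(rbind, lapply(split(anchors, anchors$block_id), function(d)
    data.frame(block_id = d$block_id[1], n_anchors = nrow(d),
               span_a = max(d$rank_a) - min(d$rank_a) + 1L,
               span_b = max(d$rank_b) - min(d$rank_b) + 1L)))
  rownames(summ) <- NULL
  attr(anchors, "blocks") <- summ
  anchors
}

#' Assign an origination branch from outgroup synteny presence
#'
#' A gene's branch is the *oldest* branch whose outgroup shows the gene
#' inside a conserved synteny block; presence in intermediate outgroups is
#' not required (gene loss in intermediates is tolerated, the standard
#' phylostratigraphic reading). A gene absent from every outgroup is
#' focal-specific, `br1`.
#'
#' @param gene_id Gene identifier (carried through to the output).
#' @param synteny_presence Named logical vector: for each outgroup branch
#'   (`br2..br9`), is the gene found within a conserved synteny block of
#'   that outgroup?
#' @param branch_ladder Character vector of the outgroup branches from
#'   nearest to farthest (default `br2..br9`).
#' @return A list with `gene_id`, `branch`, and `support` (the outgroup
#'   branches with conserved synteny).
#' @export
assign_branch <- function(gene_id, synteny_presence,
                          branch_ladder = BRANCH_IDS[-1]) {
  unknown <- setdiff(names(synteny_presence), branch_ladder)
  if (length(unknown))
    stop_ds("unknown outgroup(s): %s", paste(unknown, collapse = ", "))
  present <- names(synteny_presence)[as.logical(synteny_presence)]
  branch <- if (length(present) == 0L) "br1" else
    branch_ladder[max(match(present, branch_ladder))]
  list(gene_id = gene_id, branch = branch, support = present)
}

#' Homology-detection-failure null expectation
#'
#' Linearly rescales a published null-model count of spurious "young genes"
#' from a source lineage to a focal lineage by the ratio of per-generation
#' mutation rates and the ratio of elapsed times:
#' `n_source * (mu_focal / mu_source) * (t_focal / t_source)`.
#' This is one defensible reading of the published scaling; generation-time
#' or rate-unit conversions, if intended, must be folded into the rates by
#' the caller.
#'
#' @param n_source Null-model gene count in the source lineage.
#' @param mu_source,mu_focal Mutation rates (substitutions/site/generation).
#' @param t_source,t_focal Elapsed times (My).
#' @return Expected number of genes explainable by detection failure.
#' @examples
#' hdf_null_expectation(85, 1.7e-7, 6.5e-9, 20, 2.4)
#' @export
hdf_null_expectation <- function(n_source, mu_source, mu_focal,
                                 t_source, t_focal) {
  for (nm in c("n_source", "mu_source", "mu_focal", "t_source", "t_focal"))
    check_scalar_number(get(nm), nm, positive = TRUE)
  n_source * (mu_focal / mu_source) * (t_focal / t_source)
}

#' Genes with conserved syntenic presence in an outgroup
#'
#' Runs [reciprocal_best_hits()] and [build_synteny_blocks()] for one
#' focal/outgroup genome pair and returns the focal gene ids that sit as
#' anchors inside a conserved block, i.e. a block with at least
#' `min_anchors` anchors (a lone hit with no conserved neighbourhood is not
#' synteny evidence).
#'
#' @param hits_ab,hits_ba Directed similarity tables (focal to outgroup and
#'   back), as in [reciprocal_best_hits()].
#' @param order_a,order_b Gene-order tables for the focal and outgroup
#'   genomes.
#' @param max_gap Gap criterion for [build_synteny_blocks()].
#' @param min_anchors Minimum anchors for a block to count as conserved
#'   synteny (default 2).
#' @return Character vector of focal gene ids.
#' @export
synteny_presence <- function(hits_ab, hits_ba, order_a, order_b,
                             max_gap = 5, min_anchors = 2) {
  rbh <- reciprocal_best_hits(hits_ab, hits_ba)
  anchors <- build_synteny_blocks(rbh, order_a, order_b, max_gap = max_gap)
  if (nrow(anchors) == 0L) return(character())
  sizes <- table(anchors$block_id)
  good <- as.integer(names(sizes)[sizes >= min_anchors])
  unique(anchors$a_id[anchors$block_id %in% good])
}

#' Date focal genes against a ladder of outgroups
#'
#' For each outgroup branch, determines syntenic presence of every focal
#' gene via [synteny_presence()], then assigns each requested gene the
#' oldest branch with presence ([assign_branch()]); genes absent everywhere
#' are focal-specific (`br1`).
#'
#' @param gene_ids Focal genes to date.
#' @param focal_order Focal gene-order table.
#' @param outgroups Named list (names are outgroup branches, nearest
#'   first), each element a list with `hits_ab`, `hits_ba`, `order`.
#' @param max_gap,min_anchors Passed to [synteny_presence()].
#' @return A `data.frame` with columns `gene_id`, `branch`, `support`
#'   (comma-separated supporting outgroups).
#' @export
date_genes <- function(gene_ids, focal_order, outgroups, max_gap = 5,
                       min_anchors = 2) {
  ladder <- names(outgroups)
  present <- lapply(outgroups, function(og)
    synteny_presence(og$hits_ab, og$hits_ba, focal_order, og$order,
                     max_gap = max_gap, min_anchors = min_anchors))
  rows <- lapply(gene_ids, function(g) {
    presence <- stats::setNames(
      vapply(present, function(ids) g %in% ids, logical(1)), ladder)
    res <- assign_branch(g, presence, branch_ladder = ladder)
    data.frame(gene_id = g, branch = res$branch,
               support = paste(res$support, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
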