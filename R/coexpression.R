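# Pearson coexpression against a TPM expression matrix and top-partner
# selection. TPM values are correlated on the raw scale by default; a log
# transform can be applied by the caller before [top_partners()].

#' Pearson correlation with a two-sided p-value
#'
#' `r` with the usual t-transform p-value,
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' (as computed by [stats::cor.test()]). Vectors with zero variance have no
#' defined correlation and are reported as `NA` with `defined = FALSE` so
#' callers can exclude them.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return A list with `r`, `p` and `defined`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop_ds("x and y differ in length")
  if (length(x) < 3L) stop_ds("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, defined = FALSE))
  ct <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, defined = TRUE)
}

#' Top coexpressed partners of a target gene
#'
#' Correlates the target's expression profile with every other gene, keeps
#' genes with `p < alpha`, and returns the `k` with the largest `r`
#' (descending), breaking ties by gene id for determinism. Genes with zero
#' expression variance are excluded (their count is reported in
#' `attr(, "n_zero_variance")`).
#'
#' @param target Gene id present in `matrix`.
#' @param matrix Genes x samples numeric matrix with gene ids as rownames.
#' @param k Number of partners to keep (default 30).
#' @param alpha Raw p-value threshold (default 1e-5).
#' @return A `data.frame` with columns `target`, `partner`, `r`, `p`,
#'   `rank`; fewer than `k` rows if fewer genes reach `alpha`.
#' @export
top_partners <- function(target, matrix, k = 30, alpha = 1e-5) {
  if (!target %in% rownames(matrix))
    stop_ds("target '%s' absent from the expression matrix", target)
  if (ncol(matrix) < 3L) stop_ds("need at least 3 samples")
  x <- matrix[target, ]
  others <- setdiff(rownames(matrix), target)
  res <- lapply(others, function(g) pearson_with_p(x, matrix[g, ]))
  defined <- vapply(res, `[[`, logical(1), "defined")
  tab <- data.frame(
    target = target, partner = others[defined],
    r = vapply(res[defined], `[[`, numeric(1), "r"),
    p = vapply(res[defined], `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE)
  tab <- tab[tab$p < alpha, , drop = FALSE]
  tab <- tab[order(-tab$r, tab$partner), , drop = FALSE]
  tab <- utils::head(tab, k)
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "n_zero_variance") <- sum(!defined)
  tab
}
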