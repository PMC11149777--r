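# Shared test helpers: tiny in-code fixtures and independent oracles.

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# independent OLS oracle: closed-form normal equations
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x^2)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}

# independent Pearson oracle: direct summation formula
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# independent Wilcoxon oracle: full enumeration of all rank splits
wilcoxon_enum_oracle <- function(x, y, alternative) {
  nx <- length(x); ny <- length(y)
  pooled <- rank(c(x, y))
  u_obs <- sum(pooled[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(nx + ny, nx)
  all_ranks <- seq_len(nx + ny)
  u_all <- apply(splits, 2, function(ix)
    sum(all_ranks[ix]) - nx * (nx + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  switch(alternative,
         less = p_le, greater = p_ge,
         two_sided = min(1, 2 * min(p_le, p_ge)))
}

# brute-force residue contact oracle (double loop over atoms)
contact_oracle <- function(model, cutoff) {
  a <- model$chains[[1]]; b <- model$chains[[2]]
  out <- list()
  for (ra in unique(a$resno)) for (rb in unique(b$resno)) {
    pa <- a[a$resno == ra, c("x", "y", "z"), drop = FALSE]
    pb <- b[b$resno == rb, c("x", "y", "z"), drop = FALSE]
    dmin <- Inf
    for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(pb)))
      dmin <- min(dmin, sqrt(sum((pa[i, ] - pb[j, ])^2)))
    if (dmin <= cutoff)
      out[[length(out) + 1L]] <- data.frame(res_a = ra, res_b = rb,
                                            min_dist = dmin)
  }
  if (!length(out))
    return(data.frame(res_a = integer(), res_b = integer(),
                      min_dist = numeric()))
  res <- do.call(rbind, out)
  res[order(res$res_a, res$res_b), , drop = FALSE]
}

# random single-atom two-chain complex for geometry property tests
random_complex <- function(n_a, n_b, box = 10) {
  mk <- function(n) data.frame(
    resno = seq_len(n), resid = "GLY",
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box),
    plddt = 0.8)
  complex_model(list(A = mk(n_a), B = mk(n_b)))
}
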