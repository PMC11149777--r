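test_that("branch medians pair metric medians with divergence times", {
  med <- branch_medians(list(br1 = c(0.2, 0.4, 0.9)))
  expect_equal(med$median, 0.4)
  expect_equal(med$time_mya, 0.1)

  even <- branch_medians(list(br2 = c(1, 2, 3, 4)))
  expect_equal(even$median, 2.5)

  set.seed(61)
  vals <- lapply(setNames(nm = paste0("br", 1:6)), function(b) runif(31))
  med6 <- branch_medians(vals)
  for (i in seq_len(6)) {  # sort-based oracle
    sorted <- sort(vals[[med6$branch[i]]])
    expect_equal(med6$median[i], sorted[16])
  }
  expect_error(branch_medians(list(br1 = numeric())), "no values")
  expect_error(branch_medians(list(brZ = 1:3)), "brZ")
})

test_that("linear trend fitting equals the closed-form normal equations", {
  exact <- fit_linear_trend(data.frame(time_mya = c(0, 1, 2),
                                       median = c(1.0, 0.9, 0.8)))
  expect_equal(exact$slope, -0.1, tolerance = 1e-12)
  expect_equal(exact$intercept, 1.0, tolerance = 1e-12)
  expect_equal(exact$adj_r2, 1, tolerance = 1e-9)

  set.seed(63)
  for (i in 1:10) {
    pts <- data.frame(time_mya = sort(runif(6, 0, 3)),
                      median = runif(6))
    fit <- fit_linear_trend(pts)
    want <- ols_oracle(pts$time_mya, pts$median)
    expect_equal(fit$slope, unname(want["slope"]), tolerance = 1e-10)
    expect_equal(fit$intercept, unname(want["intercept"]),
                 tolerance = 1e-10)
    # adjusted R2 definition
    r2 <- 1 - sum(residuals(lm(median ~ time_mya, pts))^2) /
      sum((pts$median - mean(pts$median))^2)
    expect_equal(fit$adj_r2, 1 - (1 - r2) * 5 / 4, tolerance = 1e-10)
  }

  flat <- fit_linear_trend(data.frame(time_mya = c(0, 1, 2, 3),
                                      median = rep(0.4, 4)))
  expect_equal(flat$slope, 0)
  expect_error(fit_linear_trend(data.frame(time_mya = c(1, 1, 1),
                                           median = 1:3)), "degenerate")
})

test_that("log10 trend fits on the log time scale and rejects t <= 0", {
  fit <- fit_log10_trend(data.frame(time_mya = c(1, 10, 100),
                                    median = c(0.3, 0.2, 0.1)))
  expect_equal(fit$slope, -0.1, tolerance = 1e-12)
  expect_equal(fit$time_scale, "log10")
  expect_error(fit_log10_trend(data.frame(time_mya = c(0, 1, 2),
                                          median = 1:3)), "positive")
})

test_that("benchmark extrapolation inverts the fitted line", {
  mk_fit <- function(intercept, slope)
    fit_linear_trend(data.frame(time_mya = c(0, 1, 2),
                                median = intercept + slope * c(0, 1, 2)))
  expect_equal(time_to_benchmark(mk_fit(1.0, -0.1), 0.5), 5.0,
               tolerance = 1e-9)
  # disorder decay from 0.97 at -0.14/My reaches the duplicate median 0.31
  expect_equal(time_to_benchmark(mk_fit(0.97, -0.14), 0.31), 4.714286,
               tolerance = 1e-6)
  expect_equal(time_to_benchmark(mk_fit(0.8, -0.1), 0.8), 0)
  expect_error(time_to_benchmark(mk_fit(0.8, 0.1), 0.5), "backwards")
  zero <- mk_fit(0.8, -0.1); zero$slope <- 0
  expect_error(time_to_benchmark(zero, 0.5), "zero slope")
})

test_that("Wilcoxon exact branch equals full enumeration for n <= 12", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4), "less"), 1 / 6)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1)

  set.seed(65)
  for (nx in c(1, 2, 3, 4, 5, 6)) for (ny in c(2, 4, 12 - nx)) {
    if (ny < 1 || nx + ny > 12) next
    x <- sample(seq(1, 100), nx)
    y <- sample(setdiff(seq(1, 100), x), ny)
    for (alt in c("two_sided", "less", "greater")) {
      expect_equal(wilcoxon_rank_sum(x, y, alt),
                   wilcoxon_enum_oracle(x, y, alt), tolerance = 1e-12,
                   label = sprintf("nx=%d ny=%d alt=%s", nx, ny, alt))
    }
  }
})

test_that("large-sample Wilcoxon matches the reference implementation", {
  set.seed(67)
  x <- rnorm(40); y <- rnorm(35, 0.4)
  expect_equal(wilcoxon_rank_sum(x, y, "two_sided"),
               suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE)$p.value),
               tolerance = 1e-6)
  # ties force the corrected normal approximation
  xt <- rep(1:5, 3); yt <- rep(2:6, 3)
  expect_equal(wilcoxon_rank_sum(xt, yt, "less"),
               suppressWarnings(wilcox.test(xt, yt, alternative = "less",
                                            exact = FALSE)$p.value),
               tolerance = 1e-6)
})

test_that("per-amino-acid age correlations carry sign and flags", {
  up <- data.frame(time_mya = 1:5, median = seq(0.1, 0.5, by = 0.1))
  down <- data.frame(time_mya = 1:5, median = seq(0.5, 0.1, by = -0.1))
  flat <- data.frame(time_mya = 1:5, median = rep(0.2, 5))
  got <- per_aa_age_correlation(list(K = up, G = down, A = flat))
  expect_equal(got$r[got$aa == "K"], 1)
  expect_equal(got$r[got$aa == "G"], -1)
  expect_false(got$defined[got$aa == "A"])
})

test_that("2x2 ratios reproduce hand arithmetic with Wald intervals", {
  rr <- ratio_2x2(53, 215, 26, 252, kind = "risk")
  expect_equal(rr$estimate, (53 / 215) / (26 / 252), tolerance = 1e-12)
  expect_equal(rr$estimate, 2.389, tolerance = 1e-3)
  or <- ratio_2x2(53, 215, 26, 252, kind = "odds")
  expect_equal(or$estimate, (53 / 162) / (26 / 226), tolerance = 1e-12)
  expect_equal(or$estimate, 2.844, tolerance = 1e-3)
  expect_lt(or$p, 0.001)
  expect_true(or$ci_low > 1 && or$ci_high > or$ci_low)

  trivial <- ratio_2x2(10, 10, 5, 5, kind = "risk")
  expect_equal(trivial$estimate, 1, tolerance = 1e-12)

  expect_error(ratio_2x2(0, 10, 5, 10, kind = "odds"), "correct")
  corrected <- ratio_2x2(0, 10, 5, 10, kind = "odds", correct = TRUE)
  expect_true(is.finite(corrected$estimate))

  fisher <- ratio_2x2(53, 215, 26, 252, kind = "odds", fisher = TRUE)
  expect_equal(fisher$p,
               fisher.test(matrix(c(53, 162, 26, 226), 2,
                                  byrow = TRUE))$p.value)
})
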