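test_that("cohort specs validate the planted law range", {
  expect_s3_class(cohort_spec(paste0("br", 1:6), 10, 0.97, -0.14),
                  "cohort_spec")
  expect_error(cohort_spec(paste0("br", 1:6), 10, 0.1, -0.2), "\\[0, 1\\]")
  expect_error(cohort_spec("br1", 10, 0.5, 0, sigma = -1), ">= 0")
})

test_that("generation is a pure function of spec and seed", {
  spec <- cohort_spec(paste0("br", 1:3), 20, 0.8, -0.1)
  a <- gen_disorder_cohort(spec, seed = 5)
  b <- gen_disorder_cohort(spec, seed = 5)
  expect_identical(a, b)
  c <- gen_disorder_cohort(spec, seed = 6)
  expect_false(identical(a$truth$target_fraction, c$truth$target_fraction))

  s1 <- gen_ss_cohort(cohort_preset("denovo-ss", n_per_branch = 5), seed = 2)
  s2 <- gen_ss_cohort(cohort_preset("denovo-ss", n_per_branch = 5), seed = 2)
  expect_identical(s1, s2)
})

test_that("noise-free disorder cohorts hit the law at every branch", {
  btab <- data.frame(branch = paste0("br", 1:6),
                     time_mya = seq(0.5, 3, by = 0.5))
  spec <- cohort_spec(paste0("br", 1:6), 25, intercept = 0.9, slope = -0.2,
                      sigma = 0, branch_table = btab)
  cohort <- gen_disorder_cohort(spec, seed = 1, track_length = 100)
  fr <- vapply(cohort$records, function(r) track_fraction(r$disorder_track),
               numeric(1))
  br <- vapply(cohort$records, `[[`, character(1), "branch")
  med <- branch_medians(split(fr, br), btab)
  expect_equal(med$median, 0.9 - 0.2 * med$time_mya, tolerance = 1e-12)
})

test_that("record tracks mirror the truth sidecar exactly", {
  spec <- cohort_spec(paste0("br", 1:3), 15, 0.7, -0.1, sigma = 0.4)
  cohort <- gen_disorder_cohort(spec, seed = 8)
  fr <- vapply(cohort$records, function(r) track_fraction(r$disorder_track),
               numeric(1))
  expect_equal(fr, cohort$truth$realized_fraction)
  lens <- vapply(cohort$records, function(r) length(r$disorder_track),
                 integer(1))
  expect_true(all(lens == 150L))
})

test_that("secondary-structure cohorts concentrate on their targets", {
  spec1 <- ss_cohort_spec("br1", 1,
                          laws = data.frame(
                            class = c("coil", "helix", "p310helix",
                                      "strand", "bridge"),
                            intercept = c(0.5, 0.3, 0, 0.2, 0),
                            slope = 0),
                          string_length = 1000)
  rec <- gen_ss_cohort(spec1, seed = 3)$records[[1]]
  p <- ss_proportions(rec$ss_string)
  expect_lt(abs(p[["p_coil"]] - 0.5), 0.05)
  expect_lt(abs(p[["p_helix"]] - 0.3), 0.05)
  expect_lt(abs(p[["p_strand"]] - 0.2), 0.05)

  # single-class law: uniform string
  mono <- ss_cohort_spec("br1", 1,
                         laws = data.frame(
                           class = c("coil", "helix", "p310helix",
                                     "strand", "bridge"),
                           intercept = c(0, 1, 0, 0, 0), slope = 0),
                         string_length = 50)
  expect_equal(gen_ss_cohort(mono, seed = 1)$records[[1]]$ss_string,
               strrep("H", 50))

  bad <- data.frame(class = c("coil", "helix", "p310helix", "strand",
                              "bridge"),
                    intercept = c(0.5, 0.5, 0.5, 0, 0), slope = 0)
  expect_error(ss_cohort_spec("br1", 1, laws = bad), "sum")
})

test_that("opposing coil and strand laws are recovered with both signs", {
  coil <- recover_preset_slope("denovo-ss", seed = 17, n_per_branch = 100,
                               ss_class = "coil")
  strand <- recover_preset_slope("denovo-ss", seed = 17, n_per_branch = 100,
                                 ss_class = "strand")
  expect_lt(coil$slope, 0)
  expect_gt(strand$slope, 0)
})

test_that("sequence cohorts plant recoverable composition trends", {
  cohort <- gen_sequence_cohort(paste0("br", 1:6), n_per_branch = 60,
                                seed = 19)
  comp <- t(vapply(cohort$records, function(r) aa_composition(r$sequence),
                   numeric(20)))
  br <- vapply(cohort$records, `[[`, character(1), "branch")
  btab <- default_branch_table()
  meds <- lapply(setNames(nm = colnames(comp)), function(aa) {
    m <- branch_medians(split(comp[, aa], br), btab)
    m[, c("time_mya", "median")]
  })
  cors <- per_aa_age_correlation(meds)
  for (aa in c("G", "A"))
    expect_lt(cors$r[cors$aa == aa], 0)
  for (aa in c("Y", "F", "K", "L"))
    expect_gt(cors$r[cors$aa == aa], 0)

  # degenerate single-residue composition gives a homopolymer
  mono <- gen_sequence_cohort("br1", 1, seed = 1, seq_length = 30,
                              base = setNames(c(1, rep(0, 19)),
                                              denovostruct:::AA_LETTERS),
                              trends = c(A = 0))
  expect_equal(mono$records[[1]]$sequence, strrep("A", 30))
})

test_that("toy complexes plant exact contact sets", {
  none <- gen_toy_complex(5, 4, 0, seed = 1)
  expect_equal(nrow(interface_contacts(none$model)), 0L)

  one <- gen_toy_complex(5, 4, 1, seed = 2)
  got1 <- interface_contacts(one$model)
  expect_equal(nrow(got1), 1L)
  expect_equal(got1$res_a, one$truth$res_a)

  seven <- gen_toy_complex(10, 8, 7, seed = 3)
  got7 <- interface_contacts(seven$model)
  expect_equal(got7$res_a, seven$truth$res_a)
  expect_equal(got7$res_b, seven$truth$res_b)
  # non-planted pairs all clear the cutoff by the stated margin
  all_d <- contact_oracle(seven$model, Inf)
  planted_key <- paste(seven$truth$res_a, seven$truth$res_b)
  others <- all_d[!paste(all_d$res_a, all_d$res_b) %in% planted_key, ]
  expect_true(all(others$min_dist > 5.5 + 1))

  expect_error(gen_toy_complex(3, 3, 10, seed = 1), "k_contacts")
})

test_that("synteny fixtures are dated back to their planted branches", {
  planted <- c(gA = "br1", gB = "br2", gC = "br6")
  fx <- gen_synteny_fixture(planted, seed = 11)
  # br1 gene absent from every outgroup genome
  for (og in fx$outgroups)
    expect_false(any(grepl("gA", og$order$gene_id)))
  # br6 gene present in outgroups br2..br6, absent from br7..br9
  for (b in paste0("br", 2:6))
    expect_true(any(grepl("gC", fx$outgroups[[b]]$order$gene_id)))
  for (b in paste0("br", 7:9))
    expect_false(any(grepl("gC", fx$outgroups[[b]]$order$gene_id)))

  ages <- date_genes(names(planted), fx$focal_order, fx$outgroups)
  expect_equal(setNames(ages$branch, ages$gene_id), planted)
})

test_that("a 100-gene fixture recovers at least 95% of planted branches", {
  set.seed(23)
  planted <- setNames(sample(paste0("br", 1:9), 100, replace = TRUE),
                      sprintf("g%03d", 1:100))
  fx <- gen_synteny_fixture(planted, seed = 23)
  ages <- date_genes(names(planted), fx$focal_order, fx$outgroups)
  recovery <- mean(ages$branch == planted[ages$gene_id])
  expect_gte(recovery, 0.95)
})

test_that("expression fixtures land near the planted correlation", {
  ex <- gen_expression_matrix(60, 80, 4, r_target = 0.9, seed = 29)
  for (p in ex$truth) {
    r <- pearson_with_p(ex$matrix["target", ], ex$matrix[p, ])$r
    expect_gt(r, 0.8)
  }
  noise_r <- pearson_with_p(ex$matrix["target", ],
                            ex$matrix["noise_0001", ])$r
  expect_lt(abs(noise_r), 0.4)
  expect_true(all(ex$matrix >= 0))
  expect_error(gen_expression_matrix(10, 10, 2, r_target = 1.2), "0, 1")
})
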