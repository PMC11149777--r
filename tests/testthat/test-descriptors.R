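test_that("disorder binarization applies the inclusive threshold", {
  expect_equal(binarize_disorder(c(0.9, 0.1)), c(1L, 0L))
  expect_equal(binarize_disorder(rep(0.5, 4)), rep(1L, 4))  # boundary: >=
  expect_error(binarize_disorder(c(0.2, 1.3)), "outside")

  set.seed(7)
  p <- runif(100)
  expect_equal(binarize_disorder(p, 0.35), as.integer(p >= 0.35))
})

test_that("track fractions and full-ISD classification are exact", {
  expect_equal(track_fraction(rep(1, 5)), 1)
  expect_equal(track_fraction(c(rep(1, 5), rep(0, 5))), 0.5)
  planted <- sample(c(rep(1, 44), rep(0, 56)))
  expect_equal(track_fraction(planted), 0.44)
  expect_error(track_fraction(numeric()), "empty")

  expect_true(classify_full_isd(1.0))
  expect_false(classify_full_isd(0.99))
})

test_that("planted full-ISD proteins are recovered by classification", {
  spec <- cohort_spec("br1", n_per_branch = 181, intercept = 0.6,
                      slope = 0, sigma = 0.4)
  cohort <- gen_disorder_cohort(spec, seed = 9, n_full_isd = 68)
  ratios <- vapply(cohort$records, function(r)
    track_fraction(r$disorder_track), numeric(1))
  expect_equal(sum(classify_full_isd(ratios)), 68L)
  expect_equal(sum(cohort$truth$full_isd), 68L)
})

test_that("secondary-structure proportions follow the partition", {
  p <- ss_proportions("CCCCHHHHHHEEEE")
  expect_equal(unname(p[c("p_coil", "p_helix", "p_strand")]),
               c(4, 6, 4) / 14)
  expect_equal(unname(ss_proportions("GGGG")["p_310helix"]), 1)
  expect_equal(unname(ss_proportions("CTCT")["p_coil"]), 1)  # T counts as coil
  expect_error(ss_proportions("HHZZ"), "Z")

  # sum-to-1 invariant under the default and a re-routed partition
  set.seed(11)
  for (i in 1:20) {
    s <- paste(sample(c("H", "G", "I", "E", "B", "T", "C"), 50,
                      replace = TRUE), collapse = "")
    expect_equal(sum(ss_proportions(s)), 1, tolerance = 1e-9)
    alt <- c(H = "helix", I = "helix", G = "helix", E = "strand",
             B = "strand", C = "coil", T = "coil")
    expect_equal(sum(ss_proportions(s, alt)), 1, tolerance = 1e-9)
  }
})

test_that("composition excludes X and matches a counting oracle", {
  expect_equal(unname(aa_composition("AAG")[c("A", "G")]), c(2, 1) / 3)
  expect_equal(unname(aa_composition("AXG")[c("A", "G")]), c(0.5, 0.5))

  set.seed(3)
  s <- paste(sample(c("A", "C", "D", "G", "K"), 200, replace = TRUE),
             collapse = "")
  comp <- aa_composition(s)
  chars <- strsplit(s, "")[[1]]
  for (aa in c("A", "C", "D", "G", "K"))
    expect_equal(unname(comp[aa]), sum(chars == aa) / 200)
  expect_equal(sum(comp), 1)
})

test_that("molecular weight matches the residue-mass table and is additive", {
  expect_equal(molecular_weight("G"), 75.07, tolerance = 1e-3)
  expect_equal(molecular_weight("GG"), 132.12, tolerance = 1e-3)
  set.seed(5)
  for (i in 1:10) {
    s1 <- paste(sample(LETTERS[LETTERS %in% c("A","C","D","E","F","G","H")],
                       sample(3:10, 1), replace = TRUE), collapse = "")
    s2 <- paste(sample(c("K", "L", "M", "N", "P"), sample(3:10, 1),
                       replace = TRUE), collapse = "")
    expect_equal(molecular_weight(paste0(s1, s2)),
                 molecular_weight(s1) + molecular_weight(s2) - 18.0153,
                 tolerance = 1e-9)
  }
})

test_that("net charge has the expected limits and signs", {
  expect_equal(net_charge("G", 0), 1, tolerance = 1e-3)
  expect_equal(net_charge("G", 14), -1, tolerance = 1e-3)
  expect_gt(net_charge("KKKK", 7), 0)
  expect_lt(net_charge("DDDD", 7), 0)
})

test_that("pI is the unique zero of a monotone charge curve", {
  expect_equal(isoelectric_point("G"), 6.10, tolerance = 1e-3)
  expect_gt(isoelectric_point("KKKKKK"), 9)
  expect_lt(isoelectric_point("DDDDDD"), 4)

  set.seed(13)
  for (i in 1:10) {
    s <- paste(sample(denovostruct:::AA_LETTERS, 30, replace = TRUE),
               collapse = "")
    pi <- isoelectric_point(s)
    expect_lt(abs(net_charge(s, pi)), 1e-4)
    # monotone non-increasing in pH
    grid <- vapply(seq(0, 14, by = 0.5), function(ph) net_charge(s, ph),
                   numeric(1))
    expect_true(all(diff(grid) <= 0))
  }
})

test_that("hydrophobicity is the mean Kyte-Doolittle value", {
  expect_equal(hydrophobicity_score("III"), 4.5)
  expect_equal(hydrophobicity_score("RRR"), -4.5)
  expect_equal(hydrophobicity_score("IR"), 0)
  expect_error(hydrophobicity_score("AAA", scale = c(G = 1)), "A")
})

test_that("folding confidence needs a long-enough high-pLDDT run", {
  expect_equal(folding_confidence(rep(0.95, 50)), "high")
  # run of exactly 10 is not "over ten": falls through to low
  t10 <- c(rep(0.95, 10), rep(0.2, 40))
  expect_equal(folding_confidence(t10), "low")
  t11 <- c(rep(0.95, 11), rep(0.2, 40))
  expect_equal(folding_confidence(t11), "high")
  med <- c(rep(0.72, 12), rep(0.5, 30))
  expect_equal(folding_confidence(med), "medium")

  # agreement with an independent run-scan oracle on random tracks
  set.seed(21)
  for (i in 1:20) {
    tr <- runif(60)
    runs <- function(th) {
      best <- 0; cur <- 0
      for (v in tr) { cur <- if (v >= th) cur + 1 else 0
                      best <- max(best, cur) }
      best
    }
    want <- if (runs(0.9) >= 11) "high" else if (runs(0.7) >= 11) "medium"
            else "low"
    expect_equal(folding_confidence(tr), want)
  }
})

test_that("fold similarity classes follow the TM-score thresholds", {
  expect_equal(fold_similarity_class(c(0.8, 0.9, 0.7)), "similar")
  expect_equal(fold_similarity_class(c(0.1, 0.12)), "random")
  expect_equal(fold_similarity_class(0.3), "intermediate")
  expect_equal(fold_similarity_class(c(0.5, 0.5)), "intermediate")  # > rule
  expect_error(fold_similarity_class(numeric()), "empty")
})

test_that("describe_cohort assembles rows with provenance", {
  recs <- list(
    protein_record("p1", "MKVLAAGG", disorder_track = rep(1, 8),
                   ss_string = "CCHHHHEE"),
    protein_record("p2", "GGSSRRKK", gene_class = "duplicate",
                   branch = "br3", morf_track = c(1, 1, 0, 0, 0, 0, 0, 0)))
  tab <- describe_cohort(recs)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$isd_ratio[1], 1)
  expect_true(tab$is_full_isd[1])
  expect_equal(tab$morf_fraction[2], 0.25)
  expect_equal(tab$hydro_scale, rep("kyte-doolittle", 2))
  expect_equal(tab$p_coil[1] + tab$p_helix[1] + tab$p_strand[1], 1)
})
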