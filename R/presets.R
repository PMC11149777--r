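# Named cohort presets: the study conditions for the simulation-based rate
# recoveries. Each preset fixes branches, sample size and the planted law;
# the slope magnitudes are the published per-My rates and the intercepts
# are chosen so each law stays inside its admissible range over br1..br6
# (see the methods vignette for rationale).

#' Built-in cohort presets
#'
#' * `denovo-isd` - de novo disorder-fraction decline, slope -0.14/My from
#'   intercept 0.97, branches br1..br6, logit noise 0.5.
#' * `duplicate-isd` - duplicate disorder decline, slope -0.099/My from
#'   intercept 0.40.
#' * `denovo-ss` - secondary-structure class laws: coil -0.084/My from
#'   0.55, helix +0.041/My from 0.23, strand +0.065/My from 0.13, 3-10
#'   helix flat at 0.028, bridge absorbing the remainder.
#' * `denovo-hydro` - mean hydrophobicity rising at +0.048/My from -1.0
#'   (Kyte-Doolittle units), Gaussian noise 0.25.
#' * `denovo-morf` - MoRF fraction rising at +0.023/My from 0.05 over
#'   branches br2..br6.
#'
#' All presets use 200 proteins per branch by default.
#'
#' @param name Preset name.
#' @param n_per_branch Proteins per branch (default 200).
#' @param branch_table Branch-time table.
#' @return A [cohort_spec()] or [ss_cohort_spec()].
#' @export
cohort_preset <- function(name = c("denovo-isd", "duplicate-isd",
                                   "denovo-ss", "denovo-hydro",
                                   "denovo-morf"),
                          n_per_branch = 200,
                          branch_table = default_branch_table()) {
  name <- match.arg(name)
  br16 <- paste0("br", 1:6)
  switch(name,
    "denovo-isd" = cohort_spec(br16, n_per_branch, intercept = 0.97,
                               slope = -0.14, sigma = 0.5,
                               kind = "proportion",
                               branch_table = branch_table),
    "duplicate-isd" = cohort_spec(br16, n_per_branch, intercept = 0.40,
                                  slope = -0.099, sigma = 0.5,
                                  kind = "proportion",
                                  branch_table = branch_table),
    "denovo-ss" = ss_cohort_spec(
      br16, n_per_branch,
      laws = data.frame(
        class = c("coil", "helix", "p310helix", "strand", "bridge"),
        intercept = c(0.55, 0.23, 0.028, 0.13, 0.062),
        slope = c(-0.084, 0.041, 0, 0.065, -0.022)),
      string_length = 300, branch_table = branch_table),
    "denovo-hydro" = cohort_spec(br16, n_per_branch, intercept = -1.0,
                                 slope = 0.048, sigma = 0.25,
                                 kind = "metric",
                                 branch_table = branch_table),
    "denovo-morf" = cohort_spec(paste0("br", 2:6), n_per_branch,
                                intercept = 0.05, slope = 0.023,
                                sigma = 0.5, kind = "proportion",
                                branch_table = branch_table)
  )
}

#' Recover a planted rate by cohort simulation
#'
#' The simulation analogue of the real-data rate estimates: generate a
#' cohort under a preset law, reduce each protein to its metric (disorder
#' or MoRF fraction via [track_fraction()], a secondary-structure class
#' proportion via [ss_proportions()], or the raw metric value), take
#' branch medians, and fit the median-versus-time ordinary least squares
#' line. Repeated over seeds this measures how well the pipeline recovers
#' the generating rate.
#'
#' @param preset Preset name (see [cohort_preset()]).
#' @param seed Integer seed for the cohort draw.
#' @param n_per_branch Proteins per branch (default 200).
#' @param ss_class For `denovo-ss`: which class proportion to follow
#'   (`"coil"`, `"helix"` or `"strand"`).
#' @return A `trend_fit` (see [fit_linear_trend()]); the planted slope is
#'   attached as `attr(, "planted_slope")`.
#' @export
recover_preset_slope <- function(preset, seed, n_per_branch = 200,
                                 ss_class = c("coil", "helix", "strand")) {
  ss_class <- match.arg(ss_class)
  spec <- cohort_preset(preset, n_per_branch = n_per_branch)
  if (preset == "denovo-ss") {
    cohort <- gen_ss_cohort(spec, seed = seed)
    col <- paste0("p_", sub("p310helix", "310helix", ss_class))
    vals <- vapply(cohort$records, function(r)
      ss_proportions(r$ss_string)[[col]], numeric(1))
    branches <- vapply(cohort$records, `[[`, character(1), "branch")
    planted <- spec$laws$slope[spec$laws$class == ss_class]
  } else if (preset == "denovo-hydro") {
    cohort <- gen_metric_cohort(spec, seed = seed)
    vals <- cohort$values$value
    branches <- cohort$values$branch
    planted <- spec$slope
  } else {
    cohort <- gen_disorder_cohort(spec, seed = seed,
                                  morf = identical(preset, "denovo-morf"))
    tracks <- lapply(cohort$records, function(r)
      if (is.null(r$morf_track)) r$disorder_track else r$morf_track)
    vals <- vapply(tracks, track_fraction, numeric(1))
    branches <- vapply(cohort$records, `[[`, character(1), "branch")
    planted <- spec$slope
  }
  med <- branch_medians(split(vals, branches),
                        branch_table = if (inherits(spec, "ss_cohort_spec"))
                          spec$branch_table else spec$branch_table)
  fit <- fit_linear_trend(med)
  attr(fit, "planted_slope") <- planted
  fit
}
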