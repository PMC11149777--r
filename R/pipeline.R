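# Config-driven orchestration: simulate -> describe -> aggregate -> fit ->
# report. Each stage is an ordinary function writing TSV/JSON artifacts;
# the `run_pipeline()` dispatcher is what the command-line wrapper in
# inst/cli calls. A global seed fans out to per-stage seeds
# deterministically, so two runs with the same config produce identical
# artifacts.

KNOWN_CONFIG_KEYS <- c(
  "preset", "n_per_branch", "seed", "out_dir", "fasta", "tracks",
  "stride_dir", "pdb", "expression", "target", "k", "alpha", "cutoff",
  "temperature", "branch_table", "descriptors", "ages", "metric",
  "time_scale", "disorder_threshold", "log_level")

#' Resolve a pipeline configuration
#'
#' Reads a YAML config file (if given), overlays explicit overrides, and
#' rejects unknown keys. All resolved values are echoed into the run log so
#' every artifact records its provenance.
#'
#' @param config Path to a YAML file, or a named list, or `NULL`.
#' @param ... Named overrides (command-line flags beat the file).
#' @return A named list of settings.
#' @export
resolve_config <- function(config = NULL, ...) {
  base <- list()
  if (is.character(config)) {
    if (!file.exists(config)) stop_ds("config file not found: %s", config)
    base <- yaml::read_yaml(config)
  } else if (is.list(config)) base <- config
  over <- list(...)
  over <- over[!vapply(over, is.null, logical(1))]
  cfg <- utils::modifyList(base, over)
  unknown <- setdiff(names(cfg), KNOWN_CONFIG_KEYS)
  if (length(unknown))
    stop_ds("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg
}

stage_seed <- function(seed, stage) {
  # deterministic per-stage fan-out; stays well below 2^31
  offsets <- c(simulate = 101L, age = 211L, describe = 307L, coexpr = 401L,
               complex = 503L, trends = 601L, report = 701L)
  (as.integer(seed) * 977L + offsets[[stage]]) %% 2000000011L
}

pipeline_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf(...))
}

#' Run one pipeline stage
#'
#' Subcommands: `simulate` writes a preset cohort (FASTA, track TSV,
#' truth sidecar); `describe` computes the descriptor table for a FASTA
#' plus optional tracks; `coexpr` writes top coexpression partners;
#' `complex` writes interface contacts and RR statistics for a PDB file;
#' `trends` fits a median-versus-time trend from a descriptor table with
#' ages; `report` joins descriptors with ages and emits the full trend
#' table. Artifacts go to `out_dir` (created if needed).
#'
#' @param subcommand One of `simulate`, `describe`, `coexpr`, `complex`,
#'   `trends`, `report`.
#' @param config Path to a YAML config, or a named list (see
#'   [resolve_config()]).
#' @param ... Overrides for individual config keys.
#' @return A named list of the paths written, invisibly.
#' @export
run_pipeline <- function(subcommand = c("simulate", "describe", "coexpr",
                                        "complex", "trends", "report"),
                         config = NULL, ...) {
  subcommand <- match.arg(subcommand)
  cfg <- resolve_config(config, ...)
  if (is.null(cfg$out_dir)) cfg$out_dir <- "."
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  pipeline_log(cfg, "[%s] config: %s", subcommand,
               paste(sprintf("%s=%s", names(cfg),
                             vapply(cfg, function(x)
                               paste(format(x), collapse = ","),
                               character(1))),
                     collapse = " "))
  switch(subcommand,
         simulate = stage_simulate(cfg),
         describe = stage_describe(cfg),
         coexpr = stage_coexpr(cfg),
         complex = stage_complex(cfg),
         trends = stage_trends(cfg),
         report = stage_report(cfg))
}

out_path <- function(cfg, name) file.path(cfg$out_dir, name)

stage_simulate <- function(cfg) {
  if (is.null(cfg$preset)) stop_ds("simulate needs a 'preset'")
  n <- if (is.null(cfg$n_per_branch)) 200L else as.integer(cfg$n_per_branch)
  seed <- stage_seed(cfg$seed, "simulate")
  spec <- cohort_preset(cfg$preset, n_per_branch = n)
  paths <- list()
  if (cfg$preset == "denovo-ss") {
    cohort <- gen_ss_cohort(spec, seed = seed)
    ss <- vapply(cohort$records, `[[`, character(1), "ss_string")
    writeLines(paste(vapply(cohort$records, `[[`, character(1), "id"),
                     ss, sep = "\t"),
               paths$ss <- out_path(cfg, "ss_strings.tsv"))
  } else if (cfg$preset == "denovo-hydro") {
    cohort <- gen_metric_cohort(spec, seed = seed)
    write_descriptor_table(cohort$values,
                           paths$values <- out_path(cfg, "metric_values.tsv"))
  } else {
    cohort <- gen_disorder_cohort(spec, seed = seed,
                                  morf = identical(cfg$preset, "denovo-morf"))
    tracks <- lapply(cohort$records, function(r)
      if (is.null(r$morf_track)) r$disorder_track else r$morf_track)
    names(tracks) <- vapply(cohort$records, `[[`, character(1), "id")
    write_track_tsv(tracks, paths$tracks <- out_path(cfg, "tracks.tsv"))
    write_descriptor_table(cohort$truth,
                           paths$truth <- out_path(cfg, "truth.tsv"))
  }
  if (!is.null(cohort$records)) {
    fa <- data.frame(
      id = vapply(cohort$records, `[[`, character(1), "id"),
      sequence = vapply(cohort$records, `[[`, character(1), "sequence"))
    write_fasta(fa, paths$fasta <- out_path(cfg, "proteins.fasta"))
    ages <- data.frame(
      gene_id = fa$id,
      branch = vapply(cohort$records, `[[`, character(1), "branch"))
    write_descriptor_table(ages, paths$ages <- out_path(cfg, "ages.tsv"))
  }
  invisible(paths)
}

stage_describe <- function(cfg) {
  if (is.null(cfg$fasta)) stop_ds("describe needs a 'fasta' path")
  seqs <- read_fasta(cfg$fasta)
  tracks <- if (!is.null(cfg$tracks)) read_track_tsv(cfg$tracks) else list()
  ss <- if (!is.null(cfg$stride_dir)) {
    files <- list.files(cfg$stride_dir, full.names = TRUE)
    stats::setNames(lapply(files, function(f) read_stride(f)[[1]]),
                    sub("\\.[^.]+$", "", basename(files)))
  } else list()
  thr <- if (is.null(cfg$disorder_threshold)) 0.5 else cfg$disorder_threshold
  records <- lapply(seq_len(nrow(seqs)), function(i) {
    id <- seqs$id[i]
    protein_record(id = id, sequence = seqs$sequence[i],
                   disorder_track = tracks[[id]],
                   ss_string = if (id %in% names(ss)) ss[[id]] else NULL)
  })
  tab <- describe_cohort(records, disorder_threshold = thr)
  path <- out_path(cfg, "descriptors.tsv")
  write_descriptor_table(tab, path)
  invisible(list(descriptors = path))
}

stage_coexpr <- function(cfg) {
  if (is.null(cfg$expression) || is.null(cfg$target))
    stop_ds("coexpr needs 'expression' and 'target'")
  m <- read_expression_matrix(cfg$expression)
  k <- if (is.null(cfg$k)) 30 else cfg$k
  alpha <- if (is.null(cfg$alpha)) 1e-5 else cfg$alpha
  partners <- top_partners(cfg$target, m, k = k, alpha = alpha)
  path <- out_path(cfg, "partners.tsv")
  write_descriptor_table(partners, path)
  invisible(list(partners = path))
}

stage_complex <- function(cfg) {
  if (is.null(cfg$pdb)) stop_ds("complex needs a 'pdb' path")
  cutoff <- if (is.null(cfg$cutoff)) 5.5 else cfg$cutoff
  model <- read_pdb_complex(cfg$pdb)
  contacts <- interface_contacts(model, cutoff = cutoff)
  stats <- rr_statistics(contacts)
  cpath <- out_path(cfg, "contacts.tsv")
  write_descriptor_table(contacts, cpath)
  spath <- out_path(cfg, "rr_stats.json")
  jsonlite::write_json(
    list(raw_count = stats$raw_count,
         nonredundant_ratio = stats$nonredundant_ratio,
         cutoff = cutoff),
    spath, auto_unbox = TRUE, digits = NA)
  invisible(list(contacts = cpath, rr_stats = spath))
}

stage_trends <- function(cfg) {
  if (is.null(cfg$descriptors) || is.null(cfg$ages))
    stop_ds("trends needs 'descriptors' and 'ages' tables")
  if (is.null(cfg$metric)) stop_ds("trends needs a 'metric' column name")
  desc <- read_descriptor_table(cfg$descriptors)
  ages <- read_descriptor_table(cfg$ages)
  merged <- merge(desc, ages, by.x = "id", by.y = "gene_id",
                  suffixes = c("", ".age"))
  br <- if ("branch.age" %in% names(merged)) merged$branch.age
        else merged$branch
  btab <- if (is.null(cfg$branch_table)) default_branch_table()
          else read_branch_table(cfg$branch_table)
  med <- branch_medians(split(merged[[cfg$metric]], br), btab)
  fit <- if (identical(cfg$time_scale, "log10")) fit_log10_trend(med)
         else fit_linear_trend(med)
  path <- out_path(cfg, "trend.json")
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(list(trend = path))
}

stage_report <- function(cfg) {
  # full preset sweep: the simulation analogue of the published rate table
  seed <- stage_seed(cfg$seed, "report")
  n <- if (is.null(cfg$n_per_branch)) 200L else as.integer(cfg$n_per_branch)
  rows <- list(
    c(preset = "denovo-isd", metric = "isd_ratio", ss_class = NA),
    c(preset = "duplicate-isd", metric = "isd_ratio", ss_class = NA),
    c(preset = "denovo-ss", metric = "p_coil", ss_class = "coil"),
    c(preset = "denovo-ss", metric = "p_helix", ss_class = "helix"),
    c(preset = "denovo-ss", metric = "p_strand", ss_class = "strand"),
    c(preset = "denovo-hydro", metric = "hydrophobicity", ss_class = NA),
    c(preset = "denovo-morf", metric = "morf_fraction", ss_class = NA))
  out <- do.call(rbind, lapply(rows, function(r) {
    fit <- if (is.na(r[["ss_class"]]))
      recover_preset_slope(r[["preset"]], seed = seed, n_per_branch = n)
    else recover_preset_slope(r[["preset"]], seed = seed, n_per_branch = n,
                              ss_class = r[["ss_class"]])
    data.frame(preset = r[["preset"]], metric = r[["metric"]],
               slope_per_my = fit$slope, planted = attr(fit, "planted_slope"),
               p_value = fit$p_value, adj_r2 = fit$adj_r2,
               n_points = fit$n_points, stringsAsFactors = FALSE)
  }))
  path <- out_path(cfg, "trend_report.tsv")
  write_descriptor_table(out, path)
  invisible(list(report = path))
}
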