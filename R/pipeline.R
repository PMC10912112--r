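#' Run the full mosaicism-detection pipeline
#'
#' Ties the stages together: obtain a genotyping table (either simulate a
#' synthetic cohort, or genotype real inputs from a target table, manifest
#' and per-sample mpileup files), test every parent against the pooled
#' control background, compute per-position detection limits, and
#' assemble the cohort report. All outputs are written under `out_dir`
#' together with a run-metadata JSON recording version, seed, alpha and
#' grid settings. The pipeline is pure given (inputs, config, seed): a
#' rerun with the same arguments produces an identical detection report.
#'
#' @param out_dir Output directory (created if needed).
#' @param config [cohort_config()] for the synthetic route; ignored when
#'   `targets_path` is supplied.
#' @param targets_path,manifest_path,pileup_dir Real-input route: paths to
#'   the target table, the sample manifest, and a directory of
#'   `<sample_id>.pileup` files.
#' @param annotations Optional family annotation data frame for the
#'   cohort report (the synthetic route supplies its own).
#' @param alpha Per-test significance level; `NULL` (default) recomputes
#'   it from the number of testable families in the actual input via
#'   [bonferroni_alpha()].
#' @param base_alpha Family-wise budget when `alpha` is `NULL`.
#' @param spec [power_spec()] settings for the power stage; its alpha is
#'   synchronized with the detection alpha.
#' @param emit_pileups Synthetic route only: also write mpileup files and
#'   re-derive the genotyping table by parsing them (exercises the pileup
#'   counter end-to-end; slower).
#' @return Invisibly, a list with `table`, `detection`, `limits`,
#'   `power_summary`, `report`, `paths`.
#' @export
run_pipeline <- function(out_dir,
                         config = cohort_config(),
                         targets_path = NULL,
                         manifest_path = NULL,
                         pileup_dir = NULL,
                         annotations = NULL,
                         alpha = NULL,
                         base_alpha = 0.05,
                         spec = NULL,
                         emit_pileups = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  real_input <- !is.null(targets_path)
  if (real_input && (is.null(manifest_path) || is.null(pileup_dir))) {
    stop("stage genotype: targets_path requires manifest_path and pileup_dir")
  }

  if (real_input) {
    targets <- parse_target_table(targets_path)
    manifest <- read_manifest(manifest_path)
    files <- file.path(pileup_dir, paste0(manifest$sample_id, ".pileup"))
    present <- file.exists(files)
    pileups <- lapply(files[present], read_mpileup)
    names(pileups) <- manifest$sample_id[present]
    table <- build_genotyping_table(pileups, targets, manifest)
    sim <- NULL
  } else {
    sim <- simulate_cohort(config)
    if (emit_pileups) {
      pdir <- file.path(out_dir, "pileups")
      emit_mpileup(sim, pdir)
      pileups <- lapply(file.path(pdir, paste0(sim$manifest$sample_id,
                                               ".pileup")), read_mpileup)
      names(pileups) <- sim$manifest$sample_id
      table <- build_genotyping_table(pileups, sim$targets, sim$manifest)
    } else {
      table <- sim$table
    }
    if (is.null(annotations)) annotations <- sim$annotations
    write_tsv_commented(sim$targets, file.path(out_dir, "targets.tsv"),
                        "synthetic variant target table")
    write_tsv_commented(sim$manifest, file.path(out_dir, "manifest.tsv"),
                        "synthetic sample manifest")
    write_tsv_commented(sim$truth, file.path(out_dir, "truth.tsv"),
                        "synthetic ground truth (planted mosaics, error rates)")
  }

  table_path <- file.path(out_dir, "genotyping_table.tsv")
  write_genotyping_table(table, table_path)

  detection <- call_candidates(table, alpha = alpha, base_alpha = base_alpha)
  report_path <- file.path(out_dir, "detection_report.tsv")
  write_detection_report(detection, report_path)

  if (is.null(spec)) {
    spec <- power_spec(alpha = detection$alpha)
  }
  limits <- power_table(table, spec)
  power_path <- file.path(out_dir, "power_limits.tsv")
  write_tsv_commented(limits, power_path, comments = c(
    "per-position minimum detectable allele fraction",
    paste0("alpha = ", format(spec$alpha, digits = 6), "; grid ",
           format(min(spec$grid)), " .. ", format(max(spec$grid)), " (",
           length(spec$grid), " log-spaced points)")
  ))
  power_summary <- detectability_summary(limits)

  report <- cohort_report(annotations, detection, power_summary)
  cohort_json <- file.path(out_dir, "cohort_report.json")
  write_cohort_report(report, cohort_json,
                      file.path(out_dir, "cohort_report.tsv"))

  meta <- list(
    package = "mosaiscan",
    version = as.character(utils::packageVersion("mosaiscan")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input = if (real_input) {
      list(mode = "genotyped",
           targets = targets_path, manifest = manifest_path,
           pileup_dir = pileup_dir)
    } else {
      list(mode = "synthetic", seed = config$seed,
           n_families = config$n_families,
           depth_median = config$depth_median,
           prevalence = config$prevalence)
    },
    alpha = detection$alpha,
    n_families_tested = detection$n_families_tested,
    power_grid = list(min = min(spec$grid), max = max(spec$grid),
                      points = length(spec$grid), spacing = "log"),
    target_powers = spec$target_powers
  )
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    table = table, detection = detection, limits = limits,
    power_summary = power_summary, report = report, sim = sim,
    paths = list(table = table_path, detection = report_path,
                 power = power_path, cohort = cohort_json,
                 metadata = file.path(out_dir, "run_metadata.json"))
  ))
}
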