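#' Mosaicism prevalence with exact binomial confidence interval
#'
#' @param n_mosaic Number of families with a (confirmed) parental mosaic.
#' @param n_families Total families investigated (>= 1).
#' @param conf_level Confidence level of the Clopper-Pearson interval.
#' @return List with `n_mosaic`, `n_families`, `fraction`, `percent`
#'   (rounded to 1 decimal), `ci_lower`, `ci_upper` (on the fraction
#'   scale).
#' @export
prevalence <- function(n_mosaic, n_families, conf_level = 0.95) {
  if (n_families < 1) stop("n_families must be >= 1")
  if (n_mosaic < 0 || n_mosaic > n_families) {
    stop("n_mosaic must be between 0 and n_families")
  }
  ci <- stats::binom.test(n_mosaic, n_families,
                          conf.level = conf_level)$conf.int
  frac <- n_mosaic / n_families
  list(
    n_mosaic = n_mosaic,
    n_families = n_families,
    fraction = frac,
    percent = round(100 * frac, 1),
    ci_lower = ci[1],
    ci_upper = ci[2]
  )
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric test with the probability-mass two-sided rule: the
#' p-value is the sum over the support of all table probabilities not
#' exceeding that of the observed table. A table with a zero row or
#' column margin carries no information and returns p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts (rows = groups,
#'   columns = outcome), or a vector `c(a, b, c, d)` read row-wise.
#' @return Two-sided p-value in (0, 1\].
#' @export
fisher_exact_2x2 <- function(tab) {
  if (is.vector(tab) && length(tab) == 4L) {
    tab <- matrix(tab, nrow = 2, byrow = TRUE)
  }
  if (!is.matrix(tab) || !all(dim(tab) == c(2L, 2L))) {
    stop("tab must be a 2x2 matrix or a length-4 vector")
  }
  if (any(tab < 0) || any(tab != floor(tab))) {
    stop("cell counts must be non-negative integers")
  }
  if (sum(tab) == 0) stop("table total must be positive")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Mirrors R's default behaviour: the exact distribution is used when both
#' groups have fewer than 50 observations and there are no ties, otherwise
#' the normal approximation with tie and continuity correction. The method
#' actually used is recorded in the result. Two identical samples carry no
#' location information and return p = 1.
#'
#' @param x,y Numeric vectors (non-empty; NAs dropped).
#' @return List with `p_value`, `statistic` (W), `method` (`"exact"` or
#'   `"normal_approx"`), `n_x`, `n_y`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be non-empty")
  }
  exact <- length(x) < 50 && length(y) < 50 && !any(duplicated(c(x, y)))
  if (length(unique(c(x, y))) == 1L) {
    return(list(p_value = 1, statistic = length(x) * length(y) / 2,
                method = "degenerate", n_x = length(x), n_y = length(y)))
  }
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  list(
    p_value = min(res$p.value, 1),
    statistic = unname(res$statistic),
    method = if (exact) "exact" else "normal_approx",
    n_x = length(x),
    n_y = length(y)
  )
}

#' Assemble the cohort-level report
#'
#' Aggregates detection results, family annotations and the power summary
#' into one structured report: overall and per-subgroup mosaicism
#' prevalence, variant-type association (Fisher), subgroup association
#' (Fisher), parent-of-origin counts, allele-fraction range of the calls,
#' paternal-age comparison (Wilcoxon), and the cohort detectability
#' summary. Missing annotation fields make the corresponding section
#' unavailable, never fatal. Candidate calls are treated as confirmed
#' (orthogonal confirmation is modelled as a pass-through).
#'
#' @param annotations Data frame with `family_id`, `subgroup` (one of
#'   `DD_ID_autism`, `cohesinopathy`), `variant_type_class` (`SNV` or
#'   `indel`), `paternal_age` (years, NA allowed).
#' @param detection Result of [call_candidates()].
#' @param power_summary Optional result of [detectability_summary()].
#' @return List of class `cohort_report`.
#' @export
cohort_report <- function(annotations, detection, power_summary = NULL) {
  res <- detection$results
  cand <- detection$candidates
  n_families <- length(unique(res$family_id))
  mosaic_fams <- unique(cand$family_id)
  n_mosaic <- length(mosaic_fams)

  report <- list(
    n_families = n_families,
    n_mosaic = n_mosaic,
    alpha = detection$alpha,
    prevalence_overall = prevalence(n_mosaic, max(n_families, 1L)),
    af_range = if (n_mosaic > 0) range(cand$af) else c(NA_real_, NA_real_),
    parent_of_origin = c(
      father = sum(cand$parent_role == "father" & !cand$both_parents_flag),
      mother = sum(cand$parent_role == "mother" & !cand$both_parents_flag),
      both_flagged = length(unique(cand$family_id[cand$both_parents_flag]))
    )
  )

  if (n_mosaic == 0L) {
    report$note <- "no candidate mosaic calls; association tests skipped"
    report$power_summary <- power_summary
    class(report) <- "cohort_report"
    return(report)
  }

  ann_ok <- !is.null(annotations) && nrow(annotations) > 0
  if (ann_ok) {
    ann <- annotations
    ann$mosaic <- ann$family_id %in% mosaic_fams

    if ("subgroup" %in% names(ann)) {
      by_sub <- lapply(split(ann, ann$subgroup), function(d) {
        prevalence(sum(d$mosaic), nrow(d))
      })
      report$prevalence_by_subgroup <- by_sub
      tab <- with(ann, table(factor(subgroup,
                                    levels = unique(subgroup)),
                             factor(mosaic, levels = c(TRUE, FALSE))))
      if (all(dim(tab) == c(2L, 2L))) {
        report$fisher_subgroup_p <- fisher_exact_2x2(unclass(tab))
      }
    }

    if ("variant_type_class" %in% names(ann)) {
      tab <- with(ann, table(factor(mosaic, levels = c(TRUE, FALSE)),
                             factor(variant_type_class,
                                    levels = c("SNV", "indel"))))
      report$variant_type_table <- unclass(tab)
      report$fisher_variant_type_p <- fisher_exact_2x2(unclass(tab))
    }

    if ("paternal_age" %in% names(ann)) {
      ages_m <- ann$paternal_age[ann$mosaic]
      ages_n <- ann$paternal_age[!ann$mosaic]
      ages_m <- ages_m[!is.na(ages_m)]
      ages_n <- ages_n[!is.na(ages_n)]
      if (length(ages_m) > 0 && length(ages_n) > 0) {
        w <- wilcoxon_rank_sum(ages_m, ages_n)
        report$paternal_age <- list(
          mean_mosaic = mean(ages_m),
          mean_non_mosaic = mean(ages_n),
          n_mosaic = length(ages_m),
          n_non_mosaic = length(ages_n),
          wilcoxon_p = w$p_value,
          wilcoxon_method = w$method
        )
      }
    }
  } else {
    report$note <- "no family annotations supplied; association tests unavailable"
  }

  report$power_summary <- power_summary
  class(report) <- "cohort_report"
  report
}

#' Serialize a cohort report
#'
#' Writes the report as JSON (lossless) and as a flat key/value TSV.
#'
#' @param report [cohort_report()] result.
#' @param json_path,tsv_path Output paths (either may be `NULL` to skip).
#' @export
write_cohort_report <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  }
  if (!is.null(tsv_path)) {
    flat <- unlist(unclass(report))
    df <- data.frame(key = names(flat), value = as.character(flat),
                     stringsAsFactors = FALSE)
    write_tsv_commented(df, tsv_path,
                        comments = "cohort report (flattened key/value view)")
  }
  invisible(report)
}

#' Read back a JSON cohort report
#'
#' @param json_path Path written by [write_cohort_report()].
#' @return Nested list.
#' @export
read_cohort_report <- function(json_path) {
  jsonlite::read_json(json_path, simplifyVector = TRUE)
}
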