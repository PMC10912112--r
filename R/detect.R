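#' Upper tail of the Poisson distribution
#'
#' Returns `P(X >= k)` for `X ~ Poisson(lambda0)`, the p-value of the
#' one-sided exact Poisson test of an observed count `k` against expected
#' null count `lambda0`. Conventions at the boundary: `k == 0` gives
#' exactly 1 (no evidence can come from zero reads), and `lambda0 == 0`
#' with `k >= 1` gives exactly 0 (any read over a zero background is
#' incompatible with the null).
#'
#' @param k Observed count(s), non-negative integer(s).
#' @param lambda0 Expected count(s) under the null, non-negative.
#' @return p-value(s) in \[0, 1\], vectorized over `k` and `lambda0`.
#' @export
poisson_sf <- function(k, lambda0) {
  if (length(k) == 0L) return(numeric(0))
  if (any(is.na(k)) || any(is.na(lambda0))) stop("k and lambda0 must be non-missing")
  if (any(k < 0) || any(k != floor(k))) stop("k must be a non-negative integer")
  if (any(lambda0 < 0)) stop("lambda0 must be non-negative")
  p <- stats::ppois(k - 1, lambda0, lower.tail = FALSE)
  p[k == 0] <- 1
  zl <- lambda0 == 0  # recycled against k
  p[zl & k >= 1] <- 0
  p
}

#' Experiment-wide Bonferroni significance level
#'
#' Two tests are run per family (father and mother), so the family-wise
#' error budget is divided by twice the number of families: for the
#' default cohort of 189 families, 0.05 / 378 = 1.3228e-4.
#'
#' @param n_families Number of tested families (>= 1).
#' @param base_alpha Family-wise type-I error budget (default 0.05).
#' @return The per-test significance level.
#' @export
bonferroni_alpha <- function(n_families, base_alpha = 0.05) {
  if (length(n_families) != 1L || is.na(n_families) || n_families < 1 ||
      n_families != floor(n_families)) {
    stop("n_families must be a single integer >= 1")
  }
  if (base_alpha <= 0 || base_alpha >= 1) stop("base_alpha must be in (0, 1)")
  base_alpha / (2 * n_families)
}

#' Pool control counts at a targeted position
#'
#' The background allele fraction `p0` at a position is the overall ratio
#' of alternative to total counts among the control samples of the pool
#' (parents of families with a distinct variant). Controls with zero depth
#' contribute nothing; the tested family's own parents are never controls
#' for themselves (the genotyping table's `role` column enforces this).
#'
#' @param table Genotyping table rows.
#' @param family_id Family whose target is being tested.
#' @return One-row data frame with `family_id`, `n_controls` (controls
#'   with positive depth), `pooled_alt`, `pooled_depth`, `p0`, and
#'   `testable` (FALSE when no control has positive depth).
#' @export
pool_controls <- function(table, family_id) {
  ctl <- table[table$family_id == family_id & table$role == "control" &
                 table$depth > 0, , drop = FALSE]
  pooled_alt <- sum(ctl$alt_count)
  pooled_depth <- sum(ctl$depth)
  data.frame(
    family_id = family_id,
    n_controls = nrow(ctl),
    pooled_alt = pooled_alt,
    pooled_depth = pooled_depth,
    p0 = if (pooled_depth > 0) pooled_alt / pooled_depth else NA_real_,
    testable = pooled_depth > 0,
    stringsAsFactors = FALSE
  )
}

#' Test one parent against the pooled control background
#'
#' The parent's alternative count is compared to its expectation under the
#' control background: `lambda0 = depth_parent * p0`. The p-value is the
#' one-sided exact Poisson upper tail `P(X >= alt_count | lambda0)`.
#' Significance uses `p <= alpha` (a tie at alpha is significant). A
#' parent with zero depth, or a position with no usable controls, yields
#' an untestable result (never counted as negative evidence).
#'
#' @param parent One genotyping-table row for the father or mother.
#' @param controls One-row summary from [pool_controls()].
#' @param alpha Per-test significance level (see [bonferroni_alpha()]).
#' @param pseudocount Optional count added to the pooled control
#'   alternative reads before computing `p0` (default 0, i.e. a single
#'   read over a clean background is significant at any alpha).
#' @return One-row data frame with `sample_id`, `family_id`,
#'   `parent_role`, `observed_k`, `parent_depth`, `af`, `p0`,
#'   `expected_lambda0`, `p_value`, `alpha`, `significant`,
#'   `zero_background`, `testable`.
#' @export
test_parent <- function(parent, controls, alpha, pseudocount = 0) {
  testable <- isTRUE(controls$testable) && parent$depth > 0
  p0 <- if (isTRUE(controls$testable)) {
    (controls$pooled_alt + pseudocount) / controls$pooled_depth
  } else NA_real_
  lambda0 <- if (testable) parent$depth * p0 else NA_real_
  p <- if (testable) poisson_sf(parent$alt_count, lambda0) else NA_real_
  data.frame(
    sample_id = parent$sample_id,
    family_id = parent$family_id,
    parent_role = parent$role,
    observed_k = parent$alt_count,
    parent_depth = parent$depth,
    af = parent$af,
    p0 = p0,
    expected_lambda0 = lambda0,
    p_value = p,
    alpha = alpha,
    significant = if (testable) p <= alpha else NA,
    zero_background = if (testable) p0 == 0 else NA,
    testable = testable,
    stringsAsFactors = FALSE
  )
}

#' Call candidate parental mosaics across a cohort
#'
#' Runs exactly two one-sided exact Poisson tests per testable family (one
#' per parent) at the experiment-wide Bonferroni level, and returns both
#' the full per-parent report and the candidate calls (significant
#' parents). Families with a missing parent sample, a zero-depth parent,
#' or no usable controls are carried in the report flagged untestable. A
#' family in which *both* parents are significant is flagged as a suspect
#' artifact (a true parental mosaic is carried by one parent), never
#' suppressed.
#'
#' @param table Genotyping table.
#' @param alpha Per-test significance level; when `NULL` (default) it is
#'   computed as `bonferroni_alpha(n_testable_families, base_alpha)` from
#'   the cohort actually supplied.
#' @param base_alpha Family-wise budget used when `alpha` is `NULL`.
#' @param pseudocount Passed to [test_parent()].
#' @return List with `results` (one row per parent), `candidates`
#'   (significant calls sorted by p-value, with `both_parents_flag`),
#'   `alpha`, and `n_families_tested`.
#' @export
call_candidates <- function(table, alpha = NULL, base_alpha = 0.05,
                            pseudocount = 0) {
  parents <- table[table$role %in% c("father", "mother"), , drop = FALSE]
  if ("parent_missing" %in% names(table)) {
    disabled <- unique(table$family_id[table$parent_missing])
  } else {
    disabled <- character(0)
  }

  # pooled control background per family (vectorized over the cohort)
  ctl <- table[table$role == "control" & table$depth > 0, , drop = FALSE]
  sums <- rowsum(cbind(alt = ctl$alt_count, depth = ctl$depth),
                 group = ctl$family_id)
  fam_ids <- rownames(sums)
  p0 <- (sums[, "alt"] + pseudocount) / sums[, "depth"]

  idx <- match(parents$family_id, fam_ids)
  pooled_depth <- ifelse(is.na(idx), 0, sums[idx, "depth"])
  p0p <- ifelse(is.na(idx), NA_real_, p0[idx])
  testable <- pooled_depth > 0 & parents$depth > 0 &
    !(parents$family_id %in% disabled)

  n_fam_tested <- length(unique(parents$family_id[testable]))
  if (is.null(alpha)) {
    if (n_fam_tested == 0L) stop("no testable family in the cohort")
    alpha <- bonferroni_alpha(n_fam_tested, base_alpha)
  }

  lambda0 <- ifelse(testable, parents$depth * p0p, NA_real_)
  pv <- rep(NA_real_, nrow(parents))
  pv[testable] <- poisson_sf(parents$alt_count[testable], lambda0[testable])

  results <- data.frame(
    sample_id = parents$sample_id,
    family_id = parents$family_id,
    parent_role = parents$role,
    chrom = parents$chrom,
    pos = parents$pos,
    observed_k = parents$alt_count,
    parent_depth = parents$depth,
    af = parents$af,
    p0 = p0p,
    expected_lambda0 = lambda0,
    p_value = pv,
    alpha = alpha,
    significant = ifelse(testable, pv <= alpha, NA),
    zero_background = ifelse(testable, p0p == 0, NA),
    testable = testable,
    stringsAsFactors = FALSE
  )

  sig <- results[!is.na(results$significant) & results$significant, ,
                 drop = FALSE]
  both <- names(which(table(sig$family_id) == 2L))
  candidates <- sig[order(sig$p_value, sig$family_id), , drop = FALSE]
  candidates$both_parents_flag <- candidates$family_id %in% both
  rownames(results) <- rownames(candidates) <- NULL

  list(results = results, candidates = candidates, alpha = alpha,
       n_families_tested = n_fam_tested)
}

#' Write the per-parent detection report
#'
#' @param detection Result of [call_candidates()].
#' @param path Output TSV path.
#' @export
write_detection_report <- function(detection, path) {
  write_tsv_commented(detection$results, path, comments = c(
    "detection report: one row per parental sample",
    paste0("one-sided exact Poisson test; alpha = ",
           format(detection$alpha, digits = 6),
           " (Bonferroni over 2 x ", detection$n_families_tested,
           " tests unless overridden)")
  ))
}
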