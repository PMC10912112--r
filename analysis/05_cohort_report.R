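#!/usr/bin/env Rscript
# Stage 5 — cohort-level statistics.
#
# Aggregates the detection report, the family annotations and the power
# summary: mosaicism prevalence (overall and by clinical subgroup),
# variant-type and subgroup associations (Fisher exact), parent of
# origin, allele-fraction range of the calls, and the paternal-age
# comparison (Wilcoxon rank-sum; mosaics arise in parental embryogenesis
# and so are not enriched by paternal age, unlike spermatogonial
# mutations).

suppressMessages(library(mosaiscan))
SEED <- 20240304

sim <- simulate_cohort(cohort_config(seed = SEED))
det <- call_candidates(sim$table)
lim <- power_table(sim$table, power_spec(alpha = det$alpha))
rep_ <- cohort_report(sim$annotations, det, detectability_summary(lim))

dir.create("results", showWarnings = FALSE)
write_cohort_report(rep_, "results/cohort_report.json",
                    "results/cohort_report.tsv")

p <- rep_$prevalence_overall
cat(sprintf("prevalence: %d/%d families = %.1f%% (95%% CI %.1f%%..%.1f%%)\n",
            p$n_mosaic, p$n_families, p$percent,
            100 * p$ci_lower, 100 * p$ci_upper))
for (sg in names(rep_$prevalence_by_subgroup)) {
  ps <- rep_$prevalence_by_subgroup[[sg]]
  cat(sprintf("  %s: %d/%d = %.1f%%\n", sg, ps$n_mosaic, ps$n_families,
              ps$percent))
}
cat(sprintf("parent of origin: %d paternal / %d maternal\n",
            rep_$parent_of_origin[["father"]],
            rep_$parent_of_origin[["mother"]]))
if (!is.null(rep_$fisher_variant_type_p)) {
  cat(sprintf("variant type (SNV vs indel) Fisher p = %.2f\n",
              rep_$fisher_variant_type_p))
}
if (!is.null(rep_$fisher_subgroup_p)) {
  cat(sprintf("subgroup Fisher p = %.2f\n", rep_$fisher_subgroup_p))
}
if (!is.null(rep_$paternal_age)) {
  pa <- rep_$paternal_age
  cat(sprintf("paternal age: %.1f y (mosaic, n=%d) vs %.1f y (non-mosaic, n=%d), Wilcoxon (%s) p = %.3f\n",
              pa$mean_mosaic, pa$n_mosaic, pa$mean_non_mosaic,
              pa$n_non_mosaic, pa$wilcoxon_method, pa$wilcoxon_p))
}
cat("full report: results/cohort_report.json\n")
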