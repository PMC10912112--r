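#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates the default synthetic cohort: 189 trio families in 8 capture
# pools, two parents plus up to 46 controls sequenced per targeted
# position, log-normal UMI-deduplicated depth (median 7225x), a
# zero-inflated Beta background-error model and 7 planted parental
# mosaics with allele fractions log-uniform on [0.02%, 31.5%].
# Every later stage re-derives this cohort deterministically from the
# same seed, so this script's outputs are documentation, not a handoff.

suppressMessages(library(mosaiscan))
SEED <- 20240304

cfg <- cohort_config(seed = SEED)
sim <- simulate_cohort(cfg)

dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)
dir.create("scratch/sim", recursive = TRUE, showWarnings = FALSE)
write_tsv_commented(sim$targets, "results/sim/targets.tsv",
                    "synthetic variant target table (one row per family)")
write_tsv_commented(sim$manifest, "results/sim/manifest.tsv",
                    "synthetic sample manifest")
write_tsv_commented(sim$truth, "results/sim/truth.tsv",
                    "ground truth: error rates and planted mosaics")
# the full genotyping table is bulky; it lives under scratch/
write_genotyping_table(sim$table, "scratch/sim/genotyping_table.tsv")

cat("cohort:", cfg$n_families, "families,",
    length(unique(sim$table$sample_id)), "parental samples,",
    nrow(sim$table), "(sample, position) rows\n")
cat("median depth:", stats::median(sim$table$depth),
    "(configured median", cfg$depth_median, ")\n")
cat("positions with zero background:",
    sum(sim$truth$error_rate == 0), "/", cfg$n_families, "\n")
noisy <- sim$truth$error_rate[sim$truth$error_rate > 0]
cat(sprintf("noisy positions: mean error %.4f, max %.4f\n",
            mean(noisy), max(noisy)))
mos <- sim$truth[sim$truth$mosaic, ]
cat("planted mosaics:", nrow(mos),
    sprintf("(%d paternal / %d maternal), AF %.3f%% .. %.1f%%\n",
            sum(mos$mosaic_parent == "father"),
            sum(mos$mosaic_parent == "mother"),
            100 * min(mos$true_af), 100 * max(mos$true_af)))
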