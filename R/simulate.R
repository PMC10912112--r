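#' Synthetic cohort configuration
#'
#' Bundles the parameters of the synthetic-cohort generator. The defaults
#' emulate the study conditions the pipeline was designed for: 189 trio
#' families split across 8 capture pools, two parents plus 46 control
#' samples per targeted position, UMI-deduplicated depth log-normal with
#' median 7225x, a zero-inflated Beta background-error model (70% of
#' positions error-free; noisy positions Beta-distributed with mean 0.3%
#' and capped near 1%), 7/189 families carrying a parental mosaic with
#' allele fraction log-uniform on \[0.02%, 31.5%\] and a 5/7 paternal
#' bias, and a 124:62 SNV:indel target mix.
#'
#' @param n_families Number of trio families.
#' @param n_pools Number of capture pools (families split evenly).
#' @param n_controls Maximum control samples per position (other parents
#'   of the pool, truncated to this count).
#' @param depth_median Median of the per-sample, per-position log-normal
#'   depth distribution.
#' @param depth_log_sd Log-scale standard deviation of depth.
#' @param clean_prob Probability that a position is noise-free.
#' @param clean_error Error rate at clean positions (default 0: the
#'   zero-inflation component).
#' @param noise_mean Mean error rate at noisy positions.
#' @param noise_shape1 Beta shape1 at noisy positions (shape2 follows from
#'   the mean).
#' @param noise_max Upper cap on noisy-position error rates (rejection
#'   resampling).
#' @param prevalence Fraction of families planted with a parental mosaic;
#'   the planted count is `round(prevalence * n_families)`.
#' @param af_range Range of planted mosaic allele fractions (log-uniform).
#' @param paternal_prob Probability a planted mosaic is paternal.
#' @param mosaic_plan Optional explicit plan: data frame with `family`
#'   (integer index), `parent` (`"father"`/`"mother"`), `true_af`.
#'   Overrides `prevalence`/`af_range`/`paternal_prob`.
#' @param variant_mix Named vector `c(SNV=, indel=)` giving the target
#'   type mix (scaled to `n_families`).
#' @param subgroup_mix Named vector `c(cohesinopathy=, DD_ID_autism=)`
#'   clinical subgroup mix (scaled to `n_families`).
#' @param age_meanlog,age_sdlog Log-normal paternal age-at-conception
#'   parameters (defaults give mean ~33.7 years).
#' @param age_shift Years subtracted from mosaic families' paternal ages
#'   (mosaics arise in parental embryogenesis, so they are not enriched by
#'   paternal age; default 4.1).
#' @param age_missing_frac Fraction of (non-mosaic) families with missing
#'   paternal age (default 14/189).
#' @param seed RNG seed; the generator is fully deterministic given the
#'   seed.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_families = 189L,
                          n_pools = 8L,
                          n_controls = 46L,
                          depth_median = 7225,
                          depth_log_sd = 0.6,
                          clean_prob = 0.7,
                          clean_error = 0,
                          noise_mean = 0.003,
                          noise_shape1 = 2,
                          noise_max = 0.01,
                          prevalence = 7 / 189,
                          af_range = c(2e-4, 0.315),
                          paternal_prob = 5 / 7,
                          mosaic_plan = NULL,
                          variant_mix = c(SNV = 124, indel = 62),
                          subgroup_mix = c(cohesinopathy = 45,
                                           DD_ID_autism = 144),
                          age_meanlog = log(33.3),
                          age_sdlog = 0.15,
                          age_shift = 4.1,
                          age_missing_frac = 14 / 189,
                          seed = 1L) {
  stopifnot(n_families >= 2L, n_pools >= 1L, n_controls >= 1L,
            depth_median > 0, depth_log_sd >= 0,
            clean_prob >= 0, clean_prob <= 1,
            clean_error >= 0, clean_error < 1,
            noise_mean > 0, noise_max > noise_mean / 10,
            prevalence >= 0, prevalence <= 1)
  if (is.null(mosaic_plan) && prevalence > 0) {
    if (length(af_range) != 2L || af_range[1] <= 0 || af_range[2] >= 1 ||
        af_range[1] > af_range[2]) {
      stop("af_range must be an increasing pair inside (0, 1)")
    }
  }
  if (n_families / n_pools < 2) {
    stop("each pool needs at least 2 families to provide controls")
  }
  structure(as.list(environment()), class = "cohort_config")
}

rbeta_capped <- function(n, shape1, mean, cap) {
  shape2 <- shape1 / mean - shape1
  x <- stats::rbeta(n, shape1, shape2)
  bad <- which(x > cap)
  while (length(bad)) {
    x[bad] <- stats::rbeta(length(bad), shape1, shape2)
    bad <- bad[x[bad] > cap]
  }
  x
}

random_motif <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate a synthetic trio cohort
#'
#' Draws, for each family, a targeted variant (locus, alleles, type) and,
#' for each sample sequenced at that position (two parents plus the pool's
#' controls), a depth from the log-normal depth model and an alternative
#' count from the binomial noise model: `Binomial(depth, e)` for controls
#' and non-mosaic parents, `Binomial(depth, e + af * (1 - e))` for the
#' mosaic parent (signal composes with noise, so AF estimates are slightly
#' biased upward at noisy positions). Counts are binomial rather than
#' Poisson, so the Poisson test's adequacy is a tested property, not an
#' assumption. Fully deterministic given `config$seed`.
#'
#' @param config [cohort_config()].
#' @return List of class `mosaic_cohort` with `config`, `targets`,
#'   `manifest`, `table` (genotyping table in the
#'   [build_genotyping_table()] schema), `annotations` (family subgroup /
#'   variant class / paternal age), and `truth` (per-family ground truth:
#'   error rate, mosaic status, mosaic parent, true allele fraction).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  nf <- as.integer(config$n_families)
  fam <- sprintf("FAM%04d", seq_len(nf))
  pool <- paste0("pool", sort(rep_len(seq_len(config$n_pools), nf)))

  # targets: type mix scaled to the cohort, indels split INS/DEL
  n_snv <- round(nf * config$variant_mix[["SNV"]] / sum(config$variant_mix))
  types <- sample(c(rep("SNV", n_snv), rep("INS", ceiling((nf - n_snv) / 2)),
                    rep("DEL", floor((nf - n_snv) / 2))))
  chrom <- paste0("chr", sample(1:22, nf, replace = TRUE))
  pos <- sample(1e6:2e8, nf)  # unique positions
  bases <- c("A", "C", "G", "T")
  ref <- character(nf); alt <- character(nf)
  for (i in seq_len(nf)) {
    anchor <- sample(bases, 1)
    if (types[i] == "SNV") {
      ref[i] <- anchor
      alt[i] <- sample(setdiff(bases, anchor), 1)
    } else if (types[i] == "INS") {
      ref[i] <- anchor
      alt[i] <- paste0(anchor, random_motif(sample(1:5, 1)))
    } else {
      ref[i] <- paste0(anchor, random_motif(sample(1:5, 1)))
      alt[i] <- anchor
    }
  }
  targets <- data.frame(family_id = fam, chrom = chrom, pos = pos,
                        ref = ref, alt = alt, variant_type = types,
                        pool_id = pool, stringsAsFactors = FALSE)

  manifest <- data.frame(
    sample_id = c(paste0(fam, "_F"), paste0(fam, "_M")),
    family_id = c(fam, fam),
    role = rep(c("father", "mother"), each = nf),
    pool_id = c(pool, pool),
    stringsAsFactors = FALSE
  )
  manifest <- manifest[order(manifest$family_id, manifest$role), ]
  rownames(manifest) <- NULL

  # position-specific background error: zero-inflated Beta
  clean <- stats::runif(nf) < config$clean_prob
  err <- numeric(nf)
  err[clean] <- config$clean_error
  if (any(!clean)) {
    err[!clean] <- rbeta_capped(sum(!clean), config$noise_shape1,
                                config$noise_mean, config$noise_max)
  }

  # mosaic plan
  if (!is.null(config$mosaic_plan)) {
    plan <- config$mosaic_plan
  } else {
    n_mos <- round(config$prevalence * nf)
    if (n_mos > 0) {
      plan <- data.frame(
        family = sample(nf, n_mos),
        parent = ifelse(stats::runif(n_mos) < config$paternal_prob,
                        "father", "mother"),
        true_af = exp(stats::runif(n_mos, log(config$af_range[1]),
                                   log(config$af_range[2]))),
        stringsAsFactors = FALSE
      )
    } else {
      plan <- data.frame(family = integer(), parent = character(),
                         true_af = numeric(), stringsAsFactors = FALSE)
    }
  }
  mosaic <- rep(FALSE, nf)
  mosaic_parent <- rep("none", nf)
  true_af <- rep(NA_real_, nf)
  mosaic[plan$family] <- TRUE
  mosaic_parent[plan$family] <- plan$parent
  true_af[plan$family] <- plan$true_af

  # per-family sample blocks: 2 parents + controls (other parents in pool)
  pool_parents <- split(manifest$sample_id, manifest$pool_id)
  s_id <- vector("list", nf); s_role <- vector("list", nf)
  for (i in seq_len(nf)) {
    own <- manifest$sample_id[manifest$family_id == fam[i]]
    own_roles <- manifest$role[manifest$family_id == fam[i]]
    others <- setdiff(pool_parents[[pool[i]]], own)
    ctl <- others[seq_len(min(length(others), config$n_controls))]
    s_id[[i]] <- c(own, ctl)
    s_role[[i]] <- c(own_roles, rep("control", length(ctl)))
  }
  block_len <- lengths(s_id)
  fam_row <- rep(seq_len(nf), block_len)
  sample_id <- unlist(s_id)
  role <- unlist(s_role)
  N <- length(sample_id)

  depth <- pmax(1L, as.integer(round(
    stats::rlnorm(N, meanlog = log(config$depth_median),
                  sdlog = config$depth_log_sd))))
  e_row <- err[fam_row]
  p <- e_row
  is_mos_parent <- mosaic[fam_row] & role == mosaic_parent[fam_row]
  p[is_mos_parent] <- e_row[is_mos_parent] +
    true_af[fam_row][is_mos_parent] * (1 - e_row[is_mos_parent])
  alt_count <- stats::rbinom(N, depth, p)
  # indel-bearing reads still match the reference at the anchor base
  ref_count <- depth - ifelse(types[fam_row] == "SNV", alt_count, 0L)

  table <- data.frame(
    sample_id = sample_id,
    family_id = fam[fam_row],
    role = role,
    chrom = chrom[fam_row],
    pos = pos[fam_row],
    ref = ref[fam_row],
    alt = alt[fam_row],
    variant_type = types[fam_row],
    pool_id = pool[fam_row],
    ref_count = ref_count,
    alt_count = alt_count,
    depth = depth,
    af = alt_count / depth,
    missing = FALSE,
    parent_missing = FALSE,
    stringsAsFactors = FALSE
  )

  # annotations: clinical subgroup, variant class, paternal age
  n_coh <- round(nf * config$subgroup_mix[["cohesinopathy"]] /
                   sum(config$subgroup_mix))
  subgroup <- rep("DD_ID_autism", nf)
  subgroup[sample(nf, n_coh)] <- "cohesinopathy"
  age <- stats::rlnorm(nf, config$age_meanlog, config$age_sdlog)
  age[mosaic] <- pmax(18, age[mosaic] - config$age_shift)
  n_miss <- round(nf * config$age_missing_frac)
  miss_pool <- which(!mosaic)
  if (n_miss > 0 && length(miss_pool) > 0) {
    age[sample(miss_pool, min(n_miss, length(miss_pool)))] <- NA_real_
  }
  annotations <- data.frame(
    family_id = fam,
    subgroup = subgroup,
    variant_type_class = ifelse(types == "SNV", "SNV", "indel"),
    paternal_age = age,
    stringsAsFactors = FALSE
  )

  truth <- data.frame(
    family_id = fam, chrom = chrom, pos = pos, ref = ref, alt = alt,
    variant_type = types, pool_id = pool, error_rate = err,
    mosaic = mosaic, mosaic_parent = mosaic_parent, true_af = true_af,
    stringsAsFactors = FALSE
  )

  structure(list(config = config, targets = targets, manifest = manifest,
                 table = table, annotations = annotations, truth = truth),
            class = "mosaic_cohort")
}

render_bases <- function(depth, alt_count, variant_type, alt_base, motif,
                         marker_prob) {
  fwd <- stats::runif(depth) < 0.5
  tok <- ifelse(fwd, ".", ",")
  if (alt_count > 0) {
    ai <- sample.int(depth, alt_count)
    if (variant_type == "SNV") {
      tok[ai] <- ifelse(fwd[ai], toupper(alt_base), tolower(alt_base))
    } else {
      sign <- if (variant_type == "INS") "+" else "-"
      m <- ifelse(fwd[ai], toupper(motif), tolower(motif))
      tok[ai] <- paste0(tok[ai], sign, nchar(motif), m)
    }
  }
  starts <- stats::runif(depth) < marker_prob
  ends <- stats::runif(depth) < marker_prob
  tok[starts] <- paste0("^I", tok[starts])
  tok[ends] <- paste0(tok[ends], "$")
  paste(tok, collapse = "")
}

#' Emit per-sample mpileup files for a simulated cohort
#'
#' Renders every (sample, position) row of the simulated genotyping table
#' as a valid samtools-mpileup line: reference matches as `.`/`,`,
#' alternative reads as the target's substitution character or
#' `+nSEQ`/`-nSEQ` motif with randomized strand case, and occasional
#' read-start (`^I`) / read-end (`$`) markers. Parsing the emitted files
#' with the pileup counter recovers the simulated counts exactly.
#'
#' @param sim [simulate_cohort()] result.
#' @param out_dir Output directory (created if needed); one
#'   `<sample_id>.pileup` file per sample.
#' @param marker_prob Per-read probability of a start/end marker.
#' @return Invisibly, the named vector of file paths.
#' @export
emit_mpileup <- function(sim, out_dir, marker_prob = 0.02) {
  stopifnot(inherits(sim, "mosaic_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- sim$table
  motifs <- vapply(seq_len(nrow(tab)), function(i) {
    if (tab$variant_type[i] == "SNV") "" else indel_motif(tab[i, ])
  }, character(1))
  paths <- character(0)
  for (s in unique(tab$sample_id)) {
    idx <- which(tab$sample_id == s)
    idx <- idx[order(tab$chrom[idx], tab$pos[idx])]
    lines <- vapply(idx, function(i) {
      b <- render_bases(tab$depth[i], tab$alt_count[i], tab$variant_type[i],
                        tab$alt[i], motifs[i], marker_prob)
      paste(tab$chrom[i], tab$pos[i], substr(tab$ref[i], 1, 1),
            tab$depth[i], b, strrep("I", tab$depth[i]), sep = "\t")
    }, character(1))
    path <- file.path(out_dir, paste0(s, ".pileup"))
    writeLines(lines, path)
    paths[s] <- path
  }
  invisible(paths)
}

#' Score detection calls against the simulated truth
#'
#' @param sim [simulate_cohort()] result (the ground truth).
#' @param detection [call_candidates()] result on the same cohort.
#' @param limits Optional [power_table()] output; when supplied,
#'   sensitivity is additionally stratified by the ratio of true AF to the
#'   position's 90%-power detection limit.
#' @return List with `n_true_mosaic`, `n_calls`, `tp` (calls matching the
#'   planted family and parent), `fp`, `sensitivity`, `fpr` (significant
#'   fraction among testable non-mosaic parent tests), `ppv` (NA when
#'   there are no calls), and optionally `sensitivity_by_ratio`.
#' @export
evaluate_detection <- function(sim, detection, limits = NULL) {
  stopifnot(inherits(sim, "mosaic_cohort"))
  truth <- sim$truth
  if (!setequal(truth$family_id, unique(detection$results$family_id))) {
    stop("detection report and truth cover different family sets")
  }
  cand <- detection$candidates
  key_truth <- paste(truth$family_id[truth$mosaic],
                     truth$mosaic_parent[truth$mosaic])
  key_call <- paste(cand$family_id, cand$parent_role)
  tp <- sum(key_call %in% key_truth)
  fp <- nrow(cand) - tp

  res <- detection$results
  res$is_mosaic_test <- paste(res$family_id, res$parent_role) %in% key_truth
  null_tests <- res[!res$is_mosaic_test & res$testable, , drop = FALSE]

  out <- list(
    n_true_mosaic = sum(truth$mosaic),
    n_calls = nrow(cand),
    tp = tp,
    fp = fp,
    sensitivity = if (sum(truth$mosaic) > 0) tp / sum(truth$mosaic)
                  else NA_real_,
    fpr = if (nrow(null_tests) > 0) mean(null_tests$significant)
          else NA_real_,
    n_null_tests = nrow(null_tests),
    ppv = if (nrow(cand) > 0) tp / nrow(cand) else NA_real_
  )

  if (!is.null(limits) && sum(truth$mosaic) > 0) {
    lim <- limits$min_af_90[match(truth$family_id, limits$family_id)]
    ratio <- truth$true_af / lim
    bins <- cut(ratio, c(0, 1, 2, 10, Inf),
                labels = c("<1x", "1-2x", "2-10x", ">10x"))
    detected <- paste(truth$family_id, truth$mosaic_parent) %in% key_call
    sel <- truth$mosaic & !is.na(ratio)
    out$sensitivity_by_ratio <- tapply(detected[sel], bins[sel], mean)
  }
  out
}
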