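#' Log-spaced allele-fraction grid
#'
#' @param af_min,af_max Grid range (defaults 1e-4 to 0.4, i.e. 0.01% to
#'   40%).
#' @param n Number of grid points (default 400).
#' @return Strictly increasing numeric vector.
#' @export
af_grid <- function(af_min = 1e-4, af_max = 0.4, n = 400L) {
  stopifnot(af_min > 0, af_max > af_min, n >= 2L)
  exp(seq(log(af_min), log(af_max), length.out = n))
}

#' Power-analysis settings
#'
#' Bundles the per-test significance level, the allele-fraction grid and
#' the target power levels used for every position's power curve.
#'
#' @param alpha Per-test significance level; default is the experiment-wide
#'   Bonferroni level for 189 families, 0.05/378.
#' @param grid Allele-fraction grid, see [af_grid()].
#' @param target_powers Power levels at which detection limits are
#'   reported.
#' @return List of class `power_spec`.
#' @export
power_spec <- function(alpha = bonferroni_alpha(189), grid = af_grid(),
                       target_powers = c(0.8, 0.9)) {
  stopifnot(alpha > 0, alpha < 1, all(diff(grid) > 0),
            all(target_powers > 0 & target_powers < 1))
  structure(list(alpha = alpha, grid = grid, target_powers = target_powers),
            class = "power_spec")
}

#' Critical value of the one-sided exact Poisson test
#'
#' The smallest integer `k` whose upper tail probability under the null
#' does not exceed alpha: `P(X >= k | lambda0) <= alpha` and
#' `P(X >= k - 1 | lambda0) > alpha`. Observing `k_star` or more reads
#' rejects the null. For a zero background (`lambda0 == 0`) a single read
#' rejects, so `k_star = 1`.
#'
#' @param lambda0 Expected null count(s) (>= 0).
#' @param alpha Significance level in (0, 1).
#' @return Integer critical value(s), vectorized over `lambda0`.
#' @export
critical_value <- function(lambda0, alpha) {
  if (any(lambda0 < 0)) stop("lambda0 must be non-negative")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  k <- as.integer(stats::qpois(1 - alpha, lambda0) + 1)
  k[lambda0 == 0] <- 1L
  k
}

#' Power of the exact Poisson test at an alternative allele fraction
#'
#' The test statistic is the parent's alternative count, with sample size
#' taken as the average control depth `n_bar` at the position. Under the
#' null the count is Poisson with rate `n_bar * p0` (control allele
#' fraction); under the alternative, Poisson with rate `n_bar * p1`
#' (targeted allele fraction; set `add_background = TRUE` to use
#' `n_bar * (p0 + p1)` instead). Power is the alternative's mass at or
#' above the critical value.
#'
#' @param n_bar Average control sequencing depth (> 0, real-valued).
#' @param p0 Background allele fraction under the null, in \[0, 1\].
#' @param p1 Targeted allele fraction(s) under the alternative, in
#'   (0, 1\].
#' @param alpha Significance level.
#' @param add_background If TRUE the alternative rate includes the
#'   background (sensitivity-analysis variant); default FALSE.
#' @return Power value(s) in \[0, 1\], vectorized over `p1`.
#' @export
power_at_af <- function(n_bar, p0, p1, alpha, add_background = FALSE) {
  stopifnot(n_bar > 0, p0 >= 0, p0 <= 1, all(p1 > 0), all(p1 <= 1))
  if (any(p1 <= p0)) {
    warning("alternative allele fraction(s) at or below the background p0; ",
            "power may fall below the nominal level")
  }
  k_star <- critical_value(n_bar * p0, alpha)
  lambda1 <- n_bar * (if (add_background) p0 + p1 else p1)
  stats::ppois(k_star - 1, lambda1, lower.tail = FALSE)
}

#' Power curve of one targeted position
#'
#' @param n_bar Average control depth at the position.
#' @param p0 Control (background) allele fraction at the position.
#' @param spec [power_spec()] settings.
#' @param add_background Passed to [power_at_af()].
#' @return List of class `power_curve` with `n_bar`, `p0`, `grid`,
#'   `power` (aligned with `grid`), `alpha`.
#' @export
power_curve <- function(n_bar, p0, spec = power_spec(),
                        add_background = FALSE) {
  pw <- suppressWarnings(
    power_at_af(n_bar, p0, spec$grid, spec$alpha, add_background)
  )
  structure(list(n_bar = n_bar, p0 = p0, grid = spec$grid, power = pw,
                 alpha = spec$alpha),
            class = "power_curve")
}

#' Detection limit: minimum allele fraction at a target power
#'
#' Scans the power curve for the first grid point whose power reaches the
#' target level. Because the critical value is fixed by (`n_bar`, `p0`,
#' alpha), power is non-decreasing along the grid and the first crossing
#' is the minimum. A curve that never reaches the level yields an
#' undefined limit (`min_af = NA`, `censored = TRUE`), interpreted
#' downstream as censored at the grid's upper bound.
#'
#' @param curve [power_curve()] result.
#' @param power_level Target power in (0, 1), e.g. 0.9.
#' @return One-row data frame with `power_level`, `min_af`, `censored`.
#' @export
detection_limit <- function(curve, power_level) {
  stopifnot(inherits(curve, "power_curve"),
            power_level > 0, power_level < 1)
  i <- which(curve$power >= power_level)[1]
  data.frame(
    power_level = power_level,
    min_af = if (is.na(i)) NA_real_ else curve$grid[i],
    censored = is.na(i),
    stringsAsFactors = FALSE
  )
}

#' Per-position power table for a cohort
#'
#' For each targeted position: the average control depth, the pooled
#' control allele fraction, and the minimum detectable allele fraction at
#' each target power level.
#'
#' @param table Genotyping table.
#' @param spec [power_spec()] settings.
#' @return Data frame with one row per family/position: `family_id`,
#'   `chrom`, `pos`, `n_bar`, `p0`, then `min_af_<level>` and
#'   `censored_<level>` per target power (levels printed as percent, e.g.
#'   `min_af_90`).
#' @export
power_table <- function(table, spec = power_spec()) {
  fams <- unique(table$family_id)
  rows <- vector("list", length(fams))
  for (i in seq_along(fams)) {
    f <- fams[i]
    ctl <- table[table$family_id == f & table$role == "control" &
                   table$depth > 0, , drop = FALSE]
    first <- table[table$family_id == f, , drop = FALSE][1, ]
    if (nrow(ctl) == 0L) {
      row <- data.frame(family_id = f, chrom = first$chrom, pos = first$pos,
                        n_bar = NA_real_, p0 = NA_real_,
                        stringsAsFactors = FALSE)
      for (lv in spec$target_powers) {
        row[[sprintf("min_af_%.0f", 100 * lv)]] <- NA_real_
        row[[sprintf("censored_%.0f", 100 * lv)]] <- TRUE
      }
      rows[[i]] <- row
      next
    }
    n_bar <- mean(ctl$depth)
    p0 <- sum(ctl$alt_count) / sum(ctl$depth)
    curve <- power_curve(n_bar, p0, spec)
    row <- data.frame(family_id = f, chrom = first$chrom, pos = first$pos,
                      n_bar = n_bar, p0 = p0, stringsAsFactors = FALSE)
    for (lv in spec$target_powers) {
      dl <- detection_limit(curve, lv)
      row[[sprintf("min_af_%.0f", 100 * lv)]] <- dl$min_af
      row[[sprintf("censored_%.0f", 100 * lv)]] <- dl$censored
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort-level detectability summary
#'
#' Summarizes the per-position detection limits at one power level:
#' median and quartiles of the minimum detectable allele fraction (over
#' positions with a defined limit), and the fraction of *all* positions
#' whose limit is at or below each allele fraction of interest (undefined
#' limits count as not reaching any threshold).
#'
#' @param limits [power_table()] output.
#' @param power_level Power level to summarize (must match a
#'   `min_af_<level>` column), default 0.9.
#' @param thresholds Allele fractions of interest (default 1% and 0.5%).
#' @return List with `power_level`, `n_positions`, `n_defined`,
#'   `median_min_af`, `q1_min_af`, `q3_min_af`, and `frac_detectable` (a
#'   named vector, one entry per threshold).
#' @export
detectability_summary <- function(limits, power_level = 0.9,
                                  thresholds = c(0.01, 0.005)) {
  col <- sprintf("min_af_%.0f", 100 * power_level)
  if (!col %in% names(limits)) {
    stop("limits table has no column '", col, "' for power level ",
         power_level)
  }
  mins <- limits[[col]]
  if (nrow(limits) == 0L) stop("empty detection-limit table")
  defined <- mins[!is.na(mins)]
  if (length(defined) == 0L) stop("no position has a defined detection limit")
  q <- stats::quantile(defined, c(0.25, 0.5, 0.75), names = FALSE)
  frac <- vapply(thresholds, function(t) mean(!is.na(mins) & mins <= t),
                 numeric(1))
  names(frac) <- paste0("af_le_", format(thresholds))
  list(
    power_level = power_level,
    n_positions = nrow(limits),
    n_defined = length(defined),
    median_min_af = q[2],
    q1_min_af = q[1],
    q3_min_af = q[3],
    frac_detectable = frac
  )
}
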