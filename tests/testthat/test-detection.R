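test_that("Poisson upper tail follows the boundary conventions", {
  expect_identical(poisson_sf(0, 5), 1)
  expect_identical(poisson_sf(0, 0), 1)
  expect_identical(poisson_sf(1, 0), 0)
  expect_identical(poisson_sf(3, 0), 0)
  # frozen from the pmf-summation oracle: 1 - e^-1 (1 + 1 + 1/2)
  expect_equal(poisson_sf(3, 1), 0.0803014, tolerance = 1e-6)
  expect_equal(poisson_sf(3, 1), oracle_poisson_sf(3, 1), tolerance = 1e-14)
  expect_error(poisson_sf(-1, 1), "non-negative")
  expect_error(poisson_sf(1, -1), "non-negative")
  expect_error(poisson_sf(1.5, 1), "integer")
})

test_that("p-values are monotone in the observed count and in the rate", {
  lambdas <- c(0.01, 0.5, 1, 2.1, 10, 40)
  for (l in lambdas) {
    p <- poisson_sf(0:50, l)
    expect_true(all(diff(p) <= 0))
  }
  for (k in c(1L, 3L, 10L, 30L)) {
    p <- poisson_sf(rep(k, 6), lambdas)
    expect_true(all(diff(p) >= 0))
  }
})

test_that("the Bonferroni level divides the budget over two tests per family", {
  expect_identical(bonferroni_alpha(1), 0.025)
  expect_identical(bonferroni_alpha(5, base_alpha = 0.10), 0.01)
  expect_error(bonferroni_alpha(0), "integer")
  expect_error(bonferroni_alpha(10, base_alpha = 1.5), "in \\(0, 1\\)")
})

test_that("control pooling sums alt and depth over controls only", {
  tab <- data.frame(
    sample_id = c("P1", "P2", paste0("C", 1:3)),
    family_id = "F1",
    role = c("father", "mother", "control", "control", "control"),
    alt_count = c(50L, 0L, 1L, 1L, 0L),
    depth = c(1000L, 1000L, 2L, 998L, 0L),
    stringsAsFactors = FALSE)
  cs <- pool_controls(tab, "F1")
  expect_equal(cs$n_controls, 2L)  # zero-depth control excluded
  expect_equal(cs$pooled_alt, 2L)
  expect_equal(cs$pooled_depth, 1000L)
  expect_equal(cs$p0, 0.002)
  expect_true(cs$testable)

  # single minimal control
  tab1 <- tab[c(1, 3), ]
  tab1$alt_count[2] <- 1L; tab1$depth[2] <- 2L
  expect_equal(pool_controls(tab1, "F1")$p0, 0.5)

  # no usable control: untestable
  tab0 <- tab
  tab0$depth[tab0$role == "control"] <- 0L
  expect_false(pool_controls(tab0, "F1")$testable)
})

test_that("a parent is tested against depth times the control background", {
  ctl <- data.frame(family_id = "F1", n_controls = 46L, pooled_alt = 0L,
                    pooled_depth = 320000L, p0 = 0, testable = TRUE)
  parent <- data.frame(sample_id = "P", family_id = "F1", role = "father",
                       alt_count = 1L, depth = 5000L, af = 1 / 5000)
  alpha <- bonferroni_alpha(189)

  # single read over a zero background is significant at any alpha
  r <- test_parent(parent, ctl, alpha)
  expect_identical(r$p_value, 0)
  expect_true(r$significant)
  expect_true(r$zero_background)
  expect_equal(r$af, 2e-4)

  # zero observed reads can never be significant
  parent0 <- parent; parent0$alt_count <- 0L; parent0$af <- 0
  r <- test_parent(parent0, ctl, alpha)
  expect_identical(r$p_value, 1)
  expect_false(r$significant)

  # noisy background: frozen from the pmf-summation oracle
  ctl2 <- ctl; ctl2$pooled_alt <- 96L; ctl2$p0 <- 3e-4
  parent2 <- parent; parent2$alt_count <- 10L; parent2$depth <- 7000L
  r <- test_parent(parent2, ctl2, alpha)
  expect_equal(r$expected_lambda0, 2.1)
  expect_equal(r$p_value, oracle_poisson_sf(10, 2.1), tolerance = 1e-12)
  expect_lt(r$p_value, alpha)
  expect_true(r$significant)

  # pseudocount option softens the zero-background rule
  r <- test_parent(parent, ctl, alpha, pseudocount = 1)
  expect_gt(r$p_value, 0)

  # zero-depth parent is untestable, not negative
  parentz <- parent; parentz$depth <- 0L
  r <- test_parent(parentz, ctl, alpha)
  expect_false(r$testable)
  expect_true(is.na(r$significant))
})

test_that("cohort calling runs two tests per family and flags artifacts", {
  sim <- simulate_cohort(small_config(seed = 5))
  det <- call_candidates(sim$table)
  expect_equal(nrow(det$results), 40L)  # 2 per family
  expect_equal(det$alpha, bonferroni_alpha(20))
  expect_equal(sort(table(det$results$family_id)), sort(rep(2L, 20)),
               ignore_attr = TRUE)
  expect_equal(nrow(det$candidates), 0L)  # null cohort, conservative test

  # planted mosaics well above the detection limit are all called
  plan <- data.frame(family_id = c("FAM0003", "FAM0011"),
                     parent = c("father", "mother"),
                     true_af = c(0.05, 0.10), stringsAsFactors = FALSE)
  set.seed(99)
  sim2 <- plant_mosaics(sim, plan)
  det2 <- call_candidates(sim2$table)
  expect_equal(sort(unique(det2$candidates$family_id)), sort(plan$family_id))
  expect_false(any(det2$candidates$both_parents_flag))
  expect_true(all(diff(det2$candidates$p_value) >= 0))  # sorted by p

  # both parents significant in one family -> flagged, not suppressed
  plan3 <- data.frame(family_id = "FAM0007",
                      parent = c("father", "mother"),
                      true_af = c(0.2, 0.2), stringsAsFactors = FALSE)
  sim3 <- plant_mosaics(sim, plan3)
  det3 <- call_candidates(sim3$table)
  fam7 <- det3$candidates[det3$candidates$family_id == "FAM0007", ]
  expect_equal(nrow(fam7), 2L)
  expect_true(all(fam7$both_parents_flag))
})

test_that("calls depend on the background fraction, not control scale", {
  sim <- simulate_cohort(small_config(seed = 8))
  plan <- data.frame(family_id = "FAM0002", parent = "father",
                     true_af = 0.03, stringsAsFactors = FALSE)
  set.seed(1)
  sim <- plant_mosaics(sim, plan)
  det1 <- call_candidates(sim$table, alpha = bonferroni_alpha(20))
  # scale every control's counts by an integer factor: p0 unchanged
  tab <- sim$table
  ctl <- tab$role == "control"
  tab$alt_count[ctl] <- tab$alt_count[ctl] * 5L
  tab$depth[ctl] <- tab$depth[ctl] * 5L
  det5 <- call_candidates(tab, alpha = bonferroni_alpha(20))
  expect_equal(det1$results$p_value, det5$results$p_value, tolerance = 1e-12)
  expect_identical(det1$candidates$family_id, det5$candidates$family_id)
})
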