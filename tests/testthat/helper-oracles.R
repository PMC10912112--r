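# Independent oracles used to check the implementation by a different route.

# Poisson upper tail by direct pmf summation (recurrence on the pmf terms,
# no distribution functions involved).
oracle_poisson_sf <- function(k, lambda) {
  if (k == 0) return(1)
  if (lambda == 0) return(0)
  terms <- numeric(k)
  terms[1] <- exp(-lambda)
  if (k > 1) {
    for (i in 2:k) terms[i] <- terms[i - 1] * lambda / (i - 1)
  }
  max(0, 1 - sum(terms))
}

# Two-sided Fisher exact p by full enumeration of the hypergeometric
# support with the probability-mass rule (tables no more extreme than the
# observed one, i.e. probability <= observed, summed). Probabilities from
# log-binomial coefficients; relative tolerance guards float ties.
oracle_fisher_2x2 <- function(a, b, c, d, rel_tol = 1e-7) {
  m <- a + b
  n <- c + d
  k <- a + c
  support <- max(0, k - n):min(m, k)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  p <- exp(logp)
  p_obs <- p[support == a]
  sum(p[p <= p_obs * (1 + rel_tol)])
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of group
# assignments (doubling rule, as in R's exact branch). No ties assumed.
oracle_wilcoxon <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  w_all <- apply(combos, 2, function(idx) sum(r[idx])) - nx * (nx + 1) / 2
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Small synthetic cohort used across tests (fast; deterministic).
small_config <- function(seed = 42, prevalence = 0, ...) {
  cohort_config(n_families = 20L, n_pools = 2L, n_controls = 18L,
                prevalence = prevalence, seed = seed, ...)
}

# Plant mosaics into a simulated null cohort by redrawing the chosen
# parent's alt count at the target allele fraction (composed with the
# position's error rate). Returns the modified cohort.
plant_mosaics <- function(sim, plan) {
  tab <- sim$table
  for (j in seq_len(nrow(plan))) {
    f <- plan$family_id[j]
    i <- which(tab$family_id == f & tab$role == plan$parent[j])
    stopifnot(length(i) == 1L)
    e <- sim$truth$error_rate[sim$truth$family_id == f]
    p <- e + plan$true_af[j] * (1 - e)
    tab$alt_count[i] <- stats::rbinom(1, tab$depth[i], p)
    tab$af[i] <- tab$alt_count[i] / tab$depth[i]
  }
  sim$table <- tab
  sim$truth$mosaic[sim$truth$family_id %in% plan$family_id] <- TRUE
  idx <- match(plan$family_id, sim$truth$family_id)
  sim$truth$mosaic_parent[idx] <- plan$parent
  sim$truth$true_af[idx] <- plan$true_af
  sim
}
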