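# Independent brute-force oracles used to check the package's statistics.
# Everything here is computed from first principles (choose(), explicit
# enumeration), deliberately not through the code paths under test.

# Hypergeometric probability of table [[a, b], [c, d]] with fixed margins.
table_prob <- function(a, b, c, d) {
  choose(a + b, a) * choose(c + d, c) / choose(a + b + c + d, a + c)
}

# Two-sided Fisher exact p: sum of probabilities of all tables with the
# same margins that are no more probable than the observed table.
oracle_fisher_two_sided <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) {
    table_prob(x, r1 - x, c1 - x, r2 - c1 + x)
  }, numeric(1))
  p_obs <- table_prob(a, b, c, d)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# One-sided (greater in cell [1,1]) Fisher exact p.
oracle_fisher_greater <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  hi <- min(r1, c1)
  sum(vapply(a:hi, function(x) {
    table_prob(x, r1 - x, c1 - x, r2 - c1 + x)
  }, numeric(1)))
}

# Upper tail P(X >= k) for k significant of n draws from N with K marked.
oracle_hyper_tail <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Benjamini-Hochberg step-up from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (tie-free data): doubles the smaller tail of the exact U distribution.
oracle_mwu_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!any(duplicated(pooled)))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(nx + ny, nx)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - nx * (nx + 1) / 2)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Spearman rho as Pearson correlation of average ranks.
oracle_spearman_rho <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# Grid search over (pi, lambda) for the best ZIP log-likelihood,
# independent of zip_fit's closed-form solution.
oracle_zip_grid_best <- function(counts, n_grid = 50) {
  pis <- seq(0, 0.98, length.out = n_grid)
  lams <- seq(max(mean(counts), 0.05) * 0.2,
              max(counts) + 1, length.out = n_grid)
  best <- -Inf
  for (p in pis) for (l in lams) {
    n0 <- sum(counts == 0)
    pos <- counts[counts > 0]
    ll <- n0 * log(p + (1 - p) * exp(-l)) +
      sum(log(1 - p) + pos * log(l) - l - lgamma(pos + 1))
    if (ll > best) best <- ll
  }
  best
}

# Small default cohort config used across tests: few visits, small
# feature spaces and shallow depths so generation stays fast.
small_cohort_config <- function(seed = 1, ...) {
  args <- list(n_subjects = 40, visit_ages = c(61, 365),
               n_kos = 30, n_genera = 10, n_otus = 10,
               n_metabolites = 10, n_modules = 3,
               stool_depth = 2000, nasal_depth = 1000, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(cohort_config, args)
}
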