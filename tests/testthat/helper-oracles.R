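# Independent brute-force oracles used to cross-check the implementation.

# Expansion Index by explicit enumerate-filter-normalize-dot-product, written
# against plain vectors with no shared code with compute_expansion_index().
oracle_ei <- function(repeats, heights, reference, threshold = 0.10,
                      window = "modal_and_above") {
  h_max <- -Inf
  modal <- NA_integer_
  for (i in seq_along(repeats)) {
    if (heights[i] > h_max || (heights[i] == h_max && repeats[i] < modal)) {
      h_max <- heights[i]
      modal <- repeats[i]
    }
  }
  num <- 0
  den <- 0
  for (i in seq_along(repeats)) {
    if (heights[i] < threshold * h_max) next
    if (window == "modal_and_above" && repeats[i] < modal) next
    num <- num + heights[i] * (repeats[i] - reference)
    den <- den + heights[i]
  }
  num / den
}

# Mann-Whitney U by direct pair counting (ties count half): no ranks involved.
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) u <- u + sum(xi > y) + 0.5 * sum(xi == y)
  u
}

# Exact p-value by complete enumeration of all group labelings, with U
# recomputed by pair counting for every labeling.
oracle_ranksum_p <- function(x, y, alternative = "two_sided") {
  pool <- c(x, y)
  n1 <- length(x)
  n <- length(pool)
  u_obs <- oracle_u(x, y)
  mu <- n1 * (n - n1) / 2
  labelings <- utils::combn(n, n1, simplify = FALSE)
  u_all <- vapply(labelings, function(idx) oracle_u(pool[idx], pool[-idx]),
                  numeric(1))
  eps <- 1e-9
  switch(alternative,
         greater = mean(u_all >= u_obs - eps),
         less = mean(u_all <= u_obs + eps),
         two_sided = mean(abs(u_all - mu) >= abs(u_obs - mu) - eps))
}

# Random repeat profile with occasional ties and a controlled bin count.
random_profile <- function(n_bins = sample(1:12, 1), base = sample(250:300, 1)) {
  reps <- sort(sample(base + 0:25, n_bins))
  h <- round(stats::runif(n_bins, 1, 1000), 2)
  repeat_profile(reps, h)
}

# Population modal allele straight from the allele multiset (smallest tie).
pop_mode <- function(alleles) {
  tab <- table(alleles)
  as.integer(names(tab)[which.max(tab)])
}

# Exact pmf of the per-cell repeat gain under a two-point {+1,+2} step
# distribution: gain = N1 + 2*N2 with independent Poisson thinned counts.
gain_pmf_mode <- function(rate, p1, p2, t, kmax = 200) {
  l1 <- rate * p1 * t
  l2 <- rate * p2 * t
  pmf <- numeric(kmax + 1)
  for (j in 0:floor(kmax / 2)) {
    w <- stats::dpois(j, l2)
    k <- 0:(kmax - 2 * j)
    pmf[k + 2 * j + 1] <- pmf[k + 2 * j + 1] + stats::dpois(k, l1) * w
  }
  which.max(pmf) - 1L
}
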