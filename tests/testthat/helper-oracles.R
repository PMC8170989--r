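# Independent brute-force oracles used by the unit and acceptance suites.
# These deliberately avoid the code paths they check.

# Exact rank-sum tail probabilities by full enumeration of all
# choose(n, n1) group assignments (midranks handled implicitly).
oracle_rank_sum_p <- function(x, y, alternative = "two.sided") {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  W_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  W_all <- apply(combos, 2, function(idx) sum(r[idx]))
  p_less <- mean(W_all <= W_obs)
  p_greater <- mean(W_all >= W_obs)
  switch(alternative,
         two.sided = min(1, 2 * min(p_less, p_greater)),
         greater = p_greater,
         less = p_less)
}

# BH as "smallest alpha at which the step-up procedure rejects feature i".
# Rejection status can only change at alphas of the form p_(j)*m/j; sweep
# them in increasing order and run the step-up rule directly at each.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  qs <- ps * m / seq_len(m)  # p_(j) <= a*j/m  <=>  p_(j)*m/j <= a
  alphas <- sort(unique(qs))
  q <- rep(Inf, m)
  for (a in alphas) {
    ok <- qs <= a
    if (!any(ok)) next
    cut <- max(which(ok))
    rejected <- ord[seq_len(cut)]
    q[rejected] <- pmin(q[rejected], a)
  }
  pmin(q, 1)
}

# Two-sided Fisher p by direct hypergeometric enumeration over all
# tables with the observed margins.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (n == 0) return(1)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(support, function(x) {
    exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1))
  }, numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# One-sided binomial tail P(X >= k) by direct summation.
oracle_binom_greater <- function(k, n, p0) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(x) choose(n, x) * p0^x * (1 - p0)^(n - x),
             numeric(1)))
}

# P(overlap >= k) for drawing size_a from universe U against a set of
# size m, by hypergeometric summation.
oracle_hyper_greater <- function(k, U, m, size_a) {
  support <- max(0, size_a + m - U):min(size_a, m)
  probs <- vapply(support, function(x) {
    exp(lchoose(m, x) + lchoose(U - m, size_a - x) - lchoose(U, size_a))
  }, numeric(1))
  sum(probs[support >= k])
}

# Adjusted Rand index between two label vectors (mclust is the
# cross-check where available; this keeps the suite self-contained).
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  n <- sum(tab)
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}
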