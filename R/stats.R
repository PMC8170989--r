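#' Mann-Whitney / Wilcoxon rank-sum test
#'
#' Exact permutation p-values (including under midrank ties, via a
#' subset-sum dynamic program over the pooled rank multiset) whenever
#' \code{n_A * n_B <= 400}; otherwise the tie-corrected normal
#' approximation with continuity correction. Two-sided p is twice the
#' smaller tail, capped at 1.
#'
#' @param x,y numeric samples for the two groups (NAs dropped).
#' @param alternative \code{"two.sided"}, \code{"greater"} (x tends
#'   larger) or \code{"less"}.
#' @return list with \code{statistic} (the Mann-Whitney U of x),
#'   \code{p.value}, \code{exact}.
#' @export
rank_sum_test <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) {
    stop_typed("epimutr_validation_error", "both groups must be non-empty")
  }
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- n1 * n2 <= 400
  if (exact) {
    if (!ties) {
      p_less <- stats::pwilcox(U, n1, n2)
      p_greater <- if (U >= 1) stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE) else 1
    } else {
      tails <- rank_sum_tails_dp(r, n1, W)
      p_less <- tails[["less"]]
      p_greater <- tails[["greater"]]
    }
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    tie_tab <- table(r)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p_less <- p_greater <- 1
    } else {
      sd0 <- sqrt(sigma2)
      p_greater <- stats::pnorm((U - 0.5 - mu) / sd0, lower.tail = FALSE)
      p_less <- stats::pnorm((U + 0.5 - mu) / sd0)
    }
  }
  p <- switch(alternative,
              two.sided = min(1, 2 * min(p_less, p_greater)),
              greater = p_greater,
              less = p_less)
  list(statistic = c(U = U), p.value = p, exact = exact,
       alternative = alternative)
}

# Exact null tail probabilities of the rank-sum W under random n1-subsets
# of the pooled (midrank) multiset. Ranks are doubled to integers; the DP
# counts subsets of each size by sum.
rank_sum_tails_dp <- function(r, n1, W) {
  ri <- as.integer(round(2 * r))
  n <- length(ri)
  maxS <- sum(sort(ri, decreasing = TRUE)[seq_len(n1)])
  # counts[[k]][s+1] = number of k-subsets with doubled-sum s
  counts <- vector("list", n1 + 1)
  counts[[1]] <- c(1, numeric(maxS))
  for (k in seq_len(n1)) counts[[k + 1]] <- numeric(maxS + 1)
  for (item in ri) {
    for (k in rev(seq_len(n1))) {
      prev <- counts[[k]]
      shifted <- c(numeric(item), prev[seq_len(maxS + 1 - item)])
      counts[[k + 1]] <- counts[[k + 1]] + shifted
    }
  }
  dist <- counts[[n1 + 1]]
  total <- sum(dist)
  w2 <- as.integer(round(2 * W))
  c(less = sum(dist[seq_len(min(w2, maxS) + 1)]) / total,
    greater = sum(dist[(w2 + 1):(maxS + 1)]) / total)
}

# Vectorized rank-sum p-values over matrix rows for two column index sets.
# Rows containing NA or ties fall back to the scalar test. Returns a list
# with U, p, and the group means/sizes actually used.
row_rank_sum <- function(mat, idx_a, idx_b, alternative = "two.sided") {
  sub <- mat[, c(idx_a, idx_b), drop = FALSE]
  n1 <- length(idx_a); n2 <- length(idx_b)
  has_na <- rowSums(is.na(sub)) > 0
  p <- rep(NA_real_, nrow(sub))
  U <- rep(NA_real_, nrow(sub))
  ok <- !has_na
  if (any(ok)) {
    stat <- apply(sub[ok, , drop = FALSE], 1, function(v) {
      c(sum(rank(v)[seq_len(n1)]), anyDuplicated(v) > 0)
    })
    Wv <- stat[1, ]
    tied <- stat[2, ] > 0
    Uv <- Wv - n1 * (n1 + 1) / 2
    U[ok] <- Uv
    clean <- ok
    clean[ok] <- !tied
    if (n1 * n2 <= 400) {
      Uc <- Uv[!tied]
      pl <- stats::pwilcox(Uc, n1, n2)
      pg <- ifelse(Uc >= 1, stats::pwilcox(Uc - 1, n1, n2, lower.tail = FALSE), 1)
      p[clean] <- two_sided_or_tail(pl, pg, alternative)
    } else {
      mu <- n1 * n2 / 2
      n <- n1 + n2
      sd0 <- sqrt(n1 * n2 * (n + 1) / 12)
      Uc <- Uv[!tied]
      pg <- stats::pnorm((Uc - 0.5 - mu) / sd0, lower.tail = FALSE)
      pl <- stats::pnorm((Uc + 0.5 - mu) / sd0)
      p[clean] <- two_sided_or_tail(pl, pg, alternative)
    }
    slow <- which(ok & is.na(p))
  } else {
    slow <- integer()
  }
  slow <- union(slow, which(has_na))
  for (i in slow) {
    a <- mat[i, idx_a]; b <- mat[i, idx_b]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) >= 1 && length(b) >= 1) {
      res <- rank_sum_test(a, b, alternative)
      p[i] <- res$p.value
      U[i] <- unname(res$statistic)
    }
  }
  list(U = U, p = p)
}

two_sided_or_tail <- function(pl, pg, alternative) {
  switch(alternative,
         two.sided = pmin(1, 2 * pmin(pl, pg)),
         greater = pg,
         less = pl)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up q-values: \code{q_(i) = min_(j >= i) p_(j) * m / j}, capped at
#' 1, returned in the original order.
#'
#' @param p numeric vector of p-values in \code{[0, 1]}.
#' @return q-values of the same length.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop_typed("epimutr_validation_error", "p-values outside [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by summing hypergeometric probabilities no larger than the
#' observed table's; the odds ratio is the conditional MLE. The all-zero
#' table returns p = 1 with an undefined (NA) odds ratio.
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise
#'   (\code{matrix(c(a, b, c, d), 2, byrow = TRUE)}).
#' @return list with \code{odds_ratio} and \code{p_value}.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop_typed("epimutr_validation_error",
               "cells must be non-negative integers")
  }
  if (sum(cells) == 0) {
    return(list(odds_ratio = NA_real_, p_value = 1))
  }
  ft <- stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

# Spearman correlation with midrank ties and the t approximation for the
# p-value (two-sided). cor.test switches methods under ties; this is the
# single documented convention used throughout.
spearman_rho_p <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) return(c(rho = NA_real_, p = NA_real_))
  rho <- stats::cor(rank(x), rank(y))
  if (is.na(rho)) return(c(rho = NA_real_, p = NA_real_))
  if (abs(rho) >= 1) return(c(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}
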