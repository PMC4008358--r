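# Brute-force oracles, independent of the implementation paths they check.

# one-sided Fisher p by explicit enumeration of the hypergeometric tail:
# sum over all tables at least as extreme (x >= a) with the margins fixed
oracle_fisher_greater <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- choose(r1, xs) * choose(n - r1, c1 - xs) / choose(n, c1)
  sum(probs[xs >= a])
}

# BH step-up written out from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Spearman rho from the classical rank-difference formula (tie-free data)
oracle_spearman_rho <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# exact two-sided Wilcoxon rank-sum p by enumerating all rank assignments
oracle_wilcoxon_exact <- function(a, b) {
  n <- length(a) + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  combos <- utils::combn(n, length(a))
  w_all <- apply(combos, 2, function(idx)
    sum(seq_len(n)[idx]) - length(a) * (length(a) + 1) / 2)
  mu <- length(a) * length(b) / 2
  min(1, 2 * min(mean(w_all >= w_obs), mean(w_all <= w_obs)))
}

# one-way F from explicit sums of squares
oracle_anova_F <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- length(groups) - 1
  dfw <- length(all_v) - length(groups)
  F <- (ssb / dfb) / (ssw / dfw)
  list(F = F, p = stats::pf(F, dfb, dfw, lower.tail = FALSE))
}

# pooled-variance t p-value from the textbook formula
oracle_students_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * stats::pt(-abs(tstat), df = na + nb - 2)
}
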