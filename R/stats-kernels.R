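# Statistical kernels shared by every analysis stage.  These are thin,
# strictly-specified front-ends over base R's implementations (phyper,
# p.adjust, cor.test, wilcox.test, oneway.test, t.test) so that every stage
# uses one documented convention for sidedness, tie handling and exactness.

#' One-sided (enrichment) Fisher exact test on a 2x2 table
#'
#' Computes the hypergeometric upper tail `P(X >= a)` with the table margins
#' fixed, i.e. the classical one-sided Fisher exact test for
#' over-representation.  Rows index list membership (`a` = in list and in
#' category, `b` = in list only), columns the category (`c` = in category
#' only, `d` = in neither).  Enrichment semantics make the greater tail the
#' relevant side for all gene-set tests in this package.
#'
#' @param a,b,c,d non-negative integer counts; vectors are recycled to a
#'   common length and tested element-wise.
#' @return p-value(s) in `[0, 1]`.
#' @export
fisher_exact_greater <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  if (any(a + b + c + d == 0)) stop("table total must be positive")
  # P(X >= a) for X ~ Hypergeometric(m = a+b, n = c+d, k = a+c)
  stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min_(j >= i) p_(j) * m / j` on the sorted p-values, mapped back
#' to the input order; `q >= p` element-wise and `q <= 1`.  Controls the
#' false-discovery rate within one test family.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
benjamini_hochberg <- function(p) {
  if (!length(p)) return(numeric())
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Spearman rank correlation with p-value
#'
#' Rho is the Pearson correlation of mid-ranks.  The p-value is two-sided:
#' exact by permutation enumeration for `n <= 9` on tie-free data, the
#' t-approximation (`t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` df)
#' otherwise.  Constant input is flagged rather than returned as a number.
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @return list with `rho`, `p` and `ok` (`FALSE` with `NA` statistics when
#'   either vector is constant).
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, ok = FALSE))
  }
  ties <- anyDuplicated(x) || anyDuplicated(y)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = (length(x) <= 9 && !ties)))
  list(rho = unname(ct$estimate), p = ct$p.value, ok = TRUE)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when the pooled size is at most 12 and the data are
#' tie-free; otherwise the tie- and continuity-corrected normal
#' approximation (the corrected form is what keeps the two paths within
#' 0.02 of each other at the cross-over sample size).
#'
#' @param a,b numeric vectors, both non-empty.
#' @return two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  p <- suppressWarnings(
    stats::wilcox.test(a, b, exact = (length(a) + length(b) <= 12 && !ties),
                       correct = TRUE)$p.value)
  # identical multisets with zero rank variance degenerate to NaN
  if (is.na(p)) 1 else p
}

#' Classical one-way ANOVA
#'
#' Equal-variance F test of equality of group means.
#'
#' @param groups list of `>= 2` numeric vectors, each with `>= 2` values and
#'   positive pooled within-group variance.
#' @return list with `F` and `p`.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs at least 2 values")
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 0))
  if (ssw <= 0) stop("zero within-group variance: F undefined")
  ht <- stats::oneway.test(v ~ g, var.equal = TRUE)
  list(F = unname(ht$statistic), p = ht$p.value)
}

#' Two-sided pooled-variance Student t-test
#'
#' @param a,b numeric vectors with `>= 2` values each and positive pooled
#'   variance.
#' @return two-sided p-value.
#' @export
students_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs at least 2 values")
  pooled <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  if (pooled <= 0) stop("zero pooled variance: t undefined")
  stats::t.test(a, b, var.equal = TRUE)$p.value
}

# Spearman correlation of every row of X against every row of Y, computed
# block-wise over Y.  Rows are mid-rank-transformed once, so the result is
# independent of the chunk size; p-values use the t-approximation.
spearman_matrix <- function(X, Y, chunk_size = 2000) {
  stopifnot(ncol(X) == ncol(Y))
  n <- ncol(X)
  rx <- t(apply(X, 1, rank))
  rho <- matrix(NA_real_, nrow(X), nrow(Y),
                dimnames = list(rownames(X), rownames(Y)))
  idx <- split(seq_len(nrow(Y)), ceiling(seq_len(nrow(Y)) / chunk_size))
  for (block in idx) {
    ry <- t(apply(Y[block, , drop = FALSE], 1, rank))
    rho[, block] <- suppressWarnings(stats::cor(t(rx), t(ry)))
  }
  p <- spearman_p_approx(rho, n)
  list(rho = rho, p = p, n = n)
}

spearman_p_approx <- function(rho, n) {
  r <- pmin(pmax(rho, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tstat), df = n - 2)
}
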