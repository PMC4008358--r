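# Intrinsic-subtype assignment by nearest-centroid classification and
# discovery of subtype-specific miRNAs.

#' Nearest-centroid subtype assignment
#'
#' Correlates each sample's gene expression with every subtype centroid over
#' the intersecting gene panel (Spearman by default, following common
#' practice for intrinsic-subtype centroids; rank correlation makes the call
#' invariant to any monotone per-sample transform) and assigns the
#' subtype with the largest correlation.  An optional balanced-subsample
#' majority vote repeats the assignment on `votes_rounds` random gene
#' subsets and takes the modal label, for panels where single-shot
#' assignment is unstable.
#'
#' @param gene_expr gene x sample expression matrix.
#' @param centroids gene x subtype centroid matrix (`>= 10` panel genes must
#'   be present in `gene_expr`).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param votes_rounds number of majority-vote rounds (0 = single-shot).
#' @param votes_fraction fraction of panel genes drawn per round.
#' @return data.frame with `sample_id`, `subtype` and `max_cor`; the full
#'   sample x subtype correlation matrix is attached as
#'   `attr(x, "correlations")` for auditing.
#' @export
assign_subtypes <- function(gene_expr, centroids,
                            method = c("spearman", "pearson"),
                            votes_rounds = 0, votes_fraction = 0.8) {
  method <- match.arg(method)
  panel <- intersect(rownames(gene_expr), rownames(centroids))
  if (length(panel) < 10)
    stop("fewer than 10 centroid panel genes present in the expression matrix")
  X <- gene_expr[panel, , drop = FALSE]
  C <- centroids[panel, , drop = FALSE]
  cors <- stats::cor(X, C, method = method)
  label_from <- function(cm) colnames(C)[max.col(cm, ties.method = "first")]
  if (votes_rounds > 0) {
    votes <- matrix("", ncol(X), votes_rounds)
    for (b in seq_len(votes_rounds)) {
      idx <- sample(length(panel), max(10, round(votes_fraction *
                                                   length(panel))))
      votes[, b] <- label_from(stats::cor(X[idx, , drop = FALSE],
                                          C[idx, , drop = FALSE],
                                          method = method))
    }
    labels <- apply(votes, 1, function(v)
      names(which.max(table(factor(v, levels = colnames(C))))))
  } else {
    labels <- label_from(cors)
  }
  out <- data.frame(sample_id = colnames(X), subtype = labels,
                    max_cor = cors[cbind(seq_len(nrow(cors)),
                                         match(labels, colnames(C)))],
                    stringsAsFactors = FALSE)
  attr(out, "correlations") <- cors
  out
}

#' miRNAs differentially expressed across intrinsic subtypes
#'
#' One-way ANOVA of each miRNA's expression across subtype groups,
#' Benjamini-Hochberg correction across miRNAs, and a subtype-specific flag
#' at `q < q_threshold`.  The peak subtype is the group with maximal mean
#' expression.  Subtypes with fewer than two samples are dropped with a
#' warning; miRNAs with zero within-group variance are flagged and excluded
#' from the FDR family.
#'
#' @param mirna_expr miRNA x sample matrix.
#' @param labels character vector of subtype labels, parallel to the matrix
#'   columns (or named by sample id).
#' @param q_threshold call threshold (default 0.001).
#' @return data.frame with `mirna_id`, `F`, `p`, `anova_q`, `peak_subtype`,
#'   `subtype_specific` and a status `flag`.
#' @export
subtype_specific_mirnas <- function(mirna_expr, labels, q_threshold = 0.001) {
  validate_expression_matrix(mirna_expr)
  if (!is.null(names(labels))) labels <- labels[colnames(mirna_expr)]
  if (length(labels) != ncol(mirna_expr))
    stop("one subtype label per sample required")
  counts <- table(labels)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("dropping subtype(s) with < 2 samples: ",
            paste(small, collapse = ", "))
    keep <- !(labels %in% small)
    mirna_expr <- mirna_expr[, keep, drop = FALSE]
    labels <- labels[keep]
  }
  if (length(unique(labels)) < 2) stop("need >= 2 subtypes with >= 2 samples")
  groups_of <- function(x) split(x, labels)
  rows <- lapply(rownames(mirna_expr), function(m) {
    gr <- groups_of(mirna_expr[m, ])
    means <- vapply(gr, mean, 0)
    res <- tryCatch(anova_oneway(gr), error = function(e) NULL)
    data.frame(mirna_id = m,
               F = if (is.null(res)) NA_real_ else res$F,
               p = if (is.null(res)) NA_real_ else res$p,
               peak_subtype = names(means)[which.max(means)],
               flag = if (is.null(res)) "degenerate" else "ok",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$anova_q <- NA_real_
  ok <- res$flag == "ok"
  res$anova_q[ok] <- benjamini_hochberg(res$p[ok])
  res$subtype_specific <- ok & res$anova_q < q_threshold
  rownames(res) <- NULL
  res
}

#' miRNAs differentially expressed between two histopathological groups
#'
#' Per-miRNA pooled-variance t-test between the two groups,
#' Benjamini-Hochberg correction across miRNAs, flag at `q < q_threshold`.
#'
#' @param mirna_expr miRNA x sample matrix.
#' @param group logical or two-level factor parallel to the columns (or
#'   named by sample id).
#' @param q_threshold call threshold (default 0.01).
#' @return data.frame with `mirna_id`, `mean_diff` (group TRUE/level 2 minus
#'   the other), `p`, `q`, `differential` and a status `flag`.
#' @export
group_contrast_mirnas <- function(mirna_expr, group, q_threshold = 0.01) {
  validate_expression_matrix(mirna_expr)
  if (!is.null(names(group))) group <- group[colnames(mirna_expr)]
  if (length(group) != ncol(mirna_expr))
    stop("one group value per sample required")
  g <- as.factor(group)
  if (nlevels(g) != 2) stop("grouping must have exactly two levels")
  if (any(table(g) < 2)) stop("both groups need >= 2 samples")
  in2 <- g == levels(g)[2]
  rows <- lapply(rownames(mirna_expr), function(m) {
    x <- mirna_expr[m, ]
    p <- tryCatch(students_t(x[in2], x[!in2]), error = function(e) NA_real_)
    data.frame(mirna_id = m, mean_diff = mean(x[in2]) - mean(x[!in2]),
               p = p, flag = if (is.na(p)) "degenerate" else "ok",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  ok <- res$flag == "ok"
  res$q[ok] <- benjamini_hochberg(res$p[ok])
  res$differential <- ok & res$q < q_threshold
  rownames(res) <- NULL
  res
}
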