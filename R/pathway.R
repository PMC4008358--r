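# Gene-set signature scoring, miRNA-pathway correlation selection,
# two-way hierarchical clustering with bootstrap stability, and inference
# of the gene sets transcriptionally influenced by each miRNAapt.

#' Signature scores for a gene-set collection
#'
#' The score of a set in a sample is the mean expression of the set's genes
#' that are present in the matrix; sets without any measured gene are
#' dropped with a warning.
#'
#' @param gene_expr gene x sample matrix.
#' @param sets gene-set collection.
#' @return set x sample numeric matrix.
#' @export
score_gene_sets <- function(gene_expr, sets) {
  validate_expression_matrix(gene_expr)
  present <- lapply(sets, function(g) intersect(g, rownames(gene_expr)))
  empty <- names(present)[lengths(present) == 0]
  if (length(empty)) {
    warning("dropping gene set(s) with no measured gene: ",
            paste(empty, collapse = ", "))
    present <- present[lengths(present) > 0]
  }
  if (!length(present)) stop("no scorable gene sets")
  out <- t(vapply(present, function(g)
    colMeans(gene_expr[g, , drop = FALSE]), numeric(ncol(gene_expr))))
  dimnames(out) <- list(names(present), colnames(gene_expr))
  out
}

#' Correlations between miRNAs and gene-set signature scores
#'
#' Spearman correlation of each miRNA with each signature score across the
#' shared samples.  A (miRNA, set) pair is selected when (1) the absolute
#' correlation exceeds `rho_threshold`, (2) the correlation p-value is below
#' `p_threshold`, and (3) the one-way ANOVA of that set's correlation values
#' across the supplied miRNA groups (e.g. favourable vs unfavourable
#' prognostic direction, or peak subtype) is below `anova_threshold`.  No
#' multiple-testing correction is applied; the thresholds are deliberately
#' conservative because signature scores are strongly inter-dependent.
#' When fewer than two groups have two or more miRNAs, the ANOVA criterion
#' is not evaluable and the records are flagged.
#'
#' @param mirna_expr miRNA x sample matrix.
#' @param scores set x sample signature-score matrix.
#' @param mirna_groups named character vector: miRNA id -> group label.
#' @param rho_threshold,p_threshold,anova_threshold selection thresholds
#'   (defaults 0.5, 1e-6, 1e-4).
#' @return data.frame with `mirna_id`, `set_name`, `rho`, `rho_p`,
#'   `group_anova_p`, `selected`, `flag`.
#' @export
mirna_pathway_correlations <- function(mirna_expr, scores, mirna_groups,
                                       rho_threshold = 0.5,
                                       p_threshold = 1e-6,
                                       anova_threshold = 1e-4) {
  samples <- intersect(colnames(mirna_expr), colnames(scores))
  if (length(samples) < 3) stop("too few shared samples")
  mirnas <- intersect(rownames(mirna_expr), names(mirna_groups))
  if (!length(mirnas)) stop("no miRNA has a group label")
  sm <- spearman_matrix(mirna_expr[mirnas, samples, drop = FALSE],
                        scores[, samples, drop = FALSE])
  groups <- mirna_groups[mirnas]
  gtab <- table(groups)
  evaluable <- sum(gtab >= 2) >= 2
  anova_p <- rep(NA_real_, nrow(scores))
  names(anova_p) <- rownames(scores)
  if (evaluable) {
    keep <- groups %in% names(gtab)[gtab >= 2]
    for (s in rownames(scores)) {
      gr <- split(sm$rho[keep, s], groups[keep])
      anova_p[s] <- tryCatch(anova_oneway(gr)$p, error = function(e) NA_real_)
    }
  }
  res <- data.frame(
    mirna_id = rep(mirnas, times = nrow(scores)),
    set_name = rep(rownames(scores), each = length(mirnas)),
    rho = as.vector(sm$rho), rho_p = as.vector(sm$p),
    group_anova_p = rep(anova_p, each = length(mirnas)),
    stringsAsFactors = FALSE)
  res$flag <- ifelse(is.na(res$group_anova_p), "anova_not_evaluable", "ok")
  res$selected <- res$flag == "ok" &
    abs(res$rho) > rho_threshold & res$rho_p < p_threshold &
    res$group_anova_p < anova_threshold
  rownames(res) <- NULL
  res
}

# all member sets (of size >= 2 and < n) of the internal nodes of an hclust
hclust_node_sets <- function(hc) {
  n <- length(hc$order)
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    left <- hc$merge[i, 1]; right <- hc$merge[i, 2]
    members[[i]] <- c(if (left < 0) hc$labels[-left] else members[[left]],
                      if (right < 0) hc$labels[-right] else members[[right]])
  }
  members <- members[vapply(members, length, 0L) < n]
  lapply(members, sort)
}

#' Two-way hierarchical clustering with bootstrap cluster stability
#'
#' Clusters the rows and the columns of a correlation matrix (Euclidean
#' distance, average linkage by default) and assesses the stability of
#' every internal cluster by bootstrap: the features (the opposite axis) are
#' resampled with replacement `n_boot` times, the clustering is recomputed,
#' and a cluster's stability p-value is one minus the fraction of resamples
#' in which exactly its member set reappears as a cluster.  This is the
#' plain bootstrap proportion, not the multiscale AU correction.
#'
#' @param mat numeric matrix (e.g. miRNA x gene-set correlations), complete,
#'   with at least 3 items on each clustered axis.
#' @param n_boot bootstrap resamples (default 10000; scale down for quick
#'   checks).
#' @param linkage agglomeration method (default `"average"`).
#' @param seed optional integer seed.
#' @return list with `row_hclust`, `col_hclust` and data.frames
#'   `row_clusters` / `col_clusters` (cluster members, size, `stability_p`).
#' @export
cluster_with_bootstrap <- function(mat, n_boot = 10000,
                                   linkage = "average", seed = NULL) {
  if (anyNA(mat)) stop("matrix must be complete")
  if (nrow(mat) < 3 || ncol(mat) < 3)
    stop("need at least 3 items on each clustered axis")
  if (!is.null(seed)) set.seed(seed)
  cluster_axis <- function(items) {   # items x features
    hc <- stats::hclust(stats::dist(items), method = linkage)
    nodes <- hclust_node_sets(hc)
    hits <- integer(length(nodes))
    keys <- vapply(nodes, paste, "", collapse = "\r")
    nf <- ncol(items)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nf, nf, replace = TRUE)
      bhc <- stats::hclust(stats::dist(items[, idx, drop = FALSE]),
                           method = linkage)
      bkeys <- vapply(hclust_node_sets(bhc), paste, "", collapse = "\r")
      hits <- hits + (keys %in% bkeys)
    }
    list(hclust = hc,
         clusters = data.frame(
           members = vapply(nodes, paste, "", collapse = ","),
           size = lengths(nodes),
           stability_p = 1 - hits / n_boot,
           stringsAsFactors = FALSE))
  }
  rows <- cluster_axis(mat)
  cols <- cluster_axis(t(mat))
  list(row_hclust = rows$hclust, col_hclust = cols$hclust,
       row_clusters = rows$clusters, col_clusters = cols$clusters)
}

#' Gene sets enriched in each miRNAapt's anti-correlated targets
#'
#' For every called miRNAapt and every gene set smaller than
#' `max_set_size` (measured over the gene universe), a one-sided Fisher test
#' of the overlap between the set and the miRNA's anti-correlated predicted
#' targets, over the same universe used for miRNAapt discovery.  A set is
#' assigned to a miRNAapt when the Fisher p-value is below `p_threshold`,
#' the overlap strictly exceeds `min_overlap` genes, and the set size is
#' below `max_set_size`.
#'
#' @param mirnapt_res result of [mirnapt_enrichment()].
#' @param sets gene-set collection.
#' @param p_threshold Fisher p cut-off (default 0.001).
#' @param min_overlap overlap must be strictly greater than this
#'   (default 3, i.e. at least 4 shared genes).
#' @param max_set_size sets at or above this size are excluded
#'   (default 500).
#' @return data.frame with `mirna_id`, `set_name`, `set_size`, `overlap`,
#'   `fisher_p`, `selected`.
#' @export
targeted_gene_sets <- function(mirnapt_res, sets, p_threshold = 0.001,
                               min_overlap = 3, max_set_size = 500) {
  stopifnot(inherits(mirnapt_res, "mirnapt_result"))
  universe <- mirnapt_res$universe
  apt <- mirnapt_res$table$mirna_id[mirnapt_res$table$is_mirnapt]
  set_genes <- lapply(sets, function(g) intersect(unique(g), universe))
  sizes <- lengths(set_genes)
  keep_sets <- names(set_genes)[sizes > 0 & sizes < max_set_size]
  rows <- lapply(apt, function(mi) {
    tg <- intersect(mirnapt_res$anticorrelated_targets[[mi]]$union, universe)
    a <- vapply(set_genes[keep_sets], function(g)
      length(intersect(g, tg)), 0L)
    size <- sizes[keep_sets]
    b <- size - a
    cc <- length(tg) - a
    d <- length(universe) - a - b - cc
    p <- if (length(tg) == 0) rep(1, length(a)) else
      fisher_exact_greater(a, b, cc, d)
    data.frame(mirna_id = mi, set_name = keep_sets, set_size = size,
               overlap = a, fisher_p = p, stringsAsFactors = FALSE)
  })
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(), set_name = character(),
               set_size = integer(), overlap = integer(),
               fisher_p = numeric(), stringsAsFactors = FALSE)
  res$selected <- res$fisher_p < p_threshold & res$overlap > min_overlap &
    res$set_size < max_set_size
  rownames(res) <- NULL
  res
}
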