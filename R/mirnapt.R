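# Identification of miRNAs anti-correlated with their predicted targets
# ("miRNAapt"): per-pair Spearman correlations, enrichment of
# anti-correlated genes among the predicted targets (one-sided Fisher with
# per-algorithm FDR), and a global correlation QC profile.
#
# The Fisher background ("universe") is the full set of genes present in
# the expression matrix after filtering; anti-correlation flags are
# therefore computed for every universe gene, not just predicted targets,
# so that the 2x2 margins are complete.

#' Spearman correlations between miRNAs and their predicted targets
#'
#' Computes Spearman rho for every (miRNA, predicted target) pair of every
#' prediction algorithm, across the shared samples, and flags pairs with
#' `rho < rho_threshold` (strict: a pair exactly at the threshold is not
#' anti-correlated).  Predicted targets absent from the gene expression
#' matrix are dropped, with a message stating the count.
#'
#' @param mirna_expr miRNA x sample matrix.
#' @param gene_expr gene x sample matrix.
#' @param targets target-prediction map.
#' @param rho_threshold anti-correlation cut-off (default -0.3).
#' @param rho optional precomputed miRNA x gene Spearman matrix (as
#'   returned in `attr(, "rho")` of [mirnapt_enrichment()]) to avoid
#'   recomputation.
#' @return data.frame with `mirna_id`, `gene_id`, `algorithm`, `rho`,
#'   `anti_correlated`.
#' @export
mirna_target_correlations <- function(mirna_expr, gene_expr, targets,
                                      rho_threshold = -0.3, rho = NULL) {
  validate_target_map(targets)
  if (is.null(rho)) rho <- mirna_gene_rho(mirna_expr, gene_expr)
  genes <- colnames(rho)
  dropped <- 0L
  rows <- list()
  for (alg in names(targets)) {
    m <- targets[[alg]]
    m <- m[names(m) %in% rownames(rho)]
    for (mi in names(m)) {
      tg <- m[[mi]]
      present <- tg[tg %in% genes]
      dropped <- dropped + length(tg) - length(present)
      if (!length(present)) next
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = mi, gene_id = present, algorithm = alg,
        rho = rho[mi, present], stringsAsFactors = FALSE)
    }
  }
  if (dropped > 0)
    message(dropped, " predicted target entr",
            if (dropped == 1) "y" else "ies",
            " absent from the expression matrix were dropped")
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(), gene_id = character(),
               algorithm = character(), rho = numeric(),
               stringsAsFactors = FALSE)
  out$anti_correlated <- out$rho < rho_threshold
  rownames(out) <- NULL
  out
}

# full miRNA x gene Spearman matrix over the shared samples, chunked over
# genes; results do not depend on the chunk size
mirna_gene_rho <- function(mirna_expr, gene_expr, chunk_size = 2000) {
  samples <- intersect(colnames(mirna_expr), colnames(gene_expr))
  if (length(samples) < 3) stop("no (or too few) shared samples")
  spearman_matrix(mirna_expr[, samples, drop = FALSE],
                  gene_expr[, samples, drop = FALSE],
                  chunk_size = chunk_size)$rho
}

#' Identify miRNAs anti-correlated with their predicted targets
#'
#' For every miRNA and every prediction algorithm, a 2x2 table over the gene
#' universe (all genes in the expression matrix) is tested with the
#' one-sided Fisher exact test: predicted target of the miRNA (yes/no)
#' against anti-correlated with the miRNA (`rho < rho_threshold`, computed
#' for every universe gene).  P-values are Benjamini-Hochberg corrected
#' across miRNAs within each algorithm (the per-algorithm analyses are
#' independent), the minimum q over algorithms is taken after correction,
#' and a miRNA is called miRNAapt when `min_q < q_threshold`.  miRNAs with
#' fewer than `min_targets` measured predicted targets in an algorithm are
#' excluded from that algorithm's family.
#'
#' @param mirna_expr miRNA x sample matrix.
#' @param gene_expr gene x sample matrix.
#' @param targets target-prediction map.
#' @param rho_threshold anti-correlation cut-off (default -0.3, strict).
#' @param q_threshold miRNAapt call threshold on `min_q` (default 0.05).
#' @param min_targets minimum measured predicted targets per algorithm
#'   (default 10).
#' @param chunk_size genes per correlation block (result-invariant).
#' @return list of class `"mirnapt_result"` with elements `table` (one row
#'   per miRNA: `min_q`, `is_mirnapt`, `n_anticorrelated`), `by_algorithm`
#'   (per miRNA x algorithm: 2x2 counts, `p`, `q`), and
#'   `anticorrelated_targets` (per miRNA: per-algorithm gene lists plus
#'   their union).  The miRNA x gene rho matrix is attached as
#'   `attr(x, "rho")`.
#' @export
mirnapt_enrichment <- function(mirna_expr, gene_expr, targets,
                               rho_threshold = -0.3, q_threshold = 0.05,
                               min_targets = 10, chunk_size = 2000) {
  validate_target_map(targets)
  rho <- mirna_gene_rho(mirna_expr, gene_expr, chunk_size = chunk_size)
  universe <- colnames(rho)
  anti <- rho < rho_threshold   # strict
  mirnas <- rownames(rho)

  per_alg <- list()
  target_lists <- stats::setNames(vector("list", length(mirnas)), mirnas)
  for (alg in names(targets)) {
    m <- targets[[alg]]
    rows <- lapply(mirnas, function(mi) {
      tg <- unique(m[[mi]])
      tg <- tg[tg %in% universe]
      if (length(tg) < min_targets)
        return(data.frame(mirna_id = mi, algorithm = alg,
                          n_targets = length(tg), a = NA_integer_,
                          b = NA_integer_, c = NA_integer_, d = NA_integer_,
                          p = NA_real_, flag = "too_few_targets",
                          stringsAsFactors = FALSE))
      is_t <- universe %in% tg
      is_a <- anti[mi, ]
      a <- sum(is_t & is_a); b <- sum(is_t & !is_a)
      c <- sum(!is_t & is_a); d <- sum(!is_t & !is_a)
      data.frame(mirna_id = mi, algorithm = alg, n_targets = length(tg),
                 a = a, b = b, c = c, d = d,
                 p = fisher_exact_greater(a, b, c, d), flag = "ok",
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$q <- NA_real_
    ok <- tab$flag == "ok"
    tab$q[ok] <- benjamini_hochberg(tab$p[ok])
    per_alg[[alg]] <- tab
    for (mi in mirnas) {
      tg <- unique(m[[mi]])
      tg <- tg[tg %in% universe]
      target_lists[[mi]][[alg]] <- tg[anti[mi, tg]]
    }
  }
  by_algorithm <- do.call(rbind, per_alg)
  rownames(by_algorithm) <- NULL

  min_q <- vapply(mirnas, function(mi) {
    q <- by_algorithm$q[by_algorithm$mirna_id == mi]
    if (all(is.na(q))) NA_real_ else min(q, na.rm = TRUE)
  }, 0)
  union_targets <- lapply(target_lists, function(l)
    unique(unlist(l, use.names = FALSE)))
  table <- data.frame(mirna_id = mirnas, min_q = min_q,
                      is_mirnapt = !is.na(min_q) & min_q < q_threshold,
                      n_anticorrelated = lengths(union_targets),
                      stringsAsFactors = FALSE)
  rownames(table) <- NULL
  out <- list(table = table, by_algorithm = by_algorithm,
              anticorrelated_targets = lapply(
                stats::setNames(mirnas, mirnas), function(mi)
                  c(target_lists[[mi]], list(union = union_targets[[mi]]))),
              universe = universe,
              rho_threshold = rho_threshold, q_threshold = q_threshold)
  attr(out, "rho") <- rho
  class(out) <- "mirnapt_result"
  out
}

#' @export
print.mirnapt_result <- function(x, ...) {
  cat("miRNAapt enrichment over", length(x$universe), "genes,",
      nrow(x$table), "miRNAs,",
      length(unique(x$by_algorithm$algorithm)), "algorithms\n")
  cat(sum(x$table$is_mirnapt), "miRNA(s) called miRNAapt at min(q) <",
      x$q_threshold, "\n")
  invisible(x)
}

#' Per-algorithm summary of the miRNA-target correlation distribution
#'
#' QC profile of the general relationship between miRNAs and their
#' predicted targets: per algorithm, the quantiles and the fraction of
#' anti-correlated pairs.
#'
#' @param correlations output of [mirna_target_correlations()].
#' @param probs quantiles to report.
#' @return data.frame, one row per algorithm.
#' @export
global_correlation_profile <- function(correlations,
                                       probs = c(0.05, 0.25, 0.5, 0.75,
                                                 0.95)) {
  if (!nrow(correlations)) {
    warning("empty correlation table")
    return(data.frame(algorithm = character(), n_pairs = integer()))
  }
  rows <- lapply(split(correlations, correlations$algorithm), function(d) {
    qs <- stats::quantile(d$rho, probs)
    out <- data.frame(algorithm = d$algorithm[1], n_pairs = nrow(d),
                      mean_rho = mean(d$rho),
                      frac_anticorrelated = mean(d$anti_correlated),
                      stringsAsFactors = FALSE)
    for (i in seq_along(qs)) out[[paste0("q", probs[i] * 100)]] <- qs[[i]]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
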