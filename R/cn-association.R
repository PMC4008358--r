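# Association between miRNA expression and DNA copy number: gain/loss
# stratification, dosage correlation, per-family FDR, and genomic
# annotation of copy-number-driven miRNAs.

#' Stratify samples by absolute copy number
#'
#' Gains are more than `gain_above` copies, losses fewer than `loss_below`
#' copies, everything else is neutral (both cut-offs strict, so 2.3 and 1.7
#' copies are neutral at the defaults).
#'
#' @param copies numeric vector of absolute copy numbers.
#' @param gain_above,loss_below stratification cut-offs (defaults 2.3 / 1.7).
#' @return character vector in `{"gain", "loss", "neutral"}`.
#' @export
stratify_by_cn <- function(copies, gain_above = 2.3, loss_below = 1.7) {
  if (any(!is.finite(copies))) stop("copy numbers must be finite")
  out <- rep("neutral", length(copies))
  out[copies > gain_above] <- "gain"
  out[copies < loss_below] <- "loss"
  names(out) <- names(copies)
  out
}

#' Identify copy-number-driven miRNAs
#'
#' For each miRNA shared between the expression and copy-number matrices:
#' Spearman correlation between copy number and expression; Wilcoxon
#' rank-sum tests of expression in gain vs neutral and loss vs neutral
#' samples; Benjamini-Hochberg correction across miRNAs separately within
#' the gain and the loss family (or pooled with `bh_family = "pooled"`).  A
#' Wilcoxon side in which either group has fewer than `min_group` samples is
#' skipped and reports q = 1.  A miRNA is called copy-number driven when its
#' signed correlation exceeds `rho_threshold` and the smaller of the two
#' q-values is below `q_threshold`.
#'
#' miRNAs co-located with transposable elements must be excluded before this
#' analysis; pass `loci` to have them dropped here.
#'
#' @param expr miRNA x patient expression matrix.
#' @param cn miRNA x patient absolute copy-number matrix.
#' @param loci optional locus table; TE-flagged miRNAs are removed.
#' @param q_threshold,rho_threshold call thresholds (defaults 0.05 / 0.25).
#' @param gain_above,loss_below stratification cut-offs.
#' @param min_group minimum samples per Wilcoxon group (default 3).
#' @param bh_family `"separate"` (default) corrects gains and losses as two
#'   families; `"pooled"` corrects them together.
#' @return data.frame with one row per miRNA: `rho_cn`, `rho_p`, `q_gain`,
#'   `q_loss`, group counts and the `cn_driven` flag.
#' @export
cn_expression_association <- function(expr, cn, loci = NULL,
                                      q_threshold = 0.05,
                                      rho_threshold = 0.25,
                                      gain_above = 2.3, loss_below = 1.7,
                                      min_group = 3,
                                      bh_family = c("separate", "pooled")) {
  bh_family <- match.arg(bh_family)
  mirnas <- intersect(rownames(expr), rownames(cn))
  if (!is.null(loci)) {
    te <- loci$mirna_id[loci$te_colocated]
    mirnas <- setdiff(mirnas, te)
  }
  samples <- intersect(colnames(expr), colnames(cn))
  if (!length(samples)) stop("no overlapping samples between expression and CN")
  if (!length(mirnas)) stop("no overlapping miRNAs between expression and CN")

  res <- lapply(mirnas, function(m) {
    e <- expr[m, samples]
    k <- cn[m, samples]
    lab <- stratify_by_cn(k, gain_above, loss_below)
    st <- spearman_test(k, e)
    testable <- function(side) {
      sum(lab == side) >= min_group && sum(lab == "neutral") >= min_group
    }
    p_gain <- if (testable("gain"))
      wilcoxon_rank_sum(e[lab == "gain"], e[lab == "neutral"]) else NA_real_
    p_loss <- if (testable("loss"))
      wilcoxon_rank_sum(e[lab == "loss"], e[lab == "neutral"]) else NA_real_
    data.frame(mirna_id = m, rho_cn = st$rho, rho_p = st$p,
               p_gain = p_gain, p_loss = p_loss,
               n_gain = sum(lab == "gain"), n_loss = sum(lab == "loss"),
               n_neutral = sum(lab == "neutral"), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)

  adjust_family <- function(p) {
    q <- rep(1, length(p))
    q[!is.na(p)] <- benjamini_hochberg(p[!is.na(p)])
    q
  }
  if (bh_family == "separate") {
    res$q_gain <- adjust_family(res$p_gain)
    res$q_loss <- adjust_family(res$p_loss)
  } else {
    pooled <- c(res$p_gain, res$p_loss)
    q <- rep(1, length(pooled))
    q[!is.na(pooled)] <- benjamini_hochberg(pooled[!is.na(pooled)])
    res$q_gain <- q[seq_len(nrow(res))]
    res$q_loss <- q[nrow(res) + seq_len(nrow(res))]
  }
  res$cn_driven <- !is.na(res$rho_cn) & res$rho_cn > rho_threshold &
    pmin(res$q_gain, res$q_loss) < q_threshold
  rownames(res) <- NULL
  res
}

loci_to_granges <- function(loci, pad = 0L) {
  GenomicRanges::GRanges(
    seqnames = loci$chromosome,
    ranges = IRanges::IRanges(pmax(1L, loci$start - as.integer(pad)),
                              loci$end + as.integer(pad)),
    mirna_id = loci$mirna_id)
}

regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chromosome,
    ranges = IRanges::IRanges(regions$start, regions$end),
    label = regions$label, category = regions$category)
}

#' Annotate miRNAs with overlapping recurrent aberration regions
#'
#' A miRNA is labelled with every recurrent-amplification or
#' recurrent-deletion region overlapping its locus by at least one base
#' (1-based inclusive coordinates on both sides).
#'
#' @param loci miRNA locus table.
#' @param regions genomic region table; only `recurrent_*` categories used.
#' @return named list: miRNA id -> character vector of region labels.
#' @export
annotate_recurrent_regions <- function(loci, regions) {
  validate_mirna_loci(loci)
  validate_genomic_regions(regions)
  regions <- regions[regions$category %in%
                       c("recurrent_amplification", "recurrent_deletion"), ,
                     drop = FALSE]
  unmatched <- setdiff(unique(loci$chromosome), unique(regions$chromosome))
  if (length(unmatched) && nrow(regions))
    warning("no regions on chromosome(s): ",
            paste(unmatched, collapse = ", "))
  overlap_labels(loci, regions, pad = 0L, keep = "label")
}

#' Cancer genes co-located with each miRNA locus
#'
#' Reports oncogenes and tumour-suppressor genes overlapping a closed window
#' extending `window` bases on either side of the miRNA locus (clamped at
#' position 1); a gene starting exactly `window` bases past the locus end is
#' included.
#'
#' @param loci miRNA locus table.
#' @param genes genomic region table with `oncogene` / `tumour_suppressor`
#'   categories.
#' @param window flank size in bases (default 10000).
#' @return named list: miRNA id -> data.frame(label, category).
#' @export
colocated_cancer_genes <- function(loci, genes, window = 10000) {
  validate_mirna_loci(loci)
  validate_genomic_regions(genes)
  genes <- genes[genes$category %in% c("oncogene", "tumour_suppressor"), ,
                 drop = FALSE]
  overlap_labels(loci, genes, pad = window, keep = c("label", "category"))
}

overlap_labels <- function(loci, regions, pad, keep) {
  empty <- if (length(keep) == 1) character() else
    data.frame(label = character(), category = character(),
               stringsAsFactors = FALSE)
  out <- stats::setNames(rep(list(empty), nrow(loci)), loci$mirna_id)
  if (!nrow(regions) || !nrow(loci)) return(out)
  q <- loci_to_granges(loci, pad = pad)
  s <- regions_to_granges(regions)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, s))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  for (i in unique(qi)) {
    rows <- si[qi == i]
    out[[loci$mirna_id[i]]] <- if (length(keep) == 1)
      regions$label[rows]
    else
      data.frame(label = regions$label[rows],
                 category = regions$category[rows], stringsAsFactors = FALSE)
  }
  out
}

#' One-sided Fisher test for the overlap of two feature lists
#'
#' Tests whether lists A and B share more members than expected for random
#' draws from `universe` (hypergeometric upper tail).
#'
#' @param listA,listB character vectors, subsets of `universe`.
#' @param universe character vector of all eligible features.
#' @return one-sided p-value.
#' @export
overlap_fisher <- function(listA, listB, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  listA <- unique(listA); listB <- unique(listB)
  if (!all(listA %in% universe) || !all(listB %in% universe))
    stop("lists must be subsets of the universe")
  a <- length(intersect(listA, listB))
  b <- length(setdiff(listA, listB))
  c <- length(setdiff(listB, listA))
  d <- length(universe) - a - b - c
  fisher_exact_greater(a, b, c, d)
}
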