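# Cohort-level preprocessing: replicate averaging, detection filtering and
# exclusion of transposable-element-co-located miRNAs.  Replicate averaging
# runs before every downstream analysis so that all statistics are computed
# on one column per patient.

#' Average replicate samples per patient
#'
#' Collapses the sample-level matrix to one column per patient by taking the
#' arithmetic mean of that patient's replicate columns; patients profiled
#' once pass through unchanged.  Output columns follow the patient order of
#' the clinical table, so the result does not depend on the input column
#' order.  If detection flags are attached, a patient-level flag is the
#' maximum code over the replicates (i.e. a feature is "bad" for a patient
#' when any replicate was not detected or saturated).
#'
#' @param expr feature x sample matrix (optionally with flags).
#' @param clinical clinical table supplying the sample -> patient mapping.
#' @return feature x patient matrix.
#' @export
average_replicates <- function(expr, clinical) {
  validate_expression_matrix(expr)
  map <- sample_to_patient(clinical)
  unknown <- setdiff(colnames(expr), names(map))
  if (length(unknown))
    stop("sample id(s) with no patient mapping: ",
         paste(unknown, collapse = ", "))
  patients <- intersect(clinical$patient_id, unname(map[colnames(expr)]))
  out <- vapply(patients, function(p) {
    cols <- colnames(expr)[map[colnames(expr)] == p]
    if (length(cols) == 1L) expr[, cols] else rowMeans(expr[, cols, drop = FALSE])
  }, numeric(nrow(expr)))
  out <- matrix(out, nrow = nrow(expr),
                dimnames = list(rownames(expr), patients))
  fl <- expression_flags(expr)
  if (!is.null(fl)) {
    ofl <- vapply(patients, function(p) {
      cols <- colnames(expr)[map[colnames(expr)] == p]
      as.integer(apply(fl[, cols, drop = FALSE], 1, max))
    }, integer(nrow(expr)))
    ofl <- matrix(ofl, nrow = nrow(expr), dimnames = dimnames(out))
    out <- set_expression_flags(out, ofl)
  }
  out
}

#' Filter features undetected or saturated in too many samples
#'
#' Removes every feature whose count of samples flagged not-detected or
#' saturated exceeds `max_bad_samples` (strictly more than; a feature bad in
#' exactly `max_bad_samples` samples is retained).
#'
#' @param expr matrix with a detection-flag attribute (see
#'   [set_expression_flags()]).
#' @param max_bad_samples maximum tolerated number of flagged samples
#'   (default 10).
#' @return the filtered matrix (flags subset accordingly).
#' @export
filter_undetected <- function(expr, max_bad_samples = 10) {
  fl <- expression_flags(expr)
  if (is.null(fl))
    stop("no detection flags attached: supply flags via ",
         "set_expression_flags() or skip this filter")
  bad <- rowSums(fl != FLAG_CODES[["detected"]])
  keep <- bad <= max_bad_samples
  out <- expr[keep, , drop = FALSE]
  set_expression_flags(out, fl[keep, , drop = FALSE])
}

#' Exclude transposable-element-co-located miRNAs
#'
#' Drops loci flagged `te_colocated` (their genomic position is considered
#' unreliable), preserving the input order.  Idempotent.
#'
#' @param loci miRNA locus data.frame.
#' @return the filtered locus data.frame.
#' @export
exclude_te_mirnas <- function(loci) {
  validate_mirna_loci(loci)
  out <- loci[!loci$te_colocated, , drop = FALSE]
  if (nrow(out) == 0 && nrow(loci) > 0)
    warning("all miRNAs are TE-co-located; no usable loci remain")
  rownames(out) <- NULL
  out
}
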