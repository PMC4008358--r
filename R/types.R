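#' @keywords internal
"_PACKAGE"

# Internal container conventions
#
# ExpressionMatrix / CopyNumberMatrix : base numeric matrix, features in rows,
#   samples in columns, both dimensions named.  Detection flags, when present,
#   travel as an integer matrix of the same shape in attr(x, "flags") with
#   codes 0 = detected, 1 = not detected, 2 = saturated.
# MirnaLocus set   : data.frame(mirna_id, chromosome, start, end, strand,
#   te_colocated), coordinates 1-based inclusive (GFF3 convention).
# GenomicRegionSet : data.frame(chromosome, start, end, label, category).
# TargetPredictionMap : named list algorithm -> named list mirna -> character
#   vector of gene ids.
# GeneSetCollection   : named list set -> character vector of gene ids, with
#   parallel named character attributes "description" and "source".
# ClinicalTable    : data.frame, one row per patient, with a list-column
#   `sample_ids` mapping each patient to one or more assay samples.

REGION_CATEGORIES <- c("recurrent_amplification", "recurrent_deletion",
                       "oncogene", "tumour_suppressor")
SUBTYPES <- c("basal", "lumA", "lumB", "her2", "normal")
RECEPTOR_LEVELS <- c("pos", "neg", "unknown")
FLAG_CODES <- c(detected = 0L, not_detected = 1L, saturated = 2L)

#' Construct a feature-by-sample expression matrix
#'
#' Builds the container used for log-scale miRNA and gene expression
#' throughout the pipeline: a plain numeric matrix with unique feature row
#' names and unique sample column names, optionally carrying a detection-flag
#' matrix of identical shape (codes 0 = detected, 1 = not detected,
#' 2 = saturated) as the `"flags"` attribute.
#'
#' @param values numeric matrix, features x samples, finite, with dimnames.
#' @param flags optional integer matrix of the same shape with values in
#'   `{0, 1, 2}`.
#' @return the validated matrix (with the flags attribute if supplied).
#' @export
expression_matrix <- function(values, flags = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  validate_expression_matrix(values)
  if (!is.null(flags)) values <- set_expression_flags(values, flags)
  values
}

validate_expression_matrix <- function(values, what = "expression matrix") {
  if (!is.matrix(values) || !is.numeric(values))
    stop(what, " must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop(what, " must have feature row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids in ", what)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in ", what)
  if (!all(is.finite(values)))
    stop(what, " contains non-finite values")
  invisible(values)
}

#' Attach or retrieve detection flags
#'
#' @param x expression matrix.
#' @param flags integer matrix, same shape as `x`, codes in `{0, 1, 2}`.
#' @return `set_expression_flags` returns `x` with the attribute set;
#'   `expression_flags` returns the flag matrix or `NULL`.
#' @export
set_expression_flags <- function(x, flags) {
  flags <- as.matrix(flags)
  storage.mode(flags) <- "integer"
  if (!identical(dim(flags), dim(x)))
    stop("flags must have the same shape as the expression matrix")
  if (!all(flags %in% FLAG_CODES))
    stop("flags must use codes 0 (detected), 1 (not detected), 2 (saturated)")
  dimnames(flags) <- dimnames(x)
  attr(x, "flags") <- flags
  x
}

#' @rdname set_expression_flags
#' @export
expression_flags <- function(x) attr(x, "flags")

#' Construct a miRNA-level absolute copy-number matrix
#'
#' @param copies numeric matrix, miRNAs x samples, non-negative and finite
#'   (diploid loci are close to 2).
#' @return the validated matrix.
#' @export
copy_number_matrix <- function(copies) {
  copies <- as.matrix(copies)
  storage.mode(copies) <- "double"
  validate_expression_matrix(copies, what = "copy-number matrix")
  if (any(copies < 0)) stop("copy numbers must be non-negative")
  copies
}

#' Construct a table of miRNA genomic loci
#'
#' Coordinates follow the GFF3 convention (1-based, both ends inclusive).
#' miRNAs co-located with transposable elements keep their nominal
#' coordinates but are marked `te_colocated`; their positions are considered
#' unreliable and they are excluded from locus-based copy-number analyses.
#'
#' @param mirna_id,chromosome,strand character vectors.
#' @param start,end integer vectors, `start <= end`.
#' @param te_colocated logical vector.
#' @return a `data.frame` with one row per miRNA.
#' @export
mirna_loci <- function(mirna_id, chromosome, start, end, strand,
                       te_colocated = FALSE) {
  df <- data.frame(mirna_id = as.character(mirna_id),
                   chromosome = as.character(chromosome),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   te_colocated = as.logical(rep_len(te_colocated,
                                                     length(mirna_id))),
                   stringsAsFactors = FALSE)
  validate_mirna_loci(df)
  df
}

validate_mirna_loci <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("mirna_id", "chromosome", "start", "end", "strand",
                  "te_colocated") %in% names(df)))
  if (anyDuplicated(df$mirna_id)) stop("duplicate miRNA ids in locus table")
  if (any(df$start > df$end)) stop("locus start must not exceed end")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  invisible(df)
}

#' Construct a set of labelled genomic regions
#'
#' Holds recurrent aberration regions and cancer-gene loci used to annotate
#' copy-number-driven miRNAs.
#'
#' @param chromosome,label,category character vectors; categories from
#'   `recurrent_amplification`, `recurrent_deletion`, `oncogene`,
#'   `tumour_suppressor`.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @return a `data.frame` with one row per region.
#' @export
genomic_regions <- function(chromosome, start, end, label, category) {
  df <- data.frame(chromosome = as.character(chromosome),
                   start = as.integer(start), end = as.integer(end),
                   label = as.character(label),
                   category = as.character(category),
                   stringsAsFactors = FALSE)
  validate_genomic_regions(df)
  df
}

validate_genomic_regions <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("chromosome", "start", "end", "label", "category")
                %in% names(df)))
  if (any(df$start > df$end)) stop("region start must not exceed end")
  bad <- setdiff(unique(df$category), REGION_CATEGORIES)
  if (length(bad))
    stop("unknown region category: ", paste(bad, collapse = ", "))
  invisible(df)
}

#' Construct a target-prediction map
#'
#' @param map named list (one element per prediction algorithm) of named
#'   lists (one element per miRNA) of character vectors of predicted target
#'   gene ids.
#' @return the validated map.
#' @export
target_prediction_map <- function(map) {
  validate_target_map(map)
  map
}

validate_target_map <- function(map) {
  if (!is.list(map) || is.null(names(map)) || anyDuplicated(names(map)))
    stop("target map must be a list with unique algorithm names")
  for (alg in names(map)) {
    m <- map[[alg]]
    if (!is.list(m) || is.null(names(m)))
      stop("algorithm '", alg, "' must map miRNA ids to gene vectors")
    n <- lengths(m)
    if (any(n == 0))
      stop("algorithm '", alg, "' lists a miRNA with no targets: ",
           names(m)[which(n == 0)[1]])
  }
  invisible(map)
}

#' Construct a gene-set collection
#'
#' @param sets named list of non-empty character vectors of gene ids.
#' @param description,source optional character vectors parallel to `sets`.
#' @return named list of gene vectors with `"description"` and `"source"`
#'   attributes.
#' @export
gene_set_collection <- function(sets, description = NULL, source = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("gene sets must be a named list with unique set names")
  if (any(lengths(sets) == 0)) stop("gene sets must be non-empty")
  sets <- lapply(sets, as.character)
  if (is.null(description)) description <- rep("", length(sets))
  if (is.null(source)) source <- rep("", length(sets))
  attr(sets, "description") <- stats::setNames(as.character(description),
                                               names(sets))
  attr(sets, "source") <- stats::setNames(as.character(source), names(sets))
  sets
}

#' Construct a clinical/pathology table
#'
#' One row per patient.  `sample_ids` is a list-column mapping each patient
#' to the assay sample(s) profiled for them; survival endpoints are
#' distant-metastasis-free survival (DMFS) and breast-cancer-specific
#' survival (BCSS) given as positive times plus logical event indicators.
#'
#' @param df data.frame with columns `patient_id`, `sample_ids`
#'   (list-column), `er`, `pr`, `her2` (`pos`/`neg`/`unknown`), `grade`
#'   (1-3), `node_positive`, `lymph_infiltration_pct` (0-100),
#'   `tumour_size_cm` (> 0), `neoadjuvant`, `dmfs_time`, `dmfs_event`,
#'   `bcss_time`, `bcss_event`, optional `subtype`.
#' @return the validated data.frame.
#' @export
clinical_table <- function(df) {
  validate_clinical_table(df)
  df
}

CLINICAL_COLUMNS <- c("patient_id", "sample_ids", "er", "pr", "her2",
                      "grade", "node_positive", "lymph_infiltration_pct",
                      "tumour_size_cm", "neoadjuvant",
                      "dmfs_time", "dmfs_event", "bcss_time", "bcss_event")

validate_clinical_table <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(CLINICAL_COLUMNS, names(df))
  if (length(missing_cols))
    stop("clinical table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$patient_id)) stop("one row per patient required")
  if (!is.list(df$sample_ids)) stop("sample_ids must be a list-column")
  if (any(lengths(df$sample_ids) < 1)) stop("every patient needs >= 1 sample")
  sids <- unlist(df$sample_ids, use.names = FALSE)
  if (anyDuplicated(sids)) stop("a sample id is assigned to two patients")
  for (col in c("er", "pr", "her2"))
    if (!all(df[[col]] %in% RECEPTOR_LEVELS))
      stop(col, " status must be pos/neg/unknown")
  if (!all(df$grade %in% 1:3)) stop("grade must be 1, 2 or 3")
  stopifnot(is.logical(df$node_positive), is.logical(df$neoadjuvant),
            is.logical(df$dmfs_event), is.logical(df$bcss_event))
  if (any(df$lymph_infiltration_pct < 0 | df$lymph_infiltration_pct > 100))
    stop("lymphocytic infiltration must be a percentage in [0, 100]")
  if (any(df$tumour_size_cm <= 0)) stop("tumour size must be positive")
  if (any(df$dmfs_time <= 0) || any(df$bcss_time <= 0))
    stop("survival times must be positive")
  if ("subtype" %in% names(df)) {
    ok <- is.na(df$subtype) | df$subtype %in% SUBTYPES
    if (!all(ok)) stop("subtype must be one of ", paste(SUBTYPES, collapse = ", "))
  }
  invisible(df)
}

# sample id -> patient id lookup from the clinical table
sample_to_patient <- function(clinical) {
  n <- lengths(clinical$sample_ids)
  stats::setNames(rep(clinical$patient_id, n),
                  unlist(clinical$sample_ids, use.names = FALSE))
}
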