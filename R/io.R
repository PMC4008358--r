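# Readers and writers for the external file formats.
#
# All tabular formats are plain TSV.  Numeric values are written with the
# %.17g format so a write -> read round trip reproduces doubles exactly.

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

stop_at_line <- function(path, line, msg) {
  stop(basename(path), " line ", line, ": ", msg, call. = FALSE)
}

#' Read / write an expression or copy-number matrix
#'
#' TSV layout: first column holds feature ids, the header row holds sample
#' ids, remaining cells are numbers (decimal point, no NA).  An optional
#' companion flag file with identical layout carries detection codes
#' (0 = detected, 1 = not detected, 2 = saturated).
#'
#' @param path TSV file.
#' @param flags_path optional detection-flag TSV of identical layout.
#' @return numeric matrix (features x samples), with the flag matrix in
#'   `attr(x, "flags")` when `flags_path` is given.
#' @export
read_expression_matrix <- function(path, flags_path = NULL) {
  m <- read_matrix_tsv(path)
  x <- expression_matrix(m)
  if (!is.null(flags_path)) {
    f <- read_matrix_tsv(flags_path)
    if (!identical(dimnames(f), dimnames(x)))
      stop("flag matrix ", basename(flags_path),
           " does not match the expression matrix layout")
    x <- set_expression_flags(x, f)
  }
  x
}

#' @rdname read_expression_matrix
#' @param x matrix to write.
#' @export
write_expression_matrix <- function(x, path, flags_path = NULL) {
  write_matrix_tsv(x, path)
  fl <- expression_flags(x)
  if (!is.null(flags_path)) {
    if (is.null(fl)) stop("no flags attached to write to ", flags_path)
    write_matrix_tsv(fl, flags_path, integer = TRUE)
  }
  invisible(path)
}

#' @rdname read_expression_matrix
#' @export
read_copy_number_matrix <- function(path) copy_number_matrix(read_matrix_tsv(path))

#' @rdname read_expression_matrix
#' @export
write_copy_number_matrix <- function(x, path) write_matrix_tsv(x, path)

read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop_at_line(path, 1, "empty file")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  if (anyDuplicated(samples)) stop_at_line(path, 1, "duplicate sample ids")
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  nfield <- lengths(body)
  bad <- which(nfield != length(header))
  if (length(bad))
    stop_at_line(path, bad[1] + 1, "wrong number of fields")
  ids <- vapply(body, `[[`, "", 1)
  if (anyDuplicated(ids)) stop_at_line(path, which(duplicated(ids))[1] + 1,
                                       "duplicate feature id")
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1]), numeric(length(samples))))
  vals <- matrix(vals, ncol = length(samples), byrow = TRUE,
                 dimnames = list(ids, samples))
  if (anyNA(vals)) {
    row <- which(apply(is.na(vals), 1, any))[1]
    stop_at_line(path, row + 1, "non-numeric or missing value")
  }
  vals
}

write_matrix_tsv <- function(x, path, integer = FALSE) {
  cells <- if (integer) format(x) else fmt_num(x)
  cells <- matrix(trimws(cells), nrow = nrow(x))
  lines <- c(paste(c("feature_id", colnames(x)), collapse = "\t"),
             paste(rownames(x), apply(cells, 1, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write miRNA genomic loci (miRBase-style GFF3)
#'
#' Accepts the miRBase GFF3 dialect: records of type `miRNA` or
#' `miRNA_primary_transcript` whose `Name` attribute is the miRNA id.
#' Transposable-element co-location is not part of GFF3 and is supplied as a
#' separate one-id-per-line file.
#'
#' @param path GFF3 file.
#' @param te_path optional text file listing TE-co-located miRNA ids.
#' @return locus `data.frame` (see [mirna_loci()]).
#' @export
read_mirna_gff3 <- function(path, te_path = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% c("miRNA", "miRNA_primary_transcript")
  gr <- gr[keep]
  ids <- as.character(gr$Name)
  if (anyNA(ids) || any(ids == ""))
    stop("GFF3 record without a Name attribute in ", basename(path))
  if (anyDuplicated(ids))
    stop("duplicate miRNA Name in ", basename(path), ": ",
         ids[which(duplicated(ids))[1]])
  te <- character()
  if (!is.null(te_path)) {
    te <- trimws(readLines(te_path))
    te <- te[nzchar(te)]
  }
  mirna_loci(mirna_id = ids,
             chromosome = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                             "-", "+"),
             te_colocated = ids %in% te)
}

#' @rdname read_mirna_gff3
#' @param loci locus data.frame.
#' @export
write_mirna_gff3 <- function(loci, path, te_path = NULL) {
  validate_mirna_loci(loci)
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chromosome,
    ranges = IRanges::IRanges(loci$start, loci$end),
    strand = loci$strand)
  gr$type <- "miRNA"
  gr$source <- "mirnapt"
  gr$ID <- loci$mirna_id
  gr$Name <- loci$mirna_id
  rtracklayer::export(gr, path, format = "gff3")
  if (!is.null(te_path))
    writeLines(loci$mirna_id[loci$te_colocated], te_path)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file.
#' @param source optional source label applied to every set read.
#' @return a gene-set collection (see [gene_set_collection()]).
#' @export
read_gmt <- function(path, source = "") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop_at_line(path, short[1], "GMT line needs a name, description and >= 1 gene")
  nm <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(nm))
    stop_at_line(path, which(duplicated(nm))[1], "duplicate gene-set name")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  gene_set_collection(sets,
                      description = vapply(fields, `[[`, "", 2),
                      source = rep(source, length(sets)))
}

#' @rdname read_gmt
#' @param sets gene-set collection.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write genomic regions and cancer genes (BED-like)
#'
#' BED input uses 0-based half-open coordinates and is converted to the
#' internal 1-based inclusive convention on read; columns are chrom, start,
#' end, label, category.
#'
#' @param path BED file.
#' @return region `data.frame` (see [genomic_regions()]).
#' @export
read_region_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 5)
  if (length(bad))
    stop_at_line(path, bad[1], "BED line needs chrom, start, end, label, category")
  genomic_regions(chromosome = vapply(fields, `[[`, "", 1),
                  start = as.integer(vapply(fields, `[[`, "", 2)) + 1L,
                  end = as.integer(vapply(fields, `[[`, "", 3)),
                  label = vapply(fields, `[[`, "", 4),
                  category = vapply(fields, `[[`, "", 5))
}

#' @rdname read_region_bed
#' @param regions region data.frame.
#' @export
write_region_bed <- function(regions, path) {
  validate_genomic_regions(regions)
  writeLines(paste(regions$chromosome, regions$start - 1L, regions$end,
                   regions$label, regions$category, sep = "\t"), path)
  invisible(path)
}

#' Read / write the per-algorithm target-prediction map
#'
#' TSV with three columns: `algorithm<TAB>mirna<TAB>gene`.
#'
#' @param path TSV file.
#' @return target-prediction map (see [target_prediction_map()]).
#' @export
read_target_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("algorithm", "mirna_id", "gene_id") %in% names(df)))
    stop(basename(path), ": need columns algorithm, mirna_id, gene_id")
  map <- lapply(split(df, df$algorithm), function(d)
    lapply(split(d$gene_id, d$mirna_id), unique))
  target_prediction_map(map)
}

#' @rdname read_target_map
#' @param map target-prediction map.
#' @export
write_target_map <- function(map, path) {
  validate_target_map(map)
  rows <- lapply(names(map), function(alg) {
    m <- map[[alg]]
    data.frame(algorithm = alg,
               mirna_id = rep(names(m), lengths(m)),
               gene_id = unlist(m, use.names = FALSE),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the clinical table
#'
#' TSV with one row per patient; logical columns are encoded 0/1 and the
#' `sample_ids` column joins multiple sample ids with commas.
#'
#' @param path TSV file.
#' @return clinical `data.frame` (see [clinical_table()]).
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- setdiff(CLINICAL_COLUMNS, names(df))
  if (length(need))
    stop(basename(path), " lacks columns: ", paste(need, collapse = ", "))
  out <- data.frame(patient_id = df$patient_id, stringsAsFactors = FALSE)
  out$sample_ids <- strsplit(df$sample_ids, ",", fixed = TRUE)
  for (col in c("er", "pr", "her2")) out[[col]] <- df[[col]]
  out$grade <- as.integer(df$grade)
  for (col in c("node_positive", "neoadjuvant", "dmfs_event", "bcss_event"))
    out[[col]] <- df[[col]] == "1"
  for (col in c("lymph_infiltration_pct", "tumour_size_cm",
                "dmfs_time", "bcss_time"))
    out[[col]] <- as.numeric(df[[col]])
  if ("subtype" %in% names(df)) {
    out$subtype <- df$subtype
    out$subtype[out$subtype == ""] <- NA_character_
  }
  clinical_table(out)
}

#' @rdname read_clinical_table
#' @param clinical clinical data.frame.
#' @export
write_clinical_table <- function(clinical, path) {
  validate_clinical_table(clinical)
  df <- clinical
  df$sample_ids <- vapply(clinical$sample_ids, paste, "", collapse = ",")
  for (col in c("node_positive", "neoadjuvant", "dmfs_event", "bcss_event"))
    df[[col]] <- as.integer(df[[col]])
  for (col in c("lymph_infiltration_pct", "tumour_size_cm",
                "dmfs_time", "bcss_time"))
    df[[col]] <- trimws(fmt_num(df[[col]]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a subtype centroid matrix
#'
#' TSV with genes in rows and subtype names in the header.
#'
#' @param path TSV file.
#' @return numeric matrix genes x subtypes.
#' @export
read_centroids <- function(path) read_matrix_tsv(path)

#' @rdname read_centroids
#' @param centroids numeric matrix.
#' @export
write_centroids <- function(centroids, path) write_matrix_tsv(centroids, path)
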