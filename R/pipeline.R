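# End-to-end orchestration: preprocess -> copy-number association ->
# survival screening -> subtype analysis -> miRNAapt discovery -> pathway
# analysis, with structured logging, a reproducibility manifest and
# deterministic outputs under a single seed.
#
# All stage results are computed in memory first and written together at
# the end, so a failing stage aborts with its name and leaves no partial
# output files behind.

#' Pipeline configuration
#'
#' Collects the input file paths and every analysis threshold.  Threshold
#' defaults are the reference values used throughout the package: gains
#' above 2.3 copies and losses below 1.7; copy-number association at
#' q < 0.05 and rho > 0.25; prognostic calls at Wald p < 0.002 and FDR
#' q < 0.2; subtype-specific miRNAs at ANOVA q < 0.001 and two-group
#' contrasts at q < 0.01; anti-correlation below Spearman -0.3 with
#' miRNAapt enrichment at min(q) < 0.05; targeted gene sets at Fisher
#' p < 0.001, overlap > 3 and set size < 500; pathway correlations at
#' |rho| > 0.5, p < 1e-6 and group ANOVA p < 1e-4.
#'
#' @param input_dir directory holding the cohort files (layout of
#'   [write_cohort()]).
#' @param out_dir output directory.
#' @param seed integer seed fanned out to the stages that use randomness.
#' @param thresholds named list overriding individual defaults (see
#'   Details).
#' @return configuration list (class `"pipeline_config"`).
#' @export
pipeline_config <- function(input_dir, out_dir, seed = 1,
                            thresholds = list()) {
  defaults <- list(
    max_bad_samples = 10,
    gain_above = 2.3, loss_below = 1.7, cn_q = 0.05, cn_rho = 0.25,
    cn_min_group = 3, cn_window = 10000,
    surv_p = 0.002, surv_q = 0.2,
    subtype_q = 0.001, contrast_q = 0.01,
    anti_rho = -0.3, mirnapt_q = 0.05, min_targets = 10,
    targeted_p = 0.001, targeted_overlap = 3, targeted_max_size = 500,
    pathway_rho = 0.5, pathway_p = 1e-6, pathway_anova = 1e-4,
    n_boot = 10000, n_perm = 10000)
  unknown <- setdiff(names(thresholds), names(defaults))
  if (length(unknown))
    stop("unknown threshold(s): ", paste(unknown, collapse = ", "))
  defaults[names(thresholds)] <- thresholds
  cfg <- list(input_dir = input_dir, out_dir = out_dir,
              seed = as.integer(seed), thresholds = defaults)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `input_dir`, `out_dir`, `seed` and an optional
#' `thresholds` mapping.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(input_dir = y$input_dir, out_dir = y$out_dir,
                  seed = if (is.null(y$seed)) 1 else y$seed,
                  thresholds = if (is.null(y$thresholds)) list() else
                    y$thresholds)
}

# deterministic per-stage child seeds derived from the global seed
stage_seed <- function(seed, k) (seed %% 1000003L) * 1009L + k

log_stage <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Run the integrated analysis pipeline
#'
#' Executes preprocess, copy-number association, survival screening,
#' subtype analysis, miRNAapt discovery and pathway analysis on the cohort
#' in `config$input_dir`, then writes every result table plus a
#' reproducibility manifest (input checksums, configuration, seed) to
#' `config$out_dir`.  Re-running with identical inputs and seed produces
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the list of in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  th <- config$thresholds
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## ---- load -------------------------------------------------------------
  inputs <- run_stage("load", function() {
    f <- function(nm) file.path(config$input_dir, COHORT_FILES[[nm]])
    for (nm in c("mirna_expr", "gene_expr", "cn", "loci", "targets",
                 "gene_sets", "regions", "clinical", "centroids"))
      if (!file.exists(f(nm)))
        stop("missing input file: ", f(nm))
    flags <- if (file.exists(f("mirna_flags"))) f("mirna_flags") else NULL
    te <- if (file.exists(f("te"))) f("te") else NULL
    list(mirna_expr = read_expression_matrix(f("mirna_expr"),
                                             flags_path = flags),
         gene_expr = read_expression_matrix(f("gene_expr")),
         cn = read_copy_number_matrix(f("cn")),
         loci = read_mirna_gff3(f("loci"), te_path = te),
         targets = read_target_map(f("targets")),
         gene_sets = read_gmt(f("gene_sets")),
         regions = read_region_bed(f("regions")),
         clinical = read_clinical_table(f("clinical")),
         centroids = read_centroids(f("centroids")))
  })

  ## ---- preprocess -------------------------------------------------------
  pre <- run_stage("preprocess", function() {
    me <- inputs$mirna_expr
    n0 <- nrow(me)
    if (!is.null(expression_flags(me))) {
      me <- filter_undetected(me, max_bad_samples = th$max_bad_samples)
      log_stage("preprocess", "detection filter: ", n0, " -> ", nrow(me),
                " miRNAs")
    } else {
      warning("no detection flags: skipping the detection filter")
    }
    me <- average_replicates(me, inputs$clinical)
    ge <- average_replicates(inputs$gene_expr, inputs$clinical)
    cn <- average_replicates(inputs$cn, inputs$clinical)
    log_stage("preprocess", "replicates averaged: ", ncol(inputs$mirna_expr),
              " samples -> ", ncol(me), " patients")
    list(mirna_expr = me, gene_expr = ge, cn = cn)
  })

  ## ---- copy-number association -------------------------------------------
  cn_res <- run_stage("cn_association", function() {
    loci_ok <- exclude_te_mirnas(inputs$loci)
    log_stage("cn_association", "TE exclusion: ", nrow(inputs$loci), " -> ",
              nrow(loci_ok), " loci")
    assoc <- cn_expression_association(
      pre$mirna_expr, pre$cn, loci = inputs$loci,
      q_threshold = th$cn_q, rho_threshold = th$cn_rho,
      gain_above = th$gain_above, loss_below = th$loss_below,
      min_group = th$cn_min_group)
    rec <- annotate_recurrent_regions(loci_ok, inputs$regions)
    cg <- colocated_cancer_genes(loci_ok, inputs$regions,
                                 window = th$cn_window)
    assoc$recurrent_regions <- vapply(assoc$mirna_id, function(m)
      paste(rec[[m]], collapse = ";"), "")
    assoc$colocated_genes <- vapply(assoc$mirna_id, function(m) {
      g <- cg[[m]]
      if (is.null(g) || !nrow(g)) "" else
        paste(paste0(g$label, "(", g$category, ")"), collapse = ";")
    }, "")
    log_stage("cn_association", sum(assoc$cn_driven),
              " copy-number-driven miRNA(s)")
    assoc
  })

  ## ---- survival ----------------------------------------------------------
  surv_res <- run_stage("survival", function() {
    ladder <- list(character(),
                   c("node_positive", "tumour_size_cm"),
                   c("node_positive", "tumour_size_cm", "lymph_high"))
    out <- list()
    for (endpoint in ENDPOINTS) for (cohort in COHORTS)
      for (covs in ladder) {
        r <- tryCatch(
          cox_multivariate(pre$mirna_expr, inputs$clinical,
                           endpoint = endpoint, cohort = cohort,
                           covariates = covs,
                           p_threshold = th$surv_p,
                           q_threshold = th$surv_q),
          error = function(e) NULL)
        if (!is.null(r)) out[[length(out) + 1L]] <- r
      }
    res <- do.call(rbind, out)
    log_stage("survival", sum(res$prognostic), " prognostic call(s) over ",
              length(out), " screen(s)")
    res
  })

  ## ---- subtype -----------------------------------------------------------
  sub_res <- run_stage("subtype", function() {
    assign <- assign_subtypes(pre$gene_expr, inputs$centroids)
    labels <- stats::setNames(assign$subtype, assign$sample_id)
    specific <- subtype_specific_mirnas(pre$mirna_expr, labels,
                                        q_threshold = th$subtype_q)
    log_stage("subtype", sum(specific$subtype_specific),
              " subtype-specific miRNA(s)")
    cl <- inputs$clinical
    pid <- colnames(pre$mirna_expr)
    cli <- cl[match(pid, cl$patient_id), ]
    contrasts <- list(
      er_neg_vs_pos = ifelse(cli$er == "unknown", NA, cli$er == "neg"),
      tnbc_vs_rest = cli$er == "neg" & cli$pr == "neg" & cli$her2 == "neg",
      grade_high_vs_low = cli$grade == 3)
    contrast_res <- lapply(names(contrasts), function(nm) {
      g <- contrasts[[nm]]
      keep <- !is.na(g)
      r <- tryCatch(group_contrast_mirnas(
        pre$mirna_expr[, keep, drop = FALSE], g[keep],
        q_threshold = th$contrast_q), error = function(e) NULL)
      if (!is.null(r)) r$contrast <- nm
      r
    })
    contrast_res <- do.call(rbind, contrast_res)
    list(assignments = assign, specific = specific,
         contrasts = contrast_res)
  })

  ## ---- miRNAapt ----------------------------------------------------------
  apt_res <- run_stage("mirnapt", function() {
    res <- mirnapt_enrichment(pre$mirna_expr, pre$gene_expr,
                              inputs$targets,
                              rho_threshold = th$anti_rho,
                              q_threshold = th$mirnapt_q,
                              min_targets = th$min_targets)
    log_stage("mirnapt", sum(res$table$is_mirnapt), " miRNAapt call(s)")
    res
  })

  ## ---- pathways ----------------------------------------------------------
  path_res <- run_stage("pathways", function() {
    scores <- score_gene_sets(pre$gene_expr, inputs$gene_sets)
    prog <- surv_res[surv_res$model == "" & surv_res$prognostic, ]
    groups <- NULL
    if (nrow(prog) >= 4 &&
        length(unique(prog$direction[!is.na(prog$direction)])) == 2) {
      groups <- tapply(prog$direction, prog$mirna_id, function(d) d[1])
      groups <- stats::setNames(as.character(groups), names(groups))
      log_stage("pathways", "grouping ", length(groups),
                " prognostic miRNA(s) by direction")
    } else {
      spec <- sub_res$specific
      spec <- spec[spec$subtype_specific, ]
      if (nrow(spec) >= 4 && length(unique(spec$peak_subtype)) >= 2) {
        groups <- stats::setNames(spec$peak_subtype, spec$mirna_id)
        log_stage("pathways", "grouping ", length(groups),
                  " subtype-specific miRNA(s) by peak subtype")
      }
    }
    correlations <- NULL
    clusters <- NULL
    if (!is.null(groups)) {
      correlations <- mirna_pathway_correlations(
        pre$mirna_expr, scores, groups,
        rho_threshold = th$pathway_rho, p_threshold = th$pathway_p,
        anova_threshold = th$pathway_anova)
      mir_sel <- unique(correlations$mirna_id)
      if (length(mir_sel) >= 3 && nrow(scores) >= 3) {
        rho_mat <- matrix(correlations$rho, nrow = length(mir_sel),
                          dimnames = list(mir_sel,
                                          unique(correlations$set_name)))
        clusters <- cluster_with_bootstrap(rho_mat, n_boot = th$n_boot,
                                           seed = stage_seed(config$seed, 6))
      }
    } else {
      log_stage("pathways", "no usable miRNA grouping; ",
                "correlation selection skipped")
    }
    targeted <- targeted_gene_sets(apt_res, inputs$gene_sets,
                                   p_threshold = th$targeted_p,
                                   min_overlap = th$targeted_overlap,
                                   max_set_size = th$targeted_max_size)
    log_stage("pathways", sum(targeted$selected),
              " targeted gene-set assignment(s)")
    list(scores = scores, correlations = correlations,
         clusters = clusters, targeted = targeted)
  })

  ## ---- write -------------------------------------------------------------
  run_stage("write", function() {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    o <- function(nm) file.path(config$out_dir, nm)
    wt <- function(df, nm) utils::write.table(
      df, o(nm), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(cn_res, "cn_association.tsv")
    wt(surv_res, "survival_screen.tsv")
    wt(sub_res$assignments, "subtype_assignments.tsv")
    wt(sub_res$specific, "subtype_mirnas.tsv")
    if (!is.null(sub_res$contrasts)) wt(sub_res$contrasts,
                                        "group_contrasts.tsv")
    wt(apt_res$table, "mirnapt.tsv")
    wt(apt_res$by_algorithm, "mirnapt_by_algorithm.tsv")
    apt_sets <- lapply(apt_res$anticorrelated_targets, `[[`, "union")
    apt_sets <- apt_sets[lengths(apt_sets) > 0]
    if (length(apt_sets))
      write_gmt(gene_set_collection(
        stats::setNames(apt_sets, paste0("ANTICORR_", names(apt_sets)))),
        o("mirnapt_targets.gmt"))
    write_matrix_tsv(path_res$scores, o("gene_set_scores.tsv"))
    if (!is.null(path_res$correlations))
      wt(path_res$correlations, "pathway_correlations.tsv")
    if (!is.null(path_res$clusters)) {
      ape::write.tree(ape::as.phylo(path_res$clusters$row_hclust),
                      o("mirna_dendrogram.nwk"))
      ape::write.tree(ape::as.phylo(path_res$clusters$col_hclust),
                      o("gene_set_dendrogram.nwk"))
      wt(path_res$clusters$row_clusters, "mirna_cluster_stability.tsv")
    }
    wt(path_res$targeted, "targeted_gene_sets.tsv")
    manifest <- list(
      seed = config$seed,
      thresholds = config$thresholds,
      inputs = as.list(tools::md5sum(
        sort(list.files(config$input_dir, full.names = TRUE)))),
      counts = list(
        patients = ncol(pre$mirna_expr),
        mirnas_analysed = nrow(pre$mirna_expr),
        genes = nrow(pre$gene_expr),
        cn_driven = sum(cn_res$cn_driven),
        prognostic_calls = sum(surv_res$prognostic),
        subtype_specific = sum(sub_res$specific$subtype_specific),
        mirnapt = sum(apt_res$table$is_mirnapt),
        targeted_sets = sum(path_res$targeted$selected)))
    yaml::write_yaml(manifest, o("manifest.yaml"))
    invisible(NULL)
  })

  invisible(list(inputs = inputs, preprocessed = pre, cn = cn_res,
                 survival = surv_res, subtype = sub_res, mirnapt = apt_res,
                 pathways = path_res))
}

#' Summarise the result tables of a pipeline run
#'
#' @param out_dir directory written by [run_pipeline()].
#' @return invisibly, a named list of result data.frames.
#' @export
report_pipeline <- function(out_dir) {
  files <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  if (!length(files)) {
    message("no results found in ", out_dir)
    return(invisible(list()))
  }
  out <- list()
  for (f in files) {
    df <- utils::read.table(f, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    out[[basename(f)]] <- df
    message(basename(f), ": ", nrow(df), " row(s)")
    flag_cols <- intersect(c("cn_driven", "prognostic", "subtype_specific",
                             "is_mirnapt", "selected", "differential"),
                           names(df))
    for (fc in flag_cols)
      message("  ", fc, ": ", sum(df[[fc]] %in% c(TRUE, "TRUE")))
  }
  invisible(out)
}
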