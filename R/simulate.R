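# Synthetic multi-omics cohort generator with plantable ground truth.
#
# The generator emits a matched breast-tumour-like cohort: subtype-structured
# gene expression with matching classification centroids, miRNA expression,
# miRNA-level absolute DNA copy numbers correlated with expression at
# planted loci, per-algorithm predicted-target maps seeded with true
# targets, gene sets (random plus one TRUE_TARGETS_<mirna> set per planted
# repressor), genomic loci/regions, and a clinical table with exponential
# survival endpoints whose hazard depends on planted miRNAs.  Every planted
# effect is recorded in a ground-truth object so downstream stages can be
# validated by recovery.

#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic cohort.  The
#' defaults describe the reference cohort used throughout the package's
#' validation: 200 patients in five intrinsic subtypes (basal-enriched, as
#' in triple-negative-rich series), 300 miRNAs, 5000 genes, 10
#' copy-number-driven miRNAs (aberration frequency 0.3, one-copy gains or
#' losses, 1-SD expression shift per copy), 3 prognostic miRNAs (log hazard
#' ratio 0.7 per SD), 10 repressor miRNAs ("miRNAapt": 30% of their 100
#' predicted targets are true targets with repression slope -1), and 10
#' subtype-specific miRNAs (1.5-SD mean shift), 5 of which are also
#' copy-number driven with the aberration concentrated in their peak
#' subtype (mirroring basal-like copy-gain-driven miRNA clusters).
#'
#' @param n_patients,n_mirnas,n_genes cohort dimensions.
#' @param replicate_fraction fraction of patients profiled twice.
#' @param subtype_proportions named vector over basal/lumA/lumB/her2/normal
#'   summing to 1.
#' @param planted_cn_driven data.frame(mirna, frequency, direction,
#'   shift_sd): miRNA row index, aberration frequency, `"gain"` or
#'   `"loss"`, expression shift (in noise SDs) per copy.
#' @param planted_prognostic data.frame(mirna, endpoint, log_hazard_per_sd).
#' @param planted_mirnapt data.frame(mirna, true_target_fraction,
#'   repression_slope), slopes negative.
#' @param planted_subtype_mirnas data.frame(mirna, subtype, mean_shift_sd).
#' @param targets_per_mirna predicted targets per miRNA and algorithm.
#' @param n_algorithms,algorithm_agreement number of prediction algorithms
#'   and the probability that an algorithm lists a true target.
#' @param n_gene_sets,genes_per_set random gene sets and their size range.
#' @param noise_sd residual expression SD (log scale).
#' @param baseline_hazard,censoring_rate exponential survival parameters
#'   (events per time unit; approximate fraction censored).
#' @param te_fraction fraction of miRNAs flagged as co-located with
#'   transposable elements.
#' @param n_signature_genes,signature_separation_sd size of the subtype
#'   signature panel and the SD of the subtype-specific centroid pattern
#'   (in noise SDs).
#' @param cn_noise_sd,replicate_noise_sd measurement noise on copy numbers
#'   and on replicate samples.
#' @param n_undetected_mirnas miRNAs planted to fail the detection filter.
#' @param neoadjuvant_n patients marked as neo-adjuvant treated.
#' @param covariate_effects named numeric vector of additional log hazards
#'   on encoded covariates (e.g. `c(lymph_high = 0.8)`).
#' @param confounded_mirna,confounding_strength optional miRNA index whose
#'   expression is coupled to lymphocytic infiltration.
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @return validated configuration (class `"sim_config"`).
#' @export
simulation_config <- function(
    n_patients = 200, replicate_fraction = 0.04,
    n_mirnas = 300, n_genes = 5000,
    subtype_proportions = c(basal = 0.45, lumA = 0.20, lumB = 0.15,
                            her2 = 0.10, normal = 0.10),
    planted_cn_driven = data.frame(
      mirna = 1:10,
      frequency = 0.3,
      direction = c(rep("gain", 3), "loss", "loss", rep("gain", 5)),
      shift_sd = 1),
    planted_prognostic = data.frame(
      mirna = 21:23,
      endpoint = c("DMFS", "DMFS", "BCSS"),
      log_hazard_per_sd = c(0.7, -0.7, 0.7)),
    planted_mirnapt = data.frame(
      mirna = 41:50, true_target_fraction = 0.3, repression_slope = -1),
    planted_subtype_mirnas = data.frame(
      mirna = c(6:10, 61:65),
      subtype = c(rep("basal", 5), "lumA", "lumA", "lumB", "her2", "normal"),
      mean_shift_sd = 1.5),
    targets_per_mirna = 100, n_algorithms = 6, algorithm_agreement = 0.8,
    n_gene_sets = 200, genes_per_set = c(20, 100),
    noise_sd = 1, baseline_hazard = 0.08, censoring_rate = 0.3,
    te_fraction = 0.1,
    n_signature_genes = 50, signature_separation_sd = 1,
    cn_noise_sd = 0.05, replicate_noise_sd = 0.2,
    n_undetected_mirnas = 5, neoadjuvant_n = 3,
    covariate_effects = numeric(), confounded_mirna = 0,
    confounding_strength = 0,
    seed = 1) {
  cfg <- list(n_patients = n_patients, replicate_fraction = replicate_fraction,
              n_mirnas = n_mirnas, n_genes = n_genes,
              subtype_proportions = subtype_proportions,
              planted_cn_driven = as.data.frame(planted_cn_driven),
              planted_prognostic = as.data.frame(planted_prognostic),
              planted_mirnapt = as.data.frame(planted_mirnapt),
              planted_subtype_mirnas = as.data.frame(planted_subtype_mirnas),
              targets_per_mirna = targets_per_mirna,
              n_algorithms = n_algorithms,
              algorithm_agreement = algorithm_agreement,
              n_gene_sets = n_gene_sets, genes_per_set = genes_per_set,
              noise_sd = noise_sd, baseline_hazard = baseline_hazard,
              censoring_rate = censoring_rate, te_fraction = te_fraction,
              n_signature_genes = n_signature_genes,
              signature_separation_sd = signature_separation_sd,
              cn_noise_sd = cn_noise_sd,
              replicate_noise_sd = replicate_noise_sd,
              n_undetected_mirnas = n_undetected_mirnas,
              neoadjuvant_n = neoadjuvant_n,
              covariate_effects = covariate_effects,
              confounded_mirna = confounded_mirna,
              confounding_strength = confounding_strength,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (abs(sum(cfg$subtype_proportions) - 1) > 1e-9)
    stop("subtype proportions must sum to 1")
  if (!all(names(cfg$subtype_proportions) %in% SUBTYPES))
    stop("subtype proportions must be named over ",
         paste(SUBTYPES, collapse = ", "))
  planted <- c(cfg$planted_cn_driven$mirna, cfg$planted_prognostic$mirna,
               cfg$planted_mirnapt$mirna, cfg$planted_subtype_mirnas$mirna)
  if (length(planted) && (min(planted) < 1 || max(planted) > cfg$n_mirnas))
    stop("planted miRNA index out of range 1..n_mirnas")
  if (nrow(cfg$planted_mirnapt)) {
    if (any(cfg$planted_mirnapt$repression_slope >= 0))
      stop("repression slopes must be negative")
    n_true <- round(cfg$planted_mirnapt$true_target_fraction *
                      cfg$targets_per_mirna)
    if (any(n_true > cfg$targets_per_mirna))
      stop("true targets exceed targets_per_mirna: infeasible configuration")
  }
  if (nrow(cfg$planted_cn_driven) &&
      !all(cfg$planted_cn_driven$direction %in% c("gain", "loss")))
    stop("copy-number direction must be 'gain' or 'loss'")
  if (nrow(cfg$planted_prognostic) &&
      !all(cfg$planted_prognostic$endpoint %in% ENDPOINTS))
    stop("prognostic endpoint must be DMFS or BCSS")
  if (cfg$censoring_rate < 0 || cfg$censoring_rate >= 1)
    stop("censoring rate must lie in [0, 1)")
  if (max(cfg$genes_per_set) > cfg$n_genes)
    stop("gene sets larger than n_genes: infeasible configuration")
  if (cfg$targets_per_mirna > cfg$n_genes)
    stop("targets_per_mirna exceeds n_genes: infeasible configuration")
  if (cfg$noise_sd <= 0 || cfg$baseline_hazard <= 0)
    stop("noise_sd and baseline_hazard must be positive")
  invisible(cfg)
}

#' Read a simulation configuration from YAML
#'
#' Planted-effect blocks are given as lists of records (fields as in the
#' corresponding `planted_*` data.frames); omitted fields take the
#' [simulation_config()] defaults.
#'
#' @param path YAML file.
#' @return configuration (class `"sim_config"`).
#' @export
read_simulation_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (f in grep("^planted_", names(y), value = TRUE))
    y[[f]] <- do.call(rbind, lapply(y[[f]], as.data.frame))
  if (!is.null(y$subtype_proportions))
    y$subtype_proportions <- unlist(y$subtype_proportions)
  if (!is.null(y$covariate_effects))
    y$covariate_effects <- unlist(y$covariate_effects)
  if (!is.null(y$genes_per_set)) y$genes_per_set <- unlist(y$genes_per_set)
  do.call(simulation_config, y)
}

#' Simulate a matched multi-omics cohort
#'
#' Deterministic given the configuration (including its seed).  See
#' [simulation_config()] for the generative model and the reference
#' defaults.
#'
#' @param config a `"sim_config"` object.
#' @return list with `mirna_expr` (sample level, detection flags attached),
#'   `gene_expr`, `cn`, `loci`, `targets`, `gene_sets`, `regions`,
#'   `clinical`, `centroids` and `truth` (the planted ground truth,
#'   including per-patient subtype labels and true target gene lists).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  patients <- sprintf("P%04d", seq_len(cfg$n_patients))
  mirnas <- sprintf("sim-mir-%03d", seq_len(cfg$n_mirnas))
  genes <- sprintf("GENE%05d", seq_len(cfg$n_genes))
  subtypes <- names(cfg$subtype_proportions)
  subtype <- sample(subtypes, cfg$n_patients, replace = TRUE,
                    prob = cfg$subtype_proportions)

  ## --- miRNA expression and copy number (patient level) ----------------
  mu_m <- stats::rnorm(cfg$n_mirnas, 6, 1)
  cn <- matrix(2 + stats::rnorm(cfg$n_mirnas * cfg$n_patients, 0,
                                cfg$cn_noise_sd),
               cfg$n_mirnas, cfg$n_patients,
               dimnames = list(mirnas, patients))
  M <- matrix(stats::rnorm(cfg$n_mirnas * cfg$n_patients, 0, cfg$noise_sd),
              cfg$n_mirnas, cfg$n_patients,
              dimnames = list(mirnas, patients)) + mu_m

  sub_of <- stats::setNames(cfg$planted_subtype_mirnas$subtype,
                            cfg$planted_subtype_mirnas$mirna)
  if (nrow(cfg$planted_cn_driven)) for (i in seq_len(nrow(cfg$planted_cn_driven))) {
    row <- cfg$planted_cn_driven[i, ]
    m <- row$mirna
    freq <- rep(row$frequency, cfg$n_patients)
    peak <- sub_of[as.character(m)]
    if (!is.na(peak)) {
      # jointly planted subtype+CN miRNA: concentrate the aberration in the
      # peak subtype while keeping the marginal frequency
      prop <- cfg$subtype_proportions[[peak]]
      f_peak <- min(0.9, row$frequency * 1.8)
      f_other <- max(0, (row$frequency - prop * f_peak) / (1 - prop))
      freq <- ifelse(subtype == peak, f_peak, f_other)
    }
    hit <- stats::runif(cfg$n_patients) < freq
    delta <- if (row$direction == "gain") 1 else -1
    cn[m, ] <- cn[m, ] + delta * hit
    M[m, ] <- M[m, ] + row$shift_sd * cfg$noise_sd * (cn[m, ] - 2)
  }
  if (nrow(cfg$planted_subtype_mirnas))
    for (i in seq_len(nrow(cfg$planted_subtype_mirnas))) {
      row <- cfg$planted_subtype_mirnas[i, ]
      M[row$mirna, subtype == row$subtype] <-
        M[row$mirna, subtype == row$subtype] +
        row$mean_shift_sd * cfg$noise_sd
    }

  ## --- clinical covariates ----------------------------------------------
  lymph_noise <- stats::rnorm(cfg$n_patients)
  lymph_base <- stats::runif(cfg$n_patients, 0, 40)
  if (cfg$confounded_mirna > 0 && cfg$confounding_strength != 0) {
    z <- as.vector(scale(M[cfg$confounded_mirna, ]))
    lymph_base <- pmin(100, pmax(0, 20 + 12 * (cfg$confounding_strength * z +
                                                 lymph_noise)))
  }
  receptor <- function(p_pos) ifelse(stats::runif(cfg$n_patients) < p_pos,
                                     "pos", "neg")
  er <- receptor(c(basal = 0.05, lumA = 0.95, lumB = 0.9, her2 = 0.4,
                   normal = 0.5)[subtype])
  pr <- receptor(c(basal = 0.05, lumA = 0.8, lumB = 0.6, her2 = 0.3,
                   normal = 0.5)[subtype])
  her2 <- receptor(c(basal = 0.05, lumA = 0.1, lumB = 0.3, her2 = 0.95,
                     normal = 0.1)[subtype])
  grade_probs <- list(basal = c(0.05, 0.20, 0.75), lumA = c(0.50, 0.40, 0.10),
                      lumB = c(0.15, 0.55, 0.30), her2 = c(0.05, 0.30, 0.65),
                      normal = c(0.30, 0.50, 0.20))
  grade <- vapply(subtype, function(s)
    sample(1:3, 1, prob = grade_probs[[s]]), 0L)
  clinical <- data.frame(patient_id = patients, stringsAsFactors = FALSE)
  clinical$sample_ids <- as.list(paste0(patients, "-s1"))
  clinical$er <- er; clinical$pr <- pr; clinical$her2 <- her2
  clinical$grade <- grade
  clinical$node_positive <- stats::runif(cfg$n_patients) < 0.4
  clinical$lymph_infiltration_pct <- lymph_base
  clinical$tumour_size_cm <- stats::rlnorm(cfg$n_patients, log(2.2), 0.35)
  clinical$neoadjuvant <- FALSE
  if (cfg$neoadjuvant_n > 0)
    clinical$neoadjuvant[sample.int(cfg$n_patients,
                                    min(cfg$neoadjuvant_n,
                                        cfg$n_patients))] <- TRUE

  ## --- survival endpoints ------------------------------------------------
  cov_lp <- rep(0, cfg$n_patients)
  if (length(cfg$covariate_effects)) {
    enc <- data.frame(grade_high = grade == 3,
                      node_positive = clinical$node_positive,
                      lymph_high = clinical$lymph_infiltration_pct >= 15,
                      tumour_size_cm = clinical$tumour_size_cm)
    for (nm in names(cfg$covariate_effects))
      cov_lp <- cov_lp + cfg$covariate_effects[[nm]] * as.numeric(enc[[nm]])
  }
  gen_endpoint <- function(endpoint) {
    lp <- cov_lp
    pl <- cfg$planted_prognostic
    pl <- pl[pl$endpoint == endpoint, , drop = FALSE]
    if (nrow(pl)) for (i in seq_len(nrow(pl)))
      lp <- lp + pl$log_hazard_per_sd[i] * as.vector(scale(M[pl$mirna[i], ]))
    hz <- cfg$baseline_hazard * exp(lp)
    t_event <- stats::rexp(cfg$n_patients, rate = hz)
    if (cfg$censoring_rate > 0) {
      c_rate <- cfg$baseline_hazard * cfg$censoring_rate /
        (1 - cfg$censoring_rate)
      t_cens <- stats::rexp(cfg$n_patients, rate = c_rate)
    } else t_cens <- rep(Inf, cfg$n_patients)
    list(time = pmin(t_event, t_cens), event = t_event <= t_cens)
  }
  dm <- gen_endpoint("DMFS"); bc <- gen_endpoint("BCSS")
  clinical$dmfs_time <- dm$time; clinical$dmfs_event <- dm$event
  clinical$bcss_time <- bc$time; clinical$bcss_event <- bc$event
  clinical$subtype <- subtype

  ## --- gene expression with subtype signature and planted repression ----
  mu_g <- stats::rnorm(cfg$n_genes, 8, 1)
  sig_idx <- seq_len(min(cfg$n_signature_genes, cfg$n_genes))
  delta <- matrix(stats::rnorm(length(sig_idx) * length(subtypes), 0,
                               cfg$signature_separation_sd * cfg$noise_sd),
                  length(sig_idx), length(subtypes),
                  dimnames = list(genes[sig_idx], subtypes))
  G <- matrix(stats::rnorm(cfg$n_genes * cfg$n_patients, 0, cfg$noise_sd),
              cfg$n_genes, cfg$n_patients,
              dimnames = list(genes, patients)) + mu_g
  G[sig_idx, ] <- G[sig_idx, ] + delta[, subtype]
  centroids <- mu_g[sig_idx] + delta

  true_targets <- list()
  if (nrow(cfg$planted_mirnapt)) {
    pool <- setdiff(seq_len(cfg$n_genes), sig_idx)
    for (i in seq_len(nrow(cfg$planted_mirnapt))) {
      row <- cfg$planted_mirnapt[i, ]
      n_true <- round(row$true_target_fraction * cfg$targets_per_mirna)
      tt <- sample(pool, n_true)
      pool <- setdiff(pool, tt)
      z <- as.vector(scale(M[row$mirna, ]))
      G[tt, ] <- G[tt, ] + row$repression_slope * cfg$noise_sd *
        matrix(z, length(tt), cfg$n_patients, byrow = TRUE)
      true_targets[[mirnas[row$mirna]]] <- genes[tt]
    }
  }

  ## --- predicted targets --------------------------------------------------
  algorithms <- sprintf("algo%d", seq_len(cfg$n_algorithms))
  targets <- stats::setNames(vector("list", cfg$n_algorithms), algorithms)
  for (alg in algorithms) {
    per_mirna <- lapply(seq_len(cfg$n_mirnas), function(m) {
      tt <- true_targets[[mirnas[m]]]
      if (!is.null(tt))
        tt <- tt[stats::runif(length(tt)) < cfg$algorithm_agreement]
      decoys <- sample(setdiff(genes, tt),
                       cfg$targets_per_mirna - length(tt))
      c(tt, decoys)
    })
    targets[[alg]] <- stats::setNames(per_mirna, mirnas)
  }

  ## --- gene sets -----------------------------------------------------------
  set_sizes <- sample(cfg$genes_per_set[1]:cfg$genes_per_set[2],
                      cfg$n_gene_sets, replace = TRUE)
  sets <- lapply(set_sizes, function(k) sample(genes, k))
  names(sets) <- sprintf("SET%03d", seq_len(cfg$n_gene_sets))
  desc <- rep("random gene set", cfg$n_gene_sets)
  src <- rep("random", cfg$n_gene_sets)
  if (length(true_targets)) {
    tt_names <- paste0("TRUE_TARGETS_", names(true_targets))
    sets <- c(sets, stats::setNames(unname(true_targets), tt_names))
    desc <- c(desc, rep("planted true target genes", length(true_targets)))
    src <- c(src, rep("truth", length(true_targets)))
  }
  gene_sets <- gene_set_collection(sets, description = desc, source = src)

  ## --- loci, TE flags, regions and cancer genes ---------------------------
  chrom <- sample(sprintf("chr%d", 1:22), cfg$n_mirnas, replace = TRUE)
  within <- stats::ave(seq_len(cfg$n_mirnas), chrom, FUN = seq_along)
  start <- 1000000L * within + sample.int(500000L, cfg$n_mirnas,
                                          replace = TRUE)
  te_pool <- setdiff(seq_len(cfg$n_mirnas), cfg$planted_cn_driven$mirna)
  n_te <- min(round(cfg$te_fraction * cfg$n_mirnas), length(te_pool))
  te_idx <- sample(te_pool, n_te)
  loci <- mirna_loci(mirna_id = mirnas, chromosome = chrom,
                     start = start, end = start + 81L,
                     strand = sample(c("+", "-"), cfg$n_mirnas,
                                     replace = TRUE),
                     te_colocated = seq_len(cfg$n_mirnas) %in% te_idx)

  regions <- data.frame(chromosome = character(), start = integer(),
                        end = integer(), label = character(),
                        category = character(), stringsAsFactors = FALSE)
  if (nrow(cfg$planted_cn_driven)) {
    covered <- cfg$planted_cn_driven[seq(1, nrow(cfg$planted_cn_driven),
                                         by = 2), , drop = FALSE]
    regions <- rbind(regions, data.frame(
      chromosome = chrom[covered$mirna],
      start = pmax(1L, start[covered$mirna] - 50000L),
      end = start[covered$mirna] + 81L + 50000L,
      label = sprintf("%s_%s", ifelse(covered$direction == "gain",
                                      "amp", "del"), mirnas[covered$mirna]),
      category = ifelse(covered$direction == "gain",
                        "recurrent_amplification", "recurrent_deletion"),
      stringsAsFactors = FALSE))
    near <- utils::head(cfg$planted_cn_driven, 3)
    regions <- rbind(regions, data.frame(
      chromosome = chrom[near$mirna],
      start = start[near$mirna] + 82L + 5000L,
      end = start[near$mirna] + 82L + 7000L,
      label = sprintf("CG_%s", mirnas[near$mirna]),
      category = ifelse(near$direction == "gain", "oncogene",
                        "tumour_suppressor"),
      stringsAsFactors = FALSE))
  }
  regions <- rbind(regions, data.frame(
    chromosome = c("chr1", "chr2", "chr3"),
    start = c(900L, 950L, 990L) * 1000000L,
    end = c(900L, 950L, 990L) * 1000000L + 200000L,
    label = c("decoy_amp", "decoy_del", "decoy_onco"),
    category = c("recurrent_amplification", "recurrent_deletion",
                 "oncogene"),
    stringsAsFactors = FALSE))

  ## --- sample-level matrices, replicates and detection flags --------------
  n_rep <- round(cfg$replicate_fraction * cfg$n_patients)
  rep_idx <- if (n_rep > 0) sample.int(cfg$n_patients, n_rep) else integer()
  sample_patient <- c(seq_len(cfg$n_patients), rep_idx)
  sample_ids <- paste0(patients[sample_patient], "-s1")
  if (n_rep > 0)
    sample_ids[cfg$n_patients + seq_len(n_rep)] <-
      paste0(patients[rep_idx], "-s2")
  clinical$sample_ids <- lapply(seq_len(cfg$n_patients), function(i)
    sample_ids[sample_patient == i])

  expand <- function(X, noise_sd) {
    out <- X[, sample_patient, drop = FALSE] +
      stats::rnorm(nrow(X) * length(sample_patient), 0, noise_sd)
    colnames(out) <- sample_ids
    out
  }
  mirna_expr <- expand(M, cfg$replicate_noise_sd)
  gene_expr <- expand(G, cfg$replicate_noise_sd)
  cn_samples <- expand(cn, cfg$cn_noise_sd / 2)
  cn_samples[cn_samples < 0] <- 0

  flags <- matrix(0L, nrow(mirna_expr), ncol(mirna_expr),
                  dimnames = dimnames(mirna_expr))
  undetected_idx <- integer()
  if (cfg$n_undetected_mirnas > 0) {
    undetected_idx <- cfg$n_mirnas - seq_len(cfg$n_undetected_mirnas) + 1L
    for (m in undetected_idx) {
      bad <- sample.int(ncol(flags), min(15L, ncol(flags)))
      flags[m, bad] <- sample(c(1L, 2L), length(bad), replace = TRUE,
                              prob = c(0.8, 0.2))
    }
  }
  sprinkle <- matrix(stats::runif(length(flags)) < 0.002, nrow(flags))
  if (length(undetected_idx)) sprinkle[undetected_idx, ] <- FALSE
  flags[sprinkle] <- 1L
  mirna_expr <- set_expression_flags(mirna_expr, flags)

  truth <- list(
    cn_driven = data.frame(mirna_id = mirnas[cfg$planted_cn_driven$mirna],
                           cfg$planted_cn_driven[-1],
                           stringsAsFactors = FALSE),
    prognostic = data.frame(mirna_id = mirnas[cfg$planted_prognostic$mirna],
                            cfg$planted_prognostic[-1],
                            stringsAsFactors = FALSE),
    mirnapt = data.frame(mirna_id = mirnas[cfg$planted_mirnapt$mirna],
                         cfg$planted_mirnapt[-1],
                         stringsAsFactors = FALSE),
    subtype_mirnas = data.frame(
      mirna_id = mirnas[cfg$planted_subtype_mirnas$mirna],
      cfg$planted_subtype_mirnas[-1], stringsAsFactors = FALSE),
    true_targets = true_targets,
    subtype = stats::setNames(subtype, patients),
    te_mirnas = mirnas[te_idx],
    undetected_mirnas = mirnas[undetected_idx])

  list(mirna_expr = expression_matrix(mirna_expr, flags),
       gene_expr = expression_matrix(gene_expr),
       cn = copy_number_matrix(cn_samples),
       loci = loci, targets = target_prediction_map(targets),
       gene_sets = gene_sets,
       regions = genomic_regions(regions$chromosome, regions$start,
                                 regions$end, regions$label,
                                 regions$category),
       clinical = clinical_table(clinical),
       centroids = centroids, truth = truth, config = cfg)
}

COHORT_FILES <- c(mirna_expr = "mirna_expression.tsv",
                  mirna_flags = "mirna_flags.tsv",
                  gene_expr = "gene_expression.tsv",
                  cn = "mirna_copy_number.tsv",
                  loci = "mirna_loci.gff3",
                  te = "te_mirnas.txt",
                  targets = "predicted_targets.tsv",
                  gene_sets = "gene_sets.gmt",
                  regions = "regions.bed",
                  clinical = "clinical.tsv",
                  centroids = "centroids.tsv",
                  truth = "truth.tsv")

#' Write / read a simulated cohort to a directory
#'
#' Writes every cohort component in the package's external formats plus a
#' `truth.tsv` manifest listing the planted effects; `read_cohort`
#' reconstructs the in-memory cohort (ground-truth gene lists are recovered
#' from the `TRUE_TARGETS_*` gene sets).
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `write_cohort` the directory, `read_cohort` the cohort list.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory ", dir)
  f <- function(nm) file.path(dir, COHORT_FILES[[nm]])
  write_expression_matrix(cohort$mirna_expr, f("mirna_expr"),
                          flags_path = f("mirna_flags"))
  write_expression_matrix(cohort$gene_expr, f("gene_expr"))
  write_copy_number_matrix(cohort$cn, f("cn"))
  write_mirna_gff3(cohort$loci, f("loci"), te_path = f("te"))
  write_target_map(cohort$targets, f("targets"))
  write_gmt(cohort$gene_sets, f("gene_sets"))
  write_region_bed(cohort$regions, f("regions"))
  write_clinical_table(cohort$clinical, f("clinical"))
  write_centroids(cohort$centroids, f("centroids"))
  write_truth_manifest(cohort$truth, f("truth"))
  invisible(dir)
}

write_truth_manifest <- function(truth, path) {
  detail <- function(df) apply(df, 1, function(r)
    paste(names(r), trimws(as.character(r)), sep = "=", collapse = ";"))
  rows <- list()
  for (type in c("cn_driven", "prognostic", "mirnapt", "subtype_mirnas")) {
    df <- truth[[type]]
    if (nrow(df))
      rows[[type]] <- data.frame(type = type, mirna_id = df$mirna_id,
                                 detail = detail(df[-1]),
                                 stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(), mirna_id = character(),
               detail = character(), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  f <- function(nm) file.path(dir, COHORT_FILES[[nm]])
  truth_df <- utils::read.table(f("truth"), sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE,
                                colClasses = "character")
  gene_sets <- read_gmt(f("gene_sets"))
  tt_names <- grep("^TRUE_TARGETS_", names(gene_sets), value = TRUE)
  true_targets <- stats::setNames(gene_sets[tt_names],
                                  sub("^TRUE_TARGETS_", "", tt_names))
  list(mirna_expr = read_expression_matrix(f("mirna_expr"),
                                           flags_path = f("mirna_flags")),
       gene_expr = read_expression_matrix(f("gene_expr")),
       cn = read_copy_number_matrix(f("cn")),
       loci = read_mirna_gff3(f("loci"), te_path = f("te")),
       targets = read_target_map(f("targets")),
       gene_sets = gene_sets,
       regions = read_region_bed(f("regions")),
       clinical = read_clinical_table(f("clinical")),
       centroids = read_centroids(f("centroids")),
       truth_manifest = truth_df,
       true_targets = true_targets)
}

#' One-line description of the planted ground truth
#'
#' @param truth the `truth` element of a simulated cohort.
#' @return data.frame: one row per planted miRNA with its effect type.
#' @export
describe_truth <- function(truth) {
  rows <- lapply(c("cn_driven", "prognostic", "mirnapt", "subtype_mirnas"),
                 function(type) {
    df <- truth[[type]]
    if (!nrow(df)) return(NULL)
    data.frame(type = type, mirna_id = df$mirna_id,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(type = character(), mirna_id = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
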