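# Small programmatic fixtures shared across test files.

make_expr <- function(nrow = 4, ncol = 6, seed = 1, prefix = "f") {
  set.seed(seed)
  m <- matrix(rnorm(nrow * ncol), nrow, ncol,
              dimnames = list(paste0(prefix, seq_len(nrow)),
                              paste0("S", seq_len(ncol))))
  expression_matrix(m)
}

make_clinical <- function(n = 6, samples_per_patient = 1, seed = 1) {
  set.seed(seed)
  pid <- sprintf("P%02d", seq_len(n))
  sample_ids <- lapply(seq_len(n), function(i)
    paste0("S", (i - 1) * samples_per_patient + seq_len(samples_per_patient)))
  clinical_table(data.frame(
    patient_id = pid,
    sample_ids = I(sample_ids),
    er = sample(c("pos", "neg"), n, replace = TRUE),
    pr = sample(c("pos", "neg"), n, replace = TRUE),
    her2 = sample(c("pos", "neg"), n, replace = TRUE),
    grade = sample(1:3, n, replace = TRUE),
    node_positive = sample(c(TRUE, FALSE), n, replace = TRUE),
    lymph_infiltration_pct = runif(n, 0, 60),
    tumour_size_cm = runif(n, 0.5, 5),
    neoadjuvant = FALSE,
    dmfs_time = rexp(n, 0.1) + 0.01,
    dmfs_event = sample(c(TRUE, FALSE), n, replace = TRUE),
    bcss_time = rexp(n, 0.1) + 0.01,
    bcss_event = sample(c(TRUE, FALSE), n, replace = TRUE),
    stringsAsFactors = FALSE))
}

# a small but fully featured simulated cohort, cheap enough for unit tests
small_sim_config <- function(seed = 1, ...) {
  defaults <- list(
    n_patients = 100, n_mirnas = 40, n_genes = 600,
    planted_cn_driven = data.frame(mirna = 1:3, frequency = 0.3,
                                   direction = c("gain", "loss", "gain"),
                                   shift_sd = 1),
    planted_prognostic = data.frame(mirna = 11, endpoint = "DMFS",
                                    log_hazard_per_sd = 0.7),
    planted_mirnapt = data.frame(mirna = 21:22, true_target_fraction = 0.3,
                                 repression_slope = -1),
    planted_subtype_mirnas = data.frame(mirna = c(3, 31),
                                        subtype = c("basal", "lumA"),
                                        mean_shift_sd = 1.5),
    targets_per_mirna = 40, n_algorithms = 3,
    n_gene_sets = 30, genes_per_set = c(10, 40),
    n_undetected_mirnas = 2, seed = seed)
  args <- list(...)
  defaults[names(args)] <- args   # wholesale replacement, no recursion
  do.call(simulation_config, defaults)
}

empty_planted <- function() list(
  planted_cn_driven = data.frame(mirna = integer(), frequency = numeric(),
                                 direction = character(),
                                 shift_sd = numeric()),
  planted_prognostic = data.frame(mirna = integer(), endpoint = character(),
                                  log_hazard_per_sd = numeric()),
  planted_mirnapt = data.frame(mirna = integer(),
                               true_target_fraction = numeric(),
                               repression_slope = numeric()),
  planted_subtype_mirnas = data.frame(mirna = integer(),
                                      subtype = character(),
                                      mean_shift_sd = numeric()))

# null cohort: no planted effects at all
null_sim_config <- function(seed = 1, ...) {
  do.call(small_sim_config,
          c(list(seed = seed), empty_planted(), list(...)))
}
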