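test_that("simulation is deterministic given the seed", {
  a <- simulate_cohort(small_sim_config(seed = 5))
  b <- simulate_cohort(small_sim_config(seed = 5))
  expect_identical(a$mirna_expr, b$mirna_expr)
  expect_identical(a$gene_expr, b$gene_expr)
  expect_identical(a$cn, b$cn)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$targets, b$targets)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(small_sim_config(seed = 6))
  expect_false(identical(unclass(a$mirna_expr)[, ],
                         unclass(c$mirna_expr)[, ]))
})

test_that("infeasible and invalid configurations are rejected", {
  expect_error(simulation_config(subtype_proportions = c(basal = 0.5,
                                                         lumA = 0.4)),
               "sum to 1")
  expect_error(small_sim_config(planted_mirnapt = data.frame(
    mirna = 1, true_target_fraction = 0.3, repression_slope = 0.5)),
    "negative")
  expect_error(small_sim_config(planted_prognostic = data.frame(
    mirna = 999, endpoint = "DMFS", log_hazard_per_sd = 1)),
    "out of range")
  expect_error(small_sim_config(n_genes = 20), "infeasible")
})

test_that("zero censoring yields all-event cohorts; censoring rate is honoured", {
  co <- simulate_cohort(small_sim_config(seed = 2, censoring_rate = 0))
  expect_true(all(co$clinical$dmfs_event))
  expect_true(all(co$clinical$bcss_event))
  co2 <- simulate_cohort(small_sim_config(seed = 2, censoring_rate = 0.5,
                                          n_patients = 400))
  expect_gt(mean(!co2$clinical$dmfs_event), 0.3)
  expect_lt(mean(!co2$clinical$dmfs_event), 0.7)
})

test_that("null repression gives target correlations centred at zero", {
  co <- simulate_cohort(small_sim_config(
    seed = 3,
    planted_mirnapt = data.frame(mirna = integer(),
                                 true_target_fraction = numeric(),
                                 repression_slope = numeric())))
  me <- average_replicates(co$mirna_expr, co$clinical)
  ge <- average_replicates(co$gene_expr, co$clinical)
  cors <- mirna_target_correlations(me, ge, co$targets)
  expect_lt(abs(median(cors$rho)), 0.05)
})

test_that("planted structure is present in the generated data", {
  co <- simulate_cohort(small_sim_config(seed = 4, n_patients = 200))
  me <- average_replicates(co$mirna_expr, co$clinical)
  ge <- average_replicates(co$gene_expr, co$clinical)
  cnp <- average_replicates(co$cn, co$clinical)
  # CN-driven loci correlate with dosage
  for (m in co$truth$cn_driven$mirna_id)
    expect_gt(cor(cnp[m, ], me[m, ], method = "spearman"), 0.2)
  # true targets are anti-correlated with their repressor
  for (m in co$truth$mirnapt$mirna_id) {
    tt <- co$truth$true_targets[[m]]
    rhos <- apply(ge[tt, , drop = FALSE], 1, cor, y = me[m, ],
                  method = "spearman")
    expect_lt(median(rhos), -0.3)
  }
  # true targets appear among every algorithm's predictions (with agreement)
  hit <- vapply(names(co$targets), function(alg) {
    m <- co$truth$mirnapt$mirna_id[1]
    mean(co$truth$true_targets[[m]] %in% co$targets[[alg]][[m]])
  }, 0)
  expect_gt(mean(hit), 0.6)
  # TRUE_TARGETS gene sets are injected into the collection
  expect_true(all(paste0("TRUE_TARGETS_", co$truth$mirnapt$mirna_id) %in%
                    names(co$gene_sets)))
  # TE flags avoid planted CN-driven miRNAs
  expect_length(intersect(co$truth$te_mirnas, co$truth$cn_driven$mirna_id), 0)
  # planted-undetected miRNAs fail the detection filter
  kept <- rownames(filter_undetected(co$mirna_expr))
  expect_length(intersect(kept, co$truth$undetected_mirnas), 0)
})

test_that("cohort write/read round trip and the truth manifest", {
  co <- simulate_cohort(small_sim_config(seed = 8))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_identical(unclass(back$mirna_expr)[, ], unclass(co$mirna_expr)[, ])
  expect_identical(expression_flags(back$mirna_expr),
                   expression_flags(co$mirna_expr))
  expect_identical(back$gene_expr, co$gene_expr)
  expect_identical(back$cn, co$cn)
  loci <- back$loci[match(co$loci$mirna_id, back$loci$mirna_id), ]
  rownames(loci) <- NULL
  expect_equal(loci, co$loci)
  expect_identical(back$targets, co$targets)
  expect_identical(back$clinical$dmfs_time, co$clinical$dmfs_time)
  expect_identical(back$centroids, co$centroids)
  expect_setequal(back$truth_manifest$mirna_id,
                  describe_truth(co$truth)$mirna_id)
  expect_identical(back$true_targets[co$truth$mirnapt$mirna_id],
                   co$truth$true_targets[co$truth$mirnapt$mirna_id])
  # empty planted lists -> header-only manifest
  co0 <- simulate_cohort(null_sim_config(seed = 1))
  dir0 <- withr::local_tempdir()
  write_cohort(co0, dir0)
  tm <- utils::read.table(file.path(dir0, "truth.tsv"), sep = "\t",
                          header = TRUE)
  expect_identical(nrow(tm), 0L)
})

test_that("YAML configuration round trip", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(list(
    n_patients = 60, n_mirnas = 20, n_genes = 200,
    targets_per_mirna = 20, n_gene_sets = 10,
    genes_per_set = c(5, 20), seed = 99,
    planted_mirnapt = list(list(mirna = 1, true_target_fraction = 0.5,
                                repression_slope = -1)),
    planted_cn_driven = list(list(mirna = 2, frequency = 0.4,
                                  direction = "gain", shift_sd = 1)),
    planted_prognostic = list(list(mirna = 3, endpoint = "BCSS",
                                   log_hazard_per_sd = 0.5)),
    planted_subtype_mirnas = list(list(mirna = 4, subtype = "basal",
                                       mean_shift_sd = 1))), path)
  cfg <- read_simulation_config(path)
  expect_equal(cfg$n_patients, 60)
  expect_identical(cfg$planted_mirnapt$repression_slope, -1)
  expect_identical(cfg$planted_prognostic$endpoint, "BCSS")
  co <- simulate_cohort(cfg)
  expect_equal(ncol(co$gene_expr), 60 + round(0.04 * 60))
})
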