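test_that("covariate codings follow the fixed conventions", {
  cl <- make_clinical(6)
  cl$grade <- c(1, 2, 3, 3, 2, 1)
  cl$lymph_infiltration_pct <- c(0, 14.9, 15, 15.1, 50, 5)
  cov <- encode_covariates(cl)
  expect_identical(cov$grade_high, c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_identical(cov$lymph_high, c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_identical(cov$tumour_size_cm, cl$tumour_size_cm)  # unscaled
})

test_that("cox screen is invariant to positive rescaling of expression", {
  co <- simulate_cohort(small_sim_config(seed = 21))
  me <- average_replicates(co$mirna_expr, co$clinical)
  r1 <- cox_univariate_screen(me[1:8, ], co$clinical, "DMFS", "all")
  r2 <- cox_univariate_screen(me[1:8, ] * 37.5, co$clinical, "DMFS", "all")
  expect_equal(r1$hr_per_sd, r2$hr_per_sd, tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
  expect_equal(r1$q, r2$q, tolerance = 1e-10)
})

test_that("planted prognostic miRNA is recovered; constants are flagged", {
  co <- simulate_cohort(small_sim_config(seed = 22, n_patients = 200))
  me <- average_replicates(co$mirna_expr, co$clinical)
  me["sim-mir-005", ] <- 3  # constant row
  scr <- cox_univariate_screen(me, co$clinical, "DMFS", "all")
  planted <- co$truth$prognostic$mirna_id[
    co$truth$prognostic$endpoint == "DMFS"]
  expect_true(all(scr$prognostic[scr$mirna_id %in% planted]))
  expect_identical(scr$flag[scr$mirna_id == "sim-mir-005"], "constant")
  expect_true(is.na(scr$p[scr$mirna_id == "sim-mir-005"]))
  # direction is consistent with the hazard ratio
  expect_identical(unique(scr$direction[!is.na(scr$hr_per_sd) &
                                          scr$hr_per_sd > 1]),
                   "unfavourable")
  # neo-adjuvant patients are excluded from the fit
  expect_identical(sum(co$clinical$neoadjuvant), 3L)
})

test_that("multivariate screen with empty covariates equals univariate", {
  co <- simulate_cohort(small_sim_config(seed = 23))
  me <- average_replicates(co$mirna_expr, co$clinical)[1:10, ]
  uni <- cox_univariate_screen(me, co$clinical, "DMFS", "all")
  multi <- cox_multivariate(me, co$clinical, "DMFS", "all",
                            covariates = character())
  expect_equal(multi$log_hr, uni$log_hr, tolerance = 1e-10)
  expect_equal(multi$p, uni$p, tolerance = 1e-10)
  expect_error(cox_multivariate(me, co$clinical, "DMFS", "all",
                                covariates = "shoe_size"), "unknown")
})

test_that("a neutral covariate leaves the miRNA p essentially unchanged, a planted confounder attenuates it", {
  # neutral: node status independent of outcome and miRNA
  diff_neutral <- vapply(1:8, function(s) {
    co <- simulate_cohort(small_sim_config(seed = 300 + s, n_patients = 150))
    me <- average_replicates(co$mirna_expr, co$clinical)["sim-mir-011", ,
                                                         drop = FALSE]
    uni <- cox_univariate_screen(me, co$clinical, "DMFS", "all")
    mul <- cox_multivariate(me, co$clinical, "DMFS", "all",
                            covariates = "node_positive")
    abs(log(uni$p) - log(mul$p))
  }, 0)
  expect_lt(median(diff_neutral), 1)
  # confounder: lymphocytic infiltration drives hazard and tracks the miRNA
  attenuated <- vapply(1:10, function(s) {
    co <- simulate_cohort(small_sim_config(
      seed = 400 + s, n_patients = 150,
      planted_prognostic = data.frame(mirna = integer(),
                                      endpoint = character(),
                                      log_hazard_per_sd = numeric()),
      covariate_effects = c(lymph_high = 1.2),
      confounded_mirna = 11, confounding_strength = 1.5))
    me <- average_replicates(co$mirna_expr, co$clinical)["sim-mir-011", ,
                                                         drop = FALSE]
    uni <- cox_univariate_screen(me, co$clinical, "DMFS", "all")
    mul <- cox_multivariate(me, co$clinical, "DMFS", "all",
                            covariates = "lymph_high")
    mul$p > uni$p
  }, TRUE)
  expect_gte(mean(attenuated), 0.8)
})

test_that("km_tertiles splits 9 distinct values into balanced thirds", {
  cl <- make_clinical(9)
  x <- stats::setNames(as.numeric(1:9), cl$patient_id)
  km <- km_tertiles(x, cl, "DMFS", exclude_neoadjuvant = FALSE)
  expect_identical(as.vector(table(km$groups)), rep(3L, 3))
  expect_identical(names(km$groups)[km$groups == "low"], cl$patient_id[1:3])
  expect_identical(names(km$groups)[km$groups == "high"], cl$patient_id[7:9])
  expect_true(km$logrank_p >= 0 && km$logrank_p <= 1)
  expect_error(km_tertiles(stats::setNames(rep(1, 9), cl$patient_id), cl,
                           "DMFS", exclude_neoadjuvant = FALSE),
               "constant")
})

test_that("log-rank p is 1 when the groups carry identical survival", {
  # two identical groups duplicated across the tertile split
  cl <- make_clinical(12)
  cl$dmfs_time <- rep(c(1, 2, 3, 4), 3)
  cl$dmfs_event <- rep(c(TRUE, TRUE, FALSE, TRUE), 3)
  x <- stats::setNames(as.numeric(1:12), cl$patient_id)
  # groups of 4; survival identical in each -> chi-square statistic 0
  km <- km_tertiles(x, cl, "DMFS", exclude_neoadjuvant = FALSE)
  expect_equal(km$logrank_p, 1, tolerance = 1e-9)
})

test_that("null screens are calibrated and the KS calibration behaves", {
  ps <- unlist(lapply(1:3, function(s) {
    co <- simulate_cohort(small_sim_config(
      seed = 29 + s, n_patients = 150, n_mirnas = 200, n_genes = 300,
      targets_per_mirna = 20, genes_per_set = c(5, 20),
      planted_prognostic = data.frame(mirna = integer(),
                                      endpoint = character(),
                                      log_hazard_per_sd = numeric()),
      n_undetected_mirnas = 0))
    me <- average_replicates(co$mirna_expr, co$clinical)
    scr <- cox_univariate_screen(me, co$clinical, "DMFS", "all")
    scr$p[!is.na(scr$p)]
  }))
  frac <- mean(ps < 0.05)   # pooled over 600 null miRNAs
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
  cal <- pvalue_calibration(ps)
  expect_gt(cal$ks_p, 0.01)      # null p-values look uniform
  bad <- pvalue_calibration(runif(1000, 0, 0.01))
  expect_lt(bad$ks_p, 1e-6)      # concentration near 0 is detected
})

test_that("permutation reference reproduces uniformity within the DKW bound", {
  co <- simulate_cohort(small_sim_config(seed = 31, n_patients = 120))
  me <- average_replicates(co$mirna_expr, co$clinical)[1:20, ]
  n_perm <- 200
  cal <- pvalue_calibration(runif(50), n_perm = n_perm, expr = me,
                            clinical = co$clinical, endpoint = "DMFS",
                            seed = 99)
  expect_length(cal$perm_pvalues, n_perm)
  # Dvoretzky-Kiefer-Wolfowitz envelope at alpha = 0.001
  eps <- sqrt(log(2 / 0.001) / (2 * n_perm))
  grid <- seq(0.05, 0.95, by = 0.05)
  ecdf_vals <- stats::ecdf(cal$perm_pvalues)(grid)
  expect_true(all(abs(ecdf_vals - grid) <= eps))
})
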