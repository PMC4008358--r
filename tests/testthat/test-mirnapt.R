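test_that("anti-correlation flag is strict at the threshold", {
  set.seed(50)
  n <- 40
  m <- matrix(rnorm(2 * n), 2, n,
              dimnames = list(c("mir1", "mir2"), paste0("S", 1:n)))
  g <- matrix(rnorm(2 * n), 2, n,
              dimnames = list(c("gA", "gB"), paste0("S", 1:n)))
  map <- list(alg = list(mir1 = c("gA", "gB"), mir2 = "gA"))
  cors <- mirna_target_correlations(m, g, map)
  expect_identical(cors$anti_correlated, cors$rho < -0.3)
  # a pair exactly at the threshold is not anti-correlated: build one whose
  # Spearman rho is exactly -0.3 (Sum d^2 = 26 at n = 5 gives 1 - 156/120)
  x <- c(1, 2, 3, 4, 5)
  y <- c(3, 5, 1, 4, 2)  # Sum d^2 = 26: rho = 1 - 6*26/120 = -0.3
  expect_equal(oracle_spearman_rho(x, y), -0.3)
  m2 <- matrix(c(x, y), 2, byrow = TRUE,
               dimnames = list(c("mirx", "gx"), paste0("S", 1:5)))
  cors2 <- mirna_target_correlations(m2["mirx", , drop = FALSE],
                                     m2["gx", , drop = FALSE],
                                     list(alg = list(mirx = "gx")))
  expect_equal(cors2$rho, -0.3)
  expect_false(cors2$anti_correlated)
})

test_that("missing predicted targets are dropped with a count message", {
  m <- make_expr(2, 20, seed = 51, prefix = "mir")
  g <- make_expr(3, 20, seed = 52, prefix = "g")
  map <- list(alg = list(mir1 = c("g1", "NOT_MEASURED1", "NOT_MEASURED2")))
  expect_message(cors <- mirna_target_correlations(m, g, map), "2 predicted")
  expect_identical(nrow(cors), 1L)
})

test_that("planted repressors are recovered; 2x2 margins cover the universe", {
  co <- simulate_cohort(small_sim_config(seed = 53, n_patients = 150))
  me <- average_replicates(co$mirna_expr, co$clinical)
  ge <- average_replicates(co$gene_expr, co$clinical)
  res <- mirnapt_enrichment(me, ge, co$targets)
  planted <- co$truth$mirnapt$mirna_id
  expect_true(all(res$table$is_mirnapt[res$table$mirna_id %in% planted]))
  expect_lte(mean(res$table$is_mirnapt[!res$table$mirna_id %in% planted]),
             0.05)
  # margins: a+b+c+d = |universe| for every tested miRNA
  ok <- res$by_algorithm[res$by_algorithm$flag == "ok", ]
  expect_identical(unique(ok$a + ok$b + ok$c + ok$d),
                   length(res$universe))
  # true targets are flagged anti-correlated at a high rate
  tt <- co$truth$true_targets[[planted[1]]]
  rho <- attr(res, "rho")
  expect_gt(mean(rho[planted[1], tt] < -0.3), 0.9)
  # a decoy gene is rarely anti-correlated
  decoys <- setdiff(colnames(rho), unlist(co$truth$true_targets))
  expect_lt(mean(rho[planted[1], decoys] < -0.3), 0.01)
})

test_that("enrichment q is invariant to gene and sample order; a=0 gives p=1", {
  co <- simulate_cohort(small_sim_config(seed = 54))
  me <- average_replicates(co$mirna_expr, co$clinical)
  ge <- average_replicates(co$gene_expr, co$clinical)
  r1 <- mirnapt_enrichment(me, ge, co$targets)
  set.seed(3)
  gperm <- ge[sample(nrow(ge)), sample(ncol(ge))]
  mperm <- me[, colnames(gperm)]
  r2 <- mirnapt_enrichment(mperm, gperm, co$targets)
  expect_equal(r2$table$min_q[match(r1$table$mirna_id, r2$table$mirna_id)],
               r1$table$min_q, tolerance = 1e-12)
  # chunking does not change the result
  r3 <- mirnapt_enrichment(me, ge, co$targets, chunk_size = 123)
  expect_identical(r3$table, r1$table)
  # a miRNA whose predicted targets contain no anti-correlated gene
  flat <- r1$by_algorithm[r1$by_algorithm$flag == "ok" &
                            r1$by_algorithm$a == 0, ]
  if (nrow(flat)) expect_true(all(flat$p == 1))
})

test_that("miRNAs with too few measured targets are excluded with a flag", {
  m <- make_expr(2, 30, seed = 55, prefix = "mir")
  g <- make_expr(20, 30, seed = 56, prefix = "g")
  map <- list(alg = c(
    list(mir1 = rownames(g)[1:12]),   # enough targets
    list(mir2 = c("g1", "g2"))))      # too few
  res <- mirnapt_enrichment(m, g, map, min_targets = 10)
  ba <- res$by_algorithm
  expect_identical(ba$flag[ba$mirna_id == "mir2"], "too_few_targets")
  expect_true(is.na(res$table$min_q[res$table$mirna_id == "mir2"]))
  expect_false(res$table$is_mirnapt[res$table$mirna_id == "mir2"])
})

test_that("stronger planted repression never weakens median enrichment", {
  fracs <- c(0.1, 0.3, 0.5)
  med_logq <- vapply(fracs, function(f) {
    qs <- vapply(1:8, function(s) {
      co <- simulate_cohort(small_sim_config(
        seed = 700 + s, n_patients = 100, n_mirnas = 25, n_genes = 400,
        targets_per_mirna = 30, genes_per_set = c(5, 20),
        planted_mirnapt = data.frame(mirna = 21,
                                     true_target_fraction = f,
                                     repression_slope = -1),
        planted_prognostic = data.frame(mirna = integer(),
                                        endpoint = character(),
                                        log_hazard_per_sd = numeric()),
        planted_subtype_mirnas = data.frame(mirna = 3, subtype = "basal",
                                            mean_shift_sd = 1.5),
        n_undetected_mirnas = 0))
      me <- average_replicates(co$mirna_expr, co$clinical)
      ge <- average_replicates(co$gene_expr, co$clinical)
      res <- mirnapt_enrichment(me, ge, co$targets)
      res$table$min_q[res$table$mirna_id == "sim-mir-021"]
    }, 0)
    median(-log10(pmax(qs, 1e-300)))
  }, 0)
  expect_true(all(diff(med_logq) >= 0))
})

test_that("global correlation profile summarises per algorithm", {
  co <- simulate_cohort(small_sim_config(seed = 57))
  me <- average_replicates(co$mirna_expr, co$clinical)
  ge <- average_replicates(co$gene_expr, co$clinical)
  cors <- mirna_target_correlations(me, ge, co$targets)
  prof <- global_correlation_profile(cors)
  expect_setequal(prof$algorithm, names(co$targets))
  expect_true(all(abs(prof$mean_rho) <= 1))
  # an all-planted cohort shows a clearly left-shifted median
  coL <- simulate_cohort(small_sim_config(
    seed = 59,
    planted_mirnapt = data.frame(mirna = 1:10, true_target_fraction = 0.8,
                                 repression_slope = -1.5)))
  meL <- average_replicates(coL$mirna_expr, coL$clinical)
  geL <- average_replicates(coL$gene_expr, coL$clinical)
  profL <- global_correlation_profile(
    mirna_target_correlations(meL, geL, coL$targets))
  # null cohort: medians near zero
  co0 <- simulate_cohort(null_sim_config(seed = 58))
  me0 <- average_replicates(co0$mirna_expr, co0$clinical)
  ge0 <- average_replicates(co0$gene_expr, co0$clinical)
  prof0 <- global_correlation_profile(
    mirna_target_correlations(me0, ge0, co0$targets))
  expect_true(all(abs(prof0$q50) < 0.05))
  # the all-planted cohort's medians sit clearly to the left of the null's
  expect_lt(max(profL$q50), min(prof0$q50))
  expect_warning(res <- global_correlation_profile(
    data.frame(mirna_id = character(), gene_id = character(),
               algorithm = character(), rho = numeric(),
               anti_correlated = logical())), "empty")
  expect_identical(nrow(res), 0L)
})
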