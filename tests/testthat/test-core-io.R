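test_that("expression matrix round trip is exact, flags included", {
  x <- make_expr(5, 4, seed = 10)
  fl <- matrix(sample(0:2, 20, replace = TRUE, prob = c(0.8, 0.15, 0.05)),
               5, 4)
  x <- set_expression_flags(x, fl)
  f <- withr::local_tempfile(fileext = ".tsv")
  ff <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(x, f, flags_path = ff)
  y <- read_expression_matrix(f, flags_path = ff)
  expect_identical(unclass(y)[, ], unclass(x)[, ])
  expect_identical(expression_flags(y), expression_flags(x))
})

test_that("matrix reader reports malformed input with file and line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tS1\tS2", "m1\t1.5\t2.5", "m2\t3.5"), f)
  expect_error(read_expression_matrix(f), "line 3")
  writeLines(c("feature_id\tS1\tS2", "m1\t1.5\t2.5", "m1\t1\t2"), f)
  expect_error(read_expression_matrix(f), "duplicate feature")
  writeLines(c("feature_id\tS1\tS2", "m1\t1.5\tNA"), f)
  expect_error(read_expression_matrix(f), "line 2")
})

test_that("GFF3 round trip preserves loci and the TE flag list", {
  loci <- mirna_loci(mirna_id = c("hsa-mir-17", "hsa-mir-21", "hsa-mir-9"),
                     chromosome = c("chr13", "chr17", "chr1"),
                     start = c(100, 5000, 77), end = c(183, 5090, 160),
                     strand = c("+", "-", "+"),
                     te_colocated = c(FALSE, TRUE, FALSE))
  g <- withr::local_tempfile(fileext = ".gff3")
  te <- withr::local_tempfile(fileext = ".txt")
  write_mirna_gff3(loci, g, te_path = te)
  back <- read_mirna_gff3(g, te_path = te)
  back <- back[match(loci$mirna_id, back$mirna_id), ]
  rownames(back) <- NULL
  expect_equal(back, loci)
  # miRBase-style attribute parsing: Name is the miRNA id
  writeLines(c("##gff-version 3",
               paste("chr7", ".", "miRNA", "120", "200", ".", "+", ".",
                     "ID=MI0000060;Name=hsa-mir-17", sep = "\t")), g)
  one <- read_mirna_gff3(g)
  expect_identical(one$mirna_id, "hsa-mir-17")
  expect_identical(one$start, 120L)
})

test_that("GMT parsing and round trip", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SETA\tdesc\tG1\tG2", "SETB\t\tG3"), f)
  sets <- read_gmt(f)
  expect_identical(sets$SETA, c("G1", "G2"))
  expect_identical(attr(sets, "description")[["SETA"]], "desc")
  g <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, g)
  expect_identical(read_gmt(g)[], sets[])
  writeLines("ONLYNAME\tdesc", f)
  expect_error(read_gmt(f), ">= 1 gene")
})

test_that("BED regions convert coordinates and validate categories", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200\tamp1\trecurrent_amplification", f)
  r <- read_region_bed(f)
  expect_identical(r$start, 100L)  # 0-based half-open -> 1-based inclusive
  expect_identical(r$end, 200L)
  g <- withr::local_tempfile(fileext = ".bed")
  write_region_bed(r, g)
  expect_identical(readLines(g), readLines(f))
  writeLines("chr1\t99\t200\tx\tbogus_category", f)
  expect_error(read_region_bed(f), "category")
})

test_that("clinical table and target map round trips", {
  cl <- make_clinical(5, samples_per_patient = 2)
  cl$subtype <- c("basal", "lumA", NA, "her2", "normal")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_clinical_table(cl, f)
  back <- read_clinical_table(f)
  expect_equal(back$sample_ids, unclass(cl$sample_ids),
               ignore_attr = TRUE)
  expect_identical(back$dmfs_time, cl$dmfs_time)
  expect_identical(back$subtype, cl$subtype)
  expect_identical(back$node_positive, cl$node_positive)

  map <- target_prediction_map(list(
    algo1 = list(m1 = c("G1", "G2"), m2 = "G3"),
    algo2 = list(m1 = "G2")))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_target_map(map, tf)
  expect_identical(read_target_map(tf), map)
})

test_that("container validators reject malformed objects", {
  m <- matrix(1:4, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  expect_error(expression_matrix(m), "duplicate feature")
  expect_error(copy_number_matrix(
    matrix(c(-1, 1, 2, 3), 2, dimnames = list(c("a", "b"), c("s1", "s2")))),
    "non-negative")
  expect_error(mirna_loci("m1", "chr1", 10, 5, "+"), "start")
  cl <- make_clinical(3)
  cl$dmfs_time[2] <- -1
  expect_error(clinical_table(cl), "positive")
})

test_that("average_replicates averages per patient, in clinical order", {
  cl <- make_clinical(3, samples_per_patient = 2)  # S1..S6
  x <- expression_matrix(matrix(
    c(1, 3, 0, 0, 6, 0,
      2, 2, 1, 5, 3, 3), nrow = 2, byrow = TRUE,
    dimnames = list(c("m1", "m2"), paste0("S", 1:6))))
  out <- average_replicates(x, cl)
  expect_identical(colnames(out), cl$patient_id)
  expect_equal(out["m1", ], c(P01 = 2, P02 = 0, P03 = 3))
  # single-sample patient passes through unchanged
  cl1 <- make_clinical(6, samples_per_patient = 1)
  y <- make_expr(3, 6, seed = 2)
  expect_equal(unclass(average_replicates(y, cl1))[, ], unclass(y)[, ],
               ignore_attr = TRUE)
  # three replicates 0, 0, 6 -> arithmetic mean 2
  cl3 <- make_clinical(1, samples_per_patient = 3)
  z <- expression_matrix(matrix(c(0, 0, 6), 1,
                                dimnames = list("m1", paste0("S", 1:3))))
  expect_equal(unname(average_replicates(z, cl3)["m1", 1]), 2)
  # unmapped sample is an error naming the sample
  colnames(y)[1] <- "UNKNOWN"
  expect_error(average_replicates(y, cl1), "UNKNOWN")
})

test_that("filter_undetected applies the strict more-than rule", {
  n <- 20
  x <- make_expr(3, n, seed = 3)
  fl <- matrix(0L, 3, n)
  fl[1, 1:11] <- 1L   # bad in 11 samples -> removed
  fl[2, 1:10] <- 2L   # bad in exactly 10 -> retained
  x <- set_expression_flags(x, fl)
  out <- filter_undetected(x, max_bad_samples = 10)
  expect_identical(rownames(out), c("f2", "f3"))
  expect_error(filter_undetected(make_expr(2, 4)), "flags")
})

test_that("exclude_te_mirnas filters, preserves order and is idempotent", {
  loci <- mirna_loci(paste0("m", 1:5), "chr1", 1:5 * 100, 1:5 * 100 + 50,
                     "+", te_colocated = c(FALSE, TRUE, FALSE, TRUE, FALSE))
  out <- exclude_te_mirnas(loci)
  expect_identical(out$mirna_id, c("m1", "m3", "m5"))
  expect_identical(exclude_te_mirnas(out), out)
  none <- mirna_loci("m1", "chr1", 1, 10, "+", te_colocated = FALSE)
  expect_identical(exclude_te_mirnas(none), none)
  all_te <- mirna_loci("m1", "chr1", 1, 10, "+", te_colocated = TRUE)
  expect_warning(res <- exclude_te_mirnas(all_te), "no usable loci")
  expect_identical(nrow(res), 0L)
})

test_that("replicate averaging then filtering commutes with column permutation", {
  cl <- make_clinical(4, samples_per_patient = 2)
  set.seed(9)
  x <- make_expr(6, 8, seed = 9)
  fl <- matrix(sample(0:1, 48, replace = TRUE, prob = c(0.7, 0.3)), 6, 8)
  x <- set_expression_flags(x, fl)
  perm <- sample(ncol(x))
  xp <- set_expression_flags(unclass(x)[, perm], fl[, perm])
  a <- filter_undetected(average_replicates(x, cl), max_bad_samples = 2)
  b <- filter_undetected(average_replicates(xp, cl), max_bad_samples = 2)
  expect_identical(unclass(a)[, ], unclass(b)[, ])
})
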