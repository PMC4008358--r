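# Per-miRNA Cox proportional-hazards screening, multivariate covariate
# adjustment, Kaplan-Meier tertile curves and p-value calibration.
#
# Conventions: each miRNA is scaled to unit variance before the fit, so the
# hazard ratio is per standard deviation of expression; ties use the Efron
# approximation; patients who received neo-adjuvant treatment are excluded
# before any fit; the FDR family is the set of testable miRNAs within one
# endpoint x cohort x model combination.

ENDPOINTS <- c("DMFS", "BCSS")
COHORTS <- c("all", "ER_neg", "TNBC")
COVARIATE_NAMES <- c("grade_high", "node_positive", "lymph_high",
                     "tumour_size_cm")

#' Encode the histopathological covariates
#'
#' Grade is dichotomised low (grades 1-2) vs high (grade 3); lymphocytic
#' infiltration low (< 15%) vs high (>= 15%); node positivity is kept as a
#' logical and tumour size as unscaled centimetres.
#'
#' @param clinical clinical table.
#' @return data.frame with `patient_id`, `grade_high`, `node_positive`,
#'   `lymph_high`, `tumour_size_cm`.
#' @export
encode_covariates <- function(clinical) {
  validate_clinical_table(clinical)
  data.frame(patient_id = clinical$patient_id,
             grade_high = clinical$grade == 3,
             node_positive = clinical$node_positive,
             lymph_high = clinical$lymph_infiltration_pct >= 15,
             tumour_size_cm = clinical$tumour_size_cm,
             stringsAsFactors = FALSE)
}

# patients eligible for a cohort, neo-adjuvant cases removed
cohort_patients <- function(clinical, cohort = c("all", "ER_neg", "TNBC"),
                            exclude_neoadjuvant = TRUE) {
  cohort <- match.arg(cohort)
  keep <- if (exclude_neoadjuvant) !clinical$neoadjuvant else
    rep(TRUE, nrow(clinical))
  keep <- keep & switch(cohort,
    all = TRUE,
    ER_neg = clinical$er == "neg",
    TNBC = clinical$er == "neg" & clinical$pr == "neg" &
      clinical$her2 == "neg")
  clinical$patient_id[keep]
}

surv_object <- function(clinical, endpoint = c("DMFS", "BCSS")) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "DMFS")
    survival::Surv(clinical$dmfs_time, clinical$dmfs_event)
  else
    survival::Surv(clinical$bcss_time, clinical$bcss_event)
}

#' Per-miRNA univariate Cox screen
#'
#' Fits one Cox proportional-hazards model per miRNA (expression scaled to
#' unit variance), reports the Wald p-value (or the score/log-rank test with
#' `test = "score"`), applies Benjamini-Hochberg correction across the
#' testable miRNAs, and flags a miRNA prognostic when `p < p_threshold` and
#' `q < q_threshold` simultaneously.  Constant miRNAs and non-converged fits
#' are flagged and excluded from the FDR family.
#'
#' @param expr miRNA x patient matrix (patient-level, replicates averaged).
#' @param clinical clinical table.
#' @param endpoint `"DMFS"` or `"BCSS"`.
#' @param cohort `"all"`, `"ER_neg"` or `"TNBC"`.
#' @param p_threshold,q_threshold prognostic call thresholds
#'   (defaults 0.002 / 0.2).
#' @param test `"wald"` (default) or `"score"` p-value.
#' @param exclude_neoadjuvant drop neo-adjuvant-treated patients
#'   (default TRUE).
#' @return data.frame with one row per miRNA: `hr_per_sd`, `log_hr`, `p`,
#'   `q`, `prognostic`, `direction` and a status `flag` (`"ok"`,
#'   `"constant"` or `"no_fit"`).
#' @export
cox_univariate_screen <- function(expr, clinical,
                                  endpoint = c("DMFS", "BCSS"),
                                  cohort = c("all", "ER_neg", "TNBC"),
                                  p_threshold = 0.002, q_threshold = 0.2,
                                  test = c("wald", "score"),
                                  exclude_neoadjuvant = TRUE) {
  cox_screen(expr, clinical, endpoint = match.arg(endpoint),
             cohort = match.arg(cohort), covariates = character(),
             p_threshold = p_threshold, q_threshold = q_threshold,
             test = match.arg(test),
             exclude_neoadjuvant = exclude_neoadjuvant)
}

#' Per-miRNA multivariate Cox screen
#'
#' As [cox_univariate_screen()] but each model additionally contains the
#' requested histopathological covariates (additively); the reported p-value
#' is the miRNA Wald test adjusted for those covariates.  The supported
#' model ladder is: no covariates; node positivity + tumour size; node
#' positivity + tumour size + lymphocytic infiltration.  With an empty
#' covariate list the result equals the univariate screen.
#'
#' @inheritParams cox_univariate_screen
#' @param covariates subset of `grade_high`, `node_positive`, `lymph_high`,
#'   `tumour_size_cm`.
#' @return as [cox_univariate_screen()].
#' @export
cox_multivariate <- function(expr, clinical, endpoint = c("DMFS", "BCSS"),
                             cohort = c("all", "ER_neg", "TNBC"),
                             covariates = character(),
                             p_threshold = 0.002, q_threshold = 0.2,
                             exclude_neoadjuvant = TRUE) {
  bad <- setdiff(covariates, COVARIATE_NAMES)
  if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  cox_screen(expr, clinical, endpoint = match.arg(endpoint),
             cohort = match.arg(cohort), covariates = covariates,
             p_threshold = p_threshold, q_threshold = q_threshold,
             test = "wald", exclude_neoadjuvant = exclude_neoadjuvant)
}

cox_screen <- function(expr, clinical, endpoint, cohort, covariates,
                       p_threshold, q_threshold, test,
                       exclude_neoadjuvant) {
  validate_expression_matrix(expr)
  patients <- intersect(colnames(expr),
                        cohort_patients(clinical, cohort,
                                        exclude_neoadjuvant))
  if (length(patients) < 10)
    stop("fewer than 10 eligible patients in cohort '", cohort, "'")
  cl <- clinical[match(patients, clinical$patient_id), ]
  y <- surv_object(cl, endpoint)
  covs <- encode_covariates(cl)
  cdata <- covs[, covariates, drop = FALSE]
  for (cv in covariates) {
    v <- cdata[[cv]]
    if (length(unique(v)) < 2)
      stop("covariate '", cv, "' is constant in this cohort")
  }
  if (length(covariates) >= 2) {
    num <- vapply(cdata, as.numeric, numeric(nrow(cdata)))
    if (qr(cbind(1, num))$rank < ncol(num) + 1)
      stop("collinear covariates: ", paste(covariates, collapse = ", "))
  }

  fit_one <- function(m) {
    x <- expr[m, patients]
    if (stats::sd(x) == 0)
      return(c(log_hr = NA_real_, p = NA_real_, flag = 1))
    z <- as.vector(scale(x))
    df <- cbind(data.frame(z = z), cdata)
    fit <- tryCatch(
      suppressWarnings(survival::coxph(y ~ ., data = df, ties = "efron")),
      error = function(e) NULL)
    if (is.null(fit) || is.na(stats::coef(fit)["z"]))
      return(c(log_hr = NA_real_, p = NA_real_, flag = 2))
    beta <- stats::coef(fit)["z"]
    se <- sqrt(diag(fit$var))[1]
    p <- if (test == "score" && length(covariates) == 0)
      summary(fit)$sctest["pvalue"]
    else
      2 * stats::pnorm(-abs(beta / se))
    c(log_hr = unname(beta), p = unname(p), flag = 0)
  }

  rows <- t(vapply(rownames(expr), fit_one, numeric(3)))
  res <- data.frame(mirna_id = rownames(expr),
                    endpoint = endpoint, cohort = cohort,
                    model = paste(covariates, collapse = "+"),
                    log_hr = rows[, "log_hr"],
                    hr_per_sd = exp(rows[, "log_hr"]),
                    p = rows[, "p"],
                    flag = c("ok", "constant", "no_fit")[rows[, "flag"] + 1],
                    stringsAsFactors = FALSE)
  res$q <- NA_real_
  ok <- res$flag == "ok"
  res$q[ok] <- benjamini_hochberg(res$p[ok])
  res$prognostic <- ok & res$p < p_threshold & res$q < q_threshold
  res$direction <- ifelse(is.na(res$hr_per_sd), NA_character_,
                          ifelse(res$hr_per_sd < 1, "favourable",
                                 "unfavourable"))
  rownames(res) <- NULL
  res
}

#' Kaplan-Meier curves over expression tertiles
#'
#' Splits patients into three groups at the empirical 1/3 and 2/3 quantiles
#' of one miRNA's expression (ties broken by stable rank order, so the three
#' groups are always as balanced as the sample size allows), estimates a
#' Kaplan-Meier curve per group and tests the difference with a three-group
#' log-rank test.
#'
#' @param expr_row named numeric vector: one miRNA's expression per patient.
#' @param clinical clinical table.
#' @param endpoint `"DMFS"` or `"BCSS"`.
#' @param exclude_neoadjuvant drop neo-adjuvant-treated patients.
#' @return list with the `survfit` object (`fit`), the per-patient `groups`
#'   factor and `logrank_p`.
#' @export
km_tertiles <- function(expr_row, clinical, endpoint = c("DMFS", "BCSS"),
                        exclude_neoadjuvant = TRUE) {
  endpoint <- match.arg(endpoint)
  patients <- intersect(names(expr_row),
                        cohort_patients(clinical, "all",
                                        exclude_neoadjuvant))
  if (length(patients) < 9) stop("need at least 9 patients")
  x <- expr_row[patients]
  if (stats::sd(x) == 0) stop("constant expression: no tertiles")
  r <- rank(x, ties.method = "first")
  g <- cut(r, breaks = stats::quantile(r, c(0, 1/3, 2/3, 1)),
           include.lowest = TRUE, labels = c("low", "mid", "high"))
  if (any(table(g) == 0)) stop("a tertile collapsed to zero members")
  cl <- clinical[match(patients, clinical$patient_id), ]
  y <- surv_object(cl, endpoint)
  fit <- survival::survfit(y ~ g)
  sd_ <- survival::survdiff(y ~ g)
  logrank_p <- stats::pchisq(sd_$chisq, df = length(sd_$n) - 1,
                             lower.tail = FALSE)
  list(fit = fit, groups = stats::setNames(g, patients),
       logrank_p = logrank_p)
}

#' Calibration of a screening p-value distribution
#'
#' Compares observed p-values to the uniform distribution
#' (Kolmogorov-Smirnov) and, when the expression matrix and clinical table
#' are supplied, builds an empirical null reference by Monte-Carlo
#' permutation of the survival (time, event) pairs across patients: each of
#' the `n_perm` permutations refits the Cox model for one miRNA (cycling
#' through the matrix rows) and contributes one null p-value.
#'
#' @param pvalues numeric vector of observed p-values.
#' @param n_perm number of permutations (default 10000; scale down for
#'   quick checks).
#' @param expr,clinical optional inputs for the permutation reference.
#' @param endpoint survival endpoint for the permutation reference.
#' @param seed optional integer seed for the permutations.
#' @return list with `ks_statistic`, `ks_p` and (when computed)
#'   `perm_pvalues`.
#' @export
pvalue_calibration <- function(pvalues, n_perm = 10000, expr = NULL,
                               clinical = NULL,
                               endpoint = c("DMFS", "BCSS"), seed = NULL) {
  endpoint <- match.arg(endpoint)
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  ks <- suppressWarnings(stats::ks.test(pvalues, "punif"))
  out <- list(ks_statistic = unname(ks$statistic), ks_p = ks$p.value)
  if (!is.null(expr) && !is.null(clinical)) {
    if (!is.null(seed)) set.seed(seed)
    patients <- intersect(colnames(expr), cohort_patients(clinical, "all"))
    cl <- clinical[match(patients, clinical$patient_id), ]
    time <- if (endpoint == "DMFS") cl$dmfs_time else cl$bcss_time
    event <- if (endpoint == "DMFS") cl$dmfs_event else cl$bcss_event
    rows <- rep_len(seq_len(nrow(expr)), n_perm)
    perm <- vapply(rows, function(i) {
      ord <- sample.int(length(patients))
      z <- as.vector(scale(expr[i, patients]))
      fit <- survival::coxph(survival::Surv(time[ord], event[ord]) ~ z,
                             ties = "efron")
      beta <- stats::coef(fit)[1]
      2 * stats::pnorm(-abs(beta / sqrt(fit$var[1, 1])))
    }, 0)
    out$perm_pvalues <- perm
  }
  out
}
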