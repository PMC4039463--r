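# Recompute the headline statistics of the shipped cervical carcinoma
# cohort tables: burden summaries, the dosage cross-tabulation, the
# burden-expression regression, exclusive-set bounds, and survival.

#' Paths to the example cohort tables shipped with the package
#' @param file one of `"cohort"`, `"clinical"`, `"set_counts"`.
#' @return File path.
#' @export
cnadose_example <- function(file = c("cohort", "clinical", "set_counts")) {
  file <- match.arg(file)
  fn <- switch(file, cohort = "cc_cohort_table.tsv",
               clinical = "cc_clinical_table.tsv",
               set_counts = "cc_sam_set_counts.tsv")
  system.file("extdata", fn, package = "cnadose", mustWork = TRUE)
}

#' Read the per-tumor cohort summary table
#' @param path TSV path (defaults to the shipped example).
#' @return data.frame, one row per tumor.
#' @export
read_cohort_table <- function(path = cnadose_example("cohort")) {
  df <- read_tsv(path)
  need <- c("tumor", "pct_genome", "genes_cn", "alt_n", "alt_ex",
            "cn2_n", "cn2_ex", "all_ex")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("malformed cohort table, missing columns: ",
         paste(miss, collapse = ", "))
  df
}

#' Read the clinical follow-up table
#' @param path TSV path (defaults to the shipped example).
#' @return data.frame, one row per patient.
#' @export
read_clinical_table <- function(path = cnadose_example("clinical")) {
  df <- read_tsv(path)
  need <- c("sample", "stage", "treatment", "followup_months", "status")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("malformed clinical table, missing columns: ",
         paste(miss, collapse = ", "))
  df
}

read_set_counts <- function(path = cnadose_example("set_counts")) {
  df <- read_tsv(path)
  setNames(df$value, df$key)
}

#' Recompute headline cohort statistics from the summary tables
#'
#' From the per-tumor table: mean burden, low/medium/high group means, the
#' pooled deregulation rates among CN-altered and 2-copy genes with their
#' difference (the direct-dosage estimate), the CN-altered share of
#' deregulated genes, the burden-vs-deregulation regression, and the
#' altered-gene-count/burden correlation. From the SAM set counts: shared,
#' exclusive-high and recurrence-bound percentages. From the clinical
#' table joined with the per-tumor table: treated-cohort size, crude
#' survival rate, mean time to tumor death, per-stage survival, the
#' Youden-optimal burden cutoff with its split summary and log-rank test,
#' and the FIGO-burden Spearman correlation.
#'
#' @param cohort_table,clinical_table,set_counts paths to the three input
#'   TSVs; default to the tables shipped with the package.
#' @param checks optional path to a TSV with columns `key`, `expected`,
#'   `tolerance`: matching report entries gain pass/fail marks.
#' @return Named list of class `headline_report` (numbers, plus `$checks`
#'   when requested).
#' @export
reproduce_tables <- function(cohort_table = cnadose_example("cohort"),
                             clinical_table = cnadose_example("clinical"),
                             set_counts = cnadose_example("set_counts"),
                             checks = NULL) {
  t1 <- read_cohort_table(cohort_table)
  t2 <- read_clinical_table(clinical_table)
  sc <- read_set_counts(set_counts)

  r <- list()
  # burden over all CN-profiled tumors
  r$n_tumors_cn <- nrow(t1)
  r$mean_pct_cnag <- mean(t1$pct_genome)
  r$sd_pct_cnag <- sd(t1$pct_genome)
  grp <- group_by_burden(data.frame(sample = t1$tumor,
                                    pct_cnag_total = t1$pct_genome))
  gm <- tapply(t1$pct_genome, grp[t1$tumor], mean)
  r$burden_low_mean <- unname(gm["low"])
  r$burden_medium_mean <- unname(gm["medium"])
  r$burden_high_mean <- unname(gm["high"])
  r$genes_burden_r <- cor(t1$pct_genome, t1$genes_cn)

  # dosage cross-tabulation over the expression-profiled tumors
  att <- attribution_from_counts(t1)
  r$n_tumors_expr <- att$n_tumors
  r$rate_cn_altered <- att$rate_altered
  r$rate_cn2 <- att$rate_cn2
  r$dosage_difference <- att$dosage_difference
  r$dereg_share_cn_altered <- att$dereg_share_altered

  e <- t1[!is.na(t1$all_ex), ]
  reg <- burden_expression_regression(e$pct_genome, e$all_ex)
  r$regression_slope <- reg$slope
  r$regression_intercept <- reg$intercept
  r$regression_r <- reg$r
  r$regression_p <- reg$p

  # exclusive-set statistics from the SAM set counts
  es <- exclusive_set_stats(
    sc[["n_deregulated_high"]], sc[["n_deregulated_low"]],
    sc[["n_common"]],
    strata = c(ge6 = sc[["exclusive_high_altered_ge6"]],
               s4_5 = sc[["exclusive_high_altered_4to5"]],
               s1_3 = sc[["exclusive_high_altered_1to3"]],
               s0 = sc[["exclusive_high_altered_0"]]))
  r$pct_shared <- es$pct_shared
  r$pct_exclusive_of_high <- es$pct_exclusive_of_high
  r$pct_dosage_bound <- es$pct_dosage_bound

  # survival of the CN-profiled, treated patients
  cn <- t2[t2$analysis %in% c("CN", "CN/EX"), ]
  cohort <- suppressWarnings(build_survival_cohort(cn))
  r$n_survival <- nrow(cohort)
  r$survival_rate <- survival_rate(cohort)
  r$mean_time_to_death <- mean(cohort$time[cohort$event == 1])
  stage4 <- ifelse(as.character(cohort$figo) %in% c("IVA", "IVB"), "IV",
                   as.character(cohort$figo))
  by_stage <- survival_rate(cohort, stage4)
  for (s in names(by_stage))
    r[[paste0("survival_rate_", s)]] <- unname(by_stage[s])

  m <- merge(cohort, t1, by.x = "sample", by.y = "tumor")
  roc <- roc_burden_cutoff(m$pct_genome, m$event)
  r$roc_cutoff <- roc$cutoff
  r$roc_n_high <- roc$n_high
  r$roc_mean_burden_high <- roc$mean_high
  r$roc_mean_burden_low <- roc$mean_low
  r$roc_death_rate_high <- roc$death_rate_high
  r$roc_death_rate_low <- roc$death_rate_low
  r$roc_logrank_p <- logrank_test(m, m$pct_genome >= roc$cutoff)$p
  sp <- spearman_colinearity(m$figo, data.frame(burden = m$pct_genome))
  r$figo_burden_spearman_rho <- sp$rho[1]
  r$figo_burden_spearman_p <- sp$p[1]

  if (!is.null(checks)) {
    ck <- read_tsv(checks)
    if (nrow(ck) > 0) {
      stopifnot(all(c("key", "expected", "tolerance") %in% names(ck)))
      ck$value <- vapply(ck$key, function(k)
        if (is.null(r[[k]])) NA_real_ else r[[k]], numeric(1))
      ck$pass <- !is.na(ck$value) & abs(ck$value - ck$expected) <= ck$tolerance
      r$checks <- ck
    }
  }
  structure(r, class = "headline_report")
}

#' @export
print.headline_report <- function(x, ...) {
  f1 <- function(v) formatC(v, format = "f", digits = 1)
  cat("Cohort headline statistics\n",
      sprintf("  burden: mean %s%% (SD %s) over %d tumors; groups %s / %s / %s\n",
              f1(x$mean_pct_cnag), f1(x$sd_pct_cnag), x$n_tumors_cn,
              f1(x$burden_low_mean), f1(x$burden_medium_mean),
              f1(x$burden_high_mean)),
      sprintf("  deregulated: %s%% of CN-altered vs %s%% of 2-copy genes (difference %s points)\n",
              f1(x$rate_cn_altered), f1(x$rate_cn2), f1(x$dosage_difference)),
      sprintf("  CN-altered share of deregulated genes: %s%%\n",
              f1(x$dereg_share_cn_altered)),
      sprintf("  deregulated ~ burden: y = %.3gx + %.4g (r = %.2f, p = %.3g)\n",
              x$regression_slope, x$regression_intercept, x$regression_r,
              x$regression_p),
      sprintf("  exclusive sets: shared %s%%, exclusive-high %s%%, dosage bound %s%%\n",
              f1(x$pct_shared), f1(x$pct_exclusive_of_high),
              f1(x$pct_dosage_bound)),
      sprintf("  survival: %s%% of %d treated patients; mean time to death %s months\n",
              f1(x$survival_rate), x$n_survival, f1(x$mean_time_to_death)),
      sprintf("  ROC split: cutoff %.3g%% -> high n = %d (mean %s%%, %s%% died; log-rank p = %.3g)\n",
              x$roc_cutoff, x$roc_n_high, f1(x$roc_mean_burden_high),
              f1(x$roc_death_rate_high), x$roc_logrank_p),
      sprintf("  FIGO ~ burden Spearman rho = %.2f (p = %.3g)\n",
              x$figo_burden_spearman_rho, x$figo_burden_spearman_p))
  if (!is.null(x$checks)) {
    cat("  checks:\n")
    print(x$checks[, c("key", "expected", "value", "tolerance", "pass")],
          row.names = FALSE)
  }
  invisible(x)
}
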