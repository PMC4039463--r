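# The core inference: how much expression deregulation is attributable to
# gene dosage -- cross-tabulation, regression decompositions, and
# exclusive-set recurrence bounds.

#' Pooled attribution rates from per-tumor counts
#'
#' Given, per tumor, the number of CN-altered genes on the expression
#' array, how many of them were deregulated, and the same pair for 2-copy
#' genes, computes the pooled deregulation rate in each dosage class as a
#' ratio of means (mean deregulated count over mean class size -- the
#' convention that reproduces the published per-class averages), their
#' difference in percentage points (the direct gene-dosage estimate), a
#' 2x2 chi-square on the pooled counts, and the share of deregulated genes
#' that are CN-altered.
#'
#' @param counts data.frame with per-tumor columns `alt_n`, `alt_ex`,
#'   `cn2_n`, `cn2_ex` (class sizes and deregulated counts).
#' @return List of class `attribution_summary`.
#' @export
attribution_from_counts <- function(counts) {
  stopifnot(all(c("alt_n", "alt_ex", "cn2_n", "cn2_ex") %in% names(counts)))
  cc <- counts[complete.cases(counts[, c("alt_n", "alt_ex",
                                         "cn2_n", "cn2_ex")]), ]
  if (nrow(cc) == 0) stop("no complete per-tumor counts")
  sa <- sum(cc$alt_n); ea <- sum(cc$alt_ex)
  s2 <- sum(cc$cn2_n); e2 <- sum(cc$cn2_ex)
  rate_altered <- if (sa > 0) 100 * ea / sa else 0
  rate_cn2 <- if (s2 > 0) 100 * e2 / s2 else 0
  chisq_p <- if (ea + e2 > 0 && sa > 0 && s2 > 0)
    suppressWarnings(chisq.test(matrix(c(ea, sa - ea, e2, s2 - e2), 2),
                                correct = FALSE)$p.value)
  else NA_real_
  structure(list(
    per_tumor = cc,
    n_tumors = nrow(cc),
    mean_altered = mean(cc$alt_n), mean_altered_ex = mean(cc$alt_ex),
    mean_cn2 = mean(cc$cn2_n), mean_cn2_ex = mean(cc$cn2_ex),
    rate_altered = rate_altered, rate_cn2 = rate_cn2,
    dosage_difference = rate_altered - rate_cn2,
    chisq_p = chisq_p,
    dereg_share_altered = if (ea + e2 > 0) 100 * ea / (ea + e2) else 0),
    class = "attribution_summary")
}

#' Cross-tabulate gene dosage against expression status
#'
#' Counts, per tumor, deregulated genes among CN-altered (CN1/CN3) and
#' 2-copy (CN2) genes and pools them into the attribution summary.
#'
#' @param dosage a `gene_dosage` object from [map_genes_to_cn()].
#' @param calls expression status matrix from [call_expression_status()],
#'   same gene and tumor universes.
#' @return An `attribution_summary` (see [attribution_from_counts()]).
#' @export
crosstab_attribution <- function(dosage, calls) {
  stopifnot(inherits(dosage, "gene_dosage"))
  status <- dosage$status
  if (!setequal(colnames(status), colnames(calls)))
    stop("tumor universes differ between dosage table and calls")
  if (!identical(rownames(status), rownames(calls)))
    stop("gene universes differ between dosage table and calls")
  calls <- calls[, colnames(status), drop = FALSE]
  dereg <- calls != "unchanged"
  altered <- status != "CN2"
  counts <- data.frame(
    sample = colnames(status),
    alt_n = colSums(altered),
    alt_ex = colSums(altered & dereg),
    cn2_n = colSums(!altered),
    cn2_ex = colSums(!altered & dereg),
    row.names = NULL)
  out <- attribution_from_counts(counts)
  out$per_tumor <- counts
  out
}

#' @export
print.attribution_summary <- function(x, ...) {
  cat("Dosage attribution over", x$n_tumors, "tumors:\n",
      sprintf("  CN-altered genes deregulated: %.1f%%\n", x$rate_altered),
      sprintf("  2-copy genes deregulated:     %.1f%%\n", x$rate_cn2),
      sprintf("  dosage difference:            %.1f points (chi-square p = %.3g)\n",
              x$dosage_difference, x$chisq_p),
      sprintf("  deregulated genes CN-altered: %.1f%%\n",
              x$dereg_share_altered))
  invisible(x)
}

#' Regression of deregulated-gene count on burden
#'
#' Ordinary least squares of the per-tumor total deregulated gene count on
#' the percentage of CN-altered genome, with the Pearson correlation and
#' its two-sided p-value.
#'
#' @param pct_cnag numeric vector of per-tumor burden percentages.
#' @param n_deregulated numeric vector of per-tumor deregulated counts.
#' @return List of class `dosage_regression`: slope, intercept, r, p, n.
#' @export
burden_expression_regression <- function(pct_cnag, n_deregulated) {
  if (length(pct_cnag) != length(n_deregulated))
    stop("inputs differ in length")
  ok <- complete.cases(pct_cnag, n_deregulated)
  x <- pct_cnag[ok]; y <- n_deregulated[ok]
  if (length(x) < 3) stop("need at least 3 tumors")
  if (var(x) == 0) stop("burden has zero variance; correlation undefined")
  fit <- lm(y ~ x)
  ct <- cor.test(x, y)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = unname(ct$estimate), p = ct$p.value,
                 n = length(x)),
            class = "dosage_regression")
}

#' @export
print.dosage_regression <- function(x, ...) {
  cat(sprintf("y = %.3gx + %.4g  (r = %.2f, p = %.3g, n = %d)\n",
              x$slope, x$intercept, x$r, x$p, x$n))
  invisible(x)
}

#' Forward-stepwise decomposition of a response over per-arm burdens
#'
#' Forward selection by partial-F p-value (enter while p < `p_enter`),
#' reporting the selected arms in entry order, the adjusted R-squared of
#' the final model, and the first predictor's share of the final model's
#' R-squared (the "arm X accounts for Y% of the variation" statistic).
#' Predictors that are collinear with already-selected ones are dropped
#' with a warning.
#'
#' @param predictors numeric matrix or data.frame, one column per arm.
#' @param response numeric vector (global burden or deregulated counts).
#' @param p_enter partial-F entry threshold.
#' @return List of class `mlr_decomposition`: `selected`, `coefficients`,
#'   `adj_r2`, `r2`, `first_share`, `steps`.
#' @export
arm_mlr_decomposition <- function(predictors, response, p_enter = 0.05) {
  X <- as.data.frame(predictors)
  y <- response
  stopifnot(nrow(X) == length(y))
  keep <- vapply(X, function(col) var(col) > 0, logical(1))
  if (any(!keep)) {
    warning("dropping constant predictors: ",
            paste(names(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  selected <- character(0)
  steps <- list()
  bt <- function(v) paste0("`", v, "`")
  repeat {
    remaining <- setdiff(names(X), selected)
    if (length(remaining) == 0) break
    cur_fml <- if (length(selected) == 0) "y ~ 1"
    else paste("y ~", paste(bt(selected), collapse = " + "))
    fit0 <- lm(as.formula(cur_fml), data = cbind(X, y = y))
    cand <- vapply(remaining, function(v) {
      dat <- cbind(X, y = y)
      fit1 <- lm(as.formula(paste(cur_fml, "+", bt(v))), data = dat)
      # collinear additions contribute no df
      if (anyNA(coef(fit1))) return(NA_real_)
      av <- anova(fit0, fit1)
      av$`Pr(>F)`[2]
    }, numeric(1))
    cand <- cand[!is.na(cand)]
    if (length(cand) == 0) break
    best <- names(cand)[which.min(cand)]
    if (cand[best] >= p_enter) break
    selected <- c(selected, best)
    steps[[length(steps) + 1]] <- data.frame(arm = best,
                                             partial_f_p = unname(cand[best]))
  }
  if (length(selected) == 0) {
    return(structure(list(selected = character(0), coefficients = numeric(0),
                          adj_r2 = 0, r2 = 0, first_share = NA_real_,
                          steps = data.frame()),
                     class = "mlr_decomposition"))
  }
  final <- lm(as.formula(paste("y ~", paste(bt(selected), collapse = " + "))),
              data = cbind(X, y = y))
  sm <- summary(final)
  first_fit <- lm(y ~ ., data = data.frame(X[, selected[1], drop = FALSE],
                                           y = y))
  first_share <- summary(first_fit)$r.squared / sm$r.squared
  structure(list(selected = selected, coefficients = coef(final),
                 adj_r2 = sm$adj.r.squared, r2 = sm$r.squared,
                 first_share = first_share,
                 steps = do.call(rbind, steps)),
            class = "mlr_decomposition")
}

#' @export
print.mlr_decomposition <- function(x, ...) {
  if (length(x$selected) == 0) {
    cat("Forward stepwise: no predictor entered\n")
    return(invisible(x))
  }
  cat("Forward stepwise selection:", paste(x$selected, collapse = " -> "),
      sprintf("\n  adjusted r^2 = %.3f; first predictor accounts for %.0f%% of model r^2\n",
              x$adj_r2, 100 * x$first_share))
  invisible(x)
}

#' Exclusive-set statistics from set sizes
#'
#' Arithmetic core of [exclusive_set_analysis()], usable directly when only
#' the set sizes are known: percentage of the low-burden group's
#' deregulated genes shared with the high-burden group, percentage of the
#' high group's deregulated genes exclusive to it, and the conservative
#' dosage bound -- the fraction of the exclusive-high set CN-altered in at
#' least `recurrence_threshold` tumors.
#'
#' @param n_high,n_low,n_common sizes of the deregulated-gene sets.
#' @param strata named integer vector of exclusive-high recurrence strata
#'   `c(ge6, s4_5, s1_3, s0)` (altered in >= 6, 4-5, 1-3, 0 tumors).
#' @param recurrence_threshold tumors with the alteration required to count
#'   toward the dosage bound (default 4, i.e. strata `ge6 + s4_5`).
#' @return List of class `exclusive_set_report`.
#' @export
exclusive_set_stats <- function(n_high, n_low, n_common,
                                strata = NULL, recurrence_threshold = 4) {
  if (n_common > min(n_high, n_low)) stop("common set larger than a parent set")
  n_excl <- n_high - n_common
  out <- list(n_high = n_high, n_low = n_low, n_common = n_common,
              n_exclusive_high = n_excl,
              pct_shared = if (n_low > 0) 100 * n_common / n_low else NA_real_,
              pct_exclusive_of_high =
                if (n_high > 0) 100 * n_excl / n_high else NA_real_,
              strata = strata, recurrence_threshold = recurrence_threshold,
              pct_dosage_bound = NA_real_)
  if (!is.null(strata)) {
    stopifnot(all(c("ge6", "s4_5", "s1_3", "s0") %in% names(strata)))
    if (sum(strata) != n_excl)
      stop("recurrence strata do not sum to the exclusive-high set size")
    if (n_excl > 0) {
      n_bound <- if (recurrence_threshold <= 3) NA_real_
      else strata[["ge6"]] + strata[["s4_5"]]
      out$pct_dosage_bound <- 100 * n_bound / n_excl
    }
  }
  structure(out, class = "exclusive_set_report")
}

#' Exclusive-set analysis of high- vs low-burden SAM calls
#'
#' Compares the genes called deregulated (vs the common control group) in
#' the high-burden tumors with those called in the low-burden tumors:
#' genes exclusive to the high group are candidates for dosage-driven
#' deregulation, bounded above by the fraction recurrently CN-altered in
#' the high-burden tumors.
#'
#' @param sam_high,sam_low `sam_fit` objects (or plain character vectors of
#'   gene ids) for the high- and low-burden groups.
#' @param dosage `gene_dosage` table over the full cohort.
#' @param high_tumors sample ids forming the high-burden group.
#' @param recurrence_threshold minimum number of high-burden tumors with
#'   the alteration for the conservative dosage bound (default 4).
#' @return List of class `exclusive_set_report` with the gene sets attached.
#' @export
exclusive_set_analysis <- function(sam_high, sam_low, dosage, high_tumors,
                                   recurrence_threshold = 4) {
  ids <- function(x) if (inherits(x, "sam_fit")) sam_called_genes(x) else x
  d_high <- unique(ids(sam_high)); d_low <- unique(ids(sam_low))
  common <- intersect(d_high, d_low)
  exclusive <- setdiff(d_high, common)
  stopifnot(inherits(dosage, "gene_dosage"))
  if (!all(high_tumors %in% colnames(dosage$status)))
    stop("unknown high-group tumors")
  sub <- dosage$status[, high_tumors, drop = FALSE]
  rec <- rowSums(sub != "CN2")[exclusive]
  rec[is.na(rec)] <- 0  # genes outside the dosage table: never altered
  strata <- c(ge6 = sum(rec >= 6),
              s4_5 = sum(rec >= 4 & rec <= 5),
              s1_3 = sum(rec >= 1 & rec <= 3),
              s0 = sum(rec == 0))
  out <- exclusive_set_stats(length(d_high), length(d_low), length(common),
                             strata, recurrence_threshold)
  out$genes <- list(high = d_high, low = d_low, common = common,
                    exclusive_high = exclusive)
  out
}

#' @export
print.exclusive_set_report <- function(x, ...) {
  cat("Exclusive-set analysis:",
      sprintf("|high| = %d, |low| = %d, |common| = %d\n",
              x$n_high, x$n_low, x$n_common),
      sprintf("  shared with high group: %.1f%% of low-group calls\n",
              x$pct_shared),
      sprintf("  exclusive to high group: %d (%.1f%% of high-group calls)\n",
              x$n_exclusive_high, x$pct_exclusive_of_high))
  if (!is.na(x$pct_dosage_bound))
    cat(sprintf("  conservative dosage bound (altered in >= %d tumors): %.1f%%\n",
                x$recurrence_threshold, x$pct_dosage_bound))
  invisible(x)
}

#' Per-gene correlation of expression with arm burden
#'
#' Pearson correlation of each gene's intensity with the per-tumor burden
#' of one arm, with the two-sided t-based p-value. No multiplicity
#' correction is applied by default (an optional Benjamini-Hochberg flag is
#' provided); constant genes are excluded and flagged.
#'
#' @param arm_burden numeric vector of per-tumor arm burden percentages.
#' @param expr intensity matrix (genes x tumors), columns aligned with
#'   `arm_burden`.
#' @param alpha significance level.
#' @param bh_adjust apply Benjamini-Hochberg across genes before flagging.
#' @return data.frame: gene_id, r, p, significant, excluded.
#' @export
arm_burden_gene_correlation <- function(arm_burden, expr, alpha = 0.05,
                                        bh_adjust = FALSE) {
  if (length(arm_burden) != ncol(expr)) stop("dimension mismatch")
  if (length(arm_burden) < 3) stop("need at least 3 tumors")
  res <- lapply(seq_len(nrow(expr)), function(i) {
    y <- expr[i, ]
    if (var(y) == 0 || var(arm_burden) == 0)
      return(data.frame(r = NA_real_, p = NA_real_, excluded = TRUE))
    ct <- cor.test(arm_burden, y)
    data.frame(r = unname(ct$estimate), p = ct$p.value, excluded = FALSE)
  })
  out <- do.call(rbind, res)
  out <- cbind(gene_id = rownames(expr), out)
  padj <- if (bh_adjust) p.adjust(out$p, "BH") else out$p
  out$significant <- !out$excluded & !is.na(padj) & padj < alpha
  rownames(out) <- NULL
  out
}
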