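# Survival analysis of burden and expression-profile groups: cohort
# construction, Kaplan-Meier, log-rank, ROC burden cutoff, Cox adjustment,
# and FIGO co-linearity checks.

figo_ordinal <- function(stage) {
  f <- factor(stage, levels = figo_levels, ordered = TRUE)
  if (anyNA(f) && !anyNA(stage)) stop("unknown FIGO stage value")
  f
}

#' Build a cause-specific survival cohort from a clinical table
#'
#' Untreated patients are excluded (with a warning counting them); deaths
#' from the primary tumor are events; deaths of other/unknown cause are
#' censored at the death time, as are patients alive at last follow-up.
#'
#' @param clinical data.frame with columns `sample`, `figo_stage` (or
#'   `stage`), `followup_months`, `status` (alive / death /
#'   censored-death), and either `treated` (logical) or `treatment`
#'   (character; `"UNTREATED"` marks refusals).
#' @return data.frame of class `surv_cohort` with `sample`, `time`,
#'   `event`, `figo` (ordered factor) and any grouping columns carried
#'   through.
#' @export
build_survival_cohort <- function(clinical) {
  cl <- clinical
  if (is.null(cl$figo_stage) && !is.null(cl$stage)) cl$figo_stage <- cl$stage
  if (is.null(cl$treated)) {
    if (is.null(cl$treatment)) stop("need a treated flag or treatment column")
    cl$treated <- cl$treatment != "UNTREATED"
  }
  stopifnot(all(c("sample", "followup_months", "status") %in% names(cl)))
  bad <- is.na(cl$followup_months)
  if (any(bad))
    stop("missing follow-up time for: ",
         paste(cl$sample[bad], collapse = ", "))
  if (!all(cl$status %in% c("alive", "death", "censored-death")))
    stop("status must be alive / death / censored-death")
  n_untreated <- sum(!cl$treated)
  if (n_untreated > 0)
    warning(n_untreated, " untreated patient(s) excluded from survival analysis")
  cl <- cl[cl$treated, , drop = FALSE]
  if (nrow(cl) == 0) {
    warning("no treated patients; empty survival cohort")
  }
  out <- data.frame(sample = cl$sample,
                    time = as.numeric(cl$followup_months),
                    event = as.integer(cl$status == "death"),
                    figo = if (!is.null(cl$figo_stage))
                      figo_ordinal(cl$figo_stage) else NA,
                    row.names = NULL)
  class(out) <- c("surv_cohort", "data.frame")
  out
}

#' Kaplan-Meier estimates per group
#'
#' Product-limit estimator (ties handled as simultaneous events) via the
#' survival package.
#'
#' @param cohort a `surv_cohort`.
#' @param group factor/vector aligned with the cohort rows (or NULL for a
#'   single curve).
#' @return Named list (per group) of data.frames `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(cohort, group = NULL) {
  df <- data.frame(time = cohort$time, event = cohort$event,
                   group = if (is.null(group)) "all" else as.character(group))
  out <- lapply(split(df, df$group), function(g) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = g)
    data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
               n_censor = fit$n.censor, surv = fit$surv)
  })
  out
}

#' Log-rank test of survival between groups
#'
#' @param cohort a `surv_cohort`.
#' @param group grouping vector (>= 2 groups, each non-empty).
#' @return List: `chisq`, `df`, `p`.
#' @export
logrank_test <- function(cohort, group) {
  g <- droplevels(factor(group))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  sd <- survival::survdiff(survival::Surv(cohort$time, cohort$event) ~ g)
  df <- length(sd$n) - 1
  list(chisq = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Burden cutoff maximising the Youden index
#'
#' Scans every observed burden value as a candidate threshold (high group:
#' burden >= threshold) and returns the one maximising
#' J = sensitivity + specificity - 1 for predicting the event, ties
#' resolved toward the lower cutoff. Invariant to patient order.
#'
#' @param burdens numeric per-patient burden percentages.
#' @param events logical/0-1 event indicators.
#' @return List of class `roc_cutoff`: cutoff, sensitivity, specificity,
#'   J, group sizes and group means at the split.
#' @export
roc_burden_cutoff <- function(burdens, events) {
  ev <- as.logical(events)
  if (all(ev) || !any(ev)) stop("need both event classes")
  if (length(burdens) != length(ev)) stop("length mismatch")
  cand <- sort(unique(burdens))
  J <- vapply(cand, function(cc) {
    hi <- burdens >= cc
    sum(ev & hi) / sum(ev) + sum(!ev & !hi) / sum(!ev) - 1
  }, numeric(1))
  best <- which.max(J)  # first maximum = lowest cutoff on ties
  cutoff <- cand[best]
  hi <- burdens >= cutoff
  structure(list(cutoff = cutoff,
                 sensitivity = sum(ev & hi) / sum(ev),
                 specificity = sum(!ev & !hi) / sum(!ev),
                 J = J[best],
                 n_high = sum(hi), n_low = sum(!hi),
                 mean_high = mean(burdens[hi]),
                 mean_low = mean(burdens[!hi]),
                 death_rate_high = 100 * mean(ev[hi]),
                 death_rate_low = 100 * mean(ev[!hi])),
            class = "roc_cutoff")
}

#' @export
print.roc_cutoff <- function(x, ...) {
  cat(sprintf("ROC burden cutoff %.3g%% (J = %.2f): high n = %d (mean %.1f%%, %.1f%% died), low n = %d (mean %.1f%%, %.1f%% died)\n",
              x$cutoff, x$J, x$n_high, x$mean_high, x$death_rate_high,
              x$n_low, x$mean_low, x$death_rate_low))
  invisible(x)
}

#' Cox proportional-hazards adjustment
#'
#' Partial-likelihood fit with Breslow tie handling; each covariate's
#' Wald test indicates whether it remains significant after the others
#' (typically FIGO stage) are included. Monotone-likelihood covariates
#' (perfect separation) are flagged and their coefficients capped.
#'
#' @param cohort a `surv_cohort`.
#' @param covariates data.frame of numeric/ordinal covariates aligned with
#'   the cohort rows.
#' @param alpha significance level for the `significant` flag.
#' @return data.frame: term, coef, se, z, p, significant, flagged.
#' @export
cox_adjusted <- function(cohort, covariates, alpha = 0.05) {
  if (sum(cohort$event) < 2) stop("need at least 2 events")
  constant <- vapply(covariates, function(v) var(as.numeric(v)) == 0,
                     logical(1))
  if (any(constant))
    stop("zero-variance covariate(s): ",
         paste(names(covariates)[constant], collapse = ", "))
  dat <- cbind(data.frame(time = cohort$time, event = cohort$event),
               covariates)
  fml <- as.formula(paste("survival::Surv(time, event) ~",
                          paste(names(covariates), collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = dat, ties = "breslow",
                    control = survival::coxph.control(iter.max = 50,
                                                      eps = 1e-9)),
    warning = function(w) {
      suppressWarnings(survival::coxph(fml, data = dat, ties = "breslow",
                                       control = survival::coxph.control(
                                         iter.max = 50, eps = 1e-9)))
    })
  sm <- summary(fit)
  co <- sm$coefficients
  flagged <- abs(co[, "coef"]) > 15 | is.na(co[, "se(coef)"])
  coefs <- co[, "coef"]
  coefs[flagged & coefs > 15] <- 15
  coefs[flagged & coefs < -15] <- -15
  if (any(flagged))
    warning("monotone likelihood suspected for: ",
            paste(rownames(co)[flagged], collapse = ", "),
            "; coefficient capped")
  data.frame(term = rownames(co), coef = coefs, se = co[, "se(coef)"],
             z = co[, "z"], p = co[, "Pr(>|z|)"],
             significant = !is.na(co[, "Pr(>|z|)"]) &
               co[, "Pr(>|z|)"] < alpha,
             flagged = flagged, row.names = NULL)
}

#' Spearman co-linearity of FIGO stage with continuous measures
#'
#' Rank correlation (mid-ranks for ties) with the t-approximation p-value,
#' per measure. Constant measures are flagged with NA.
#'
#' @param figo ordered factor (or integer codes) of FIGO stages.
#' @param measures data.frame/matrix of per-patient measures.
#' @return data.frame: measure, rho, p, flagged.
#' @export
spearman_colinearity <- function(figo, measures) {
  fr <- as.integer(figo_ordinal(as.character(figo)))
  if (length(fr) < 3) stop("need at least 3 patients")
  m <- as.data.frame(measures)
  out <- lapply(names(m), function(v) {
    y <- m[[v]]
    if (var(y, na.rm = TRUE) == 0 || var(fr) == 0)
      return(data.frame(measure = v, rho = NA_real_, p = NA_real_,
                        flagged = TRUE))
    ct <- suppressWarnings(cor.test(fr, y, method = "spearman",
                                    exact = FALSE))
    data.frame(measure = v, rho = unname(ct$estimate), p = ct$p.value,
               flagged = FALSE)
  })
  do.call(rbind, out)
}

#' Survival proportion at end of follow-up
#'
#' The crude proportion of patients not recorded as dying of the primary
#' tumor (alive or censored), overall or by group.
#'
#' @param cohort a `surv_cohort`.
#' @param group optional grouping vector.
#' @return Numeric (overall) or named numeric (per group), percent.
#' @export
survival_rate <- function(cohort, group = NULL) {
  if (is.null(group)) return(100 * mean(cohort$event == 0))
  100 * tapply(cohort$event == 0, group, mean)
}
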