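test_that("cohort construction excludes untreated patients and codes events", {
  t2 <- read_clinical_table()
  cn <- t2[t2$analysis %in% c("CN", "CN/EX"), ]
  expect_equal(nrow(cn), 31)
  expect_warning(cohort <- build_survival_cohort(cn), "3 untreated")
  expect_equal(nrow(cohort), 28)
  expect_equal(round(survival_rate(cohort), 1), 64.3)
  expect_equal(round(mean(cohort$time[cohort$event == 1])), 19)
  # the unknown-cause death is censored, not an event
  expect_equal(cohort$event[cohort$sample == "R221"], 0)
  # all untreated -> empty cohort with warning
  allun <- transform(cn, treatment = "UNTREATED")
  w <- capture_warnings(empty <- build_survival_cohort(allun))
  expect_match(w, "untreated", all = FALSE)
  expect_match(w, "empty", all = FALSE)
  expect_equal(nrow(empty), 0)
  # missing follow-up identifies the patient
  cn2 <- cn; cn2$followup_months[3] <- NA
  expect_error(build_survival_cohort(cn2), cn2$sample[3])
})

test_that("Kaplan-Meier matches the hand-computed worked example", {
  cohort <- structure(data.frame(sample = letters[1:6],
                                 time = c(1, 2, 3, 4, 5, 6),
                                 event = c(1, 0, 1, 1, 0, 1),
                                 figo = NA),
                      class = c("surv_cohort", "data.frame"))
  km <- km_estimate(cohort)[["all"]]
  ev <- km[km$n_event > 0, ]
  expect_equal(ev$time, c(1, 3, 4, 6))
  expect_equal(ev$surv, c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 2 / 3, 0),
               tolerance = 1e-12)
  # no events: survival stays at 1
  cohort0 <- transform(cohort, event = 0)
  class(cohort0) <- c("surv_cohort", "data.frame")
  expect_true(all(km_estimate(cohort0)[["all"]]$surv == 1))
})

test_that("log-rank statistic is null for identical groups and shifts invariant", {
  cohort <- structure(data.frame(sample = 1:10,
                                 time = c(2, 4, 6, 8, 10, 2, 4, 6, 8, 10),
                                 event = c(1, 0, 1, 1, 0, 1, 0, 1, 1, 0),
                                 figo = NA),
                      class = c("surv_cohort", "data.frame"))
  lr <- logrank_test(cohort, rep(c("a", "b"), each = 5))
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  expect_error(logrank_test(cohort, rep("a", 10)), "2 groups")
  # invariance to adding a constant to all times
  set.seed(60)
  cohort2 <- cohort
  cohort2$time <- cohort$time + 7
  g <- rep(c("a", "b"), 5)
  expect_equal(logrank_test(cohort, g)$chisq,
               logrank_test(cohort2, g)$chisq, tolerance = 1e-12)
})

test_that("log-rank p agrees with a label-permutation Monte Carlo null", {
  set.seed(61)
  cohort <- structure(data.frame(sample = 1:12,
                                 time = c(3, 5, 7, 8, 9, 12, 2, 4, 6, 10,
                                          11, 13),
                                 event = c(1, 1, 0, 1, 1, 0, 1, 0, 1, 1,
                                           0, 1),
                                 figo = NA),
                      class = c("surv_cohort", "data.frame"))
  g <- rep(c("a", "b"), each = 6)
  obs <- logrank_test(cohort, g)$chisq
  B <- 4000
  null <- replicate(B, logrank_test(cohort, sample(g))$chisq)
  p_mc <- mean(null >= obs - 1e-12)
  p_asym <- logrank_test(cohort, g)$p
  se <- sqrt(p_mc * (1 - p_mc) / B)
  expect_lt(abs(p_asym - p_mc), 2 * se + 0.05)
})

test_that("burden-linked hazards give the log-rank test power", {
  g <- small_genome(marker_spacing = 5e4, n_genes = 50)
  rej <- 0; n_rep <- 50
  for (r in seq_len(n_rep)) {
    co <- generate_cohort(cohort_config(genome = g, n_trans_genes = 5,
                                        untreated_prob = 0), seed = 300 + r)
    cohort <- build_survival_cohort(co$clinical)
    burden <- co$truth$burden$pct_altered[match(cohort$sample,
                                                co$truth$burden$sample)]
    grp <- group_by_burden(data.frame(sample = cohort$sample,
                                      pct_cnag_total = burden))
    if (logrank_test(cohort, grp[cohort$sample])$p < 0.05) rej <- rej + 1
  }
  expect_gt(rej / n_rep, 0.8)
})

test_that("ROC cutoff maximises Youden J with ties to the lower threshold", {
  # perfectly separating burdens
  roc <- roc_burden_cutoff(c(1, 2, 3, 10, 11, 12),
                           c(0, 0, 0, 1, 1, 1))
  expect_equal(roc$J, 1)
  expect_equal(roc$cutoff, 10)
  expect_error(roc_burden_cutoff(1:5, rep(1, 5)), "both event classes")
  # exhaustive-scan oracle and order invariance
  set.seed(62)
  for (r in 1:10) {
    b <- round(runif(25, 0, 30), 1)
    ev <- rbinom(25, 1, plogis((b - 15) / 5))
    if (all(ev == ev[1])) next
    roc <- roc_burden_cutoff(b, ev)
    cand <- sort(unique(b))
    J <- vapply(cand, function(cc) {
      hi <- b >= cc
      sum(ev == 1 & hi) / sum(ev) + sum(ev == 0 & !hi) / sum(ev == 0) - 1
    }, numeric(1))
    expect_equal(roc$J, max(J), tolerance = 1e-12)
    expect_equal(roc$cutoff, cand[which(J == max(J))[1]])
    o <- sample(25)
    roc2 <- roc_burden_cutoff(b[o], ev[o])
    expect_equal(roc2$cutoff, roc$cutoff)
  }
})

test_that("the Youden optimum agrees with an independent ROC implementation", {
  set.seed(65)
  b <- round(runif(40, 0, 30), 1)
  ev <- rbinom(40, 1, plogis((b - 14) / 5))
  roc <- roc_burden_cutoff(b, ev)
  pr <- pROC::roc(response = ev, predictor = b, levels = c(0, 1),
                  direction = "<", quiet = TRUE)
  cs <- pROC::coords(pr, "best", best.method = "youden",
                     ret = c("sensitivity", "specificity"))
  expect_equal(roc$J, max(cs$sensitivity + cs$specificity - 1),
               tolerance = 1e-12)
})

test_that("Cox fit matches the hand-derived two-event partial likelihood", {
  # 4 patients, binary covariate, events at t=1 (x=1) and t=2 (x=0):
  # score equation gives exp(beta) = sqrt(2)
  cohort <- structure(data.frame(sample = 1:4, time = c(1, 2, 3, 4),
                                 event = c(1, 1, 0, 0), figo = NA),
                      class = c("surv_cohort", "data.frame"))
  fit <- cox_adjusted(cohort, data.frame(x = c(1, 0, 1, 0)))
  expect_equal(fit$coef, log(sqrt(2)), tolerance = 1e-6)
  expect_error(cox_adjusted(cohort, data.frame(x = rep(1, 4))),
               "zero-variance")
})

test_that("Wald p-values are near-uniform for an independent covariate", {
  set.seed(63)
  ps <- replicate(150, {
    n <- 40
    time <- rexp(n, 0.1)
    cens <- runif(n, 5, 25)
    cohort <- structure(data.frame(sample = seq_len(n),
                                   time = pmin(time, cens),
                                   event = as.integer(time <= cens),
                                   figo = NA),
                        class = c("surv_cohort", "data.frame"))
    cox_adjusted(cohort, data.frame(x = rnorm(n)))$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Spearman co-linearity equals Pearson on mid-ranks", {
  figo <- c("IB1", "IB1", "IB2", "IIA", "IIB", "IIIB", "IIIB", "IVA",
            "IVB", "IB1", "IIB", "IIIB", "IB2", "IVB", "IIA")
  set.seed(64)
  y <- rnorm(15)
  got <- spearman_colinearity(figo, data.frame(m = y))
  fr <- as.integer(factor(figo, levels = c("IB1", "IB2", "IIA", "IIB",
                                           "IIIB", "IVA", "IVB")))
  expect_equal(got$rho, cor(rank(fr), rank(y)), tolerance = 1e-12)
  # perfect monotone measure
  got2 <- spearman_colinearity(figo, data.frame(m = fr * 2 + 1))
  expect_equal(got2$rho, 1)
  # constant measure flagged
  got3 <- spearman_colinearity(figo, data.frame(m = rep(3, 15)))
  expect_true(got3$flagged)
})
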