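test_that("all-unchanged calls give zero rates and zero difference", {
  status <- matrix(c("CN3", "CN2", "CN2", "CN1", "CN2", "CN2"), 3, 2,
                   dimnames = list(c("g1", "g2", "g3"), c("t1", "t2")))
  dos <- structure(list(status = status,
                        recurrence = data.frame(gene_id = rownames(status))),
                   class = "gene_dosage")
  calls <- matrix("unchanged", 3, 2, dimnames = dimnames(status))
  att <- crosstab_attribution(dos, calls)
  expect_equal(att$rate_altered, 0)
  expect_equal(att$rate_cn2, 0)
  expect_equal(att$dosage_difference, 0)
  # mismatched tumor universes error
  expect_error(crosstab_attribution(dos, calls[, 1, drop = FALSE]),
               "tumor universes")
})

test_that("pooled rates are ratios of mean counts", {
  counts <- data.frame(alt_n = c(100, 300), alt_ex = c(30, 30),
                       cn2_n = c(900, 700), cn2_ex = c(90, 35))
  att <- attribution_from_counts(counts)
  expect_equal(att$rate_altered, 100 * 60 / 400)
  expect_equal(att$rate_cn2, 100 * 125 / 1600)
  expect_equal(att$dosage_difference, att$rate_altered - att$rate_cn2)
  expect_equal(att$dereg_share_altered, 100 * 60 / 185)
})

test_that("burden regression reproduces the closed-form least squares fit", {
  # exact line
  fit <- burden_expression_regression(1:10, 2 * (1:10))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r, 1)
  # closed-form normal-equation oracle on random points
  set.seed(33)
  for (r in 1:5) {
    x <- rnorm(5); y <- rnorm(5)
    got <- burden_expression_regression(x, y)
    sxx <- sum((x - mean(x))^2)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    expect_equal(got$slope, slope, tolerance = 1e-12)
    expect_equal(got$intercept, mean(y) - slope * mean(x), tolerance = 1e-12)
    rr <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sxx * sum((y - mean(y))^2))
    expect_equal(got$r, rr, tolerance = 1e-12)
  }
  expect_error(burden_expression_regression(rep(1, 5), rnorm(5)),
               "zero variance")
  expect_error(burden_expression_regression(1:2, 1:2), "at least 3")
})

test_that("forward stepwise matches simple OLS with one predictor", {
  set.seed(40)
  x <- rnorm(30); y <- 2 * x + rnorm(30, 0, 0.5)
  m <- arm_mlr_decomposition(data.frame(a = x), y)
  expect_equal(m$selected, "a")
  expect_equal(unname(m$coefficients[2]),
               unname(coef(lm(y ~ x))[2]), tolerance = 1e-12)
  expect_equal(m$first_share, 1)
})

test_that("forward stepwise finds the planted predictor and best subsets", {
  set.seed(41)
  for (r in 1:5) {
    n <- 40
    X <- as.data.frame(matrix(rnorm(n * 5), n))
    names(X) <- paste0("x", 1:5)
    y <- X$x1 + 0.6 * X$x3 + rnorm(n, 0, 0.4)
    m <- arm_mlr_decomposition(X, y)
    expect_equal(m$selected[1], "x1")
    # exhaustive best-subset oracle: the selected set of size k attains the
    # maximum R^2 over all subsets of size k
    for (k in seq_along(m$selected)) {
      subsets <- combn(names(X), k, simplify = FALSE)
      r2 <- vapply(subsets, function(ss)
        summary(lm(y ~ ., data = data.frame(X[ss], y = y)))$r.squared,
        numeric(1))
      best <- subsets[[which.max(r2)]]
      expect_setequal(m$selected[seq_len(k)], best)
    }
  }
})

test_that("collinear and constant predictors are dropped with a warning", {
  set.seed(42)
  x <- rnorm(25)
  X <- data.frame(a = x, b = x, cst = 1)
  y <- x + rnorm(25, 0, 0.2)
  expect_warning(m <- arm_mlr_decomposition(X, y), "constant")
  expect_equal(m$selected, "a")  # b is collinear with a, never adds
})

test_that("exclusive-set statistics follow exact set algebra", {
  es <- exclusive_set_stats(1757, 1104, 895,
                            strata = c(ge6 = 79, s4_5 = 118,
                                       s1_3 = 370, s0 = 295))
  expect_equal(round(es$pct_shared, 1), 81.1)
  expect_equal(round(es$pct_exclusive_of_high, 1), 49.1)
  expect_equal(round(es$pct_dosage_bound, 1), 22.9)
  expect_equal(es$n_exclusive_high, 862)
  expect_error(exclusive_set_stats(10, 10, 11), "larger")
  expect_error(exclusive_set_stats(10, 5, 2, strata = c(ge6 = 1, s4_5 = 1,
                                                        s1_3 = 1, s0 = 1)),
               "sum")
})

test_that("exclusive-set analysis on gene sets matches brute-force sets", {
  set.seed(44)
  genes <- sprintf("g%03d", 1:120)
  status <- matrix(sample(c("CN2", "CN3", "CN1"), 120 * 10, TRUE,
                          prob = c(0.7, 0.2, 0.1)), 120, 10,
                   dimnames = list(genes, sprintf("t%d", 1:10)))
  dos <- structure(list(status = status,
                        recurrence = data.frame(gene_id = genes)),
                   class = "gene_dosage")
  d_high <- sample(genes, 60); d_low <- sample(genes, 40)
  es <- exclusive_set_analysis(d_high, d_low, dos, sprintf("t%d", 1:10))
  expect_equal(es$n_common, length(intersect(d_high, d_low)))
  expect_equal(sum(es$strata), es$n_exclusive_high)
  excl <- setdiff(d_high, d_low)
  rec <- rowSums(status[excl, ] != "CN2")
  expect_equal(unname(es$strata[["ge6"]]), sum(rec >= 6))
  expect_equal(unname(es$strata[["s0"]]), sum(rec == 0))
  expect_equal(es$pct_dosage_bound, 100 * sum(rec >= 4) / length(excl))
  # identical sets: nothing exclusive, fully shared
  es2 <- exclusive_set_analysis(d_high, d_high, dos, sprintf("t%d", 1:10))
  expect_equal(es2$n_exclusive_high, 0)
  expect_equal(es2$pct_shared, 100)
})

test_that("per-gene burden correlations match the t-distribution transform", {
  burden <- c(1, 3, 5, 8, 10, 14, 20, 22, 25, 30)
  # exact linear gene
  expr <- rbind(lin = 10 * burden,
                flat = rep(5, 10))
  got <- arm_burden_gene_correlation(burden, expr)
  expect_equal(got$r[1], 1)
  expect_true(got$significant[1])
  expect_true(got$excluded[2])
  set.seed(45)
  rnd <- matrix(rnorm(50), 5, 10)
  rownames(rnd) <- paste0("r", 1:5)
  got2 <- arm_burden_gene_correlation(burden, rnd)
  for (i in 1:5) {
    r <- cor(burden, rnd[i, ])
    tstat <- r * sqrt(8 / (1 - r^2))
    expect_equal(got2$p[i], 2 * pt(-abs(tstat), 8), tolerance = 1e-12)
  }
})

test_that("planted trans genes are recovered from amplified-arm burden", {
  g <- default_genome(marker_spacing = 1e4)
  co <- generate_cohort(cohort_config(genome = g), seed = 6)
  sub <- co$expr[co$truth$trans_genes, 1:27, drop = FALSE]
  ab <- co$truth$burden$amp_arm_pct_gained[1:27]
  got <- arm_burden_gene_correlation(ab, sub)
  expect_gte(mean(got$significant), 0.8)
})
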