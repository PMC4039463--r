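test_that("genome model enforces its invariants", {
  arms <- data.frame(arm_id = c("a", "b"), length = c(1e6, 2e6))
  genes <- data.frame(gene_id = c("g1", "g2"), arm_id = "a",
                      start = c(0, 5e5), end = c(1e4, 5.1e5))
  g <- genome_model(arms, genes, 1000)
  expect_s3_class(g, "genome_model")
  expect_error(genome_model(arms, transform(genes, end = c(6e5, 5.1e5)),
                            1000), "overlapping")
  expect_error(genome_model(arms, transform(genes, arm_id = "z"), 1000),
               "unknown arm")
  expect_error(genome_model(arms, transform(genes, end = c(1e4, 3e6)),
                            1000), "outside")
  expect_error(genome_model(arms, genes, 0), "positive")
  pos <- marker_positions(g)
  expect_true(all(vapply(pos, function(p) !is.unsorted(p, strictly = TRUE),
                         logical(1))))
})

test_that("generator rejects invalid configurations", {
  expect_error(cohort_config(n_tumors = 2), "at least 3")
  expect_error(cohort_config(direct_dosage_fraction = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(amplified_arm = "nope"), "amplified_arm")
  one_arm <- genome_model(data.frame(arm_id = "3q", length = 1e7),
                          data.frame(gene_id = "g1", arm_id = "3q",
                                     start = 0, end = 1e4), 1000)
  expect_error(cohort_config(genome = one_arm), "2 arms")
})

test_that("identical config and seed give byte-identical cohorts", {
  cfg <- small_config(n_tumors = 5, n_controls = 4)
  a <- generate_cohort(cfg, seed = 11)
  b <- generate_cohort(cfg, seed = 11)
  expect_identical(a, b)
  c <- generate_cohort(cfg, seed = 12)
  expect_false(identical(a$expr, c$expr))
})

test_that("null-effect cohort has tumor expression equal to control baseline", {
  cfg <- small_config(n_tumors = 4, n_controls = 3,
                      dosage_effect = 0, trans_effect_slope = 0,
                      noise_sd = 0)
  co <- generate_cohort(cfg, seed = 2)
  # noise-free: every control column is the baseline, tumors match it
  expect_equal(unname(co$expr[, 1]), unname(co$controls[, 1]))
  expect_true(all(co$expr == co$controls[, 1]))
})

test_that("realized stratum burdens track their targets within a point", {
  g <- default_genome(marker_spacing = 1e4)
  real <- sapply(1:10, function(s) {
    co <- generate_cohort(cohort_config(genome = g), seed = s)
    tapply(co$truth$burden$pct_altered, co$truth$burden$stratum,
           mean)[c("low", "medium", "high")]
  })
  m <- rowMeans(real)
  expect_lt(abs(m[["low"]] - 0.5), 1)
  expect_lt(abs(m[["medium"]] - 5.4), 1)
  expect_lt(abs(m[["high"]] - 19.2), 1)
})

test_that("markers inside planted segments carry the dosage signal", {
  co <- generate_cohort(small_config(n_tumors = 5, n_controls = 3), seed = 4)
  segs <- co$truth$segments
  big <- segs[segs$cn == 3 & (segs$end - segs$start) > 5e6, ]
  expect_gt(nrow(big), 0)
  s <- big[1, ]
  tr <- co$markers[[s$sample]]
  inside <- tr$arm == s$arm & tr$position >= s$start & tr$position < s$end
  expect_gt(sum(inside), 100)
  expect_lt(abs(mean(tr$log2ratio[inside]) - log2(3 / 2)), 0.05)
})

test_that("cohorts round-trip exactly through write and read", {
  co <- generate_cohort(small_config(n_tumors = 4, n_controls = 3), seed = 9)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_identical(back$expr, structure(co$expr, scale = "linear"))
  expect_identical(back$controls, structure(co$controls, scale = "linear"))
  expect_equal(back$markers[[names(co$markers)[1]]]$log2ratio,
               co$markers[[1]]$log2ratio)
  expect_equal(back$genome$genes, co$genome$genes)
  expect_equal(nrow(back$truth$segments), nrow(co$truth$segments))
  # determinism on disk: writing twice gives hash-identical files
  dir2 <- withr::local_tempdir()
  write_cohort(co, dir2)
  f <- list.files(dir, full.names = TRUE)
  f2 <- file.path(dir2, basename(f))
  expect_identical(unname(tools::md5sum(f)), unname(tools::md5sum(f2)))
})

test_that("an empty-genome cohort writes valid header-only files", {
  arms <- data.frame(arm_id = c("a", "b"), length = c(1e7, 1e7))
  genes <- data.frame(gene_id = character(), arm_id = character(),
                      start = numeric(), end = numeric())
  g <- genome_model(arms, genes, 1e5)
  co <- generate_cohort(cohort_config(n_tumors = 3, n_controls = 3,
                                      genome = g, n_trans_genes = 0,
                                      amplified_arm = "a"),
                        seed = 1)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$genome$genes), 0)
  expect_equal(nrow(back$expr), 0)
})

test_that("generated FIGO stage correlates with burden near the design target", {
  g <- default_genome(marker_spacing = 1e4)
  rho <- sapply(1:20, function(s) {
    co <- generate_cohort(cohort_config(genome = g), seed = 100 + s)
    spearman_colinearity(co$clinical$figo_stage,
                         data.frame(burden = co$truth$burden$pct_altered))$rho
  })
  expect_gt(mean(rho), 0.3)
  expect_lt(mean(rho), 0.7)
})
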