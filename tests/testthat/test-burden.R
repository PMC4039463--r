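make_genome <- function() {
  arms <- data.frame(arm_id = c("a", "b"), length = c(6e7, 4e7))
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      arm_id = c("a", "a", "b"),
                      start = c(1e6, 3.05e7, 1e6),
                      end = c(1.1e6, 3.06e7, 1.2e6))
  genome_model(arms, genes, 1e4)
}

test_that("burden arithmetic matches direct calculation", {
  g <- make_genome()
  # no CNAs
  b0 <- compute_burden(seg_df(start = 0, end = 0, state = 3)[0, ], g,
                       samples = "s1")
  expect_equal(b0$totals$pct_cnag_total, 0)
  # single 30 Mb gain against a 3,000 Mb genome: 1.0% total, all gained
  cna <- seg_df(start = 0, end = 3e7, state = 3)
  b1 <- compute_burden(cna, g)
  expect_equal(b1$totals$pct_cnag_total, 1)
  expect_equal(b1$totals$pct_gained, 1)
  expect_equal(b1$totals$pct_deleted, 0)
  # per-arm percentage uses the arm length: 30/60 Mb = 50%
  expect_equal(b1$per_arm$pct_altered[b1$per_arm$arm == "a"], 50)
})

test_that("short segments do not count toward burden and overlaps error", {
  g <- make_genome()
  cnas <- rbind(seg_df(start = 0, end = 2e6, state = 3),       # <= 2.5 Mb
                seg_df(start = 1e7, end = 1.3e7, state = 1))
  b <- compute_burden(cnas, g)
  expect_equal(b$totals$pct_cnag_total, 100 * 3e6 / 3e9)
  bad <- rbind(seg_df(start = 0, end = 1e7, state = 3),
               seg_df(start = 5e6, end = 1.5e7, state = 1))
  expect_error(compute_burden(bad, g), "overlapping")
})

test_that("per-arm altered bases sum to the genome-level total", {
  co <- generate_cohort(small_config(n_tumors = 6, n_controls = 3), seed = 3)
  cnas <- filter_cnas(collapse_cn4(viterbi_segment(co$markers, hmm_params())))
  b <- compute_burden(cnas, co$genome, samples = names(co$markers),
                      genome_size_mb = sum(co$genome$arms$length) / 1e6,
                      alteration_min_length = 2.5e5)
  arm_len <- setNames(co$genome$arms$length, co$genome$arms$arm_id)
  for (s in b$totals$sample) {
    pa <- b$per_arm[b$per_arm$sample == s, ]
    arm_bases <- sum(pa$pct_altered / 100 * arm_len[pa$arm])
    tot_bases <- b$totals$pct_cnag_total[b$totals$sample == s] / 100 *
      sum(arm_len)
    expect_equal(arm_bases, tot_bases, tolerance = 1e-9)
  }
})

test_that("burden groups are ordered, stable under permutation, and sized 11/10/10", {
  t1 <- read_cohort_table()
  tot <- data.frame(sample = t1$tumor, pct_cnag_total = t1$pct_genome)
  grp <- group_by_burden(tot)
  expect_equal(as.vector(table(grp)[c("low", "medium", "high")]),
               c(11, 10, 10))
  gm <- tapply(tot$pct_cnag_total, grp[tot$sample], mean)
  expect_true(gm[["low"]] < gm[["medium"]] && gm[["medium"]] < gm[["high"]])
  perm <- tot[sample.int(nrow(tot)), ]
  expect_equal(group_by_burden(perm)[names(grp)], grp)
  # n = 3 distinct values: one per group
  g3 <- group_by_burden(data.frame(sample = c("x", "y", "z"),
                                   pct_cnag_total = c(5, 1, 9)))
  expect_equal(as.character(g3[c("y", "x", "z")]),
               c("low", "medium", "high"))
  expect_error(group_by_burden(tot, sizes = c(10, 10, 10)), "summing")
})

test_that("gene dosage mapping follows the overlap rules", {
  g <- make_genome()
  # g1 fully inside a gain; g3 untouched
  cna <- seg_df(start = 0, end = 2e6, state = 3)
  dos <- map_genes_to_cn(cna, g)
  expect_equal(unname(dos$status[, "s1"]), c("CN3", "CN2", "CN2"))
  # tumor with zero CNAs: all CN2, zero recurrence
  dos0 <- map_genes_to_cn(cna[0, ], g, samples = "t0")
  expect_true(all(dos0$status == "CN2"))
  expect_true(all(dos0$recurrence$n_altered == 0))
  # mixed gain+loss: larger overlap wins; tie goes to the gain
  mix <- rbind(seg_df(start = 1e6, end = 1.04e6, state = 1),
               seg_df(start = 1.04e6, end = 2e6, state = 3))
  expect_equal(unname(map_genes_to_cn(mix, g)$status[1, 1]), "CN3")
  mix2 <- rbind(seg_df(start = 1e6, end = 1.05e6, state = 1),
                seg_df(start = 1.05e6, end = 2e6, state = 3))
  expect_equal(unname(map_genes_to_cn(mix2, g)$status[1, 1]), "CN3")
  mix3 <- rbind(seg_df(start = 1e6, end = 1.06e6, state = 1),
                seg_df(start = 1.06e6, end = 2e6, state = 3))
  expect_equal(unname(map_genes_to_cn(mix3, g)$status[1, 1]), "CN1")
  # CNA outside the genome errors
  expect_error(map_genes_to_cn(seg_df(start = 0, end = 9e7, state = 3), g),
               "outside")
})

test_that("gene dosage mapping agrees with a brute-force per-base scan", {
  set.seed(14)
  arms <- data.frame(arm_id = "a", length = 1e4)
  starts <- seq(0, 9900, by = 200)
  genes <- data.frame(gene_id = sprintf("g%02d", seq_along(starts)),
                      arm_id = "a", start = starts, end = starts + 150)
  g <- genome_model(arms, genes, 10)
  for (rep in 1:5) {
    s1 <- sample(0:9000, 1); l1 <- sample(100:3000, 1)
    s2 <- sample(0:9000, 1); l2 <- sample(100:3000, 1)
    cnas <- rbind(seg_df(start = s1, end = min(s1 + l1, 1e4), state = 3),
                  seg_df(start = s2, end = min(s2 + l2, 1e4), state = 1))
    dos <- map_genes_to_cn(cnas, g)
    for (i in seq_len(nrow(genes))) {
      bases <- (genes$start[i] + 1):genes$end[i]  # 1-based base positions
      in_gain <- bases > cnas$start[1] & bases <= cnas$end[1]
      in_loss <- bases > cnas$start[2] & bases <= cnas$end[2]
      expected <- if (!any(in_gain) && !any(in_loss)) "CN2"
      else if (sum(in_gain) >= sum(in_loss)) "CN3" else "CN1"
      expect_equal(unname(dos$status[i, 1]), expected)
    }
  }
})

test_that("recurrence curves are monotone and normalised at k = 1", {
  status <- matrix("CN2", 5, 4,
                   dimnames = list(sprintf("g%d", 1:5), sprintf("t%d", 1:4)))
  status[1, ] <- "CN3"          # altered in all 4 tumors
  status[2, 1] <- "CN1"         # altered once
  status[3, 2] <- "CN3"         # altered once
  dos <- structure(list(status = status, recurrence = data.frame(
    gene_id = rownames(status),
    n_gained = rowSums(status == "CN3"),
    n_deleted = rowSums(status == "CN1"),
    n_altered = rowSums(status != "CN2"))), class = "gene_dosage")
  rc <- recurrence_curve(dos)
  expect_equal(rc$fraction[1], 1)
  expect_true(all(diff(rc$fraction) <= 0))
  expect_equal(rc$fraction[4], 1 / 3)  # one of three altered genes in all tumors
  # every altered gene in exactly one tumor: 1 at k = 1, 0 beyond
  status2 <- status; status2[1, 2:4] <- "CN2"
  dos2 <- dos; dos2$status <- status2
  dos2$recurrence$n_altered <- rowSums(status2 != "CN2")
  dos2$recurrence$n_gained <- rowSums(status2 == "CN3")
  rc2 <- recurrence_curve(dos2)
  expect_equal(rc2$fraction, c(1, 0, 0, 0))
})

test_that("a recurrently gained arm keeps its curve high while the genome decays", {
  set.seed(15)
  g <- small_genome()
  n_t <- 31
  amp_genes <- g$genes$gene_id[g$genes$arm_id == "3q"]
  status <- matrix("CN2", nrow(g$genes), n_t,
                   dimnames = list(g$genes$gene_id, sprintf("t%02d", 1:n_t)))
  status[amp_genes, 1:10] <- "CN3"  # arm analog fully gained in 10 tumors
  # sporadic background: each other gene altered in at most 2 tumors
  others <- setdiff(g$genes$gene_id, amp_genes)
  for (gn in sample(others, 100))
    status[gn, sample(n_t, sample(1:2, 1))] <- "CN1"
  dos <- structure(list(status = status, recurrence = data.frame(
    gene_id = rownames(status),
    n_gained = rowSums(status == "CN3"),
    n_deleted = rowSums(status == "CN1"),
    n_altered = rowSums(status != "CN2"))), class = "gene_dosage")
  arm_curve <- recurrence_curve(dos, g, scope = "arm", arm = "3q")
  genome_curve <- recurrence_curve(dos)
  expect_equal(arm_curve$fraction[10], 1)
  expect_lt(genome_curve$fraction[10], 0.5)
  expect_equal(genome_curve$fraction[11], 0)
})
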