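# Synthetic study generator: genome, marker tracks, tumor CN profiles,
# expression matrices, clinical table -- with planted ground truth so every
# downstream stage can be checked against known answers.

#' Generator settings for a synthetic cohort
#'
#' The defaults emulate the study design the pipeline targets: 31 tumors
#' with a skewed altered-genome burden spanning roughly 0-32% in three
#' strata (low/medium/high), one preferentially amplified arm (the "3q
#' analog") carrying about 55% of gained genome, 17 controls, a direct
#' gene-dosage effect planted in a small fraction of CN-altered genes,
#' trans-regulated genes driven by the amplified arm's burden, and
#' burden-correlated survival and FIGO stage.
#'
#' @param n_tumors,n_controls cohort sizes (each at least 3).
#' @param genome a [genome_model()]; defaults to [default_genome()].
#' @param burden_strata data.frame with columns `mean`, `sd` (percent of the
#'   genome altered) and `weight`; tumors are assigned to strata by the
#'   remainder-to-low rule (n = 31 gives 11/10/10).
#' @param amplified_arm arm id of the preferentially amplified arm.
#' @param amp_arm_gain_share share of gained genome placed on that arm.
#' @param gain_fraction fraction of altered genome that is gained (the rest
#'   is deleted).
#' @param segment_length_range_mb min/max planted segment length, Mb.
#' @param direct_dosage_fraction fraction of CN-altered genes whose
#'   expression follows copy number directly (in `[0, 1]`).
#' @param dosage_effect exponent of the multiplicative dosage response:
#'   expression of a direct gene is scaled by `(CN/2)^dosage_effect`.
#' @param n_trans_genes number of trans-regulated genes (never CN-altered,
#'   off the amplified arm).
#' @param trans_effect_slope log2 expression shift of a trans gene per
#'   percentage point of amplified-arm burden.
#' @param marker_noise_sd Gaussian noise SD of marker log2 ratios.
#' @param noise_sd log2-scale expression noise SD (tumors and controls).
#' @param baseline_log2_mean,baseline_log2_sd distribution of per-gene
#'   control baselines on the log2 scale (RMA-like intensities).
#' @param survival_beta log hazard ratio per percentage point of burden.
#' @param baseline_hazard monthly baseline hazard of tumor death.
#' @param other_death_prob probability of an (independent) death from
#'   another cause during follow-up, censored in cause-specific analysis.
#' @param untreated_prob probability a patient refused treatment (such
#'   patients are excluded from survival analysis downstream).
#' @param figo_noise_sd noise SD of the latent stage score; the default
#'   targets a Spearman correlation of about 0.5 between stage and burden.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_tumors = 31, n_controls = 17,
                          genome = default_genome(),
                          burden_strata = data.frame(
                            stratum = c("low", "medium", "high"),
                            mean = c(0.5, 5.4, 19.2),
                            sd = c(0.6, 2.4, 6.6),
                            weight = c(1, 1, 1)),
                          amplified_arm = "3q",
                          amp_arm_gain_share = 0.55,
                          gain_fraction = 2 / 3,
                          segment_length_range_mb = c(0.6, 12),
                          direct_dosage_fraction = 0.05,
                          dosage_effect = 3,
                          n_trans_genes = 40,
                          trans_effect_slope = 0.02,
                          marker_noise_sd = 0.25,
                          noise_sd = 0.35,
                          baseline_log2_mean = 6,
                          baseline_log2_sd = 1.5,
                          survival_beta = 0.12,
                          baseline_hazard = 0.007,
                          other_death_prob = 0.05,
                          untreated_prob = 0.1,
                          figo_noise_sd = 1.55) {
  if (n_tumors < 3 || n_controls < 3)
    stop("need at least 3 tumors and 3 controls")
  stopifnot(inherits(genome, "genome_model"))
  if (nrow(genome$arms) < 2) stop("genome needs at least 2 arms")
  if (direct_dosage_fraction < 0 || direct_dosage_fraction > 1)
    stop("direct_dosage_fraction must be in [0, 1]")
  if (!amplified_arm %in% genome$arms$arm_id)
    stop("amplified_arm not in genome")
  if (marker_noise_sd < 0 || noise_sd < 0) stop("noise SDs must be >= 0")
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

figo_levels <- c("IB1", "IB2", "IIA", "IIB", "IIIB", "IVA", "IVB")
# stage mix of the study cohort, used as bin proportions for the latent score
figo_props <- c(0.34, 0.17, 0.03, 0.10, 0.26, 0.04, 0.06)

# split n into k ordered group sizes, remainder assigned to the first groups
split_sizes <- function(n, k) {
  base <- n %/% k
  sizes <- rep(base, k)
  rem <- n %% k
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
  sizes
}

# place a segment of length len uniformly in the free space of [0, arm_len)
# given occupied intervals (data.frame start/end); NULL if nothing fits
place_segment <- function(arm_len, occupied, len) {
  if (nrow(occupied) == 0) {
    gaps <- data.frame(start = 0, end = arm_len)
  } else {
    occ <- occupied[order(occupied$start), ]
    edges_s <- c(0, occ$end)
    edges_e <- c(occ$start, arm_len)
    gaps <- data.frame(start = edges_s, end = edges_e)
    gaps <- gaps[gaps$end - gaps$start > 0, ]
  }
  fits <- gaps[gaps$end - gaps$start >= len, , drop = FALSE]
  if (nrow(fits) == 0) return(NULL)
  slack <- fits$end - fits$start - len
  g <- fits[sample.int(nrow(fits), 1, prob = slack + 1), ]
  start <- floor(g$start + runif(1) * (g$end - g$start - len))
  c(start = start, end = start + len)
}

# plant integer-CN segments for one tumor given an altered-bp budget
plant_tumor_segments <- function(cfg, target_pct) {
  genome <- cfg$genome
  arms <- genome$arms
  total_bp <- sum(arms$length)
  budget <- target_pct / 100 * total_bp
  segs <- data.frame(arm = character(), start = numeric(), end = numeric(),
                     cn = integer())
  if (budget < cfg$segment_length_range_mb[1] * 1e6) return(segs)
  gain_budget <- budget * cfg$gain_fraction
  loss_budget <- budget - gain_budget
  occ <- setNames(vector("list", nrow(arms)), arms$arm_id)
  for (a in arms$arm_id) occ[[a]] <- data.frame(start = numeric(), end = numeric())
  add_seg <- function(arm, start, end, cn) {
    occ[[arm]] <<- rbind(occ[[arm]], data.frame(start = start, end = end))
    segs <<- rbind(segs, data.frame(arm = arm, start = start, end = end,
                                    cn = cn))
  }

  # amplified-arm gain first: one long segment carrying its share of gains
  amp <- cfg$amplified_arm
  amp_len <- min(round(gain_budget * cfg$amp_arm_gain_share),
                 arms$length[arms$arm_id == amp])
  if (amp_len >= cfg$segment_length_range_mb[1] * 1e6) {
    pos <- place_segment(arms$length[arms$arm_id == amp],
                         occ[[amp]], amp_len)
    if (!is.null(pos)) {
      add_seg(amp, pos["start"], pos["end"],
              if (runif(1) < 0.15) 4L else 3L)
      gain_budget <- gain_budget - amp_len
    }
  }

  draw_into <- function(budget_bp, cn_draw, arm_pool) {
    min_len <- cfg$segment_length_range_mb[1] * 1e6
    max_len <- cfg$segment_length_range_mb[2] * 1e6
    guard <- 0
    while (budget_bp >= min_len && guard < 200) {
      guard <- guard + 1
      len <- round(runif(1, min_len, min(max_len, budget_bp)))
      w <- arms$length[match(arm_pool, arms$arm_id)]
      a <- if (length(arm_pool) == 1) arm_pool else
        sample(arm_pool, 1, prob = w)
      pos <- place_segment(arms$length[arms$arm_id == a], occ[[a]], len)
      if (is.null(pos)) next
      add_seg(a, pos["start"], pos["end"], cn_draw())
      budget_bp <- budget_bp - len
    }
  }
  non_amp <- setdiff(arms$arm_id, amp)
  draw_into(gain_budget, function() if (runif(1) < 0.15) 4L else 3L, non_amp)
  draw_into(loss_budget, function() if (runif(1) < 0.10) 0L else 1L,
            arms$arm_id)
  segs[order(segs$arm, segs$start), , drop = FALSE]
}

# integer CN per gene for one tumor: status of the segment covering the
# gene midpoint (planted segments never overlap)
truth_gene_cn <- function(genome, segs) {
  cn <- rep(2L, nrow(genome$genes))
  if (nrow(segs) > 0) {
    mid <- (genome$genes$start + genome$genes$end) / 2
    for (i in seq_len(nrow(segs))) {
      hit <- genome$genes$arm_id == segs$arm[i] &
        mid >= segs$start[i] & mid < segs$end[i]
      cn[hit] <- segs$cn[i]
    }
  }
  setNames(cn, genome$genes$gene_id)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws per-tumor burden targets from the configured strata, plants
#' integer-CN segments meeting those targets (the amplified arm takes its
#' configured share of gains), simulates noisy marker log2 ratios
#' (`log2(CN/2)` with homozygous deletions floored at -2), builds linear
#' expression matrices in which direct-dosage genes scale as
#' `(CN/2)^dosage_effect` and trans genes shift with amplified-arm burden,
#' and draws survival and FIGO stage with hazard increasing in burden.
#' Identical `(config, seed)` give byte-identical output.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; all randomness derives from it.
#' @return A list of class `cna_cohort` with elements `markers` (per-tumor
#'   data.frames of arm/position/log2ratio), `expr` and `controls` (linear
#'   intensity matrices, genes x samples), `genome`, `clinical`
#'   (sample/figo_stage/followup_months/status/treated) and `truth`
#'   (planted segments, per-gene CN, direct and trans gene sets, per-tumor
#'   burden, generator parameters).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed))
  cfg <- config
  genome <- cfg$genome
  arms <- genome$arms
  total_bp <- sum(arms$length)
  tumor_ids <- sprintf("T%02d", seq_len(cfg$n_tumors))
  control_ids <- sprintf("C%02d", seq_len(cfg$n_controls))

  # -- burden targets by stratum (remainder-to-low, ascending means) -------
  st <- cfg$burden_strata[order(cfg$burden_strata$mean), ]
  sizes <- split_sizes(cfg$n_tumors, nrow(st))
  stratum <- rep(st$stratum, sizes)
  target <- pmin(pmax(rnorm(cfg$n_tumors, rep(st$mean, sizes),
                            rep(st$sd, sizes)), 0), 33)

  # -- planted segments and marker tracks ---------------------------------
  positions <- marker_positions(genome)
  truth_segments <- list()
  gene_cn <- matrix(2L, nrow = nrow(genome$genes), ncol = cfg$n_tumors,
                    dimnames = list(genome$genes$gene_id, tumor_ids))
  markers <- setNames(vector("list", cfg$n_tumors), tumor_ids)
  amp_arm_len <- arms$length[arms$arm_id == cfg$amplified_arm]
  amp_burden <- numeric(cfg$n_tumors)   # % of amplified arm gained
  real_burden <- numeric(cfg$n_tumors)  # % of genome altered (truth)
  for (i in seq_len(cfg$n_tumors)) {
    segs <- plant_tumor_segments(cfg, target[i])
    truth_segments[[tumor_ids[i]]] <- segs
    if (nrow(genome$genes) > 0)
      gene_cn[, i] <- truth_gene_cn(genome, segs)
    real_burden[i] <- 100 * sum(segs$end - segs$start) / total_bp
    amp <- segs[segs$arm == cfg$amplified_arm & segs$cn > 2, ]
    amp_burden[i] <- 100 * sum(amp$end - amp$start) / amp_arm_len
    tr <- do.call(rbind, lapply(arms$arm_id, function(a) {
      pos <- positions[[a]]
      cn <- rep(2L, length(pos))
      sa <- segs[segs$arm == a, ]
      if (nrow(sa) > 0)
        for (j in seq_len(nrow(sa)))
          cn[pos >= sa$start[j] & pos < sa$end[j]] <- sa$cn[j]
      mu <- ifelse(cn == 0, -2, log2(cn / 2))
      data.frame(arm = a, position = pos,
                 log2ratio = mu + rnorm(length(pos), 0, cfg$marker_noise_sd))
    }))
    markers[[tumor_ids[i]]] <- tr
  }

  # -- expression ----------------------------------------------------------
  n_genes <- nrow(genome$genes)
  gene_ids <- genome$genes$gene_id
  baseline <- rnorm(n_genes, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  altered_any <- rownames(gene_cn)[rowSums(gene_cn != 2L) > 0]
  n_direct <- round(cfg$direct_dosage_fraction * length(altered_any))
  direct_genes <- if (n_direct > 0) sort(sample(altered_any, n_direct))
  else character(0)
  never_altered <- setdiff(gene_ids, altered_any)
  trans_pool <- setdiff(never_altered,
                        gene_ids[genome$genes$arm_id == cfg$amplified_arm])
  trans_genes <- if (cfg$n_trans_genes > 0 && length(trans_pool) > 0)
    sort(sample(trans_pool, min(cfg$n_trans_genes, length(trans_pool))))
  else character(0)

  controls <- matrix(2^(baseline +
                          rnorm(n_genes * cfg$n_controls, 0, cfg$noise_sd)),
                     nrow = n_genes, ncol = cfg$n_controls,
                     dimnames = list(gene_ids, control_ids))
  lfc <- matrix(0, n_genes, cfg$n_tumors,
                dimnames = list(gene_ids, tumor_ids))
  if (length(direct_genes) > 0 && cfg$dosage_effect != 0) {
    ratio <- pmax(gene_cn[direct_genes, , drop = FALSE], 0.25) / 2
    lfc[direct_genes, ] <- cfg$dosage_effect * log2(ratio)
  }
  if (length(trans_genes) > 0 && cfg$trans_effect_slope != 0)
    lfc[trans_genes, ] <- lfc[trans_genes, ] +
      rep(cfg$trans_effect_slope * amp_burden, each = length(trans_genes))
  expr <- matrix(2^(baseline + lfc +
                      rnorm(n_genes * cfg$n_tumors, 0, cfg$noise_sd)),
                 nrow = n_genes, ncol = cfg$n_tumors,
                 dimnames = list(gene_ids, tumor_ids))

  # -- clinical ------------------------------------------------------------
  death_t <- rexp(cfg$n_tumors,
                  cfg$baseline_hazard * exp(cfg$survival_beta * real_burden))
  admin_c <- runif(cfg$n_tumors, 36, 86)
  other_t <- ifelse(runif(cfg$n_tumors) < cfg$other_death_prob,
                    runif(cfg$n_tumors, 1, 60), Inf)
  time <- pmin(death_t, admin_c, other_t)
  status <- ifelse(death_t <= pmin(admin_c, other_t), "death",
                   ifelse(other_t <= admin_c, "censored-death", "alive"))
  latent <- scale(rank(real_burden, ties.method = "average"))[, 1] +
    rnorm(cfg$n_tumors, 0, cfg$figo_noise_sd)
  breaks <- quantile(latent, probs = cumsum(c(0, figo_props / sum(figo_props))))
  breaks[1] <- -Inf; breaks[length(breaks)] <- Inf
  figo <- figo_levels[as.integer(cut(latent, breaks, labels = FALSE,
                                     include.lowest = TRUE))]
  clinical <- data.frame(
    sample = tumor_ids,
    figo_stage = figo,
    followup_months = pmax(1L, as.integer(round(time))),
    status = status,
    treated = runif(cfg$n_tumors) >= cfg$untreated_prob)

  truth <- list(
    segments = do.call(rbind, lapply(names(truth_segments), function(s) {
      x <- truth_segments[[s]]
      if (nrow(x) == 0) return(NULL)
      cbind(sample = s, x)
    })),
    gene_cn = gene_cn,
    direct_genes = direct_genes,
    trans_genes = trans_genes,
    burden = data.frame(sample = tumor_ids, stratum = stratum,
                        target_pct = target, pct_altered = real_burden,
                        amp_arm_pct_gained = amp_burden),
    params = list(direct_dosage_fraction = cfg$direct_dosage_fraction,
                  dosage_effect = cfg$dosage_effect,
                  trans_effect_slope = cfg$trans_effect_slope,
                  survival_beta = cfg$survival_beta,
                  amplified_arm = cfg$amplified_arm,
                  seed = as.integer(seed)))
  if (is.null(truth$segments))
    truth$segments <- data.frame(sample = character(), arm = character(),
                                 start = numeric(), end = numeric(),
                                 cn = integer())

  structure(list(markers = markers, expr = expr, controls = controls,
                 genome = genome, clinical = clinical, truth = truth,
                 config = cfg, seed = as.integer(seed)),
            class = "cna_cohort")
}

#' @export
print.cna_cohort <- function(x, ...) {
  cat("Synthetic CN/expression cohort:",
      length(x$markers), "tumors,", ncol(x$controls), "controls,",
      nrow(x$expr), "genes;",
      nrow(x$truth$segments), "planted segments; seed", x$seed, "\n")
  invisible(x)
}

#' Write a cohort to a directory of plain-text files
#'
#' Emits marker tracks, linear expression and control matrices, the gene
#' annotation (BED), arm table, clinical table, ground-truth tables and a
#' YAML stub config pointing at the files. Everything round-trips exactly
#' through [read_cohort()].
#'
#' @param cohort a `cna_cohort`.
#' @param out_dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "cna_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir)
  p <- function(f) file.path(out_dir, f)
  seed <- cohort$seed
  write_marker_tracks(cohort$markers, p("markers.tsv"), seed = seed)
  write_matrix_tsv(cohort$expr, p("expression.tsv"), seed = seed)
  write_matrix_tsv(cohort$controls, p("controls.tsv"), seed = seed)
  write_genes_bed(cohort$genome$genes, p("genes.bed"))
  write_tsv(cohort$genome$arms, p("arms.tsv"), seed = seed)
  write_tsv(cohort$clinical, p("clinical.tsv"), seed = seed)
  write_tsv(cohort$truth$segments, p("truth_segments.tsv"), seed = seed)
  write_tsv(cohort$truth$burden, p("truth_burden.tsv"), seed = seed)
  write_tsv(data.frame(gene_id = c(cohort$truth$direct_genes,
                                   cohort$truth$trans_genes),
                       role = c(rep("direct", length(cohort$truth$direct_genes)),
                                rep("trans", length(cohort$truth$trans_genes)))),
            p("truth_genes.tsv"), seed = seed)
  yaml::write_yaml(list(
    seed = seed,
    marker_spacing = cohort$genome$marker_spacing,
    paths = list(markers = "markers.tsv", expression = "expression.tsv",
                 controls = "controls.tsv", annotation = "genes.bed",
                 arms = "arms.tsv", clinical = "clinical.tsv")),
    p("cohort.yaml"))
  invisible(out_dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory path.
#' @return A list of class `cna_cohort` (without the generator truth unless
#'   the truth tables are present).
#' @export
read_cohort <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "cohort.yaml"))
  p <- function(f) file.path(dir, f)
  genes <- read_genes_bed(p("genes.bed"))
  arms <- read_tsv(p("arms.tsv"))
  genome <- genome_model(arms, genes, meta$marker_spacing)
  out <- list(markers = read_marker_tracks(p("markers.tsv")),
              expr = read_matrix_tsv(p("expression.tsv")),
              controls = read_matrix_tsv(p("controls.tsv")),
              genome = genome,
              clinical = read_tsv(p("clinical.tsv")),
              truth = NULL, config = NULL,
              seed = as.integer(meta$seed))
  if (file.exists(p("truth_segments.tsv")))
    out$truth <- list(segments = read_tsv(p("truth_segments.tsv")),
                      burden = read_tsv(p("truth_burden.tsv")),
                      genes = read_tsv(p("truth_genes.tsv")))
  class(out) <- "cna_cohort"
  out
}
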