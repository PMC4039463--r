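# End-to-end orchestration: read the cohort inputs, run the stages in
# order, write every stage's outputs as TSV, and record a manifest with
# content hashes so identical configs reproduce identical outputs.

#' Pipeline configuration
#'
#' @param markers,expression,controls,annotation,clinical input paths
#'   (marker-track TSV, linear expression and control matrices, gene BED,
#'   clinical TSV). `germline_cnvs` (BED) is optional.
#' @param arms path to the arm table TSV (`arm_id`, `length`).
#' @param marker_spacing marker spacing of the tracks, bp.
#' @param min_markers,min_length,max_cnv_overlap CNA filter thresholds.
#' @param burden_min_length minimum CNA length counting toward burden, bp.
#' @param genome_size_mb burden denominator, Mb.
#' @param fc_min SAM fold-change cutoff.
#' @param alpha significance level for enrichment/correlation calls.
#' @param recurrence_threshold exclusive-set dosage-bound threshold.
#' @param n_permutations SAM Monte-Carlo permutation count.
#' @param seed seed for all stochastic stages.
#' @param expression_scale `"linear"` or `"log2"` intensity scale of the
#'   expression matrices (mandatory; matrices are converted to linear).
#' @param amplified_arm arm whose burden drives the trans-correlation
#'   stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(markers, expression, controls, annotation,
                            clinical, arms, germline_cnvs = NULL,
                            marker_spacing = 2000,
                            min_markers = 50, min_length = 5e5,
                            max_cnv_overlap = 0.5,
                            burden_min_length = 2.5e6,
                            genome_size_mb = 3000,
                            fc_min = 1.5, alpha = 0.05,
                            recurrence_threshold = 4,
                            n_permutations = 1000,
                            seed = 1L,
                            expression_scale = c("linear", "log2"),
                            amplified_arm = NULL) {
  expression_scale <- match.arg(expression_scale)
  cfg <- as.list(environment())
  for (th in c("min_markers", "min_length", "max_cnv_overlap",
               "burden_min_length", "genome_size_mb", "fc_min", "alpha"))
    if (cfg[[th]] < 0) stop(th, " must be non-negative")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] arguments;
#'   relative input paths are resolved against the YAML's directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (k in c("markers", "expression", "controls", "annotation",
              "clinical", "arms", "germline_cnvs"))
    if (!is.null(y[[k]]) && !startsWith(y[[k]], "/"))
      y[[k]] <- file.path(base, y[[k]])
  do.call(pipeline_config, y)
}

pipeline_stages <- c("segment", "burden", "express", "attribute",
                     "cluster", "survive")

#' Run the dosage-attribution pipeline
#'
#' Executes segmentation, burden, expression calling + SAM, attribution,
#' clustering and survival in order (any contiguous subset selectable),
#' writing each stage's tables under `out_dir` and a manifest with md5
#' hashes of every output. A failing stage halts the run with the stage
#' named and leaves a `FAILED` marker.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param stages character vector of stages to run (default all).
#' @return The manifest data.frame (file, stage, md5), invisibly; stage
#'   results are also returned in the `results` attribute.
#' @export
run_pipeline <- function(config, out_dir, stages = pipeline_stages) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(); results <- list()
  emit <- function(df, name, stage) {
    path <- file.path(out_dir, name)
    write_tsv(df, path, seed = config$seed)
    manifest[[length(manifest) + 1]] <<-
      data.frame(file = name, stage = stage,
                 md5 = unname(tools::md5sum(path)))
  }
  fail <- function(stage, e) {
    writeLines(c(stage, conditionMessage(e)), file.path(out_dir, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  run_stage <- function(stage, fn) {
    message(sprintf("[cnadose] stage %-9s seed=%d", stage, config$seed))
    tryCatch(fn(), error = function(e) fail(stage, e))
  }

  genes <- read_genes_bed(config$annotation)
  arms <- read_tsv(config$arms)
  genome <- genome_model(arms, genes, config$marker_spacing)
  cnvs <- if (!is.null(config$germline_cnvs))
    read_intervals_bed(config$germline_cnvs) else NULL

  cnas <- NULL
  if ("segment" %in% stages) run_stage("segment", function() {
    tracks <- read_marker_tracks(config$markers)
    segs <- viterbi_segment(tracks, hmm_params())
    segs <- collapse_cn4(segs)
    cnas <<- filter_cnas(segs, cnvs, config$min_markers,
                         config$min_length, config$max_cnv_overlap)
    message(sprintf("[cnadose]   %d tracks -> %d segments -> %d CNAs",
                    length(tracks), nrow(segs), nrow(cnas)))
    emit(cnas, "cnas.tsv", "segment")
    results$cnas <<- cnas
  })
  if (is.null(cnas) && file.exists(file.path(out_dir, "cnas.tsv")))
    cnas <- read_tsv(file.path(out_dir, "cnas.tsv"))

  burden <- NULL; dosage <- NULL; groups <- NULL
  if ("burden" %in% stages) run_stage("burden", function() {
    tracks_samples <- unique(read_tsv(config$markers)$sample)
    burden <<- compute_burden(cnas, genome, samples = tracks_samples,
                              genome_size_mb = config$genome_size_mb,
                              alteration_min_length = config$burden_min_length)
    groups <<- group_by_burden(burden)
    dosage <<- map_genes_to_cn(cnas, genome, samples = tracks_samples)
    emit(burden$totals, "burden_totals.tsv", "burden")
    emit(burden$per_arm, "burden_per_arm.tsv", "burden")
    emit(data.frame(sample = names(groups), group = as.character(groups)),
         "burden_groups.tsv", "burden")
    emit(data.frame(gene_id = rownames(dosage$status),
                    as.data.frame(dosage$status)),
         "gene_dosage.tsv", "burden")
    emit(dosage$recurrence, "gene_recurrence.tsv", "burden")
    rc <- recurrence_curve(dosage)
    emit(rc, "recurrence_curve.tsv", "burden")
    results$burden <<- burden; results$groups <<- groups
    results$dosage <<- dosage
  })

  expr <- NULL; controls <- NULL; calls <- NULL
  sam_high <- NULL; sam_low <- NULL
  if ("express" %in% stages) run_stage("express", function() {
    expr <<- read_matrix_tsv(config$expression)
    controls <<- read_matrix_tsv(config$controls)
    if (config$expression_scale == "log2") {
      expr <<- 2^expr; controls <<- 2^controls
    }
    baseline <- control_baseline(controls)
    calls <<- call_expression_status(expr, baseline)
    emit(data.frame(gene_id = rownames(calls), as.data.frame(calls)),
         "expression_calls.tsv", "express")
    if (!is.null(groups)) {
      common <- intersect(colnames(expr), names(groups))
      hi <- common[groups[common] == "high"]
      lo <- common[groups[common] == "low"]
      if (length(hi) >= 2 && length(lo) >= 2) {
        sam_high <<- sam_two_class(expr[, hi, drop = FALSE], controls,
                                   fc_min = config$fc_min,
                                   n_permutations = config$n_permutations,
                                   seed = config$seed)
        sam_low <<- sam_two_class(expr[, lo, drop = FALSE], controls,
                                  fc_min = config$fc_min,
                                  n_permutations = config$n_permutations,
                                  seed = config$seed)
        emit(sam_high$table, "sam_high.tsv", "express")
        emit(sam_low$table, "sam_low.tsv", "express")
      }
    }
    results$calls <<- calls
    results$sam_high <<- sam_high; results$sam_low <<- sam_low
  })

  attribution <- NULL
  if ("attribute" %in% stages) run_stage("attribute", function() {
    common <- intersect(colnames(dosage$status), colnames(calls))
    if (length(common) == 0) stop("no tumors shared between CN and expression")
    sub_dosage <- dosage
    sub_dosage$status <- dosage$status[, common, drop = FALSE]
    attribution <<- crosstab_attribution(sub_dosage,
                                         calls[, common, drop = FALSE])
    emit(attribution$per_tumor, "attribution_per_tumor.tsv", "attribute")
    emit(data.frame(statistic = c("rate_cn_altered", "rate_cn2",
                                  "dosage_difference", "chisq_p",
                                  "dereg_share_cn_altered"),
                    value = c(attribution$rate_altered, attribution$rate_cn2,
                              attribution$dosage_difference,
                              attribution$chisq_p,
                              attribution$dereg_share_altered)),
         "attribution_summary.tsv", "attribute")
    tot <- burden$totals[match(common, burden$totals$sample), ]
    dereg_tot <- colSums(calls[, common, drop = FALSE] != "unchanged")
    reg <- burden_expression_regression(tot$pct_cnag_total, dereg_tot)
    emit(data.frame(slope = reg$slope, intercept = reg$intercept,
                    r = reg$r, p = reg$p, n = reg$n),
         "burden_regression.tsv", "attribute")
    pa <- burden$per_arm[burden$per_arm$sample %in% common, ]
    arm_ids <- unique(pa$arm)
    Xarm <- sapply(arm_ids, function(a) {
      pa_a <- pa[pa$arm == a, ]
      pa_a$pct_altered[match(common, pa_a$sample)]
    })
    Xarm <- Xarm[, colSums(Xarm) > 0, drop = FALSE]
    colnames(Xarm) <- paste0("arm_", colnames(Xarm))
    mlr <- arm_mlr_decomposition(Xarm, tot$pct_cnag_total)
    emit(data.frame(rank = seq_along(mlr$selected), arm = mlr$selected,
                    adj_r2 = mlr$adj_r2, first_share = mlr$first_share),
         "arm_mlr.tsv", "attribute")
    if (!is.null(sam_high) && !is.null(sam_low)) {
      hi <- names(groups)[groups == "high"]
      es <- exclusive_set_analysis(sam_high, sam_low, dosage, hi,
                                   config$recurrence_threshold)
      emit(data.frame(statistic = c("n_high", "n_low", "n_common",
                                    "n_exclusive_high", "pct_shared",
                                    "pct_exclusive_of_high",
                                    "pct_dosage_bound"),
                      value = c(es$n_high, es$n_low, es$n_common,
                                es$n_exclusive_high, es$pct_shared,
                                es$pct_exclusive_of_high,
                                es$pct_dosage_bound)),
           "exclusive_sets.tsv", "attribute")
      results$exclusive <<- es
    }
    if (!is.null(config$amplified_arm)) {
      pa_amp <- pa[pa$arm == config$amplified_arm, ]
      ab <- pa_amp$pct_altered[match(common, pa_amp$sample)]
      corr <- arm_burden_gene_correlation(ab, expr[, common, drop = FALSE],
                                          alpha = config$alpha)
      emit(corr, "amp_arm_gene_correlation.tsv", "attribute")
      results$amp_corr <<- corr
    }
    results$attribution <<- attribution
    results$regression <<- reg; results$mlr <<- mlr
  })

  if ("cluster" %in% stages) run_stage("cluster", function() {
    # cluster samples on the most variable genes (log2 profiles)
    lx <- log2(pmax(expr, 1e-6))
    vsel <- order(apply(lx, 1, var), decreasing = TRUE)
    vsel <- vsel[seq_len(min(50, nrow(lx)))]
    cl <- hierarchical_profile_clustering(lx[vsel, , drop = FALSE], k = 3,
                                          burden_groups = groups,
                                          seed = config$seed)
    emit(data.frame(sample = names(cl$groups), cluster = cl$groups),
         "clusters.tsv", "cluster")
    writeLines(cl$newick, file.path(out_dir, "clusters.nwk"))
    manifest[[length(manifest) + 1]] <<-
      data.frame(file = "clusters.nwk", stage = "cluster",
                 md5 = unname(tools::md5sum(file.path(out_dir,
                                                      "clusters.nwk"))))
    results$clustering <<- cl
  })

  if ("survive" %in% stages) run_stage("survive", function() {
    clinical <- read_tsv(config$clinical)
    cohort <- suppressWarnings(build_survival_cohort(clinical))
    tot <- burden$totals[match(cohort$sample, burden$totals$sample), ]
    keep <- !is.na(tot$sample)
    cohort <- cohort[keep, ]; tot <- tot[keep, ]
    grp <- groups[cohort$sample]
    lr <- logrank_test(cohort, grp)
    roc <- roc_burden_cutoff(tot$pct_cnag_total, cohort$event)
    lr_roc <- logrank_test(cohort, tot$pct_cnag_total >= roc$cutoff)
    sp <- spearman_colinearity(cohort$figo,
                               data.frame(burden = tot$pct_cnag_total))
    cox <- cox_adjusted(cohort,
                        data.frame(burden = tot$pct_cnag_total,
                                   figo = as.integer(cohort$figo)))
    emit(data.frame(statistic = c("logrank_groups_chisq", "logrank_groups_p",
                                  "roc_cutoff", "roc_n_high",
                                  "roc_logrank_p", "figo_spearman_rho",
                                  "figo_spearman_p", "survival_rate",
                                  "n_included"),
                    value = c(lr$chisq, lr$p, roc$cutoff, roc$n_high,
                              lr_roc$p, sp$rho[1], sp$p[1],
                              survival_rate(cohort), nrow(cohort))),
         "survival_summary.tsv", "survive")
    emit(cox, "cox_adjusted.tsv", "survive")
    km <- km_estimate(cohort, grp)
    emit(do.call(rbind, lapply(names(km), function(g)
      cbind(group = g, km[[g]]))), "km_curves.tsv", "survive")
    results$survival <<- list(logrank = lr, roc = roc, cox = cox,
                              spearman = sp, cohort = cohort)
  })

  man <- do.call(rbind, manifest)
  man$parameters <- NULL
  write_tsv(man, file.path(out_dir, "manifest.tsv"))
  yaml::write_yaml(list(version = as.character(utils::packageVersion("cnadose")),
                        seed = config$seed,
                        timestamp = format(Sys.time(), tz = "UTC"),
                        stages = stages),
                   file.path(out_dir, "run_info.yaml"))
  attr(man, "results") <- results
  invisible(man)
}
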