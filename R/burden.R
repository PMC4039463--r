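# Per-tumor copy-number burden statistics and gene-level dosage status.

#' Percentage of copy-number-altered genome per tumor
#'
#' Burden counts only alterations longer than `alteration_min_length`
#' (default 2.5 Mb) and is expressed against a fixed haploid genome size
#' (default 3,000 Mb), independent of the explored genome. Per-arm
#' percentages use the arm lengths of the genome model as denominators.
#'
#' @param cnas filtered CNA data.frame (`sample`, `arm`, `start`, `end`,
#'   `state`, `length`).
#' @param genome a [genome_model()].
#' @param samples optional character vector fixing the sample universe
#'   (tumors with zero CNAs are kept as 0% rows).
#' @param genome_size_mb haploid genome size used as denominator, Mb.
#' @param alteration_min_length minimum length (bp, exclusive) for a
#'   segment to count as a CN alteration in the burden.
#' @return List of class `burden_table`: `$totals` (per-tumor percentages
#'   and CNA counts) and `$per_arm` (long data.frame of per-arm
#'   percentages).
#' @export
compute_burden <- function(cnas, genome, samples = NULL,
                           genome_size_mb = 3000,
                           alteration_min_length = 2.5e6) {
  stopifnot(inherits(genome, "genome_model"))
  if (genome_size_mb <= 0) stop("genome_size_mb must be positive")
  if (is.null(samples)) samples <- unique(cnas$sample)
  gsize <- genome_size_mb * 1e6
  arm_len <- setNames(genome$arms$length, genome$arms$arm_id)
  keep <- cnas[cnas$length > alteration_min_length, , drop = FALSE]
  totals <- list(); per_arm <- list()
  for (s in samples) {
    x <- keep[keep$sample == s, , drop = FALSE]
    # sanity: segmentation must not emit overlapping segments per tumor
    for (a in unique(x$arm)) {
      xa <- x[x$arm == a, ]
      xa <- xa[order(xa$start), ]
      if (nrow(xa) > 1 && any(xa$start[-1] < xa$end[-nrow(xa)]))
        stop("overlapping segments in tumor ", s, " arm ", a)
    }
    gained <- sum(x$length[x$state > 2])
    deleted <- sum(x$length[x$state < 2])
    totals[[s]] <- data.frame(
      sample = s,
      pct_cnag_total = 100 * (gained + deleted) / gsize,
      pct_gained = 100 * gained / gsize,
      pct_deleted = 100 * deleted / gsize,
      n_cnas = nrow(x))
    pa <- do.call(rbind, lapply(names(arm_len), function(a) {
      xa <- x[x$arm == a, ]
      g <- sum(xa$length[xa$state > 2]); d <- sum(xa$length[xa$state < 2])
      data.frame(sample = s, arm = a,
                 pct_altered = 100 * (g + d) / arm_len[[a]],
                 pct_gained = 100 * g / arm_len[[a]],
                 pct_deleted = 100 * d / arm_len[[a]])
    }))
    per_arm[[s]] <- pa
  }
  if (length(totals) == 0) {
    totals <- list(data.frame(sample = character(), pct_cnag_total = numeric(),
                              pct_gained = numeric(), pct_deleted = numeric(),
                              n_cnas = integer()))
    per_arm <- list(data.frame(sample = character(), arm = character(),
                               pct_altered = numeric(), pct_gained = numeric(),
                               pct_deleted = numeric()))
  }
  structure(list(totals = do.call(rbind, c(totals, list(make.row.names = FALSE))),
                 per_arm = do.call(rbind, c(per_arm, list(make.row.names = FALSE)))),
            class = "burden_table")
}

#' @export
print.burden_table <- function(x, ...) {
  cat("CN-altered genome burden for", nrow(x$totals), "tumors; mean",
      sprintf("%.1f%%\n", mean(x$totals$pct_cnag_total)))
  print(head(x$totals, 10), row.names = FALSE)
  if (nrow(x$totals) > 10) cat("...\n")
  invisible(x)
}

#' Group tumors into low / medium / high burden
#'
#' Tumors are sorted by total burden (ties broken by sample id) and split
#' into three consecutive groups. When the cohort size is not divisible by
#' 3 the extra tumors go to the lower groups first (n = 31 gives 11/10/10).
#'
#' @param burden a `burden_table` or its `$totals` data.frame.
#' @param sizes optional explicit group sizes (low, medium, high).
#' @return Named factor (low/medium/high) keyed by sample id.
#' @export
group_by_burden <- function(burden, sizes = NULL) {
  tot <- if (inherits(burden, "burden_table")) burden$totals else burden
  n <- nrow(tot)
  if (n < 3) stop("need at least 3 tumors")
  if (is.null(sizes)) sizes <- split_sizes(n, 3)
  if (length(sizes) != 3 || sum(sizes) != n)
    stop("sizes must be 3 values summing to the number of tumors")
  o <- order(tot$pct_cnag_total, tot$sample)
  grp <- rep(c("low", "medium", "high"), sizes)
  setNames(factor(grp, levels = c("low", "medium", "high")),
           tot$sample[o])[tot$sample]
}

#' Map CNAs onto genes: per-gene, per-tumor copy status
#'
#' A gene overlapping (by at least one base) a deletion CNA is CN1, a gain
#' CNA is CN3, and no CNA is CN2. A gene overlapping both a gain and a loss
#' in the same tumor takes the status of the larger overlap, ties going to
#' the gain.
#'
#' @param cnas CNA data.frame (`sample`, `arm`, `start`, `end`, `state`).
#' @param genome a [genome_model()].
#' @param samples optional sample universe (tumors without CNAs get all-CN2
#'   columns).
#' @return List of class `gene_dosage`: `$status` (character matrix genes x
#'   tumors with values CN1/CN2/CN3) and `$recurrence` (per-gene counts of
#'   tumors gained, deleted, altered).
#' @export
map_genes_to_cn <- function(cnas, genome, samples = NULL) {
  stopifnot(inherits(genome, "genome_model"))
  genes <- genome$genes
  arm_len <- setNames(genome$arms$length, genome$arms$arm_id)
  if (any(genes$start < 0 | genes$end > arm_len[genes$arm_id]))
    stop("gene outside genome bounds")
  if (nrow(cnas) > 0) {
    bad <- cnas$start < 0 | cnas$end > arm_len[cnas$arm]
    if (any(bad)) stop("CNA outside genome bounds")
  }
  if (is.null(samples)) samples <- unique(cnas$sample)
  status <- matrix("CN2", nrow = nrow(genes), ncol = length(samples),
                   dimnames = list(genes$gene_id, samples))
  gene_ir_by_arm <- lapply(split(seq_len(nrow(genes)), genes$arm_id),
                           function(i) list(
                             idx = i,
                             ir = IRanges::IRanges(genes$start[i] + 1,
                                                   genes$end[i])))
  for (s in samples) {
    x <- cnas[cnas$sample == s & cnas$state != 2, , drop = FALSE]
    if (nrow(x) == 0) next
    for (a in intersect(unique(x$arm), names(gene_ir_by_arm))) {
      ga <- gene_ir_by_arm[[a]]
      xa <- x[x$arm == a, ]
      seg_ir <- IRanges::IRanges(xa$start + 1, xa$end)
      hits <- IRanges::findOverlaps(ga$ir, seg_ir)
      if (length(hits) == 0) next
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      w <- IRanges::width(IRanges::pintersect(ga$ir[qh], seg_ir[sh]))
      dir <- ifelse(xa$state[sh] > 2, "CN3", "CN1")
      # per gene: larger total overlap wins, tie -> gain
      for (g in unique(qh)) {
        sel <- qh == g
        wg <- tapply(w[sel], dir[sel], sum)
        gain <- if ("CN3" %in% names(wg)) wg[["CN3"]] else 0
        loss <- if ("CN1" %in% names(wg)) wg[["CN1"]] else 0
        status[ga$idx[g], s] <- if (gain >= loss) "CN3" else "CN1"
      }
    }
  }
  recurrence <- data.frame(
    gene_id = genes$gene_id,
    n_gained = rowSums(status == "CN3"),
    n_deleted = rowSums(status == "CN1"),
    n_altered = rowSums(status != "CN2"),
    row.names = NULL)
  structure(list(status = status, recurrence = recurrence),
            class = "gene_dosage")
}

#' @export
print.gene_dosage <- function(x, ...) {
  cat("Gene dosage table:", nrow(x$status), "genes x", ncol(x$status),
      "tumors;", sum(x$recurrence$n_altered > 0), "genes altered in >= 1 tumor\n")
  invisible(x)
}

#' Recurrence curve of CN-altered genes
#'
#' Among genes altered in at least one tumor (within the requested scope
#' and direction), the fraction altered in at least k tumors, for k = 1 ...
#' number of tumors. Monotone non-increasing, equal to 1 at k = 1.
#'
#' @param dosage a `gene_dosage` object.
#' @param genome genome model (needed for `scope = "arm"`).
#' @param scope `"genome"` or `"arm"`.
#' @param arm arm id when `scope = "arm"`.
#' @param direction `"combined"`, `"gained"` or `"deleted"`.
#' @return data.frame with columns `k` and `fraction`.
#' @export
recurrence_curve <- function(dosage, genome = NULL,
                             scope = c("genome", "arm"), arm = NULL,
                             direction = c("combined", "gained", "deleted")) {
  scope <- match.arg(scope)
  direction <- match.arg(direction)
  stopifnot(inherits(dosage, "gene_dosage"))
  counts <- switch(direction,
                   combined = dosage$recurrence$n_altered,
                   gained = dosage$recurrence$n_gained,
                   deleted = dosage$recurrence$n_deleted)
  names(counts) <- dosage$recurrence$gene_id
  if (scope == "arm") {
    if (is.null(genome) || is.null(arm)) stop("arm scope needs genome and arm")
    keep <- genome$genes$gene_id[genome$genes$arm_id == arm]
    counts <- counts[names(counts) %in% keep]
  }
  counts <- counts[counts > 0]
  n_tumors <- ncol(dosage$status)
  if (length(counts) == 0)
    return(data.frame(k = seq_len(n_tumors), fraction = NA_real_))
  data.frame(k = seq_len(n_tumors),
             fraction = vapply(seq_len(n_tumors),
                               function(k) mean(counts >= k), numeric(1)))
}
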