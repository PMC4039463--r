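#' Construct a genome model
#'
#' A genome model is the coordinate system the pipeline works in: a set of
#' chromosome arms, a gene annotation, and a marker spacing. All intervals
#' are 0-based, half-open.
#'
#' @param arms data.frame with columns `arm_id` (character) and `length`
#'   (base pairs).
#' @param genes data.frame with columns `gene_id`, `arm_id`, `start`, `end`
#'   (0-based half-open, within the arm).
#' @param marker_spacing distance between adjacent markers, base pairs.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(arms, genes, marker_spacing) {
  stopifnot(is.data.frame(arms), all(c("arm_id", "length") %in% names(arms)),
            is.data.frame(genes),
            all(c("gene_id", "arm_id", "start", "end") %in% names(genes)))
  if (marker_spacing <= 0) stop("marker_spacing must be positive")
  if (anyDuplicated(arms$arm_id)) stop("duplicated arm ids")
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene ids")
  if (!all(genes$arm_id %in% arms$arm_id)) stop("gene on unknown arm")
  if (any(genes$end <= genes$start)) stop("gene intervals must have end > start")
  arm_len <- setNames(arms$length, arms$arm_id)
  if (any(genes$start < 0) || any(genes$end > arm_len[genes$arm_id]))
    stop("gene interval outside its arm")
  for (a in unique(genes$arm_id)) {
    g <- genes[genes$arm_id == a, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)]))
      stop("overlapping genes on arm ", a)
  }
  structure(list(arms = arms, genes = genes,
                 marker_spacing = as.numeric(marker_spacing)),
            class = "genome_model")
}

#' Default desk-scale genome model
#'
#' Eight arms totalling 300 Mb (a 1/10-scale stand-in for the 3,000 Mb
#' haploid genome) with evenly laid out, non-overlapping genes. The arm
#' named `"3q"` plays the role of the preferentially amplified arm.
#'
#' @param n_genes number of genes, distributed proportionally to arm length.
#' @param marker_spacing marker spacing in bp (default 2 kb, i.e. ~150,000
#'   markers genome-wide).
#' @param gene_length gene length in bp.
#' @return A `genome_model`.
#' @export
default_genome <- function(n_genes = 2000, marker_spacing = 2000,
                           gene_length = 2e4) {
  arms <- data.frame(
    arm_id = c("1p", "1q", "2q", "3p", "3q", "5p", "Xp", "Xq"),
    length = c(40, 45, 40, 35, 40, 30, 35, 35) * 1e6)
  n_per <- round(n_genes * arms$length / sum(arms$length))
  n_per[1] <- n_per[1] + (n_genes - sum(n_per))
  genes <- do.call(rbind, lapply(seq_len(nrow(arms)), function(i) {
    n <- n_per[i]
    step <- arms$length[i] / n
    start <- floor((seq_len(n) - 1) * step + (step - gene_length) / 2)
    data.frame(gene_id = sprintf("G_%s_%04d", arms$arm_id[i], seq_len(n)),
               arm_id = arms$arm_id[i], start = start,
               end = start + gene_length)
  }))
  genome_model(arms, genes, marker_spacing)
}

#' Marker positions of a genome model
#'
#' @param genome a `genome_model`.
#' @return Named list (per arm) of strictly increasing marker positions.
#' @export
marker_positions <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  sp <- genome$marker_spacing
  setNames(lapply(genome$arms$length,
                  function(L) seq(sp / 2, L - 1, by = sp)),
           genome$arms$arm_id)
}

#' @export
print.genome_model <- function(x, ...) {
  cat("Genome model:", nrow(x$arms), "arms,",
      sprintf("%.1f Mb,", sum(x$arms$length) / 1e6),
      nrow(x$genes), "genes, marker spacing", x$marker_spacing, "bp\n")
  invisible(x)
}
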