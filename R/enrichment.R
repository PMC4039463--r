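# Per-arm deregulation enrichment and sample clustering on gene-set
# expression profiles.

#' Per-arm deregulation enrichment
#'
#' For each chromosome arm, compares the deregulation rate of its genes
#' against the rest of the gene universe with a 2x2 chi-square test and
#' flags arms whose rate is above the genome-wide rate at `p < alpha`.
#'
#' @param deregulated logical vector named by gene id (the full explored
#'   universe: TRUE = deregulated).
#' @param genome a [genome_model()] mapping every gene to exactly one arm.
#' @param alpha significance level for the enrichment flag.
#' @return data.frame: arm, n_genes, n_deregulated, pct, chisq, p, enriched.
#' @export
per_arm_deregulation_test <- function(deregulated, genome, alpha = 0.05) {
  stopifnot(inherits(genome, "genome_model"), is.logical(deregulated))
  genes <- genome$genes
  if (!all(names(deregulated) %in% genes$gene_id))
    stop("deregulated vector contains genes absent from the genome")
  arm <- setNames(genes$arm_id, genes$gene_id)[names(deregulated)]
  out <- lapply(unique(genome$arms$arm_id), function(a) {
    on_arm <- arm == a
    n <- sum(on_arm)
    if (n == 0) {
      warning("arm ", a, " has no genes; excluded")
      return(NULL)
    }
    k <- sum(deregulated[on_arm])
    k_rest <- sum(deregulated[!on_arm])
    n_rest <- sum(!on_arm)
    tab <- matrix(c(k, n - k, k_rest, n_rest - k_rest), 2)
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    data.frame(arm = a, n_genes = n, n_deregulated = k,
               pct = 100 * k / n,
               chisq = unname(ct$statistic), p = ct$p.value,
               enriched = (k / n > k_rest / n_rest) &&
                 !is.na(ct$p.value) && ct$p.value < alpha)
  })
  do.call(rbind, out)
}

#' Hierarchical clustering of samples on a gene-set expression profile
#'
#' Average-linkage agglomeration on Euclidean distances between sample
#' profiles, cut into `k` flat groups. When burden groups are supplied the
#' association between cluster membership and burden group is tested with
#' Fisher's exact test (Monte Carlo above 60 observations).
#'
#' @param expr numeric matrix (genes of the set x samples).
#' @param k number of flat groups to cut.
#' @param burden_groups optional factor named by sample.
#' @param seed seed for the Monte-Carlo Fisher test on large tables.
#' @return List of class `profile_clustering`: `hclust` tree, `groups`
#'   (named integer), `newick` string, and `fisher_p` (NA when skipped).
#' @export
hierarchical_profile_clustering <- function(expr, k = 2,
                                            burden_groups = NULL,
                                            seed = 1L) {
  if (ncol(expr) < 2) stop("need at least 2 samples")
  if (nrow(expr) == 0) stop("empty gene set")
  d <- stats::dist(t(expr), method = "euclidean")
  constant <- all(d == 0)
  hc <- stats::hclust(d, method = "average")
  groups <- if (constant) setNames(rep(1L, ncol(expr)), colnames(expr))
  else stats::cutree(hc, k = k)
  fisher_p <- NA_real_
  if (!is.null(burden_groups) && !constant && length(unique(groups)) > 1) {
    bg <- burden_groups[names(groups)]
    tab <- table(groups, droplevels(factor(bg)))
    if (all(dim(tab) >= 2)) {
      if (sum(tab) <= 60) {
        fisher_p <- fisher.test(tab)$p.value
      } else {
        set.seed(as.integer(seed))
        fisher_p <- fisher.test(tab, simulate.p.value = TRUE,
                                B = 10000)$p.value
      }
    }
  }
  phylo <- ape::as.phylo(hc)
  structure(list(hclust = hc, groups = groups,
                 newick = ape::write.tree(phylo),
                 fisher_p = fisher_p, constant = constant),
            class = "profile_clustering")
}

#' @export
print.profile_clustering <- function(x, ...) {
  cat("Profile clustering:", length(x$groups), "samples in",
      length(unique(x$groups)), "groups")
  if (!is.na(x$fisher_p))
    cat(sprintf("; association with burden group p = %.3g (Fisher)",
                x$fisher_p))
  cat("\n")
  invisible(x)
}
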