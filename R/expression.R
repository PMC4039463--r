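# Per-tumor expression-status calling against a control baseline.

#' Control baseline statistics
#'
#' Per-gene mean and SD of the control samples on the linear intensity
#' scale.
#'
#' @param controls numeric matrix (genes x control samples), linear scale.
#' @return data.frame of class `control_baseline` with `gene_id`, `mean`,
#'   `sd`, `n_controls`.
#' @export
control_baseline <- function(controls) {
  if (ncol(controls) < 2) stop("need at least 2 control samples")
  if (any(controls < 0)) stop("negative intensities")
  out <- data.frame(gene_id = rownames(controls),
                    mean = rowMeans(controls),
                    sd = apply(controls, 1, sd),
                    n_controls = ncol(controls),
                    row.names = NULL)
  class(out) <- c("control_baseline", "data.frame")
  out
}

#' Dual-cutoff per-tumor expression status
#'
#' A gene is called up in a tumor when its intensity is at least twice the
#' control mean AND above the control mean plus one control SD; down when
#' at most half the control mean AND below the mean minus one SD; otherwise
#' unchanged. Intensities are linear-scale; the two conditions cannot hold
#' simultaneously for a valid baseline (checked).
#'
#' @param expr numeric matrix (genes x tumors), linear intensities, rows
#'   aligned with the baseline; or a single numeric vector per gene set.
#' @param baseline a [control_baseline()].
#' @return Character matrix (genes x tumors) with values `"down"`,
#'   `"unchanged"`, `"up"`.
#' @export
call_expression_status <- function(expr, baseline) {
  stopifnot(inherits(baseline, "control_baseline"))
  if (is.vector(expr)) expr <- matrix(expr, ncol = 1,
                                      dimnames = list(baseline$gene_id, "s"))
  if (nrow(expr) != nrow(baseline)) stop("gene universes differ")
  if (!is.null(rownames(expr)) &&
      !identical(rownames(expr), baseline$gene_id))
    stop("gene order differs from baseline")
  if (any(expr < 0)) stop("negative intensities")
  if (any(!is.finite(baseline$mean)) || any(baseline$mean <= 0))
    stop("baseline means must be finite and positive")
  m <- baseline$mean
  s <- baseline$sd
  up <- expr >= 2 * m & expr > m + s
  down <- expr <= 0.5 * m & expr < m - s
  if (any(up & down)) stop("internal error: up and down cannot both hold")
  out <- matrix("unchanged", nrow(expr), ncol(expr),
                dimnames = dimnames(expr))
  out[up] <- "up"
  out[down] <- "down"
  out
}
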