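# 5-state HMM smoothing/segmentation of marker-level log2 copy ratios.
# States 0..4 are integer copy numbers; state 2 is diploid.

#' Parameters of the 5-state copy-number HMM
#'
#' Emission means default to `log2(CN/2)` with the homozygous-deletion mean
#' floored at -2. Transitions are homogeneous: a single self-transition
#' probability per marker, with the remaining mass spread uniformly over
#' the other states.
#'
#' @param state_means emission means on the log2-ratio scale, one per state.
#' @param emission_sd Gaussian emission SD (> 0).
#' @param self_transition per-marker probability of staying in a state.
#' @param switch_matrix optional explicit row-stochastic transition matrix,
#'   overriding `self_transition`.
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(state_means = c(-2, -1, 0, log2(3 / 2), 1),
                       emission_sd = 0.25,
                       self_transition = 0.999,
                       switch_matrix = NULL) {
  k <- length(state_means)
  if (emission_sd <= 0) stop("emission_sd must be > 0")
  if (is.null(switch_matrix)) {
    if (self_transition <= 0 || self_transition >= 1)
      stop("self_transition must be in (0, 1)")
    switch_matrix <- matrix((1 - self_transition) / (k - 1), k, k)
    diag(switch_matrix) <- self_transition
  }
  if (!is.matrix(switch_matrix) || any(dim(switch_matrix) != k))
    stop("switch_matrix must be ", k, "x", k)
  if (any(abs(rowSums(switch_matrix) - 1) > 1e-9))
    stop("switch_matrix rows must sum to 1")
  structure(list(state_means = state_means, emission_sd = emission_sd,
                 switch_matrix = switch_matrix,
                 log_trans = log(switch_matrix),
                 log_init = rep(-log(k), k)),
            class = "hmm_params")
}

#' Viterbi segmentation of a marker track
#'
#' Decodes the most probable state path per arm and collapses it into
#' maximal runs of constant state. Segment boundaries are placed at the
#' midpoint between adjacent markers of differing state; the first and last
#' segments are anchored at the first marker position and one past the last
#' marker, so the segments tile the marker span (0-based half-open).
#'
#' @param track data.frame with columns `arm`, `position`, `log2ratio`
#'   (one sample), or a named list of such data.frames keyed by sample.
#' @param params an [hmm_params()].
#' @param sample_id sample label attached to the output.
#' @return data.frame of segments: `sample`, `arm`, `start`, `end`, `state`
#'   (0-4), `n_markers`, `length`.
#' @export
viterbi_segment <- function(track, params = hmm_params(),
                            sample_id = "sample") {
  stopifnot(inherits(params, "hmm_params"))
  if (is.data.frame(track)) {
    segs <- lapply(split(track, track$arm), function(tr) {
      pos <- tr$position
      x <- tr$log2ratio
      if (length(pos) == 0) return(NULL)
      if (any(!is.finite(x))) stop("non-finite log2 ratios")
      if (is.unsorted(pos, strictly = TRUE))
        stop("marker positions must be strictly increasing within an arm")
      path <- viterbi_path_cpp(x, params$state_means, params$emission_sd,
                               params$log_trans, params$log_init)$path
      runs <- rle(path)
      ends_i <- cumsum(runs$lengths)
      starts_i <- c(1L, head(ends_i, -1) + 1L)
      bounds <- c(pos[1],
                  if (length(ends_i) > 1)
                    floor((pos[ends_i[-length(ends_i)]] +
                             pos[starts_i[-1]]) / 2),
                  pos[length(pos)] + 1)
      data.frame(arm = tr$arm[1],
                 start = bounds[-length(bounds)],
                 end = bounds[-1],
                 state = runs$values,
                 n_markers = runs$lengths)
    })
    segs <- do.call(rbind, segs)
    if (is.null(segs))
      segs <- data.frame(arm = character(), start = numeric(),
                         end = numeric(), state = integer(),
                         n_markers = integer())
    segs$length <- segs$end - segs$start
    rownames(segs) <- NULL
    return(cbind(sample = rep(sample_id, nrow(segs)), segs))
  }
  # list of tracks: segment each sample
  do.call(rbind, lapply(names(track), function(s)
    viterbi_segment(track[[s]], params, sample_id = s)))
}

#' Filter copy-number-altered segments
#'
#' Retains non-diploid segments with at least `min_markers` altered
#' markers, length at least `min_length`, and at most `max_cnv_overlap` of
#' their bases inside germline constitutive CNVs (overlap measured against
#' the union of the CNV intervals). Idempotent.
#'
#' @param segments segment data.frame from [viterbi_segment()].
#' @param germline_cnvs optional data.frame `arm_id`/`start`/`end` of
#'   germline CNV intervals.
#' @param min_markers minimum run of CN-altered markers (default 50).
#' @param min_length minimum segment length in bp (default 500 kb).
#' @param max_cnv_overlap maximum germline-CNV overlap fraction, inclusive
#'   (default 0.5).
#' @return The filtered segment data.frame with a `cnv_overlap_fraction`
#'   column added.
#' @export
filter_cnas <- function(segments, germline_cnvs = NULL,
                        min_markers = 50, min_length = 5e5,
                        max_cnv_overlap = 0.5) {
  if (min_markers < 0 || min_length < 0 || max_cnv_overlap < 0)
    stop("thresholds must be non-negative")
  segs <- segments
  if (is.null(segs$cnv_overlap_fraction))
    segs$cnv_overlap_fraction <- 0
  if (!is.null(germline_cnvs) && nrow(segs) > 0) {
    for (a in unique(segs$arm)) {
      cnv <- germline_cnvs[germline_cnvs$arm_id == a, , drop = FALSE]
      if (nrow(cnv) == 0) next
      cnv_ir <- IRanges::reduce(IRanges::IRanges(cnv$start + 1, cnv$end))
      idx <- which(segs$arm == a)
      seg_ir <- IRanges::IRanges(segs$start[idx] + 1, segs$end[idx])
      # per-segment overlapped bases against the reduced CNV union
      hits <- IRanges::findOverlaps(seg_ir, cnv_ir)
      ovw <- rep(0, length(idx))
      if (length(hits) > 0) {
        w <- IRanges::width(IRanges::pintersect(
          seg_ir[S4Vectors::queryHits(hits)],
          cnv_ir[S4Vectors::subjectHits(hits)]))
        ovw <- as.numeric(tapply(w, factor(S4Vectors::queryHits(hits),
                                           levels = seq_along(idx)), sum))
        ovw[is.na(ovw)] <- 0
      }
      segs$cnv_overlap_fraction[idx] <- ovw / segs$length[idx]
    }
  }
  keep <- segs$state != 2 &
    segs$n_markers >= min_markers &
    segs$length >= min_length &
    segs$cnv_overlap_fraction <= max_cnv_overlap
  out <- segs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pool amplification states
#'
#' Relabels state 4 (amplification) as state 3 (single-copy gain) and
#' merges resulting same-state neighbours, summing marker counts.
#'
#' @param segments segment data.frame.
#' @return Segment data.frame with states in 0..3.
#' @export
collapse_cn4 <- function(segments) {
  if (nrow(segments) == 0) return(segments)
  segs <- segments
  segs$state[segs$state == 4] <- 3L
  segs <- segs[order(segs$sample, segs$arm, segs$start), ]
  merged <- list()
  cur <- segs[1, ]
  for (i in seq_len(nrow(segs))[-1]) {
    nxt <- segs[i, ]
    if (nxt$sample == cur$sample && nxt$arm == cur$arm &&
        nxt$state == cur$state && nxt$start == cur$end) {
      cur$end <- nxt$end
      cur$n_markers <- cur$n_markers + nxt$n_markers
      cur$length <- cur$end - cur$start
    } else {
      merged[[length(merged) + 1]] <- cur
      cur <- nxt
    }
  }
  merged[[length(merged) + 1]] <- cur
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}

#' Cross-platform concordance of CNA calls by segment size
#'
#' A segment of `a` agrees with call set `b` when at least half of its
#' bases are covered by same-direction (gain vs loss) segments of `b`.
#' Agreement is summarised per segment-size bin, overall, and as a Spearman
#' correlation of bin midpoint against agreement.
#'
#' @param a,b segment data.frames for the same sample/genome.
#' @param size_bins size bin breakpoints in bp (left-closed); an `Inf` top
#'   edge is added if missing.
#' @return List of class `concordance_table`: per-bin table, overall
#'   agreement percent, and the size-agreement Spearman rho.
#' @export
platform_concordance <- function(a, b,
                                 size_bins = c(2.5, 3, 4, 5, 7.5, 10, Inf) * 1e6) {
  if (is.finite(size_bins[length(size_bins)]))
    size_bins <- c(size_bins, Inf)
  empty <- data.frame(bin = character(), n = integer(),
                      agreement_pct = numeric())
  if (nrow(a) == 0)
    return(structure(list(by_bin = empty, overall_pct = NA_real_,
                          spearman_rho = NA_real_),
                     class = "concordance_table"))
  direction <- function(s) ifelse(s$state > 2, "gain", "loss")
  a$dir <- direction(a); b$dir <- direction(b)
  agree <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    bb <- b[b$arm == a$arm[i] & b$dir == a$dir[i], , drop = FALSE]
    if (nrow(bb) == 0) { agree[i] <- FALSE; next }
    cov_ir <- IRanges::reduce(IRanges::IRanges(bb$start + 1, bb$end))
    seg_ir <- IRanges::IRanges(a$start[i] + 1, a$end[i])
    covered <- sum(IRanges::width(IRanges::intersect(cov_ir, seg_ir)))
    agree[i] <- covered >= 0.5 * (a$end[i] - a$start[i])
  }
  bin_idx <- findInterval(a$length, size_bins)
  keep <- bin_idx >= 1 & bin_idx < length(size_bins)
  labs <- paste0(size_bins[-length(size_bins)] / 1e6, "-",
                 size_bins[-1] / 1e6, "Mb")
  mids <- ifelse(is.finite(size_bins[-1]),
                 (size_bins[-length(size_bins)] + size_bins[-1]) / 2,
                 size_bins[-length(size_bins)] * 1.5)
  by_bin <- do.call(rbind, lapply(seq_len(length(size_bins) - 1), function(k) {
    sel <- keep & bin_idx == k
    data.frame(bin = labs[k], midpoint = mids[k], n = sum(sel),
               agreement_pct = if (any(sel)) 100 * mean(agree[sel]) else NA)
  }))
  nz <- by_bin[by_bin$n > 0, ]
  rho <- if (nrow(nz) >= 3 && var(nz$agreement_pct) > 0)
    suppressWarnings(cor(nz$midpoint, nz$agreement_pct, method = "spearman"))
  else NA_real_
  structure(list(by_bin = by_bin, overall_pct = 100 * mean(agree),
                 spearman_rho = rho),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("Cross-platform CNA concordance:",
      sprintf("overall %.1f%%", x$overall_pct),
      sprintf("(size trend rho = %.2f)\n", x$spearman_rho))
  print(x$by_bin, row.names = FALSE)
  invisible(x)
}
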