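# Significance Analysis of Microarrays, two-class unpaired, from scratch:
# moderated d statistic with a fudge constant s0, class-label permutations
# for the null, delta-band calling with a median-false-positive FDR, and a
# permutation-density local fdr.

sam_d_stat <- function(x, idx1, idx2, s0) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(x[, idx1, drop = FALSE])
  m2 <- rowMeans(x[, idx2, drop = FALSE])
  ss1 <- rowSums((x[, idx1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, idx2, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  denom <- s + s0
  d <- ifelse(denom == 0, 0, (m1 - m2) / denom)
  list(d = d, s = s)
}

# Tusher-style fudge constant: the percentile of the gene-wise standard
# errors that minimises the coefficient of variation of the d spread
# across 100 windows of s.
sam_choose_s0 <- function(r, s) {
  alphas <- seq(0, 1, by = 0.05)
  cand <- quantile(s, alphas, names = FALSE)
  qcut <- quantile(s, seq(0, 1, by = 0.01), names = FALSE)
  win <- cut(s, unique(qcut), include.lowest = TRUE)
  if (nlevels(win) < 3) return(stats::median(s))
  cvs <- vapply(cand, function(s0) {
    denom <- s + s0
    d <- ifelse(denom == 0, 0, r / denom)
    v <- tapply(d, win, mad)
    v <- v[!is.na(v)]
    if (mean(v) == 0) Inf else sd(v) / mean(v)
  }, numeric(1))
  cand[which.min(cvs)]
}

sam_assignments <- function(n, n1, n_permutations, seed) {
  total <- choose(n, n1)
  if (total <= 2000) {
    asn <- combn(n, n1)
    list(idx = asn, exhaustive = TRUE)
  } else {
    set.seed(as.integer(seed))
    asn <- replicate(n_permutations, sort(sample.int(n, n1)))
    list(idx = asn, exhaustive = FALSE)
  }
}

#' Two-class SAM differential expression
#'
#' Computes the SAM statistic `d = (mean difference) / (s + s0)` per gene,
#' builds a permutation null over class-label assignments (full enumeration
#' when at most 2,000 assignments exist, otherwise seeded Monte Carlo),
#' selects the smallest delta whose median-false-positive FDR estimate is
#' within the target, and calls genes that clear the delta band, a linear
#' fold-change cutoff, and a local false-discovery cap estimated from the
#' permutation null density.
#'
#' @param tumors,controls linear-intensity matrices (genes x samples) with
#'   aligned rows; at least 2 samples per class.
#' @param fc_min minimum linear fold change (up: `>= fc_min`, down:
#'   `<= 1/fc_min`).
#' @param n_permutations Monte-Carlo permutation count when full
#'   enumeration is not feasible.
#' @param fdr_target target median-false-positive FDR for delta selection
#'   (0 reproduces the "general FDR 0" operating point).
#' @param local_fdr_max per-gene local fdr cap (default 0.10).
#' @param seed seed for Monte-Carlo label assignments.
#' @param log2_input set TRUE if the matrices are log2 scale; they are
#'   then exponentiated before analysis.
#' @return Object of class `sam_fit`: per-gene table (`d`, `s`,
#'   `fold_change`, `lfdr`, `called`, `direction`), `s0`, `delta`,
#'   estimated `fdr`, `pi0`, and (for small problems) the permutation null
#'   `null_d`.
#' @export
sam_two_class <- function(tumors, controls, fc_min = 1.5,
                          n_permutations = 1000, fdr_target = 0,
                          local_fdr_max = 0.1, seed = 1L,
                          log2_input = FALSE) {
  if (ncol(tumors) < 2 || ncol(controls) < 2)
    stop("need at least 2 samples per class")
  if (nrow(tumors) != nrow(controls)) stop("gene universes differ")
  if (!is.null(rownames(tumors)) && !is.null(rownames(controls)) &&
      !identical(rownames(tumors), rownames(controls)))
    stop("gene order differs between classes")
  if (log2_input) { tumors <- 2^tumors; controls <- 2^controls }
  x <- cbind(tumors, controls)
  n1 <- ncol(tumors); n2 <- ncol(controls); n <- n1 + n2
  p <- nrow(x)
  gene_ids <- rownames(x)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%d", seq_len(p))

  idx1 <- seq_len(n1); idx2 <- n1 + seq_len(n2)
  m1 <- rowMeans(tumors); m2 <- rowMeans(controls)
  base <- sam_d_stat(x, idx1, idx2, s0 = 0)
  s0 <- sam_choose_s0(m1 - m2, base$s)
  obs <- sam_d_stat(x, idx1, idx2, s0)
  d <- obs$d

  asn <- sam_assignments(n, n1, n_permutations, seed)
  B <- ncol(asn$idx)
  null_d <- matrix(0, p, B)
  for (b in seq_len(B)) {
    i1 <- asn$idx[, b]
    null_d[, b] <- sam_d_stat(x, i1, setdiff(seq_len(n), i1), s0)$d
  }

  ord <- order(d)
  ds <- d[ord]
  dbar <- rowMeans(apply(null_d, 2, sort))
  diffs <- ds - dbar

  qn <- quantile(null_d, c(0.25, 0.75), names = FALSE)
  pi0 <- min(1, sum(d >= qn[1] & d <= qn[2]) / (0.5 * p))

  deltas <- sort(unique(abs(diffs)))
  if (length(deltas) > 300)
    deltas <- unique(quantile(deltas, seq(0, 1, length.out = 300),
                              names = FALSE))
  delta_stats <- function(delta) {
    upcut <- suppressWarnings(min(ds[diffs >= delta & ds > 0]))
    lowcut <- suppressWarnings(max(ds[diffs <= -delta & ds < 0]))
    called <- (d >= upcut) | (d <= lowcut)
    nc <- sum(called)
    if (nc == 0) return(list(called = called, fdr = 0, upcut = upcut,
                             lowcut = lowcut))
    false_b <- colSums(null_d >= upcut | null_d <= lowcut)
    list(called = called, fdr = pi0 * median(false_b) / nc,
         upcut = upcut, lowcut = lowcut)
  }
  chosen <- NULL; chosen_delta <- Inf
  for (delta in deltas) {
    st <- delta_stats(delta)
    if (sum(st$called) > 0 && st$fdr <= fdr_target + 1e-12) {
      chosen <- st; chosen_delta <- delta
      break
    }
  }
  if (is.null(chosen))
    chosen <- list(called = rep(FALSE, p), fdr = NA_real_,
                   upcut = Inf, lowcut = -Inf)

  # local fdr from the permutation null density
  rng <- range(c(d, null_d))
  f0 <- density(as.numeric(null_d), from = rng[1], to = rng[2], n = 512)
  f1 <- density(d, from = rng[1], to = rng[2], n = 512)
  f0d <- approx(f0$x, f0$y, xout = d, rule = 2)$y
  f1d <- pmax(approx(f1$x, f1$y, xout = d, rule = 2)$y, 1e-12)
  lfdr <- pmin(1, pi0 * f0d / f1d)

  fc <- ifelse(m2 == 0, Inf, m1 / m2)
  fc_ok <- (d > 0 & fc >= fc_min) | (d < 0 & fc <= 1 / fc_min)
  called <- chosen$called & fc_ok & lfdr < local_fdr_max
  direction <- ifelse(!called, "none", ifelse(d > 0, "up", "down"))

  tab <- data.frame(gene_id = gene_ids, d = d, s = obs$s, fold_change = fc,
                    lfdr = lfdr, called = called, direction = direction,
                    row.names = NULL)
  structure(list(table = tab, s0 = s0, delta = chosen_delta,
                 fdr = chosen$fdr, pi0 = pi0,
                 upcut = chosen$upcut, lowcut = chosen$lowcut,
                 n_assignments = B, exhaustive = asn$exhaustive,
                 fc_min = fc_min, fdr_target = fdr_target,
                 null_d = if (p * B <= 2e6) null_d else NULL,
                 dbar = dbar, d_sorted = ds),
            class = "sam_fit")
}

#' Genes called by a SAM fit
#' @param fit a `sam_fit`.
#' @param direction `"both"`, `"up"` or `"down"`.
#' @return Character vector of gene ids.
#' @export
sam_called_genes <- function(fit, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  tab <- fit$table[fit$table$called, ]
  if (direction != "both") tab <- tab[tab$direction == direction, ]
  tab$gene_id
}

#' @export
print.sam_fit <- function(x, ...) {
  cat("SAM two-class fit:", nrow(x$table), "genes,",
      x$n_assignments,
      if (x$exhaustive) "exhaustive assignments;" else "sampled assignments;",
      "\n  s0 =", signif(x$s0, 3),
      " delta =", signif(x$delta, 3),
      " est. FDR =", signif(x$fdr, 3),
      " called:", sum(x$table$called),
      sprintf("(%d up, %d down)\n", sum(x$table$direction == "up"),
              sum(x$table$direction == "down")))
  invisible(x)
}
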