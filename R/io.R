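# Plain-text readers and writers. All files are TSV (or BED) with an
# optional leading "#" comment block; numeric columns are written with 17
# significant digits so that write -> read round-trips are exact.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

write_tsv <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

#' Write / read a numeric matrix as TSV
#'
#' Genes are rows (first column `gene_id`), samples are columns. A header
#' comment records the seed and, for expression matrices, the intensity
#' scale (`linear` or `log2`).
#'
#' @param m numeric matrix with rownames (gene ids) and colnames (samples).
#' @param path file path.
#' @param seed integer recorded in the header comment, or NULL.
#' @param scale intensity scale flag written to the header.
#' @return The path (writer) or the matrix (reader), invisibly/visibly.
#' @export
write_matrix_tsv <- function(m, path, seed = NULL, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  writeLines(sprintf("# scale: %s", scale), con)
  df <- data.frame(gene_id = rownames(m), check.names = FALSE)
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- fmt_num(m[, j])
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  hdr <- readLines(path, n = 5L)
  scale <- sub("^# scale: ", "", grep("^# scale:", hdr, value = TRUE)[1])
  df <- read_tsv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$gene_id
  attr(m, "scale") <- if (is.na(scale)) "linear" else scale
  m
}

#' Write / read marker tracks
#'
#' Long-format TSV with columns `sample`, `arm`, `position`, `log2ratio`.
#'
#' @param tracks named list (per sample) of data.frames with columns
#'   `arm`, `position`, `log2ratio`.
#' @param path file path.
#' @param seed integer recorded in the header comment, or NULL.
#' @return The path (writer); a named list of per-sample data.frames (reader).
#' @export
write_marker_tracks <- function(tracks, path, seed = NULL) {
  long <- do.call(rbind, lapply(names(tracks), function(s)
    cbind(sample = s, tracks[[s]])))
  if (is.null(long))
    long <- data.frame(sample = character(), arm = character(),
                       position = numeric(), log2ratio = numeric())
  write_tsv(long, path, seed = seed)
}

#' @rdname write_marker_tracks
#' @export
read_marker_tracks <- function(path) {
  long <- read_tsv(path)
  if (nrow(long) == 0) return(structure(list(), names = character()))
  split(long[, c("arm", "position", "log2ratio")], long$sample)
}

#' Write / read a gene annotation as BED
#'
#' BED columns: arm, start, end, gene_id (0-based half-open, as internal).
#'
#' @param genes data.frame with `gene_id`, `arm_id`, `start`, `end`.
#' @param path file path.
#' @return The path (writer); the annotation data.frame (reader).
#' @export
write_genes_bed <- function(genes, path) {
  bed <- data.frame(chrom = genes$arm_id, start = genes$start,
                    end = genes$end, name = genes$gene_id)
  con <- file(path, "w")
  on.exit(close(con))
  write.table(bed, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_genes_bed
#' @export
read_genes_bed <- function(path) {
  empty <- data.frame(gene_id = character(), arm_id = character(),
                      start = numeric(), end = numeric())
  if (file.size(path) == 0) return(empty)
  bed <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (nrow(bed) == 0) return(empty)
  if (ncol(bed) < 4) stop("BED file needs at least 4 columns")
  data.frame(gene_id = bed[[4]], arm_id = bed[[1]],
             start = bed[[2]], end = bed[[3]])
}

read_intervals_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  data.frame(arm_id = bed[[1]], start = bed[[2]], end = bed[[3]])
}
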