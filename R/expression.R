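# Exon-level expression analyses: gene centering, breakpoint-consistent
# 3'-exon overexpression scoring, and fusion-sample outlier ranking.

#' Construct an exon expression matrix
#'
#' @param rows Data frame with columns `gene`, `exon_index`, `contig`,
#'   `start`, `end` describing the exon rows.
#' @param values Numeric matrix (exons x samples) of non-negative FPKM.
#' @return Object of class `exon_matrix` with elements `rows` and `values`.
#' @export
exon_matrix <- function(rows, values) {
  rows <- as.data.frame(rows)
  values <- as.matrix(values)
  stopifnot(nrow(rows) == nrow(values))
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    ff_format_error("exon matrix sample names must be present and unique")
  }
  if (any(values < 0)) ff_format_error("negative expression values")
  for (g in unique(rows$gene)) {
    idx <- rows$exon_index[rows$gene == g]
    if (!identical(as.integer(sort(idx)), seq_along(idx))) {
      ff_format_error(paste0("exon_index not consecutive from 1 for gene ", g))
    }
  }
  structure(list(rows = rows, values = values), class = "exon_matrix")
}

#' @export
print.exon_matrix <- function(x, ...) {
  cat(sprintf("<exon_matrix> %d exons / %d genes x %d samples\n",
              nrow(x$rows), length(unique(x$rows$gene)), ncol(x$values)))
  invisible(x)
}

#' Read an exon expression matrix from TSV
#'
#' Expects columns `gene`, `exon_index`, `contig`, `start`, `end` followed
#' by one numeric column per sample.
#'
#' @param path Input TSV path.
#' @return An `exon_matrix`.
#' @export
read_exon_matrix <- function(path) {
  if (!file.exists(path)) ff_format_error(paste0("exon matrix not found: ", path))
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("gene", "exon_index", "contig", "start", "end")
  missing <- setdiff(meta_cols, names(tab))
  if (length(missing)) {
    ff_format_error(paste0("exon matrix missing column(s): ",
                           paste(missing, collapse = ", ")))
  }
  sample_cols <- setdiff(names(tab), meta_cols)
  if (length(sample_cols) == 0L) ff_format_error("exon matrix has no sample columns")
  exon_matrix(tab[, meta_cols], as.matrix(tab[, sample_cols, drop = FALSE]))
}

#' Write an exon expression matrix to TSV
#' @param mat An `exon_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exon_matrix <- function(mat, path) {
  tab <- cbind(mat$rows, as.data.frame(mat$values, check.names = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene-centre an exon expression matrix
#'
#' Transforms FPKM values to `log2(x + 1)` (the heatmap scale; FPKM spans
#' orders of magnitude) and subtracts the across-sample mean of each exon
#' row, so every row of the result has mean zero. Set `log = FALSE` to
#' centre on the linear FPKM scale instead.
#'
#' @param mat An `exon_matrix` with at least two samples.
#' @param log Centre on the log2 scale (default) or the linear scale.
#' @return An `exon_matrix` of centred values (rows retained; values may be
#'   negative).
#' @export
center_by_gene <- function(mat, log = TRUE) {
  v <- mat$values
  if (ncol(v) < 2L) ff_stop("center_by_gene: need at least 2 samples")
  if (log) v <- log2(v + 1)
  v <- v - rowMeans(v)
  out <- mat
  out$values <- v
  class(out) <- c("centered_exon_matrix", "exon_matrix")
  out
}

#' Breakpoint-consistent 3'-exon overexpression score
#'
#' For a 3' fusion partner whose exons at and downstream of the breakpoint
#' exon `k` are retained in the chimera, the score contrasts the sample's
#' mean centred expression over exons `>= k` with exons `< k`. The same
#' statistic computed in every other sample forms the null distribution
#' used to standardise the carrier's score.
#'
#' @param centered A centred exon matrix from [center_by_gene()].
#' @param gene Gene name of the 3' partner.
#' @param k Breakpoint exon index (first retained exon); must leave at
#'   least one exon on each side.
#' @param sample Sample id to score.
#' @return List with `sample_id`, `gene`, `breakpoint_exon`, `score`,
#'   `null_mean`, `null_sd` and `z` (`NA` when `null_sd` is zero).
#' @export
breakpoint_imbalance_score <- function(centered, gene, k, sample) {
  if (!inherits(centered, "centered_exon_matrix")) {
    ff_stop("breakpoint_imbalance_score expects a centred matrix (center_by_gene)")
  }
  idx <- which(centered$rows$gene == gene)
  if (length(idx) == 0L) ff_stop(paste0("gene not in exon matrix: ", gene))
  if (!sample %in% colnames(centered$values)) {
    ff_stop(paste0("sample not in exon matrix: ", sample))
  }
  exon_index <- centered$rows$exon_index[idx]
  if (k <= min(exon_index) || k > max(exon_index)) {
    ff_stop("breakpoint exon must leave at least one exon on each side")
  }
  up <- idx[exon_index < k]
  down <- idx[exon_index >= k]
  stat <- function(s) {
    mean(centered$values[down, s]) - mean(centered$values[up, s])
  }
  score <- stat(sample)
  others <- setdiff(colnames(centered$values), sample)
  null_scores <- vapply(others, stat, numeric(1))
  null_mean <- mean(null_scores)
  null_sd <- sd(null_scores)
  z <- if (is.na(null_sd) || null_sd == 0) NA_real_ else (score - null_mean) / null_sd
  list(sample_id = sample, gene = gene, breakpoint_exon = as.integer(k),
       score = score, null_mean = null_mean, null_sd = null_sd, z = z)
}

#' Gene-level expression from an exon matrix
#'
#' Exon-length-weighted mean of exon FPKM per gene, the gene-level value
#' used for outlier ranking when no gene-level matrix is supplied.
#'
#' @param mat An (uncentred) `exon_matrix`.
#' @param gene Gene name.
#' @return Named numeric vector across samples.
#' @export
gene_level_expression <- function(mat, gene) {
  idx <- which(mat$rows$gene == gene)
  if (length(idx) == 0L) ff_stop(paste0("gene not in exon matrix: ", gene))
  w <- mat$rows$end[idx] - mat$rows$start[idx] + 1
  colSums(mat$values[idx, , drop = FALSE] * w) / sum(w)
}

#' Rank of a sample's expression within the cohort
#'
#' Dense rank in descending order (1 = highest expression); tied samples
#' share the better (smaller) rank.
#'
#' @param values Named numeric vector of gene-level expression, one entry
#'   per sample.
#' @param sample Sample id to rank.
#' @return List with `rank` and `n`.
#' @export
outlier_rank <- function(values, sample) {
  if (length(values) < 2L) ff_stop("outlier_rank: need at least 2 samples")
  if (!sample %in% names(values)) {
    ff_stop(paste0("sample not present in expression vector: ", sample))
  }
  uvals <- sort(unique(values), decreasing = TRUE)
  r <- match(values[[sample]], uvals)
  list(rank = as.integer(r), n = length(values))
}
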