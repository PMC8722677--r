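#' Gene-by-cell UMI count matrix
#'
#' Sparse-friendly container for non-negative integer UMI counts with a
#' two-population cell grouping.
#'
#' @param counts gene x cell matrix (dense or `dgCMatrix`), with dimnames.
#' @param group character/factor of length `ncol(counts)`.
#' @return an object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, group) {
  counts <- as_csparse(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must carry gene and cell ids as dimnames")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stopf("duplicate gene or cell ids")
  if (length(group) != ncol(counts)) stopf("group must have one label per cell")
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stopf("counts must be non-negative integers")
  structure(list(counts = counts, genes = rownames(counts),
                 cells = colnames(counts),
                 group = setNames(as.character(group), colnames(counts))),
            class = "CountMatrix")
}

#' Quality-control filtering of cells and genes
#'
#' Removes cells expressing fewer than `min_genes` detected genes or fewer
#' than `min_umi` total unique molecular identifiers, then removes genes
#' detected in fewer than `min_cells` of the surviving cells (cell filters
#' first, then the gene filter). All thresholds use strict "less than"
#' semantics: a cell with exactly 200 detected genes, or a gene detected in
#' exactly 3 cells, is retained.
#'
#' @param m a [count_matrix()].
#' @param min_genes minimum detected genes per cell (default 200).
#' @param min_cells minimum cells per gene (default 3).
#' @param min_umi minimum UMIs per cell (default 3000).
#' @return list with `matrix` (filtered `CountMatrix`) and `report`
#'   (removed cell/gene ids and counts).
#' @export
qc_filter <- function(m, min_genes = 200, min_cells = 3, min_umi = 3000) {
  stopifnot(inherits(m, "CountMatrix"))
  x <- m$counts
  detected <- Matrix::colSums(x > 0)
  umi <- Matrix::colSums(x)
  keep_cells <- detected >= min_genes & umi >= min_umi
  if (!any(keep_cells)) stopf("QC removed every cell")
  x2 <- x[, keep_cells, drop = FALSE]
  keep_genes <- Matrix::rowSums(x2 > 0) >= min_cells
  out <- count_matrix(x2[keep_genes, , drop = FALSE], m$group[keep_cells])
  list(matrix = out,
       report = list(removed_cells = m$cells[!keep_cells],
                     removed_genes = m$genes[!keep_genes],
                     n_cells_removed = sum(!keep_cells),
                     n_genes_removed = sum(!keep_genes)))
}

#' Library-size log-normalization
#'
#' value = ln(1 + scale * count / cell_total), the standard normalization
#' preceding marker testing.
#'
#' @param m a [count_matrix()].
#' @param scale scale factor (default 10000).
#' @return list with `norm` (sparse normalized matrix) and `group`.
#' @export
lognormalize <- function(m, scale = 10000) {
  stopifnot(inherits(m, "CountMatrix"))
  totals <- Matrix::colSums(m$counts)
  if (any(totals == 0)) stopf("zero-total cell encountered (run qc_filter first)")
  x <- m$counts
  x@x <- log1p(scale * x@x / rep.int(totals, diff(x@p)))
  list(norm = x, group = m$group)
}

# Two-sided Wilcoxon rank-sum p-value. Exact by enumeration over group
# assignments when both groups are small and the number of assignments is
# enumerable (handles ties exactly; the two-sided p doubles the smaller
# inclusive tail); otherwise the normal approximation with tie correction.
wilcox_rank_sum <- function(x, y, exact_max = 25, enum_max = 2e5) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  if (n1 <= exact_max && n2 <= exact_max && choose(N, n1) <= enum_max) {
    combos <- utils::combn(N, n1)
    null_W <- colSums(matrix(r[combos], nrow = n1))
    p <- 2 * min(mean(null_W <= W), mean(null_W >= W))
    return(min(1, p))
  }
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- (W - n1 * (N + 1) / 2) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Two-group marker detection (Wilcoxon rank-sum)
#'
#' Tests every gene detected in at least `min_pct` of the cells of one of
#' the two groups. P-values come from a two-sided Wilcoxon rank-sum test on
#' the normalized values; the average log2 fold change is computed on
#' de-logged normalized expression, avg_log2FC = log2((mean1 + eps) /
#' (mean2 + eps)) with eps = 1e-9. Benjamini-Hochberg correction runs
#' across the tested genes. Group-1 markers are the rows with avg_log2FC >
#' 0, group-2 markers those with avg_log2FC < 0.
#'
#' @param norm normalized matrix (from [lognormalize()]) or its `$norm`.
#' @param group per-cell labels (exactly two levels, each with >= 3 cells).
#' @param min_pct minimum detection fraction in at least one group
#'   (default 0.3).
#' @param logfc_threshold minimum |avg_log2FC| to report (default 0).
#' @param ident_1 optional label to treat as group 1 (default: first level).
#' @return data.frame of class `MarkerTable`, sorted by p: `gene`,
#'   `avg_log2FC`, `pct_1`, `pct_2`, `p`, `p_adj`.
#' @export
find_markers <- function(norm, group = NULL, min_pct = 0.3, logfc_threshold = 0,
                         ident_1 = NULL) {
  if (is.list(norm) && !is.null(norm$norm)) {
    if (is.null(group)) group <- norm$group
    norm <- norm$norm
  }
  lv <- unique(group)
  if (length(lv) != 2) stopf("exactly two groups required, got %d", length(lv))
  if (!is.null(ident_1)) lv <- c(ident_1, setdiff(lv, ident_1))
  i1 <- which(group == lv[1]); i2 <- which(group == lv[2])
  if (length(i1) < 3 || length(i2) < 3) stopf("each group needs >= 3 cells")

  x1 <- norm[, i1, drop = FALSE]; x2 <- norm[, i2, drop = FALSE]
  pct1 <- Matrix::rowSums(x1 > 0) / length(i1)
  pct2 <- Matrix::rowSums(x2 > 0) / length(i2)
  test <- which(pct1 >= min_pct | pct2 >= min_pct)
  if (!length(test)) stopf("no genes pass the min_pct filter")

  eps <- 1e-9
  m1 <- Matrix::rowSums(expm1(x1[test, , drop = FALSE])) / length(i1)
  m2 <- Matrix::rowSums(expm1(x2[test, , drop = FALSE])) / length(i2)
  lfc <- log2((m1 + eps) / (m2 + eps))
  d1 <- as.matrix(x1[test, , drop = FALSE])
  d2 <- as.matrix(x2[test, , drop = FALSE])
  p <- vapply(seq_along(test), function(i) wilcox_rank_sum(d1[i, ], d2[i, ]),
              numeric(1))
  out <- data.frame(gene = rownames(norm)[test], avg_log2FC = lfc,
                    pct_1 = pct1[test], pct_2 = pct2[test], p = p,
                    p_adj = p.adjust(p, method = "BH"),
                    row.names = NULL)
  out <- out[abs(out$avg_log2FC) >= logfc_threshold, , drop = FALSE]
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ident_1") <- lv[1]; attr(out, "ident_2") <- lv[2]
  class(out) <- c("MarkerTable", "data.frame")
  out
}

#' TPM normalization with log2 scaling (bulk RNA-seq)
#'
#' rate = count / transcript_length; TPM = 1e6 * rate / sum(rate); returns
#' log2(TPM + 1). Accepts a vector (one sample) or a gene x sample matrix.
#'
#' @param counts non-negative counts.
#' @param lengths positive transcript lengths, one per gene.
#' @return log2(TPM + 1) values, same shape as `counts`.
#' @export
tpm_log2 <- function(counts, lengths) {
  if (any(lengths <= 0)) stopf("transcript lengths must be positive")
  if (any(counts < 0)) stopf("counts must be non-negative")
  f <- function(v) {
    rate <- v / lengths
    s <- sum(rate)
    if (s == 0) stopf("all-zero sample: TPM undefined")
    log2(1e6 * rate / s + 1)
  }
  if (is.matrix(counts)) apply(counts, 2, f) else f(counts)
}
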