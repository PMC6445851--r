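#' Log2-transform an expression study
#'
#' Elementwise log2 for variance stabilization of microarray-style
#' intensities. All values must be strictly positive; a violation is
#' rejected with the offending gene/sample coordinates.
#'
#' @param study An [expression_study()] of positive intensities.
#' @return The study with log2 values; labels preserved.
#' @export
log2_transform <- function(study) {
  bad <- which(study$values <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-positive intensity at gene '%s', sample '%s' (value %g)",
                 rownames(study$values)[bad[1, 1]],
                 colnames(study$values)[bad[1, 2]],
                 study$values[bad[1, , drop = FALSE]]))
  }
  study$values <- log2(study$values)
  study
}

#' Quantile-normalize the arrays of a study
#'
#' Forces every array (column) to share the same distribution: each
#' column's sorted values are replaced by the per-rank means across
#' columns, preserving within-column rank order; tied values receive the
#' mean of the tied ranks' reference values. This is the cross-array
#' normalization step of the RMA pipeline.
#'
#' @param study An [expression_study()] (any scale).
#' @return The normalized study. With a single column the input is
#'   returned unchanged with a warning.
#' @export
quantile_normalize <- function(study) {
  if (ncol(study$values) < 2L) {
    warning("quantile normalization needs >= 2 arrays; returning input")
    return(study)
  }
  out <- limma::normalizeQuantiles(study$values, ties = TRUE)
  dimnames(out) <- dimnames(study$values)
  study$values <- out
  study
}

#' Tukey median polish of a probe-by-sample matrix
#'
#' Iteratively sweeps row and column medians (rows first) to decompose
#' `table = overall + row + col + residual`, stopping when the maximum
#' absolute change falls below `tol` or after `maxiter` iterations. The
#' per-sample gene summary is `overall + column effect`, the RMA-style
#' robust summarization of probe-level values.
#'
#' @param table Numeric matrix (probes x samples), at least 1x1.
#' @param tol Convergence tolerance on the residual sweep.
#' @param maxiter Maximum sweep iterations.
#' @return List with `overall`, `row` (row effects), `col` (column
#'   effects), `residuals`, and `summary = overall + col`.
#' @export
median_polish <- function(table, tol = 1e-6, maxiter = 20L) {
  table <- as.matrix(table)
  if (!length(table)) stop("empty matrix")
  mp <- stats::medpolish(table, eps = tol, maxiter = maxiter,
                         trace.iter = FALSE, na.rm = FALSE)
  list(overall = mp$overall, row = mp$row, col = mp$col,
       residuals = mp$residuals, summary = mp$overall + mp$col)
}

#' Summarize probe-level values to gene level by median polish
#'
#' @param values Probe-by-sample numeric matrix (log2 scale).
#' @param probe_map data.frame with columns `probe`, `gene` mapping each
#'   row of `values` to its gene.
#' @return Gene-by-sample matrix of median-polish summaries.
#' @export
summarize_genes <- function(values, probe_map) {
  stopifnot(all(rownames(values) %in% probe_map$probe))
  gene_of <- setNames(probe_map$gene, probe_map$probe)
  genes <- unique(gene_of[rownames(values)])
  out <- t(vapply(genes, function(g) {
    rows <- values[gene_of[rownames(values)] == g, , drop = FALSE]
    median_polish(rows)$summary
  }, numeric(ncol(values))))
  dimnames(out) <- list(genes, colnames(values))
  out
}

#' Standard preprocessing chain
#'
#' log2 transform, then quantile normalization across arrays.
#'
#' @param study An [expression_study()] of positive intensities.
#' @return The preprocessed (log2-scale) study.
#' @export
preprocess_study <- function(study) {
  quantile_normalize(log2_transform(study))
}
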