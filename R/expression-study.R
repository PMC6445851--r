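#' Construct a labeled expression study
#'
#' Container for one cohort's genes-by-samples intensity matrix with
#' case/control labels, the unit of input to preprocessing and to the
#' rank-product meta-analysis.
#'
#' @param study_id Character scalar identifying the cohort.
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   unique row and column names.
#' @param labels Character vector of `"case"`/`"control"`, one per column.
#' @return An object of class `expression_study`: a list with elements
#'   `study_id`, `values` and `labels`.
#' @export
expression_study <- function(study_id, values, labels) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have row (gene) and column (sample) names")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("gene and sample ids must be unique")
  labels <- as.character(labels)
  if (length(labels) != ncol(values))
    stop("need one case/control label per sample")
  if (!all(labels %in% c("case", "control")))
    stop("labels must be 'case' or 'control'")
  structure(list(study_id = as.character(study_id),
                 values = values, labels = labels),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study '%s'> %d genes x %d samples (%d case, %d control)\n",
              x$study_id, nrow(x$values), ncol(x$values),
              sum(x$labels == "case"), sum(x$labels == "control")))
  invisible(x)
}

case_cols <- function(study) which(study$labels == "case")
control_cols <- function(study) which(study$labels == "control")
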