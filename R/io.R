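#' Read and write pipeline file formats
#'
#' Thin wrappers over the standard formats the pipeline exchanges:
#' TSV tables, GMT gene sets, BED intervals (0-based half-open) and
#' 2-column edge lists.
#'
#' @name io
NULL

#' @rdname io
#' @param x Object to write (data.frame, matrix, study, graph or
#'   [pathway_db()] depending on the writer).
#' @param path File path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname io
#' @param study An [expression_study()]; written as a gene-by-sample TSV
#'   with a `gene` id column and a `#labels:` comment header line.
#' @export
write_study_tsv <- function(study, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#labels: ", paste(study$labels, collapse = "\t")),
             con)
  df <- data.frame(gene = rownames(study$values), study$values,
                   check.names = FALSE)
  suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' @rdname io
#' @param study_id Study identifier to attach on read.
#' @export
read_study_tsv <- function(path, study_id = basename(path)) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#labels: "))
    stop("missing '#labels:' header in ", path)
  labels <- strsplit(sub("^#labels: ", "", first), "\t")[[1]]
  df <- read.delim(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_study(study_id, m, labels)
}

#' @rdname io
#' @param db A [pathway_db()]; written as standard GMT (name, description,
#'   genes; tab-separated).
#' @export
write_gmt <- function(db, path) {
  fgsea::writeGmtPathways(db$sets, path)
  invisible(path)
}

#' @rdname io
#' @param universe Background universe to attach; defaults to the union
#'   of the sets.
#' @export
read_gmt <- function(path, universe = NULL) {
  sets <- fgsea::gmtPathways(path)
  pathway_db(sets, universe %||% sort(unique(unlist(sets))))
}

#' @rdname io
#' @param intervals data.frame with `chr`, `start`, `end`, `label`
#'   (0-based half-open); written as 4-column BED.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chr", "start", "end", "label") %in% names(intervals)))
  write.table(intervals[, c("chr", "start", "end", "label")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED needs at least 3 columns")
  names(df)[1:3] <- c("chr", "start", "end")
  df$label <- if (ncol(df) >= 4L) as.character(df[[4]]) else "."
  df[, c("chr", "start", "end", "label")]
}

#' @rdname io
#' @param graph An `igraph` interactome; written as a 2-column TSV edge
#'   list of gene symbols.
#' @export
write_edges <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  write.table(data.frame(from = el[, 1], to = el[, 2]), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_edges <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  interactome_from_edges(df)
}

#' Read a GTEx-portal-style eQTL association table
#'
#' Accepts a minimal TSV dialect with columns `snp`, `gene`, `p` and
#' optionally `slope` and `tissue`; any extra columns are ignored.
#'
#' @param path TSV path.
#' @return data.frame of eQTL records.
#' @export
read_eqtl_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp", "gene", "p")
  if (!all(need %in% names(df)))
    stop("eQTL table needs columns: ", paste(need, collapse = ", "))
  if (is.null(df$slope)) df$slope <- NA_real_
  if (is.null(df$tissue)) df$tissue <- NA_character_
  df[, c("snp", "gene", "slope", "p", "tissue")]
}
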