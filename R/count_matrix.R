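#' Panel count matrix with probe annotation
#'
#' A `count_matrix` holds a genes x samples matrix of nonnegative counts
#' (or normalized, possibly fractional, counts) together with a per-gene
#' annotation giving the probe class and pathway label.  Probe classes
#' follow the nCounter convention: `endogenous` probes measure the genes
#' of interest, `housekeeping` probes are stable reference genes used
#' for input correction, and `positive` / `negative` probes are the
#' synthetic spike-in controls used for within-sample scaling and
#' background estimation.
#'
#' @param counts numeric matrix, genes in rows (rownames required),
#'   samples in columns (colnames required); all values must be
#'   nonnegative and finite.
#' @param annotation data.frame with columns `gene`, `probe_class`
#'   (one of `"endogenous"`, `"housekeeping"`, `"positive"`,
#'   `"negative"`) and `pathway` (character, may be `NA` for control
#'   probes).  Every row of `counts` must have exactly one annotation
#'   row.
#'
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` (the matrix) and `annotation` (the data.frame, reordered
#'   to match the matrix rows).
#' @export
count_matrix <- function(counts, annotation) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (nrow(counts) > 0L && is.null(rownames(counts)))
    stop("`counts` must have rownames (genes)")
  if (is.null(colnames(counts)))
    stop("`counts` must have colnames (samples)")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene identifiers in `counts`")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers in `counts`")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("`counts` must be finite and nonnegative")
  req <- c("gene", "probe_class", "pathway")
  if (!all(req %in% names(annotation)))
    stop("`annotation` must have columns gene, probe_class, pathway")
  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  if (anyDuplicated(annotation$gene))
    stop("duplicate gene identifiers in `annotation`")
  missing <- setdiff(rownames(counts), annotation$gene)
  if (length(missing) > 0L)
    stop("genes lacking annotation: ", paste(utils::head(missing, 5), collapse = ", "))
  classes <- c("endogenous", "housekeeping", "positive", "negative")
  if (!all(annotation$probe_class %in% classes))
    stop("probe_class must be one of: ", paste(classes, collapse = ", "))
  annotation <- annotation[match(rownames(counts), annotation$gene), req,
                           drop = FALSE]
  rownames(annotation) <- NULL
  structure(list(counts = counts, annotation = annotation),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  tab <- table(x$annotation$probe_class)
  cat("count_matrix:", nrow(x$counts), "probes x", ncol(x$counts),
      "samples\n  ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Gene identifiers of a given probe class
#'
#' @param x a [count_matrix].
#' @param class probe class or classes to select.
#' @return Character vector of gene identifiers.
#' @export
probe_genes <- function(x, class) {
  stopifnot(inherits(x, "count_matrix"))
  x$annotation$gene[x$annotation$probe_class %in% class]
}

#' Subset a count matrix by genes or samples
#'
#' @param x a [count_matrix].
#' @param genes gene identifiers to keep (default: all).
#' @param samples sample identifiers to keep (default: all).
#' @return A [count_matrix] restricted to the requested rows/columns.
#' @export
subset_counts <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(genes)) genes <- rownames(x$counts)
  if (is.null(samples)) samples <- colnames(x$counts)
  bad <- setdiff(genes, rownames(x$counts))
  if (length(bad) > 0L)
    stop("unknown genes: ", paste(utils::head(bad, 5), collapse = ", "))
  bad <- setdiff(samples, colnames(x$counts))
  if (length(bad) > 0L)
    stop("unknown samples: ", paste(utils::head(bad, 5), collapse = ", "))
  count_matrix(x$counts[genes, samples, drop = FALSE], x$annotation)
}

#' Read a count matrix from delimited text files
#'
#' Reads a genes x samples table (first column = gene identifier,
#' remaining columns = samples) and an annotation table with columns
#' `gene`, `probe_class`, `pathway`.  Tab- and comma-separated files are
#' both accepted (chosen by file extension; `.csv` means comma).
#'
#' @param counts_file path to the counts table.
#' @param annotation_file path to the annotation table.
#' @return A [count_matrix].
#' @export
read_count_tables <- function(counts_file, annotation_file) {
  cnt <- read_delim_auto(counts_file)
  ann <- read_delim_auto(annotation_file)
  mat <- as.matrix(cnt[, -1, drop = FALSE])
  rownames(mat) <- as.character(cnt[[1]])
  count_matrix(mat, ann)
}

#' Write a count matrix (and its annotation) as TSV
#'
#' @param x a [count_matrix].
#' @param counts_file output path for the counts table (first column
#'   `gene`, then one column per sample).
#' @param annotation_file optional output path for the annotation table.
#' @return Invisibly, `x`.
#' @export
write_count_tables <- function(x, counts_file, annotation_file = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(annotation_file))
    utils::write.table(x$annotation, annotation_file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(x)
}

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
}
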