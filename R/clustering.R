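#' Row-scale an expression matrix
#'
#' Centers and scales each gene (row) to mean 0 and standard deviation
#' 1 (sample SD, n-1 denominator), the standardization applied before
#' heatmap clustering to remove per-probe efficiency differences.
#' Zero-variance rows cannot be scaled; they are dropped with a
#' warning and listed in the `dropped` attribute.
#'
#' @param mat numeric matrix, genes in rows, >= 2 columns.
#' @return The scaled matrix with attributes `center` and `scale`
#'   (the original row means/SDs) and `dropped` (zero-variance genes).
#' @export
scale_rows <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need >= 2 samples to scale rows")
  ctr <- rowMeans(mat)
  sd <- apply(mat, 1, stats::sd)
  drop <- sd == 0
  if (any(drop))
    warning("dropping zero-variance rows: ",
            paste(rownames(mat)[drop], collapse = ", "))
  out <- (mat[!drop, , drop = FALSE] - ctr[!drop]) / sd[!drop]
  attr(out, "center") <- ctr[!drop]
  attr(out, "scale") <- sd[!drop]
  attr(out, "dropped") <- rownames(mat)[drop]
  out
}

#' Spearman correlation distance matrix
#'
#' `d(i, j) = 1 - rho_spearman(i, j)` between rows (`axis = "genes"`)
#' or columns (`axis = "samples"`) of the matrix; the range is
#' [0, 2], with 0 for identical rank profiles and 2 for exactly
#' reversed ones.
#'
#' @param mat numeric matrix.
#' @param axis cluster `"genes"` (rows) or `"samples"` (columns).
#' @return A symmetric distance matrix with zero diagonal.
#' @export
spearman_distance <- function(mat, axis = c("genes", "samples")) {
  axis <- match.arg(axis)
  mat <- as.matrix(mat)
  if (axis == "genes") mat <- t(mat)
  if (nrow(mat) < 3L)
    stop("need >= 3 observations per vector for Spearman distance")
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance vector(s): ",
         paste(colnames(mat)[sds == 0], collapse = ", "))
  d <- 1 - stats::cor(mat, method = "spearman")
  diag(d) <- 0
  d
}

#' Complete-linkage hierarchical clustering
#'
#' Standard complete-linkage agglomeration of a distance matrix
#' (delegated to [stats::hclust()]); complete linkage guarantees
#' non-decreasing merge heights.
#'
#' @param d symmetric distance matrix (or `dist` object).
#' @return An `hclust` object.
#' @export
complete_linkage <- function(d) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d), tol = 1e-12))
      stop("distance matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  stats::hclust(d, method = "complete")
}

#' Cluster genes and samples of an expression matrix
#'
#' Reproduces the heatmap computation: rows are scaled to mean 0 / SD 1,
#' then genes and samples are each clustered by complete linkage on
#' `1 - Spearman's rho` distances.  (Gene-axis Spearman correlations
#' are invariant to the row scaling; the scaling matters for display
#' and for any non-rank downstream use.)
#'
#' @param x a [count_matrix] or plain numeric matrix (genes x samples).
#' @param probe_classes probe classes to include when `x` is a
#'   [count_matrix].
#' @return A list with `scaled` (the row-scaled matrix), `genes` and
#'   `samples` (`hclust` objects), and `gene_order` / `sample_order`
#'   (leaf orders as identifiers).
#' @export
cluster_expression <- function(x, probe_classes = "endogenous") {
  mat <- if (inherits(x, "count_matrix"))
    x$counts[probe_genes(x, probe_classes), , drop = FALSE]
  else as.matrix(x)
  sc <- scale_rows(mat)
  hg <- complete_linkage(spearman_distance(sc, axis = "genes"))
  hs <- complete_linkage(spearman_distance(sc, axis = "samples"))
  list(scaled = sc, genes = hg, samples = hs,
       gene_order = rownames(sc)[hg$order],
       sample_order = colnames(sc)[hs$order])
}

#' Purity of a two-way sample split against known labels
#'
#' Cuts the sample dendrogram into `k` clusters and reports the
#' fraction of samples whose cluster matches the best-matching label
#' assignment (for `k = 2`, the maximum over the two possible
#' cluster-to-label pairings).
#'
#' @param hs an `hclust` object over samples.
#' @param labels character/factor vector of true labels, named by
#'   sample or ordered as the clustering input.
#' @param k number of clusters (default 2).
#' @return Label purity in [0, 1].
#' @export
cluster_purity <- function(hs, labels, k = 2) {
  cl <- stats::cutree(hs, k = k)
  if (!is.null(names(labels))) labels <- labels[names(cl)]
  tab <- table(cl, labels)
  sum(apply(tab, 1, max)) / sum(tab)
}
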