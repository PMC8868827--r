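#' Fisher Z transform and its inverse
#'
#' `fisher_z(rho) = atanh(rho)`; averaging correlations on the z scale
#' and back-transforming with `tanh` avoids the bias of averaging
#' bounded correlation coefficients directly.
#'
#' @param rho correlation coefficient(s) in (-1, 1).
#' @param z Fisher z value(s).
#' @return Transformed value(s).
#' @export
fisher_z <- function(rho) atanh(rho)

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

# Clamp |rho| away from 1 so atanh stays finite; warns when clamping.
clamp_rho <- function(rho, eps = 1e-12) {
  hit <- abs(rho) >= 1 - eps
  if (any(hit)) {
    warning("correlation(s) of magnitude 1 clamped to +/-(1 - 1e-12) ",
            "before Fisher Z pooling")
    rho[hit] <- sign(rho[hit]) * (1 - eps)
  }
  rho
}

#' Pooled Spearman correlation between an anchor gene and a gene set
#'
#' Computes the Spearman correlation of the anchor's expression with
#' each target gene across samples, transforms each coefficient with
#' Fisher's Z, averages on the z scale, and back-transforms with
#' `tanh`.  The pooled value is the statistic for the extent of
#' co-regulation between the anchor and the set.
#'
#' @param anchor numeric vector: the anchor gene's expression across
#'   samples (length >= 3).
#' @param targets numeric matrix with target genes in rows and the
#'   same samples in columns; the anchor must not be among the rows.
#' @return A list with `rho` (named per-target Spearman coefficients),
#'   `z` (their Fisher z values), and `pooled` (the back-transformed
#'   mean).
#' @export
pooled_rho <- function(anchor, targets) {
  targets <- as.matrix(targets)
  if (length(anchor) < 3L) stop("need >= 3 samples")
  if (ncol(targets) != length(anchor))
    stop("anchor and targets disagree on sample count")
  if (nrow(targets) == 0L) stop("empty target set")
  rho <- apply(targets, 1, function(y)
    stats::cor(anchor, y, method = "spearman"))
  z <- fisher_z(clamp_rho(rho))
  list(rho = rho, z = z, pooled = fisher_z_inv(mean(z)))
}

#' Random-subset permutation null for the pooled correlation
#'
#' Draws `m` random size-`k` subsets (without replacement by default)
#' from a pool of candidate genes and recomputes the Fisher-Z-pooled
#' Spearman correlation with the anchor for each draw.  Because the
#' anchor-target correlations do not depend on the subset, the
#' per-gene coefficients are computed once and each draw pools a
#' sampled subset of their z values.
#'
#' @param anchor numeric vector of anchor expression across samples.
#' @param mat numeric matrix, genes x samples, containing the pool
#'   genes.
#' @param pool character vector of candidate gene identifiers (rows of
#'   `mat`); must not contain the anchor gene and must have >= `k`
#'   members.
#' @param k subset size per draw.
#' @param m number of draws.
#' @param seed integer RNG seed.
#' @param replace draw subsets with replacement (default `FALSE`).
#' @return A list of class `null_distribution` with `draws` (the `m`
#'   pooled statistics), `null_mean` (the Fisher-pooled mean over
#'   draws), `per_gene_rho`, `pool`, `k`, `m`, `seed`.
#' @export
permutation_null <- function(anchor, mat, pool, k, m = 10000L, seed = 1L,
                             replace = FALSE) {
  mat <- as.matrix(mat)
  missing <- setdiff(pool, rownames(mat))
  if (length(missing) > 0L)
    stop("pool genes not in matrix: ", paste(missing, collapse = ", "))
  if (!replace && length(pool) < k)
    stop("pool (", length(pool), ") smaller than subset size k = ", k)
  obs <- pooled_rho(anchor, mat[pool, , drop = FALSE])
  z <- obs$z
  rng <- local_rng(seed)
  draws <- vapply(seq_len(m), function(i)
    mean(z[sample.int(length(z), k, replace = replace)]),
    numeric(1))
  rng()
  draws <- fisher_z_inv(draws)
  structure(list(draws = draws,
                 null_mean = fisher_z_inv(mean(fisher_z(clamp_rho(draws)))),
                 per_gene_rho = obs$rho, pool = pool, k = k, m = m,
                 seed = seed),
            class = "null_distribution")
}

#' Empirical p-value against a simulated null
#'
#' `P = (n + 1) / (m + 1)`, where `n` counts null draws at least as
#' high as the observed statistic and `m` is the number of draws.  The
#' add-one smoothing keeps `P` in (0, 1].
#'
#' @param observed observed statistic.
#' @param null a [permutation_null()] result or a numeric vector of
#'   null draws.
#' @return The one-sided empirical p-value.
#' @export
empirical_p <- function(observed, null) {
  draws <- if (inherits(null, "null_distribution")) null$draws else null
  m <- length(draws)
  if (m < 1L) stop("need >= 1 null draw")
  (sum(draws >= observed) + 1) / (m + 1)
}

#' Split tumors into low/high groups at the anchor's median
#'
#' Low contains samples whose anchor expression is equal to or below
#' the cohort median; high contains those above it (even-sized cohorts
#' use the midpoint median).  The tie rule is configurable because the
#' opposite convention (ties to the high group) is also in use.
#'
#' @param values named numeric vector of anchor expression over tumors
#'   (length >= 2).
#' @param ties put median-tied samples in the `"low"` (default) or
#'   `"high"` group.
#' @return A list with `low`, `high` (sample identifiers), and
#'   `median`.
#' @export
median_split <- function(values, ties = c("low", "high")) {
  ties <- match.arg(ties)
  if (length(values) < 2L) stop("need >= 2 samples")
  if (is.null(names(values))) names(values) <- seq_along(values)
  med <- stats::median(values)
  low <- if (ties == "low") values <= med else values < med
  list(low = names(values)[low], high = names(values)[!low], median = med)
}

#' Anchored co-regulation test with a subset-permutation null
#'
#' Composes [pooled_rho()], [permutation_null()] and [empirical_p()]:
#' the observed statistic is the Fisher-Z-pooled Spearman correlation
#' between the anchor gene and the target set; the null re-pools the
#' anchor's correlation with `m` random size-`k` subsets of the
#' candidate pool; significance is the one-sided empirical p-value of
#' the observed statistic against those draws.
#'
#' @param mat numeric matrix or [count_matrix], genes x samples.
#' @param anchor anchor gene identifier (a row of `mat`).
#' @param targets target gene identifiers (rows of `mat`), excluding
#'   the anchor.
#' @param pool candidate pool for null subsets; default `targets`'
#'   upregulated-gene superset must be supplied by the caller.  The
#'   anchor is always removed from the pool.
#' @param k null subset size; default `length(targets)`.
#' @param m number of null draws.
#' @param seed integer RNG seed.
#' @param replace draw null subsets with replacement.
#' @return An object of class `coreg_test`: a list with `anchor`,
#'   `targets`, `per_gene_rho`, `observed`, `null_mean`, `p_empirical`,
#'   `n_as_high`, `m`, `k`, `seed`.
#' @export
coregulation_test <- function(mat, anchor, targets, pool,
                              k = length(targets), m = 10000L, seed = 1L,
                              replace = FALSE) {
  if (inherits(mat, "count_matrix")) mat <- mat$counts
  mat <- as.matrix(mat)
  if (!anchor %in% rownames(mat)) stop("anchor not in matrix: ", anchor)
  if (anchor %in% targets) stop("anchor must not be in the target set")
  missing <- setdiff(targets, rownames(mat))
  if (length(missing) > 0L)
    stop("target genes not in matrix: ", paste(missing, collapse = ", "))
  pool <- setdiff(pool, anchor)
  av <- mat[anchor, ]
  obs <- pooled_rho(av, mat[targets, , drop = FALSE])
  null <- permutation_null(av, mat, pool, k = k, m = m, seed = seed,
                           replace = replace)
  n_as_high <- sum(null$draws >= obs$pooled)
  structure(list(anchor = anchor, targets = targets,
                 per_gene_rho = obs$rho, observed = obs$pooled,
                 null_mean = null$null_mean,
                 p_empirical = (n_as_high + 1) / (m + 1),
                 n_as_high = n_as_high, m = m, k = k, seed = seed),
            class = "coreg_test")
}

#' @export
print.coreg_test <- function(x, ...) {
  cat("Anchored co-regulation test\n",
      " anchor:    ", x$anchor, "  (", length(x$targets),
      " target genes)\n",
      " observed pooled Spearman rho: ", formatC(x$observed, digits = 4),
      "\n  null mean (", x$m, " random ", x$k, "-subsets): ",
      formatC(x$null_mean, digits = 4), "\n",
      " empirical P = (n+1)/(m+1) = ", formatC(x$p_empirical, digits = 4),
      "   [n = ", x$n_as_high, "]\n", sep = "")
  invisible(x)
}
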