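#' Background-adjust counts using negative controls
#'
#' Subtracts, within each sample, the background level estimated from
#' that sample's negative-control probes from every endogenous and
#' housekeeping count, clamping at zero.  Control rows are kept
#' unmodified for audit.  The default background statistic is the mean
#' of the negative controls; `mean + k*SD` thresholding is available.
#'
#' @param x a [count_matrix] containing at least one negative-control
#'   probe.
#' @param stat background statistic, `"mean"` (default) or
#'   `"mean_sd"` (mean plus `k` standard deviations).
#' @param k multiplier of the negative-control SD when
#'   `stat = "mean_sd"`.
#' @return A [count_matrix] with adjusted endogenous/housekeeping
#'   counts; the per-sample background is attached as attribute
#'   `"background"`.
#' @export
background_adjust <- function(x, stat = c("mean", "mean_sd"), k = 2) {
  stopifnot(inherits(x, "count_matrix"))
  stat <- match.arg(stat)
  neg <- probe_genes(x, "negative")
  if (length(neg) == 0L)
    stop("no probes of class 'negative' present; cannot estimate background")
  negm <- x$counts[neg, , drop = FALSE]
  bg <- colMeans(negm)
  if (stat == "mean_sd")
    bg <- bg + k * apply(negm, 2, stats::sd)
  target <- probe_genes(x, c("endogenous", "housekeeping"))
  counts <- x$counts
  counts[target, ] <- pmax(sweep(counts[target, , drop = FALSE], 2, bg), 0)
  out <- count_matrix(counts, x$annotation)
  attr(out, "background") <- bg
  out
}

#' Within-sample normalization using positive controls
#'
#' Computes, per sample, the geometric mean of the positive-control
#' counts; the scale factor for a sample is the grand (arithmetic) mean
#' of these geometric means divided by the sample's own geometric mean.
#' Endogenous and housekeeping counts are multiplied by the factor.
#' Factors outside `flag_range` set a QC flag on the sample but the
#' sample is kept; dropping is the caller's decision.
#'
#' @param x a [count_matrix] with >= 2 positive-control probes, all
#'   with positive counts.
#' @param flag_range numeric length-2; factors outside this interval
#'   are flagged.
#' @return A list with `matrix` (normalized [count_matrix]) and
#'   `factors` (data.frame: sample, pos_geomean, pos_factor, pos_flag).
#' @export
positive_control_normalize <- function(x, flag_range = c(0.3, 3)) {
  stopifnot(inherits(x, "count_matrix"))
  pos <- probe_genes(x, "positive")
  if (length(pos) < 2L)
    stop("need >= 2 positive-control probes")
  posm <- x$counts[pos, , drop = FALSE]
  if (any(posm <= 0))
    stop("zero positive-control count: geometric mean undefined (samples: ",
         paste(colnames(posm)[colSums(posm <= 0) > 0], collapse = ", "), ")")
  gm <- exp(colMeans(log(posm)))
  factor <- mean(gm) / gm
  target <- probe_genes(x, c("endogenous", "housekeeping"))
  counts <- x$counts
  counts[target, ] <- sweep(counts[target, , drop = FALSE], 2, factor, `*`)
  list(matrix = count_matrix(counts, x$annotation),
       factors = data.frame(sample = colnames(counts),
                            pos_geomean = unname(gm),
                            pos_factor = unname(factor),
                            pos_flag = unname(factor < flag_range[1] |
                                                factor > flag_range[2]),
                            stringsAsFactors = FALSE))
}

#' Across-sample normalization using housekeeping genes
#'
#' Corrects for RNA input: the scale factor for a sample is the grand
#' (arithmetic) mean over samples of the per-sample housekeeping means
#' divided by that sample's housekeeping mean.  Endogenous and
#' housekeeping counts are multiplied by the factor, which makes the
#' per-sample housekeeping means exactly equal afterwards.
#'
#' @param x a [count_matrix] with >= 1 housekeeping gene.
#' @return A list with `matrix` (normalized [count_matrix]) and
#'   `factors` (data.frame: sample, hk_mean, hk_factor).
#' @export
housekeeping_normalize <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  hk <- probe_genes(x, "housekeeping")
  if (length(hk) == 0L) stop("no housekeeping genes present")
  hkm <- colMeans(x$counts[hk, , drop = FALSE])
  if (any(hkm == 0))
    stop("housekeeping mean is zero for sample(s): ",
         paste(names(hkm)[hkm == 0], collapse = ", "))
  factor <- mean(hkm) / hkm
  target <- probe_genes(x, c("endogenous", "housekeeping"))
  counts <- x$counts
  counts[target, ] <- sweep(counts[target, , drop = FALSE], 2, factor, `*`)
  list(matrix = count_matrix(counts, x$annotation),
       factors = data.frame(sample = colnames(counts),
                            hk_mean = unname(hkm),
                            hk_factor = unname(factor),
                            stringsAsFactors = FALSE))
}

#' Drop excluded genes from the panel
#'
#' Removes the listed genes (typically a faulty-TagSet list, see
#' [tagset_exclusions()]) before analysis.  Genes absent from the
#' matrix raise a warning, not an error: panel dialects differ.
#'
#' @param x a [count_matrix].
#' @param exclude character vector of gene identifiers to drop.
#' @return A [count_matrix] without the listed genes; the number of
#'   retained endogenous genes is reported as attribute
#'   `"n_endogenous_retained"`.
#' @export
apply_exclusions <- function(x, exclude) {
  stopifnot(inherits(x, "count_matrix"))
  if (length(exclude) == 0L) return(x)
  absent <- setdiff(exclude, rownames(x$counts))
  if (length(absent) > 0L)
    warning("excluded genes not in matrix: ",
            paste(absent, collapse = ", "))
  keep <- setdiff(rownames(x$counts), exclude)
  out <- subset_counts(x, genes = keep)
  attr(out, "n_endogenous_retained") <- length(probe_genes(out, "endogenous"))
  out
}

#' Average technical replicate lanes
#'
#' Collapses every replicate group defined by the sample sheet's
#' `replicate_of` column to a single sample holding the per-gene
#' arithmetic mean; non-replicated samples pass through.  Groups of any
#' size >= 2 are supported.
#'
#' @param x a [count_matrix].
#' @param samples data.frame with columns `sample` and `replicate_of`
#'   (`NA` for primary lanes; otherwise the identifier of the primary
#'   lane the row replicates).
#' @return A [count_matrix] with one column per replicate group, named
#'   after the primary sample, in the primary samples' original order.
#' @export
average_replicates <- function(x, samples) {
  stopifnot(inherits(x, "count_matrix"))
  if (!all(c("sample", "replicate_of") %in% names(samples)))
    stop("sample sheet needs columns `sample` and `replicate_of`")
  sheet <- samples[match(colnames(x$counts), samples$sample), ]
  if (anyNA(sheet$sample))
    stop("samples missing from sheet: ",
         paste(setdiff(colnames(x$counts), samples$sample), collapse = ", "))
  primary <- ifelse(is.na(sheet$replicate_of), sheet$sample,
                    sheet$replicate_of)
  missing_primary <- setdiff(primary, colnames(x$counts))
  if (length(missing_primary) > 0L)
    stop("replicate_of references missing sample(s): ",
         paste(missing_primary, collapse = ", "))
  keep <- unique(primary[is.na(sheet$replicate_of)])
  counts <- vapply(keep, function(s)
    rowMeans(x$counts[, primary == s, drop = FALSE]),
    numeric(nrow(x$counts)))
  rownames(counts) <- rownames(x$counts)
  count_matrix(counts, x$annotation)
}

#' Full normalization chain for panel counts
#'
#' Applies, in order: background adjustment via negative controls,
#' within-sample positive-control scaling, across-sample housekeeping
#' normalization, gene exclusion, and replicate averaging.  Normalized
#' values are kept as real numbers (no re-rounding); downstream testing
#' is rank-based.
#'
#' @param x a raw [count_matrix].
#' @param samples optional sample sheet for replicate averaging (see
#'   [average_replicates()]); `NULL` skips that step.
#' @param exclude genes to drop (default none); pass
#'   [tagset_exclusions()] for the standard panel exclusion list.
#' @param background_stat,background_k see [background_adjust()].
#' @param flag_range see [positive_control_normalize()].
#' @return A list with `matrix` (the normalized [count_matrix]) and
#'   `factors` (per-sample data.frame: background, positive-control
#'   and housekeeping factors and QC flags).
#' @export
normalize_counts <- function(x, samples = NULL, exclude = character(),
                             background_stat = "mean", background_k = 2,
                             flag_range = c(0.3, 3)) {
  bgd <- background_adjust(x, stat = background_stat, k = background_k)
  pos <- positive_control_normalize(bgd, flag_range = flag_range)
  hk <- housekeeping_normalize(pos$matrix)
  out <- apply_exclusions(hk$matrix, exclude)
  if (!is.null(samples)) out <- average_replicates(out, samples)
  factors <- merge(pos$factors, hk$factors, by = "sample", sort = FALSE)
  factors <- data.frame(sample = factors$sample,
                        background = unname(attr(bgd, "background")),
                        factors[, -1, drop = FALSE],
                        stringsAsFactors = FALSE)
  list(matrix = out, factors = factors)
}
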