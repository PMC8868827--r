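#' Pooled rank transform
#'
#' Ranks a vector 1..n with ties receiving average ranks (the
#' convention under which the rank sum is always n(n+1)/2).
#'
#' @param values numeric vector, length >= 2.
#' @return Numeric vector of ranks.
#' @export
rank_transform <- function(values) {
  if (length(values) < 2L) stop("need >= 2 values to rank")
  rank(values, ties.method = "average")
}

#' Welch's t-test on two groups of (rank) values
#'
#' The two-sample t statistic with unpooled variances,
#' `t = (mean_a - mean_b) / sqrt(s2_a/n_a + s2_b/n_b)`, with
#' Welch-Satterthwaite degrees of freedom and a two-tailed p-value from
#' the Student t distribution.  Applied to pooled ranks this is the
#' rank-based Welch test used for differential expression.
#'
#' Degenerate inputs: zero variance in both groups with equal means
#' gives `t = 0, p = 1` by convention; zero variance with unequal
#' means gives the `p = 0` limit with `flag = "zero_variance"`.
#'
#' @param a,b numeric vectors (each length >= 2), e.g. the two groups'
#'   subsets of pooled ranks.
#' @return A list with `t`, `df`, `p`, and `flag` (`NA` or
#'   `"zero_variance"`).
#' @export
welch_on_ranks <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs >= 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  dm <- mean(a) - mean(b)
  if (va == 0 && vb == 0) {
    if (dm == 0) return(list(t = 0, df = NA_real_, p = 1, flag = NA_character_))
    return(list(t = sign(dm) * Inf, df = NA_real_, p = 0,
                flag = "zero_variance"))
  }
  se2 <- va / na + vb / nb
  t <- dm / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, flag = NA_character_)
}

#' Rank-based Welch differential expression with Bonferroni correction
#'
#' For each tested gene, the normalized values of all samples (both
#' groups pooled) are rank-transformed, Welch's t-test is applied to
#' the two groups' rank subsets, and the two-tailed p-value is
#' Bonferroni-corrected over the number of genes tested.  The log2 fold
#' change is `log2(mean_tumor / mean_normal)` of the normalized values;
#' a gene with a nonpositive group mean gets `log2fc = NA` and
#' `flag = "nonpositive_mean"`.
#'
#' By default both endogenous and housekeeping probes are tested (the
#' housekeeping probes can themselves shift between groups) and the
#' Bonferroni multiplier is the number of genes tested; both are
#' configurable.
#'
#' @param x a normalized [count_matrix].
#' @param samples sample sheet with columns `sample` and `group`;
#'   `group` must take exactly two values.
#' @param case_group the group treated as "tumor" for the fold-change
#'   numerator; default `"tumor"`.
#' @param probe_classes probe classes to test.
#' @param n_tests Bonferroni multiplier; default the number of genes
#'   tested.
#' @param alpha family-wise significance level for the `significant`
#'   flag.
#' @return data.frame sorted by corrected p with columns `gene`,
#'   `pathway`, `log2fc`, `t`, `df`, `p`, `p_bonferroni`,
#'   `significant`, `direction`, `flag`.
#' @export
differential_expression <- function(x, samples, case_group = "tumor",
                                    probe_classes = c("endogenous",
                                                      "housekeeping"),
                                    n_tests = NULL, alpha = 0.05) {
  stopifnot(inherits(x, "count_matrix"))
  sheet <- samples[match(colnames(x$counts), samples$sample), ]
  if (anyNA(sheet$sample))
    stop("samples missing from sheet: ",
         paste(setdiff(colnames(x$counts), samples$sample), collapse = ", "))
  groups <- unique(sheet$group)
  if (length(groups) != 2L)
    stop("`group` must take exactly two values, got: ",
         paste(groups, collapse = ", "))
  if (!case_group %in% groups)
    stop("case_group '", case_group, "' not present in sample sheet")
  is_case <- sheet$group == case_group
  if (sum(is_case) < 2L || sum(!is_case) < 2L)
    stop("each group needs >= 2 samples")
  genes <- probe_genes(x, probe_classes)
  if (length(genes) == 0L) stop("no genes of the requested probe classes")
  if (is.null(n_tests)) n_tests <- length(genes)

  mat <- x$counts[genes, , drop = FALSE]
  res <- lapply(genes, function(g) {
    v <- mat[g, ]
    r <- rank_transform(v)
    w <- welch_on_ranks(r[is_case], r[!is_case])
    m_case <- mean(v[is_case]); m_ctrl <- mean(v[!is_case])
    l2fc <- if (m_case > 0 && m_ctrl > 0) log2(m_case / m_ctrl) else NA_real_
    flag <- w$flag
    if (is.na(l2fc) && is.na(flag)) flag <- "nonpositive_mean"
    data.frame(gene = g, log2fc = l2fc, t = w$t, df = w$df, p = w$p,
               flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$pathway <- x$annotation$pathway[match(out$gene, x$annotation$gene)]
  out$p_bonferroni <- pmin(1, out$p * n_tests)
  out$significant <- out$p_bonferroni < alpha
  out$direction <- ifelse(ifelse(is.na(out$log2fc), out$t >= 0,
                                 out$log2fc >= 0), "up", "down")
  out <- out[order(out$p_bonferroni, out$p, out$gene),
             c("gene", "pathway", "log2fc", "t", "df", "p",
               "p_bonferroni", "significant", "direction", "flag")]
  rownames(out) <- NULL
  attr(out, "n_tests") <- n_tests
  out
}
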