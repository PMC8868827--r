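#' Poisson concentration estimate from droplet counts
#'
#' Under Poisson partitioning the mean occupancy (copies per droplet,
#' CPD) is `lambda = -ln(negatives / total)` and the absolute
#' concentration is `lambda / V_d` copies/uL for droplet volume `V_d`
#' in uL.  The 95% CI uses the delta method:
#' `SE(lambda) = sqrt(phat / ((1 - phat) * total))` with
#' `phat = positives / total`, and the interval is
#' `(lambda +/- 1.96 SE) / V_d`, clamped at 0.
#'
#' Boundary cases: zero positives give `lambda = 0` with a one-sided
#' upper limit from the rule of three (`-ln(1 - 3/total)`); a
#' saturated well (all droplets positive) is unbounded above and is
#' reported as a finite lower bound by substituting 0.5 pseudo
#' negatives, with flag `"saturated"`.  Counts may be fractional
#' (e.g. merged wells); only `0 <= positives <= total` is required.
#'
#' @param n_droplets total accepted droplets (> 0).
#' @param n_positive positive droplets in the channel.
#' @param droplet_volume droplet volume in uL; the package's reporting
#'   convention is 0.001 uL (1 nL), under which 0.05 CPD equals 50
#'   copies/uL; the QX200 instrument constant 0.00085 uL is also
#'   common, and every estimate records the volume used.
#' @return An object of class `concentration_estimate`: a list with
#'   `lambda_cpd`, `copies_per_ul`, `ci_low`, `ci_high`,
#'   `droplet_volume`, `n_droplets`, `n_positive`, `flag`.
#' @export
estimate_concentration <- function(n_droplets, n_positive,
                                   droplet_volume = 0.001) {
  if (n_droplets <= 0) stop("n_droplets must be > 0")
  if (droplet_volume <= 0) stop("droplet_volume must be > 0")
  if (n_positive < 0 || n_positive > n_droplets)
    stop("need 0 <= n_positive <= n_droplets")
  flag <- NA_character_
  if (n_positive == n_droplets) {
    n_positive <- n_droplets - 0.5  # finite lower bound for saturation
    flag <- "saturated"
  }
  phat <- n_positive / n_droplets
  lambda <- -log1p(-phat)
  if (n_positive == 0) {
    upper <- -log1p(-min(3 / n_droplets, 1)) / droplet_volume
    return(structure(list(lambda_cpd = 0, copies_per_ul = 0,
                          ci_low = 0, ci_high = upper,
                          droplet_volume = droplet_volume,
                          n_droplets = n_droplets, n_positive = 0,
                          flag = "zero_positive"),
                     class = "concentration_estimate"))
  }
  se <- sqrt(phat / ((1 - phat) * n_droplets))
  structure(list(lambda_cpd = lambda,
                 copies_per_ul = lambda / droplet_volume,
                 ci_low = max(0, (lambda - 1.96 * se)) / droplet_volume,
                 ci_high = (lambda + 1.96 * se) / droplet_volume,
                 droplet_volume = droplet_volume,
                 n_droplets = n_droplets, n_positive = n_positive,
                 flag = flag),
            class = "concentration_estimate")
}

#' @export
print.concentration_estimate <- function(x, ...) {
  cat(sprintf(
    "%.4g copies/uL (lambda = %.4g CPD; 95%% CI %.4g-%.4g; V_d = %g uL)%s\n",
    x$copies_per_ul, x$lambda_cpd, x$ci_low, x$ci_high, x$droplet_volume,
    if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Target/reference concentration ratio with a delta-method CI
#'
#' Ratio of two channel concentrations (typically FAM target over HEX
#' reference in a duplex well), with a 95% CI propagated on the log
#' scale treating the two estimates as independent (they share
#' droplets; the approximation is conservative at low occupancy).
#'
#' @param target,reference [estimate_concentration()] results; the
#'   reference concentration must be positive.
#' @return A list with `ratio`, `ci_low`, `ci_high`.
#' @export
normalized_ratio <- function(target, reference) {
  stopifnot(inherits(target, "concentration_estimate"),
            inherits(reference, "concentration_estimate"))
  if (reference$copies_per_ul <= 0)
    stop("reference concentration must be > 0")
  ratio <- target$copies_per_ul / reference$copies_per_ul
  if (target$copies_per_ul == 0)
    return(list(ratio = 0, ci_low = 0,
                ci_high = target$ci_high / reference$copies_per_ul))
  se_log <- sqrt(se_lambda(target)^2 / target$lambda_cpd^2 +
                   se_lambda(reference)^2 / reference$lambda_cpd^2)
  list(ratio = ratio,
       ci_low = ratio * exp(-1.96 * se_log),
       ci_high = ratio * exp(1.96 * se_log))
}

se_lambda <- function(est) {
  phat <- est$n_positive / est$n_droplets
  sqrt(phat / ((1 - phat) * est$n_droplets))
}

#' Second-assay RNA input under the 0.05-CPD loading scheme
#'
#' Input equalization across samples: a first assay loads `mass1` ng
#' of total RNA and measures the reference gene's occupancy; the
#' second assay loads the mass that brings the reference to the target
#' occupancy (default 0.05 CPD, i.e. 50 copies/uL at 1 nL droplets),
#' assuming linearity of input.
#'
#' @param measured_cpd reference-gene occupancy measured in assay 1
#'   (> 0).
#' @param mass1 RNA mass loaded in assay 1 (ng), default 30.
#' @param target_cpd desired reference occupancy for assay 2, default
#'   0.05.
#' @param max_load_ng flag threshold: masses above it are flagged as
#'   exceeding well capacity (default 100 ng).
#' @return A list with `mass2_ng` and `flag` (`NA` or
#'   `"exceeds_max_load"`).
#' @export
loading_mass <- function(measured_cpd, mass1 = 30, target_cpd = 0.05,
                         max_load_ng = 100) {
  if (measured_cpd <= 0) stop("measured CPD must be > 0")
  if (mass1 <= 0 || target_cpd <= 0) stop("masses and CPDs must be positive")
  mass2 <- mass1 * target_cpd / measured_cpd
  list(mass2_ng = mass2,
       flag = if (mass2 > max_load_ng) "exceeds_max_load" else NA_character_)
}

#' Contamination check on a no-RT control well
#'
#' A no-reverse-transcriptase control should contain no amplifiable
#' cDNA; the well fails if its estimated concentration exceeds the
#' threshold (default 0.2 copies/uL, just above the 0.16 copies/uL
#' maximum seen in accepted runs).
#'
#' @param n_droplets,n_positive droplet counts of the no-RT well.
#' @param droplet_volume droplet volume in uL.
#' @param threshold copies/uL above which the control fails.
#' @return A list with `pass` (logical), `copies_per_ul`, `threshold`.
#' @export
no_rt_check <- function(n_droplets, n_positive, droplet_volume = 0.001,
                        threshold = 0.2) {
  est <- estimate_concentration(n_droplets, n_positive, droplet_volume)
  list(pass = est$copies_per_ul <= threshold,
       copies_per_ul = est$copies_per_ul, threshold = threshold)
}

#' Quantify a table of duplex wells
#'
#' Applies [estimate_concentration()] to both channels of each well in
#' a duplex export (schema of [simulate_duplex_wells()]).
#'
#' @param wells data.frame with columns `well`, `target_fam`,
#'   `target_hex`, `n_droplets`, `n_pos_fam`, `n_pos_hex`.
#' @param droplet_volume droplet volume in uL.
#' @return data.frame with one row per well and channel: `well`,
#'   `channel`, `target`, `lambda_cpd`, `copies_per_ul`, `ci_low`,
#'   `ci_high`, `flag`.
#' @export
quantify_wells <- function(wells, droplet_volume = 0.001) {
  req <- c("well", "target_fam", "target_hex", "n_droplets",
           "n_pos_fam", "n_pos_hex")
  if (!all(req %in% names(wells)))
    stop("`wells` needs columns: ", paste(req, collapse = ", "))
  one <- function(i, channel) {
    pos <- if (channel == "FAM") wells$n_pos_fam[i] else wells$n_pos_hex[i]
    target <- if (channel == "FAM") wells$target_fam[i] else wells$target_hex[i]
    est <- estimate_concentration(wells$n_droplets[i], pos, droplet_volume)
    data.frame(well = wells$well[i], channel = channel, target = target,
               lambda_cpd = est$lambda_cpd,
               copies_per_ul = est$copies_per_ul,
               ci_low = est$ci_low, ci_high = est$ci_high,
               flag = est$flag, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(lapply(seq_len(nrow(wells)), one, "FAM"),
                          lapply(seq_len(nrow(wells)), one, "HEX")))
  rownames(out) <- NULL
  out
}

#' Cross-platform concordance of paired expression values
#'
#' Spearman and Pearson correlation between two platforms' values for
#' the same samples, plus a per-sample discordance flag for samples
#' whose rank differs between platforms by more than a configurable
#' fraction of the cohort size.
#'
#' @param a,b numeric vectors of paired values (>= 3 pairs).
#' @param ids sample identifiers; if `a` and `b` are named, their
#'   names must agree and `ids` may be omitted.
#' @param flag_fraction rank-difference fraction above which a sample
#'   is flagged discordant (default 0.25).
#' @return A list with `spearman`, `pearson`, and `discordant`
#'   (data.frame: id, rank_a, rank_b, rank_diff, flagged).
#' @export
concordance <- function(a, b, ids = NULL, flag_fraction = 0.25) {
  if (is.null(ids)) {
    if (!is.null(names(a)) && !is.null(names(b))) {
      if (!setequal(names(a), names(b))) stop("mismatched sample ids")
      b <- b[names(a)]
      ids <- names(a)
    } else ids <- as.character(seq_along(a))
  }
  if (length(a) != length(b) || length(a) != length(ids))
    stop("a, b and ids must have equal length")
  if (length(a) < 3L) stop("need >= 3 paired samples")
  ra <- rank(a); rb <- rank(b)
  dif <- abs(ra - rb)
  list(spearman = stats::cor(a, b, method = "spearman"),
       pearson = stats::cor(a, b, method = "pearson"),
       discordant = data.frame(id = ids, rank_a = ra, rank_b = rb,
                               rank_diff = dif,
                               flagged = dif > flag_fraction * length(a),
                               stringsAsFactors = FALSE))
}

#' Select the reporting assay for a gene measured by several amplicons
#'
#' When a transcript is measured by multiple amplicon assays (e.g.
#' different exon junctions), fragmented template depresses some
#' amplicons more than others; the assay reporting the highest
#' expression across samples is taken as closest to the true abundance.
#' Selection is by maximum median across samples.
#'
#' @param values numeric matrix of normalized expression values,
#'   assays in rows, samples in columns.
#' @return A list with `assay` (the selected row name) and `medians`
#'   (per-assay medians).
#' @export
select_assay <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("`values` needs assay rownames")
  med <- apply(values, 1, stats::median)
  list(assay = names(which.max(med)), medians = med)
}
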