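test_that("Fisher-Z pooling matches hand arithmetic", {
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z_inv(fisher_z(0.73)), 0.73, tolerance = 1e-12)
  # rho {0.5, 0.8} -> tanh((atanh 0.5 + atanh 0.8)/2) = 0.67722...
  expect_equal(tanh(mean(fisher_z(c(0.5, 0.8)))), 0.67722, tolerance = 1e-4)
})

test_that("pooled_rho pools per-target Spearman coefficients", {
  anchor <- c(3, 1, 4, 1.5, 9, 2.6, 5)
  t1 <- c(2, 1, 5, 3, 9, 4, 6)            # some positive rho r
  t2 <- -t1                               # exactly -r (rank reversal)
  pr <- pooled_rho(anchor, rbind(A = t1, B = t2))
  expect_equal(pr$rho[["A"]], -pr$rho[["B"]])
  expect_equal(pr$pooled, 0, tolerance = 1e-12)  # odd symmetry of atanh
  # all targets with equal rho -> pooled equals that rho
  same <- pooled_rho(anchor, rbind(A = t1, B = t1 * 2 + 1))  # same ranks
  expect_equal(same$pooled, same$rho[["A"]], tolerance = 1e-12)
  # perfect correlation is clamped with a warning, not an error
  expect_warning(sat <- pooled_rho(anchor, rbind(A = anchor)), "clamped")
  expect_lt(sat$pooled, 1)
  expect_error(pooled_rho(anchor[1:2], rbind(A = t1[1:2])), ">= 3 samples")
})

test_that("pooled_rho is invariant to monotone per-gene transforms", {
  set.seed(13)
  mat <- matrix(stats::rlnorm(5 * 20), 5,
                dimnames = list(paste0("G", 1:5), NULL))
  anchor <- stats::rlnorm(20)
  a <- pooled_rho(anchor, mat)$pooled
  b <- pooled_rho(log(anchor), exp(mat / max(mat)))$pooled
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("the permutation null is reproducible and degenerate-safe", {
  set.seed(2)
  mat <- matrix(stats::rnorm(8 * 15), 8,
                dimnames = list(paste0("G", 1:8), NULL))
  anchor <- stats::rnorm(15)
  n1 <- permutation_null(anchor, mat, paste0("G", 1:8), k = 3, m = 50,
                         seed = 4)
  n2 <- permutation_null(anchor, mat, paste0("G", 1:8), k = 3, m = 50,
                         seed = 4)
  expect_identical(n1$draws, n2$draws)
  expect_error(permutation_null(anchor, mat, paste0("G", 1:3), k = 5),
               "smaller than subset size")
  # pool == target set with k = pool size: every draw equals the observed
  obs <- pooled_rho(anchor, mat[1:4, ])$pooled
  deg <- permutation_null(anchor, mat, paste0("G", 1:4), k = 4, m = 25,
                          seed = 1)
  expect_true(all(abs(deg$draws - obs) < 1e-12))
  expect_equal(empirical_p(obs, deg), 1)
  # null mean lies within the span of single-gene pooled values
  rho <- n1$per_gene_rho
  expect_gte(n1$null_mean, min(rho))
  expect_lte(n1$null_mean, max(rho))
})

test_that("empirical p follows (n+1)/(m+1) exactly", {
  expect_equal(empirical_p(0.9, rep(0, 10000)), 1 / 10001)
  expect_equal(empirical_p(0.1, rep(0.5, 12)), 1)          # n = m
  # rank-only dependence: any observed below every draw gives n = m
  expect_equal(empirical_p(-100, c(0.1, 0.2, 0.3)), 1)
  expect_equal(empirical_p(0.2, c(0.1, 0.2, 0.3)), 3 / 4)  # ties count (>=)
  draws <- stats::runif(99)
  p <- empirical_p(0.5, draws)
  expect_gt(p, 0); expect_lte(p, 1)
})

test_that("median split honors the tie rule on both parities", {
  expect_equal(median_split(c(a = 1, b = 2, c = 3))$low, c("a", "b"))
  expect_equal(median_split(c(a = 1, b = 2, c = 3))$high, "c")
  all_eq <- median_split(c(a = 2, b = 2, c = 2))
  expect_equal(all_eq$low, c("a", "b", "c"))
  expect_equal(all_eq$high, character(0))
  even <- median_split(c(a = 1, b = 2, c = 3, d = 4))
  expect_equal(even$median, 2.5)
  expect_equal(even$low, c("a", "b"))
  hi <- median_split(c(a = 1, b = 2, c = 3), ties = "high")
  expect_equal(hi$low, "a")
  expect_equal(hi$high, c("b", "c"))
})

test_that("coregulation_test composes the statistic, null and p-value", {
  st <- primary_study(77)
  tum <- st$samples$sample[st$samples$group == "tumor"]
  mat <- st$counts$counts[, tum]
  targets <- setdiff(hr_module_genes_default(), c("BRCA1", "BRCA2"))
  pool <- intersect(upregulated_panel_genes(), rownames(mat))
  ct <- coregulation_test(mat, "BRCA1", targets, pool = pool, m = 500,
                          seed = 5)
  expect_s3_class(ct, "coreg_test")
  expect_true(abs(ct$observed) < 1)
  expect_equal(ct$p_empirical, (ct$n_as_high + 1) / (ct$m + 1))
  expect_gt(ct$p_empirical, 0); expect_lte(ct$p_empirical, 1)
  # under the default latent module the co-regulation stands out
  expect_lt(ct$p_empirical, 0.05)
  expect_gt(ct$observed, ct$null_mean)
  # k = pool size makes every draw the observed value: P = 1
  ct1 <- coregulation_test(mat, "BRCA1", targets, pool = targets,
                           k = length(targets), m = 50, seed = 6)
  expect_equal(ct1$p_empirical, 1)
  expect_error(coregulation_test(mat, "BRCA1", c("BRCA1", targets), pool),
               "anchor must not be in the target set")
})
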