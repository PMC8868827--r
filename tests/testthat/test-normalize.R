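test_that("background adjustment subtracts the negative-control mean and clamps", {
  m <- matrix(c(15, 8, 400, 100, 90, 8, 12,
                20, 30, 400, 100, 90, 0, 0), ncol = 2,
              dimnames = list(NULL, c("S1", "S2")))
  cm <- toy_count_matrix(m)
  adj <- background_adjust(cm)
  # S1 negatives {8, 12}: mean 10; 15 -> 5, 8 -> 0 (clamped)
  expect_equal(unname(adj$counts[c("G1", "G2"), "S1"]), c(5, 0))
  # S2 negatives all zero: unchanged
  expect_equal(adj$counts[, "S2"], cm$counts[, "S2"])
  # controls untouched, output never negative
  expect_equal(adj$counts["NEG_A", ], cm$counts["NEG_A", ])
  expect_true(all(adj$counts >= 0))
  expect_equal(unname(attr(adj, "background")), c(10, 0))
  # no negative controls -> explicit error
  keep <- setdiff(rownames(cm$counts), c("NEG_A", "NEG_B"))
  expect_error(background_adjust(subset_counts(cm, genes = keep)),
               "negative")
})

test_that("positive-control scaling uses geometric means and flags outliers", {
  m <- matrix(c(10, 20, 50, 50, 200, 0, 0,
                10, 20, 50, 200, 800, 0, 0), ncol = 2,
              dimnames = list(NULL, c("S1", "S2")))
  cm <- toy_count_matrix(m)
  res <- positive_control_normalize(cm)
  # geometric means 100 and 400; grand mean 250 -> factors 2.5 and 0.625
  expect_equal(res$factors$pos_factor, c(2.5, 0.625))
  expect_equal(unname(res$matrix$counts["G1", ]), c(25, 6.25))
  expect_false(any(res$factors$pos_flag))
  # identical profiles -> all factors 1, matrix unchanged
  m2 <- m; m2[4:5, 2] <- m[4:5, 1]
  same <- positive_control_normalize(toy_count_matrix(m2))
  expect_equal(same$factors$pos_factor, c(1, 1))
  expect_equal(same$matrix$counts, m2, ignore_attr = TRUE)
  # a factor outside [0.3, 3] flags its sample (S1 here: grand mean
  # 2050 over geomeans {100, 4000} gives factor 20.5)
  m3 <- m; m3[4:5, 2] <- c(2000, 8000)
  flags <- positive_control_normalize(toy_count_matrix(m3))$factors$pos_flag
  expect_equal(flags, c(TRUE, FALSE))
  # zero positive-control count is an error
  m4 <- m; m4[4, 1] <- 0
  expect_error(positive_control_normalize(toy_count_matrix(m4)),
               "geometric mean undefined")
})

test_that("housekeeping normalization equalizes input exactly", {
  m <- matrix(c(30, 60, 200, 100, 100, 0, 0,
                40, 10, 100, 100, 100, 0, 0), ncol = 2,
              dimnames = list(NULL, c("S1", "S2")))
  cm <- toy_count_matrix(m)
  res <- housekeeping_normalize(cm)
  # housekeeping means 200 and 100 -> factors 0.75 and 1.5
  expect_equal(res$factors$hk_factor, c(0.75, 1.5))
  hk <- res$matrix$counts["HK1", ]
  expect_equal(unname(hk[1]), unname(hk[2]))
  # scaling one sample by k cancels in x/hk; only the global grand-mean
  # factor (shared by every sample) changes
  m2 <- m; m2[1:3, 2] <- m[1:3, 2] * 7
  res2 <- housekeeping_normalize(toy_count_matrix(m2))
  endo <- c("G1", "G2")
  ratio <- res2$matrix$counts[endo, ] / res$matrix$counts[endo, ]
  expect_equal(max(ratio) / min(ratio), 1, tolerance = 1e-12)
  # zero housekeeping mean identifies the sample
  m3 <- m; m3[3, 2] <- 0
  expect_error(housekeeping_normalize(toy_count_matrix(m3)), "S2")
})

test_that("exclusion handles empty, missing and total lists", {
  st <- primary_study(3)
  expect_identical(apply_exclusions(st$counts, character()), st$counts)
  out <- apply_exclusions(st$counts, tagset_exclusions())
  expect_equal(attr(out, "n_endogenous_retained"), 168L)
  expect_warning(apply_exclusions(st$counts, c("BRCA1", "NOPE")), "NOPE")
  empty <- suppressWarnings(
    apply_exclusions(st$counts, rownames(st$counts$counts)))
  expect_equal(nrow(empty$counts), 0L)
  expect_equal(ncol(empty$counts), 49L)
})

test_that("replicate averaging collapses groups to arithmetic means", {
  m <- matrix(c(100, 10, 200, 100, 100, 0, 0,
                200, 20, 200, 100, 100, 0, 0,
                50, 30, 200, 100, 100, 0, 0), ncol = 3,
              dimnames = list(NULL, c("S1", "S1r", "S2")))
  cm <- toy_count_matrix(m)
  sheet <- data.frame(sample = c("S1", "S1r", "S2"),
                      replicate_of = c(NA, "S1", NA))
  avg <- average_replicates(cm, sheet)
  expect_equal(colnames(avg$counts), c("S1", "S2"))
  expect_equal(unname(avg$counts["G1", ]), c(150, 50))
  # identical runs collapse to either run
  m2 <- m; m2[, 2] <- m[, 1]
  expect_equal(average_replicates(toy_count_matrix(m2), sheet)$counts[, "S1"],
               cm$counts[, "S1"])
  # three-way group {90, 100, 110} -> 100
  m3 <- cbind(m, m[, 1]); colnames(m3) <- c("S1", "S1r", "S2", "S1rr")
  m3[1, ] <- c(90, 100, 30, 110)
  sheet3 <- data.frame(sample = colnames(m3),
                       replicate_of = c(NA, "S1", NA, "S1"))
  expect_equal(unname(average_replicates(toy_count_matrix(m3),
                                         sheet3)$counts["G1", "S1"]), 100)
  # dangling replicate_of reference
  bad <- data.frame(sample = c("S1", "S1r", "S2"),
                    replicate_of = c(NA, "GHOST", NA))
  expect_error(average_replicates(cm, bad), "GHOST")
})

test_that("the normalization chain recovers lane-free signal and is idempotent", {
  st <- simulate_nanostring_study(study_config(seed = 17))
  nm <- normalize_counts(st$counts, samples = st$samples,
                         exclude = tagset_exclusions())
  expect_equal(ncol(nm$matrix$counts), 49L)
  # per-sample housekeeping means equal across samples (by construction)
  hk <- colMeans(nm$matrix$counts[probe_genes(nm$matrix, "housekeeping"), ])
  expect_lt(diff(range(hk)) / mean(hk), 0.02)  # replicate averaging perturbs slightly
  # normalized values track the lane-factor-free true means
  endo <- probe_genes(nm$matrix, "endogenous")
  prim <- st$samples$sample[is.na(st$samples$replicate_of)]
  lane <- st$truth$efficiency[prim] * st$truth$input[prim]
  truth <- sweep(st$truth$mu[endo, prim], 2, lane, `/`)
  expect_gt(stats::cor(as.vector(nm$matrix$counts[endo, prim]),
                       as.vector(truth)), 0.95)
  # factors recomputed on already-normalized output are all 1
  renorm <- housekeeping_normalize(nm$matrix)
  expect_equal(renorm$factors$hk_factor, rep(1, 49), tolerance = 1e-12)
})
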