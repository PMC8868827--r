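test_that("study generation is deterministic under a fixed seed", {
  a <- simulate_nanostring_study(study_config(seed = 11))
  b <- simulate_nanostring_study(study_config(seed = 11))
  c <- simulate_nanostring_study(study_config(seed = 12))
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$counts$counts, c$counts$counts))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_nanostring_study(study_config(seed = 1)))
  invisible(simulate_droplet_well(ddpcr_sim_config(50, seed = 2)))
  invisible(simulate_transcript_fixtures(seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("study shape matches the configured cohort and panel", {
  st <- simulate_nanostring_study(study_config(seed = 2))
  expect_equal(dim(st$counts), c(180L + 12L + 6L + 8L, 49L + 2L))
  expect_equal(sum(st$samples$group == "fallopian_tube" &
                     is.na(st$samples$replicate_of)), 11L)
  expect_equal(sum(st$samples$group == "tumor" &
                     is.na(st$samples$replicate_of)), 38L)
  expect_equal(sum(!is.na(st$samples$replicate_of)), 2L)
  expect_true(all(st$counts$counts == round(st$counts$counts)))
  expect_true(all(st$counts$counts >= 0))
  # replicate lanes redraw Poisson counts from the same lane means
  rep_rows <- st$samples[!is.na(st$samples$replicate_of), ]
  expect_equal(st$truth$mu[, rep_rows$sample],
               st$truth$mu[, rep_rows$replicate_of],
               ignore_attr = TRUE)
  # negative controls are background-only Poisson draws
  neg <- st$counts$counts[probe_genes(st$counts, "negative"), ]
  expect_lt(abs(mean(neg) - 10), 1)
  expect_error(simulate_nanostring_study(
    study_config(hr_module_genes = "NOT_A_GENE")), "not in the generated panel")
})

test_that("no latent factor and no tumor effect give null correlation structure", {
  # normalized counts: the per-lane efficiency/input factors shared by
  # all genes are removed, leaving no source of module correlation
  st <- simulate_nanostring_study(
    study_config(seed = 21, latent_sd = 0, tumor_upshift = 1))
  nm <- normalize_counts(st$counts, samples = st$samples)
  m <- nm$matrix$counts[hr_module_genes_default(), ]
  cc <- stats::cor(t(m), method = "spearman")
  expect_lt(abs(stats::median(cc[upper.tri(cc)])), 0.2)
})

test_that("latent factor induces the closed-form module correlation", {
  # one-factor log-normal model: corr = latent_sd^2/(latent_sd^2+noise_sd^2);
  # defaults target ~0.6.  Large-n check without lane factors first:
  cfg <- study_config(seed = 31, n_tumor = 2000, lane_sd = 0, input_sd = 0,
                      tumor_upshift = 1)
  target <- cfg$latent_sd^2 / (cfg$latent_sd^2 + cfg$noise_sd^2)
  st <- simulate_nanostring_study(cfg)
  sam <- st$samples$sample[is.na(st$samples$replicate_of)]
  m <- st$counts$counts[hr_module_genes_default(), sam]
  cc <- stats::cor(t(m), method = "spearman")
  expect_lt(abs(mean(cc[upper.tri(cc)]) - target), 0.08)

  # under full default conditions, mean pairwise rho near 0.6 over 20 seeds
  obs <- vapply(1:20, function(s) {
    st <- simulate_nanostring_study(study_config(seed = 100 + s))
    tum <- st$samples$sample[st$samples$group == "tumor" &
                               is.na(st$samples$replicate_of)]
    m <- st$counts$counts[hr_module_genes_default(), tum]
    cc <- stats::cor(t(m), method = "spearman")
    mean(cc[upper.tri(cc)])
  }, numeric(1))
  expect_lt(abs(mean(obs) - 0.6), 0.15)
})

test_that("droplet wells follow the Poisson occupancy law", {
  expect_equal(simulate_droplet_well(
    ddpcr_sim_config(0, n_droplets = 10000, seed = 1))$n_positive, 0L)
  sat <- simulate_droplet_well(
    ddpcr_sim_config(1e6, droplet_volume = 0.001, n_droplets = 5000, seed = 1))
  expect_equal(sat$n_positive, sat$n_droplets)
  # closed-form binomial mean/SD at c = 50 copies/uL
  w <- simulate_droplet_well(
    ddpcr_sim_config(50, droplet_volume = 0.001, n_droplets = 20000, seed = 8))
  p <- 1 - exp(-0.05)
  expect_lt(abs(w$n_positive - 20000 * p), 4 * sqrt(20000 * p * (1 - p)))
  # law of large numbers: occupancy fraction converges to 1 - exp(-cV)
  fracs <- vapply(c(2e3, 2e4, 2e5), function(n)
    simulate_droplet_well(ddpcr_sim_config(200, n_droplets = n,
                                           seed = 4))$n_positive / n,
    numeric(1))
  expect_lt(abs(fracs[3] - (1 - exp(-0.2))), 0.005)
  # duplex table keeps droplet totals in the observed plate range
  plate <- simulate_duplex_wells(
    data.frame(well = c("A01", "A02"), target_fam = "BRCA1",
               target_hex = "GUSB", conc_fam = c(10, 30), conc_hex = 50),
    seed = 3)
  expect_true(all(plate$n_droplets >= 5549 & plate$n_droplets <= 19264))
  expect_identical(plate, simulate_duplex_wells(
    data.frame(well = c("A01", "A02"), target_fam = "BRCA1",
               target_hex = "GUSB", conc_fam = c(10, 30), conc_hex = 50),
    seed = 3))
})

test_that("transcript fixtures cover the rule boundaries deterministically", {
  fx <- simulate_transcript_fixtures(seed = 4)
  expect_identical(fx, simulate_transcript_fixtures(seed = 4))
  expect_true(all(c("ptc_last_exon", "two_exon", "junction_below",
                    "junction_above", "start_proximal", "start_distal",
                    "frameshift_mid_cds", "missense",
                    "inframe_exon_skip") %in% names(fx)))
  # frameshift fixture really creates a stop in the shifted frame
  loc <- locate_ptc(fx$frameshift_mid_cds$transcript,
                    fx$frameshift_mid_cds$variant)
  expect_false(is.na(loc$ptc))
  stop_codon <- substr(loc$transcript$seq, loc$ptc, loc$ptc + 2L)
  expect_true(stop_codon %in% c("TAA", "TAG", "TGA"))
  expect_equal((loc$ptc - loc$transcript$cds_start) %% 3L, 0L)
})
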