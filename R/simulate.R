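#' Default co-regulated HR module genes
#'
#' BRCA1, BRCA2 and the twelve other homologous-recombination genes
#' whose expression tracks BRCA1/2 across tumors.  These fourteen genes
#' share the latent factor in [simulate_nanostring_study()].
#'
#' @return Character vector of 14 gene symbols.
#' @export
hr_module_genes_default <- function() {
  c("BRCA1", "BRCA2",
    "BRIP1", "BLM", "FANCD2", "FANCG", "FANCI", "GEN1", "RAD51",
    "RAD54L", "UBE2T", "USP1", "XRCC2", "XRCC3")
}

#' TagSet probe exclusion list
#'
#' The twelve panel genes dropped from analysis because one reagent lot
#' of their TagSets produced abnormally low counts.
#'
#' @return Character vector of 12 gene symbols.
#' @export
tagset_exclusions <- function() {
  c("ERCC1", "ERCC2", "ERCC3", "ERCC4", "ERCC5", "ERCC6", "ERCC8",
    "EXO1", "FAN1", "FANCA", "FANCB", "FANCC")
}

# Curated endogenous panel names, ordered so that small panels retain
# the HR module first, then the remaining differentially expressed
# genes, the TagSet-excluded genes, and generic padding.
panel_gene_names <- function(n_endogenous, n_housekeeping) {
  up_rest <- c("BCL2L1", "CASP8", "MYD88", "APEX2", "FEN1", "NEIL3",
               "PARP1", "SMUG1", "UNG", "PCNA", "AURKA", "BUB1B",
               "CDKN2A", "KRAS", "RAD21", "RM12", "SUMO3", "H2AFX",
               "CHEK1", "CHEK2", "DNA2", "POLQ", "POLD1", "POLD4",
               "POLE2", "MAD2L2", "POLR2D", "POLR2H", "HLTF", "MSH2",
               "RFC4", "PRKDC", "RAD18")
  down <- c("AKT3", "BCL2", "NFKB2", "PIK3R1", "NEIL1", "NEIL2", "OGG1",
            "ABL1", "CCND2", "CDKN1A", "EGFR", "TIPIN", "RAD51B", "WRN",
            "ALKBH3", "CRY1", "POLK", "REV1", "POLI", "MSH3", "LIG4",
            "XPA", "PTEN")
  curated <- c(hr_module_genes_default(), up_rest, down, tagset_exclusions())
  endo <- if (n_endogenous <= length(curated)) curated[seq_len(n_endogenous)]
          else c(curated, sprintf("DDR%03d", seq_len(n_endogenous - length(curated))))
  hk_named <- c("GUSB", "POLR1E", "NUBP1", "SF3FA3", "COG7")
  hk <- if (n_housekeeping <= length(hk_named)) hk_named[seq_len(n_housekeeping)]
        else c(hk_named, sprintf("HK%02d", seq_len(n_housekeeping - length(hk_named)) + length(hk_named)))
  list(endogenous = endo, housekeeping = hk)
}

panel_pathways <- function(genes) {
  hr <- "Homologous Recombination and Fanconi Anemia"
  map <- c(
    BRCA1 = hr, BRCA2 = hr, BRIP1 = hr, BLM = hr, FANCD2 = hr,
    FANCG = hr, FANCI = hr, GEN1 = hr, RAD51 = hr, RAD54L = hr,
    UBE2T = hr, USP1 = hr, XRCC2 = hr, XRCC3 = hr, RAD51B = hr,
    WRN = hr, FAN1 = hr, FANCA = hr, FANCB = hr, FANCC = hr,
    BCL2L1 = "Apoptosis", CASP8 = "Apoptosis", MYD88 = "Apoptosis",
    AKT3 = "Apoptosis", BCL2 = "Apoptosis", NFKB2 = "Apoptosis",
    PIK3R1 = "Apoptosis",
    APEX2 = "Base excision repair", FEN1 = "Base excision repair",
    NEIL3 = "Base excision repair", PARP1 = "Base excision repair",
    SMUG1 = "Base excision repair", UNG = "Base excision repair",
    NEIL1 = "Base excision repair", NEIL2 = "Base excision repair",
    OGG1 = "Base excision repair",
    PCNA = "Base excision repair—Translesion Synthesis—Cell Cycle and Signaling",
    AURKA = "Cell Cycle and Signaling", BUB1B = "Cell Cycle and Signaling",
    CDKN2A = "Cell Cycle and Signaling", KRAS = "Cell Cycle and Signaling",
    RAD21 = "Cell Cycle and Signaling", RM12 = "Cell Cycle and Signaling",
    SUMO3 = "Cell Cycle and Signaling", ABL1 = "Cell Cycle and Signaling",
    CCND2 = "Cell Cycle and Signaling", CDKN1A = "Cell Cycle and Signaling",
    EGFR = "Cell Cycle and Signaling",
    H2AFX = "Checkpoint Activation", TIPIN = "Checkpoint Activation",
    CHEK1 = "Checkpoint Activation—Cell Cycle and Signaling",
    CHEK2 = "Checkpoint Activation—Cell Cycle and Signaling",
    DNA2 = "Independent Repair Enzymes/Polymerases",
    POLQ = "Independent Repair Enzymes/Polymerases",
    ALKBH3 = "Independent Repair Enzymes/Polymerases",
    CRY1 = "Independent Repair Enzymes/Polymerases",
    POLK = "Independent Repair Enzymes/Polymerases",
    REV1 = "Independent Repair Enzymes/Polymerases",
    POLD1 = "Independent Repair Enzymes/Polymerases–Base excision repair",
    POLD4 = "Independent Repair Enzymes/Polymerases–Base excision repair",
    POLE2 = "Independent Repair Enzymes/Polymerases–Base excision repair",
    MAD2L2 = "Independent Repair Enzymes/Polymerases—Cell Cycle and Signaling",
    POLR2D = "Independent Repair Enzymes/Polymerases–Nucleotide Excision Repair",
    POLR2H = "Independent Repair Enzymes/Polymerases–Nucleotide Excision Repair",
    HLTF = "Independent Repair Enzymes/Polymerases–Translesion Synthesis",
    POLI = "Independent Repair Enzymes/Polymerases–Translesion Synthesis",
    MSH2 = "Mismatch Repair", MSH3 = "Mismatch Repair",
    EXO1 = "Mismatch Repair",
    RFC4 = "Mismatch Repair–Translesion Synthesis",
    PRKDC = "Non-homologous End Joining—Cell Cycle and Signaling",
    LIG4 = "Non-homologous End Joining",
    RAD18 = "Translesion Synthesis",
    XPA = "Nucleotide Excision Repair",
    PTEN = "Nucleotide Excision Repair—Apoptosis",
    ERCC1 = "Nucleotide Excision Repair", ERCC2 = "Nucleotide Excision Repair",
    ERCC3 = "Nucleotide Excision Repair", ERCC4 = "Nucleotide Excision Repair",
    ERCC5 = "Nucleotide Excision Repair", ERCC6 = "Nucleotide Excision Repair",
    ERCC8 = "Nucleotide Excision Repair")
  out <- unname(map[genes])
  generic <- c("Cell Cycle and Signaling", "Base excision repair",
               "Nucleotide Excision Repair", "Mismatch Repair",
               "Apoptosis", "Translesion Synthesis")
  pad <- is.na(out)
  out[pad] <- generic[(seq_len(sum(pad)) - 1L) %% length(generic) + 1L]
  out
}

#' Configuration for a synthetic nCounter-style study
#'
#' Defines the cohort shape and statistical structure of a simulated
#' expression panel study: 11 normal fallopian-tube and 38 tumor
#' samples, 180 endogenous probes, 12 housekeeping probes, and the
#' positive/negative spike-in controls, with a latent factor shared by
#' the designated HR module genes and a multiplicative tumor effect on
#' the designated upregulated genes.
#'
#' The latent factor acts on the log scale: for module genes the
#' log-mean gains a shared per-sample term with standard deviation
#' `latent_sd`, while every endogenous gene has independent log-normal
#' noise of standard deviation `noise_sd`.  The model (log-scale)
#' pairwise correlation between two module genes is therefore
#' `latent_sd^2 / (latent_sd^2 + noise_sd^2)`.  The default
#' `noise_sd = 0.25` reflects the biological dispersion implied by
#' normal-tissue counts of roughly 185 +/- 45 and 86 +/- 29 once the
#' Poisson component is removed, and `latent_sd = 0.306` then puts the
#' module correlation near 0.6, the regime of the pooled Spearman
#' correlations observed between BRCA1/2 and the other upregulated HR
#' genes.
#'
#' @param n_normal,n_tumor sample counts for the fallopian-tube and
#'   tumor groups.
#' @param n_endogenous,n_housekeeping,n_pos_controls,n_neg_controls
#'   probe counts per class.
#' @param hr_module_genes genes sharing the latent co-regulation
#'   factor; must be a subset of the generated endogenous genes.
#' @param upregulated_genes endogenous genes whose tumor-group mean is
#'   multiplied by `tumor_upshift`; default is the 46 endogenous genes
#'   upregulated in tumors in the packaged differential-expression
#'   table (see [read_table1()]).
#' @param latent_sd standard deviation of the shared latent factor on
#'   the log scale (>= 0).
#' @param noise_sd per-gene log-scale biological noise (>= 0).
#' @param tumor_upshift multiplicative tumor-group effect applied to
#'   `upregulated_genes` (> 0; 1 disables it).
#' @param background_mean Poisson mean of the negative-control probes;
#'   the same ambient background is added to every probe's lane mean.
#' @param lane_sd log-scale standard deviation of the per-lane binding
#'   efficiency factor (affects all probes; corrected by the positive
#'   controls).
#' @param input_sd log-scale standard deviation of the per-lane RNA
#'   input factor (affects endogenous and housekeeping probes;
#'   corrected by the housekeeping genes).
#' @param seed integer RNG seed; the same seed reproduces the study
#'   byte-for-byte.
#' @return A validated list of class `study_config`.
#' @export
study_config <- function(n_normal = 11, n_tumor = 38, n_endogenous = 180,
                         n_housekeeping = 12, n_pos_controls = 6,
                         n_neg_controls = 8,
                         hr_module_genes = hr_module_genes_default(),
                         upregulated_genes = NULL,
                         latent_sd = 0.306, noise_sd = 0.25,
                         tumor_upshift = 2, background_mean = 10,
                         lane_sd = 0.15, input_sd = 0.25, seed = 1L) {
  counts <- c(n_normal = n_normal, n_tumor = n_tumor,
              n_endogenous = n_endogenous, n_housekeeping = n_housekeeping,
              n_pos_controls = n_pos_controls, n_neg_controls = n_neg_controls)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all sample/probe counts must be positive integers")
  if (latent_sd < 0 || noise_sd < 0)
    stop("latent_sd and noise_sd must be >= 0")
  if (tumor_upshift <= 0) stop("tumor_upshift must be > 0")
  if (background_mean < 0) stop("background_mean must be >= 0")
  panel <- panel_gene_names(n_endogenous, n_housekeeping)
  if (is.null(upregulated_genes)) {
    tab1 <- read_table1()
    upregulated_genes <- intersect(tab1$gene[tab1$direction == "up"],
                                   panel$endogenous)
  }
  bad <- setdiff(hr_module_genes, panel$endogenous)
  if (length(bad) > 0L)
    stop("hr_module_genes not in the generated panel: ",
         paste(bad, collapse = ", "))
  bad <- setdiff(upregulated_genes, panel$endogenous)
  if (length(bad) > 0L)
    stop("upregulated_genes not in the generated panel: ",
         paste(bad, collapse = ", "))
  structure(list(n_normal = as.integer(n_normal),
                 n_tumor = as.integer(n_tumor),
                 n_endogenous = as.integer(n_endogenous),
                 n_housekeeping = as.integer(n_housekeeping),
                 n_pos_controls = as.integer(n_pos_controls),
                 n_neg_controls = as.integer(n_neg_controls),
                 hr_module_genes = hr_module_genes,
                 upregulated_genes = upregulated_genes,
                 latent_sd = latent_sd, noise_sd = noise_sd,
                 tumor_upshift = tumor_upshift,
                 background_mean = background_mean,
                 lane_sd = lane_sd, input_sd = input_sd,
                 seed = as.integer(seed), panel = panel),
            class = "study_config")
}

#' Simulate an nCounter-style expression study
#'
#' Draws a complete synthetic study under a [study_config()]: Poisson
#' counts with log-normal means built from a per-lane binding
#' efficiency, a per-lane RNA input factor, per-gene baselines, a
#' latent factor shared by the HR module genes, and a multiplicative
#' tumor effect on the designated upregulated genes.  Positive controls
#' follow a fixed 4-fold titration series scaled by the lane
#' efficiency; negative controls are pure Poisson background; the same
#' background is added to every probe.  Two extra lanes re-run the
#' first normal and the first tumor sample as technical replicates
#' (independent Poisson redraws of the same lane means).
#'
#' @param config a [study_config()].
#' @return A list with elements `counts` (a [count_matrix] including
#'   control probes and replicate lanes), `samples` (data.frame with
#'   columns `sample`, `group` in \{`tumor`, `fallopian_tube`\},
#'   `replicate_of`), and `truth` (the latent generating quantities:
#'   signal mean matrix `mu` for endogenous+housekeeping probes, lane
#'   `efficiency` and `input` factors, latent factor values).
#' @export
simulate_nanostring_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  rng <- local_rng(config$seed)
  panel <- config$panel
  pos_genes <- paste0("POS_", LETTERS[seq_len(config$n_pos_controls)])
  neg_genes <- paste0("NEG_", LETTERS[seq_len(config$n_neg_controls)])

  n_base <- config$n_normal + config$n_tumor
  base_samples <- c(sprintf("FT%02d", seq_len(config$n_normal)),
                    sprintf("T%02d", seq_len(config$n_tumor)))
  group <- rep(c("fallopian_tube", "tumor"),
               c(config$n_normal, config$n_tumor))
  # technical replicate lanes: re-runs of the first lane of each group
  rep_src <- c(base_samples[1L], base_samples[config$n_normal + 1L])
  samples <- c(base_samples, paste0(rep_src, "_rep2"))
  sample_sheet <- data.frame(
    sample = samples,
    group = c(group, group[match(rep_src, base_samples)]),
    replicate_of = c(rep(NA_character_, n_base), rep_src),
    stringsAsFactors = FALSE)

  n_lanes <- length(samples)
  efficiency <- exp(stats::rnorm(n_lanes, 0, config$lane_sd))
  input <- exp(stats::rnorm(n_lanes, 0, config$input_sd))
  latent <- stats::rnorm(n_lanes, 0, 1)
  # replicate lanes are independent Poisson redraws of the same lane
  # means: they inherit every latent quantity from their source lane
  src_idx <- match(rep_src, base_samples)
  efficiency[n_base + seq_along(src_idx)] <- efficiency[src_idx]
  input[n_base + seq_along(src_idx)] <- input[src_idx]
  latent[n_base + seq_along(src_idx)] <- latent[src_idx]

  endo_base <- exp(stats::rnorm(config$n_endogenous, log(200), 0.8))
  names(endo_base) <- panel$endogenous
  hk_base <- exp(stats::rnorm(config$n_housekeeping, log(400), 0.5))
  names(hk_base) <- panel$housekeeping

  is_tumor_lane <- sample_sheet$group == "tumor"
  in_module <- panel$endogenous %in% config$hr_module_genes
  is_up <- panel$endogenous %in% config$upregulated_genes

  log_mu <- matrix(log(endo_base), config$n_endogenous, n_lanes)
  log_mu <- log_mu + rep(log(efficiency * input), each = config$n_endogenous)
  log_mu[is_up, is_tumor_lane] <- log_mu[is_up, is_tumor_lane] +
    log(config$tumor_upshift)
  log_mu[in_module, ] <- log_mu[in_module, ] +
    rep(config$latent_sd * latent, each = sum(in_module))
  noise <- matrix(stats::rnorm(config$n_endogenous * n_base, 0,
                               config$noise_sd),
                  config$n_endogenous, n_base)
  noise <- cbind(noise, noise[, src_idx, drop = FALSE])  # replicates share biology
  mu_endo <- exp(log_mu + noise)
  dimnames(mu_endo) <- list(panel$endogenous, samples)

  mu_hk <- outer(hk_base, efficiency * input)
  dimnames(mu_hk) <- list(panel$housekeeping, samples)

  pos_series <- 8192 / 4^(seq_len(config$n_pos_controls) - 1L)
  mu_pos <- outer(pos_series, efficiency)

  bg <- config$background_mean
  counts <- rbind(
    matrix(stats::rpois(length(mu_endo), mu_endo + bg),
           nrow(mu_endo), dimnames = list(panel$endogenous, samples)),
    matrix(stats::rpois(length(mu_hk), mu_hk + bg),
           nrow(mu_hk), dimnames = list(panel$housekeeping, samples)),
    matrix(stats::rpois(length(mu_pos), mu_pos + bg),
           nrow(mu_pos), dimnames = list(pos_genes, samples)),
    matrix(stats::rpois(config$n_neg_controls * n_lanes, bg),
           config$n_neg_controls, dimnames = list(neg_genes, samples)))

  ann <- data.frame(
    gene = c(panel$endogenous, panel$housekeeping, pos_genes, neg_genes),
    probe_class = rep(c("endogenous", "housekeeping", "positive", "negative"),
                      c(config$n_endogenous, config$n_housekeeping,
                        config$n_pos_controls, config$n_neg_controls)),
    pathway = c(panel_pathways(panel$endogenous),
                rep("Housekeeping", config$n_housekeeping),
                rep(NA_character_, config$n_pos_controls + config$n_neg_controls)),
    stringsAsFactors = FALSE)

  rng()  # restore caller RNG state
  list(counts = count_matrix(counts, ann),
       samples = sample_sheet,
       truth = list(mu = rbind(mu_endo, mu_hk),
                    efficiency = stats::setNames(efficiency, samples),
                    input = stats::setNames(input, samples),
                    latent = stats::setNames(latent, samples)))
}

#' Write the three study tables as TSV
#'
#' Writes `counts.tsv` (genes x samples), `annotation.tsv` (gene,
#' probe_class, pathway) and `samples.tsv` (sample, group,
#' replicate_of) under `dir`.
#'
#' @param study result of [simulate_nanostring_study()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_study_tables <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("counts.tsv", "annotation.tsv", "samples.tsv"))
  write_count_tables(study$counts, paths[1], paths[2])
  utils::write.table(study$samples, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Configuration for a simulated ddPCR well
#'
#' @param true_concentration target concentration in copies/microliter
#'   (>= 0).
#' @param droplet_volume droplet volume in microliters (> 0); the
#'   package's reporting convention is 0.001 uL (1 nL) per droplet, so
#'   an occupancy of 0.05 copies/droplet corresponds to 50 copies/uL.
#' @param n_droplets number of accepted droplets; if `NULL`, drawn
#'   uniformly from 5549..19264, the range of read droplets per well
#'   the assay produces in practice.
#' @param seed integer RNG seed.
#' @return A validated list of class `ddpcr_sim_config`.
#' @export
ddpcr_sim_config <- function(true_concentration, droplet_volume = 0.001,
                             n_droplets = NULL, seed = 1L) {
  if (true_concentration < 0) stop("true_concentration must be >= 0")
  if (droplet_volume <= 0) stop("droplet_volume must be > 0")
  if (!is.null(n_droplets) &&
      (n_droplets < 1 || n_droplets != round(n_droplets)))
    stop("n_droplets must be a positive integer")
  structure(list(true_concentration = true_concentration,
                 droplet_volume = droplet_volume,
                 n_droplets = n_droplets, seed = as.integer(seed)),
            class = "ddpcr_sim_config")
}

#' Simulate one ddPCR well (single channel)
#'
#' Each droplet is independently positive with probability
#' `1 - exp(-concentration * droplet_volume)`, the Poisson occupancy
#' model underlying digital PCR.
#'
#' @param config a [ddpcr_sim_config()].
#' @return A list with `n_droplets`, `n_positive`, and the
#'   `droplet_volume` used.
#' @export
simulate_droplet_well <- function(config) {
  stopifnot(inherits(config, "ddpcr_sim_config"))
  rng <- local_rng(config$seed)
  n <- config$n_droplets
  if (is.null(n)) n <- sample(5549:19264, 1L)
  p <- 1 - exp(-config$true_concentration * config$droplet_volume)
  pos <- stats::rbinom(1L, n, p)
  rng()
  list(n_droplets = as.integer(n), n_positive = as.integer(pos),
       droplet_volume = config$droplet_volume)
}

#' Simulate a plate of duplex ddPCR wells
#'
#' One row per well in the duplex export schema: a FAM-labeled target
#' and a HEX-labeled reference measured on the same droplets.
#'
#' @param targets data.frame with columns `well`, `target_fam`,
#'   `target_hex`, `conc_fam`, `conc_hex` (copies/uL), and optionally
#'   `no_rt` (logical).
#' @param droplet_volume droplet volume in microliters.
#' @param seed integer RNG seed.
#' @return data.frame with columns `well`, `target_fam`, `target_hex`,
#'   `n_droplets`, `n_pos_fam`, `n_pos_hex`, `no_rt`.
#' @export
simulate_duplex_wells <- function(targets, droplet_volume = 0.001,
                                  seed = 1L) {
  req <- c("well", "target_fam", "target_hex", "conc_fam", "conc_hex")
  if (!all(req %in% names(targets)))
    stop("`targets` needs columns: ", paste(req, collapse = ", "))
  rng <- local_rng(seed)
  n <- sample(5549:19264, nrow(targets), replace = TRUE)
  p_fam <- 1 - exp(-targets$conc_fam * droplet_volume)
  p_hex <- 1 - exp(-targets$conc_hex * droplet_volume)
  out <- data.frame(
    well = targets$well,
    target_fam = targets$target_fam,
    target_hex = targets$target_hex,
    n_droplets = n,
    n_pos_fam = stats::rbinom(nrow(targets), n, p_fam),
    n_pos_hex = stats::rbinom(nrow(targets), n, p_hex),
    no_rt = if ("no_rt" %in% names(targets)) targets$no_rt else FALSE,
    stringsAsFactors = FALSE)
  rng()
  out
}

#' Write droplet wells as CSV
#'
#' @param wells data.frame as returned by [simulate_duplex_wells()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_droplet_wells <- function(wells, path) {
  utils::write.csv(wells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Seed an isolated RNG stream; the returned function restores the
# caller's .Random.seed.  One stream per generator call, never the
# global state.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
  }
}
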