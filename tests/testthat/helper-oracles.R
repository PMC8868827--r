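# Independent oracles and fixture builders used across test files.

# Exhaustive complete-linkage agglomeration: singletons merged by the
# minimum pairwise distance (lowest-index pair on ties), cluster
# distance = maximum over member pairs.  Returns the merge heights.
brute_complete_linkage <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dij <- max(d[clusters[[i]], clusters[[j]]])
      if (dij < best_d) { best_d <- dij; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Frameshift PTC oracle: apply the indel and translate with
# Biostrings, independent of the package's codon scanner.  Returns the
# transcript coordinate of the first nucleotide of the first stop.
biostrings_ptc <- function(tx, var) {
  s <- Biostrings::DNAString(tx$seq)
  if (var$type == "frameshift_ins") {
    s <- Biostrings::replaceAt(s, IRanges::IRanges(var$position + 1L,
                                                   var$position),
                               var$alt)
  } else if (var$type == "frameshift_del") {
    s <- Biostrings::replaceAt(s, IRanges::IRanges(var$position,
                                                   var$position + var$length - 1L),
                               "")
  }
  n_codons <- (length(s) - tx$cds_start + 1L) %/% 3L
  cds <- Biostrings::subseq(s, tx$cds_start,
                            tx$cds_start + 3L * n_codons - 1L)
  aa <- as.character(Biostrings::translate(cds, no.init.codon = TRUE))
  star <- regexpr("*", aa, fixed = TRUE)
  if (star < 0) return(NA_integer_)
  tx$cds_start + 3L * (as.integer(star) - 1L)
}

# Minimal RCC lane file for one sample.
write_rcc_fixture <- function(path, sample_id, codeclass, name, count) {
  lines <- c("<Header>", "FileVersion,1.7", "</Header>",
             "<Sample_Attributes>", paste0("ID,", sample_id),
             "</Sample_Attributes>",
             "<Code_Summary>", "CodeClass,Name,Count",
             paste(codeclass, name, count, sep = ","),
             "</Code_Summary>")
  writeLines(lines, path)
}

# Small fully-annotated count matrix for normalization tests:
# 2 endogenous, 1 housekeeping, 2 positive, 2 negative probes.
toy_count_matrix <- function(values) {
  genes <- c("G1", "G2", "HK1", "POS_A", "POS_B", "NEG_A", "NEG_B")
  stopifnot(nrow(values) == length(genes))
  rownames(values) <- genes
  ann <- data.frame(gene = genes,
                    probe_class = c("endogenous", "endogenous",
                                    "housekeeping", "positive", "positive",
                                    "negative", "negative"),
                    pathway = c("Apoptosis", "Mismatch Repair",
                                "Housekeeping", NA, NA, NA, NA),
                    stringsAsFactors = FALSE)
  count_matrix(values, ann)
}

# Default-condition synthetic study restricted to primary lanes.
primary_study <- function(seed, ...) {
  st <- simulate_nanostring_study(study_config(seed = seed, ...))
  sheet <- st$samples[is.na(st$samples$replicate_of), ]
  list(counts = subset_counts(st$counts, samples = sheet$sample),
       samples = sheet, full = st)
}

upregulated_panel_genes <- function() {
  tab <- read_table1()
  tab$gene[tab$direction == "up"]
}
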