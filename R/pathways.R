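#' Packaged table of differentially expressed panel genes
#'
#' The transcription of the published list of 72 genes significantly
#' differentially expressed between tumor and fallopian-tube samples
#' (47 upregulated, 25 downregulated), with their pathway labels.  The
#' fixture preserves the printed symbols verbatim, including the
#' combined entry `CHEK1/2` and the symbols `RM12` and `SF3FA3`
#' (apparent typographical variants of RMI2 and SF3A3; they are kept
#' as printed rather than silently corrected).
#'
#' @param expand_combined if `TRUE` (default) combined entries such as
#'   `CHEK1/2` are expanded to one row per gene (`CHEK1`, `CHEK2`).
#' @return data.frame with columns `direction` (`up`/`down`),
#'   `pathway`, `gene`.
#' @export
read_table1 <- function(expand_combined = TRUE) {
  path <- system.file("extdata", "table1_de_genes.tsv", package = "hrcoreg",
                      mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  names(tab)[names(tab) == "entry"] <- "gene"
  if (expand_combined) {
    comb <- grepl("/", tab$gene, fixed = TRUE)
    if (any(comb)) {
      expanded <- do.call(rbind, lapply(which(comb), function(i) {
        genes <- expand_combined_symbol(tab$gene[i])
        data.frame(direction = tab$direction[i], pathway = tab$pathway[i],
                   gene = genes, stringsAsFactors = FALSE)
      }))
      tab <- rbind(tab[!comb, ], expanded)
    }
  }
  rownames(tab) <- NULL
  tab
}

# "CHEK1/2" -> c("CHEK1", "CHEK2"): the text after the slash replaces
# the trailing characters of the stem.
expand_combined_symbol <- function(entry) {
  parts <- strsplit(entry, "/", fixed = TRUE)[[1]]
  stem <- parts[1]
  c(stem, vapply(parts[-1], function(suf) {
    paste0(substr(stem, 1L, nchar(stem) - nchar(suf)), suf)
  }, character(1), USE.NAMES = FALSE))
}

#' Build a gene-to-pathway map
#'
#' Builds a lookup from an annotation table (columns `gene`,
#' `pathway`), applying the convention that the Homologous
#' Recombination and Fanconi Anemia pathways are grouped and referred
#' to jointly as HR genes.
#'
#' @param annotation data.frame with columns `gene` and `pathway`;
#'   defaults to the packaged differential-expression table.
#' @return data.frame of class `pathway_map` with columns `gene`,
#'   `pathway`, `hr` (logical HR-group membership).
#' @export
pathway_map <- function(annotation = read_table1()) {
  if (!all(c("gene", "pathway") %in% names(annotation)))
    stop("annotation needs columns `gene` and `pathway`")
  out <- data.frame(gene = annotation$gene, pathway = annotation$pathway,
                    hr = is_hr_pathway(annotation$pathway),
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("pathway_map", "data.frame")
  out
}

is_hr_pathway <- function(pathway) {
  !is.na(pathway) &
    (grepl("Homologous Recombination", pathway, fixed = TRUE) |
       grepl("Fanconi Anemia", pathway, fixed = TRUE))
}

#' Look up a gene's pathway label and HR-group membership
#'
#' @param gene gene identifier (must be present in the map).
#' @param map a [pathway_map()].
#' @return A list with `gene`, `pathway`, and `hr` (`TRUE` iff the
#'   label belongs to the merged Homologous Recombination / Fanconi
#'   Anemia group).
#' @export
classify_pathway <- function(gene, map = pathway_map()) {
  i <- match(gene, map$gene)
  if (is.na(i)) stop("gene not in pathway map: ", gene)
  list(gene = gene, pathway = map$pathway[i], hr = map$hr[i])
}
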