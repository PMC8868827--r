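#' Read RCC-dialect lane files into a count matrix
#'
#' RCC files are the plain-text per-lane exports of the nCounter
#' digital analyzer.  Each file holds angle-bracketed sections; the
#' `Code_Summary` (or `CodeSummary`) section is a small CSV with columns
#' `CodeClass`, `Name`, `Count`, and the `Sample_Attributes` section
#' carries the sample identifier under `ID`.  One file corresponds to
#' one lane (sample); this reader assembles a set of lanes into a
#' [count_matrix], requiring every lane to report the same probes.
#'
#' Code classes are mapped case-insensitively onto the package's probe
#' classes: `Endogenous` -> endogenous, `Housekeeping` -> housekeeping,
#' `Positive` -> positive, `Negative` -> negative.  Probe names may
#' carry the conventional concentration suffix (e.g. `POS_A(128)`),
#' which is stripped.
#'
#' @param files character vector of RCC file paths.
#' @return A [count_matrix] with `pathway = NA` for all probes (RCC
#'   files carry no pathway labels).
#' @export
read_rcc <- function(files) {
  if (length(files) < 1L) stop("no RCC files given")
  lanes <- lapply(files, read_rcc_one)
  ids <- vapply(lanes, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids))
    stop("duplicate sample IDs across RCC files: ",
         paste(ids[duplicated(ids)], collapse = ", "))
  ref <- lanes[[1]]$table
  mat <- matrix(NA_real_, nrow = nrow(ref), ncol = length(lanes),
                dimnames = list(ref$name, ids))
  for (i in seq_along(lanes)) {
    tab <- lanes[[i]]$table
    if (!identical(tab$name, ref$name))
      stop("RCC file ", files[i], " reports a different probe set")
    mat[, i] <- tab$count
  }
  ann <- data.frame(gene = ref$name, probe_class = ref$class,
                    pathway = NA_character_, stringsAsFactors = FALSE)
  count_matrix(mat, ann)
}

read_rcc_one <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sec <- rcc_section(lines, c("Code_Summary", "CodeSummary"))
  if (is.null(sec)) stop("no Code_Summary section in ", path)
  con <- textConnection(sec)
  on.exit(close(con))
  tab <- utils::read.csv(con, header = TRUE, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if (!all(c("codeclass", "name", "count") %in% names(tab)))
    stop("Code_Summary in ", path,
         " lacks CodeClass,Name,Count columns")
  class_map <- c(endogenous = "endogenous", housekeeping = "housekeeping",
                 positive = "positive", negative = "negative")
  cls <- class_map[tolower(tab$codeclass)]
  if (anyNA(cls))
    stop("unrecognized CodeClass in ", path, ": ",
         paste(unique(tab$codeclass[is.na(cls)]), collapse = ", "))
  name <- sub("\\(.*\\)$", "", tab$name)
  sample_id <- basename(path)
  attrs <- rcc_section(lines, "Sample_Attributes")
  if (!is.null(attrs)) {
    kv <- strsplit(attrs, ",", fixed = TRUE)
    for (pair in kv)
      if (length(pair) >= 2L && pair[1] == "ID") sample_id <- pair[2]
  }
  list(sample_id = sample_id,
       table = data.frame(name = name, class = unname(cls),
                          count = as.numeric(tab$count),
                          stringsAsFactors = FALSE))
}

rcc_section <- function(lines, tags) {
  for (tag in tags) {
    open <- match(paste0("<", tag, ">"), lines)
    close <- match(paste0("</", tag, ">"), lines)
    if (!is.na(open) && !is.na(close) && close > open + 1L)
      return(lines[(open + 1L):(close - 1L)])
  }
  NULL
}
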