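#' Validate a gene-by-sample count table
#'
#' Count tables are tibbles whose first column (`gene_id`) holds unique gene
#' identifiers and whose remaining columns hold non-negative integer counts,
#' one column per sample. Sample metadata is a tibble with one row per sample
#' and columns `sample_id`, `genotype`, `fraction` (one of `"input"`,
#' `"polysome"`, `"none"`), `stage` and `replicate`.
#'
#' @param counts Tibble/data frame: `gene_id` plus one numeric column per sample.
#' @param metadata Optional sample metadata tibble; if supplied, every count
#'   column must have a metadata row and vice versa.
#' @return `counts`, invisibly, after validation.
#' @export
validate_counts <- function(counts, metadata = NULL) {
  if (!is.data.frame(counts) || ncol(counts) < 2) {
    abort("`counts` must be a data frame with a gene_id column and >= 1 sample column.")
  }
  gene_ids <- counts[[1]]
  if (anyDuplicated(gene_ids)) abort("duplicate gene ids in `counts`.")
  m <- counts_matrix(counts)
  if (anyDuplicated(colnames(m))) abort("duplicate sample ids in `counts`.")
  if (anyNA(m)) abort("`counts` contains missing values.")
  if (any(m < 0)) abort("`counts` contains negative values.")
  if (any(abs(m - round(m)) > 1e-8)) abort("`counts` must be integral.")
  if (!is.null(metadata)) {
    if (!all(c("sample_id", "genotype", "fraction") %in% names(metadata))) {
      abort("`metadata` needs columns sample_id, genotype, fraction.")
    }
    missing <- setdiff(colnames(m), metadata$sample_id)
    if (length(missing)) {
      abort(paste0("samples without metadata: ", paste(missing, collapse = ", ")))
    }
    bad <- setdiff(unique(metadata$fraction), c("input", "polysome", "none"))
    if (length(bad)) abort(paste0("unknown fraction labels: ", paste(bad, collapse = ", ")))
  }
  invisible(counts)
}

# counts tibble -> numeric matrix (genes x samples), gene ids as rownames
counts_matrix <- function(counts) {
  m <- as.matrix(counts[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("sample columns of `counts` must be numeric.")
  rownames(m) <- as.character(counts[[1]])
  m
}

# numeric matrix -> counts tibble
matrix_to_counts <- function(m, gene_ids = rownames(m)) {
  out <- as_tibble(as.data.frame(m))
  tibble::add_column(out, gene_id = gene_ids, .before = 1)
}

#' Read a count table from TSV
#'
#' First column is the gene id, the header row carries sample ids.
#'
#' @param path File path.
#' @return Count tibble (see [validate_counts()]).
#' @export
read_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  names(x)[1] <- "gene_id"
  validate_counts(x)
  x
}

#' Read sample metadata from TSV
#'
#' Expects columns `sample_id`, `genotype`, `fraction`, `stage`, `replicate`.
#'
#' @param path File path.
#' @return Metadata tibble.
#' @export
read_sample_metadata <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(sample_id = "c", genotype = "c",
                                          fraction = "c", stage = "c",
                                          .default = readr::col_guess()))
}

#' Write a per-gene test table to TSV
#'
#' @param table Tibble with columns `gene_id`, `log2fc`, `stat`, `pvalue`,
#'   `fdr`, `class` (extra columns are preserved).
#' @param path Output path.
#' @param header_comment Optional character vector written as `#`-prefixed
#'   header lines (used to record classification mode and thresholds).
#' @return `path`, invisibly.
#' @export
write_test_table <- function(table, path, header_comment = NULL) {
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), path)
    readr::write_tsv(table, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(table, path)
  }
  invisible(path)
}
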