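#' Read a per-gene differential-expression table
#'
#' Reads a delimited text file (TSV by default, CSV when the filename ends in
#' `.csv`) with columns `gene`, `effect` and `pvalue`.
#'
#' @param path Path to the file.
#' @return A tibble with columns `gene`, `effect`, `pvalue`.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  de <- reader(path, show_col_types = FALSE, progress = FALSE)
  check_de_table(de, path)
}

#' Read a GMT gene-set collection
#'
#' Parses the standard GMT layout (one set per line: name, description, then
#' tab-separated gene identifiers) into a named list of character vectors.
#'
#' @param path Path to a `.gmt` file.
#' @return A named list; each element is a character vector of gene ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets))) {
    abort(paste0("Duplicate gene-set names in ", path, "."))
  }
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @param description Second GMT column, recycled across sets.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path, description = "na") {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  description <- rep_len(description, length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], description[i], gene_sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a ranked ECI table to TSV
#'
#' @param eci_table Output of [build_eci_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eci_table <- function(eci_table, path) {
  readr::write_tsv(eci_table, path, progress = FALSE)
  invisible(path)
}

#' Write an enrichment result table to TSV
#'
#' Mirrors the usual reporting layout: pathway, FDR, NES, size and the top
#' genes (comma-joined), followed by the raw enrichment score, permutation
#' p-value and direction label.
#'
#' @param result An `ecea_result` from [ecea()] or [gsea_single()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(result, path) {
  out <- dplyr::select(tibble::as_tibble(result),
                       "pathway", "fdr", "nes", "size", "top_genes",
                       "es", "pval", "direction", "enriched")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an expression matrix and its sample-to-group map
#'
#' The matrix file is a TSV whose first column (`gene`) holds gene ids and
#' whose remaining columns are samples; the group map is a two-column TSV
#' (`sample`, `group`) with group labels `treatment` / `control`.
#'
#' @param matrix_path,group_path Paths to the two files.
#' @return A list with `values` (numeric matrix, genes x samples) and
#'   `group` (character vector aligned with the matrix columns).
#' @export
read_expression <- function(matrix_path, group_path) {
  for (p in c(matrix_path, group_path)) {
    if (!file.exists(p)) abort(paste0("File not found: ", p))
  }
  tab <- readr::read_tsv(matrix_path, show_col_types = FALSE, progress = FALSE)
  if (names(tab)[1] != "gene") {
    abort(paste0("First column of ", matrix_path, " must be `gene`."))
  }
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab$gene
  gmap <- readr::read_tsv(group_path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample", "group") %in% names(gmap))) {
    abort(paste0(group_path, " must have columns `sample` and `group`."))
  }
  idx <- match(colnames(values), gmap$sample)
  if (anyNA(idx)) {
    abort("Every matrix column must appear in the sample-to-group map.")
  }
  list(values = values, group = gmap$group[idx])
}

write_expression <- function(values, group, matrix_path, group_path) {
  tab <- tibble::as_tibble(values, rownames = "gene")
  readr::write_tsv(tab, matrix_path, progress = FALSE)
  readr::write_tsv(tibble::tibble(sample = colnames(values), group = group),
                   group_path, progress = FALSE)
  invisible(matrix_path)
}
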