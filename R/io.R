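#' Read a counts directory (Matrix Market triplets plus annotation TSVs)
#'
#' Expects the common genes-by-cells layout: `matrix.mtx` with genes as
#' rows and cells as columns, `genes.tsv` (first column gene id) and
#' `cells.tsv` (tab-separated with header: `cell_id`, `species`, `batch`,
#' `tissue`, and optionally `donor`, `cell_type`). Returns the cells-by-
#' genes orientation used throughout the package.
#'
#' @param dir Directory containing `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return List: `counts` (sparse cells-by-genes `dgCMatrix` with
#'   dimnames), `cells` (tibble), `genes` (character).
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readr::read_tsv(file.path(dir, "genes.tsv"),
                           col_types = readr::cols(.default = "c"))
  cells <- readr::read_tsv(file.path(dir, "cells.tsv"),
                           col_types = readr::cols(.default = "c"))
  if (nrow(genes) != nrow(m) || nrow(cells) != ncol(m)) {
    stop("matrix dimensions do not match genes.tsv/cells.tsv", call. = FALSE)
  }
  counts <- methods::as(Matrix::t(m), "CsparseMatrix")
  dimnames(counts) <- list(cells[[1]], genes[[1]])
  list(counts = counts, cells = cells, genes = genes[[1]])
}

#' Write a counts directory (Matrix Market triplets plus annotation TSVs)
#'
#' Inverse of [read_counts_mtx()]: writes `matrix.mtx` (genes as rows),
#' `genes.tsv` and `cells.tsv` into `dir`.
#'
#' @param counts Cells-by-genes matrix with gene column names.
#' @param cells Cell metadata data frame; first column must be `cell_id`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, cells, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(as_dense_counts(counts)), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble::tibble(gene = colnames(counts)),
                   file.path(dir, "genes.tsv"))
  readr::write_tsv(tibble::as_tibble(cells), file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read a Biomart-style ortholog edge table
#'
#' Tab-separated with header: `gene_a`, `species_a`, `gene_b`, `species_b`,
#' `percent_identity`.
#'
#' @param path TSV path.
#' @return Tibble of edges.
#' @export
read_ortholog_edges <- function(path) {
  edges <- readr::read_tsv(path, col_types = readr::cols(
    gene_a = "c", species_a = "c", gene_b = "c", species_b = "c",
    percent_identity = "d"))
  check_edge_cols(edges)
  tibble::as_tibble(edges)
}

#' Write a one-to-one ortholog table
#'
#' One row per ortholog tuple, one column per species; an empty cell means
#' the tuple has no ortholog in that species.
#'
#' @param table Ortholog table (as from [build_one_to_one()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ortholog_table <- function(table, path) {
  readr::write_tsv(table, path, na = "")
  invisible(path)
}

#' Read per-cell per-species read counts for demultiplexing
#'
#' Tab-separated with header: `cell_id`, `species`, `read_count`.
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_species_counts <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    cell_id = "c", species = "c", read_count = "i"))
}

#' Read a gene-group annotation table
#'
#' Tab-separated with header; requires columns `gene` and `group` (values
#' `XAR`, `XCR`, `AUTOSOME`); extra per-species chromosome columns are kept.
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_gene_groups <- function(path) {
  gg <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (!all(c("gene", "group") %in% names(gg))) {
    stop("gene-group table needs `gene` and `group` columns", call. = FALSE)
  }
  gg
}
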