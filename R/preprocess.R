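#' QC filter configuration
#'
#' Thresholds for species demultiplexing and count-matrix filtering.
#' Defaults: a cell is a species doublet when the second- plus third-largest
#' species read counts exceed 20% of its total; cells need at least 200
#' UMIs; genes must be expressed (count > 0) in at least 50 cells pooled
#' across datasets.
#'
#' @param doublet_fraction Doublet threshold on the non-dominant read share.
#' @param min_cell_umi Minimum UMIs per cell.
#' @param min_cells_per_gene Minimum number of cells expressing a gene.
#' @param mito_genes Mitochondrial gene identifiers (columns dropped before
#'   depth is computed).
#' @param ortholog_genes Genes with cross-species orthologs; `NULL` skips
#'   the ortholog restriction.
#' @return List of class `crossbear_filter_config`.
#' @export
filter_config <- function(doublet_fraction = 0.20, min_cell_umi = 200,
                          min_cells_per_gene = 50,
                          mito_genes = character(0),
                          ortholog_genes = NULL) {
  stopifnot(doublet_fraction > 0, min_cell_umi > 0, min_cells_per_gene > 0)
  structure(list(doublet_fraction = doublet_fraction,
                 min_cell_umi = as.integer(min_cell_umi),
                 min_cells_per_gene = as.integer(min_cells_per_gene),
                 mito_genes = mito_genes,
                 ortholog_genes = ortholog_genes),
            class = "crossbear_filter_config")
}

#' Assign species labels to cells from per-species read counts
#'
#' For each cell the candidate-species read counts are sorted in decreasing
#' order; if the sum of the second- and third-largest counts is strictly
#' greater than `doublet_fraction` of the total, the cell is flagged
#' `DOUBLET`. Otherwise the cell is labelled with the top species
#' (`AMBIGUOUS` when the top count is tied). With two candidate species the
#' third-largest count is zero; with a single species the cell is labelled
#' with that species.
#'
#' @param species_counts Data frame with columns `cell_id`, `species`,
#'   `read_count` (one row per cell/species).
#' @param doublet_fraction Threshold, default 0.20.
#' @return Tibble with one row per cell: `cell_id`, `label`, `total`,
#'   `offtarget_fraction` (second + third largest over total).
#' @export
call_species <- function(species_counts, doublet_fraction = 0.20) {
  sc <- tibble::as_tibble(species_counts)
  need <- setdiff(c("cell_id", "species", "read_count"), names(sc))
  if (length(need) > 0) {
    stop("`species_counts` lacks column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(sc$read_count < 0)) stop("negative read counts", call. = FALSE)
  out <- sc |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      total = sum(.data$read_count),
      label = {
        cnt <- sort(.data$read_count, decreasing = TRUE)
        second_third <- sum(cnt[2:3], na.rm = TRUE)
        tot <- sum(cnt)
        if (tot == 0) {
          NA_character_
        } else if (second_third > doublet_fraction * tot) {
          "DOUBLET"
        } else {
          top <- .data$species[.data$read_count == cnt[1]]
          if (length(top) > 1) "AMBIGUOUS" else top
        }
      },
      offtarget_fraction = {
        cnt <- sort(.data$read_count, decreasing = TRUE)
        if (sum(cnt) == 0) NA_real_ else sum(cnt[2:3], na.rm = TRUE) / sum(cnt)
      },
      .groups = "drop"
    )
  if (anyNA(out$label)) {
    stop("cell(s) with zero reads in every species cannot be assigned: ",
         paste(utils::head(out$cell_id[is.na(out$label)], 5), collapse = ", "),
         call. = FALSE)
  }
  out[, c("cell_id", "label", "total", "offtarget_fraction")]
}

#' Filter a count matrix with the standard QC steps
#'
#' Applies, in order: (1) keep only genes with cross-species orthologs,
#' (2) remove mitochondrial genes (so depth reflects nuclear reads),
#' (3) remove cells with fewer than `min_cell_umi` total UMIs,
#' (4) remove genes expressed (count > 0) in fewer than
#' `min_cells_per_gene` cells. Steps 3 and 4 are repeated until no further
#' row or column is removed, so the result is a fixed point and the filter
#' is idempotent.
#'
#' @param counts Cells-by-genes count matrix with gene column names.
#' @param cells Cell metadata data frame (same row order); filtered in step
#'   with the matrix.
#' @param config A [filter_config()].
#' @return List with `counts`, `cells` and `report` (tibble: `step`,
#'   `removed`, `axis`, `remaining_cells`, `remaining_genes`).
#' @export
filter_matrix <- function(counts, cells, config = filter_config()) {
  x <- as_dense_counts(counts)
  if (ncol(x) > 0 && is.null(colnames(x))) {
    stop("`counts` needs gene column names", call. = FALSE)
  }
  report <- list()
  note <- function(step, removed, axis) {
    report[[length(report) + 1]] <<- tibble::tibble(
      step = step, removed = as.integer(removed), axis = axis,
      remaining_cells = nrow(x), remaining_genes = ncol(x))
  }

  if (!is.null(config$ortholog_genes)) {
    keep <- colnames(x) %in% config$ortholog_genes
    x <- x[, keep, drop = FALSE]
    note("ortholog_genes", sum(!keep), "gene")
  } else {
    note("ortholog_genes", 0L, "gene")
  }

  keep <- !(colnames(x) %in% config$mito_genes)
  x <- x[, keep, drop = FALSE]
  note("mitochondrial", sum(!keep), "gene")

  removed_cells <- 0L; removed_genes <- 0L
  repeat {
    ck <- rowSums(x) >= config$min_cell_umi
    removed_cells <- removed_cells + sum(!ck)
    x <- x[ck, , drop = FALSE]
    cells <- cells[ck, , drop = FALSE]
    gk <- colSums(x > 0) >= config$min_cells_per_gene
    removed_genes <- removed_genes + sum(!gk)
    x <- x[, gk, drop = FALSE]
    if (all(ck) && all(gk)) break
  }
  note("min_cell_umi", removed_cells, "cell")
  note("min_cells_per_gene", removed_genes, "gene")

  if (nrow(x) == 0 || ncol(x) == 0) {
    warning("filtering removed everything along one axis")
  }
  list(counts = x, cells = cells, report = dplyr::bind_rows(report))
}
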