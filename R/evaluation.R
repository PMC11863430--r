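#' Pseudobulk profile of a set of cells
#'
#' Each cell's counts are scaled to a fixed library size (sequencing-depth
#' normalization), then averaged across cells. The log variant applies
#' `log2(x + 1)` to the averaged profile, matching how fold changes are
#' computed downstream.
#'
#' @param counts Cells-by-genes matrix (raw counts, or already
#'   depth-normalized predictions — rows are rescaled to `scale_to` either
#'   way).
#' @param scale_to Common library size, default 10,000.
#' @param log Apply `log2(x + 1)` to the mean profile.
#' @return Named numeric vector over genes.
#' @export
pseudobulk <- function(counts, scale_to = 1e4, log = FALSE) {
  x <- as_dense_counts(counts)
  if (nrow(x) == 0) stop("pseudobulk of zero cells", call. = FALSE)
  d <- rowSums(x)
  if (any(d == 0)) {
    warning(sum(d == 0), " zero-depth cell(s) excluded from pseudobulk")
    x <- x[d > 0, , drop = FALSE]
    d <- d[d > 0]
    if (nrow(x) == 0) stop("all cells have zero depth", call. = FALSE)
  }
  prof <- colMeans(x / d * scale_to)
  if (log) prof <- log2(prof + 1)
  prof
}

#' Donor baseline: mean correlation between donor pseudobulks
#'
#' A "cheating" upper-bound baseline: the mean Pearson correlation of
#' depth-normalized, log-transformed pseudobulk profiles over all unordered
#' donor pairs within the held-out cells.
#'
#' @param counts Cells-by-genes counts of the held-out cell type.
#' @param donors Donor label per cell.
#' @param scale_to Library size for normalization.
#' @return Mean pairwise Pearson correlation, or `NA` (with a message) when
#'   fewer than two donors are present.
#' @export
donor_baseline <- function(counts, donors, scale_to = 1e4) {
  x <- as_dense_counts(counts)
  dl <- unique(as.character(donors))
  if (length(dl) < 2) {
    message("donor baseline undefined with fewer than two donors")
    return(NA_real_)
  }
  profs <- vapply(dl, function(dn) {
    pseudobulk(x[donors == dn, , drop = FALSE], scale_to, log = TRUE)
  }, numeric(ncol(x)))
  prs <- utils::combn(length(dl), 2)
  mean(apply(prs, 2, function(ij) stats::cor(profs[, ij[1]], profs[, ij[2]])))
}

#' Species baseline: assume expression does not change between species
#'
#' Translates the source-species cells to target gene identifiers through
#' the one-to-one ortholog table and correlates their log pseudobulk with
#' the target-species truth over the shared gene set.
#'
#' @param source_counts Cells-by-genes counts in the source species (source
#'   gene names as columns).
#' @param target_counts Cells-by-genes counts of the held-out cells in the
#'   target species.
#' @param table One-to-one ortholog table (columns per species).
#' @param source,target Species column names in `table`.
#' @param scale_to Library size.
#' @return Pearson correlation.
#' @export
species_baseline <- function(source_counts, target_counts, table,
                             source, target, scale_to = 1e4) {
  tr <- translate_matrix(source_counts, table, source, target)
  shared <- intersect(colnames(tr), colnames(target_counts))
  if (length(shared) == 0) stop("no shared genes after translation", call. = FALSE)
  ps <- pseudobulk(tr[, shared, drop = FALSE], scale_to, log = TRUE)
  pt <- pseudobulk(as_dense_counts(target_counts)[, shared, drop = FALSE],
                   scale_to, log = TRUE)
  stats::cor(ps, pt)
}

#' Cell-type baseline: predict with the nearest profiled cell type
#'
#' Finds the cell type whose source-species log pseudobulk is closest (in
#' Euclidean distance) to the held-out type's source profile, then
#' correlates that neighbor's target-species profile with the held-out
#' truth.
#'
#' @param source_counts,source_types Source-species counts and per-cell
#'   cell-type labels (must include the held-out type).
#' @param target_counts,target_types Target-species counts and labels;
#'   must contain the held-out type (the truth) and at least one other type
#'   shared with the source.
#' @param heldout_type The held-out cell type label.
#' @param scale_to Library size.
#' @return List with `correlation`, `neighbor` (chosen cell type) and
#'   `distance`.
#' @export
celltype_baseline <- function(source_counts, source_types,
                              target_counts, target_types,
                              heldout_type, scale_to = 1e4) {
  if (!heldout_type %in% source_types) {
    stop("held-out type absent from the source species", call. = FALSE)
  }
  sp <- function(counts, types, ty) {
    pseudobulk(as_dense_counts(counts)[types == ty, , drop = FALSE],
               scale_to, log = TRUE)
  }
  held_src <- sp(source_counts, source_types, heldout_type)
  candidates <- intersect(setdiff(unique(source_types), heldout_type),
                          unique(target_types))
  if (length(candidates) == 0) {
    stop("no candidate neighbor cell types shared with the target species",
         call. = FALSE)
  }
  dists <- vapply(candidates, function(ty) {
    sqrt(sum((sp(source_counts, source_types, ty) - held_src)^2))
  }, 0)
  neighbor <- candidates[which.min(dists)]
  truth <- sp(target_counts, target_types, heldout_type)
  neigh_t <- sp(target_counts, target_types, neighbor)
  list(correlation = stats::cor(neigh_t, truth),
       neighbor = neighbor, distance = min(dists))
}

#' Relative prediction error per gene
#'
#' `|pred - target| / |source - target|` per gene on pseudobulk profiles: a
#' value of 0 means the prediction equals the target-species truth, 1 means
#' it is no better than carrying the source-species value over. Genes with
#' a zero denominator (no cross-species difference) are excluded and
#' counted.
#'
#' @param pred,target_ori,source_ori Pseudobulk profiles (named numeric
#'   vectors over a shared gene set): the prediction, the target-species
#'   truth, and the ortholog-translated source-species profile.
#' @return Tibble with columns `gene`, `relative_error`; the number of
#'   zero-denominator genes is in attribute `n_zero_denominator`.
#' @export
relative_prediction_error <- function(pred, target_ori, source_ori) {
  n <- length(target_ori)
  if (length(pred) != n || length(source_ori) != n) {
    stop("profiles must share one gene set", call. = FALSE)
  }
  genes <- names(target_ori)
  if (is.null(genes)) genes <- paste0("g", seq_len(n))
  den <- abs(source_ori - target_ori)
  keep <- den > 0
  out <- tibble::tibble(
    gene = genes[keep],
    relative_error = unname(abs(pred[keep] - target_ori[keep]) / den[keep])
  )
  attr(out, "n_zero_denominator") <- sum(!keep)
  out
}

#' Correlation of predicted and observed disease log2 fold changes
#'
#' Scales each pseudobulk profile to a library size of 10,000, adds 1, and
#' computes `log2FC = log2((AD + 1) / (WT + 1))` per gene for the predicted
#' and the observed profile pair; returns the Pearson correlation between
#' the two log2FC vectors. This measures how well a model trained on a
#' disease-model species recovers the direction and magnitude of
#' disease-versus-control expression changes in the target species.
#'
#' @param pred_case,pred_control Predicted pseudobulk profiles
#'   (disease and control).
#' @param true_case,true_control Observed pseudobulk profiles.
#' @param scale_to Library size, default 10,000.
#' @return Pearson correlation, or `NA` (with a message) when either log2FC
#'   vector is constant.
#' @export
ad_log2fc_eval <- function(pred_case, pred_control, true_case, true_control,
                           scale_to = 1e4) {
  l2 <- function(a, b) {
    a <- a / sum(a) * scale_to
    b <- b / sum(b) * scale_to
    log2((a + 1) / (b + 1))
  }
  fc_pred <- l2(pred_case, pred_control)
  fc_true <- l2(true_case, true_control)
  if (stats::sd(fc_pred) == 0 || stats::sd(fc_true) == 0) {
    message("degenerate (constant) log2FC vector; correlation undefined")
    return(NA_real_)
  }
  stats::cor(fc_pred, fc_true)
}

#' Evaluate a cross-species prediction against held-out truth
#'
#' Bundles the prediction correlation with the three baselines into one
#' tidy row. The prediction correlation compares the log pseudobulk of the
#' predicted (depth-normalized) profiles with the held-out truth;
#' `indiv_prediction` is the mean correlation of the prediction against
#' each donor's own pseudobulk, mirroring the donor baseline's pairing.
#'
#' @param pred Predicted cells-by-genes profiles
#'   (from [predict_cross_species()]), columns matching the target gene
#'   vocabulary.
#' @param target_counts Held-out target-species counts.
#' @param target_donors Optional donor labels for the held-out cells.
#' @param source_counts Source-species counts of the corresponding cell
#'   type (for the species baseline); `NULL` skips it.
#' @param table,source,target Ortholog table and species names (species
#'   baseline).
#' @param scale_to Library size.
#' @param log Correlate log pseudobulk (default) or linear.
#' @return One-row tibble: `prediction_cor`, `donor_baseline`,
#'   `species_baseline`, `indiv_prediction`.
#' @export
evaluate_prediction <- function(pred, target_counts, target_donors = NULL,
                                source_counts = NULL, table = NULL,
                                source = NULL, target = NULL,
                                scale_to = 1e4, log = TRUE) {
  shared <- intersect(colnames(pred), colnames(target_counts))
  if (length(shared) == 0) stop("no shared genes", call. = FALSE)
  pp <- pseudobulk(pred[, shared, drop = FALSE], scale_to, log = log)
  tp <- pseudobulk(as_dense_counts(target_counts)[, shared, drop = FALSE],
                   scale_to, log = log)
  pred_cor <- stats::cor(pp, tp)

  donor_b <- NA_real_; indiv <- NA_real_
  if (!is.null(target_donors)) {
    donor_b <- donor_baseline(target_counts[, shared, drop = FALSE],
                              target_donors, scale_to)
    dl <- unique(as.character(target_donors))
    indiv <- mean(vapply(dl, function(dn) {
      dp <- pseudobulk(as_dense_counts(target_counts)[target_donors == dn,
                                                      shared, drop = FALSE],
                       scale_to, log = log)
      stats::cor(pp, dp)
    }, 0))
  }
  species_b <- NA_real_
  if (!is.null(source_counts) && !is.null(table)) {
    species_b <- species_baseline(source_counts, target_counts, table,
                                  source, target, scale_to)
  }
  tibble::tibble(prediction_cor = pred_cor, donor_baseline = donor_b,
                 species_baseline = species_b, indiv_prediction = indiv)
}
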