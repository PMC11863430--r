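#' Local inverse Simpson index (LISI) of label mixing
#'
#' For each cell, neighbors in the embedding are weighted by a Gaussian
#' kernel whose bandwidth is calibrated so that the weight distribution has
#' the requested perplexity (entropy `log(perplexity)`), as in t-SNE. The
#' per-cell score is the inverse Simpson index of the label probabilities
#' under those weights: the effective number of label categories in the
#' cell's neighborhood. Scores range from 1 (neighborhood pure) to the
#' number of label levels (perfectly mixed); a higher species-LISI means
#' better cross-species alignment.
#'
#' @param embeddings Cells-by-dimensions numeric matrix (e.g. posterior-mean
#'   cell factors, or log-normalized expression).
#' @param labels Vector of categorical labels, one per cell.
#' @param perplexity Effective neighborhood size; must be smaller than the
#'   number of cells.
#' @return Tibble with columns `cell` (row name or index), `label`, `lisi`.
#' @export
compute_lisi <- function(embeddings, labels, perplexity = 30) {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  if (n < 2) stop("LISI needs at least two cells", call. = FALSE)
  if (length(labels) != n) stop("one label per cell required", call. = FALSE)
  if (perplexity >= n) stop("`perplexity` must be below the number of cells",
                            call. = FALSE)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  li <- match(labels, lev)
  k <- min(n - 1L, max(3L, ceiling(3 * perplexity)))
  d2 <- as.matrix(stats::dist(embeddings))^2
  target <- log(perplexity)

  lisi <- vapply(seq_len(n), function(i) {
    di <- d2[i, -i]
    nb <- order(di)[seq_len(k)]
    dnb <- di[nb]
    w <- calibrate_weights(dnb, target)
    pl <- vapply(seq_along(lev), function(l) sum(w[li[-i][nb] == l]), 0)
    1 / sum(pl^2)
  }, 0)

  tibble::tibble(
    cell = if (is.null(rownames(embeddings))) as.character(seq_len(n)) else rownames(embeddings),
    label = labels,
    lisi = lisi
  )
}

# Binary search the Gaussian precision so that the neighbor weight entropy
# hits `target = log(perplexity)`; returns normalized weights.
calibrate_weights <- function(d2, target, iters = 60, tol = 1e-7) {
  d2 <- d2 - min(d2)
  beta <- 1
  lo <- 0; hi <- Inf
  for (it in seq_len(iters)) {
    w <- exp(-beta * d2)
    sw <- sum(w)
    h <- log(sw) + beta * sum(d2 * w) / sw
    if (abs(h - target) < tol) break
    if (h > target) { # too flat: increase precision
      lo <- beta
      beta <- if (is.finite(hi)) (lo + hi) / 2 else beta * 2
    } else {
      hi <- beta
      beta <- (lo + hi) / 2
    }
  }
  w / sum(w)
}

#' Median species-mixing LISI of a fitted model's validation embeddings
#'
#' Convenience wrapper: encodes the validation cells of a fit and returns
#' the median LISI over species labels.
#'
#' @param object A `crossbear_fit`.
#' @param counts,cells The training inputs (the function subsets the
#'   validation split stored in the fit).
#' @param perplexity Passed to [compute_lisi()].
#' @return A single number in `[1, n_species]`.
#' @export
validation_lisi <- function(object, counts, cells, perplexity = 30) {
  idx <- object$validation_idx
  emb <- encode_cells(object, as_dense_counts(counts)[idx, , drop = FALSE],
                      cells[idx, , drop = FALSE])$mean
  stats::median(compute_lisi(emb, cells$species[idx],
                             perplexity = min(perplexity, length(idx) - 1))$lisi)
}
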