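#' Hyperparameter grid search with LISI-based selection
#'
#' Trains one model per grid point (discriminator off/on crossed with
#' bottleneck dimensions) and selects the model whose validation-set cell
#' embeddings have the largest mean LISI over species labels, i.e. the best
#' cross-species mixing. Ties are broken by grid order: discriminator
#' `FALSE` before `TRUE`, then ascending latent dimension.
#'
#' @param counts Cells-by-genes count matrix.
#' @param cells Cell metadata (`species`, `batch`, `tissue`).
#' @param latent_dims Bottleneck dimensions to try.
#' @param use_discriminator Logical values to try.
#' @param config Base [crossbear_config()]; each grid point overrides
#'   `latent_dim` and `use_discriminator`.
#' @param perplexity LISI perplexity.
#' @return List with `best` (the selected `crossbear_fit`), `log` (tibble
#'   with one row per grid point: `use_discriminator`, `latent_dim`,
#'   `mean_lisi`, `best_val`, `selected`).
#' @export
select_hyperparameters <- function(counts, cells,
                                   latent_dims = c(25, 50, 100),
                                   use_discriminator = c(FALSE, TRUE),
                                   config = crossbear_config(),
                                   perplexity = 30) {
  grid <- expand.grid(latent_dim = sort(latent_dims),
                      use_discriminator = use_discriminator[order(use_discriminator)])
  grid <- grid[order(grid$use_discriminator, grid$latent_dim), , drop = FALSE]
  if (nrow(grid) == 0) stop("empty hyperparameter grid", call. = FALSE)

  fits <- vector("list", nrow(grid))
  score <- rep(NA_real_, nrow(grid))
  best_val <- rep(NA_real_, nrow(grid))
  errs <- character(0)
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    cfg$latent_dim <- as.integer(grid$latent_dim[i])
    cfg$use_discriminator <- grid$use_discriminator[i]
    fit <- tryCatch(crossbear_fit(counts, cells, cfg),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      errs <- c(errs, conditionMessage(fit))
      next
    }
    fits[[i]] <- fit
    best_val[i] <- fit$best_val
    idx <- fit$validation_idx
    emb <- encode_cells(fit, as_dense_counts(counts)[idx, , drop = FALSE],
                        cells[idx, , drop = FALSE])$mean
    score[i] <- mean(compute_lisi(emb, cells$species[idx],
                                  perplexity = min(perplexity, length(idx) - 1))$lisi)
  }
  if (all(is.na(score))) {
    stop("all grid points failed to train: ", paste(errs, collapse = "; "),
         call. = FALSE)
  }
  sel <- which(score == max(score, na.rm = TRUE))[1]
  list(
    best = fits[[sel]],
    log = tibble::tibble(
      use_discriminator = grid$use_discriminator,
      latent_dim = as.integer(grid$latent_dim),
      mean_lisi = score,
      best_val = best_val,
      selected = seq_len(nrow(grid)) == sel
    )
  )
}
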