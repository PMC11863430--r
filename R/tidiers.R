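#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-epoch training log of a fitted model
#'
#' @param x A `crossbear_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: reconstruction, KL, cVAE,
#'   discriminator and validation losses.
#' @export
tidy.crossbear_fit <- function(x, ...) {
  x$log
}

#' One-row summary of a fitted model
#'
#' @param x A `crossbear_fit`.
#' @param ... Unused.
#' @return Tibble: `latent_dim`, `use_discriminator`, `epochs`,
#'   `best_epoch`, `best_val_cvae`, `n_species`.
#' @export
glance.crossbear_fit <- function(x, ...) {
  tibble::tibble(
    latent_dim = x$config$latent_dim,
    use_discriminator = x$config$use_discriminator,
    epochs = nrow(x$log),
    best_epoch = x$best_epoch,
    best_val_cvae = x$best_val,
    n_species = length(x$design$species_levels)
  )
}

#' Training-curve plot for a fitted model
#'
#' Validation and training cVAE loss per epoch, with the selected epoch
#' marked.
#'
#' @param object A `crossbear_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crossbear_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$log[, c("epoch", "train_cvae", "val_cvae")],
    -"epoch", names_to = "series", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(x = "epoch", y = "cVAE loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Boxplot of cross-species fold changes by gene group
#'
#' @param fold_changes Tibble with `median_log2fc` and `group` columns (as
#'   from [xcu_report()]).
#' @param ref_lines Horizontal reference lines; defaults mark no change (0)
#'   and the halved-copy-number expectation (-1).
#' @return A ggplot object.
#' @export
plot_xcu <- function(fold_changes, ref_lines = c(0, -1)) {
  ggplot2::ggplot(fold_changes,
                  ggplot2::aes(.data$group, .data$median_log2fc)) +
    ggplot2::geom_hline(yintercept = ref_lines, linetype = 3) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "median log2 fold change") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
#' @keywords internal
"_PACKAGE"
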