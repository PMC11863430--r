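#' Model configuration for the cross-species conditional VAE
#'
#' Collects the architecture and training hyperparameters. The encoder and
#' decoder each have two hidden layers (ReLU); the bottleneck (cell factor)
#' dimension and the adversarial species discriminator are the two
#' hyperparameters explored by [select_hyperparameters()].
#'
#' @param latent_dim Dimension of the cell-factor bottleneck; the grid search
#'   considers 25, 50 and 100.
#' @param use_discriminator Train a single-layer adversarial species
#'   discriminator and make the encoder/decoder fool it.
#' @param hidden_width Width of the two hidden layers.
#' @param learning_rate Adam learning rate.
#' @param minibatch_size Cells per gradient step.
#' @param max_epochs Hard cap on training epochs.
#' @param patience_epochs Stop when the validation cVAE loss has not improved
#'   for this many consecutive epochs.
#' @param validation_fraction Fraction of cells held out for validation.
#' @param validation_cap Maximum number of validation cells.
#' @param adversarial_weight Weight on `-loss_dis` in the encoder/decoder
#'   objective when the discriminator is enabled.
#' @param encode_log1p Apply `log1p` to counts before the encoder (the
#'   likelihood always evaluates raw counts).
#' @param seed Integer seed controlling initialization, the validation split,
#'   minibatch order and reparameterization noise.
#' @return A list of class `crossbear_config`.
#' @export
crossbear_config <- function(latent_dim = 25,
                             use_discriminator = FALSE,
                             hidden_width = 128,
                             learning_rate = 1e-3,
                             minibatch_size = 128,
                             max_epochs = 500L,
                             patience_epochs = 45L,
                             validation_fraction = 0.10,
                             validation_cap = 20000L,
                             adversarial_weight = 1,
                             encode_log1p = TRUE,
                             seed = 1L) {
  stopifnot(latent_dim > 0, hidden_width > 0, learning_rate > 0,
            minibatch_size > 0, patience_epochs >= 1,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(
    latent_dim = as.integer(latent_dim),
    use_discriminator = isTRUE(use_discriminator),
    hidden_layers = 2L,
    hidden_width = as.integer(hidden_width),
    learning_rate = learning_rate,
    minibatch_size = as.integer(minibatch_size),
    max_epochs = as.integer(max_epochs),
    patience_epochs = as.integer(patience_epochs),
    validation_fraction = validation_fraction,
    validation_cap = as.integer(validation_cap),
    adversarial_weight = adversarial_weight,
    encode_log1p = isTRUE(encode_log1p),
    seed = as.integer(seed)
  ), class = "crossbear_config")
}

#' Factor design: ordered label sets and one-hot encoding
#'
#' Registers the species, batch and tissue levels observed in the cell
#' metadata (or supplied explicitly) and provides the indicator encoding used
#' to condition the encoder and decoder. A factor with a single level
#' contributes a constant indicator column.
#'
#' @param cells Data frame with columns `species`, `batch`, `tissue`.
#' @param species_levels,batch_levels,tissue_levels Optional explicit level
#'   orderings; defaults to the sorted unique values.
#' @return A list of class `crossbear_design`.
#' @export
factor_design <- function(cells, species_levels = NULL, batch_levels = NULL,
                          tissue_levels = NULL) {
  need <- setdiff(c("species", "batch", "tissue"), names(cells))
  if (length(need) > 0) {
    stop("`cells` lacks column(s): ", paste(need, collapse = ", "), call. = FALSE)
  }
  lv <- function(x, given) if (is.null(given)) sort(unique(as.character(x))) else as.character(given)
  structure(list(
    species_levels = lv(cells$species, species_levels),
    batch_levels = lv(cells$batch, batch_levels),
    tissue_levels = lv(cells$tissue, tissue_levels)
  ), class = "crossbear_design")
}

one_hot <- function(x, levels, what) {
  x <- as.character(x)
  bad <- setdiff(unique(x), levels)
  if (length(bad) > 0) {
    stop("unknown ", what, " label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  m <- matrix(0, nrow = length(x), ncol = length(levels),
              dimnames = list(NULL, levels))
  m[cbind(seq_along(x), match(x, levels))] <- 1
  m
}

# cells x (nS + nB + nT) indicator matrix
encode_factors <- function(design, cells) {
  cbind(one_hot(cells$species, design$species_levels, "species"),
        one_hot(cells$batch, design$batch_levels, "batch"),
        one_hot(cells$tissue, design$tissue_levels, "tissue"))
}

relu <- function(x) (x + abs(x)) / 2

add_bias <- function(m, b) m + rep(b, each = nrow(m))

row_logsumexp <- function(o) {
  mx <- o[cbind(seq_len(nrow(o)), max.col(o, ties.method = "first"))]
  mx + log(rowSums(exp(o - mx)))
}

glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

init_params <- function(d_in, n_fac, n_genes, cfg, n_species) {
  H <- cfg$hidden_width
  L <- cfg$latent_dim
  par <- list(
    enc = list(W1 = glorot(d_in, H), b1 = numeric(H),
               W2 = glorot(H, H), b2 = numeric(H),
               Wm = glorot(H, L), bm = numeric(L),
               Wv = glorot(H, L), bv = numeric(L)),
    dec = list(U1 = glorot(L + n_fac, H), c1 = numeric(H),
               U2 = glorot(H, H), c2 = numeric(H),
               Uo = glorot(H, n_genes), co = numeric(n_genes),
               Up = glorot(H, n_genes), cp = numeric(n_genes)),
    log_r = numeric(n_genes)
  )
  if (cfg$use_discriminator) {
    par$dis <- list(Wd = glorot(cfg$latent_dim, n_species),
                    bd = numeric(n_species))
  }
  par
}

# Encoder forward pass. x is a dense cells x genes count matrix, f the
# indicator matrix. Returns activations needed for backprop.
enc_forward <- function(par, x, f, cfg) {
  u <- cbind(if (cfg$encode_log1p) log1p(x) else x, f)
  a1 <- add_bias(u %*% par$enc$W1, par$enc$b1); h1 <- relu(a1)
  a2 <- add_bias(h1 %*% par$enc$W2, par$enc$b2); h2 <- relu(a2)
  zmu <- add_bias(h2 %*% par$enc$Wm, par$enc$bm)
  zlv_raw <- add_bias(h2 %*% par$enc$Wv, par$enc$bv)
  zlv <- pmin(pmax(zlv_raw, -10), 10)
  list(u = u, a1 = a1, h1 = h1, a2 = a2, h2 = h2,
       zmu = zmu, zlv = zlv, zlv_clip = (zlv_raw < -10) | (zlv_raw > 10))
}

# Decoder forward pass from latent z with indicator f; d is per-cell depth.
dec_forward <- function(par, z, f, d) {
  v <- cbind(z, f)
  b1 <- add_bias(v %*% par$dec$U1, par$dec$c1); g1 <- relu(b1)
  b2 <- add_bias(g1 %*% par$dec$U2, par$dec$c2); g2 <- relu(b2)
  o <- add_bias(g2 %*% par$dec$Uo, par$dec$co)
  logmu <- o - row_logsumexp(o)
  p <- add_bias(g2 %*% par$dec$Up, par$dec$cp)
  list(v = v, b1 = b1, g1 = g1, b2 = b2, g2 = g2,
       logmu = logmu, mu = exp(logmu), p = p, d = d)
}

# Stable matrix ZINB negative log-likelihood per cell given the decoder
# state; logm = log(d) + logmu keeps small means exact.
zinb_nll_rows <- function(x, dec, log_r) {
  n <- nrow(x); G <- ncol(x)
  r <- matrix(exp(log_r), n, G, byrow = TRUE)
  logm <- log(dec$d) + dec$logmu
  m <- exp(logm)
  lrm <- log(r + m)
  lognb <- lgamma(x + r) - lgamma(r) - lgamma(x + 1) +
    r * (log(r) - lrm) + x * (logm - lrm)
  p <- dec$p
  ll <- matrix(0, n, G)
  pos <- x > 0
  sp <- softplus(p)
  ll[pos] <- (-sp + lognb)[pos]
  ll[!pos] <- (logaddexp(p, lognb) - sp)[!pos]
  rowSums(-ll)
}

adam_init <- function(par) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(m = zero(par), v = zero(par), t = 0)
}

adam_step <- function(par, grad, state, lr, which = names(par),
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in names(p)) {
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      return(out)
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (nm in which) {
    if (is.null(grad[[nm]])) next
    r <- upd(par[[nm]], grad[[nm]], state$m[[nm]], state$v[[nm]])
    par[[nm]] <- r$p; state$m[[nm]] <- r$m; state$v[[nm]] <- r$v
  }
  list(par = par, state = state)
}

# One minibatch: forward, loss pieces, gradients for encoder/decoder.
# If dis_w > 0 the adversarial term -dis_w * CE(D(z), s) is added to the
# objective (discriminator parameters held fixed).
cvae_backward <- function(par, x, f, d, cfg, eps_mat, y_species = NULL,
                          dis_w = 0) {
  n <- nrow(x); G <- ncol(x); L <- cfg$latent_dim
  enc <- enc_forward(par, x, f, cfg)
  z <- enc$zmu + exp(0.5 * enc$zlv) * eps_mat
  dec <- dec_forward(par, z, f, d)

  r <- exp(par$log_r)
  nll <- zinb_nll_rows(x, dec, par$log_r)
  kl <- kl_gaussian(enc$zmu, enc$zlv)
  loss_rec <- mean(nll); loss_kl <- mean(kl)

  # --- decoder gradients ---
  m <- exp(log(dec$d) + dec$logmu)
  gr <- zinb_nll_grad(x, m, r, dec$p)
  gL <- gr$dm * dec$d / n
  s_row <- rowSums(gL * dec$mu)
  grad_o <- dec$mu * (gL - s_row)
  grad_p <- gr$dp / n
  grad_logr <- gr$dlogr / n

  dgrad <- list(
    Uo = crossprod(dec$g2, grad_o), co = colSums(grad_o),
    Up = crossprod(dec$g2, grad_p), cp = colSums(grad_p)
  )
  grad_g2 <- tcrossprod(grad_o, par$dec$Uo) + tcrossprod(grad_p, par$dec$Up)
  grad_b2 <- grad_g2 * (dec$b2 > 0)
  dgrad$U2 <- crossprod(dec$g1, grad_b2); dgrad$c2 <- colSums(grad_b2)
  grad_g1 <- tcrossprod(grad_b2, par$dec$U2)
  grad_b1 <- grad_g1 * (dec$b1 > 0)
  dgrad$U1 <- crossprod(dec$v, grad_b1); dgrad$c1 <- colSums(grad_b1)
  grad_v <- tcrossprod(grad_b1, par$dec$U1)
  grad_z <- grad_v[, seq_len(L), drop = FALSE]

  loss_dis <- NA_real_
  if (dis_w > 0) {
    dl <- add_bias(z %*% par$dis$Wd, par$dis$bd)
    lse <- row_logsumexp(dl)
    prob <- exp(dl - lse)
    loss_dis <- mean(lse - dl[cbind(seq_len(n), y_species)])
    yd <- prob
    yd[cbind(seq_len(n), y_species)] <- yd[cbind(seq_len(n), y_species)] - 1
    # encoder maximizes CE: gradient of -dis_w * CE wrt z
    grad_z <- grad_z - dis_w * (yd %*% t(par$dis$Wd)) / n
  }

  # --- encoder gradients ---
  grad_zmu <- grad_z + enc$zmu / n
  grad_zlv <- grad_z * (0.5 * exp(0.5 * enc$zlv) * eps_mat) +
    0.5 * (exp(enc$zlv) - 1) / n
  grad_zlv[enc$zlv_clip] <- 0

  egrad <- list(
    Wm = crossprod(enc$h2, grad_zmu), bm = colSums(grad_zmu),
    Wv = crossprod(enc$h2, grad_zlv), bv = colSums(grad_zlv)
  )
  grad_h2 <- tcrossprod(grad_zmu, par$enc$Wm) + tcrossprod(grad_zlv, par$enc$Wv)
  grad_a2 <- grad_h2 * (enc$a2 > 0)
  egrad$W2 <- crossprod(enc$h1, grad_a2); egrad$b2 <- colSums(grad_a2)
  grad_h1 <- tcrossprod(grad_a2, par$enc$W2)
  grad_a1 <- grad_h1 * (enc$a1 > 0)
  egrad$W1 <- crossprod(enc$u, grad_a1); egrad$b1 <- colSums(grad_a1)

  list(grad = list(enc = egrad, dec = dgrad, log_r = grad_logr),
       loss_rec = loss_rec, loss_kl = loss_kl, loss_dis = loss_dis,
       z = z)
}

# Discriminator update pieces: CE loss and gradients wrt Wd, bd at fixed z.
discriminator_backward <- function(par, z, y_species) {
  n <- nrow(z)
  dl <- add_bias(z %*% par$dis$Wd, par$dis$bd)
  lse <- row_logsumexp(dl)
  prob <- exp(dl - lse)
  loss <- mean(lse - dl[cbind(seq_len(n), y_species)])
  yd <- prob
  yd[cbind(seq_len(n), y_species)] <- yd[cbind(seq_len(n), y_species)] - 1
  yd <- yd / n
  list(loss = loss,
       grad = list(dis = list(Wd = crossprod(z, yd), bd = colSums(yd))))
}

as_dense_counts <- function(counts) {
  x <- as.matrix(counts)
  storage.mode(x) <- "double"
  x
}

#' Fit the cross-species conditional VAE
#'
#' Trains a conditional variational autoencoder on raw UMI counts. Each
#' cell's count vector, together with one-hot species, batch and tissue
#' indicators, is encoded into a Gaussian posterior over a low-dimensional
#' cell factor; the decoder reconstructs the counts through a zero-inflated
#' negative binomial likelihood whose mean is the cell's sequencing depth
#' times a depth-corrected mean `mu'` (a softmax over genes). Training
#' minimizes reconstruction plus KL loss (the cVAE loss); optionally a
#' single-layer species discriminator is trained adversarially each epoch
#' and the encoder/decoder additionally minimize `-loss_dis` to remove
#' species signal from the cell factors.
#'
#' A seeded 10% validation split (capped) drives early stopping: training
#' ends when the validation cVAE loss has not improved for
#' `patience_epochs` consecutive epochs (or at `max_epochs`), and the
#' parameter snapshot with the minimum validation loss is returned.
#' Validation losses are evaluated at the posterior mean (no sampling), so
#' they are deterministic given the parameters.
#'
#' @param counts Cells-by-genes count matrix (base or `Matrix` sparse);
#'   rows are cells.
#' @param cells Data frame with one row per cell: columns `species`,
#'   `batch`, `tissue` (extra columns such as `donor`, `cell_type` are kept
#'   but unused by training).
#' @param config A [crossbear_config()].
#' @param design Optional [factor_design()]; defaults to the levels present
#'   in `cells`.
#' @return An object of class `crossbear_fit` with elements `params`
#'   (best-validation snapshot), `config`, `design`, `genes`, `log`
#'   (per-epoch tibble of losses: `epoch`, `train_reconstruction`,
#'   `train_kl`, `train_cvae`, `train_discriminator`, `val_cvae`),
#'   `best_epoch`, `validation_idx`.
#' @seealso [predict_cross_species()], [encode_cells()],
#'   [select_hyperparameters()]
#' @export
crossbear_fit <- function(counts, cells, config = crossbear_config(),
                          design = NULL) {
  if (nrow(counts) == 0) stop("`counts` has no cells", call. = FALSE)
  if (nrow(counts) != nrow(cells)) {
    stop("`counts` and `cells` disagree on the number of cells", call. = FALSE)
  }
  x <- as_dense_counts(counts)
  d <- rowSums(x)
  if (any(d == 0)) {
    warning(sum(d == 0), " zero-depth cell(s) removed before training")
    keep <- d > 0
    x <- x[keep, , drop = FALSE]
    cells <- cells[keep, , drop = FALSE]
    d <- d[keep]
  }
  if (is.null(design)) design <- factor_design(cells)
  f <- encode_factors(design, cells)
  cfg <- config
  n <- nrow(x); G <- ncol(x)
  genes <- colnames(counts)
  if (is.null(genes)) genes <- paste0("g", seq_len(G))

  set.seed(cfg$seed)
  par <- init_params(ncol(x) + ncol(f), ncol(f), G, cfg,
                     length(design$species_levels))
  # moment-matched start for the dispersion keeps early epochs stable
  par$log_r <- rep(0, G)
  opt <- adam_init(par)

  n_val <- min(max(1L, round(cfg$validation_fraction * n)), cfg$validation_cap)
  if (n_val >= n) stop("too few cells for a validation split", call. = FALSE)
  val_idx <- sort(sample.int(n, n_val))
  tr_idx <- setdiff(seq_len(n), val_idx)
  y_species <- match(as.character(cells$species), design$species_levels)

  val_loss_fn <- function(par) {
    enc <- enc_forward(par, x[val_idx, , drop = FALSE],
                       f[val_idx, , drop = FALSE], cfg)
    dec <- dec_forward(par, enc$zmu, f[val_idx, , drop = FALSE], d[val_idx])
    mean(zinb_nll_rows(x[val_idx, , drop = FALSE], dec, par$log_r)) +
      mean(kl_gaussian(enc$zmu, enc$zlv))
  }

  mb <- cfg$minibatch_size
  best_val <- Inf; best_par <- par; best_epoch <- 0L; stall <- 0L
  log_rows <- vector("list", cfg$max_epochs)
  dis_w <- if (cfg$use_discriminator) cfg$adversarial_weight else 0

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(tr_idx)
    nb <- max(1L, floor(length(ord) / mb))
    rec_acc <- kl_acc <- dis_acc <- 0
    for (b in seq_len(nb)) {
      idx <- ord[(((b - 1L) * mb) + 1L):(if (b == nb) length(ord) else b * mb)]
      xb <- x[idx, , drop = FALSE]; fb <- f[idx, , drop = FALSE]
      eps_mat <- matrix(stats::rnorm(length(idx) * cfg$latent_dim),
                        length(idx), cfg$latent_dim)
      if (cfg$use_discriminator) {
        enc <- enc_forward(par, xb, fb, cfg)
        zb <- enc$zmu + exp(0.5 * enc$zlv) * eps_mat
        db <- discriminator_backward(par, zb, y_species[idx])
        st <- adam_step(par, db$grad, opt, cfg$learning_rate, which = "dis")
        par <- st$par; opt <- st$state
      }
      bk <- cvae_backward(par, xb, fb, d[idx], cfg, eps_mat,
                          y_species = y_species[idx], dis_w = dis_w)
      st <- adam_step(par, bk$grad, opt, cfg$learning_rate,
                      which = c("enc", "dec", "log_r"))
      par <- st$par; opt <- st$state
      rec_acc <- rec_acc + bk$loss_rec
      kl_acc <- kl_acc + bk$loss_kl
      dis_acc <- dis_acc + if (is.na(bk$loss_dis)) 0 else bk$loss_dis
    }
    val <- val_loss_fn(par)
    log_rows[[epoch]] <- tibble::tibble(
      epoch = epoch,
      train_reconstruction = rec_acc / nb,
      train_kl = kl_acc / nb,
      train_cvae = (rec_acc + kl_acc) / nb,
      train_discriminator = if (cfg$use_discriminator) dis_acc / nb else NA_real_,
      val_cvae = val
    )
    if (val < best_val) {
      best_val <- val; best_par <- par; best_epoch <- epoch; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience_epochs) break
    }
  }

  structure(list(
    params = best_par, final_params = par, config = cfg, design = design,
    genes = genes, log = dplyr::bind_rows(log_rows),
    best_epoch = best_epoch, best_val = best_val,
    validation_idx = val_idx
  ), class = "crossbear_fit")
}

#' @export
print.crossbear_fit <- function(x, ...) {
  cat("<crossbear_fit> latent_dim=", x$config$latent_dim,
      " discriminator=", x$config$use_discriminator,
      " epochs=", nrow(x$log),
      " best validation cVAE loss=", signif(x$best_val, 6),
      " (epoch ", x$best_epoch, ")\n", sep = "")
  invisible(x)
}

#' Encode cells into their latent Gaussian posteriors
#'
#' Runs the trained (or freshly initialized) encoder on raw counts plus
#' factor indicators, returning the per-cell posterior mean and log-variance
#' of the cell factor. Deterministic given the parameters and input.
#'
#' @param object A `crossbear_fit`.
#' @param counts Cells-by-genes count matrix over the same gene vocabulary.
#' @param cells Metadata data frame (`species`, `batch`, `tissue`).
#' @return List with matrices `mean` and `log_variance`
#'   (cells x latent_dim), class `crossbear_posterior`.
#' @export
encode_cells <- function(object, counts, cells) {
  stopifnot(inherits(object, "crossbear_fit"))
  x <- as_dense_counts(counts)
  if (ncol(x) != length(object$genes)) {
    stop("gene dimension mismatch: model has ", length(object$genes),
         " genes, input has ", ncol(x), call. = FALSE)
  }
  f <- encode_factors(object$design, cells)
  enc <- enc_forward(object$params, x, f, object$config)
  structure(list(mean = enc$zmu, log_variance = enc$zlv),
            class = "crossbear_posterior")
}

#' Predict a cell's expression profile in another species
#'
#' Factor swapping: each cell is encoded from its own counts and factor
#' labels, then its posterior-mean embedding is decoded with the one-hot
#' species indicator of `target_species` (keeping the cell's batch and
#' tissue). The result is the sequencing-depth-corrected, denoised mean
#' `mu'` per gene, which sums to one across genes for every cell; no
#' sampling and no dropout is applied. When `target_species` equals the
#' source species this is the within-species denoised profile.
#'
#' @param object A `crossbear_fit`.
#' @param counts Cells-by-genes count matrix for the source cells.
#' @param cells Metadata for the source cells.
#' @param target_species Species label to decode with; must be registered in
#'   the model's factor design.
#' @param apply_dropout If `TRUE` return `(1 - pi) * mu'` where `pi` is the
#'   predicted dropout probability, instead of the default `mu'`.
#' @return Cells-by-genes matrix of predicted depth-normalized expression.
#' @export
predict_cross_species <- function(object, counts, cells, target_species,
                                  apply_dropout = FALSE) {
  stopifnot(inherits(object, "crossbear_fit"))
  if (!target_species %in% object$design$species_levels) {
    stop("unregistered target species: ", target_species, call. = FALSE)
  }
  post <- encode_cells(object, counts, cells)
  cells_t <- cells
  cells_t$species <- target_species
  f_t <- encode_factors(object$design, cells_t)
  dec <- dec_forward(object$params, post$mean, f_t, rep(1, nrow(post$mean)))
  out <- dec$mu
  if (apply_dropout) out <- out * (1 - stats::plogis(dec$p))
  colnames(out) <- object$genes
  out
}

#' Cross-entropy loss of the adversarial species discriminator
#'
#' Applies the single affine-layer-plus-softmax discriminator of a fitted
#' model to latent vectors and returns the mean cross-entropy against the
#' true species labels.
#'
#' @param object A `crossbear_fit` trained with `use_discriminator = TRUE`.
#' @param z Latent matrix (cells x latent_dim) or a single latent vector.
#' @param species Character vector of true species labels.
#' @return Mean cross-entropy (non-negative scalar).
#' @export
discriminator_loss <- function(object, z, species) {
  stopifnot(inherits(object, "crossbear_fit"))
  if (is.null(object$params$dis)) {
    stop("model was trained without a discriminator", call. = FALSE)
  }
  if (!is.matrix(z)) z <- matrix(z, nrow = 1)
  y <- match(as.character(species), object$design$species_levels)
  if (anyNA(y)) stop("unknown species label", call. = FALSE)
  discriminator_backward(object$params, z, y)$loss
}
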