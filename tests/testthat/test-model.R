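test_that("encoding is deterministic and respects cell identity/order", {
  tf <- tiny_fit()
  x <- tf$sim$counts[1:6, ]
  cells <- tf$sim$cells[1:6, ]
  # duplicate cell -> identical posterior rows
  x2 <- rbind(x, x[1, , drop = FALSE])
  cells2 <- dplyr::bind_rows(cells, cells[1, ])
  post <- encode_cells(tf$fit, x2, cells2)
  expect_equal(post$mean[7, ], post$mean[1, ])
  expect_equal(post$log_variance[7, ], post$log_variance[1, ])
  # permuting cells permutes outputs identically
  perm <- c(3, 1, 2, 6, 5, 4)
  post_p <- encode_cells(tf$fit, x[perm, ], cells[perm, ])
  expect_equal(post_p$mean, encode_cells(tf$fit, x, cells)$mean[perm, ])
  # repeated call is bitwise identical
  expect_identical(encode_cells(tf$fit, x, cells)$mean,
                   encode_cells(tf$fit, x, cells)$mean)
})

test_that("encoder rejects unknown labels and wrong gene dimension", {
  tf <- tiny_fit()
  cells_bad <- tf$sim$cells[1:2, ]
  cells_bad$species <- "marmoset"
  expect_error(encode_cells(tf$fit, tf$sim$counts[1:2, ], cells_bad),
               "unknown species")
  expect_error(encode_cells(tf$fit, tf$sim$counts[1:2, 1:10], tf$sim$cells[1:2, ]),
               "dimension mismatch")
})

test_that("untrained seeded model gives reproducible posteriors", {
  sim <- generate_zinb_dataset(synthetic_config(
    n_cells = 50, n_genes = 20, n_cell_types = 2, seed = 3))
  cfg <- crossbear_config(latent_dim = 4, hidden_width = 16,
                          max_epochs = 1, patience_epochs = 5, seed = 11)
  f1 <- crossbear_fit(sim$counts, sim$cells, cfg)
  f2 <- crossbear_fit(sim$counts, sim$cells, cfg)
  p1 <- encode_cells(f1, sim$counts[1:5, ], sim$cells[1:5, ])
  p2 <- encode_cells(f2, sim$counts[1:5, ], sim$cells[1:5, ])
  expect_identical(p1$mean, p2$mean)
})

test_that("the cVAE loss decomposes as reconstruction plus KL", {
  tf <- tiny_fit()
  log <- tidy(tf$fit)
  expect_equal(log$train_cvae, log$train_reconstruction + log$train_kl,
               tolerance = 1e-6)
})

test_that("training is reproducible given the seed and stops on patience", {
  sim <- generate_zinb_dataset(synthetic_config(
    n_cells = 120, n_genes = 30, n_cell_types = 2, seed = 5))
  cfg <- crossbear_config(latent_dim = 4, hidden_width = 16,
                          max_epochs = 6, patience_epochs = 10, seed = 9)
  f1 <- crossbear_fit(sim$counts, sim$cells, cfg)
  f2 <- crossbear_fit(sim$counts, sim$cells, cfg)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$params$enc$W1, f2$params$enc$W1)

  # zero learning rate freezes the parameters, so the validation loss is
  # constant and the patience rule fires after exactly patience + 1 epochs
  cfg0 <- crossbear_config(latent_dim = 4, hidden_width = 16,
                           learning_rate = 1e-30, max_epochs = 50,
                           patience_epochs = 4, seed = 9)
  f0 <- crossbear_fit(sim$counts, sim$cells, cfg0)
  expect_equal(nrow(f0$log), 5)
  expect_equal(f0$best_epoch, 1)
})

test_that("training reduces the validation loss on synthetic ZINB data", {
  tf <- tiny_fit()
  log <- tidy(tf$fit)
  expect_lt(log$val_cvae[nrow(log)], log$val_cvae[1])
  expect_equal(glance(tf$fit)$best_val_cvae, min(log$val_cvae))
})

test_that("discriminator cross-entropy matches hand computations", {
  sim <- generate_zinb_dataset(synthetic_config(
    n_cells = 80, n_genes = 20, n_cell_types = 2, n_species = 3, seed = 4,
    heldout_type = 0))
  cfg <- crossbear_config(latent_dim = 3, hidden_width = 8, max_epochs = 1,
                          patience_epochs = 2, use_discriminator = TRUE,
                          seed = 4)
  fit <- crossbear_fit(sim$counts, sim$cells, cfg)
  z <- matrix(c(0.5, -1, 2), nrow = 1)

  # uniform prediction over k species: loss = log(k) for any true label
  fit$params$dis$Wd <- matrix(0, 3, 3)
  fit$params$dis$bd <- rep(0, 3)
  for (sp in fit$design$species_levels) {
    expect_equal(discriminator_loss(fit, z, sp), log(3))
  }
  # near-certain correct prediction: loss ~ 0
  fit$params$dis$bd <- c(50, 0, 0)
  expect_lt(discriminator_loss(fit, z, fit$design$species_levels[1]), 1e-10)
  # fixed affine weights: manual softmax + cross-entropy
  Wd <- matrix(c(1, 0, -1, 0.5, 0.5, 0, -0.2, 1, 0.3), 3, 3)
  bd <- c(0.1, -0.2, 0)
  fit$params$dis$Wd <- Wd; fit$params$dis$bd <- bd
  logits <- as.vector(z %*% Wd + bd)
  want <- -(logits[2] - log(sum(exp(logits))))
  expect_equal(discriminator_loss(fit, z, fit$design$species_levels[2]), want,
               tolerance = 1e-12)
  # disabled discriminator is a configuration error
  tf <- tiny_fit()
  expect_error(discriminator_loss(tf$fit, z, "species1"), "without a discriminator")
})

test_that("cross-species prediction decodes depth-corrected proportions", {
  tf <- tiny_fit()
  x <- tf$sim$counts[1:4, ]; cells <- tf$sim$cells[1:4, ]
  pred <- predict_cross_species(tf$fit, x, cells, "species2")
  expect_equal(unname(rowSums(pred)), rep(1, 4), tolerance = 1e-12)
  expect_true(all(pred > 0))
  # identity swap: same contract for the source species
  pred_same <- predict_cross_species(tf$fit, x, cells, cells$species[1])
  expect_equal(unname(rowSums(pred_same)), rep(1, 4), tolerance = 1e-12)
  expect_error(predict_cross_species(tf$fit, x, cells, "yeti"),
               "unregistered")
  # (1 - pi) * mu' variant is bounded by mu'
  pv <- predict_cross_species(tf$fit, x, cells, "species2",
                              apply_dropout = TRUE)
  expect_true(all(pv <= pred + 1e-15))
})

test_that("a linear toy decoder reproduces a hand-computed mu'", {
  # 2 latent dims, one factor level each, hidden width 2, 3 genes; ReLU is
  # kept in its linear region by using positive weights and inputs
  par <- list(dec = list(
    U1 = rbind(c(1, 0), c(0, 1), c(0.5, 0.5), c(0, 0), c(0, 0)),
    c1 = c(0, 0),
    U2 = diag(2), c2 = c(0, 0),
    Uo = rbind(c(1, 0, -1), c(0, 1, 0.5)), co = c(0.1, 0, -0.1),
    Up = matrix(0, 2, 3), cp = c(0, 0, 0)))
  z <- matrix(c(0.4, 0.8), nrow = 1)
  f <- matrix(c(1, 1, 1), nrow = 1) # constant indicators
  dec <- crossbear:::dec_forward(par, z, f, d = 1)
  h <- c(0.4 + 0.5, 0.8 + 0.5)      # U1 rows: z1, z2, 0.5*(f1+f2... )
  # manual: v = (0.4, 0.8, 1, 1, 1); vU1 = (0.4 + 0.5, 0.8 + 0.5)
  o <- c(h[1] * 1 + h[2] * 0 + 0.1, h[2] * 1, -h[1] + 0.5 * h[2] - 0.1)
  expect_equal(as.vector(dec$mu), exp(o) / sum(exp(o)), tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(21)
  n <- 5; G <- 7; L <- 3; Hf <- 4
  x <- matrix(rpois(n * G, 4), n, G)
  f <- cbind(one_hot_test(sample(2, n, TRUE)), 1)
  d <- rowSums(x)
  cfg <- crossbear_config(latent_dim = L, hidden_width = Hf, seed = 1)
  par <- crossbear:::init_params(G + ncol(f), ncol(f), G, cfg, 2)
  eps_mat <- matrix(stats::rnorm(n * L), n, L)
  loss_of <- function(par) {
    enc <- crossbear:::enc_forward(par, x, f, cfg)
    z <- enc$zmu + exp(0.5 * enc$zlv) * eps_mat
    dec <- crossbear:::dec_forward(par, z, f, d)
    mean(crossbear:::zinb_nll_rows(x, dec, par$log_r)) +
      mean(kl_gaussian(enc$zmu, enc$zlv))
  }
  bk <- crossbear:::cvae_backward(par, x, f, d, cfg, eps_mat)
  h <- 1e-6
  for (spec in list(c("enc", "W1"), c("enc", "Wv"), c("dec", "U1"),
                    c("dec", "Uo"), c("dec", "Up"))) {
    w <- par[[spec[1]]][[spec[2]]]
    ij <- cbind(sample(nrow(w), 3, TRUE), sample(ncol(w), 3, TRUE))
    for (k in 1:3) {
      pp <- par; pp[[spec[1]]][[spec[2]]][ij[k, 1], ij[k, 2]] <- w[ij[k, 1], ij[k, 2]] + h
      pm <- par; pm[[spec[1]]][[spec[2]]][ij[k, 1], ij[k, 2]] <- w[ij[k, 1], ij[k, 2]] - h
      num <- (loss_of(pp) - loss_of(pm)) / (2 * h)
      expect_equal(bk$grad[[spec[1]]][[spec[2]]][ij[k, 1], ij[k, 2]], num,
                   tolerance = 1e-4)
    }
  }
  # dispersion gradient
  g <- sample(G, 1)
  pp <- par; pp$log_r[g] <- par$log_r[g] + h
  pm <- par; pm$log_r[g] <- par$log_r[g] - h
  expect_equal(bk$grad$log_r[g], (loss_of(pp) - loss_of(pm)) / (2 * h),
               tolerance = 1e-4)
})
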