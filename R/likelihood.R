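#' Zero-inflated negative binomial negative log-likelihood
#'
#' Evaluates `-log P(x)` under a zero-inflated negative binomial (ZINB)
#' distribution: with probability `pi = plogis(dropout_logit)` the count is a
#' structural zero (dropout), otherwise it is drawn from a negative binomial
#' with the given mean and dispersion. This is the per-gene reconstruction
#' loss of the conditional VAE, where the mean is the sequencing-depth-scaled
#' decoder output `d * mu'`.
#'
#' The computation works on the log scale throughout and is stable for large
#' counts and extreme dropout logits (including `-Inf`, pure NB, and `+Inf`,
#' certain dropout).
#'
#' @param x Non-negative integer count(s).
#' @param mean Positive NB mean(s), typically depth times the depth-corrected
#'   mean `mu'`.
#' @param dispersion Positive NB dispersion (size) parameter(s) `r`; the NB
#'   variance is `mean + mean^2 / r`.
#' @param dropout_logit Logit(s) of the dropout probability `pi`.
#' @return Numeric vector of negative log-likelihoods, recycled to the common
#'   length of the arguments.
#' @examples
#' zinb_nll(0, mean = 1, dispersion = 1, dropout_logit = -Inf) # -log(1/2)
#' zinb_nll(0, mean = 1, dispersion = 1, dropout_logit = 0)    # -log(3/4)
#' @export
zinb_nll <- function(x, mean, dispersion, dropout_logit) {
  if (any(x < 0) || any(x != floor(x))) {
    stop("`x` must contain non-negative integers", call. = FALSE)
  }
  if (any(mean <= 0) || any(dispersion <= 0)) {
    stop("`mean` and `dispersion` must be positive", call. = FALSE)
  }
  n <- max(length(x), length(mean), length(dispersion), length(dropout_logit))
  x <- rep_len(x, n)
  m <- rep_len(mean, n)
  r <- rep_len(dispersion, n)
  p <- rep_len(dropout_logit, n)

  lognb <- lgamma(x + r) - lgamma(r) - lgamma(x + 1) +
    r * (log(r) - log(r + m)) + x * (log(m) - log(r + m))

  ll <- numeric(n)
  pos <- x > 0
  ll[pos] <- -softplus(p[pos]) + lognb[pos]
  z <- !pos
  ll[z] <- logaddexp(p[z], lognb[z]) - softplus(p[z])
  # certain dropout: P(0) = 1 exactly; P(x > 0) = 0
  inf_p <- is.infinite(p) & p > 0
  ll[inf_p & z] <- 0
  ll[inf_p & pos] <- -Inf
  -ll
}

softplus <- function(x) {
  out <- pmax(x, 0) + log1p(exp(-abs(x)))
  out[is.infinite(x) & x < 0] <- 0
  out[is.infinite(x) & x > 0] <- Inf
  out
}

logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(-abs(a - b)))
  both_inf <- is.infinite(a) & is.infinite(b) & (a == b)
  out[both_inf] <- a[both_inf]
  one_inf <- is.infinite(m) & !both_inf
  out[one_inf] <- m[one_inf]
  out
}

#' Kullback-Leibler divergence from a diagonal Gaussian to the standard normal
#'
#' Closed form `0.5 * sum(mu^2 + sigma^2 - log sigma^2 - 1)` over latent
#' dimensions, the KL regularizer applied to each cell's posterior
#' `q(z | X, b, s, t)` against the standard multivariate normal prior.
#'
#' @param mean Posterior mean: numeric vector, or a cells-by-dimensions
#'   matrix for a batch of cells.
#' @param log_variance Posterior log-variance, same shape as `mean`.
#' @return A single non-negative number, or one per row when matrices are
#'   given.
#' @examples
#' kl_gaussian(0, 0)      # 0: posterior equals the prior
#' kl_gaussian(1, 0)      # 0.5: unit mean shift
#' @export
kl_gaussian <- function(mean, log_variance) {
  if (!all(is.finite(mean)) || !all(is.finite(log_variance))) {
    stop("posterior parameters must be finite", call. = FALSE)
  }
  term <- 0.5 * (mean^2 + exp(log_variance) - log_variance - 1)
  if (is.matrix(mean)) rowSums(term) else sum(term)
}

# Gradients of the summed ZINB negative log-likelihood, used by the trainer.
# Arguments are matrices (cells x genes) except dispersion r (per-gene row
# vector recycled across cells) and depth d (per-cell). `m` is the NB mean
# d * mu'. Returns dNLL/dm, dNLL/dlog_r (per gene, summed over cells) and
# dNLL/dp.
zinb_nll_grad <- function(x, m, r, p) {
  nc <- nrow(x)
  rmat <- matrix(r, nrow = nc, ncol = length(r), byrow = TRUE)
  lognb0 <- rmat * (log(rmat) - log(rmat + m))
  pos <- x > 0
  # weight of the NB branch at zero: sigma(lognb0 - p)
  w <- stats::plogis(lognb0 - p)
  w[pos] <- 1

  dll_dm <- w * (x / m - (x + rmat) / (rmat + m))

  dll_dr <- w * (digamma(x + rmat) - digamma(rmat) +
    log(rmat / (rmat + m)) + (m - x) / (rmat + m))
  dlogr <- -colSums(dll_dr * rmat)

  sig_p <- stats::plogis(p)
  dll_dp <- ifelse(pos, -sig_p, stats::plogis(p - lognb0) - sig_p)

  list(dm = -dll_dm, dlogr = dlogr, dp = -dll_dp)
}
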