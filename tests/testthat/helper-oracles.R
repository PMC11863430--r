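# Independent oracles the tests compare the implementation against.

# ZINB pmf as an explicit mixture of a point mass at zero and the NB pmf
# provided by stats::dnbinom.
zinb_pmf_oracle <- function(x, mean, dispersion, pi) {
  pi * (x == 0) + (1 - pi) * stats::dnbinom(x, size = dispersion, mu = mean)
}

# Exact one-sample signed-rank tail by enumerating all 2^n sign assignments
# of the ranks of |values - null|.
signed_rank_enum_oracle <- function(values, null_median, alternative) {
  d <- values - null_median
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% rk)
  if (alternative == "greater") mean(w_all >= w_obs) else mean(w_all <= w_obs)
}

# Replay of the greedy matching definition, edge by edge, written
# independently of the package code path.
greedy_replay_oracle <- function(edges) {
  ord <- order(-edges$percent_identity, edges$gene_a, edges$gene_b)
  taken_a <- c(); taken_b <- c(); out <- list()
  for (i in ord) {
    a <- edges$gene_a[i]; b <- edges$gene_b[i]
    if (a %in% taken_a || b %in% taken_b) next
    taken_a <- c(taken_a, a); taken_b <- c(taken_b, b)
    out[[length(out) + 1]] <- edges[i, ]
  }
  dplyr::bind_rows(out)
}

# Regex-free sliding-window GGACH counter.
ggach_scan_oracle <- function(seq) {
  s <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  n <- length(s)
  if (n < 5) return(0L)
  hits <- 0L
  for (i in seq_len(n - 4)) {
    if (s[i] == "G" && s[i + 1] == "G" && s[i + 2] == "A" &&
        s[i + 3] == "C" && s[i + 4] %in% c("A", "C", "T")) {
      hits <- hits + 1L
    }
  }
  hits
}

# Random bipartite scored edge table between two species.
random_edges <- function(seed, n_a = 8, n_b = 8, p_edge = 0.4,
                         sp = c("mouse", "opossum"), tie_scores = FALSE) {
  set.seed(seed)
  idx <- which(matrix(stats::runif(n_a * n_b) < p_edge, n_a, n_b),
               arr.ind = TRUE)
  if (nrow(idx) == 0) idx <- cbind(1, 1)
  score <- if (tie_scores) {
    sample(seq(50, 90, by = 10), nrow(idx), replace = TRUE)
  } else {
    round(stats::runif(nrow(idx), 40, 100), 3)
  }
  tibble::tibble(
    gene_a = sprintf("%s_g%02d", sp[1], idx[, 1]), species_a = sp[1],
    gene_b = sprintf("%s_g%02d", sp[2], idx[, 2]), species_b = sp[2],
    percent_identity = score
  )
}

one_hot_test <- function(idx) {
  m <- matrix(0, length(idx), max(idx))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

# Small trained model shared by several model tests (cheap: tiny sizes).
tiny_fit_cache <- new.env(parent = emptyenv())
tiny_fit <- function() {
  if (is.null(tiny_fit_cache$fit)) {
    sim <- generate_zinb_dataset(synthetic_config(
      n_cells = 300, n_genes = 60, n_cell_types = 3, seed = 42))
    cfg <- crossbear_config(latent_dim = 6, hidden_width = 32,
                            max_epochs = 8, patience_epochs = 8, seed = 42)
    tiny_fit_cache$fit <- crossbear_fit(sim$counts, sim$cells, cfg)
    tiny_fit_cache$sim <- sim
  }
  list(fit = tiny_fit_cache$fit, sim = tiny_fit_cache$sim)
}
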