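#' Configuration for the ZINB synthetic dataset generator
#'
#' Defines the generative model the cross-species VAE assumes: cell-type
#' latents shared across species, a shared linear decoder perturbed by a
#' per-species affine effect, softmax gene proportions, and ZINB
#' observation noise. Because the species effect acts on the shared
#' decoder, "the same cell in another species" has a well-defined ground
#' truth that recovery tests can score against.
#'
#' @param n_cells,n_genes,n_cell_types,n_species Problem size.
#' @param latent_dim_true True latent dimension of the cell factors.
#' @param depth_range Per-cell sequencing depth (total UMI), drawn
#'   uniformly; the default bracket matches shallow combinatorial-indexing
#'   data (median a few hundred UMIs).
#' @param dispersion_range Per-gene NB dispersion, drawn log-uniformly.
#' @param dropout_rate_range Per-gene dropout probability, drawn uniformly.
#' @param species_effect_scale SD of the per-species per-gene shift applied
#'   to the decoder logits (natural-log scale of expression proportions).
#' @param doublet_rate Unused here (see [generate_barnyard()]); kept so one
#'   config can drive both generators.
#' @param heldout_type Cell type index absent from the last species (the
#'   held-out-type scenario); `0` disables.
#' @param n_donors Donors assigned at random (for donor-baseline tests).
#' @param seed Mandatory integer seed.
#' @return List of class `crossbear_sim_config`.
#' @export
synthetic_config <- function(n_cells = 2000, n_genes = 200, n_cell_types = 5,
                             n_species = 2, latent_dim_true = 8,
                             depth_range = c(200, 2000),
                             dispersion_range = c(0.5, 5),
                             dropout_rate_range = c(0, 0.2),
                             species_effect_scale = 1,
                             doublet_rate = 0,
                             heldout_type = n_cell_types,
                             n_donors = 3,
                             seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (n_cell_types > n_cells) stop("more cell types than cells", call. = FALSE)
  stopifnot(n_cells > 0, n_genes > 0, n_species >= 1,
            doublet_rate >= 0, doublet_rate <= 1,
            all(dropout_rate_range >= 0), all(dropout_rate_range <= 1))
  structure(as.list(environment()), class = "crossbear_sim_config")
}

#' Generate a synthetic multi-species ZINB dataset with known ground truth
#'
#' Cell latents are drawn from a mixture of standard normals centered at
#' per-type prototypes; a shared linear decoder plus a per-species shift
#' produces softmax gene proportions `mu'`; counts are ZINB draws at the
#' cell's depth. One designated cell type is absent from the last species,
#' emulating the held-out-cell-type prediction scenario. All generative
#' quantities are returned for recovery tests.
#'
#' @param config A [synthetic_config()].
#' @return List: `counts` (cells x genes integer matrix), `cells` (tibble:
#'   `cell_id`, `species`, `batch`, `tissue`, `donor`, `cell_type`),
#'   `truth` (list: `latents`, `prototypes`, `decoder` (`W`, `intercept`,
#'   `species_shift`), `type_species_mu` (type x species x gene array of
#'   ground-truth `mu'`), `dispersion`, `dropout_rate`), `config`.
#' @export
generate_zinb_dataset <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  S <- paste0("species", seq_len(cfg$n_species))
  types <- paste0("type", seq_len(cfg$n_cell_types))

  proto <- matrix(stats::rnorm(cfg$n_cell_types * cfg$latent_dim_true, sd = 1.5),
                  cfg$n_cell_types, cfg$latent_dim_true)
  W <- matrix(stats::rnorm(cfg$latent_dim_true * cfg$n_genes,
                           sd = 1 / sqrt(cfg$latent_dim_true)),
              cfg$latent_dim_true, cfg$n_genes)
  intercept <- stats::rnorm(cfg$n_genes)
  shift <- matrix(stats::rnorm(cfg$n_species * cfg$n_genes,
                               sd = cfg$species_effect_scale),
                  cfg$n_species, cfg$n_genes)

  type_of <- sample.int(cfg$n_cell_types, cfg$n_cells, replace = TRUE)
  sp_of <- sample.int(cfg$n_species, cfg$n_cells, replace = TRUE)
  if (cfg$heldout_type >= 1 && cfg$n_species > 1) {
    # the held-out type never appears in the last species
    mask <- type_of == cfg$heldout_type & sp_of == cfg$n_species
    sp_of[mask] <- sample.int(cfg$n_species - 1, sum(mask), replace = TRUE)
  }

  z <- proto[type_of, , drop = FALSE] +
    matrix(stats::rnorm(cfg$n_cells * cfg$latent_dim_true, sd = 0.3),
           cfg$n_cells, cfg$latent_dim_true)
  logits <- z %*% W + rep(intercept, each = cfg$n_cells) + shift[sp_of, ]
  mu <- exp(logits - row_logsumexp(logits))

  depth <- round(stats::runif(cfg$n_cells, cfg$depth_range[1], cfg$depth_range[2]))
  disp <- exp(stats::runif(cfg$n_genes, log(cfg$dispersion_range[1]),
                           log(cfg$dispersion_range[2])))
  drop_rate <- stats::runif(cfg$n_genes, cfg$dropout_rate_range[1],
                            cfg$dropout_rate_range[2])

  counts <- matrix(0L, cfg$n_cells, cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    x <- stats::rnbinom(cfg$n_cells, size = disp[g], mu = depth * mu[, g])
    zero <- stats::rbinom(cfg$n_cells, 1, drop_rate[g]) == 1
    x[zero] <- 0L
    counts[, g] <- x
  }
  genes <- sprintf("gene%03d", seq_len(cfg$n_genes))
  colnames(counts) <- genes
  rownames(counts) <- sprintf("cell%05d", seq_len(cfg$n_cells))

  # ground-truth mu' per (type, species): decoder applied at the prototype
  tm <- array(0, dim = c(cfg$n_cell_types, cfg$n_species, cfg$n_genes),
              dimnames = list(types, S, genes))
  for (s in seq_len(cfg$n_species)) {
    lg <- proto %*% W + rep(intercept, each = cfg$n_cell_types) +
      rep(shift[s, ], each = cfg$n_cell_types)
    tm[, s, ] <- exp(lg - row_logsumexp(lg))
  }

  cells <- tibble::tibble(
    cell_id = rownames(counts),
    species = S[sp_of],
    batch = "batch1",
    tissue = "tissue1",
    donor = paste0("donor", sample.int(cfg$n_donors, cfg$n_cells, replace = TRUE)),
    cell_type = types[type_of]
  )
  list(counts = counts, cells = cells,
       truth = list(latents = z, prototypes = proto,
                    decoder = list(W = W, intercept = intercept,
                                   species_shift = shift),
                    type_species_mu = tm,
                    dispersion = disp, dropout_rate = drop_rate,
                    depth = depth),
       config = cfg)
}

#' Generate barnyard-style per-cell per-species read counts
#'
#' Pure cells draw almost all reads from their own species (a configurable
#' contamination fraction is spread over the others); doublets mix two
#' species near 50/50. Used to exercise the species-doublet rule, whose
#' truth labels are returned.
#'
#' @param n_cells Number of cells.
#' @param species Candidate species labels (>= 2).
#' @param doublet_rate Fraction of doublets.
#' @param contamination Expected off-species read fraction in pure cells.
#' @param reads_range Total reads per cell, uniform.
#' @param doublet_mix Range of the mixing fraction for the two species in a
#'   doublet.
#' @param seed Integer seed.
#' @return List: `species_counts` (tibble `cell_id`, `species`,
#'   `read_count`), `truth` (tibble `cell_id`, `species`, `is_doublet`).
#' @export
generate_barnyard <- function(n_cells = 500, species = c("mouse", "chicken"),
                              doublet_rate = 0.1, contamination = 0.005,
                              reads_range = c(500, 5000),
                              doublet_mix = c(0.45, 0.55), seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (length(species) < 2) stop("need at least two species", call. = FALSE)
  set.seed(seed)
  k <- length(species)
  is_dbl <- stats::runif(n_cells) < doublet_rate
  host <- sample.int(k, n_cells, replace = TRUE)
  total <- round(stats::runif(n_cells, reads_range[1], reads_range[2]))

  counts <- matrix(0L, n_cells, k, dimnames = list(NULL, species))
  for (i in seq_len(n_cells)) {
    prob <- rep(contamination / (k - 1), k)
    prob[host[i]] <- 1 - contamination
    if (is_dbl[i]) {
      cands <- setdiff(seq_len(k), host[i])
      second <- if (length(cands) == 1) cands else sample(cands, 1)
      mix <- stats::runif(1, doublet_mix[1], doublet_mix[2])
      prob <- rep(0, k)
      prob[host[i]] <- mix
      prob[second] <- 1 - mix
    }
    counts[i, ] <- stats::rmultinom(1, total[i], prob)[, 1]
  }
  ids <- sprintf("bc%05d", seq_len(n_cells))
  list(
    species_counts = tibble::tibble(
      cell_id = rep(ids, each = k),
      species = rep(species, n_cells),
      read_count = as.integer(t(counts))
    ),
    truth = tibble::tibble(cell_id = ids, species = species[host],
                           is_doublet = is_dbl)
  )
}

#' Generate a scored many-to-many ortholog edge table with known truth
#'
#' True one-to-one pairs across all species receive the highest percent
#' identities; decoy edges between non-orthologous genes get lower scores;
#' for a subset of genes the hub edge to the last species is deleted while
#' the corresponding non-hub edge is kept, so transitive triangle filling
#' is exercised. The true pairing is returned for recovery scoring.
#'
#' @param n_genes True ortholog tuples.
#' @param species Species labels; the first is the hub.
#' @param decoy_per_gene Expected decoy edges per gene.
#' @param decoy_score_range Percent-identity range of decoys (default below
#'   the true-pair range, 80-100).
#' @param n_unlinked Genes whose hub-to-last-species edge is removed.
#' @param seed Integer seed.
#' @return List: `edges` (tibble `gene_a`, `species_a`, `gene_b`,
#'   `species_b`, `percent_identity`), `truth` (tibble, one column per
#'   species).
#' @export
generate_orthology <- function(n_genes = 30,
                               species = c("mouse", "opossum", "chicken"),
                               decoy_per_gene = 1,
                               decoy_score_range = c(40, 79),
                               n_unlinked = 0, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (length(species) < 2) stop("need at least two species", call. = FALSE)
  set.seed(seed)
  gene_id <- function(sp, i) sprintf("%s_g%03d", sp, i)
  truth <- tibble::as_tibble(stats::setNames(
    lapply(species, function(sp) gene_id(sp, seq_len(n_genes))), species))

  pairs <- utils::combn(species, 2, simplify = FALSE)
  edges <- dplyr::bind_rows(lapply(pairs, function(pr) {
    tibble::tibble(
      gene_a = gene_id(pr[1], seq_len(n_genes)), species_a = pr[1],
      gene_b = gene_id(pr[2], seq_len(n_genes)), species_b = pr[2],
      percent_identity = stats::runif(n_genes, 80, 100)
    )
  }))

  n_decoy <- stats::rpois(1, decoy_per_gene * n_genes)
  if (n_decoy > 0) {
    pr_i <- sample(length(pairs), n_decoy, replace = TRUE)
    decoys <- dplyr::bind_rows(lapply(seq_len(n_decoy), function(j) {
      pr <- pairs[[pr_i[j]]]
      ij <- sample.int(n_genes, 2, replace = FALSE) # off-diagonal pair
      tibble::tibble(
        gene_a = gene_id(pr[1], ij[1]), species_a = pr[1],
        gene_b = gene_id(pr[2], ij[2]), species_b = pr[2],
        percent_identity = stats::runif(1, decoy_score_range[1],
                                        decoy_score_range[2])
      )
    }))
    edges <- dplyr::bind_rows(edges, decoys)
    edges <- edges[!duplicated(edges[, c("gene_a", "gene_b")]), ]
  }

  if (n_unlinked > 0 && length(species) >= 3) {
    hub <- species[1]; last <- species[length(species)]
    drop_idx <- sample.int(n_genes, min(n_unlinked, n_genes))
    drop_a <- gene_id(hub, drop_idx)
    edges <- edges[!(edges$species_a == hub & edges$species_b == last &
                       edges$gene_a %in% drop_a), ]
  }
  list(edges = edges, truth = truth)
}
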