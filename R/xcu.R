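#' Normalize predicted profiles to housekeeping-gene mass
#'
#' Divides each cell's expression profile by that cell's summed expression
#' over a housekeeping gene set, so the housekeeping mass is 1 in every
#' cell. Because housekeeping expression is broadly constant across
#' species, this puts factor-swapped predictions from different species on
#' a comparable scale. Scale-invariant and idempotent.
#'
#' @param profiles Cells-by-genes matrix of (predicted) expression.
#' @param hk_genes Housekeeping gene identifiers; must intersect the
#'   columns.
#' @return The normalized matrix; cells with zero housekeeping mass are
#'   dropped with a warning.
#' @export
housekeeping_normalize <- function(profiles, hk_genes) {
  x <- as.matrix(profiles)
  hk <- intersect(colnames(x), hk_genes)
  if (length(hk) == 0) {
    stop("no housekeeping genes found in the profile columns", call. = FALSE)
  }
  mass <- rowSums(x[, hk, drop = FALSE])
  if (any(mass == 0)) {
    warning(sum(mass == 0), " cell(s) with zero housekeeping mass excluded")
    x <- x[mass > 0, , drop = FALSE]
    mass <- mass[mass > 0]
  }
  x / mass
}

#' Per-gene median log2 fold change between two species' predictions
#'
#' For each cell, computes `log2((upper + eps) / (lower + eps))` per gene
#' on housekeeping-normalized predictions of the same cells decoded with
#' two different species factors, then takes the median across cells as the
#' gene's overall cross-species fold change. Antisymmetric under swapping
#' the two species.
#'
#' @param pred_upper,pred_lower Cells-by-genes matrices over the same cells
#'   and genes (conventionally the evolutionarily "upper" species in the
#'   numerator).
#' @param pseudocount Small `eps` added to both terms to avoid infinite
#'   fold changes on zero predictions.
#' @return Tibble with columns `gene`, `median_log2fc`.
#' @export
per_gene_median_log2fc <- function(pred_upper, pred_lower,
                                   pseudocount = 1e-2) {
  up <- as.matrix(pred_upper); lo <- as.matrix(pred_lower)
  if (!all(dim(up) == dim(lo))) {
    stop("predictions must cover the same cells and genes", call. = FALSE)
  }
  if (!is.null(colnames(up)) && !is.null(colnames(lo)) &&
      !identical(colnames(up), colnames(lo))) {
    stop("gene columns are not aligned", call. = FALSE)
  }
  fc <- log2(up + pseudocount) - log2(lo + pseudocount)
  genes <- colnames(up)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(up)))
  tibble::tibble(
    gene = genes,
    median_log2fc = unname(apply(fc, 2, stats::median))
  )
}

#' One-sided one-sample Wilcoxon signed-rank test for fold-change shifts
#'
#' Tests whether the median of a set of per-gene log2 fold changes differs
#' from a null median in the stated direction. With
#' `alternative = "greater"` the null is "median <= null_median" (e.g.
#' `null_median = -1`: expression merely follows the halved copy number,
#' rejected when X-linked genes are upregulated); with
#' `alternative = "less"` the null is "median >= null_median" (e.g.
#' `null_median = 0`: full dosage compensation, rejected when compensation
#' is incomplete).
#'
#' Zero differences are dropped. For n <= 25 the exact signed-rank null
#' distribution is computed by dynamic programming over the (mid)ranks of
#' the absolute differences, so tied values are handled exactly; above that
#' a normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param values Numeric vector (per-gene median log2FC of a gene group).
#' @param null_median Null median to test against.
#' @param alternative `"greater"` or `"less"`.
#' @return One-sided p-value, or `NA` (with a message) when all
#'   differences are zero.
#' @export
xcu_test <- function(values, null_median, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  d <- values - null_median
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    message("all values equal the null median; test degenerate")
    return(NA_real_)
  }
  rk <- rank(abs(d))
  w <- sum(rk[d > 0])
  if (n <= 25) {
    # exact null distribution of 2W via the generating function
    # prod_i (1 + x^(2 r_i)); midranks double to integers
    r2 <- as.integer(round(2 * rk))
    coef <- numeric(sum(r2) + 1)
    coef[1] <- 1
    for (r in r2) {
      coef <- coef + c(rep(0, r), coef[seq_len(length(coef) - r)])
    }
    w2 <- as.integer(round(2 * w))
    if (alternative == "greater") {
      sum(coef[(w2 + 1):length(coef)]) / 2^n
    } else {
      sum(coef[seq_len(w2 + 1)]) / 2^n
    }
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    if (sigma2 <= 0) {
      message("degenerate rank variance")
      return(NA_real_)
    }
    if (alternative == "greater") {
      stats::pnorm((w - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
    } else {
      stats::pnorm((w - mu + 0.5) / sqrt(sigma2))
    }
  }
}

#' Benjamini-Hochberg adjustment of a vector of p-values
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param method Adjustment method passed to [stats::p.adjust()]; default
#'   `"BH"` (false discovery rate).
#' @return Adjusted p-values, same length.
#' @export
adjust_pvalues <- function(pvals, method = "BH") {
  ok <- is.na(pvals) | (pvals >= 0 & pvals <= 1)
  if (!all(ok)) stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = method)
}

#' GGACH (m6A) motif frequency in coding sequences
#'
#' Counts occurrences of the DRACH-family motif `GGACH` (H = A, C or T/U)
#' in each sequence and reports the rate per kilobase. Fewer GGACH sites
#' imply fewer m6A methylation targets and hence more stable transcripts.
#'
#' @param cds Character vector of nucleotide sequences (A/C/G/T/U/N,
#'   case-insensitive) or a `Biostrings::DNAStringSet` (e.g. from
#'   `readDNAStringSet()` on a CDS FASTA).
#' @return Tibble with columns `name`, `length`, `count`, `per_kb`.
#' @export
ggach_frequency <- function(cds) {
  if (inherits(cds, "DNAStringSet")) {
    seqs <- cds
    nms <- names(seqs)
  } else {
    cds <- toupper(chartr("Uu", "Tt", as.character(cds)))
    if (any(nchar(cds) == 0)) stop("empty sequence", call. = FALSE)
    seqs <- Biostrings::DNAStringSet(cds)
    nms <- names(cds)
  }
  len <- Biostrings::width(seqs)
  if (any(len == 0)) stop("empty sequence", call. = FALSE)
  cnt <- Biostrings::vcountPattern("GGACH", seqs, fixed = FALSE)
  if (is.null(nms)) nms <- paste0("seq", seq_along(seqs))
  tibble::tibble(name = nms, length = len, count = cnt,
                 per_kb = cnt * 1000 / len)
}

#' Rank test for motif-frequency shifts against the autosomal reference
#'
#' One-sided two-sample Mann-Whitney test of whether per-gene cross-species
#' motif-frequency differences in a gene group (XAR or XCR) are shifted
#' downward relative to autosomal genes — i.e. whether genes lose m6A
#' motifs when they move onto the X chromosome.
#'
#' @param delta_group Per-gene motif-frequency differences in the target
#'   group.
#' @param delta_autosome Differences for autosomal reference genes.
#' @param alternative Direction for the target group relative to the
#'   reference; default `"less"` (downward shift).
#' @return One-sided p-value.
#' @export
motif_shift_test <- function(delta_group, delta_autosome,
                             alternative = "less") {
  if (length(delta_group) == 0 || length(delta_autosome) == 0) {
    stop("empty group", call. = FALSE)
  }
  stats::wilcox.test(delta_group, delta_autosome,
                     alternative = alternative, exact = FALSE)$p.value
}

#' Cross-species XCU comparison report
#'
#' Full factor-swapping comparison for one species pair: predictions for
#' the same (anchor-species) cells decoded with the upper and lower species
#' factors are housekeeping-normalized, per-gene median log2 fold changes
#' are computed, genes are grouped by evolutionary origin (XAR / XCR /
#' autosome), and each group is tested for upregulation (null: median
#' log2FC <= -1) and for incomplete dosage compensation (null: median
#' log2FC >= 0), with BH correction across groups within each hypothesis.
#'
#' @param pred_upper,pred_lower Cells-by-genes predictions (same cells)
#'   decoded with the two species factors.
#' @param gene_groups Data frame with columns `gene`, `group` (values
#'   `XAR`, `XCR`, `AUTOSOME`).
#' @param hk_genes Housekeeping gene identifiers for normalization.
#' @param pseudocount Passed to [per_gene_median_log2fc()].
#' @return List with `fold_changes` (per-gene tibble with group) and
#'   `tests` (tibble: `group`, `n`, `median_log2fc`, `p_upregulated`,
#'   `p_incomplete`, plus BH-adjusted columns).
#' @export
xcu_report <- function(pred_upper, pred_lower, gene_groups, hk_genes,
                       pseudocount = 1e-2) {
  up <- housekeeping_normalize(pred_upper, hk_genes)
  lo <- housekeeping_normalize(pred_lower, hk_genes)
  fc <- per_gene_median_log2fc(up, lo, pseudocount)
  fc <- dplyr::inner_join(fc, tibble::as_tibble(gene_groups), by = "gene")
  tests <- fc |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      p_upregulated = xcu_test(.data$median_log2fc, -1, "greater"),
      p_incomplete = xcu_test(.data$median_log2fc, 0, "less"),
      median_log2fc = stats::median(.data$median_log2fc),
      .groups = "drop"
    )
  tests$p_upregulated_adj <- adjust_pvalues(tests$p_upregulated)
  tests$p_incomplete_adj <- adjust_pvalues(tests$p_incomplete)
  list(fold_changes = fc, tests = tests)
}
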