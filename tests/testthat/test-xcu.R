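test_that("housekeeping normalization fixes the housekeeping mass at 1", {
  x <- rbind(c(1, 1, 2, 4), c(2, 2, 10, 6))
  colnames(x) <- c("hk1", "hk2", "g1", "g2")
  norm <- housekeeping_normalize(x, c("hk1", "hk2"))
  expect_equal(unname(rowSums(norm[, 1:2])), c(1, 1))
  # hk mass 2 -> everything halved
  expect_equal(unname(norm[1, ]), c(0.5, 0.5, 1, 2))
  # scale invariance: a global per-cell scalar cancels
  expect_equal(housekeeping_normalize(x * c(10, 0.2), c("hk1", "hk2")), norm)
  # idempotence
  expect_equal(housekeeping_normalize(norm, c("hk1", "hk2")), norm)
  # zero housekeeping mass: cell excluded with a warning
  y <- rbind(x, c(0, 0, 3, 3))
  expect_warning(n2 <- housekeeping_normalize(y, c("hk1", "hk2")), "zero")
  expect_equal(nrow(n2), 2)
  expect_error(housekeeping_normalize(x, "absent"), "no housekeeping")
})

test_that("median log2FC is zero under identity and antisymmetric", {
  set.seed(8)
  up <- matrix(stats::runif(30, 0, 2), 6, 5,
               dimnames = list(NULL, paste0("g", 1:5)))
  lo <- matrix(stats::runif(30, 0, 2), 6, 5,
               dimnames = list(NULL, paste0("g", 1:5)))
  expect_equal(per_gene_median_log2fc(up, up)$median_log2fc, rep(0, 5))
  fc <- per_gene_median_log2fc(up, lo)
  fc_sw <- per_gene_median_log2fc(lo, up)
  expect_equal(fc$median_log2fc, -fc_sw$median_log2fc)
  # three-cell toy, one gene: median of hand-computed per-cell values
  u <- matrix(c(1, 2, 4), 3, 1, dimnames = list(NULL, "g"))
  l <- matrix(c(2, 2, 2), 3, 1, dimnames = list(NULL, "g"))
  eps <- 1e-2
  want <- stats::median(log2((c(1, 2, 4) + eps) / (2 + eps)))
  expect_equal(per_gene_median_log2fc(u, l)$median_log2fc, want)
  expect_error(per_gene_median_log2fc(up, lo[1:3, ]), "same cells")
})

test_that("fold changes compose transitively on noiseless data", {
  # identical cells: the median is the per-cell value, so
  # log2FC(a, c) = log2FC(a, b) + log2FC(b, c) exactly
  a <- matrix(rep(c(1, 3, 0.5), each = 4), 4, 3)
  b <- matrix(rep(c(2, 1, 0.25), each = 4), 4, 3)
  cc <- matrix(rep(c(4, 0.5, 1), each = 4), 4, 3)
  colnames(a) <- colnames(b) <- colnames(cc) <- paste0("g", 1:3)
  ab <- per_gene_median_log2fc(a, b)$median_log2fc
  bc <- per_gene_median_log2fc(b, cc)$median_log2fc
  ac <- per_gene_median_log2fc(a, cc)$median_log2fc
  expect_equal(ac, ab + bc, tolerance = 1e-12)
})

test_that("signed-rank test matches exact enumeration for small n", {
  set.seed(9)
  for (case in 1:100) {
    n <- sample(3:12, 1)
    vals <- if (case %% 4 == 0) {
      round(stats::rnorm(n, sd = 2) * 2) / 2 # coarse grid: forces ties
    } else {
      round(stats::rnorm(n, sd = 2), 6)
    }
    null <- round(stats::rnorm(1), 6)
    if (all(vals == null)) next
    alt <- sample(c("greater", "less"), 1)
    expect_equal(xcu_test(vals, null, alt),
                 signed_rank_enum_oracle(vals, null, alt),
                 tolerance = 1e-12)
  }
})

test_that("all-positive unit shifts of n = 20 give exactly 2^-20", {
  vals <- -1 + rep(1, 20) # null median -1, all differences +1
  expect_equal(xcu_test(vals, -1, "greater"), 2^-20)
})

test_that("large-n test matches the reference normal approximation", {
  set.seed(10)
  vals <- stats::rnorm(200, mean = 0.05)
  for (alt in c("greater", "less")) {
    ref <- stats::wilcox.test(vals, mu = 0, alternative = alt,
                              exact = FALSE, correct = TRUE)$p.value
    expect_equal(xcu_test(vals, 0, alt), ref, tolerance = 1e-8)
  }
  # exactly antisymmetric values: the statistic sits at its null mean
  v <- stats::rnorm(100)
  sym <- c(v, -v)
  expect_equal(xcu_test(sym, 0, "greater"), 0.5, tolerance = 0.01)
  expect_equal(xcu_test(sym, 0, "less"), 0.5, tolerance = 0.01)
})

test_that("one-sided tails are complementary up to the point mass", {
  set.seed(11)
  for (case in 1:20) {
    vals <- stats::rnorm(sample(5:15, 1))
    pg <- xcu_test(vals, 0, "greater")
    pl <- xcu_test(vals, 0, "less")
    expect_gte(pg + pl, 1 - 1e-12)
  }
  # degenerate: every value equals the null median
  expect_message(dv <- xcu_test(rep(2, 5), 2, "greater"), "degenerate")
  expect_true(is.na(dv))
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(adjust_pvalues(0.03), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_pvalues(rep(0.2, 4)), rep(0.2, 4))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.6)
  expect_equal(adjust_pvalues(p), stats::p.adjust(p, "BH"))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
})

test_that("GGACH counting matches a sliding-window oracle", {
  expect_equal(ggach_frequency("GGACT")$count, 1L)
  expect_equal(ggach_frequency("GGACG")$count, 0L) # H excludes G
  expect_equal(ggach_frequency("GGACAGGACC")$count, 2L)
  expect_equal(ggach_frequency("GGACAGGACC")$per_kb, 200)
  # U is treated as T
  expect_equal(ggach_frequency("GGACU")$count, 1L)
  set.seed(12)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(20:300, 1),
                      replace = TRUE), collapse = "")
    expect_equal(ggach_frequency(s)$count, ggach_scan_oracle(s))
  }
  # DNAStringSet input
  ss <- Biostrings::DNAStringSet(c(x = "GGACTGGACA"))
  expect_equal(ggach_frequency(ss)$count, 2L)
  expect_error(ggach_frequency(""), "empty")
})

test_that("motif shift test detects downward shifts against autosomes", {
  set.seed(13)
  auto <- stats::rnorm(300)
  same <- stats::rnorm(300)
  expect_gt(motif_shift_test(same, auto), 0.05)
  # identical samples: the U statistic sits exactly at its null mean
  expect_equal(motif_shift_test(auto, auto), 0.5, tolerance = 0.01)
  shifted <- stats::rnorm(300) - 1
  expect_lt(motif_shift_test(shifted, auto), 1e-6)
  # swapping the groups flips the one-sided tail
  expect_gt(motif_shift_test(auto, shifted), 0.99)
  expect_error(motif_shift_test(numeric(0), auto), "empty")
})

test_that("xcu_report groups genes and tests both hypotheses", {
  set.seed(14)
  genes <- paste0("g", 1:60)
  hk <- paste0("g", 1:10)
  lo <- matrix(stats::runif(20 * 60, 0.5, 1.5), 20, 60,
               dimnames = list(NULL, genes))
  up <- lo
  up[, 31:45] <- up[, 31:45] * 1.8 # upregulated block
  groups <- tibble::tibble(
    gene = genes,
    group = c(rep("AUTOSOME", 30), rep("XAR", 15), rep("XCR", 15)))
  rep <- xcu_report(up, lo, groups, hk)
  expect_setequal(rep$tests$group, c("AUTOSOME", "XAR", "XCR"))
  expect_equal(nrow(rep$fold_changes), 60)
  # the upregulated XAR block rejects "median <= -1" hard
  expect_lt(rep$tests$p_upregulated[rep$tests$group == "XAR"], 1e-4)
  expect_true(all(rep$tests$p_upregulated_adj >= rep$tests$p_upregulated))
})
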