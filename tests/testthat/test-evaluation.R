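test_that("pseudobulk averages depth-normalized cells", {
  counts <- rbind(c(10, 30, 60), c(5, 15, 30))
  colnames(counts) <- c("g1", "g2", "g3")
  # single cell: its normalized profile
  expect_equal(unname(pseudobulk(counts[1, , drop = FALSE], scale_to = 100)),
               c(10, 30, 60))
  # identical normalized profiles collapse to that profile
  expect_equal(unname(pseudobulk(counts, scale_to = 100)), c(10, 30, 60))
  # three unequal-depth cells: hand-computed mean of scaled rows
  x <- rbind(c(1, 1), c(3, 1), c(0, 10))
  colnames(x) <- c("g1", "g2")
  want <- colMeans(rbind(c(50, 50), c(75, 25), c(0, 100)))
  expect_equal(unname(pseudobulk(x, scale_to = 100)), unname(want))
  # invariant to per-cell depth rescaling and to cell order
  x2 <- x * c(7, 1, 3)
  expect_equal(pseudobulk(x2, 100), pseudobulk(x, 100))
  expect_equal(pseudobulk(x[c(3, 1, 2), ], 100), pseudobulk(x, 100))
  # log variant
  expect_equal(pseudobulk(x, 100, log = TRUE), log2(pseudobulk(x, 100) + 1))
  # zero-depth cell excluded with a warning
  expect_warning(pb <- pseudobulk(rbind(x, c(0, 0)), 100), "zero-depth")
  expect_equal(pb, pseudobulk(x, 100))
})

test_that("donor baseline is the mean over donor pairs", {
  set.seed(3)
  counts <- matrix(rpois(60 * 20, 5), 60, 20)
  colnames(counts) <- paste0("g", 1:20)
  donors <- rep(c("d1", "d2", "d3"), each = 20)
  got <- donor_baseline(counts, donors, scale_to = 1e4)
  profs <- sapply(c("d1", "d2", "d3"), function(d) {
    log2(pseudobulk(counts[donors == d, ], 1e4) + 1)
  })
  want <- mean(c(cor(profs[, 1], profs[, 2]), cor(profs[, 1], profs[, 3]),
                 cor(profs[, 2], profs[, 3])))
  expect_equal(got, want, tolerance = 1e-12)
  # identical donors correlate perfectly
  expect_equal(donor_baseline(rbind(counts[1:5, ], counts[1:5, ]),
                              rep(c("a", "b"), each = 5)), 1)
  expect_message(nb <- donor_baseline(counts, rep("d1", 60)), "fewer than two")
  expect_true(is.na(nb))
})

test_that("species baseline translates genes and correlates log pseudobulk", {
  set.seed(4)
  src <- matrix(rpois(40 * 10, 6), 40, 10,
                dimnames = list(NULL, paste0("m", 1:10)))
  tab <- tibble::tibble(mouse = paste0("m", 1:10), human = paste0("h", 1:10))
  # identical expression across species -> correlation 1
  tgt <- src
  colnames(tgt) <- paste0("h", 1:10)
  expect_equal(species_baseline(src, tgt, tab, "mouse", "human"), 1)
  # dropping an unmapped gene changes the gene set only
  tab2 <- tab[-3, ]
  got <- species_baseline(src, tgt, tab2, "mouse", "human")
  ps <- pseudobulk(src[, -3], log = TRUE); pt <- pseudobulk(tgt[, -3], log = TRUE)
  expect_equal(got, cor(ps, pt))
  expect_error(species_baseline(src, tgt[, 0], tab, "mouse", "human"),
               "no shared genes")
})

test_that("cell-type baseline picks the Euclidean nearest neighbor", {
  set.seed(5)
  g <- 15
  base <- stats::runif(g, 5, 100) # varied per-gene means
  mk <- function(shift, n = 10) {
    t(replicate(n, rpois(g, pmax(base + shift, 1))))
  }
  src <- rbind(mk(0), mk(1), mk(40))
  src_types <- rep(c("held", "twin", "far"), each = 10)
  tgt <- rbind(mk(0), mk(0), mk(40))
  tgt_types <- src_types
  colnames(src) <- colnames(tgt) <- paste0("g", seq_len(g))
  res <- celltype_baseline(src, src_types, tgt, tgt_types, "held")
  expect_equal(res$neighbor, "twin") # argmin distance
  # the twin's target profile is distributed like the held-out truth
  expect_gt(res$correlation, 0.9)
  expect_error(celltype_baseline(src, rep("twin", 30), tgt, tgt_types, "held"),
               "absent from the source")
})

test_that("relative prediction error has its defining identities", {
  truth <- c(a = 1, b = 2, c = 5)
  src <- c(a = 2, b = 4, c = 5)
  # prediction equals truth -> 0 everywhere the denominator is nonzero
  r0 <- relative_prediction_error(truth, truth, src)
  expect_equal(r0$relative_error, c(0, 0))
  expect_equal(attr(r0, "n_zero_denominator"), 1L)
  # prediction equals the source profile -> 1
  r1 <- relative_prediction_error(src, truth, src)
  expect_equal(r1$relative_error, c(1, 1))
  # hand-computed toy values
  pred <- c(a = 1.5, b = 3, c = 6)
  r <- relative_prediction_error(pred, truth, src)
  expect_equal(r$relative_error, c(0.5, 0.5))
  # invariant under common positive rescaling
  r_s <- relative_prediction_error(10 * pred, 10 * truth, 10 * src)
  expect_equal(r_s$relative_error, r$relative_error)
  expect_error(relative_prediction_error(pred[1:2], truth, src), "share")
})

test_that("disease log2FC evaluation normalizes, offsets and correlates", {
  g <- 20
  set.seed(6)
  wt <- rpois(g, 30) + 1
  ad <- wt * exp(stats::rnorm(g, 0, 0.4))
  # perfect prediction: correlation 1
  expect_equal(ad_log2fc_eval(ad, wt, ad, wt), 1)
  # no change anywhere: degenerate constant log2FC
  expect_message(nv <- ad_log2fc_eval(wt, wt, wt, wt), "degenerate")
  expect_true(is.na(nv))
  # a gene at 9 vs 4 post-normalization has log2FC log2(10/5) = 1
  l2 <- function(a, b) {
    a <- a / sum(a) * 10; b <- b / sum(b) * 10
    log2((a + 1) / (b + 1))
  }
  fc <- l2(c(9, 1), c(4, 6))
  expect_equal(fc[1], 1)
  expect_equal(ad_log2fc_eval(c(9, 1), c(4, 6), c(9, 1), c(4, 6),
                              scale_to = 10), 1)
})

test_that("evaluate_prediction bundles the metrics into one tidy row", {
  set.seed(7)
  genes <- paste0("g", 1:15)
  truth <- matrix(rpois(20 * 15, 8), 20, 15, dimnames = list(NULL, genes))
  pred <- truth / rowSums(truth)
  donors <- rep(c("d1", "d2"), each = 10)
  tab <- tibble::tibble(mouse = genes, human = genes)
  res <- evaluate_prediction(pred, truth, target_donors = donors,
                             source_counts = truth, table = tab,
                             source = "mouse", target = "human")
  expect_s3_class(res, "tbl_df")
  expect_equal(nrow(res), 1)
  expect_true(all(abs(unlist(res)) <= 1))
  expect_equal(res$species_baseline, 1) # source == target here
})
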