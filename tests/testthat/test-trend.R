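test_that("height binning is contiguous, near-equal and deterministic", {
  set.seed(21)
  ps <- rand_peaks(100)
  bins <- bin_by_height(ps)
  expect_equal(as.vector(table(bins)), rep(10, 10))
  ps103 <- rand_peaks(103)
  sizes <- as.vector(table(bin_by_height(ps103)))
  expect_true(all(sizes %in% c(10, 11)))
  expect_equal(sizes, c(rep(10, 7), rep(11, 3)))  # remainder to highest bins
  # concatenating bins in order recovers a height-sorted permutation
  ord <- order(bins, ps$height)
  expect_true(!is.unsorted(ps$height[ord]))
  # ties broken by peak_id
  tied <- peak_set("chr1", 1:20 * 100, 1:20 * 100 + 50, rep(7, 20), "TF", "A")
  expect_identical(bin_by_height(tied, 4), bin_by_height(tied, 4))
  expect_error(bin_by_height(rand_peaks(5), 10), "fewer peaks")
})

test_that("bin trends fit OLS on the bin means", {
  set.seed(22)
  ps <- rand_peaks(200)
  bins <- bin_by_height(ps)
  tr <- bin_trend(bins, as.numeric(bins))
  expect_equal(tr$slope, 1, tolerance = 1e-9)
  expect_true(tr$significant)
  # hand-computed OLS on a fixed 10-point toy input (one peak per bin)
  toy <- peak_set("chr1", 1:10 * 10, 1:10 * 10 + 5, 1:10, "TF", "A")
  y <- c(2.1, 1.9, 3.2, 2.8, 3.9, 4.4, 4.1, 5.2, 5.8, 6.1)
  tr2 <- bin_trend(bin_by_height(toy, 10), y)
  x <- 1:10
  b_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(tr2$slope, b_hat, tolerance = 1e-12)
  expect_equal(tr2$bin_means, y)
  # degenerate: zero variance of means
  flat <- bin_trend(bins, rep(3.3, 200))
  expect_true(flat$degenerate)
  expect_equal(flat$slope, 0)
  expect_equal(flat$p, 1)
})

test_that("slope test type-I error is near alpha on null data", {
  set.seed(23)
  hits <- replicate(400, {
    ps <- rand_peaks(200)
    bin_trend(bin_by_height(ps), stats::rnorm(200))$significant
  })
  rate <- mean(hits)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("GC-balanced subsets equalise GC-bin counts within height bins", {
  set.seed(24)
  n <- 400
  ps <- rand_peaks(n)
  gc <- stats::runif(n, 0.2, 0.8)
  bins <- bin_by_height(ps, 4)
  sel <- gc_balanced_subset(ps, gc, bins, n_gc_bins = 4, seed = 9)
  qs <- stats::quantile(gc, c(0.05, 0.95), names = FALSE)
  keep <- gc >= qs[1] & gc <= qs[2]
  brk <- seq(min(gc[keep]), max(gc[keep]), length.out = 5)
  gbin <- findInterval(gc[sel], brk, rightmost.closed = TRUE,
                       all.inside = TRUE)
  for (hb in unique(bins[sel])) {
    counts <- table(gbin[bins[sel] == hb])
    expect_true(length(unique(as.vector(counts))) == 1)
  }
  # determinism and GC-identical degenerate case
  expect_identical(sel, gc_balanced_subset(ps, gc, bins, n_gc_bins = 4,
                                           seed = 9))
  same_gc <- gc_balanced_subset(ps, rep(0.5, n), bins, seed = 1)
  expect_identical(same_gc, seq_len(n))
  # two GC bins with 30 and 10 peaks: 10 sampled from each
  ps2 <- rand_peaks(40)
  gc2 <- c(stats::runif(30, 0.1, 0.45), stats::runif(10, 0.55, 0.9))
  sel2 <- gc_balanced_subset(ps2, gc2, rep(1L, 40), n_gc_bins = 2,
                             trim = 0, seed = 2)
  expect_identical(length(sel2), 20L)
  expect_identical(sum(gc2[sel2] > 0.5), 10L)
})

test_that("extreme-height strata compare specific-peak signals by KS", {
  set.seed(25)
  n <- 200
  h <- stats::rexp(n, 0.1)
  common <- stats::runif(n) < 0.4
  own <- stats::rnorm(n, 1)
  same <- extreme_height_comparison(h, common, own, own)
  expect_equal(same$D, 0)
  expect_gt(same$p, 0.99)
  sep <- extreme_height_comparison(h, common, own + 10, own)
  expect_equal(sep$D, 1)
  expect_lt(sep$p, 1e-6)
  # stratum size: 30% highest selected by rank before labels
  expect_equal(sep$n_specific + sep$n_common, round(0.3 * n))
  low <- extreme_height_comparison(h, common, own, own, side = "lowest")
  expect_false(low$skipped)
})

test_that("per-bin median differences recover planted monotone effects", {
  bins <- rep(1:5, each = 40)
  own <- stats::rnorm(200, bins)
  expect_equal(median_diff_by_height(bins, own, own), rep(0, 5))
  other <- own - bins
  md <- median_diff_by_height(bins, own, other)
  for (b in 1:5) {
    i <- bins == b
    expect_equal(md[b], stats::median(own[i]) - stats::median(other[i]))
  }
  with_gap <- median_diff_by_height(c(1L, 1L, 3L, 3L), 1:4, c(0, 0, 1, 1),
                                    n_bins = 3)
  expect_true(is.na(with_gap[2]))
})

test_that("cofactor KS comparison agrees with the reference implementation", {
  set.seed(26)
  a <- stats::rnorm(200); b <- stats::rnorm(200, 1.2)
  res <- cofactor_pwm_ks(a, b)
  ref <- suppressWarnings(stats::ks.test(a, b))
  expect_equal(res$D, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
  expect_lt(res$p, 0.05)
  same <- cofactor_pwm_ks(a, a)
  expect_equal(same$D, 0)
  expect_error(cofactor_pwm_ks(1, a), "at least 2")
})

test_that("expression/peak-count correlation handles outlier exclusion", {
  tfs <- sprintf("TF%d", 1:8)
  ea <- stats::setNames(c(2, 4, 6, 8, 10, 12, 14, 16), tfs)
  eb <- stats::setNames(rep(2, 8), tfs)
  ca <- ea * 10; cb <- eb * 10
  names(ca) <- names(cb) <- tfs
  res <- expression_peakcount_correlation(ea, eb, ca, cb)
  expect_equal(res$all$r, 1, tolerance = 1e-9)
  # a planted outlier pulls r down; removing it restores the fit
  ca2 <- ca; ca2["TF8"] <- 1
  res2 <- expression_peakcount_correlation(ea, eb, ca2, cb,
                                           exclude = "TF8")
  expect_lt(res2$all$r, res2$excluded$r)
  expect_equal(res2$excluded$r, 1, tolerance = 1e-9)
  expect_error(expression_peakcount_correlation(ea[1:2], eb[1:2],
                                                ca[1:2], cb[1:2]),
               "at least 3")
})

test_that("balancing removes a planted GC-height confound", {
  set.seed(27)
  n <- 1000
  ps <- rand_peaks(n)
  # GC rises with height: the confound the balanced subset must remove
  gc <- 0.3 + 0.4 * rank(ps$height) / n + stats::rnorm(n, 0, 0.05)
  bins <- bin_by_height(ps, 5)
  sel <- gc_balanced_subset(ps, gc, bins, n_gc_bins = 5, seed = 4)
  confounded <- suppressWarnings(
    stats::chisq.test(table(bins, cut(gc, 5)))$p.value)
  balanced <- suppressWarnings(
    stats::chisq.test(table(bins[sel], cut(gc[sel], 5)))$p.value)
  expect_lt(confounded, 0.01)
  expect_gt(balanced, 0.01)
})
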