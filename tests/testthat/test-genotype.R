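toy_snps <- function() {
  snp_records(snp_id = sprintf("s%d", 1:6), chrom = "chr1",
              pos = c(100, 200, 300, 400, 500, 600),
              ref_allele = "A", alt_allele = "T",
              gt_a = c(0L, 1L, 0L, NA, 1L, 0L),
              gt_b = c(1L, 1L, 1L, 1L, 0L, 1L),
              Q = c(50, 60, 10, 70, 80, 90),
              AF = 0.5, DP = 20L,
              peak_id = sprintf("pk%d", 1:6))
}

test_that("homozygous-different selection filters genotype and quality", {
  expect_warning(sel <- select_homozygous_different(toy_snps()), "missing")
  # (0,1) selected; (1,1) not; low-Q homo-diff excluded; NA skipped
  expect_identical(sel$snp_id, c("s1", "s5", "s6"))
  set.seed(17)
  n <- 200
  snps <- snp_records(sprintf("r%d", 1:n), "chr1", 1:n, "A", "G",
                      gt_a = sample(c(0L, 1L, NA), n, TRUE),
                      gt_b = sample(c(0L, 1L, NA), n, TRUE),
                      Q = stats::runif(n, 0, 100))
  got <- suppressWarnings(select_homozygous_different(snps))
  keep <- !is.na(snps$gt_a) & !is.na(snps$gt_b) & snps$gt_a != snps$gt_b &
    snps$Q >= 20
  expect_identical(got$snp_id, snps$snp_id[keep])
  expect_error(snp_records("x", "chr1", 1, "AT", "G", 0, 1), "single bases")
})

test_that("SNP-in-best-motif uses the hit footprint on forward coordinates", {
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  mat <- logodds_matrix(pwm(matrix(c(30, 0, 0, 0, 0, 30, 0, 0,
                                     0, 0, 30, 0), 4, 3)), bg)
  s <- paste0("TTTTT", "ACG", "TTTTT")
  expect_true(snp_in_best_motif(s, mat, 5))
  expect_true(snp_in_best_motif(s, mat, 7))
  expect_false(snp_in_best_motif(s, mat, 11))
  expect_error(snp_in_best_motif(s, mat, 50), "outside")
  set.seed(18)
  for (i in 1:30) {
    mat <- rand_logodds(4)
    s <- rand_seq(20)
    off <- sample(0:19, 1)
    hit <- bf_pwm_scan(mat, s)
    expect_identical(snp_in_best_motif(s, mat, off),
                     off >= hit$offset && off < hit$offset + 4)
  }
})

test_that("paired genotype test detects planted disruption and is calibrated", {
  set.seed(19)
  own <- stats::rnorm(100, 2, 0.3)
  res <- genotype_motif_test(own, own - 1.5 + stats::rnorm(100, 0, 0.1))
  expect_lt(res$p, 0.01)
  expect_gt(res$n_own_higher, res$n_other_higher)
  # all-equal scores: undefined path
  flat <- genotype_motif_test(rep(1, 10), rep(1, 10))
  expect_true(flat$degenerate)
  expect_equal(flat$p, 1)
  # sign flip reverses the one-sided direction
  a <- stats::rnorm(40); b <- stats::rnorm(40)
  p1 <- genotype_motif_test(a, b)$p
  p2 <- genotype_motif_test(b, a)$p
  expect_equal(p1 + p2, 1, tolerance = 1e-9)
})

test_that("height/motif-score correlation matches the textbook formula", {
  dh <- c(1, 3, 2, 5, 4)
  ds <- c(0.5, 2.2, 1.0, 4.8, 3.1)
  res <- height_motifscore_correlation(dh, ds)
  r_hand <- sum((dh - mean(dh)) * (ds - mean(ds))) /
    sqrt(sum((dh - mean(dh))^2) * sum((ds - mean(ds))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(height_motifscore_correlation(dh, dh)$r, 1)
  expect_true(height_motifscore_correlation(dh, rep(1, 5))$degenerate)
  # independent pairs: small correlation on average
  set.seed(20)
  rs <- replicate(200, height_motifscore_correlation(stats::rnorm(1000),
                                                     stats::rnorm(1000))$r)
  expect_lt(stats::median(abs(rs)), 0.05)
  ps <- replicate(200, height_motifscore_correlation(stats::rnorm(50),
                                                     stats::rnorm(50))$p)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 1e-3)
})

test_that("SNP summaries tabulate per overlap category", {
  cat <- c(pk1 = "common", pk2 = "common", pk3 = "specific_A",
           pk4 = "specific_A", pk5 = "specific_B", pk6 = "specific_B")
  sm <- snp_peak_summary(cat, toy_snps())
  expect_true(all(sm$frac_with_snp >= 0 & sm$frac_with_snp <= 1))
  expect_equal(sum(sm$n_peaks), 6)
  expect_equal(sm$frac_with_snp, rep(1, 3))  # every peak has exactly one SNP
  # brute-force recount of homozygous-different fractions
  hd <- suppressWarnings(select_homozygous_different(toy_snps()))
  for (i in seq_len(nrow(sm))) {
    ids <- names(cat)[cat == sm$category[i]]
    expect_equal(sm$frac_homo_diff[i],
                 sum(hd$peak_id %in% ids) / sum(toy_snps()$peak_id %in% ids))
  }
  none <- snp_peak_summary(cat, toy_snps()[0, , drop = FALSE])
  expect_true(all(none$frac_with_snp == 0))
})

test_that("full disruption makes every pair score higher under its own genotype", {
  st <- small_study(seed = 23, motif_disruption_prob = 1,
                    peaks_per_tf = 120)
  bg <- genome_background(st$genome)
  pairs <- do.call(rbind, lapply(names(st$pwms), function(tf) {
    sel <- st$peaks$A$tf == tf
    genotype_motif_pairs(st$peaks$A[sel, , drop = FALSE],
                         label_by_overlap(st$peaks$A[sel, , drop = FALSE],
                                          st$peaks$B[st$peaks$B$tf == tf, ]),
                         st$snps, st$genome,
                         logodds_matrix(st$pwms[[tf]], bg))
  }))
  expect_gt(nrow(pairs), 20)
  expect_true(all(pairs$score_own > pairs$score_other))
  expect_lt(genotype_motif_test(pairs$score_own, pairs$score_other)$p, 1e-4)
})
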