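test_that("genome background counts bases and floors degenerate frequencies", {
  expect_equal(unname(genome_background("ACGT")), rep(0.25, 4))
  bg <- genome_background("AAAN")
  expect_true(all(bg > 0))
  expect_equal(sum(bg), 1, tolerance = 1e-12)
  expect_equal(unname(bg["A"]), 1, tolerance = 1e-5)
  set.seed(13)
  s <- rand_seq(5000, c("A", "C", "G", "T", "N"))
  ch <- strsplit(s, "")[[1]]
  counts <- table(factor(ch[ch != "N"], levels = c("A", "C", "G", "T")))
  expect_equal(unname(genome_background(s)),
               as.numeric(counts / sum(counts)), tolerance = 1e-9)
  expect_error(genome_background("NNN"), "no A/C/G/T")
})

test_that("log-odds entries follow the pseudocount formula", {
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  uniform <- pwm(matrix(3, 4, 2))
  expect_equal(logodds_matrix(uniform, bg), matrix(0, 4, 2),
               ignore_attr = TRUE)
  col <- pwm(matrix(c(9, 0, 0, 0), 4, 1))
  lo <- logodds_matrix(col, bg)
  expect_equal(unname(lo["A", 1]), log2((10 / 13) / 0.25), tolerance = 1e-12)
  expect_equal(unname(lo["C", 1]), log2((1 / 13) / 0.25), tolerance = 1e-12)
  # flattening counts shrinks entries toward zero
  flat <- pwm(col$counts + 50)
  expect_true(all(abs(logodds_matrix(flat, bg)) <=
                    abs(lo) + 1e-12))
  expect_true(all(is.finite(logodds_matrix(pwm(matrix(0, 4, 3)), bg))))
})

test_that("both-strand maximum matches exhaustive enumeration", {
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  # consensus sequence scores the column-max sum at offset 0
  p <- pwm(matrix(c(9, 0, 0, 0,  0, 9, 0, 0,  0, 0, 9, 0), 4, 3))
  lo <- logodds_matrix(p, bg)
  hit <- max_pwm_score(lo, "ACG")
  expect_equal(hit$score, sum(apply(lo, 2, max)), tolerance = 1e-12)
  expect_identical(hit$offset, 0L)
  # palindromic-symmetric matrix: tie broken to '+'
  pal <- logodds_matrix(pwm(matrix(c(0, 0, 0, 9,  9, 0, 0, 0), 4, 2)), bg)
  expect_identical(max_pwm_score(pal, "TATA")$strand, "+")
  set.seed(14)
  for (i in 1:200) {
    w <- sample(2:8, 1)
    mat <- rand_logodds(w)
    s <- rand_seq(sample((w + 1):40, 1),
                  c("A", "C", "G", "T", if (i %% 4 == 0) "N"))
    want <- bf_pwm_scan(mat, s)
    got <- max_pwm_score(mat, s)
    if (is.null(want)) {
      expect_true(is.na(got$score))
    } else {
      expect_equal(got$score, want$score, tolerance = 1e-9)
      expect_identical(as.integer(got$offset), as.integer(want$offset))
      expect_identical(got$strand, want$strand)
    }
  }
  expect_error(max_pwm_score(rand_logodds(5), "ACG"), "shorter")
})

test_that("reverse-complementing the sequence preserves the best score", {
  set.seed(15)
  for (i in 1:40) {
    mat <- rand_logodds(5)
    s <- rand_seq(30)
    expect_equal(max_pwm_score(mat, s)$score,
                 max_pwm_score(mat, revcomp(s))$score, tolerance = 1e-9)
  }
})

test_that("allele substitution rescoring behaves like editing the sequence", {
  set.seed(16)
  mat <- rand_logodds(4)
  s <- rand_seq(25)
  ch <- strsplit(s, "")[[1]]
  # no-op substitution
  same <- rescore_with_allele(mat, s, 10, ch[11])
  base <- max_pwm_score(mat, s)
  expect_equal(same$score, base$score)
  expect_identical(same$offset, base$offset)
  for (i in 1:30) {
    pos <- sample(0:24, 1)
    allele <- sample(c("A", "C", "G", "T"), 1)
    edited <- paste0(substr(s, 1, pos), allele, substr(s, pos + 2, 25))
    expect_equal(rescore_with_allele(mat, s, pos, allele)$score,
                 bf_pwm_scan(mat, edited)$score, tolerance = 1e-9)
  }
  # disrupting the consensus base of a high-information column lowers the
  # best score through that window
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  strong <- logodds_matrix(pwm(matrix(c(30, 0, 0, 0, 0, 30, 0, 0,
                                        0, 0, 30, 0, 0, 0, 0, 30), 4, 4)), bg)
  seq0 <- paste0("TTTTT", "ACGT", "TTTTT")
  worst <- rescore_with_allele(strong, seq0, 5, "T")
  expect_lt(worst$score, max_pwm_score(strong, seq0)$score)
  expect_error(rescore_with_allele(mat, s, 99, "A"), "out of range")
})

test_that("PWM selection picks the highest information content per length", {
  sharp <- pwm(matrix(c(30, 0, 0, 0), 4, 3), name = "sharp")
  fuzzy <- pwm(matrix(7, 4, 3), name = "fuzzy")
  expect_gt(pwm_information_content(sharp), pwm_information_content(fuzzy))
  sel <- select_pwms(list(TFX = fuzzy, TFX = sharp))
  expect_identical(sel$TFX$name, "sharp")
})
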