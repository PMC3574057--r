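test_that("region signal follows the tags / length / depth formula", {
  reg <- data.frame(chrom = "chr1", start = 1000, end = 1200)
  ts <- tag_set(data.frame(chrom = "chr1",
                           start = seq(1000, 1180, by = 20),
                           end = seq(1036, 1216, by = 20)), 2e6)
  expect_identical(region_tag_counts(ts, reg), 10L)
  expect_equal(region_signal(ts, reg), 10 / 200 / 2, tolerance = 1e-12)
  none <- data.frame(chrom = "chr1", start = 5000, end = 5100)
  expect_equal(region_signal(ts, none), 0)
  # doubling the library size halves the value
  ts2 <- tag_set(ts$tags, 4e6)
  expect_equal(region_signal(ts2, reg), region_signal(ts, reg) / 2)
  expect_error(region_signal(tag_set(ts$tags[0, ], 0), reg), "positive")
})

test_that("signal averages and differences behave as stated", {
  expect_equal(signal_avg_diff(0.4, 0.4), data.frame(avg = 0.4, diff = 0))
  expect_equal(signal_avg_diff(1, 0), data.frame(avg = 0.5, diff = 1))
  expect_equal(signal_avg_diff(0.2, 0.9)$diff, -signal_avg_diff(0.9, 0.2)$diff)
})

test_that("conservation scores are length-weighted segment averages", {
  tr <- signal_track(data.frame(chrom = "chr1", start = c(100, 150),
                                end = c(110, 180), value = c(1, 2)))
  reg <- data.frame(chrom = "chr1", start = 50, end = 300)
  expect_equal(phylop_region_score(tr, reg)$score, 1.75)
  one <- signal_track(data.frame(chrom = "chr1", start = 0, end = 1000,
                                 value = 0.37))
  expect_equal(phylop_region_score(one, reg)$score, 0.37)
  off <- data.frame(chrom = "chr2", start = 50, end = 300)
  res <- phylop_region_score(tr, off)
  expect_equal(res$score, 0)
  expect_false(res$covered)
  set.seed(9)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    starts <- sort(sample(seq(0, 900, by = 10), n))
    seg <- data.frame(chrom = "chr1", start = starts,
                      end = starts + sample(5:9, n, replace = TRUE),
                      value = round(stats::rnorm(n), 3))
    tr <- signal_track(seg)
    reg <- data.frame(chrom = "chr1", start = sample(0:500, 1))
    reg$end <- reg$start + sample(50:400, 1)
    got <- phylop_region_score(tr, reg)
    want <- bf_phylop(seg, reg)
    expect_equal(got$score, want, tolerance = 1e-12)
    ov <- seg$value[seg$start < reg$end & seg$end > reg$start]
    if (length(ov))
      expect_true(got$score >= min(ov) - 1e-12 && got$score <= max(ov) + 1e-12)
  }
})

test_that("GC fraction counts G and C over the full length", {
  expect_equal(gc_fraction("GGCC"), 1)
  expect_equal(gc_fraction("AATT"), 0)
  expect_equal(gc_fraction("ACGTN"), 2 / 5)
  set.seed(10)
  for (i in 1:20) {
    s <- rand_seq(sample(10:200, 1), c("A", "C", "G", "T", "N"))
    ch <- strsplit(s, "")[[1]]
    expect_equal(gc_fraction(s), sum(ch %in% c("G", "C")) / length(ch))
  }
  expect_error(gc_fraction(""), "empty")
})

test_that("expression is exon-normalised and averaged over expressed transcripts", {
  expect_equal(transcript_expression(100, 1000, 1e6), 0.1)
  expect_equal(transcript_expression(c(50, 50), c(500, 500), 1e6),
               transcript_expression(50, 500, 1e6))
  trs <- list(list(symbol = "X", exon_counts = 100, exon_lengths = 1000),
              list(symbol = "X", exon_counts = 0, exon_lengths = 500),
              list(symbol = "Y", exon_counts = c(10, 30),
                   exon_lengths = c(100, 100)))
  e <- gene_expression(trs, 1e6)
  expect_equal(unname(e["X"]), 0.1)  # zero-read transcript excluded
  expect_equal(unname(e["Y"]), mean(c(10, 30) / 100))
  expect_error(transcript_expression(1, 100, 0), "positive")
})

test_that("normalised differences are bounded and antisymmetric", {
  expect_equal(normalized_difference(3, 1), 0.5)
  expect_equal(normalized_difference(7, 7), 0)
  expect_equal(normalized_difference(2, 0), 1)
  set.seed(11)
  a <- stats::runif(50); b <- stats::runif(50)
  expect_equal(normalized_difference(a, b), -normalized_difference(b, a))
  expect_true(all(abs(normalized_difference(a, b)) <= 1))
  expect_error(normalized_difference(0, 0), "undefined")
})

test_that("region signal is invariant to splitting the tag collection", {
  set.seed(12)
  tg <- data.frame(chrom = "chr1", start = sample.int(1000, 200, TRUE))
  tg$end <- tg$start + 36L
  reg <- data.frame(chrom = "chr1", start = 200, end = 600)
  whole <- region_tag_counts(tag_set(tg, 1e6), reg)
  half <- region_tag_counts(tag_set(tg[1:100, ], 1e6), reg) +
    region_tag_counts(tag_set(tg[101:200, ], 1e6), reg)
  expect_identical(whole, half)
})
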