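toy_genes <- function() {
  gene_models(
    name = c("g1", "g2", "g3"), symbol = c("ALPHA", "Beta", "GAMMA"),
    chrom = c("chr1", "chr1", "chr2"), strand = c("+", "-", "+"),
    tx_start = c(10000, 30000, 5000), tx_end = c(12500, 33000, 5400),
    exons = list(data.frame(start = c(10000, 12000), end = c(10100, 12500)),
                 data.frame(start = c(30000, 32000), end = c(30800, 33000)),
                 data.frame(start = 5000, end = 5400)))
}

test_that("promoter regions are strand-aware windows plus first introns", {
  pr <- promoter_regions(toy_genes())
  win <- pr[pr$kind == "window", ]
  # '+' gene at TSS 10000
  expect_true(any(win$chrom == "chr1" & win$start == 8000 & win$end == 10200))
  # '-' gene: TSS at tx_end, upstream to the right
  expect_true(any(win$chrom == "chr1" & win$start == 33000 - 200 &
                    win$end == 33000 + 2000))
  fi <- pr[pr$kind == "first_intron", ]
  # '+' first intron between exon1 and exon2
  expect_true(any(fi$start == 10100 & fi$end == 12000))
  # '-' first intron in transcription order = last genomic gap
  expect_true(any(fi$start == 30800 & fi$end == 32000))
  # single-exon gene contributes no intron
  expect_identical(nrow(pr), nrow(toy_genes()) + 2L)
  # clamping at zero
  g0 <- gene_models("g0", "G0", "chr1", "+", 100, 900,
                    list(data.frame(start = 100, end = 900)))
  expect_identical(promoter_regions(g0)$start, 0L)
})

test_that("Pol III promoter windows reflect with strand", {
  trna <- data.frame(chrom = c("chr1", "chr1"), pos = c(5000, 5000),
                     strand = c("+", "-"))
  r <- pol3_promoter_regions(trna)
  expect_equal(r$start, c(3000, 4800))
  expect_equal(r$end, c(5200, 7000))
  empty <- pol3_promoter_regions(data.frame(chrom = character(0),
                                            pos = integer(0),
                                            strand = character(0)))
  expect_identical(nrow(empty), 0L)
})

test_that("TSS distance is the capped midpoint minimum over all TSS", {
  g <- toy_genes()
  at_tss <- peak_set("chr1", 9950, 10050, 1, "TF", "A")  # midpoint 10000
  expect_equal(tss_distance(at_tss, g), 0)
  far <- peak_set("chr1", 79950, 80050, 1, "TF", "A")
  expect_equal(tss_distance(far, g), 20000)
  no_tss_chrom <- peak_set("chrX", 100, 200, 1, "TF", "A")
  expect_equal(tss_distance(no_tss_chrom, g), 20000)
  set.seed(6)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    rg <- gene_models(sprintf("g%d", 1:n), sprintf("S%d", 1:n),
                      sample(c("chr1", "chr2"), n, replace = TRUE),
                      sample(c("+", "-"), n, replace = TRUE),
                      tx_start = (s <- sample.int(50000, n)),
                      tx_end = s + 1000,
                      exons = lapply(s, function(x)
                        data.frame(start = x, end = x + 1000)))
    pk <- rand_peaks(15, span = 60000)
    d <- tss_distance(pk, rg)
    expect_equal(d, bf_tss_distance(pk, rg))
    expect_true(all(d >= 0 & d <= 20000))
  }
})

test_that("CpG classification matches its definitions and the 1 bp oracle", {
  expect_identical(classify_cpg(strrep("A", 500)), "poor")
  expect_identical(classify_cpg(strrep("CG", 250)), "rich")
  # the CGCG window numbers: GC = 1, observed 250, expected 125
  st <- cpg_stats(strrep("CG", 250))
  expect_equal(st$region_gc, 1.0)
  expect_equal(st$region_oe, 2.0)
  set.seed(7)
  for (i in 1:12) {
    # mix plain and island-flavoured stretches to hit all three classes
    s <- paste0(rand_seq(700),
                if (i %% 3 == 0) strrep("CG", 300) else rand_seq(600),
                if (i %% 2 == 0) rand_seq(700, c("A", "T", "T", "A", "C"))
                else rand_seq(700))
    expect_identical(classify_cpg(s, step = 10), bf_classify_cpg(s))
    expect_identical(classify_cpg(s, step = 1), bf_classify_cpg(s))
  }
  expect_error(classify_cpg(""), "empty")
})

test_that("raising the GC threshold can only shrink the rich set", {
  set.seed(8)
  seqs <- replicate(20, paste0(rand_seq(300), strrep("CG", sample(50:200, 1)),
                               rand_seq(300)))
  rich_55 <- vapply(seqs, function(s)
    classify_cpg(s, gc_min = 0.55) == "rich", logical(1))
  rich_70 <- vapply(seqs, function(s)
    classify_cpg(s, gc_min = 0.70) == "rich", logical(1))
  expect_true(all(rich_55 | !rich_70))
})

test_that("region membership uses half-open overlap", {
  regions <- data.frame(chrom = "chr1", start = 1000, end = 2000)
  inside <- peak_set("chr1", 1200, 1300, 1, "TF", "A")
  abutting <- peak_set("chr1", 2000, 2100, 1, "TF", "A")
  expect_true(in_region(inside, regions))
  expect_false(in_region(abutting, regions))
})

test_that("housekeeping promoters match symbols case-insensitively", {
  g <- toy_genes()
  expect_identical(nrow(housekeeping_promoters(g, character(0))), 0L)
  all_pr <- housekeeping_promoters(g, c("alpha", "BETA", "gamma"))
  expect_identical(nrow(all_pr), nrow(promoter_regions(g)))
  one <- housekeeping_promoters(g, "beta")
  expect_identical(nrow(one), 2L)  # window + first intron of g2
})
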