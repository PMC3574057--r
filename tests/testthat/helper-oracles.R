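# Brute-force oracles, independent of the package's implementations.

rand_peaks <- function(n, chroms = c("chr1", "chr2"), span = 10000,
                       max_len = 300, tf = "TF", cell = "A",
                       prefix = "p") {
  start <- sample.int(span, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  peak_set(chrom = sample(chroms, n, replace = TRUE), start = start,
           end = start + len, height = sample.int(100, n, replace = TRUE),
           tf = tf, cell_type = cell,
           peak_id = sprintf("%s%04d", prefix, seq_len(n)))
}

rand_seq <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# base-by-base interval overlap
bf_overlap <- function(ca, sa, ea, cb, sb, eb) {
  if (ca != cb) return(FALSE)
  length(intersect(seq(sa, ea - 1L), seq(sb, eb - 1L))) > 0
}

# all-pairs O(n^2) overlap count
bf_count_overlapping <- function(query, target) {
  hits <- 0L
  for (i in seq_len(nrow(query))) {
    for (j in seq_len(nrow(target))) {
      if (query$chrom[i] == target$chrom[j] &&
          max(query$start[i], target$start[j]) <
          min(query$end[i], target$end[j])) {
        hits <- hits + 1L
        break
      }
    }
  }
  hits
}

# transitive closure of the all-pairs extended-overlap matrix
bf_clusters <- function(peaks, target_length = 2000) {
  n <- nrow(peaks)
  len <- peaks$end - peaks$start
  extra <- pmax(0L, as.integer(target_length) - len)
  left <- extra %/% 2L
  s <- pmax(0L, peaks$start - left)
  e <- peaks$end + (extra - left)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- peaks$chrom[i] == peaks$chrom[j] &&
      max(s[i], s[j]) < min(e[i], e[j])
  }
  reach <- adj
  repeat {
    nxt <- (reach %*% reach > 0) | reach
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[which(reach[i, ])] <- cid
    }
  }
  comp
}

# 1 bp step CpG classification straight from the definitions
bf_classify_cpg <- function(s, window = 500, gc_min = 0.55, oe_rich = 0.75,
                            oe_poor = 0.48) {
  ch <- strsplit(toupper(s), "")[[1]]
  len <- length(ch)
  stat <- function(a, b) {
    seg <- ch[a:b]
    nc <- sum(seg == "C"); ng <- sum(seg == "G")
    ncpg <- if (b > a) sum(seg[-length(seg)] == "C" & seg[-1] == "G") else 0
    gc <- (nc + ng) / (b - a + 1L)
    expd <- nc * ng / (b - a + 1L)
    oe <- if (expd > 0) ncpg / expd else 0
    c(gc = gc, oe = oe)
  }
  whole <- stat(1L, len)
  if (len <= window) {
    if (whole["gc"] > gc_min && whole["oe"] > oe_rich) return("rich")
    if (whole["oe"] < oe_poor) return("poor")
    return("intermediate")
  }
  rich <- FALSE
  for (a in 1:(len - window + 1L)) {
    w <- stat(a, a + window - 1L)
    if (w["gc"] > gc_min && w["oe"] > oe_rich) { rich <- TRUE; break }
  }
  if (rich) "rich" else if (whole["oe"] < oe_poor) "poor" else "intermediate"
}

# exhaustive min distance from midpoints to TSS
bf_tss_distance <- function(peaks, genes, cap = 20000) {
  tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)
  vapply(seq_len(nrow(peaks)), function(i) {
    mid <- (peaks$start[i] + peaks$end[i]) %/% 2L
    d <- abs(mid - tss[genes$chrom == peaks$chrom[i]])
    if (!length(d)) cap else min(min(d), cap)
  }, numeric(1))
}

# per-base expansion oracle for the length-weighted track average
bf_phylop <- function(track, region) {
  vals <- numeric(0)
  for (j in seq_len(nrow(track))) {
    if (track$chrom[j] != region$chrom) next
    ov <- intersect(seq(track$start[j], track$end[j] - 1L),
                    seq(region$start, region$end - 1L))
    vals <- c(vals, rep(track$value[j], length(ov)))
  }
  if (!length(vals)) 0 else mean(vals)
}

# exhaustive both-strand PWM scan with the documented tie-break
bf_pwm_scan <- function(mat, s) {
  bases <- c("A", "C", "G", "T")
  w <- ncol(mat)
  ch <- strsplit(toupper(s), "")[[1]]
  rc <- rev(chartr("ACGTN", "TGCAN", ch))
  len <- length(ch)
  cand <- NULL
  for (i in 0:(len - w)) {
    win <- ch[(i + 1):(i + w)]
    if (all(win %in% bases))
      cand <- rbind(cand, data.frame(
        offset = i, strand = "+",
        score = sum(mat[cbind(match(win, bases), seq_len(w))])))
    win <- rc[(i + 1):(i + w)]
    if (all(win %in% bases))
      cand <- rbind(cand, data.frame(
        offset = len - w - i, strand = "-",
        score = sum(mat[cbind(match(win, bases), seq_len(w))])))
  }
  if (is.null(cand)) return(NULL)
  cand <- cand[cand$score == max(cand$score), , drop = FALSE]
  cand <- cand[order(cand$offset, cand$strand), , drop = FALSE]
  cand[1, ]
}

rand_logodds <- function(w = 6) {
  matrix(stats::rnorm(4 * w), 4, w,
         dimnames = list(c("A", "C", "G", "T"), NULL))
}

# small full-level study used by several suites
small_study <- function(seed = 42, ...) {
  defaults <- list(chrom_lengths = c(chr1 = 1.5e6, chr2 = 1.5e6),
                   n_genes = 40, n_tfs = 3, peaks_per_tf = 200)
  args <- utils::modifyList(defaults, list(...))
  simulate_peak_study(do.call(sim_config, args), seed = seed)
}
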