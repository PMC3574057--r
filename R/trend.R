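#' Height-binned trend analyses
#'
#' Peaks are binned into approximately equally-sized groups by height; a
#' feature's per-bin means are regressed on the bin index by ordinary least
#' squares and the slope tested against zero. Additional tools cover the
#' GC-balanced subset, the top/bottom-30% chromatin comparisons, per-bin
#' median signal differences and the cofactor / expression correlation
#' analyses.
#'
#' @name trend
NULL

#' Bin peaks into height groups
#'
#' Peaks are sorted by height (ties broken by `peak_id` for determinism) and
#' split into `n_bins` contiguous groups whose sizes differ by at most 1;
#' remainder peaks go to the highest bins. Bin 1 holds the lowest heights.
#'
#' @param peaks peak frame with `height` and `peak_id`.
#' @param n_bins number of bins (default 10).
#' @return integer vector of bin indices (1..n_bins) along `peaks` rows.
#' @export
bin_by_height <- function(peaks, n_bins = 10) {
  n <- nrow(peaks)
  if (n < n_bins) stop("fewer peaks than bins")
  ord <- order(peaks$height, peaks$peak_id)
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins)
  if (extra) sizes[(n_bins - extra + 1L):n_bins] <- base + 1L
  bins <- integer(n)
  bins[ord] <- rep(seq_len(n_bins), times = sizes)
  bins
}

#' Regression of per-bin feature means on bin index
#'
#' Computes the mean feature value in each height bin and fits ordinary
#' least squares of those means on the bin index 1..n. The two-sided t-test
#' on the slope is flagged significant at `alpha`. Bin means with zero
#' variance yield slope 0 and p 1 with `degenerate = TRUE`.
#'
#' @param bins bin indices from [bin_by_height()].
#' @param values per-peak feature values (aligned with `bins`).
#' @param alpha significance level (default 0.05).
#' @return list of class `trend_result`: `bin_means`, `slope`, `se`, `p`,
#'   `significant`, `degenerate`, `n_bins`.
#' @export
bin_trend <- function(bins, values, alpha = 0.05) {
  if (length(bins) != length(values)) stop("bins and values lengths differ")
  if (anyNA(values)) stop("feature values missing for some binned peaks")
  m <- tapply(values, bins, mean)
  idx <- as.numeric(names(m))
  out <- list(bin_means = as.numeric(m), n_bins = length(m), alpha = alpha)
  if (stats::sd(m) == 0) {
    out$slope <- 0; out$se <- NA_real_; out$p <- 1
    out$significant <- FALSE; out$degenerate <- TRUE
  } else {
    fit <- stats::lm(as.numeric(m) ~ idx)
    # summary.lm warns on numerically perfect fits; the slope is still valid
    sm <- suppressWarnings(summary(fit))$coefficients
    out$slope <- unname(sm["idx", "Estimate"])
    out$se <- unname(sm["idx", "Std. Error"])
    out$p <- unname(sm["idx", "Pr(>|t|)"])
    out$significant <- out$p <= alpha
    out$degenerate <- FALSE
  }
  class(out) <- "trend_result"
  out
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("height-bin trend: slope %.4g (se %.3g), p = %.3g%s\n",
              x$slope, x$se, x$p,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' GC-balanced subset of peaks
#'
#' Removes the top and bottom `trim` GC fraction (GC outliers), bins the
#' remaining peaks into `n_gc_bins` equal-interval GC bins, and within each
#' height bin draws the same number of peaks from every non-empty GC bin
#' (the minimum count available across GC bins for that height bin),
#' keeping GC content approximately equal across height bins.
#'
#' @param peaks peak frame.
#' @param gc per-peak GC fractions.
#' @param bins height-bin indices from [bin_by_height()].
#' @param n_gc_bins number of equal-interval GC bins (default 10).
#' @param trim tail fraction trimmed from each GC extreme (default 0.05).
#' @param seed integer seed for the within-bin sampling.
#' @return integer vector of selected row indices into `peaks`.
#' @export
gc_balanced_subset <- function(peaks, gc, bins, n_gc_bins = 10, trim = 0.05,
                               seed = 1L) {
  stopifnot(nrow(peaks) == length(gc), length(gc) == length(bins))
  qs <- stats::quantile(gc, c(trim, 1 - trim), names = FALSE)
  keep <- which(gc >= qs[1] & gc <= qs[2])
  gck <- gc[keep]
  brk <- seq(min(gck), max(gck), length.out = n_gc_bins + 1L)
  gbin <- findInterval(gck, brk, rightmost.closed = TRUE, all.inside = TRUE)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  sel <- integer(0)
  for (hb in sort(unique(bins[keep]))) {
    i_h <- keep[bins[keep] == hb]
    g_h <- gbin[match(i_h, keep)]
    counts <- table(g_h)
    take <- min(counts)
    for (gb in names(counts)) {
      pool <- i_h[g_h == as.integer(gb)]
      sel <- c(sel, pool[sample.int(length(pool), take)])
    }
  }
  sort(sel)
}

#' Chromatin comparison in an extreme height stratum
#'
#' Selects the `top_fraction` highest (or lowest) peaks by height rank
#' within the full peak set, then, within that stratum, compares the
#' own-cell-type and other-cell-type signal distributions at cell-type
#' specific peaks with a two-sample Kolmogorov-Smirnov test; the common-peak
#' own-cell distribution is summarised for reference.
#'
#' @param heights per-peak heights of the full set.
#' @param is_common logical per peak: common to both cell types?
#' @param signal_own,signal_other per-peak signals in the peak-bearing and
#'   the other cell type.
#' @param top_fraction stratum size as a fraction (default 0.3).
#' @param side `"highest"` or `"lowest"`.
#' @return list: `D`, `p`, `n_specific`, `n_common`,
#'   `median_own`, `median_other`, `median_common`, `skipped` (TRUE when
#'   fewer than 2 specific peaks fall in the stratum).
#' @export
extreme_height_comparison <- function(heights, is_common, signal_own,
                                      signal_other, top_fraction = 0.3,
                                      side = c("highest", "lowest")) {
  side <- match.arg(side)
  n <- length(heights)
  k <- max(1L, round(top_fraction * n))
  ord <- order(heights, decreasing = (side == "highest"))
  stratum <- ord[seq_len(k)]
  sp <- stratum[!is_common[stratum]]
  cm <- stratum[is_common[stratum]]
  out <- list(n_specific = length(sp), n_common = length(cm),
              median_common = if (length(cm)) stats::median(signal_own[cm])
                              else NA_real_)
  if (length(sp) < 2L) {
    out$D <- NA_real_; out$p <- NA_real_
    out$median_own <- NA_real_; out$median_other <- NA_real_
    out$skipped <- TRUE
    return(out)
  }
  ks <- suppressWarnings(
    stats::ks.test(signal_own[sp], signal_other[sp],
                   exact = length(sp) < 30))
  out$D <- unname(ks$statistic); out$p <- ks$p.value
  out$median_own <- stats::median(signal_own[sp])
  out$median_other <- stats::median(signal_other[sp])
  out$skipped <- FALSE
  out
}

#' Per-bin median signal differences at specific peaks
#'
#' For each height bin: the median own-cell signal minus the median
#' other-cell signal over the peaks in the bin. Empty bins are reported as
#' `NA`.
#'
#' @param bins bin indices (over cell-type-specific peaks).
#' @param signal_own,signal_other aligned signal vectors.
#' @param n_bins total number of bins (defaults to `max(bins)`).
#' @return numeric vector of length `n_bins`.
#' @export
median_diff_by_height <- function(bins, signal_own, signal_other,
                                  n_bins = max(bins)) {
  out <- rep(NA_real_, n_bins)
  for (b in sort(unique(bins))) {
    i <- bins == b
    out[b] <- stats::median(signal_own[i]) - stats::median(signal_other[i])
  }
  out
}

#' Kolmogorov-Smirnov comparison of two PWM score samples
#'
#' Two-sample KS test between the cofactor PWM score distributions sampled
#' around the cell-type specific peaks of the two cell types.
#'
#' @param scores_a,scores_b numeric samples (>= 2 values each).
#' @return list `D`, `p`, `n_a`, `n_b`.
#' @export
cofactor_pwm_ks <- function(scores_a, scores_b) {
  if (length(scores_a) < 2L || length(scores_b) < 2L)
    stop("each sample needs at least 2 values")
  ks <- suppressWarnings(stats::ks.test(scores_a, scores_b))
  list(D = unname(ks$statistic), p = ks$p.value,
       n_a = length(scores_a), n_b = length(scores_b))
}

#' Correlation of expression differences with peak-count differences
#'
#' Per TF, the between-cell-type expression difference and peak-count
#' difference are both mapped to `[-1, 1]` with [normalized_difference()];
#' Pearson correlation and the two-sided slope test are computed with and
#' without an exclusion set (e.g. expression outliers).
#'
#' @param expr_a,expr_b named per-TF expression values for the two cell
#'   types.
#' @param count_a,count_b named per-TF peak counts.
#' @param exclude TF names excluded from the second fit.
#' @return list of two fits (`all`, `excluded`), each `r`, `p`, `n`.
#' @export
expression_peakcount_correlation <- function(expr_a, expr_b, count_a, count_b,
                                             exclude = character(0)) {
  tfs <- intersect(names(expr_a), names(count_a))
  if (length(tfs) < 3L) stop("need at least 3 TFs")
  fit <- function(use) {
    if (length(use) < 3L) stop("need at least 3 TFs after exclusion")
    x <- normalized_difference(expr_a[use], expr_b[use])
    y <- normalized_difference(count_a[use], count_b[use])
    ct <- stats::cor.test(x, y)
    list(r = unname(ct$estimate), p = ct$p.value, n = length(use))
  }
  list(all = fit(tfs), excluded = fit(setdiff(tfs, exclude)))
}
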