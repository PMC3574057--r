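#' Gene-model derived annotation features
#'
#' Promoters are the strand-aware window from 2000 bp upstream to 200 bp
#' downstream of the transcription start site, together with the gene's
#' first intron (the gap between exon 1 and exon 2 in transcription order).
#' Pol III promoters use the same window around tRNA transcription starts.
#'
#' @name annotation
NULL

#' Construct gene models
#'
#' @param name transcript identifier.
#' @param symbol gene symbol.
#' @param chrom chromosome.
#' @param strand "+" or "-".
#' @param tx_start,tx_end transcript span, 0-based half-open.
#' @param exons list of `data.frame(start, end)` per gene, sorted,
#'   non-overlapping, within the transcript span.
#' @return `data.frame` of class `gene_models` with a list-column `exons`.
#' @export
gene_models <- function(name, symbol, chrom, strand, tx_start, tx_end, exons) {
  stopifnot(all(strand %in% c("+", "-")))
  g <- data.frame(name = as.character(name), symbol = as.character(symbol),
                  chrom = as.character(chrom), strand = as.character(strand),
                  tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
                  stringsAsFactors = FALSE)
  g$exons <- lapply(exons, function(e) {
    e <- as.data.frame(e)[, c("start", "end")]
    e$start <- as.integer(e$start)
    e$end <- as.integer(e$end)
    if (nrow(e) == 0L) stop("gene model with no exons")
    if (any(diff(e$start) <= 0) && nrow(e) > 1L ||
        any(e$end <= e$start) ||
        (nrow(e) > 1L && any(e$start[-1] < e$end[-nrow(e)])))
      stop("exons must be sorted, non-empty and non-overlapping")
    e
  })
  class(g) <- c("gene_models", "data.frame")
  g
}

#' Transcription start sites of gene models
#'
#' @param genes a `gene_models` frame.
#' @return integer vector: `tx_start` for "+" genes, `tx_end` for "-" genes
#'   (the TSS base itself in 0-based coordinates is `tx_end - 1` for "-"
#'   genes; the half-open convention keeps `tx_end` as the reflection point).
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)
}

#' Promoter regions with first introns
#'
#' Per gene the strand-aware window `[TSS - 2000, TSS + 200)` (reflected for
#' "-" strand genes) plus, for multi-exon genes, the first intron in
#' transcription order. Windows are clamped at coordinate 0.
#'
#' @param genes a `gene_models` frame.
#' @param upstream,downstream window extents in bp (defaults 2000 and 200).
#' @param introns include first introns (default TRUE).
#' @return `data.frame(chrom, start, end, kind)` with `kind` in
#'   `{"window", "first_intron"}`.
#' @export
promoter_regions <- function(genes, upstream = 2000, downstream = 200,
                             introns = TRUE) {
  if (nrow(genes) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), kind = character(0)))
  tss <- gene_tss(genes)
  win_start <- ifelse(genes$strand == "+", tss - upstream, tss - downstream)
  win_end <- ifelse(genes$strand == "+", tss + downstream, tss + upstream)
  out <- data.frame(chrom = genes$chrom, start = pmax(0L, as.integer(win_start)),
                    end = as.integer(win_end), kind = "window",
                    stringsAsFactors = FALSE)
  if (introns && nrow(genes)) {
    fi <- lapply(seq_len(nrow(genes)), function(i) {
      e <- genes$exons[[i]]
      if (nrow(e) < 2L) return(NULL)
      # first intron in transcription order: between exon 1 and 2 for "+",
      # between the last two exons (genomically) for "-"
      if (genes$strand[i] == "+") {
        data.frame(chrom = genes$chrom[i], start = e$end[1], end = e$start[2])
      } else {
        k <- nrow(e)
        data.frame(chrom = genes$chrom[i], start = e$end[k - 1], end = e$start[k])
      }
    })
    fi <- do.call(rbind, fi)
    if (!is.null(fi) && nrow(fi)) {
      fi$kind <- "first_intron"
      out <- rbind(out, fi)
    }
  }
  out
}

#' Pol III promoter regions around tRNA transcription starts
#'
#' @param trna `data.frame(chrom, pos, strand)` of tRNA TSS positions.
#' @param upstream,downstream window extents in bp.
#' @return `data.frame(chrom, start, end)`.
#' @export
pol3_promoter_regions <- function(trna, upstream = 2000, downstream = 200) {
  if (nrow(trna) == 0L)
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  s <- ifelse(trna$strand == "+", trna$pos - upstream, trna$pos - downstream)
  e <- ifelse(trna$strand == "+", trna$pos + downstream, trna$pos + upstream)
  data.frame(chrom = as.character(trna$chrom), start = pmax(0L, as.integer(s)),
             end = as.integer(e), stringsAsFactors = FALSE)
}

#' Capped distance from peak midpoints to the closest TSS
#'
#' Minimum absolute distance from each peak's midpoint to any TSS on the same
#' chromosome, capped at `cap` bp; peaks on chromosomes without a TSS get the
#' cap. The cap limits the range of the feature.
#'
#' @param peaks interval frame.
#' @param genes `gene_models` frame (at least one gene).
#' @param cap maximum reported distance (default 20000).
#' @return numeric vector along peaks.
#' @export
tss_distance <- function(peaks, genes, cap = 20000) {
  if (nrow(genes) == 0L) stop("tss_distance needs at least one gene")
  tss <- gene_tss(genes)
  mid <- (peaks$start + peaks$end) %/% 2L
  out <- rep(as.numeric(cap), nrow(peaks))
  for (chr in unique(peaks$chrom)) {
    t_chr <- sort(tss[genes$chrom == chr])
    if (!length(t_chr)) next
    i <- which(peaks$chrom == chr)
    idx <- findInterval(mid[i], t_chr)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(t_chr))
    d <- pmin(abs(mid[i] - t_chr[lo]), abs(mid[i] - t_chr[hi]))
    out[i] <- pmin(d, cap)
  }
  out
}

# Observed/expected CpG ratio: obs = CpG dinucleotide count,
# exp = count(C) * count(G) / window length; 0/0 is treated as 0.
.cpg_oe <- function(n_cpg, n_c, n_g, len) {
  expec <- n_c * n_g / len
  ifelse(expec > 0, n_cpg / expec, 0)
}

#' Classify a sequence as CpG-rich, CpG-poor or intermediate
#'
#' Rich: at least one 500 bp window with GC fraction > 0.55 and
#' observed/expected CpG ratio > 0.75. Poor: the whole region's
#' observed/expected CpG ratio < 0.48 and no window qualifies as rich.
#' Otherwise intermediate. Sequences shorter than the window are evaluated
#' as a single full-length window. `N` bases count as non-G/C and never form
#' a CpG.
#'
#' @param sequence DNA string over `A,C,G,T,N` (case-insensitive).
#' @param window window length in bp (default 500).
#' @param step window step for the scan in bp (default 10).
#' @param gc_min,oe_rich,oe_poor the thresholds (defaults 0.55, 0.75, 0.48).
#' @return character scalar: `"rich"`, `"poor"` or `"intermediate"`.
#' @export
classify_cpg <- function(sequence, window = 500, step = 10,
                         gc_min = 0.55, oe_rich = 0.75, oe_poor = 0.48) {
  st <- cpg_stats(sequence, window = window, step = step, gc_min = gc_min,
                  oe_rich = oe_rich)
  if (st$any_rich) "rich"
  else if (st$region_oe < oe_poor) "poor"
  else "intermediate"
}

#' Window-scan CpG statistics of a sequence
#'
#' @inheritParams classify_cpg
#' @return list with `region_gc`, `region_oe` (whole-sequence values),
#'   `any_rich` (did any window pass both rich thresholds) and `n_windows`.
#' @export
cpg_stats <- function(sequence, window = 500, step = 10,
                      gc_min = 0.55, oe_rich = 0.75) {
  s <- toupper(sequence)
  len <- nchar(s)
  if (len == 0L) stop("empty sequence")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  is_c <- ch == "C"; is_g <- ch == "G"
  is_cpg <- c(is_c[-len] & is_g[-1], FALSE)
  cum_c <- cumsum(is_c); cum_g <- cumsum(is_g); cum_cpg <- cumsum(is_cpg)
  tot <- function(cum, a, b) cum[b] - if (a > 1L) cum[a - 1L] else 0
  region_gc <- (cum_c[len] + cum_g[len]) / len
  region_oe <- .cpg_oe(cum_cpg[len], cum_c[len], cum_g[len], len)
  if (len <= window) {
    any_rich <- region_gc > gc_min && region_oe > oe_rich
    return(list(region_gc = region_gc, region_oe = region_oe,
                any_rich = any_rich, n_windows = 1L))
  }
  starts <- unique(c(seq(1L, len - window + 1L, by = step), len - window + 1L))
  any_rich <- FALSE
  for (a in starts) {
    b <- a + window - 1L
    gc <- (tot(cum_c, a, b) + tot(cum_g, a, b)) / window
    if (gc <= gc_min) next
    # CpG dinucleotides fully inside the window: positions a..b-1
    n_cpg <- tot(cum_cpg, a, b - 1L)
    oe <- .cpg_oe(n_cpg, tot(cum_c, a, b), tot(cum_g, a, b), window)
    if (oe > oe_rich) { any_rich <- TRUE; break }
  }
  list(region_gc = region_gc, region_oe = region_oe,
       any_rich = any_rich, n_windows = length(starts))
}

#' Does each peak overlap a region set?
#'
#' @param peaks interval frame.
#' @param regions interval frame (e.g. from [promoter_regions()]).
#' @return logical vector along peaks: overlap by >= 1 bp.
#' @export
in_region <- function(peaks, regions) {
  overlaps_any(peaks, regions)
}

#' Promoters of housekeeping genes
#'
#' [promoter_regions()] restricted to genes whose symbol appears in a
#' housekeeping list; symbol matching is case-insensitive.
#'
#' @param genes `gene_models` frame.
#' @param hk_symbols character vector of housekeeping gene symbols.
#' @param ... passed to [promoter_regions()].
#' @return `data.frame(chrom, start, end, kind)`.
#' @export
housekeeping_promoters <- function(genes, hk_symbols, ...) {
  keep <- toupper(genes$symbol) %in% toupper(hk_symbols)
  promoter_regions(genes[keep, , drop = FALSE], ...)
}
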