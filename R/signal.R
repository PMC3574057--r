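#' Per-region quantification of sequencing tracks
#'
#' Tag sets hold aligned-read footprints plus the total tag count of the
#' experiment; signal tracks hold sorted non-overlapping value segments
#' (bedGraph semantics), used for conservation scores.
#'
#' @name signal
NULL

#' Construct a tag set
#'
#' @param tags `data.frame(chrom, start, end)` of read footprints (storage
#'   may be restricted to regions of interest).
#' @param total_tags total number of tags in the experiment; must be at
#'   least the number stored.
#' @return list of class `tag_set`.
#' @export
tag_set <- function(tags, total_tags) {
  tags <- as.data.frame(tags)[, c("chrom", "start", "end")]
  tags$start <- as.integer(tags$start)
  tags$end <- as.integer(tags$end)
  if (total_tags < nrow(tags))
    stop("total_tags smaller than the number of stored tags")
  structure(list(tags = tags, total_tags = as.numeric(total_tags)),
            class = "tag_set")
}

#' Construct a signal track
#'
#' @param segments `data.frame(chrom, start, end, value)`; sorted by
#'   (chrom, start) on construction; overlapping segments are rejected.
#' @return `data.frame` of class `signal_track`.
#' @export
signal_track <- function(segments) {
  seg <- as.data.frame(segments)[, c("chrom", "start", "end", "value")]
  seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]
  rownames(seg) <- NULL
  by_chr <- split(seq_len(nrow(seg)), seg$chrom)
  for (i in by_chr) {
    if (length(i) > 1L && any(seg$start[i][-1] < seg$end[i][-length(i)]))
      stop("overlapping signal segments")
  }
  class(seg) <- c("signal_track", "data.frame")
  seg
}

#' Length- and depth-normalised tag signal over regions
#'
#' For each region: the number of tags overlapping it, divided by the region
#' length in bp and by the total tag count in millions (reads-per-million
#' per bp).
#'
#' @param tags a [tag_set()].
#' @param regions interval frame.
#' @return numeric vector along regions.
#' @export
region_signal <- function(tags, regions) {
  if (tags$total_tags <= 0) stop("total_tags must be positive")
  n <- region_tag_counts(tags, regions)
  n / (regions$end - regions$start) / (tags$total_tags / 1e6)
}

#' Raw tag counts over regions
#'
#' @inheritParams region_signal
#' @return integer vector: tags overlapping each region by >= 1 bp.
#' @export
region_tag_counts <- function(tags, regions) {
  out <- integer(nrow(regions))
  if (nrow(tags$tags) == 0L || nrow(regions) == 0L) return(out)
  h <- .overlap_hits(regions, tags$tags)
  tb <- table(h$query)
  out[as.integer(names(tb))] <- as.integer(tb)
  out
}

#' Average and difference of two cell types' signals
#'
#' @param value_a reference cell type signal(s).
#' @param value_b comparison cell type signal(s).
#' @return `data.frame(avg, diff)` with `avg = (a + b) / 2` and
#'   `diff = a - b` (reference minus comparison).
#' @export
signal_avg_diff <- function(value_a, value_b) {
  data.frame(avg = (value_a + value_b) / 2, diff = value_a - value_b)
}

#' Length-weighted conservation score over regions
#'
#' Weighted average of all track values overlapping each region, each value
#' weighted by the length of its overlap with the region. Regions with no
#' overlapping segment score 0 and are flagged.
#'
#' @param track a [signal_track()].
#' @param regions interval frame.
#' @return `data.frame(score, covered)`; `covered` FALSE marks the
#'   no-coverage fallback value of 0.
#' @export
phylop_region_score <- function(track, regions) {
  score <- numeric(nrow(regions))
  wsum <- numeric(nrow(regions))
  if (nrow(track) && nrow(regions)) {
    h <- .overlap_hits(regions, track)
    if (length(h$query)) {
      ov <- pmin(regions$end[h$query], track$end[h$subject]) -
        pmax(regions$start[h$query], track$start[h$subject])
      num <- rowsum(track$value[h$subject] * ov, h$query)
      den <- rowsum(as.numeric(ov), h$query)
      idx <- as.integer(rownames(num))
      score[idx] <- num[, 1] / den[, 1]
      wsum[idx] <- den[, 1]
    }
  }
  data.frame(score = score, covered = wsum > 0)
}

#' GC fraction of sequences
#'
#' `(G + C) / length`; `N` bases are excluded from the numerator but count
#' in the denominator.
#'
#' @param sequences character vector of DNA strings.
#' @return numeric vector of fractions.
#' @export
gc_fraction <- function(sequences) {
  if (any(nchar(sequences) == 0L)) stop("empty sequence")
  s <- toupper(sequences)
  gc <- nchar(gsub("[^GC]", "", s))
  gc / nchar(s)
}

#' Exon-based expression of a transcript
#'
#' Mean over exons of count / exon length, divided by the total read count
#' in millions.
#'
#' @param exon_counts reads per exon.
#' @param exon_lengths exon lengths in bp (all > 0).
#' @param total_reads total reads in the experiment (> 0).
#' @return numeric scalar.
#' @export
transcript_expression <- function(exon_counts, exon_lengths, total_reads) {
  if (total_reads <= 0) stop("total_reads must be positive")
  if (any(exon_lengths <= 0)) stop("exon lengths must be positive")
  mean(exon_counts / exon_lengths) / (total_reads / 1e6)
}

#' Per-symbol expression from transcript-level counts
#'
#' Transcript values are computed with [transcript_expression()] and averaged
#' per gene symbol over transcripts with at least one exonic read;
#' transcripts with zero exonic reads are excluded from the average.
#'
#' @param transcripts list of `list(symbol, exon_counts, exon_lengths)`.
#' @param total_reads total reads in the experiment.
#' @return named numeric vector, one value per symbol that had any
#'   expressed transcript.
#' @export
gene_expression <- function(transcripts, total_reads) {
  vals <- lapply(transcripts, function(tr) {
    if (sum(tr$exon_counts) < 1) return(NULL)
    data.frame(symbol = tr$symbol,
               value = transcript_expression(tr$exon_counts, tr$exon_lengths,
                                             total_reads))
  })
  vals <- do.call(rbind, vals)
  if (is.null(vals)) return(stats::setNames(numeric(0), character(0)))
  out <- tapply(vals$value, vals$symbol, mean)
  stats::setNames(as.numeric(out), names(out))
}

#' Bounded normalised difference
#'
#' `(a - b) / (a + b)`, mapping non-negative pairs into `[-1, 1]`.
#'
#' @param a,b non-negative numerics with `a + b > 0` elementwise.
#' @return numeric vector in `[-1, 1]`.
#' @export
normalized_difference <- function(a, b) {
  if (any(a < 0 | b < 0)) stop("inputs must be non-negative")
  if (any(a + b == 0)) stop("normalized difference undefined when a + b == 0")
  (a - b) / (a + b)
}
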