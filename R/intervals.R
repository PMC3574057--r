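#' Peak and interval primitives
#'
#' Genomic intervals use the BED convention throughout: 0-based starts,
#' half-open `[start, end)`. Two intervals overlap when they share at least
#' one base, i.e. `max(start) < min(end)` on the same chromosome.
#'
#' @name intervals
NULL

#' Construct a set of ChIP-seq peaks
#'
#' A peak set is a plain `data.frame` with one row per called peak region and
#' the columns `chrom`, `start`, `end`, `peak_id`, `height`, `tf`,
#' `cell_type`. `height` is the tag count supporting the peak (the number of
#' reads mapping to the region).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; 0-based half-open coordinates.
#' @param height non-negative integer tag counts.
#' @param tf transcription-factor label (recycled if scalar).
#' @param cell_type cell-type label (recycled if scalar).
#' @param peak_id unique identifiers; generated when missing.
#' @return a `data.frame` of class `peak_set`.
#' @export
peak_set <- function(chrom, start, end, height, tf, cell_type, peak_id = NULL) {
  n <- length(start)
  if (is.null(peak_id)) peak_id <- sprintf("pk%06d", seq_len(n))
  ps <- data.frame(
    chrom = as.character(chrom), start = as.integer(start),
    end = as.integer(end), peak_id = as.character(peak_id),
    height = as.numeric(height),
    tf = rep_len(as.character(tf), n),
    cell_type = rep_len(as.character(cell_type), n),
    stringsAsFactors = FALSE
  )
  validate_peaks(ps)
  class(ps) <- c("peak_set", "data.frame")
  ps
}

validate_peaks <- function(ps) {
  stopifnot(is.data.frame(ps))
  need <- c("chrom", "start", "end", "peak_id", "height")
  miss <- setdiff(need, names(ps))
  if (length(miss))
    stop("peak set is missing columns: ", paste(miss, collapse = ", "))
  if (any(ps$start < 0)) stop("negative start coordinate")
  if (any(ps$end <= ps$start)) stop("empty or inverted interval (end <= start)")
  if (any(ps$height < 0)) stop("negative peak height")
  if (anyDuplicated(ps$peak_id)) stop("duplicated peak_id")
  invisible(ps)
}

# IRanges view of a BED-style interval frame (shift to 1-based closed).
.as_iranges <- function(x) IRanges::IRanges(start = x$start + 1L, end = x$end)

# Hits between two BED-style frames, chromosome-aware.
.overlap_hits <- function(a, b) {
  ia <- split(seq_len(nrow(a)), a$chrom)
  ib <- split(seq_len(nrow(b)), b$chrom)
  qi <- integer(0); si <- integer(0)
  for (chr in intersect(names(ia), names(ib))) {
    i <- ia[[chr]]; j <- ib[[chr]]
    h <- IRanges::findOverlaps(
      IRanges::IRanges(start = a$start[i] + 1L, end = a$end[i]),
      IRanges::IRanges(start = b$start[j] + 1L, end = b$end[j]))
    qi <- c(qi, i[S4Vectors::queryHits(h)])
    si <- c(si, j[S4Vectors::subjectHits(h)])
  }
  list(query = qi, subject = si)
}

#' Do two genomic intervals overlap?
#'
#' Vectorised over both arguments. Half-open intervals share a base iff
#' `max(start) < min(end)` on the same chromosome; abutting intervals do not
#' overlap.
#'
#' @param chrom_a,start_a,end_a first interval(s).
#' @param chrom_b,start_b,end_b second interval(s).
#' @return logical vector.
#' @export
intervals_overlap <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  chrom_a == chrom_b & pmax(start_a, start_b) < pmin(end_a, end_b)
}

#' Count query peaks overlapped by a target set
#'
#' Number of query peaks having at least one base in common with at least one
#' target peak; each query peak is counted at most once however many target
#' peaks it touches.
#'
#' @param query,target peak sets (or any interval `data.frame` with
#'   `chrom`/`start`/`end`).
#' @return integer count.
#' @export
count_overlapping <- function(query, target) {
  if (nrow(query) == 0L || nrow(target) == 0L) return(0L)
  length(unique(.overlap_hits(query, target)$query))
}

#' Per-peak overlap indicator
#'
#' @param query,target interval frames.
#' @return logical vector along `query` rows: does the peak overlap any
#'   target peak by >= 1 bp?
#' @export
overlaps_any <- function(query, target) {
  out <- logical(nrow(query))
  if (nrow(query) == 0L || nrow(target) == 0L) return(out)
  out[unique(.overlap_hits(query, target)$query)] <- TRUE
  out
}

#' Relative overlap of two peak sets
#'
#' The number of peaks in `setA` overlapping `setB` divided by the lesser of
#' the two set sizes. The ratio is reported literally and can exceed 1 when
#' several query peaks pile onto one target peak.
#'
#' @param setA,setB non-empty peak sets.
#' @return numeric fraction.
#' @export
relative_overlap <- function(setA, setB) {
  if (nrow(setA) == 0L || nrow(setB) == 0L)
    stop("relative overlap is undefined for empty peak sets")
  count_overlapping(setA, setB) / min(nrow(setA), nrow(setB))
}

#' Overlap counts after widening peaks
#'
#' Recounts `count_overlapping(setA, setB)` after extending every `setA` peak
#' by `e` bp in total (`e/2` to each side, clamped at coordinate 0) for each
#' requested extension. Counts are non-decreasing in the extension.
#'
#' @param setA,setB peak sets.
#' @param extensions non-negative total extensions in bp
#'   (default `c(0, 500, 1000, 4000, 10000)`).
#' @return named integer vector, one count per extension.
#' @export
windowed_overlap_counts <- function(setA, setB,
                                    extensions = c(0, 500, 1000, 4000, 10000)) {
  if (any(extensions < 0)) stop("extensions must be non-negative")
  vapply(extensions, function(e) {
    half <- floor(e / 2)
    wide <- setA
    wide$start <- pmax(0L, setA$start - half)
    wide$end <- setA$end + half
    count_overlapping(wide, setB)
  }, integer(1)) |> stats::setNames(as.character(extensions))
}

# Symmetric extension of peaks to a total footprint, clamped at 0.
# Peaks already >= target_length are left untouched; an odd remainder
# goes to the right side.
.extend_to_length <- function(x, target_length) {
  len <- x$end - x$start
  extra <- pmax(0L, as.integer(target_length) - len)
  left <- extra %/% 2L
  x$start <- pmax(0L, x$start - left)
  x$end <- x$end + (extra - left)
  x
}

#' Cluster peaks across transcription factors
#'
#' Pools peaks (any TF, one cell type), extends each to a total footprint of
#' `target_length` bp (half per side) and links peaks whose extended regions
#' share a base. Clusters are the connected components of that link graph,
#' i.e. the transitive closure of pairwise extended overlap.
#'
#' @param peaks a `data.frame` of peaks from one cell type, any number of TFs.
#' @param target_length total extended footprint in bp (default 2000).
#' @return `data.frame` along `peaks` rows with columns `cluster_id`,
#'   `cluster_n_peaks`, `cluster_tfs` (distinct TF count) and
#'   `cluster_avg_height` (mean member height).
#' @export
cluster_peaks <- function(peaks, target_length = 2000) {
  n <- nrow(peaks)
  if (n == 0L)
    return(data.frame(cluster_id = integer(0), cluster_n_peaks = integer(0),
                      cluster_tfs = integer(0), cluster_avg_height = numeric(0)))
  if (length(unique(peaks$cell_type)) > 1L)
    stop("cluster_peaks expects peaks from a single cell type")
  ext <- .extend_to_length(peaks, target_length)
  cid <- integer(n)
  for (chr in unique(ext$chrom)) {
    i <- which(ext$chrom == chr)
    r <- IRanges::IRanges(start = ext$start[i] + 1L, end = ext$end[i])
    # overlapping extended intervals merge into one reduced range = component
    red <- IRanges::reduce(r)
    comp <- S4Vectors::subjectHits(IRanges::findOverlaps(r, red))
    cid[i] <- max(cid) + comp
  }
  cid <- match(cid, unique(cid[order(peaks$chrom, peaks$start)]))
  npk <- as.integer(ave(cid, cid, FUN = length))
  ntf <- as.integer(ave(seq_len(n), cid,
                        FUN = function(i) length(unique(peaks$tf[i]))))
  avg <- ave(peaks$height, cid, FUN = mean)
  data.frame(cluster_id = cid, cluster_n_peaks = npk,
             cluster_tfs = ntf, cluster_avg_height = avg)
}
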