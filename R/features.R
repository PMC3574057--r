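#' Assembling the classifier feature vectors
#'
#' Gathers the 16 per-peak features (plus the auxiliary PWM score used by
#' the `hpp` model) from the annotation, signal, clustering and motif
#' providers.
#'
#' @name features
NULL

#' Extract peak sequences from a genome
#'
#' @param peaks interval frame.
#' @param genome named character vector of chromosome sequences.
#' @return character vector of peak-region sequences.
#' @export
peak_sequences <- function(peaks, genome) {
  miss <- setdiff(unique(peaks$chrom), names(genome))
  if (length(miss)) stop("genome is missing chromosome(s): ",
                         paste(miss, collapse = ", "))
  substring(genome[peaks$chrom], peaks$start + 1L, peaks$end)
}

#' Bundle the feature providers for one cell-type comparison
#'
#' @param genes a [gene_models()] frame.
#' @param genome named character vector of chromosome sequences.
#' @param tags nested list `tags[[mark]][[cell]]` of [tag_set()]s with marks
#'   `dnase`, `h3k4me3`, `h3k27me3` and the two cell types as inner names.
#' @param conservation a [signal_track()] of conservation scores.
#' @param cell_ref,cell_cmp reference and comparison cell-type names (must
#'   index the inner tag lists).
#' @param pwms named list of [pwm()]s keyed by TF (optional; TFs without an
#'   entry get `NA` PWM scores).
#' @param background base frequencies for [logodds_matrix()]; computed from
#'   the genome when omitted.
#' @param promoters optional precomputed promoter regions (defaults to
#'   [promoter_regions()] of `genes`).
#' @return list of class `feature_context`.
#' @export
feature_context <- function(genes, genome, tags, conservation, cell_ref,
                            cell_cmp, pwms = NULL, background = NULL,
                            promoters = NULL) {
  for (mark in c("dnase", "h3k4me3", "h3k27me3")) {
    if (!all(c(cell_ref, cell_cmp) %in% names(tags[[mark]])))
      stop("tag sets for mark '", mark, "' must cover both cell types")
  }
  if (is.null(promoters)) promoters <- promoter_regions(genes)
  if (is.null(background) && !is.null(pwms))
    background <- genome_background(genome)
  structure(list(genes = genes, genome = genome, tags = tags,
                 conservation = conservation, cell_ref = cell_ref,
                 cell_cmp = cell_cmp, pwms = pwms, background = background,
                 promoters = promoters),
            class = "feature_context")
}

#' Assemble the per-peak feature vectors
#'
#' Computes, for every peak of one reference (TF, cell type) set: height
#' percentile; region length; promoter overlap; capped TSS distance;
#' cluster distinct-TF count and average height (peaks outside any
#' multi-peak cluster count as their own singleton cluster); average and
#' difference of the DNase, H3K4me3 and H3K27me3 signals between the two
#' cell types; CpG observed/expected frequency with the high/low CpG
#' indicators; and the length-weighted conservation score. When the context
#' carries a PWM for the peak's TF, the best both-strand log-odds score of
#' the peak sequence is attached as `pwm_score` (`NA` otherwise).
#'
#' @param peaks a peak frame for one (TF, cell type).
#' @param cluster_info per-peak cluster columns from [cluster_peaks()] run
#'   on the pooled peaks of all TFs, subset to `peaks` rows.
#' @param context a [feature_context()].
#' @return `data.frame` with the 16 canonical feature columns plus
#'   `pwm_score`; attribute `phylop_covered` flags peaks with conservation
#'   coverage.
#' @export
assemble_features <- function(peaks, cluster_info, context) {
  stopifnot(inherits(context, "feature_context"))
  if (nrow(cluster_info) != nrow(peaks))
    stop("cluster_info must align with peaks")
  seqs <- peak_sequences(peaks, context$genome)
  sig <- function(mark, cell) region_signal(context$tags[[mark]][[cell]], peaks)
  dn <- signal_avg_diff(sig("dnase", context$cell_ref),
                        sig("dnase", context$cell_cmp))
  k4 <- signal_avg_diff(sig("h3k4me3", context$cell_ref),
                        sig("h3k4me3", context$cell_cmp))
  k27 <- signal_avg_diff(sig("h3k27me3", context$cell_ref),
                         sig("h3k27me3", context$cell_cmp))
  cpg <- lapply(seqs, cpg_stats)
  cpg_class <- vapply(seqs, classify_cpg, character(1), USE.NAMES = FALSE)
  ph <- phylop_region_score(context$conservation, peaks)
  out <- data.frame(
    height_pct = height_percentiles(peaks$height),
    length = peaks$end - peaks$start,
    promoter = as.integer(in_region(peaks, context$promoters)),
    tss_dist = tss_distance(peaks, context$genes),
    cluster_tfs = cluster_info$cluster_tfs,
    cluster_avg_height = cluster_info$cluster_avg_height,
    chromatin_avg = dn$avg, chromatin_diff = dn$diff,
    h3k4me3_avg = k4$avg, h3k4me3_diff = k4$diff,
    h3k27me3_avg = k27$avg, h3k27me3_diff = k27$diff,
    cpg_freq = vapply(cpg, `[[`, numeric(1), "region_oe"),
    high_cpg = as.integer(cpg_class == "rich"),
    low_cpg = as.integer(cpg_class == "poor"),
    phylop = ph$score
  )
  tf <- unique(peaks$tf)
  out$pwm_score <- NA_real_
  if (length(tf) == 1L && !is.null(context$pwms) && tf %in% names(context$pwms)) {
    mat <- logodds_matrix(context$pwms[[tf]], context$background)
    out$pwm_score <- vapply(seqs, function(s) {
      if (nchar(s) < ncol(mat)) return(NA_real_)
      max_pwm_score(mat, s)$score
    }, numeric(1), USE.NAMES = FALSE)
  }
  rownames(out) <- peaks$peak_id
  attr(out, "phylop_covered") <- ph$covered
  out
}
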