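#' Genotype-difference analysis of peak SNPs
#'
#' Works downstream of genotype calling: selects SNPs called homozygous for
#' different alleles in the two cell types, rescans peak motifs under each
#' genotype, and runs the paired one-sided test of whether the peak-bearing
#' cell type's genotype scores higher.
#'
#' @name genotype
NULL

#' Construct SNP records
#'
#' Genotype coding follows the peak+SNP exchange format: 0 = homozygous for
#' the reference allele, 1 = homozygous for the alternate allele, NA =
#' missing or heterozygous call.
#'
#' @param snp_id identifiers.
#' @param chrom,pos chromosome and 0-based position.
#' @param ref_allele,alt_allele bases in A, C, G, T (multi-allelic records
#'   are rejected).
#' @param gt_a,gt_b genotype per cell type (0/1/NA).
#' @param Q genotyping quality score.
#' @param AF alternate allele frequency in `[0, 1]`.
#' @param DP read depth at the position.
#' @param peak_id optional containing-peak identifier.
#' @return `data.frame` of class `snp_records`.
#' @export
snp_records <- function(snp_id, chrom, pos, ref_allele, alt_allele,
                        gt_a, gt_b, Q = NA_real_, AF = NA_real_,
                        DP = NA_integer_, peak_id = NA_character_) {
  ref_allele <- toupper(ref_allele); alt_allele <- toupper(alt_allele)
  if (!all(ref_allele %in% .BASES) || !all(alt_allele %in% .BASES))
    stop("alleles must be single bases in A, C, G, T (multi-allelic rejected)")
  if (any(!is.na(AF) & (AF < 0 | AF > 1))) stop("AF outside [0, 1]")
  if (any(!is.na(DP) & DP < 0)) stop("negative DP")
  x <- data.frame(snp_id = as.character(snp_id), chrom = as.character(chrom),
                  pos = as.integer(pos), ref_allele, alt_allele,
                  gt_a = as.integer(gt_a), gt_b = as.integer(gt_b),
                  Q = as.numeric(Q), AF = as.numeric(AF), DP = as.integer(DP),
                  peak_id = as.character(peak_id), stringsAsFactors = FALSE)
  class(x) <- c("snp_records", "data.frame")
  x
}

#' Select homozygous-different SNPs
#'
#' SNPs whose two cell-type genotypes are both confident homozygous calls
#' and differ (one reference-homozygous, the other alternate-homozygous).
#' Records with a missing genotype are skipped with a warning; calls below
#' the quality threshold are excluded.
#'
#' @param snps a [snp_records()] frame.
#' @param min_q minimum genotyping quality (default 20); `NA` quality passes.
#' @return the selected subset.
#' @export
select_homozygous_different <- function(snps, min_q = 20) {
  missing_gt <- is.na(snps$gt_a) | is.na(snps$gt_b)
  if (any(missing_gt))
    warning(sum(missing_gt), " SNP record(s) with missing genotype skipped")
  ok_q <- is.na(snps$Q) | snps$Q >= min_q
  keep <- !missing_gt & ok_q & snps$gt_a != snps$gt_b
  snps[keep, , drop = FALSE]
}

#' Resolve a genotype code to its allele
#'
#' @param snps a [snp_records()] frame.
#' @param genotype vector of 0/1 codes along `snps`.
#' @return character vector of bases.
#' @export
genotype_allele <- function(snps, genotype) {
  ifelse(genotype == 0L, snps$ref_allele, snps$alt_allele)
}

#' Is a SNP inside the best-scoring motif window?
#'
#' TRUE iff the SNP offset falls within the forward-strand footprint
#' `[offset, offset + width)` of the best hit of [max_pwm_score()] on the
#' peak sequence. Returns FALSE (with attribute `no_hit = TRUE`) when no
#' valid window exists.
#'
#' @param peak_sequence DNA string of the peak region.
#' @param mat log-odds matrix.
#' @param snp_offset 0-based position of the SNP within the sequence.
#' @return logical scalar.
#' @export
snp_in_best_motif <- function(peak_sequence, mat, snp_offset) {
  if (snp_offset < 0 || snp_offset >= nchar(peak_sequence))
    stop("snp_offset outside the sequence")
  hit <- max_pwm_score(mat, peak_sequence)
  if (is.na(hit$score))
    return(structure(FALSE, no_hit = TRUE))
  snp_offset >= hit$offset && snp_offset < hit$offset + hit$width
}

#' Motif score of a peak under one genotype
#'
#' Substitutes that genotype's alleles at all its homozygous SNP positions
#' within the peak sequence and rescans for the best hit.
#'
#' @param peak_sequence DNA string.
#' @param mat log-odds matrix.
#' @param offsets 0-based SNP positions within the sequence.
#' @param alleles bases carried by the genotype at those positions.
#' @return a `motif_hit`.
#' @export
genotype_motif_score <- function(peak_sequence, mat, offsets, alleles) {
  s <- peak_sequence
  for (i in seq_along(offsets)) {
    s <- paste0(substr(s, 1, offsets[i]), toupper(alleles[i]),
                substr(s, offsets[i] + 2, nchar(s)))
  }
  max_pwm_score(mat, s)
}

#' Paired one-sided test of genotype motif scores
#'
#' Tests whether peaks score higher under the genotype of the cell type that
#' carries the peak than under the other cell type's genotype, by a paired
#' one-sided t-test on `score_own - score_other`. Also reports how many
#' pairs scored higher under each genotype.
#'
#' @param score_own motif score under the peak-bearing cell type's genotype.
#' @param score_other score under the other cell type's genotype.
#' @return list: `t`, `p` (one-sided, own > other), `n`, `n_own_higher`,
#'   `n_other_higher`, `mean_diff`, `degenerate` (TRUE when every
#'   difference is zero or fewer than 2 pairs; then `p = 1`).
#' @export
genotype_motif_test <- function(score_own, score_other) {
  stopifnot(length(score_own) == length(score_other))
  d <- score_own - score_other
  res <- list(n = length(d),
              n_own_higher = sum(d > 0), n_other_higher = sum(d < 0),
              mean_diff = mean(d))
  if (length(d) < 2L || stats::sd(d) == 0) {
    res$t <- NA_real_; res$p <- 1; res$degenerate <- TRUE
    return(res)
  }
  tt <- stats::t.test(score_own, score_other, paired = TRUE,
                      alternative = "greater")
  res$t <- unname(tt$statistic); res$p <- tt$p.value; res$degenerate <- FALSE
  res
}

#' Correlation of height differences with genotype motif-score differences
#'
#' Pearson correlation (with its two-sided t-based p-value) between the
#' between-cell-type difference in peak height and the between-genotype
#' difference in motif score, over peaks common to both cell types.
#'
#' @param delta_height per-peak height difference between cell types.
#' @param delta_score per-peak motif-score difference between genotypes.
#' @return list `r`, `p`, `n`, `degenerate` (zero variance in a margin).
#' @export
height_motifscore_correlation <- function(delta_height, delta_score) {
  stopifnot(length(delta_height) == length(delta_score))
  if (length(delta_height) < 3L) stop("need at least 3 pairs")
  if (stats::sd(delta_height) == 0 || stats::sd(delta_score) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(delta_height),
                degenerate = TRUE))
  ct <- stats::cor.test(delta_height, delta_score)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(delta_height),
       degenerate = FALSE)
}

#' Per-category SNP summary over peaks
#'
#' For each overlap category (common, specific per cell type): the fraction
#' of peaks harbouring at least one SNP and, among those SNPs, the fraction
#' called homozygous-different.
#'
#' @param peak_category named character vector (names = peak_id) giving each
#'   peak's category.
#' @param snps a [snp_records()] frame with `peak_id` filled in.
#' @param min_q quality threshold passed to
#'   [select_homozygous_different()].
#' @return `data.frame(category, n_peaks, n_with_snp, frac_with_snp,
#'   n_snps, frac_homo_diff)`.
#' @export
snp_peak_summary <- function(peak_category, snps, min_q = 20) {
  hd <- suppressWarnings(select_homozygous_different(snps, min_q = min_q))
  cats <- unique(peak_category)
  rows <- lapply(cats, function(cat) {
    ids <- names(peak_category)[peak_category == cat]
    in_cat <- snps$peak_id %in% ids
    n_with <- length(unique(snps$peak_id[in_cat]))
    n_snps <- sum(in_cat)
    data.frame(category = cat, n_peaks = length(ids), n_with_snp = n_with,
               frac_with_snp = if (length(ids)) n_with / length(ids) else 0,
               n_snps = n_snps,
               frac_homo_diff = if (n_snps) sum(hd$peak_id %in% ids) / n_snps
                                else 0)
  })
  do.call(rbind, rows)
}

#' Build genotype motif-score pairs for cell-type specific peaks
#'
#' For every reference peak labelled `specific` that carries at least one
#' homozygous-different SNP: the peak sequence is rewritten under each
#' genotype (that genotype's alleles substituted at all its
#' homozygous-different SNP positions), rescanned with the TF's log-odds
#' matrix, and kept when at least one SNP falls inside the best-scoring
#' motif window of the own-genotype sequence.
#'
#' @param peaks reference peak frame (one TF).
#' @param labels factor from [label_by_overlap()] along `peaks`.
#' @param snps a [snp_records()] frame with `peak_id` set; `gt_a` is the
#'   reference (peak-bearing) cell type's genotype.
#' @param genome named chromosome sequences.
#' @param mat log-odds matrix of the peak TF's PWM.
#' @param min_q quality threshold for [select_homozygous_different()].
#' @param require_in_motif keep only peaks whose SNP hits the best motif
#'   window (default TRUE).
#' @return `data.frame(peak_id, n_snps, score_own, score_other)`.
#' @export
genotype_motif_pairs <- function(peaks, labels, snps, genome, mat,
                                 min_q = 20, require_in_motif = TRUE) {
  hd <- suppressWarnings(select_homozygous_different(snps, min_q = min_q))
  sp <- which(labels == "specific" & peaks$peak_id %in% hd$peak_id)
  rows <- lapply(sp, function(i) {
    s <- peak_sequences(peaks[i, , drop = FALSE], genome)
    if (nchar(s) < ncol(mat)) return(NULL)
    snp_i <- hd[hd$peak_id == peaks$peak_id[i], , drop = FALSE]
    offs <- snp_i$pos - peaks$start[i]
    ok <- offs >= 0 & offs < nchar(s)
    snp_i <- snp_i[ok, , drop = FALSE]; offs <- offs[ok]
    if (!nrow(snp_i)) return(NULL)
    own_al <- genotype_allele(snp_i, snp_i$gt_a)
    oth_al <- genotype_allele(snp_i, snp_i$gt_b)
    own <- genotype_motif_score(s, mat, offs, own_al)
    if (is.na(own$score)) return(NULL)
    if (require_in_motif &&
        !any(offs >= own$offset & offs < own$offset + own$width))
      return(NULL)
    oth <- genotype_motif_score(s, mat, offs, oth_al)
    data.frame(peak_id = peaks$peak_id[i], n_snps = nrow(snp_i),
               score_own = own$score, score_other = oth$score)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(peak_id = character(0), n_snps = integer(0),
                      score_own = numeric(0), score_other = numeric(0))
  out
}
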