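#' Combined peak+SNP table and the end-to-end pipeline
#'
#' The exchange table has one row per peak across all cell types with
#' per-cell overlap flags, a promoter flag, and the peak's SNPs packed into
#' one field: SNPs are dash-separated, SNP attributes semicolon-separated
#' (`id;pos;ref;alt;gtA/gtB;Q;AF;DP`; missing genotypes as `.`). A
#' typographic minus in the dash role is normalised to ASCII hyphen-minus
#' on read.
#'
#' @name pipeline
NULL

.pack_snps <- function(snps) {
  if (is.null(snps) || nrow(snps) == 0L) return(".")
  gt <- function(g) ifelse(is.na(g), ".", as.character(g))
  paste(sprintf("%s;%d;%s;%s;%s/%s;%s;%s;%s", snps$snp_id, snps$pos,
                snps$ref_allele, snps$alt_allele, gt(snps$gt_a),
                gt(snps$gt_b), snps$Q, snps$AF, snps$DP),
        collapse = "-")
}

.unpack_snps <- function(field, peak_id) {
  field <- gsub("−", "-", field)
  if (is.na(field) || field == "." || !nzchar(field)) return(NULL)
  parts <- strsplit(field, "-", fixed = TRUE)[[1]]
  rows <- lapply(parts, function(p) {
    at <- strsplit(p, ";", fixed = TRUE)[[1]]
    if (length(at) != 8L) return(NULL)
    gt <- strsplit(at[5], "/", fixed = TRUE)[[1]]
    gt <- suppressWarnings(as.integer(gt))
    snp_records(snp_id = at[1], chrom = NA_character_,
                pos = as.integer(at[2]), ref_allele = at[3],
                alt_allele = at[4], gt_a = gt[1], gt_b = gt[2],
                Q = as.numeric(at[6]), AF = as.numeric(at[7]),
                DP = as.integer(at[8]), peak_id = peak_id)
  })
  bad <- vapply(rows, is.null, logical(1))
  structure(do.call(rbind, rows[!bad]), n_malformed = sum(bad))
}

#' Write the combined peak+SNP table
#'
#' @param peaks named list of peak frames per cell type (all TFs pooled).
#' @param snps optional [snp_records()] frame keyed by `peak_id`.
#' @param promoters optional promoter regions for the promoter flag.
#' @param path output TSV.
#' @export
write_peak_snp_file <- function(peaks, path, snps = NULL, promoters = NULL) {
  cells <- names(peaks)
  all_pk <- do.call(rbind, lapply(cells, function(cl)
    as.data.frame(peaks[[cl]])))
  flags <- lapply(cells, function(cl) {
    other <- as.data.frame(peaks[[cl]])
    vapply(seq_len(nrow(all_pk)), function(i) {
      same_tf <- other[other$tf == all_pk$tf[i], , drop = FALSE]
      if (all_pk$cell_type[i] == cl) 1L
      else as.integer(overlaps_any(all_pk[i, , drop = FALSE], same_tf))
    }, integer(1))
  })
  prom_flag <- if (is.null(promoters)) rep(0L, nrow(all_pk)) else
    as.integer(in_region(all_pk, promoters))
  snp_field <- vapply(all_pk$peak_id, function(id) {
    .pack_snps(if (is.null(snps)) NULL else
      snps[snps$peak_id == id, , drop = FALSE])
  }, character(1))
  out <- data.frame(peakID = all_pk$peak_id, cellType = all_pk$cell_type,
                    TF = all_pk$tf, chromosome = all_pk$chrom,
                    peakStart = all_pk$start, peakStop = all_pk$end,
                    height = all_pk$height, stringsAsFactors = FALSE)
  for (j in seq_along(cells)) out[[paste0("overlap", cells[j])]] <- flags[[j]]
  out$overlapPromoter <- prom_flag
  out$SNPs <- snp_field
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read the combined peak+SNP table
#'
#' @param path TSV written by [write_peak_snp_file()] (or the published
#'   three-cell-type layout; overlap columns are discovered from the
#'   header).
#' @return list: `peaks` (named list of peak frames per cell type),
#'   `overlap` (flag data.frame), `snps` ([snp_records()] frame; SNP
#'   chromosomes filled from their peaks), `errors` (count of malformed SNP
#'   entries).
#' @export
read_peak_snp_file <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, comment.char = "",
                         check.names = FALSE)
  need <- c("peakID", "cellType", "TF", "chromosome", "peakStart",
            "peakStop", "height", "SNPs")
  if (!all(need %in% names(x)))
    stop(path, ": unparseable header; expected columns ",
         paste(need, collapse = ", "))
  .check_coords(x$peakStart, x$peakStop, path)
  cells <- sub("^overlap", "",
               setdiff(grep("^overlap", names(x), value = TRUE),
                       "overlapPromoter"))
  peaks <- lapply(split(seq_len(nrow(x)), x$cellType), function(i)
    peak_set(x$chromosome[i], x$peakStart[i], x$peakStop[i],
             height = x$height[i], tf = x$TF[i],
             cell_type = x$cellType[i][1], peak_id = x$peakID[i]))
  n_bad <- 0L
  snps <- do.call(rbind, lapply(seq_len(nrow(x)), function(i) {
    s <- .unpack_snps(x$SNPs[i], x$peakID[i])
    if (!is.null(s)) {
      n_bad <<- n_bad + attr(s, "n_malformed")
      s$chrom <- x$chromosome[i]
    }
    s
  }))
  ov <- x[, c("peakID", "cellType", "TF",
              grep("^overlap", names(x), value = TRUE)), drop = FALSE]
  list(peaks = peaks, overlap = ov, snps = snps, errors = n_bad)
}

# stable small hash for run provenance (polynomial rolling hash mod 2^31-1)
.config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a simulated study to an exchange directory
#'
#' Emits the formats the pipeline readers consume: `genome.fa`,
#' `genes.bed12`, `pwms.pfm`, `conservation.bedGraph`,
#' `tags_<mark>_<cell>.bed`, `expression_<cell>.tsv`,
#' `peaks_<cell>_<tf>.bed`, the combined `peaks_snps.tsv`, `truth.tsv` and
#' `study.json` (cell types, TFs, marks, seed).
#'
#' @param study a [simulate_peak_study()] result (level `"full"` for the
#'   sequence-dependent files).
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cells <- names(study$peaks)
  tfs <- unique(study$peaks$A$tf)
  for (cl in cells) for (tf in tfs) {
    pk <- study$peaks[[cl]]
    write_bed_peaks(pk[pk$tf == tf, , drop = FALSE],
                    file.path(dir, sprintf("peaks_%s_%s.bed", cl, tf)))
  }
  prom <- if (!is.null(study$genes)) promoter_regions(study$genes) else NULL
  write_peak_snp_file(study$peaks, file.path(dir, "peaks_snps.tsv"),
                      snps = study$snps, promoters = prom)
  if (!is.null(study$genes))
    write_bed12_genes(study$genes, file.path(dir, "genes.bed12"))
  for (cl in cells)
    write_expression(study$expression[[cl]],
                     file.path(dir, sprintf("expression_%s.tsv", cl)))
  utils::write.table(study$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(study$genome)) {
    write_fasta(study$genome, file.path(dir, "genome.fa"))
    write_pfm(study$pwms, file.path(dir, "pwms.pfm"))
    write_bedgraph(study$conservation, file.path(dir, "conservation.bedGraph"))
    for (mark in names(study$tags)) for (cl in cells)
      write_tagset(study$tags[[mark]][[cl]],
                   file.path(dir, sprintf("tags_%s_%s.bed", mark, cl)))
  }
  jsonlite::write_json(list(cells = cells, tfs = tfs,
                            marks = names(study$tags), seed = study$seed,
                            level = study$config$level),
                       file.path(dir, "study.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Run the full analysis pipeline on an exchange directory
#'
#' Stages, in order: overlap (relative and windowed overlap per TF),
#' clustering and feature assembly, height-binned trends, genotype
#' analysis, classification (all three models, stratified CV). Every
#' output file records the seed and a configuration hash; rerunning with
#' the same inputs and seed reproduces the files byte for byte.
#'
#' @param input_dir directory written by [write_simulation()] (or
#'   hand-assembled with the same file names).
#' @param out_dir results directory (created).
#' @param reference,comparison cell-type names (defaults `"A"`, `"B"`).
#' @param k cross-validation folds.
#' @param seed integer seed for fold assignment.
#' @param cost SVM cost.
#' @return named list of result file paths, invisibly.
#' @export
run_pipeline <- function(input_dir, out_dir, reference = "A",
                         comparison = "B", k = 10, seed = 1L, cost = 1) {
  meta <- jsonlite::read_json(file.path(input_dir, "study.json"),
                              simplifyVector = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(reference = reference, comparison = comparison, k = k,
              seed = seed, cost = cost, tfs = meta$tfs)
  tfs <- meta$tfs
  read_cell <- function(cl) {
    pk <- do.call(rbind, lapply(tfs, function(tf)
      as.data.frame(read_bed_peaks(
        file.path(input_dir, sprintf("peaks_%s_%s.bed", cl, tf)),
        tf = tf, cell_type = cl))))
    class(pk) <- c("peak_set", "data.frame")
    pk
  }
  ref <- read_cell(reference)
  cmp <- read_cell(comparison)

  ## stage 1: overlap
  overlap_rows <- lapply(tfs, function(tf) {
    a <- ref[ref$tf == tf, , drop = FALSE]
    b <- cmp[cmp$tf == tf, , drop = FALSE]
    wc <- windowed_overlap_counts(a, b)
    data.frame(tf = tf, n_ref = nrow(a), n_cmp = nrow(b),
               n_overlap = count_overlapping(a, b),
               relative_overlap = relative_overlap(a, b),
               t(as.matrix(stats::setNames(as.integer(wc),
                                           paste0("ext_", names(wc))))))
  })
  overlap_tab <- do.call(rbind, overlap_rows)
  utils::write.table(overlap_tab, file.path(out_dir, "overlap.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 2: clustering + features
  clusters <- cluster_peaks(ref)
  full <- identical(meta$level, "full")
  feats <- NULL; labels <- list()
  genes <- if (file.exists(file.path(input_dir, "genes.bed12")))
    read_bed12_genes(file.path(input_dir, "genes.bed12")) else NULL
  if (full) {
    genome <- read_fasta(file.path(input_dir, "genome.fa"))
    pwms <- select_pwms(read_pfm(file.path(input_dir, "pwms.pfm")))
    cons <- read_bedgraph(file.path(input_dir, "conservation.bedGraph"))
    tags <- lapply(stats::setNames(nm = meta$marks), function(mark)
      lapply(stats::setNames(nm = c(reference, comparison)), function(cl)
        read_tagset(file.path(input_dir,
                              sprintf("tags_%s_%s.bed", mark, cl)))))
    ctx <- feature_context(genes = genes, genome = genome, tags = tags,
                           conservation = cons, cell_ref = reference,
                           cell_cmp = comparison, pwms = pwms)
    feats <- lapply(stats::setNames(nm = tfs), function(tf) {
      sel <- ref$tf == tf
      a <- ref[sel, , drop = FALSE]
      fx <- assemble_features(a, clusters[sel, , drop = FALSE], ctx)
      utils::write.table(cbind(peak_id = a$peak_id, fx),
                         file.path(out_dir, sprintf("features_%s.tsv", tf)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      fx
    })
  }
  for (tf in tfs) {
    a <- ref[ref$tf == tf, , drop = FALSE]
    b <- cmp[cmp$tf == tf, , drop = FALSE]
    labels[[tf]] <- label_by_overlap(a, b)
  }
  lab_tab <- do.call(rbind, lapply(tfs, function(tf)
    data.frame(tf = tf, peak_id = ref$peak_id[ref$tf == tf],
               label = as.character(labels[[tf]]))))
  utils::write.table(lab_tab, file.path(out_dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## stage 3: trends
  trend_rows <- lapply(tfs, function(tf) {
    a <- ref[ref$tf == tf, , drop = FALSE]
    bins <- bin_by_height(a)
    vals <- list(overlap = as.numeric(labels[[tf]] == "common"),
                 cluster_tfs = clusters$cluster_tfs[ref$tf == tf])
    if (full) {
      fx <- feats[[tf]]
      for (v in c("promoter", "cpg_freq", "chromatin_avg", "h3k4me3_avg",
                  "phylop", "pwm_score"))
        if (!all(is.na(fx[[v]]))) vals[[v]] <- fx[[v]]
    }
    do.call(rbind, lapply(names(vals), function(v) {
      tr <- bin_trend(bins, vals[[v]])
      data.frame(tf = tf, feature = v, slope = tr$slope, p = tr$p,
                 significant = tr$significant)
    }))
  })
  utils::write.table(do.call(rbind, trend_rows),
                     file.path(out_dir, "trends.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## stage 4: genotype analysis
  geno <- list(available = FALSE)
  if (full) {
    ps <- read_peak_snp_file(file.path(input_dir, "peaks_snps.tsv"))
    if (!is.null(ps$snps)) {
      bg <- genome_background(genome)
      per_tf <- lapply(tfs, function(tf) {
        if (!tf %in% names(pwms)) return(NULL)
        a <- ref[ref$tf == tf, , drop = FALSE]
        genotype_motif_pairs(a, labels[[tf]], ps$snps, genome,
                             logodds_matrix(pwms[[tf]], bg))
      })
      pairs <- do.call(rbind, per_tf)
      if (!is.null(pairs) && nrow(pairs) >= 2L) {
        tst <- genotype_motif_test(pairs$score_own, pairs$score_other)
        geno <- c(list(available = TRUE, n_pairs = nrow(pairs)), tst)
      }
    }
  }
  jsonlite::write_json(geno, file.path(out_dir, "genotype.json"),
                       auto_unbox = TRUE, digits = NA)

  ## stage 5: classification
  cls <- list(available = full)
  if (full) {
    cls$per_tf <- lapply(stats::setNames(nm = tfs), function(tf) {
      y <- labels[[tf]]
      if (min(table(y)) < k) return(list(skipped = "class smaller than k"))
      out <- lapply(c("svm", "height", "hpp"), function(m) {
        cv <- specificity_cv(feats[[tf]], y, model = m, k = k, seed = seed,
                             cost = cost)
        list(mean_roc = cv$mean_auc, fold_roc = cv$fold_auc)
      })
      stats::setNames(out, c("svm", "height", "hpp"))
    })
  }
  jsonlite::write_json(cls, file.path(out_dir, "classify.json"),
                       auto_unbox = TRUE, digits = NA)

  ## provenance
  jsonlite::write_json(
    list(seed = seed, config_hash = .config_hash(cfg),
         version = as.character(utils::packageVersion("specpeak")),
         n_reference_peaks = nrow(ref), n_comparison_peaks = nrow(cmp)),
    file.path(out_dir, "pipeline.json"), auto_unbox = TRUE, digits = NA)
  invisible(stats::setNames(
    file.path(out_dir, c("overlap.tsv", "labels.tsv", "trends.tsv",
                         "genotype.json", "classify.json", "pipeline.json")),
    c("overlap", "labels", "trends", "genotype", "classify", "pipeline")))
}
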