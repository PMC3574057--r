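#' Synthetic paired-cell-type ChIP-seq study generator
#'
#' Generates, from explicit parameters and a single seed, everything the
#' analysis pipeline consumes: a genome, gene models, per-TF PWMs, peak
#' sets for two (optionally three) cell types, chromatin and histone tag
#' sets, a conservation track, SNP records, TF expression tables and a
#' ground-truth table. The statistical structure matches the assumptions
#' the analyses probe: the probability that a reference peak is common to
#' the other cell type follows a logistic model in height percentile and
#' cluster size; chromatin and active-histone tags are elevated in the cell
#' type carrying a peak; conservation is elevated at common peaks; and a
#' configurable fraction of cell-type specific peaks carry a
#' homozygous-different SNP that disrupts a planted high-scoring motif in
#' the partner genotype.
#'
#' @name simulate
NULL

#' Simulation configuration
#'
#' All probabilities, rates and effect sizes of the generator with their
#' default study conditions. Peak geometry uses a 500 bp slot grid so peak
#' regions never collide by construction; clusters emerge from multi-TF
#' loci occupying consecutive slots, extended-overlap chaining included.
#'
#' @param chrom_lengths named chromosome lengths in bp.
#' @param n_genes number of gene models.
#' @param n_tfs number of transcription factors.
#' @param peaks_per_tf peaks per TF per cell type; a vector is recycled
#'   across TFs (first entry = first TF), letting mate TFs carry fewer
#'   peaks than the reference TF.
#' @param peak_len_range min/max trimmed peak length in bp.
#' @param height_meanlog,height_sdlog log-normal peak-height parameters.
#' @param beta0,beta_height,beta_cluster logistic commonness coefficients:
#'   intercept, per height percentile, per distinct cluster TF.
#' @param p_cluster probability a peak joins a multi-TF locus.
#' @param promoter_peak_fraction fraction of loci placed at gene promoters.
#' @param tag_mu mean tag count over a region whose cell carries the peak.
#' @param tag_base mean tag count where the cell lacks the peak.
#' @param tag_total nominal total tag count per experiment.
#' @param chromatin_effect multiplier on `tag_mu` for the peak-bearing cell
#'   (1 disables the asymmetry).
#' @param chromatin_asym_prob fraction of cell-type specific peaks whose
#'   specificity is chromatin-driven (closed in the other cell type); the
#'   remainder are accessible in both cell types.
#' @param chromatin_height_scaling scale the elevation with height
#'   percentile (drives larger median differences at higher bins).
#' @param conservation_effect conservation elevation at common peaks.
#' @param conservation_sd conservation noise standard deviation.
#' @param motif_plant_prob probability a peak gets its TF's consensus motif
#'   planted.
#' @param motif_disruption_prob probability a cell-type specific peak
#'   carries a motif-disrupting homozygous-different SNP.
#' @param snp_rate target overall fraction of peaks harbouring at least
#'   one SNP; incidental SNPs fill in beyond the motif-disrupting ones.
#' @param cpg_island_fraction fraction of gene promoters rewritten as
#'   CpG islands.
#' @param pwm_width motif width in bp.
#' @param third_cell_type also generate a third cell type C.
#' @param context_mode `"shared"` (cell C context features behave like cell
#'   B's) or `"decoupled"` (cell C context elevation is assigned at random,
#'   independent of the labels).
#' @param level `"full"` (sequence, tracks, SNPs) or `"peaks"` (peaks,
#'   clusters and labels only; cheap, for overlap/trend studies).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 10e6, chr2 = 10e6),
                       n_genes = 1000, n_tfs = 5, peaks_per_tf = 2000,
                       peak_len_range = c(100, 400),
                       height_meanlog = 3, height_sdlog = 1,
                       beta0 = -4.4, beta_height = 0.04, beta_cluster = 0.5,
                       p_cluster = 0.6, promoter_peak_fraction = 0.35,
                       tag_mu = 15, tag_base = 6, tag_total = 1e6,
                       chromatin_effect = 1.5, chromatin_asym_prob = 0.6,
                       chromatin_height_scaling = TRUE,
                       conservation_effect = 0.25, conservation_sd = 0.3,
                       motif_plant_prob = 0.6, motif_disruption_prob = 0.1,
                       snp_rate = 0.12, cpg_island_fraction = 0.4,
                       pwm_width = 10, third_cell_type = FALSE,
                       context_mode = c("shared", "decoupled"),
                       level = c("full", "peaks")) {
  cfg <- list(chrom_lengths = chrom_lengths, n_genes = n_genes, n_tfs = n_tfs,
              peaks_per_tf = peaks_per_tf, peak_len_range = peak_len_range,
              height_meanlog = height_meanlog, height_sdlog = height_sdlog,
              beta0 = beta0, beta_height = beta_height,
              beta_cluster = beta_cluster, p_cluster = p_cluster,
              promoter_peak_fraction = promoter_peak_fraction,
              tag_mu = tag_mu, tag_base = tag_base, tag_total = tag_total,
              chromatin_effect = chromatin_effect,
              chromatin_asym_prob = chromatin_asym_prob,
              chromatin_height_scaling = chromatin_height_scaling,
              conservation_effect = conservation_effect,
              conservation_sd = conservation_sd,
              motif_plant_prob = motif_plant_prob,
              motif_disruption_prob = motif_disruption_prob,
              snp_rate = snp_rate, cpg_island_fraction = cpg_island_fraction,
              pwm_width = pwm_width, third_cell_type = third_cell_type,
              context_mode = match.arg(context_mode), level = match.arg(level))
  probs <- c(cfg$p_cluster, cfg$promoter_peak_fraction, cfg$motif_plant_prob,
             cfg$motif_disruption_prob, cfg$snp_rate, cfg$cpg_island_fraction,
             cfg$chromatin_asym_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_tfs < 1 || any(peaks_per_tf < 1) || n_genes < 0)
    stop("counts must be positive")
  cfg$peaks_per_tf <- rep_len(as.integer(peaks_per_tf), n_tfs)
  # slot feasibility: every peak consumes one 500 bp slot
  n_slots <- sum(floor(chrom_lengths / 500))
  need <- sum(cfg$peaks_per_tf) * (if (third_cell_type) 3 else 2)
  if (need > 0.8 * n_slots)
    stop("infeasible config: more peaks than the genome has room for")
  class(cfg) <- "sim_config"
  cfg
}

.SLOT <- 500L

# random DNA vector with CpG suppression: vertebrate background sequence
# is CpG-depleted (observed/expected well below 1), so most non-island
# regions classify as CpG-poor
.rand_dna <- function(n, cpg_depletion = 0.7) {
  x <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (cpg_depletion > 0 && n > 1L) {
    cg <- which(x[-n] == "C" & x[-1] == "G")
    hit <- cg[stats::runif(length(cg)) < cpg_depletion]
    if (length(hit)) x[hit + 1L] <- sample(c("A", "T"), length(hit), TRUE)
  }
  x
}

# CpG-island flavoured DNA: GC-rich with frequent CpG dinucleotides
.island_dna <- function(n) {
  out <- character(n)
  i <- 1L
  while (i <= n) {
    if (stats::runif(1) < 0.22 && i < n) {
      out[i] <- "C"; out[i + 1L] <- "G"; i <- i + 2L
    } else {
      out[i] <- sample(c("A", "C", "G", "T"), 1,
                       prob = c(0.2, 0.3, 0.3, 0.2))
      i <- i + 1L
    }
  }
  out
}

# Allocate `n_runs` runs of lengths `sizes` (in slots) on the free grid.
# Returns start slot indices; marks them used in env$free.
.alloc_runs <- function(env, sizes, prefer = NULL) {
  starts <- integer(length(sizes))
  for (i in seq_along(sizes)) {
    k <- sizes[i]
    hit <- NA_integer_
    cand <- if (!is.null(prefer) && !is.na(prefer[i])) prefer[i] else NA
    if (!is.na(cand) && cand + k - 1L <= length(env$free) &&
        all(env$free[cand:(cand + k - 1L)]) &&
        env$chrom_of[cand] == env$chrom_of[min(cand + k - 1L, length(env$free))])
      hit <- cand
    tries <- 0L
    while (is.na(hit) && tries < 200L) {
      s <- sample.int(length(env$free) - k + 1L, 1L)
      if (all(env$free[s:(s + k - 1L)]) &&
          env$chrom_of[s] == env$chrom_of[s + k - 1L]) hit <- s
      tries <- tries + 1L
    }
    if (is.na(hit)) {
      ok <- which(env$free)
      ok <- ok[vapply(ok, function(s) s + k - 1L <= length(env$free) &&
                        all(env$free[s:(s + k - 1L)]) &&
                        env$chrom_of[s] == env$chrom_of[s + k - 1L],
                      logical(1))]
      if (!length(ok)) stop("infeasible config: ran out of genome slots")
      hit <- ok[sample.int(length(ok), 1L)]
    }
    env$free[hit:(hit + k - 1L)] <- FALSE
    starts[i] <- hit
  }
  starts
}

#' Generate a synthetic two (or three) cell-type peak study
#'
#' @param config a [sim_config()].
#' @param seed integer seed; all randomness derives from it.
#' @return list of class `peak_study` with elements `config`, `seed`,
#'   `genome` (named sequences; `NULL` at level "peaks"), `genes`, `pwms`,
#'   `peaks` (named list of peak frames per cell type `A`, `B`, optionally
#'   `C`), `clusters` (cluster columns along `peaks$A`), `tags`
#'   (`tags[[mark]][[cell]]`), `conservation`, `snps`, `expression`,
#'   `truth` (per reference peak: generative covariates, probabilities,
#'   labels, disruption flags) and `coefficients`.
#' @export
simulate_peak_study <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  cfg <- config
  full <- cfg$level == "full"
  chroms <- names(cfg$chrom_lengths)
  tf_names <- sprintf("TF%d", seq_len(cfg$n_tfs))
  cells <- c("A", "B", if (cfg$third_cell_type) "C")

  ## ---- slot grid ----
  slots_per_chrom <- floor(cfg$chrom_lengths / .SLOT)
  chrom_of <- rep(chroms, slots_per_chrom)
  slot_start <- unlist(lapply(slots_per_chrom, function(m)
    (seq_len(m) - 1L) * .SLOT), use.names = FALSE)
  grid <- new.env()
  grid$free <- rep(TRUE, length(chrom_of))
  grid$chrom_of <- chrom_of

  ## ---- genes ----
  genes <- NULL
  if (cfg$n_genes > 0) {
    # genes claim 6 kb territories so they stay mutually disjoint, then the
    # slots are released: peaks are allowed to sit in promoters and introns
    g_slots <- .alloc_runs(grid, rep(12L, cfg$n_genes))
    strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    tx_len <- sample(2000:5000, cfg$n_genes, replace = TRUE)
    tx_start <- slot_start[g_slots] + sample(0:400, cfg$n_genes, replace = TRUE)
    tx_end <- tx_start + tx_len
    exons <- lapply(seq_len(cfg$n_genes), function(i) {
      e1 <- sample(100:300, 1); intr <- sample(500:1500, 1)
      e2_start <- e1 + intr
      data.frame(start = tx_start[i] + c(0L, e2_start),
                 end = c(tx_start[i] + e1, tx_end[i]))
    })
    genes <- gene_models(name = sprintf("G%03d", seq_len(cfg$n_genes)),
                         symbol = sprintf("GENE%03d", seq_len(cfg$n_genes)),
                         chrom = chrom_of[g_slots], strand = strand,
                         tx_start = tx_start, tx_end = tx_end, exons = exons)
    for (gs in g_slots) grid$free[gs:(gs + 11L)] <- TRUE
    # exon order must be genomic; transcription order handled by strand
  }

  ## ---- multi-TF loci ----
  # TFs are laid down in turn; each peak of the current TF joins (with
  # probability p_cluster) a random locus not already holding that TF, or
  # founds a new locus. Loci therefore hold at most one peak per TF.
  n_ref <- sum(cfg$peaks_per_tf)
  locus_of <- integer(n_ref)
  tf_of <- rep(tf_names, times = cfg$peaks_per_tf)
  n_loci <- 0L
  has_tf <- matrix(FALSE, nrow = 0, ncol = cfg$n_tfs)
  for (t in seq_len(cfg$n_tfs)) {
    i_tf <- which(tf_of == tf_names[t])
    cand <- if (n_loci) which(!has_tf[seq_len(n_loci), t]) else integer(0)
    want <- stats::runif(length(i_tf)) < cfg$p_cluster
    n_join <- min(sum(want), length(cand))
    joiners <- i_tf[which(want)[seq_len(n_join)]]
    if (n_join) {
      pick <- cand[sample.int(length(cand), n_join)]
      locus_of[joiners] <- pick
      has_tf[pick, t] <- TRUE
    }
    founders <- setdiff(i_tf, joiners)
    if (length(founders)) {
      new_ids <- n_loci + seq_along(founders)
      locus_of[founders] <- new_ids
      has_tf <- rbind(has_tf, matrix(FALSE, length(founders), cfg$n_tfs))
      has_tf[new_ids, t] <- TRUE
      n_loci <- n_loci + length(founders)
    }
  }
  locus_sizes <- tabulate(locus_of, nbins = n_loci)

  ## ---- place loci (some at promoters) ----
  prefer <- rep(NA_integer_, length(locus_sizes))
  if (!is.null(genes)) {
    at_prom <- stats::runif(length(locus_sizes)) < cfg$promoter_peak_fraction
    tss <- gene_tss(genes)
    pick <- sample.int(nrow(genes), sum(at_prom), replace = TRUE)
    # a random slot within the picked gene's promoter window
    prom_pos <- pmax(0L, tss[pick] - sample(200:1800, sum(at_prom),
                                            replace = TRUE))
    idx <- match(genes$chrom[pick], chroms)
    offs <- c(0L, cumsum(slots_per_chrom))[idx]
    prefer[at_prom] <- offs + pmin(prom_pos %/% .SLOT + 1L,
                                   slots_per_chrom[idx])
  }
  locus_slot <- .alloc_runs(grid, locus_sizes, prefer = prefer)

  ## ---- reference peaks ----
  ord_in_locus <- unlist(lapply(split(seq_len(n_ref), locus_of), function(i)
    stats::setNames(seq_along(i) - 1L, i)), use.names = FALSE)
  pos_in_locus <- integer(n_ref)
  pos_in_locus[unlist(split(seq_len(n_ref), locus_of), use.names = FALSE)] <-
    ord_in_locus
  slot_idx <- locus_slot[locus_of] + pos_in_locus
  len <- sample(cfg$peak_len_range[1]:cfg$peak_len_range[2], n_ref,
                replace = TRUE)
  off <- floor(stats::runif(n_ref) * (.SLOT - len + 1L))
  start <- slot_start[slot_idx] + off
  height <- pmax(1, round(stats::rlnorm(n_ref, cfg$height_meanlog,
                                        cfg$height_sdlog)))
  ref <- peak_set(chrom = chrom_of[slot_idx], start = start, end = start + len,
                  height = height, tf = tf_of, cell_type = "A",
                  peak_id = sprintf("A_%s_%05d", tf_of, seq_len(n_ref)))

  ## ---- clusters, commonness model ----
  clusters <- cluster_peaks(ref)
  pct <- stats::ave(ref$height, ref$tf, FUN = height_percentiles)
  draw_label <- function() {
    lp <- cfg$beta0 + cfg$beta_height * pct +
      cfg$beta_cluster * clusters$cluster_tfs
    p <- stats::plogis(lp)
    list(p = p, common = stats::runif(n_ref) < p)
  }
  lab_b <- draw_label()
  lab_c <- if (cfg$third_cell_type) draw_label() else NULL
  # chromatin-driven specificity: the other cell type is closed at these
  driven_a <- !lab_b$common & stats::runif(n_ref) < cfg$chromatin_asym_prob
  ref$pct <- pct
  ref$driven <- driven_a

  ## ---- partner and filler peaks per comparison cell ----
  make_partner_cell <- function(common, cell) {
    idx <- which(common)
    slack_l <- pmin(50L, off[idx])
    slack_r <- pmin(50L, .SLOT - len[idx] - off[idx])
    shift <- floor(stats::runif(length(idx)) * (slack_l + slack_r + 1L)) -
      slack_l
    p_start <- start[idx] + shift
    p_h <- pmax(1, round(exp(0.8 * log(ref$height[idx]) +
                               stats::rnorm(length(idx), 0.6,
                                            0.4 * cfg$height_sdlog))))
    partner <- peak_set(chrom = ref$chrom[idx], start = p_start,
                        end = p_start + len[idx], height = p_h,
                        tf = ref$tf[idx], cell_type = cell,
                        peak_id = sprintf("%s_p_%s", cell, ref$peak_id[idx]))
    partner$driven <- FALSE
    n_fill <- pmax(0L, cfg$peaks_per_tf -
                     as.integer(table(factor(ref$tf[idx], levels = tf_names))))
    tot_fill <- sum(n_fill)
    fill <- NULL
    if (tot_fill > 0) {
      f_slot <- .alloc_runs(grid, rep(1L, tot_fill))
      f_len <- sample(cfg$peak_len_range[1]:cfg$peak_len_range[2], tot_fill,
                      replace = TRUE)
      f_off <- floor(stats::runif(tot_fill) * (.SLOT - f_len + 1L))
      f_start <- slot_start[f_slot] + f_off
      f_tf <- rep(tf_names, n_fill)
      fill <- peak_set(chrom = chrom_of[f_slot], start = f_start,
                       end = f_start + f_len,
                       height = pmax(1, round(stats::rlnorm(
                         tot_fill, cfg$height_meanlog, cfg$height_sdlog))),
                       tf = f_tf, cell_type = cell,
                       peak_id = sprintf("%s_s_%05d", cell, seq_len(tot_fill)))
      fill$driven <- stats::runif(tot_fill) < cfg$chromatin_asym_prob
    }
    out <- rbind(as.data.frame(partner), as.data.frame(fill))
    out$pct <- stats::ave(out$height, out$tf, FUN = height_percentiles)
    out <- out[order(out$chrom, out$start), ]
    rownames(out) <- NULL
    class(out) <- c("peak_set", "data.frame")
    out
  }
  peaks <- list(A = ref, B = make_partner_cell(lab_b$common, "B"))
  if (cfg$third_cell_type) peaks$C <- make_partner_cell(lab_c$common, "C")

  truth <- data.frame(peak_id = ref$peak_id, tf = ref$tf,
                      height = ref$height, height_pct = pct,
                      cluster_tfs = clusters$cluster_tfs,
                      p_common = lab_b$p, common_B = lab_b$common,
                      chromatin_driven = driven_a,
                      disrupted = FALSE, snp_id = NA_character_,
                      stringsAsFactors = FALSE)
  if (cfg$third_cell_type) truth$common_C <- lab_c$common

  study <- list(config = cfg, seed = seed, genes = genes, peaks = peaks,
                clusters = clusters, truth = truth,
                coefficients = c(beta0 = cfg$beta0,
                                 beta_height = cfg$beta_height,
                                 beta_cluster = cfg$beta_cluster))

  ## ---- expression tables (per-TF, tied to peak counts) ----
  expr <- lapply(cells, function(cell) {
    counts <- table(factor(peaks[[cell]]$tf, levels = tf_names))
    stats::setNames(as.numeric(counts) / 100 *
                      exp(stats::rnorm(cfg$n_tfs, 0, 0.15)), tf_names)
  })
  study$expression <- stats::setNames(expr, cells)

  if (!full) {
    class(study) <- "peak_study"
    return(study)
  }

  ## ---- genome sequence ----
  gen <- lapply(cfg$chrom_lengths, .rand_dna)
  names(gen) <- chroms
  # CpG islands at a fraction of gene promoters
  if (!is.null(genes) && cfg$cpg_island_fraction > 0) {
    isl <- which(stats::runif(nrow(genes)) < cfg$cpg_island_fraction)
    for (i in isl) {
      tss <- gene_tss(genes)[i]
      a <- max(0L, tss - 700L); b <- min(cfg$chrom_lengths[genes$chrom[i]],
                                         tss + 700L)
      gen[[genes$chrom[i]]][(a + 1L):b] <- .island_dna(b - a)
    }
  }

  ## ---- PWMs and planted motifs ----
  w <- cfg$pwm_width
  hi_col <- max(1L, w %/% 2L)         # the high-information column
  pwms <- lapply(tf_names, function(tf) {
    cons <- sample(c("A", "C", "G", "T"), w, replace = TRUE)
    cts <- matrix(2, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in seq_len(w)) cts[cons[j], j] <- 10
    cts[, hi_col] <- 0.5
    cts[cons[hi_col], hi_col] <- 30
    pwm(cts, name = tf)
  })
  names(pwms) <- tf_names
  consensus <- vapply(pwms, function(p)
    paste(rownames(p$counts)[apply(p$counts, 2, which.max)], collapse = ""),
    character(1))
  plant <- stats::runif(n_ref) < cfg$motif_plant_prob
  disrupt <- !lab_b$common & (stats::runif(n_ref) < cfg$motif_disruption_prob)
  plant <- plant | disrupt
  motif_start <- start + pmax(0L, (len - w) %/% 2L)  # 0-based genome pos
  for (i in which(plant)) {
    gen[[ref$chrom[i]]][(motif_start[i] + 1L):(motif_start[i] + w)] <-
      strsplit(consensus[ref$tf[i]], "")[[1]]
  }

  ## ---- SNPs ----
  bg <- genome_background(vapply(gen, function(g)
    paste(g[seq_len(min(2e5, length(g)))], collapse = ""), character(1)))
  snp_list <- list()
  if (any(disrupt)) {
    idx <- which(disrupt)
    lo <- lapply(tf_names, function(tf) logodds_matrix(pwms[[tf]], bg))
    names(lo) <- tf_names
    worst <- vapply(tf_names, function(tf)
      rownames(lo[[tf]])[which.min(lo[[tf]][, hi_col])], character(1))
    pos <- motif_start[idx] + hi_col - 1L
    ref_al <- vapply(idx, function(i)
      gen[[ref$chrom[i]]][motif_start[i] + hi_col], character(1))
    snp_list$disrupt <- snp_records(
      snp_id = sprintf("snpD%05d", seq_along(idx)),
      chrom = ref$chrom[idx], pos = pos,
      ref_allele = ref_al, alt_allele = worst[ref$tf[idx]],
      gt_a = 0L, gt_b = 1L,
      Q = round(stats::runif(length(idx), 40, 90), 1),
      AF = round(stats::runif(length(idx), 0.4, 0.6), 2),
      DP = stats::rpois(length(idx), 20), peak_id = ref$peak_id[idx])
    truth$disrupted[idx] <- TRUE
    truth$snp_id[idx] <- snp_list$disrupt$snp_id
  }
  p_inc <- if (mean(disrupt) >= cfg$snp_rate) 0 else
    (cfg$snp_rate - mean(disrupt)) / (1 - mean(disrupt))
  inc <- which(stats::runif(n_ref) < p_inc & !disrupt)
  if (length(inc)) {
    pos <- start[inc] + floor(stats::runif(length(inc)) * len[inc])
    ref_al <- vapply(seq_along(inc), function(k)
      gen[[ref$chrom[inc[k]]]][pos[k] + 1L], character(1))
    alt_al <- vapply(ref_al, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1),
      USE.NAMES = FALSE)
    kind <- sample(c("same0", "same1", "het", "diff", "lowq_diff"),
                   length(inc), replace = TRUE,
                   prob = c(0.40, 0.15, 0.25, 0.12, 0.08))
    # incidental discordant calls point in either direction at random
    flip <- stats::rbinom(length(inc), 1, 0.5)
    snp_list$incidental <- snp_records(
      snp_id = sprintf("snpI%05d", seq_along(inc)),
      chrom = ref$chrom[inc], pos = pos, ref_allele = ref_al,
      alt_allele = alt_al,
      gt_a = ifelse(kind == "same1", 1L,
                    ifelse(kind == "het", NA_integer_,
                           ifelse(kind %in% c("diff", "lowq_diff"),
                                  flip, 0L))),
      gt_b = ifelse(kind == "same1", 1L,
                    ifelse(kind == "het", NA_integer_,
                           ifelse(kind %in% c("diff", "lowq_diff"),
                                  1L - flip, 0L))),
      Q = round(ifelse(kind == "lowq_diff", stats::runif(length(inc), 3, 15),
                       stats::runif(length(inc), 40, 90)), 1),
      AF = round(ifelse(kind == "same1", stats::runif(length(inc), 0.9, 1),
                        stats::runif(length(inc), 0, 0.6)), 2),
      DP = stats::rpois(length(inc), 20), peak_id = ref$peak_id[inc])
  }
  snps <- do.call(rbind, snp_list)
  if (!is.null(snps)) rownames(snps) <- NULL
  study$snps <- snps
  study$truth <- truth

  ## ---- chromatin and histone tag sets ----
  scale_h <- function(p) if (cfg$chromatin_height_scaling) 0.5 + p / 100 else 1
  make_tags <- function(regions, mu) {
    counts <- stats::rpois(nrow(regions), mu)
    i <- rep(seq_len(nrow(regions)), counts)
    t_start <- regions$start[i] +
      floor(stats::runif(length(i)) * pmax(1L, regions$end[i] -
                                             regions$start[i] - 36L))
    tag_set(data.frame(chrom = regions$chrom[i], start = t_start,
                       end = t_start + 36L), cfg$tag_total)
  }
  active_tags <- function(cell) {
    own <- peaks[[cell]]
    mu_own <- cfg$tag_mu * cfg$chromatin_effect * scale_h(own$pct)
    others <- do.call(rbind, lapply(setdiff(cells, cell), function(oc)
      as.data.frame(peaks[[oc]])))
    # regions the other cells call but this cell does not; closed here only
    # when the specificity is chromatin-driven
    away <- others[!overlaps_any(others, own), , drop = FALSE]
    mu_away <- ifelse(away$driven, cfg$tag_base,
                      cfg$tag_mu * cfg$chromatin_effect * scale_h(away$pct))
    if (cfg$context_mode == "decoupled" && cell == "C") {
      # elevation unrelated to where C's peaks are
      all_reg <- rbind(as.data.frame(own), away)
      up <- stats::runif(nrow(all_reg)) < 0.5
      tg <- rbind(make_tags(all_reg[up, , drop = FALSE],
                            cfg$tag_mu * cfg$chromatin_effect)$tags,
                  make_tags(all_reg[!up, , drop = FALSE], cfg$tag_base)$tags)
      return(tag_set(tg, cfg$tag_total))
    }
    tg <- rbind(make_tags(own, mu_own)$tags,
                make_tags(away, mu_away)$tags)
    tag_set(tg, cfg$tag_total)
  }
  quiet_tags <- function(cell) {
    own <- peaks[[cell]]
    others <- do.call(rbind, lapply(setdiff(cells, cell), function(oc)
      as.data.frame(peaks[[oc]])))
    away <- others[!overlaps_any(others, own), , drop = FALSE]
    make_tags(rbind(as.data.frame(own), away), cfg$tag_base)
  }
  study$tags <- list(
    dnase = stats::setNames(lapply(cells, active_tags), cells),
    h3k4me3 = stats::setNames(lapply(cells, active_tags), cells),
    h3k27me3 = stats::setNames(lapply(cells, quiet_tags), cells))

  ## ---- conservation track ----
  cons_val <- stats::rnorm(n_ref, ifelse(lab_b$common,
                                         cfg$conservation_effect, 0),
                           cfg$conservation_sd)
  seg <- data.frame(chrom = ref$chrom, start = ref$start, end = ref$end,
                    value = round(cons_val, 4))
  study$conservation <- signal_track(seg)

  study$genome <- vapply(gen, paste, character(1), collapse = "")
  study$pwms <- pwms
  class(study) <- "peak_study"
  study
}

#' @export
print.peak_study <- function(x, ...) {
  cat("Synthetic peak study (seed", x$seed, ")\n")
  for (cell in names(x$peaks))
    cat(sprintf("  cell %s: %d peaks, %d TFs\n", cell, nrow(x$peaks[[cell]]),
                length(unique(x$peaks[[cell]]$tf))))
  cat(sprintf("  commonness (A vs B): %.1f%%\n",
              100 * mean(x$truth$common_B)))
  if (!is.null(x$snps)) cat("  SNP records:", nrow(x$snps), "\n")
  invisible(x)
}

#' Feature context of a simulated study
#'
#' @param study a [simulate_peak_study()] result at level `"full"`.
#' @param comparison comparison cell type, `"B"` (default) or `"C"`.
#' @return a [feature_context()] for reference cell `A`.
#' @export
study_feature_context <- function(study, comparison = "B") {
  if (is.null(study$genome))
    stop("study was generated at level 'peaks'; no sequence context")
  feature_context(genes = study$genes, genome = study$genome,
                  tags = study$tags, conservation = study$conservation,
                  cell_ref = "A", cell_cmp = comparison, pwms = study$pwms)
}

#' Assemble features and labels for one simulated TF
#'
#' @param study a full-level [simulate_peak_study()] result.
#' @param tf TF name (default the first).
#' @param comparison comparison cell type (`"B"` or `"C"`).
#' @return list: `features` (data.frame), `labels` (factor), `peaks`,
#'   `cluster_info`.
#' @export
study_features <- function(study, tf = NULL, comparison = "B") {
  if (is.null(tf)) tf <- study$peaks$A$tf[1]
  sel <- study$peaks$A$tf == tf
  pk <- study$peaks$A[sel, , drop = FALSE]
  class(pk) <- c("peak_set", "data.frame")
  cl <- study$clusters[sel, , drop = FALSE]
  cmp <- study$peaks[[comparison]]
  cmp <- cmp[cmp$tf == tf, , drop = FALSE]
  ctx <- study_feature_context(study, comparison)
  list(features = assemble_features(pk, cl, ctx),
       labels = label_by_overlap(pk, cmp),
       peaks = pk, cluster_info = cl)
}

#' Recovery metrics of pipeline outputs against ground truth
#'
#' @param study a `peak_study`.
#' @param predicted_labels named factor/character (names = peak_id) of
#'   pipeline labels for the reference peaks vs cell B.
#' @param decision optional named decision values for a label-recovery ROC.
#' @return list: `label_accuracy`, `label_roc` (NA without decision values),
#'   `n`.
#' @export
truth_report <- function(study, predicted_labels, decision = NULL) {
  ids <- study$truth$peak_id
  if (!all(names(predicted_labels) %in% ids))
    stop("predicted labels carry unknown peak ids")
  truth_lab <- ifelse(study$truth$common_B, "common", "specific")
  names(truth_lab) <- ids
  use <- names(predicted_labels)
  acc <- mean(predicted_labels == truth_lab[use])
  roc <- NA_real_
  if (!is.null(decision)) {
    if (is.null(names(decision))) names(decision) <- use
    roc <- roc_auc(decision[use], truth_lab[use])
  }
  list(label_accuracy = acc, label_roc = roc, n = length(use))
}
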