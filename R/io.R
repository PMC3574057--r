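#' Readers and writers for the exchange formats
#'
#' Plain-text formats only: BED6 peaks, BED12 gene models, bedGraph signal
#' tracks, tag BED files with a `#total_tags` sidecar header, FASTA genomes,
#' JASPAR-style PFM files (plus a minimal TRANSFAC-like tabular dialect),
#' two-column expression tables and the combined peak+SNP table dialect.
#' Coordinates are normalised to 0-based half-open on read.
#'
#' @name io
NULL

.read_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readLines(path, warn = FALSE)
}

.check_coords <- function(start, end, path) {
  bad <- which(!(start < end))
  if (length(bad))
    stop(sprintf("%s: start >= end on line(s) %s", path,
                 paste(utils::head(bad, 5), collapse = ", ")))
}

#' Read peaks from a BED6 file
#'
#' Columns: chrom, start, end, name (peak id), score (height), strand
#' (ignored, written as ".").
#'
#' @param path BED file.
#' @param tf,cell_type labels attached to the peaks.
#' @return a [peak_set()].
#' @export
read_bed_peaks <- function(path, tf = "TF", cell_type = "cell") {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "name",
                                       "score", "strand"),
                         colClasses = c("character", "integer", "integer",
                                        "character", "numeric", "character"))
  .check_coords(x$start, x$end, path)
  peak_set(x$chrom, x$start, x$end, height = x$score, tf = tf,
           cell_type = cell_type, peak_id = x$name)
}

#' Write peaks as BED6
#'
#' @param peaks a peak frame.
#' @param path output file.
#' @export
write_bed_peaks <- function(peaks, path) {
  out <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                    peaks$height, ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read gene models from BED12
#'
#' thickStart/thickEnd are ignored; blocks are the exons. The name field
#' may be `id|symbol`; a bare name doubles as the symbol.
#'
#' @param path BED12 file.
#' @return a [gene_models()] frame.
#' @export
read_bed12_genes <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = c("character", "integer", "integer",
                                        "character", "numeric", "character",
                                        "integer", "integer", "character",
                                        "integer", "character", "character"))
  names(x) <- c("chrom", "start", "end", "name", "score", "strand",
                "thickStart", "thickEnd", "rgb", "blockCount", "blockSizes",
                "blockStarts")
  .check_coords(x$start, x$end, path)
  split_name <- strsplit(x$name, "|", fixed = TRUE)
  exons <- lapply(seq_len(nrow(x)), function(i) {
    sizes <- as.integer(strsplit(x$blockSizes[i], ",")[[1]])
    starts <- as.integer(strsplit(x$blockStarts[i], ",")[[1]])
    if (length(sizes) != x$blockCount[i])
      stop(path, ": blockCount mismatch on line ", i)
    data.frame(start = x$start[i] + starts, end = x$start[i] + starts + sizes)
  })
  gene_models(name = vapply(split_name, `[`, character(1), 1),
              symbol = vapply(split_name, function(s) s[length(s)],
                              character(1)),
              chrom = x$chrom, strand = x$strand,
              tx_start = x$start, tx_end = x$end, exons = exons)
}

#' Write gene models as BED12
#'
#' @param genes a [gene_models()] frame.
#' @param path output file.
#' @export
write_bed12_genes <- function(genes, path) {
  rows <- vapply(seq_len(nrow(genes)), function(i) {
    e <- genes$exons[[i]]
    paste(genes$chrom[i], genes$tx_start[i], genes$tx_end[i],
          paste0(genes$name[i], "|", genes$symbol[i]), 0, genes$strand[i],
          genes$tx_start[i], genes$tx_start[i], "0", nrow(e),
          paste0(paste(e$end - e$start, collapse = ","), ","),
          paste0(paste(e$start - genes$tx_start[i], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(rows, path)
}

#' Read tRNA transcription start sites from BED6
#'
#' @param path BED6 file of tRNA gene spans.
#' @return `data.frame(chrom, pos, strand)`; `pos` is the strand-aware TSS.
#' @export
read_bed6_trna <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "name",
                                       "score", "strand"),
                         colClasses = c("character", "integer", "integer",
                                        "character", "numeric", "character"))
  .check_coords(x$start, x$end, path)
  data.frame(chrom = x$chrom, pos = ifelse(x$strand == "+", x$start, x$end),
             strand = x$strand, stringsAsFactors = FALSE)
}

#' Read a bedGraph signal track
#'
#' Out-of-order segments are sorted with a warning; overlapping segments
#' are a format error.
#'
#' @param path bedGraph file.
#' @return a [signal_track()].
#' @export
read_bedgraph <- function(path) {
  lines <- .read_lines(path)
  lines <- lines[!grepl("^(track|#)", lines)]
  x <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "value"),
                         colClasses = c("character", "integer", "integer",
                                        "numeric"))
  .check_coords(x$start, x$end, path)
  if (is.unsorted(order(x$chrom, x$start)))
    warning(path, ": bedGraph not sorted; sorting")
  signal_track(x)
}

#' Write a signal track as bedGraph
#'
#' @param track a [signal_track()].
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  utils::write.table(as.data.frame(track)[, c("chrom", "start", "end",
                                              "value")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
}

#' Read a tag set (BED3 plus a total-count header)
#'
#' The first line must be `#total_tags=N`; remaining lines are one tag
#' interval each.
#'
#' @param path tag BED file.
#' @return a [tag_set()].
#' @export
read_tagset <- function(path) {
  lines <- .read_lines(path)
  if (!length(lines) || !grepl("^#total_tags=", lines[1]))
    stop(path, ": missing '#total_tags=' header")
  total <- as.numeric(sub("^#total_tags=", "", lines[1]))
  body <- lines[-1]
  if (!length(body))
    return(tag_set(data.frame(chrom = character(0), start = integer(0),
                              end = integer(0)), total))
  x <- utils::read.table(text = body, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end"),
                         colClasses = c("character", "integer", "integer"))
  .check_coords(x$start, x$end, path)
  tag_set(x, total)
}

#' Write a tag set
#'
#' @param tags a [tag_set()].
#' @param path output file.
#' @export
write_tagset <- function(tags, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#total_tags=%s", format(tags$total_tags,
                                              scientific = FALSE)), con)
  if (nrow(tags$tags))
    utils::write.table(tags$tags, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
}

#' Read a FASTA genome
#'
#' @param path FASTA file; lower-case bases are upper-cased.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a FASTA genome
#'
#' @param genome named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path,
                              width = 70)
}

#' Read PFMs (JASPAR-style, or a minimal TRANSFAC-like table)
#'
#' JASPAR: records start with `>name`, followed by four lines
#' `A [ 1 2 3 ]` in A, C, G, T order. TRANSFAC-like: a `NA` name line, a
#' `P0 A C G T` header, numbered position rows, `//` terminator.
#'
#' @param path PFM file.
#' @return named list of [pwm()] objects.
#' @export
read_pfm <- function(path) {
  lines <- trimws(.read_lines(path))
  lines <- lines[nzchar(lines)]
  if (any(grepl("^>", lines))) {
    starts <- grep("^>", lines)
    ends <- c(starts[-1] - 1L, length(lines))
    out <- lapply(seq_along(starts), function(i) {
      name <- sub("^>\\s*", "", lines[starts[i]])
      rows <- lines[(starts[i] + 1L):ends[i]][1:4]
      counts <- do.call(rbind, lapply(rows, function(r) {
        s <- sub("^[ACGT]", "", r)
        as.numeric(regmatches(s, gregexpr("[0-9][0-9.]*", s))[[1]])
      }))
      pwm(counts, name = name)
    })
    names(out) <- vapply(out, `[[`, character(1), "name")
    return(out)
  }
  # TRANSFAC-like
  recs <- split(lines, cumsum(grepl("^//", c("", lines[-length(lines)]))))
  out <- list()
  for (rec in recs) {
    rec <- rec[!grepl("^//", rec)]
    if (!length(rec)) next
    name <- sub("^NA\\s+", "", rec[grepl("^NA\\s", rec)][1])
    rows <- rec[grepl("^[0-9]+\\s", rec)]
    mat <- t(vapply(rows, function(r)
      as.numeric(strsplit(r, "\\s+")[[1]][2:5]), numeric(4)))
    out[[name]] <- pwm(t(mat), name = name)
  }
  out
}

#' Write PWMs in JASPAR PFM format
#'
#' @param pwms named list of [pwm()]s.
#' @param path output file.
#' @export
write_pfm <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$name), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$counts[b, ], trim = TRUE),
                               collapse = " ")), con)
  }
}

#' Read/write genome background frequencies
#'
#' @param path 4-value TSV (base, frequency).
#' @return named numeric vector over A, C, G, T.
#' @export
read_background <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("base", "freq"))
  stats::setNames(x$freq, x$base)[.BASES]
}

#' @rdname read_background
#' @param background named frequencies.
#' @export
write_background <- function(background, path) {
  utils::write.table(data.frame(base = .BASES,
                                freq = as.numeric(background[.BASES])),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
}

#' Read/write a two-column expression table
#'
#' @param path TSV of (symbol, value).
#' @return named numeric vector.
#' @export
read_expression <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("symbol", "value"),
                         colClasses = c("character", "numeric"))
  stats::setNames(x$value, x$symbol)
}

#' @rdname read_expression
#' @param expr named numeric vector.
#' @export
write_expression <- function(expr, path) {
  utils::write.table(data.frame(symbol = names(expr),
                                value = as.numeric(expr)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
}

#' Read a housekeeping gene list
#'
#' @param path one gene symbol per line.
#' @return character vector.
#' @export
read_housekeeping <- function(path) {
  x <- trimws(.read_lines(path))
  x[nzchar(x) & !grepl("^#", x)]
}

#' Read SNP records from a minimal VCF subset
#'
#' Uses the fixed columns (CHROM, POS, ID, REF, ALT) and the per-sample GT
#' field of the first two samples as the two cell types' genotypes
#' (`0/0` -> 0, `1/1` -> 1, anything else -> NA). QUAL becomes `Q`;
#' `AF` and `DP` are taken from INFO when present. Multi-allelic records
#' are rejected.
#'
#' @param path plain-text VCF with at least two sample columns.
#' @return a [snp_records()] frame (positions converted to 0-based).
#' @export
read_snp_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (any(nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L | grepl(",", fix$ALT)))
    stop("multi-allelic or indel records are not supported")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (ncol(gt) < 2L) stop("VCF must carry two sample columns")
  code <- function(g) ifelse(g %in% c("0/0", "0|0"), 0L,
                             ifelse(g %in% c("1/1", "1|1"), 1L, NA_integer_))
  info_num <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    suppressWarnings(as.numeric(x))
  }
  snp_records(snp_id = ifelse(fix$ID == "." | is.na(fix$ID),
                              sprintf("snp%05d", seq_len(nrow(fix))), fix$ID),
              chrom = fix$CHROM, pos = as.integer(fix$POS) - 1L,
              ref_allele = fix$REF, alt_allele = fix$ALT,
              gt_a = code(gt[, 1]), gt_b = code(gt[, 2]),
              Q = suppressWarnings(as.numeric(fix$QUAL)),
              AF = info_num("AF"), DP = as.integer(info_num("DP")))
}
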