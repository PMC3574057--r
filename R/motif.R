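#' PWM construction and log-odds motif scoring
#'
#' Position weight matrices are 4 x W count matrices over (A, C, G, T). A
#' pseudo-count of 1 is added to each base position when converting to
#' log-odds, avoiding zeros; the background is the genome-wide base
#' distribution. Scores are log2 odds; only score order matters downstream,
#' which is invariant to the log base.
#'
#' @name motif
NULL

.BASES <- c("A", "C", "G", "T")

#' Construct a PWM from base counts
#'
#' @param counts 4 x W non-negative matrix, rows in A, C, G, T order.
#' @param name motif identifier.
#' @return list of class `pwm` with `counts`, `name`, `width`.
#' @export
pwm <- function(counts, name = "pwm") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("PWM counts must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 1L) stop("PWM width must be >= 1")
  if (any(counts < 0)) stop("negative PWM counts")
  rownames(counts) <- .BASES
  structure(list(name = name, counts = counts, width = ncol(counts)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$name, "- width", x$width, "\n")
  print(round(x$counts, 2))
  invisible(x)
}

#' Genome background base frequencies
#'
#' Counts each base over the supplied sequences (N ignored) and divides by
#' the total. Frequencies are floored at `floor` and renormalised so
#' log-odds stay finite on degenerate sequence sets.
#'
#' @param sequences character vector of DNA strings.
#' @param floor minimum frequency per base (default 1e-6).
#' @return named numeric vector over A, C, G, T summing to 1.
#' @export
genome_background <- function(sequences, floor = 1e-6) {
  s <- toupper(paste(sequences, collapse = ""))
  counts <- vapply(.BASES, function(b)
    nchar(gsub(paste0("[^", b, "]"), "", s)), numeric(1))
  if (sum(counts) == 0) stop("no A/C/G/T bases in input")
  f <- counts / sum(counts)
  f <- pmax(f, floor)
  f / sum(f)
}

#' Log-odds matrix of a PWM under a background
#'
#' Entry (b, j) is `log2((counts[b, j] + pseudocount) /
#' (sum_b counts[b, j] + 4 * pseudocount) / background[b])`.
#'
#' @param x a [pwm()].
#' @param background named frequencies over A, C, G, T (see
#'   [genome_background()]).
#' @param pseudocount added to every cell (default 1).
#' @return 4 x W numeric matrix, rows A, C, G, T.
#' @export
logodds_matrix <- function(x, background, pseudocount = 1) {
  cts <- x$counts + pseudocount
  p <- sweep(cts, 2, colSums(cts), "/")
  log2(p / background[.BASES])
}

#' Reverse complement of DNA strings
#'
#' @param x character vector over A, C, G, T, N (case preserved as upper).
#' @return character vector.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(s), "")[[1]]),
                                   collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Score every window of width W on one strand; windows containing a
# non-ACGT base score NA.
.scan_strand <- function(mat, seq_chars) {
  w <- ncol(mat)
  n <- length(seq_chars) - w + 1L
  if (n < 1L) return(numeric(0))
  idx <- match(seq_chars, .BASES)  # NA for N
  sc <- numeric(n)
  for (j in seq_len(w)) {
    v <- mat[, j][idx[j:(j + n - 1L)]]
    sc <- sc + v
  }
  sc
}

#' Best-scoring motif window over both strands
#'
#' Scores every offset of the log-odds matrix on the forward sequence and on
#' its reverse complement and returns the maximum. Ties are broken by
#' smaller forward-coordinate offset, then "+" before "-". Windows
#' containing `N` are skipped; if every window contains `N` a no-hit result
#' (`score = NA`) is returned.
#'
#' @param mat log-odds matrix from [logodds_matrix()].
#' @param sequence DNA string at least as long as the matrix width.
#' @return list of class `motif_hit`: `offset` (0-based start on the forward
#'   strand of the hit's footprint), `strand`, `score`, `width`.
#' @export
max_pwm_score <- function(mat, sequence) {
  w <- ncol(mat)
  s <- toupper(sequence)
  len <- nchar(s)
  if (len < w) stop("sequence shorter than PWM width")
  fwd <- strsplit(s, "")[[1]]
  rev_ <- strsplit(revcomp(s), "")[[1]]
  sf <- .scan_strand(mat, fwd)
  sr <- .scan_strand(mat, rev_)
  # reverse-strand window i (1-based on the revcomp) has forward-strand
  # footprint starting at len - w - i + 2 (1-based) = offset len - w - i + 1
  n <- len - w + 1L
  cand <- data.frame(
    offset = c(seq_len(n) - 1L, rev(seq_len(n)) - 1L),
    strand = rep(c("+", "-"), each = n),
    score = c(sf, sr)
  )
  cand <- cand[!is.na(cand$score), , drop = FALSE]
  if (nrow(cand) == 0L)
    return(structure(list(offset = NA_integer_, strand = NA_character_,
                          score = NA_real_, width = w), class = "motif_hit"))
  best <- max(cand$score)
  cand <- cand[cand$score == best, , drop = FALSE]
  cand <- cand[order(cand$offset, cand$strand), , drop = FALSE]
  structure(list(offset = cand$offset[1], strand = cand$strand[1],
                 score = best, width = w), class = "motif_hit")
}

#' @export
print.motif_hit <- function(x, ...) {
  if (is.na(x$score)) cat("motif hit: none (all windows contain N)\n")
  else cat(sprintf("motif hit: offset %d (%s), score %.3f, width %d\n",
                   x$offset, x$strand, x$score, x$width))
  invisible(x)
}

#' Substitute an allele and rescore
#'
#' Replaces the base at `pos` with `allele` (the reverse-complement copy is
#' edited consistently through [revcomp()]) and returns the best hit of the
#' edited sequence.
#'
#' @param mat log-odds matrix.
#' @param sequence DNA string.
#' @param pos 0-based position within the sequence.
#' @param allele one of A, C, G, T.
#' @return a `motif_hit` for the edited sequence.
#' @export
rescore_with_allele <- function(mat, sequence, pos, allele) {
  len <- nchar(sequence)
  if (pos < 0 || pos >= len) stop("allele position out of range")
  if (!toupper(allele) %in% .BASES) stop("allele must be one of A, C, G, T")
  edited <- paste0(substr(sequence, 1, pos), toupper(allele),
                   substr(sequence, pos + 2, len))
  max_pwm_score(mat, edited)
}

#' Mean per-column information content of a PWM
#'
#' Columns are converted to probabilities with the pseudocount; information
#' content per column is `2 + sum(p * log2(p))` bits. Used to pick one PWM
#' when several share a TF: the matrix with the highest information content
#' per column wins.
#'
#' @param x a [pwm()].
#' @param pseudocount as in [logodds_matrix()].
#' @return numeric scalar, bits per column.
#' @export
pwm_information_content <- function(x, pseudocount = 1) {
  cts <- x$counts + pseudocount
  p <- sweep(cts, 2, colSums(cts), "/")
  mean(2 + colSums(p * log2(p)))
}

#' Choose one PWM per TF by information content
#'
#' @param pwms named list of [pwm()] objects; names are TF labels (several
#'   entries may share a TF label).
#' @return named list with one PWM per distinct TF label.
#' @export
select_pwms <- function(pwms) {
  tfs <- names(pwms)
  out <- lapply(unique(tfs), function(tf) {
    cand <- pwms[tfs == tf]
    ic <- vapply(cand, pwm_information_content, numeric(1))
    cand[[which.max(ic)]]
  })
  stats::setNames(out, unique(tfs))
}
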