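#' Per-cycle base content and quality profile
#'
#' Counts every base of every read at its sequencing cycle and accumulates
#' quality sums, giving the per-cycle base-content and mean-quality curves
#' that drive automatic trimming and the QC report.
#'
#' @param reads A [fastq_reads] data frame.
#' @return An object of class `cycle_profile` with fields `n_cycles`,
#'   `counts` (n_cycles x 5 matrix, columns A/C/G/T/N), `total` (reads
#'   covering each cycle) and `mean_qual` (arithmetic mean Phred score per
#'   cycle).
#' @export
profile_cycles <- function(reads) {
  if (nrow(reads) == 0) {
    return(structure(list(n_cycles = 0L,
                          counts = matrix(0L, 0, 5,
                                          dimnames = list(NULL, c(.BASES, "N"))),
                          total = integer(), mean_qual = numeric()),
                     class = "cycle_profile"))
  }
  raw <- cycle_profile_cpp(reads$bases, reads$quals)
  counts <- raw$counts
  colnames(counts) <- c(.BASES, "N")
  structure(list(n_cycles = nrow(counts), counts = counts,
                 total = raw$total,
                 mean_qual = ifelse(raw$total > 0, raw$qual_sum / raw$total, 0)),
            class = "cycle_profile")
}

#' @export
print.cycle_profile <- function(x, ...) {
  cat("<cycle_profile> ", x$n_cycles, " cycles, ",
      if (x$n_cycles > 0) paste0(x$total[1], " reads at cycle 1, mean Q",
                                 round(mean(x$mean_qual), 1)), "\n", sep = "")
  invisible(x)
}

#' Per-cycle base content fractions
#'
#' @param profile A `cycle_profile`.
#' @return An n_cycles x 5 matrix of fractions of the per-cycle total.
#' @export
base_content <- function(profile) {
  tot <- pmax(profile$total, 1L)
  profile$counts / tot
}

#' Per-cycle GC percentage
#'
#' GC% at a cycle is (G+C)/(A+C+G+T): N is excluded from the denominator.
#'
#' @param profile A `cycle_profile`.
#' @return Numeric vector of GC fractions per cycle.
#' @export
gc_content <- function(profile) {
  acgt <- rowSums(profile$counts[, .BASES, drop = FALSE])
  gc <- rowSums(profile$counts[, c("G", "C"), drop = FALSE])
  ifelse(acgt > 0, gc / acgt, 0)
}

#' Number of discontinued bases in a sequence
#'
#' The number of adjacent positions whose bases differ: `"ATCGA"` has 4
#' (every neighbour differs), `"AAAAA"` has 0. Sequences of length 0 or 1
#' give 0.
#'
#' @param seq Character vector of sequences (vectorised).
#' @return Integer vector of change-point counts.
#' @export
discontinued_count <- function(seq) {
  vapply(seq, function(s) {
    n <- nchar(s)
    if (n < 2) return(0L)
    r <- charToRaw(s)
    sum(r[-1] != r[-n])
  }, integer(1), USE.NAMES = FALSE)
}

#' Mean discontinuity over a sliding window of cycles
#'
#' For each window start c, the mean over reads of
#' `discontinued_count(bases[c : c+window-1])`. A stable curve is a
#' sequencing-health diagnostic; a drop usually reflects a per-cycle
#' washing issue. Reads shorter than the window end are skipped for that
#' window.
#'
#' @param reads A [fastq_reads] data frame.
#' @param window Window width in cycles (>= 2).
#' @return Numeric vector of mean discontinuity, one value per window
#'   start; `NA` where no read covers the window.
#' @export
discontinuity_curve <- function(reads, window = 5L) {
  if (window < 2) stop("window must be >= 2", call. = FALSE)
  lens <- nchar(reads$bases)
  n_cycles <- if (length(lens)) max(lens) else 0L
  n_starts <- n_cycles - window + 1L
  if (n_starts < 1) return(numeric())
  # per-read adjacent-change indicators, accumulated per position by length
  diffs <- lapply(reads$bases, function(s) {
    r <- charToRaw(s)
    n <- length(r)
    if (n < 2) logical(0) else r[-1] != r[-n]
  })
  out <- numeric(n_starts)
  for (c in seq_len(n_starts)) {
    idx <- which(lens >= c + window - 1L)
    if (length(idx) == 0) { out[c] <- NA_real_; next }
    span <- c:(c + window - 2L)
    out[c] <- mean(vapply(diffs[idx], function(d) sum(d[span]), numeric(1)))
  }
  out
}

#' K-mer strand-bias counts
#'
#' If amplification and sequencing are strand-uniform, a short k-mer and
#' its reverse complement should repeat about equally often. This slides a
#' width-k window over the first `max_reads` reads and tallies each N-free
#' k-mer under its canonical form (the lexicographically smaller of the
#' k-mer and its reverse complement): the canonical spelling counts as
#' forward, the other as reverse.
#'
#' `k` must be even, matching the default diagnostic of an 8-mer against
#' its reverse complement. Reverse-complement palindromic k-mers (possible
#' at even k) count on the forward side.
#'
#' @param reads A [fastq_reads] data frame.
#' @param k K-mer width (even, >= 2).
#' @param max_reads Sample at most this many reads (a diagnostic does not
#'   need full counting).
#' @return A data frame of class `strand_bias_table` with columns `kmer`,
#'   `fwd`, `rev` and attribute `k`.
#' @export
kmer_strand_counts <- function(reads, k = 8L, max_reads = 100000L) {
  if (k < 2 || k %% 2 != 0) stop("k must be even and >= 2", call. = FALSE)
  if (max_reads < 1) stop("max_reads must be positive", call. = FALSE)
  bases <- head(reads$bases, max_reads)
  kmers <- unlist(lapply(bases, function(b) {
    n <- nchar(b)
    if (n < k) return(character())
    substring(b, 1:(n - k + 1), k:n)
  }))
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  tab <- empty_bias_table(k)
  if (length(kmers) == 0) return(tab)
  rc <- revcomp(kmers)
  canon <- pmin(kmers, rc)
  is_fwd <- kmers <= rc
  f <- factor(canon)
  fwd <- as.integer(rowsum(as.integer(is_fwd), f))
  rev <- as.integer(rowsum(as.integer(!is_fwd), f))
  tab <- data.frame(kmer = levels(f), fwd = fwd, rev = rev,
                    stringsAsFactors = FALSE)
  structure(tab, k = k, class = c("strand_bias_table", "data.frame"))
}

empty_bias_table <- function(k) {
  structure(data.frame(kmer = character(), fwd = integer(), rev = integer(),
                       stringsAsFactors = FALSE),
            k = k, class = c("strand_bias_table", "data.frame"))
}

#' Single-number strand-bias summary
#'
#' The count-weighted mean over k-mers of |fwd - rev| / (fwd + rev):
#' 0 for perfect balance, 1 when every k-mer is seen on one strand only.
#'
#' @param table A `strand_bias_table`.
#' @return A scalar in \[0, 1\].
#' @export
bias_summary <- function(table) {
  if (nrow(table) == 0) stop("empty strand-bias table", call. = FALSE)
  sum(abs(table$fwd - table$rev)) / sum(table$fwd + table$rev)
}
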