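#' Error-tolerant polyX detection
#'
#' Detects a long near-homopolymer stretch of one base X (X in A/C/G/T):
#' a window of `P` consecutive positions starting and ending on X with at
#' most `L` positions not equal to X. Anchoring both window ends on X stops
#' tolerated non-X bases from dangling at the run edges. N counts as non-X.
#' On two-channel sequencers the no-signal artifact appears as polyG; such
#' reads carry high quality scores, so a quality filter cannot remove them.
#'
#' @param seq A single sequence.
#' @param P Minimum polyX window length (default 35).
#' @param L Maximum tolerated non-X bases inside the window (default 2).
#' @return A list: `found` (logical); when found, `base` (the X), `start`
#'   and `end` (1-based inclusive window bounds, the leftmost qualifying
#'   window for the first qualifying X in A, C, G, T order).
#' @export
detect_polyx <- function(seq, P = 35L, L = 2L) {
  stopifnot(P >= 1, L >= 0, L < P)
  n <- nchar(seq)
  if (n >= P) {
    r <- charToRaw(seq)
    for (X in .BASES) {
      isx <- r == charToRaw(X)
      if (sum(isx) < P - L) next
      cs <- c(0L, cumsum(!isx))
      starts <- seq_len(n - P + 1L)
      ok <- isx[starts] & isx[starts + P - 1L] &
        (cs[starts + P] - cs[starts]) <= L
      if (any(ok)) {
        i <- starts[which(ok)[1]]
        return(list(found = TRUE, base = X, start = i, end = i + P - 1L))
      }
    }
  }
  list(found = FALSE, base = NA_character_, start = NA_integer_,
       end = NA_integer_)
}

#' Vectorised polyX scan over a read set
#'
#' @param reads A [fastq_reads] data frame.
#' @inheritParams detect_polyx
#' @return A data frame with columns `found`, `base`, `start`, `end`, one
#'   row per read.
#' @export
detect_polyx_reads <- function(reads, P = 35L, L = 2L) {
  res <- lapply(reads$bases, detect_polyx, P = P, L = L)
  data.frame(found = vapply(res, `[[`, logical(1), "found"),
             base = vapply(res, `[[`, character(1), "base"),
             start = vapply(res, `[[`, integer(1), "start"),
             end = vapply(res, `[[`, integer(1), "end"),
             stringsAsFactors = FALSE)
}

#' Quality and N-content filter
#'
#' A read fails with reason `"quality"` when it has more than
#' `max_low_qual` bases below `low_qual_threshold` or a mean Phred score
#' below `min_mean_qual`, and with reason `"n_count"` when it has more than
#' `max_n` N bases. The quality reason is reported first when both apply.
#'
#' @param reads A [fastq_reads] data frame.
#' @param low_qual_threshold Phred score below which a base counts as low
#'   quality.
#' @param max_low_qual Maximum tolerated low-quality bases; `NULL` scales
#'   to 40% of each read's length.
#' @param max_n Maximum tolerated N bases.
#' @param min_mean_qual Minimum mean Phred score.
#' @return A data frame with columns `passed` (logical) and `reason`
#'   (`""`, `"quality"` or `"n_count"`), one row per read.
#' @export
quality_filter <- function(reads, low_qual_threshold = 15L,
                           max_low_qual = NULL, max_n = 5L,
                           min_mean_qual = 20) {
  n <- nrow(reads)
  if (n == 0)
    return(data.frame(passed = logical(), reason = character(),
                      stringsAsFactors = FALSE))
  st <- read_qual_stats_cpp(reads$bases, reads$quals,
                            as.integer(low_qual_threshold))
  lens <- nchar(reads$bases)
  maxlow <- if (is.null(max_low_qual)) floor(0.40 * lens) else max_low_qual
  fail_q <- st$low_count > maxlow | st$mean_qual < min_mean_qual
  fail_n <- st$n_count > max_n
  reason <- character(n)
  reason[fail_n] <- "n_count"
  reason[fail_q] <- "quality"  # quality reported first when both apply
  data.frame(passed = !(fail_q | fail_n), reason = reason,
             stringsAsFactors = FALSE)
}

#' Bubble-region filter
#'
#' Fails reads whose flowcell coordinates lie strictly inside a detected
#' bubble circle of their lane and tile. Reads without parseable
#' coordinates always pass.
#'
#' @param coords A data frame from [parse_coords()] (columns `lane`,
#'   `tile`, `x`, `y`; `NA` rows pass).
#' @param circles A `bubble_circles` data frame from [detect_bubbles()].
#' @return A data frame with columns `passed` and `reason` (`""` or
#'   `"bubble"`).
#' @export
bubble_filter <- function(coords, circles) {
  n <- nrow(coords)
  fail <- logical(n)
  if (!is.null(circles) && nrow(circles) > 0 && n > 0) {
    for (ci in seq_len(nrow(circles))) {
      cc <- circles[ci, ]
      sel <- !is.na(coords$lane) & coords$lane == cc$lane &
        coords$tile == cc$tile
      if (!any(sel)) next
      d2 <- (coords$x[sel] - cc$cx)^2 + (coords$y[sel] - cc$cy)^2
      fail[sel] <- fail[sel] | d2 < cc$r^2
    }
  }
  data.frame(passed = !fail, reason = ifelse(fail, "bubble", ""),
             stringsAsFactors = FALSE)
}

#' Annotate a failed read with its filter name
#'
#' Appends `" qcfail:<reason>"` to the read name; the original name is kept
#' verbatim and bases/qualities are untouched. Not idempotent: annotating
#' twice appends twice, so callers annotate once.
#'
#' @param reads A [fastq_reads] data frame.
#' @param reason Non-empty filter name(s), recycled over reads.
#' @return The annotated [fastq_reads].
#' @export
annotate_bad <- function(reads, reason) {
  stopifnot(all(nzchar(reason)))
  if (nrow(reads) > 0)
    reads$name <- paste0(reads$name, " qcfail:", reason)
  reads
}
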