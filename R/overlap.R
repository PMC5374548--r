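#' Levenshtein edit distance
#'
#' Unit-cost substitutions, insertions and deletions, via [utils::adist()].
#'
#' @param a,b Character vectors (recycled pairwise).
#' @return Integer vector of distances.
#' @export
edit_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  vapply(seq_len(n), function(i) as.integer(adist(a[i], b[i])), integer(1))
}

#' Find the best overlap of a read pair
#'
#' The engine of paired-end analysis. R2 is reverse-complemented and placed
#' under R1 at every candidate offset O; the vertically aligned slices are
#' compared by edit distance and the O with the global minimum wins (ties
#' broken toward larger overlap, then smaller |O|, then positive O — the
#' least destructive interpretation). For an error-free pair from a
#' template of length T read at length S, O = T - S: a 60 bp template at
#' 2x50 overlaps 40 bp at offset 10; a negative O means the template is
#' shorter than the read and the bases beyond it are adapter.
#'
#' The pair counts as overlapped when the overlap length reaches
#' `min_overlap` and the edit distance is at most
#' `floor(max_ed_fraction * overlap_len)`.
#'
#' @param r1,r2 One-row [fastq_reads] (or lists with `bases` and `quals`).
#' @param min_overlap Minimum acceptable overlap length (bp). This also
#'   bounds the offset search range, so detecting adapters on templates
#'   shorter than `min_overlap` requires lowering it.
#' @param max_ed_fraction Maximum edit distance as a fraction of the
#'   overlap length.
#' @return An object of class `overlap_result`: `offset`, `overlap_len`,
#'   `edit_dist`, `hamming_dist` (`NA` when no overlap was evaluated),
#'   `overlapped`, and `mismatch` — a data frame of positional mismatches
#'   of the aligned slices with 1-based positions in each mate, bases,
#'   Phred scores, and `mate_base` (R2's base expressed in R1 orientation).
#' @export
find_overlap <- function(r1, r2, min_overlap = 30L, max_ed_fraction = 0.05) {
  b1 <- r1$bases[1]; q1 <- r1$quals[1]
  b2 <- r2$bases[1]; q2 <- r2$quals[1]
  stopifnot(nchar(b1) > 0, nchar(b2) > 0)
  c2 <- revcomp(b2)
  scan <- overlap_scan_cpp(b1, c2, as.integer(min_overlap))
  res <- list(offset = scan$offset[1], overlap_len = scan$overlap_len[1],
              edit_dist = scan$edit_dist[1], hamming_dist = NA_integer_,
              overlapped = FALSE, mismatch = NULL)
  class(res) <- "overlap_result"
  if (is.na(res$offset)) return(res)
  mm <- overlap_mismatches(b1, q1, b2, q2, res$offset, res$overlap_len)
  res$hamming_dist <- nrow(mm)
  res$mismatch <- mm
  max_ed <- max(0, floor(max_ed_fraction * res$overlap_len))
  res$overlapped <- res$overlap_len >= min_overlap && res$edit_dist <= max_ed
  res
}

# Positional comparison of the aligned slices at a given offset; c2 may be
# passed in when the reverse complement of r2 is already at hand.
overlap_mismatches <- function(b1, q1, b2, q2, offset, overlap_len,
                               c2 = NULL) {
  la <- nchar(b1); lb <- nchar(b2)
  a_start <- max(offset, 0L)           # 0-based
  b_start <- max(-offset, 0L)          # 0-based, into revcomp(r2)
  L <- overlap_len
  if (is.null(c2)) c2 <- revcomp(b2)
  a <- charToRaw(substr(b1, a_start + 1L, a_start + L))
  b <- charToRaw(substr(c2, b_start + 1L, b_start + L))
  idx <- which(a != b)
  if (length(idx) == 0) {
    return(data.frame(pos_r1 = integer(), pos_r2 = integer(),
                      r1_base = character(), r1_qual = integer(),
                      r2_base = character(), r2_qual = integer(),
                      mate_base = character(), stringsAsFactors = FALSE))
  }
  pos_r1 <- a_start + idx
  pos_c <- b_start + idx
  pos_r2 <- lb - pos_c + 1L
  df <- data.frame(
    pos_r1 = pos_r1,
    pos_r2 = pos_r2,
    r1_base = substring(b1, pos_r1, pos_r1),
    r1_qual = as.integer(charToRaw(q1))[pos_r1] - 33L,
    r2_base = substring(b2, pos_r2, pos_r2),
    r2_qual = as.integer(charToRaw(q2))[pos_r2] - 33L,
    stringsAsFactors = FALSE)
  df$mate_base <- unname(.COMPLEMENT[df$r2_base])
  df
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("<overlap_result> offset =", x$offset, ", overlap_len =",
      x$overlap_len, ", edit_dist =", x$edit_dist, ", hamming =",
      x$hamming_dist, ", overlapped =", x$overlapped, "\n")
  invisible(x)
}

#' Batch overlap scan
#'
#' Runs the offset search of [find_overlap()] over whole read sets in one
#' compiled pass; mismatch details are not materialised (fetch them per
#' pair with [find_overlap()] where needed).
#'
#' @param r1,r2 [fastq_reads] data frames of equal row count.
#' @inheritParams find_overlap
#' @return A data frame with columns `offset`, `overlap_len`, `edit_dist`,
#'   `hamming_dist`, `overlapped`.
#' @export
find_overlaps <- function(r1, r2, min_overlap = 30L, max_ed_fraction = 0.05) {
  stopifnot(nrow(r1) == nrow(r2))
  if (nrow(r1) == 0)
    return(data.frame(offset = integer(), overlap_len = integer(),
                      edit_dist = integer(), hamming_dist = integer(),
                      overlapped = logical()))
  c2 <- revcomp(r2$bases)
  scan <- overlap_scan_cpp(r1$bases, c2, as.integer(min_overlap))
  out <- data.frame(offset = scan$offset, overlap_len = scan$overlap_len,
                    edit_dist = scan$edit_dist,
                    hamming_dist = NA_integer_, overlapped = FALSE)
  max_ed <- pmax(0, floor(max_ed_fraction * out$overlap_len))
  out$overlapped <- !is.na(out$offset) & out$overlap_len >= min_overlap &
    out$edit_dist <= max_ed
  # hamming needed only where the slices differ (edit_dist > 0); equal
  # slices have hamming 0 by construction
  out$hamming_dist[out$overlapped & out$edit_dist == 0] <- 0L
  need <- which(out$overlapped & out$edit_dist > 0)
  for (i in need) {
    mm <- overlap_mismatches(r1$bases[i], r1$quals[i], r2$bases[i],
                             r2$quals[i], out$offset[i], out$overlap_len[i],
                             c2 = c2[i])
    out$hamming_dist[i] <- nrow(mm)
  }
  out
}

#' Estimate the sequencing error rate from read-pair overlaps
#'
#' Runs the batch overlap scan and accumulates [error_stats()] over every
#' accepted substitution-only overlap: total and mismatched overlapped
#' bases, the 12-category base-transform spectrum from quality-asymmetric
#' mismatches, and the unprofiled remainder. The estimated per-base error
#' rate is `mismatched / total`.
#'
#' @param r1,r2 [fastq_reads] data frames of equal row count.
#' @inheritParams find_overlap
#' @inheritParams accumulate_error_stats
#' @return A list: `stats` (an `error_stats`), `overlaps` (the batch scan
#'   data frame) and `rate` (the point estimate, `NA` if nothing was
#'   profiled).
#' @export
estimate_error_rate <- function(r1, r2, min_overlap = 30L,
                                max_ed_fraction = 0.05,
                                min_profile_overlap = 50L,
                                high_q = 30L, low_q = 15L) {
  ov <- find_overlaps(r1, r2, min_overlap, max_ed_fraction)
  c2 <- revcomp(r2$bases)
  stats <- error_stats()
  for (i in which(ov$overlapped)) {
    if (ov$edit_dist[i] > 0 && ov$hamming_dist[i] != ov$edit_dist[i])
      next  # indel difference: not profiled
    mm <- if (ov$edit_dist[i] > 0)
      overlap_mismatches(r1$bases[i], r1$quals[i], r2$bases[i],
                         r2$quals[i], ov$offset[i], ov$overlap_len[i],
                         c2 = c2[i])
    else NULL
    res <- structure(list(offset = ov$offset[i],
                          overlap_len = ov$overlap_len[i],
                          edit_dist = ov$edit_dist[i],
                          hamming_dist = ov$hamming_dist[i],
                          overlapped = TRUE, mismatch = mm),
                     class = "overlap_result")
    stats <- accumulate_error_stats(res, stats, min_profile_overlap,
                                    high_q, low_q)
  }
  rate <- if (stats$total_overlapped_bases > 0)
    stats$mismatched_bases / stats$total_overlapped_bases else NA_real_
  list(stats = stats, overlaps = ov, rate = rate)
}

#' Cut read-through adapters at a negative offset
#'
#' A negative best offset means the DNA template is shorter than the read
#' length, so both 3' tails beyond the template are adapter: each mate is
#' truncated to the template length `offset + len(r2)` (no adapter sequence
#' input needed).
#'
#' @param r1,r2 One-row [fastq_reads].
#' @param result An `overlap_result` with `overlapped = TRUE` and a
#'   negative offset.
#' @return A list with truncated `r1` and `r2`.
#' @export
cut_adapters <- function(r1, r2, result) {
  if (!isTRUE(result$overlapped) || result$offset >= 0)
    stop("cut_adapters requires an overlapped result with negative offset",
         call. = FALSE)
  tlen <- result$offset + nchar(r2$bases[1])
  r1$bases[1] <- substr(r1$bases[1], 1L, tlen)
  r1$quals[1] <- substr(r1$quals[1], 1L, tlen)
  r2$bases[1] <- substr(r2$bases[1], 1L, tlen)
  r2$quals[1] <- substr(r2$quals[1], 1L, tlen)
  list(r1 = r1, r2 = r2)
}

#' Correct quality-asymmetric mismatches in an overlap
#'
#' Every overlapped base was sequenced twice. When the aligned slices
#' differ only by substitutions (Hamming distance equals edit distance) and
#' a mismatch pairs a very high quality base (>= `high_q`) with a very low
#' quality one (< `low_q`), the low-quality base is a sequencing error and
#' is overwritten with its mate's call (reverse-complemented into the
#' mate's orientation), along with its quality. Indel-bearing overlaps
#' (Hamming != edit) are uncorrectable and returned unchanged, as are
#' balanced-quality mismatches.
#'
#' @param r1,r2 One-row [fastq_reads].
#' @param result An `overlap_result` with `overlapped = TRUE` and
#'   `edit_dist > 0`.
#' @param high_q,low_q Phred thresholds for "very high" / "very low"
#'   quality.
#' @return A list: corrected `r1`, `r2`, `corrected` (number of fixed
#'   bases) and `uncorrectable` (`TRUE` when any mismatch remains).
#' @export
correct_pair <- function(r1, r2, result, high_q = 30L, low_q = 15L) {
  if (!isTRUE(result$overlapped) || result$edit_dist == 0)
    stop("correct_pair requires an overlapped result with edit_dist > 0",
         call. = FALSE)
  if (is.na(result$hamming_dist) || result$hamming_dist != result$edit_dist)
    return(list(r1 = r1, r2 = r2, corrected = 0L, uncorrectable = TRUE))
  mm <- result$mismatch
  corrected <- 0L
  remaining <- 0L
  b1 <- strsplit(r1$bases[1], "")[[1]]
  s1 <- as.integer(charToRaw(r1$quals[1])) - 33L
  b2 <- strsplit(r2$bases[1], "")[[1]]
  s2 <- as.integer(charToRaw(r2$quals[1])) - 33L
  for (k in seq_len(nrow(mm))) {
    m <- mm[k, ]
    if (m$r1_qual >= high_q && m$r2_qual < low_q) {
      # r1 is trusted: rewrite r2's base as the complement of r1's call
      b2[m$pos_r2] <- unname(.COMPLEMENT[m$r1_base])
      s2[m$pos_r2] <- m$r1_qual
      corrected <- corrected + 1L
    } else if (m$r2_qual >= high_q && m$r1_qual < low_q) {
      b1[m$pos_r1] <- m$mate_base
      s1[m$pos_r1] <- m$r2_qual
      corrected <- corrected + 1L
    } else {
      remaining <- remaining + 1L
    }
  }
  r1$bases[1] <- paste(b1, collapse = "")
  r1$quals[1] <- phred_chars(list(s1))
  r2$bases[1] <- paste(b2, collapse = "")
  r2$quals[1] <- phred_chars(list(s2))
  list(r1 = r1, r2 = r2, corrected = corrected,
       uncorrectable = remaining > 0L)
}

#' Fresh sequencing-error statistics accumulator
#'
#' @return An `error_stats` list: `total_overlapped_bases`,
#'   `mismatched_bases`, `transform_counts` (the 12 ordered true->observed
#'   substitution categories) and `unprofiled_mismatches`
#'   (balanced-quality pairs that cannot be oriented).
#' @export
error_stats <- function() {
  structure(list(total_overlapped_bases = 0L, mismatched_bases = 0L,
                 transform_counts = setNames(integer(12), .TRANSFORMS),
                 unprofiled_mismatches = 0L),
            class = "error_stats")
}

#' @export
print.error_stats <- function(x, ...) {
  rate <- if (x$total_overlapped_bases > 0)
    x$mismatched_bases / x$total_overlapped_bases else NA_real_
  cat("<error_stats> ", x$mismatched_bases, "/", x$total_overlapped_bases,
      " mismatched (rate ", format(rate, digits = 3), "), ",
      x$unprofiled_mismatches, " unprofiled\n", sep = "")
  invisible(x)
}

#' Accumulate sequencing-error statistics from one overlap
#'
#' Only long overlaps (`overlap_len > min_profile_overlap`) are profiled:
#' there, mismatches are dominated by sequencing error, so
#' mismatched/total estimates the per-base error rate. A mismatch pairing
#' a >= `high_q` base with a < `low_q` base is attributed as the
#' low-quality base being the error, and counted in the true->observed
#' transform category with both bases expressed in R1 orientation;
#' balanced mismatches are tallied as unprofiled.
#'
#' @param result An `overlap_result` (overlapped, Hamming distance
#'   available, i.e. from [find_overlap()]).
#' @param stats An `error_stats` accumulator.
#' @param min_profile_overlap Only overlaps strictly longer than this are
#'   profiled.
#' @param high_q,low_q Phred thresholds of the attribution rule.
#' @return The updated `error_stats`.
#' @export
accumulate_error_stats <- function(result, stats, min_profile_overlap = 50L,
                                   high_q = 30L, low_q = 15L) {
  if (!isTRUE(result$overlapped) || is.na(result$hamming_dist))
    stop("accumulate_error_stats requires an overlapped result with ",
         "Hamming distance", call. = FALSE)
  if (result$overlap_len <= min_profile_overlap) return(stats)
  stats$total_overlapped_bases <-
    stats$total_overlapped_bases + result$overlap_len
  stats$mismatched_bases <- stats$mismatched_bases + result$hamming_dist
  mm <- result$mismatch
  for (k in seq_len(NROW(mm))) {
    m <- mm[k, ]
    if (m$r1_qual >= high_q && m$r2_qual < low_q) {
      key <- paste0(m$r1_base, "->", m$mate_base)
    } else if (m$r2_qual >= high_q && m$r1_qual < low_q) {
      key <- paste0(m$mate_base, "->", m$r1_base)
    } else {
      stats$unprofiled_mismatches <- stats$unprofiled_mismatches + 1L
      next
    }
    if (key %in% names(stats$transform_counts))
      stats$transform_counts[key] <- stats$transform_counts[key] + 1L
    else  # mismatch involving N cannot be categorised
      stats$unprofiled_mismatches <- stats$unprofiled_mismatches + 1L
  }
  stats
}

#' Merge an overlapped pair into one high-quality read
#'
#' Returns the overlapped region as a single read in R1 orientation:
#' R1's base calls (after correction the mates agree; where they still
#' disagree R1's call is kept) with the per-position maximum of the two
#' mates' qualities — each base was confirmed twice. Converts paired-end
#' data into clean single-end data when only overlapped regions are
#' stored.
#'
#' @param r1,r2 One-row [fastq_reads] (correction already applied).
#' @param result The matching `overlap_result` with `overlapped = TRUE`.
#' @return A one-row [fastq_reads]; name is R1's name plus `" merged"`.
#' @export
merge_overlap <- function(r1, r2, result) {
  if (!isTRUE(result$overlapped))
    stop("merge_overlap requires an overlapped pair", call. = FALSE)
  a_start <- max(result$offset, 0L)
  b_start <- max(-result$offset, 0L)
  L <- result$overlap_len
  bases <- substr(r1$bases[1], a_start + 1L, a_start + L)
  qa <- (as.integer(charToRaw(r1$quals[1])) - 33L)[(a_start + 1L):(a_start + L)]
  qc_rev <- rev(as.integer(charToRaw(r2$quals[1])) - 33L)  # quals of revcomp(r2)
  qb <- qc_rev[(b_start + 1L):(b_start + L)]
  fastq_reads(paste0(r1$name[1], " merged"), bases,
              phred_chars(list(pmax(qa, qb))))
}
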