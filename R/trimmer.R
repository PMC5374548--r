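#' Is a sequencing cycle abnormal?
#'
#' A cycle is abnormal when it meets any of: (1) a single base's mean
#' content above 40% or below 15% (N exempt); (2) a base's content changing
#' by more than 10 percentage points versus the neighbouring cycle toward
#' the centre; (3) GC above 70% or below 30%; (4) mean quality below Q20.
#' All comparisons are strict. The front side applies only the GC and
#' quality criteria (3)-(4): unflat base content at the very start of reads
#' usually reflects the fragmentation method rather than a sequencing
#' artifact and is preserved, whereas tail unflatness is an artifact and
#' triggers all four criteria.
#'
#' Cycles supported by fewer than 10% of the maximum per-cycle read count
#' (sparse tails of variable-length files) are never marked abnormal.
#'
#' @param profile A `cycle_profile`.
#' @param cycle 0-based cycle index.
#' @param side `"front"` or `"tail"` — which end of the read the scan is
#'   expanding toward.
#' @param content_hi,content_lo,content_jump,gc_hi,gc_lo,min_qual Criterion
#'   thresholds (fractions for content/GC, Phred for quality).
#' @return Logical; attribute `"reason"` carries a human-readable cause
#'   when abnormal.
#' @export
is_abnormal_cycle <- function(profile, cycle, side = c("tail", "front"),
                              content_hi = 0.40, content_lo = 0.15,
                              content_jump = 0.10, gc_hi = 0.70,
                              gc_lo = 0.30, min_qual = 20) {
  side <- match.arg(side)
  n <- profile$n_cycles
  if (cycle < 0 || cycle >= n) stop("cycle out of range", call. = FALSE)
  i <- cycle + 1L
  if (profile$total[i] < 0.10 * max(profile$total))
    return(structure(FALSE, reason = ""))
  content <- base_content(profile)
  gc <- gc_content(profile)
  abn <- function(reason) structure(TRUE, reason = reason)

  if (side == "tail") {
    cc <- content[i, .BASES]
    if (any(cc > content_hi))
      return(abn(sprintf("base content %.1f%% > %.0f%%",
                         100 * max(cc), 100 * content_hi)))
    if (any(cc < content_lo))
      return(abn(sprintf("base content %.1f%% < %.0f%%",
                         100 * min(cc), 100 * content_lo)))
    centre <- n %/% 2  # 0-based
    j <- if (cycle > centre) i - 1L else i + 1L
    if (j >= 1 && j <= n) {
      jump <- abs(content[i, .BASES] - content[j, .BASES])
      if (any(jump > content_jump))
        return(abn(sprintf("base content change %.1f points > %.0f",
                           100 * max(jump), 100 * content_jump)))
    }
  }
  if (gc[i] > gc_hi)
    return(abn(sprintf("GC %.1f%% > %.0f%%", 100 * gc[i], 100 * gc_hi)))
  if (gc[i] < gc_lo)
    return(abn(sprintf("GC %.1f%% < %.0f%%", 100 * gc[i], 100 * gc_lo)))
  if (profile$mean_qual[i] < min_qual)
    return(abn(sprintf("mean quality Q%.1f < Q%.0f",
                       profile$mean_qual[i], min_qual)))
  structure(FALSE, reason = "")
}

#' Decide a global (front, tail) trim from a cycle profile
#'
#' Global trimming removes the same cycles from every read of a file, so
#' duplicated reads stay identical and downstream de-duplication keeps
#' working — unlike per-read local trimming. The central cycle is
#' initialised as good unconditionally; the good region expands outward one
#' cycle at a time on each side independently, stopping at the first
#' abnormal cycle for that side (front expansion uses the front criteria,
#' tail expansion the tail criteria). The result is capped: no more than
#' `front_max_percent`% of cycles in front and `tail_max_percent`% in tail
#' (floor), so chaotic low-quality files are not trimmed away wholesale.
#'
#' @param profile A `cycle_profile`.
#' @param front_max_percent,tail_max_percent Trim caps as percentages of
#'   the cycle count.
#' @param ... Passed to [is_abnormal_cycle()] (criterion thresholds).
#' @return A list of class `trim_decision` with integer fields `front` and
#'   `tail` (cycles removed from each end).
#' @export
compute_trim <- function(profile, front_max_percent = 10,
                         tail_max_percent = 5, ...) {
  n <- profile$n_cycles
  if (n < 1) stop("profile has no cycles", call. = FALSE)
  centre <- n %/% 2  # 0-based; forced good
  lo <- centre
  while (lo > 0 && !is_abnormal_cycle(profile, lo - 1L, side = "front", ...))
    lo <- lo - 1L
  hi <- centre
  while (hi < n - 1L && !is_abnormal_cycle(profile, hi + 1L, side = "tail", ...))
    hi <- hi + 1L
  front <- min(lo, floor(n * front_max_percent / 100))
  tail <- min(n - 1L - hi, floor(n * tail_max_percent / 100))
  structure(list(front = as.integer(front), tail = as.integer(tail)),
            class = "trim_decision")
}

#' @export
print.trim_decision <- function(x, ...) {
  cat("<trim_decision> front =", x$front, ", tail =", x$tail, "\n")
  invisible(x)
}

#' Apply a trim decision to reads
#'
#' Slices bases and qualities identically; names are unchanged. Reads too
#' short to survive (`length <= front + tail`) are not an error: they are
#' flagged so the caller can route them to the bad stream with reason
#' `"too_short_after_trim"`.
#'
#' @param reads A [fastq_reads] data frame.
#' @param decision A `trim_decision` (or list with `front`, `tail`).
#' @return A list: `reads` (trimmed survivors and untouched too-short reads,
#'   in input order) and `too_short` (logical flag per input read).
#' @export
apply_trim <- function(reads, decision) {
  front <- decision$front
  tail <- decision$tail
  stopifnot(front >= 0, tail >= 0)
  lens <- nchar(reads$bases)
  too_short <- lens < front + tail + 1L
  ok <- !too_short
  out <- reads
  out$bases[ok] <- substr(reads$bases[ok], front + 1L, lens[ok] - tail)
  out$quals[ok] <- substr(reads$quals[ok], front + 1L, lens[ok] - tail)
  list(reads = out, too_short = too_short)
}
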