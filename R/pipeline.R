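#' Pipeline options
#'
#' All knobs of [run_pipeline()] in one list. Defaults follow the
#' package-wide conventions: global trimming capped at 10% front / 5%
#' tail, polyX at P = 35 / L = 2, quality filtering at Q15/Q20,
#' overlap acceptance at 30 bp and 5% edit distance, correction and
#' error profiling at Q30/Q15, error profiling restricted to overlaps
#' longer than 50 bp. Bubble detection is off by default (recommended for
#' two-channel sequencer output).
#'
#' @param trim Apply automatic global trimming.
#' @param trim_front,trim_tail Manual overrides of the automatic decision.
#' @param trim_front_max_percent,trim_tail_max_percent Trim caps.
#' @param poly_size,poly_tolerance PolyX parameters P and L.
#' @param low_qual,max_low_qual,max_n,min_mean_qual Quality filter
#'   parameters.
#' @param debubble Enable flowcell bubble detection (first pass collects
#'   polyX coordinates, second pass filters).
#' @param bubble A [bubble_params()] list.
#' @param min_overlap,max_ed_fraction Overlap acceptance thresholds.
#' @param correction Correct quality-asymmetric overlap mismatches.
#' @param qual_high,qual_low Phred thresholds of correction/attribution.
#' @param profile_min_overlap Error profiling requires overlaps strictly
#'   longer than this.
#' @param store_overlap_only Store only merged overlapped sub-sequences
#'   (single-end output); implies discarding non-overlapped pairs.
#' @param require_overlap Discard pairs whose overlap fails acceptance.
#' @param kmer_k,kmer_max_reads Strand-bias profiling parameters.
#' @param disc_window Discontinuity window width in cycles.
#' @return A list of class `pipeline_options`.
#' @export
pipeline_options <- function(trim = TRUE, trim_front = NULL, trim_tail = NULL,
                             trim_front_max_percent = 10,
                             trim_tail_max_percent = 5,
                             poly_size = 35L, poly_tolerance = 2L,
                             low_qual = 15L, max_low_qual = NULL,
                             max_n = 5L, min_mean_qual = 20,
                             debubble = FALSE, bubble = bubble_params(),
                             min_overlap = 30L, max_ed_fraction = 0.05,
                             correction = TRUE, qual_high = 30L,
                             qual_low = 15L, profile_min_overlap = 50L,
                             store_overlap_only = FALSE,
                             require_overlap = FALSE,
                             kmer_k = 8L, kmer_max_reads = 100000L,
                             disc_window = 5L) {
  structure(as.list(environment()), class = "pipeline_options")
}

#' Run the QC and filtering pipeline on one file or pair
#'
#' Stage order: bubble detection (optional first pass), pre-filtering QC
#' profiling, automatic global trimming, per-read filtering (quality, N
#' count, polyX, bubble), overlap analysis with adapter cutting and error
#' correction for paired-end input, then output of good/bad (and
#' optionally merged) reads, post-filtering QC and the report.
#' Single-end input skips all overlap stages. For paired-end data a pair
#' is the filtering unit: if either mate fails, both go to the bad
#' stream.
#'
#' @param r1_path Path to the (first) FASTQ file.
#' @param r2_path Optional mate file for paired-end data.
#' @param outdir Optional output directory; when given, `good/`, `bad/`
#'   (and `merged/`) FASTQ plus `report.json` and `report.html` are
#'   written.
#' @param options A [pipeline_options()] list.
#' @return A `run_summary` object.
#' @export
run_pipeline <- function(r1_path, r2_path = NULL, outdir = NULL,
                         options = pipeline_options()) {
  o <- options
  r1 <- read_fastq(r1_path)
  paired <- !is.null(r2_path) && !is.na(r2_path)
  r2 <- if (paired) read_fastq(r2_path) else NULL
  if (paired && nrow(r1) != nrow(r2))
    stop("record count mismatch between mates: ", nrow(r1), " vs ",
         nrow(r2), call. = FALSE)
  n <- nrow(r1)
  message(sprintf("[pipeline] %s%s: %d %s in",
                  basename(r1_path),
                  if (paired) paste0(" + ", basename(r2_path)) else "",
                  n, if (paired) "pairs" else "reads"))

  # -- stage 1: bubble detection (first pass over polyX coordinates) -----
  circles <- NULL
  if (o$debubble) {
    hits <- collect_polyx_hits(r1, P = o$poly_size, L = o$poly_tolerance)
    if (paired)
      hits <- rbind(hits, collect_polyx_hits(r2, P = o$poly_size,
                                             L = o$poly_tolerance))
    circles <- detect_bubbles(hits, o$bubble)
    message(sprintf("[pipeline] debubble: %d polyX hits, %d circles",
                    nrow(hits), nrow(circles)))
  }

  # -- stage 2: pre-filtering QC -----------------------------------------
  pre1 <- profile_cycles(r1)
  pre2 <- if (paired) profile_cycles(r2) else NULL

  # -- stage 3: automatic global trimming --------------------------------
  decide <- function(profile) {
    if (!o$trim) return(structure(list(front = 0L, tail = 0L),
                                  class = "trim_decision"))
    if (!is.null(o$trim_front) || !is.null(o$trim_tail)) {
      return(structure(list(front = as.integer(o$trim_front %||% 0L),
                            tail = as.integer(o$trim_tail %||% 0L)),
                       class = "trim_decision"))
    }
    compute_trim(profile, o$trim_front_max_percent, o$trim_tail_max_percent)
  }
  d1 <- decide(pre1)
  d2 <- if (paired) decide(pre2) else NULL
  t1 <- apply_trim(r1, d1)
  r1 <- t1$reads
  too_short <- t1$too_short
  if (paired) {
    t2 <- apply_trim(r2, d2)
    r2 <- t2$reads
    too_short <- too_short | t2$too_short
  }

  # -- stage 4: per-read filters -----------------------------------------
  reason <- character(n)
  reason[too_short] <- "too_short_after_trim"
  filter_mate <- function(reads) {
    rs <- character(nrow(reads))
    qf <- quality_filter(reads, o$low_qual, o$max_low_qual, o$max_n,
                         o$min_mean_qual)
    px <- detect_polyx_reads(reads, P = o$poly_size, L = o$poly_tolerance)
    rs[px$found] <- "polyX"
    rs[!qf$passed] <- qf$reason[!qf$passed]  # quality/n_count outrank polyX
    if (!is.null(circles) && nrow(circles) > 0) {
      bf <- bubble_filter(parse_coords(reads$name), circles)
      rs[!bf$passed & rs == ""] <- "bubble"
    }
    rs
  }
  m1 <- filter_mate(r1)
  m2 <- if (paired) filter_mate(r2) else character(n)
  mate_reason <- ifelse(m1 != "", m1, m2)
  reason[reason == "" & mate_reason != ""] <-
    mate_reason[reason == "" & mate_reason != ""]

  # -- stage 5: overlap analysis, adapter cutting, error correction ------
  stats <- error_stats()
  n_overlapped <- 0L; adapters_cut <- 0L; bases_corrected <- 0L
  merged <- NULL
  if (paired) {
    good_idx <- which(reason == "")
    if (length(good_idx) > 0) {
      ov <- find_overlaps(r1[good_idx, ], r2[good_idx, ],
                          o$min_overlap, o$max_ed_fraction)
      c2g <- revcomp(r2$bases[good_idx])
      merged_rows <- vector("list", length(good_idx))
      for (j in seq_along(good_idx)) {
        if (!ov$overlapped[j]) next
        i <- good_idx[j]
        res <- list(offset = ov$offset[j], overlap_len = ov$overlap_len[j],
                    edit_dist = ov$edit_dist[j],
                    hamming_dist = ov$hamming_dist[j],
                    overlapped = TRUE, mismatch = NULL)
        class(res) <- "overlap_result"
        if (ov$edit_dist[j] > 0) {
          res$mismatch <- overlap_mismatches(r1$bases[i], r1$quals[i],
                                             r2$bases[i], r2$quals[i],
                                             res$offset, res$overlap_len,
                                             c2 = c2g[j])
          if (res$hamming_dist != res$edit_dist) {
            reason[i] <- "overlap_indel"  # indel difference: uncorrectable
            next
          }
        } else {
          res$mismatch <- overlap_mismatches(r1$bases[i], r1$quals[i],
                                             r2$bases[i], r2$quals[i],
                                             res$offset, res$overlap_len,
                                             c2 = c2g[j])[0, ]
        }
        n_overlapped <- n_overlapped + 1L
        stats <- accumulate_error_stats(res, stats, o$profile_min_overlap,
                                        o$qual_high, o$qual_low)
        if (o$correction && res$edit_dist > 0) {
          cr <- correct_pair(r1[i, ], r2[i, ], res, o$qual_high, o$qual_low)
          r1$bases[i] <- cr$r1$bases; r1$quals[i] <- cr$r1$quals
          r2$bases[i] <- cr$r2$bases; r2$quals[i] <- cr$r2$quals
          bases_corrected <- bases_corrected + cr$corrected
        }
        if (res$offset < 0) {
          cut <- cut_adapters(r1[i, ], r2[i, ], res)
          r1$bases[i] <- cut$r1$bases; r1$quals[i] <- cut$r1$quals
          r2$bases[i] <- cut$r2$bases; r2$quals[i] <- cut$r2$quals
          adapters_cut <- adapters_cut + 1L
        }
        if (o$store_overlap_only)
          merged_rows[[j]] <- merge_overlap(r1[i, ], r2[i, ], res)
      }
      if (o$require_overlap || o$store_overlap_only) {
        no_ov <- good_idx[!ov$overlapped]
        reason[no_ov[reason[no_ov] == ""]] <- "no_overlap"
      }
      if (o$store_overlap_only) {
        keep <- !vapply(merged_rows, is.null, logical(1))
        merged <- if (any(keep)) do.call(rbind_reads, merged_rows[keep])
                  else fastq_reads()
      }
    } else if (o$store_overlap_only) {
      merged <- fastq_reads()
    }
  }

  good <- which(reason == "")
  bad <- which(reason != "")
  bad_counts <- table(factor(reason[bad], levels = c(
    "quality", "n_count", "polyX", "bubble", "too_short_after_trim",
    "overlap_indel", "no_overlap")))
  message(sprintf("[pipeline] filtered: %d good, %d bad", length(good),
                  length(bad)))

  # -- stage 6: outputs, post-filtering QC, report -----------------------
  good_r1 <- r1[good, ]
  good_r2 <- if (paired) r2[good, ] else NULL
  post_src <- if (o$store_overlap_only && !is.null(merged)) merged else
    if (paired) rbind_reads(good_r1, good_r2) else good_r1
  post <- profile_cycles(post_src)
  bias <- kmer_strand_counts(r1, k = o$kmer_k, max_reads = o$kmer_max_reads)
  disc <- discontinuity_curve(r1, window = o$disc_window)

  summary <- structure(list(
    input = c(r1 = r1_path, r2 = if (paired) r2_path else NA),
    paired = paired,
    total = n,
    good = length(good),
    bad = as.list(bad_counts),
    trim = list(r1 = unclass(d1), r2 = if (paired) unclass(d2) else NULL),
    overlap = list(pairs_overlapped = n_overlapped,
                   adapters_cut = adapters_cut,
                   bases_corrected = bases_corrected),
    error_stats = local({
      es <- unclass(stats)
      es$transform_counts <- as.list(es$transform_counts)  # keep JSON keys
      es
    }),
    pre_profile = profile_to_list(pre1),
    pre_profile_r2 = if (paired) profile_to_list(pre2) else NULL,
    post_profile = profile_to_list(post),
    strand_bias = list(k = attr(bias, "k"),
                       table = as.data.frame(bias),
                       summary = if (nrow(bias) > 0) bias_summary(bias)
                                 else NA_real_),
    discontinuity = disc,
    circles = if (!is.null(circles)) as.data.frame(circles) else NULL),
    class = "run_summary")

  if (!is.null(outdir)) {
    dir.create(file.path(outdir, "good"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(outdir, "bad"), recursive = TRUE,
               showWarnings = FALSE)
    gz <- function(p) basename(p)
    if (!o$store_overlap_only) {
      write_fastq(good_r1, file.path(outdir, "good", gz(r1_path)))
      if (paired)
        write_fastq(good_r2, file.path(outdir, "good", gz(r2_path)))
    }
    bad_r1 <- annotate_bad(r1[bad, ], reason[bad])
    write_fastq(bad_r1, file.path(outdir, "bad", gz(r1_path)))
    if (paired) {
      bad_r2 <- annotate_bad(r2[bad, ], reason[bad])
      write_fastq(bad_r2, file.path(outdir, "bad", gz(r2_path)))
    }
    if (!is.null(merged)) {
      dir.create(file.path(outdir, "merged"), showWarnings = FALSE)
      write_fastq(merged, file.path(outdir, "merged",
                                    sub("(\\.fastq|\\.fq)", ".merged\\1",
                                        gz(r1_path))))
    }
    render_report(summary, outdir)
  }
  summary
}

`%||%` <- function(a, b) if (is.null(a)) b else a

profile_to_list <- function(p) {
  list(n_cycles = p$n_cycles,
       counts = lapply(seq_len(ncol(p$counts)),
                       function(j) unname(p$counts[, j])) |>
         setNames(colnames(p$counts)),
       total = p$total,
       mean_qual = p$mean_qual)
}

#' @export
print.run_summary <- function(x, ...) {
  cat("<run_summary> ", if (x$paired) "paired-end" else "single-end",
      ": ", x$total, " in, ", x$good, " good, ",
      x$total - x$good, " bad\n", sep = "")
  bad <- Filter(function(v) v > 0, x$bad)
  if (length(bad) > 0)
    cat("  bad by reason:",
        paste(names(bad), unlist(bad), sep = "=", collapse = ", "), "\n")
  cat("  trim r1: front", x$trim$r1$front, "tail", x$trim$r1$tail, "\n")
  if (x$paired) {
    ov <- x$overlap
    cat("  overlap: ", ov$pairs_overlapped, " pairs overlapped, ",
        ov$adapters_cut, " adapters cut, ", ov$bases_corrected,
        " bases corrected\n", sep = "")
    es <- x$error_stats
    if (es$total_overlapped_bases > 0)
      cat("  estimated error rate: ",
          format(es$mismatched_bases / es$total_overlapped_bases,
                 digits = 3), "\n", sep = "")
  }
  invisible(x)
}

#' Run the pipeline over a folder of FASTQ files
#'
#' Discovers single-end files and R1/R2 pairs with [pair_files()] and
#' processes each unit independently; results are identical for any
#' worker count. Per-unit failures are captured, not fatal, unless every
#' unit fails.
#'
#' @param folder Input folder.
#' @param outdir Optional output root; each unit writes into a subfolder
#'   named after its R1 file.
#' @param options A [pipeline_options()] list.
#' @param workers Number of parallel workers (forked; 1 = serial).
#' @return A list of `run_summary` objects (or `try-error` entries), in
#'   discovery order.
#' @export
run_batch <- function(folder, outdir = NULL, options = pipeline_options(),
                      workers = 1L) {
  units <- pair_files(folder)
  if (length(units) == 0) return(list())
  one <- function(u) {
    sub <- if (is.null(outdir)) NULL else
      file.path(outdir, sub("\\.(fq|fastq)(\\.gz)?$", "", basename(u$r1)))
    tryCatch(run_pipeline(u$r1, if (is.na(u$r2)) NULL else u$r2, sub,
                          options),
             error = function(e) structure(list(input = u, error =
                                                  conditionMessage(e)),
                                           class = "run_failure"))
  }
  res <- if (workers > 1L) {
    parallel::mclapply(units, one, mc.cores = workers)
  } else {
    lapply(units, one)
  }
  failed <- vapply(res, inherits, logical(1), "run_failure")
  if (length(res) > 0 && all(failed))
    stop("all ", length(res), " units failed; first error: ",
         res[[1]]$error, call. = FALSE)
  res
}

#' Write the JSON and HTML report for a run
#'
#' `report.json` is the full machine-readable summary; `report.html` is a
#' self-contained static page with the filtering summary, per-cycle
#' content/quality tables, discontinuity curve, the 12-category error
#' transform bar chart and the strand-bias summary (bars rendered in pure
#' CSS — no plotting device required).
#'
#' @param summary A `run_summary`.
#' @param outdir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
render_report <- function(summary, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  jpath <- file.path(outdir, "report.json")
  hpath <- file.path(outdir, "report.html")
  jsonlite::write_json(unclass(summary), jpath, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE,
                       dataframe = "columns")
  writeLines(report_html(summary), hpath)
  invisible(c(json = jpath, html = hpath))
}

#' Read a run summary back from report.json
#'
#' @param path Path to a `report.json` written by [render_report()].
#' @return The parsed summary list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

report_html <- function(s) {
  esc <- function(x) gsub("<", "&lt;", gsub("&", "&amp;", as.character(x)))
  bar <- function(label, value, maxv, color = "#4878a8") {
    w <- if (maxv > 0) round(200 * value / maxv) else 0
    sprintf(paste0('<div class="row"><span class="lbl">%s</span>',
                   '<span class="bar" style="width:%dpx;background:%s">',
                   '</span> %s</div>'),
            esc(label), w, color, esc(value))
  }
  es <- s$error_stats
  tc <- unlist(es$transform_counts)
  bad <- unlist(s$bad)
  parts <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>FASTQ QC report</title><style>",
    "body{font-family:sans-serif;margin:2em;max-width:60em}",
    ".row{margin:2px 0}.lbl{display:inline-block;width:12em}",
    ".bar{display:inline-block;height:0.9em;vertical-align:middle}",
    "table{border-collapse:collapse}td,th{border:1px solid #999;",
    "padding:2px 6px;font-size:90%}</style></head><body>",
    sprintf("<h1>FASTQ QC report</h1><p>Input: %s%s</p>",
            esc(s$input[["r1"]]),
            if (s$paired) paste0(" + ", esc(s$input[["r2"]])) else ""),
    "<h2>Filtering summary</h2>",
    sprintf("<p>%d %s in, %d good, %d bad</p>", s$total,
            if (s$paired) "pairs" else "reads", s$good, s$total - s$good),
    vapply(names(bad), function(k) bar(k, bad[[k]], max(bad, s$good)),
           character(1)),
    sprintf("<p>Trim: front %d, tail %d (R1)</p>",
            s$trim$r1$front, s$trim$r1$tail))
  if (s$paired) {
    rate <- if (es$total_overlapped_bases > 0)
      es$mismatched_bases / es$total_overlapped_bases else NA
    parts <- c(parts,
      "<h2>Overlap analysis</h2>",
      sprintf(paste0("<p>%d pairs overlapped, %d adapters cut, ",
                     "%d bases corrected</p>"),
              s$overlap$pairs_overlapped, s$overlap$adapters_cut,
              s$overlap$bases_corrected),
      sprintf(paste0("<p>Estimated sequencing error rate: %s ",
                     "(%d mismatched / %d overlapped bases)</p>"),
              if (is.na(rate)) "n/a" else format(rate, digits = 3),
              es$mismatched_bases, es$total_overlapped_bases),
      "<h2>Error transform distribution</h2>",
      vapply(names(tc), function(k)
        bar(k, tc[[k]], max(tc, 1), "#a85048"), character(1)),
      sprintf("<p>%d unprofiled (balanced-quality) mismatches</p>",
              es$unprofiled_mismatches))
  }
  parts <- c(parts,
    "<h2>Per-cycle profile (pre-filtering, R1)</h2>",
    profile_table(s$pre_profile),
    "<h2>Per-cycle profile (post-filtering)</h2>",
    profile_table(s$post_profile),
    "<h2>Discontinuity curve</h2>",
    vapply(seq_along(s$discontinuity), function(i)
      bar(sprintf("cycle %d", i), round(s$discontinuity[i], 2),
          max(s$discontinuity, na.rm = TRUE), "#48a878"), character(1)),
    sprintf("<h2>Strand bias</h2><p>%d canonical %d-mers, bias summary %s</p>",
            nrow(s$strand_bias$table), s$strand_bias$k,
            format(s$strand_bias$summary, digits = 3)),
    "</body></html>")
  unlist(parts)
}

profile_table <- function(p, every = 10L) {
  if (p$n_cycles == 0) return("<p>empty</p>")
  idx <- unique(c(seq(1L, p$n_cycles, by = every), p$n_cycles))
  tot <- pmax(unlist(p$total)[idx], 1)
  pct <- function(b) sprintf("%.1f", 100 * unlist(p$counts[[b]])[idx] / tot)
  rows <- paste0("<tr><td>", idx, "</td><td>",
                 pct("A"), "</td><td>", pct("C"), "</td><td>",
                 pct("G"), "</td><td>", pct("T"), "</td><td>",
                 pct("N"), "</td><td>",
                 sprintf("%.1f", unlist(p$mean_qual)[idx]), "</td></tr>",
                 collapse = "")
  paste0("<table><tr><th>cycle</th><th>A%</th><th>C%</th><th>G%</th>",
         "<th>T%</th><th>N%</th><th>meanQ</th></tr>", rows, "</table>")
}
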