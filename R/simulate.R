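#' Configuration for the paired-end read simulator
#'
#' The simulator synthesises paired-end FASTQ with complete ground truth
#' (templates, planted errors, adapter boundaries, flowcell coordinates),
#' so every stage of the pipeline is testable without external data.
#' Defaults mirror the canonical worked geometry of the overlap engine: a
#' 60 bp template sequenced at 2x50 (offset 10, 40 bp overlap), clean
#' flat-content reads at Q35, errors planted at Q8 — making the Q30/Q15
#' quality-asymmetry rule exactly checkable.
#'
#' @param seed Integer seed; all output is deterministic given it.
#' @param n_pairs Number of read pairs.
#' @param read_len Sequencing length S per mate.
#' @param template_mean,template_sd Normal template-length model (lengths
#'   rounded, floored at 2); `template_sd = 0` fixes the length.
#' @param template_lengths Optional explicit template lengths (recycled),
#'   overriding the normal model.
#' @param adapter Adapter sequence read through when the template is
#'   shorter than `read_len`.
#' @param error_rate Per-base substitution probability.
#' @param error_qual Phred score assigned to planted errors.
#' @param base_qual Phred score of correct bases.
#' @param error_mate Which mate receives errors: `"both"`, `"r1"` or
#'   `"r2"`. One-mate planting guarantees every overlap mismatch is
#'   quality-asymmetric (no coincident low/low collisions).
#' @param balanced_errors If `TRUE`, errors are planted at `base_qual`
#'   instead of `error_qual`, exercising the uncorrectable path.
#' @param polyx_fraction Fraction of pairs whose R1 is replaced by a
#'   whole-read polyG homopolymer.
#' @param lane,tile,tile_width Flowcell geometry for generated read names.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L, n_pairs = 1000L, read_len = 50L,
                              template_mean = 60, template_sd = 0,
                              template_lengths = NULL,
                              adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                              error_rate = 0, error_qual = 8L,
                              base_qual = 35L,
                              error_mate = c("both", "r1", "r2"),
                              balanced_errors = FALSE,
                              polyx_fraction = 0, lane = 1L, tile = 1101L,
                              tile_width = 2000L) {
  error_mate <- match.arg(error_mate)
  stopifnot(error_rate >= 0, error_rate < 1, read_len >= 20, n_pairs >= 0,
            polyx_fraction >= 0, polyx_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate paired-end reads with ground truth
#'
#' Each pair: a uniform-random template of length T; R1 is the template's
#' first S bases, R2 the reverse complement's first S bases; when T < S
#' both mates read through into the adapter. Substitution errors are
#' planted per base with probability `error_rate` at quality
#' `error_qual`. Read names carry Illumina-style lane/tile/x/y
#' coordinates.
#'
#' @param config A [simulation_config()].
#' @return A list of class `sim_pairs`: `r1`, `r2` ([fastq_reads]) and
#'   `truth` — a list with `templates`, `template_len`, `adapter`,
#'   `polyx_pairs` (indices), `coords`, and `errors`, a data frame with
#'   one row per planted error (`pair`, `mate`, `pos` in the read,
#'   `template_pos` — `NA` for adapter positions — `true_base`,
#'   `obs_base`, both in read orientation).
#' @export
simulate_pairs <- function(config = simulation_config()) {
  set.seed(config$seed)
  n <- config$n_pairs
  S <- config$read_len
  tl <- if (!is.null(config$template_lengths)) {
    as.integer(rep_len(config$template_lengths, n))
  } else if (config$template_sd == 0) {
    rep.int(as.integer(round(config$template_mean)), n)
  } else {
    pmax(2L, as.integer(round(rnorm(n, config$template_mean,
                                    config$template_sd))))
  }
  big <- paste(sample(.BASES, sum(tl), replace = TRUE), collapse = "")
  ends <- cumsum(tl)
  templates <- substring(big, ends - tl + 1L, ends)
  adapter_fill <- function(short) {
    # recycle the adapter if a very short template needs more fill than
    # one adapter length
    pad <- strrep(config$adapter,
                  ceiling(max(short, 1) / nchar(config$adapter)))
    substring(pad, 1L, short)
  }
  rc_templates <- if (n > 0) revcomp(templates) else character()
  b1 <- substr(templates, 1L, S)
  b2 <- substr(rc_templates, 1L, S)
  short <- which(tl < S)
  if (length(short) > 0) {
    fill <- adapter_fill(S - tl[short])
    b1[short] <- paste0(b1[short], fill)
    b2[short] <- paste0(b2[short], fill)
  }
  qual_chr <- rawToChar(as.raw(config$base_qual + 33L))
  q1 <- strrep(qual_chr, nchar(b1))
  q2 <- strrep(qual_chr, nchar(b2))

  errors <- list()
  plant <- function(bases, quals, mate) {
    if (config$error_rate <= 0 || n == 0) return(list(b = bases, q = quals))
    eq_chr <- rawToChar(as.raw(
      (if (config$balanced_errors) config$base_qual else config$error_qual) + 33L))
    # all reads of one mate have equal length S, so one uniform draw matrix
    hit <- which(matrix(runif(n * S) < config$error_rate, n, S),
                 arr.ind = TRUE)
    if (nrow(hit) > 0) {
      pair <- hit[, 1]; pos <- hit[, 2]
      trub <- substring(bases[pair], pos, pos)
      # substitute uniformly among the three other bases
      newb <- .BASES[(match(trub, .BASES) - 1L +
                        sample.int(3L, nrow(hit), replace = TRUE)) %% 4L + 1L]
      for (k in seq_len(nrow(hit))) {
        substr(bases[pair[k]], pos[k], pos[k]) <- newb[k]
        substr(quals[pair[k]], pos[k], pos[k]) <- eq_chr
      }
      tpos <- if (mate == 1L) ifelse(pos <= tl[pair], pos, NA_integer_)
              else ifelse(pos <= tl[pair], tl[pair] - pos + 1L, NA_integer_)
      errors[[length(errors) + 1L]] <<- data.frame(
        pair = pair, mate = mate, pos = pos, template_pos = as.integer(tpos),
        true_base = trub, obs_base = newb, stringsAsFactors = FALSE)
    }
    list(b = bases, q = quals)
  }
  if (config$error_mate %in% c("both", "r1")) {
    r <- plant(b1, q1, 1L); b1 <- r$b; q1 <- r$q
  }
  if (config$error_mate %in% c("both", "r2")) {
    r <- plant(b2, q2, 2L); b2 <- r$b; q2 <- r$q
  }
  errors <- if (length(errors) > 0) do.call(rbind, errors) else
    data.frame(pair = integer(), mate = integer(), pos = integer(),
               template_pos = integer(), true_base = character(),
               obs_base = character(), stringsAsFactors = FALSE)
  errors <- errors[order(errors$pair, errors$mate, errors$pos), ,
                   drop = FALSE]
  rownames(errors) <- NULL

  polyx_pairs <- integer()
  if (config$polyx_fraction > 0 && n > 0) {
    n_px <- round(config$polyx_fraction * n)
    if (n_px > 0) {
      polyx_pairs <- sample.int(n, n_px)
      b1[polyx_pairs] <- strrep("G", S)
      q1[polyx_pairs] <- strrep(qual_chr, S)
    }
  }

  xs <- sample.int(config$tile_width, n, replace = TRUE) - 1L
  ys <- sample.int(config$tile_width, n, replace = TRUE) - 1L
  names <- format_coord(config$lane, config$tile, xs, ys)
  # de-duplicate coordinates deterministically via the run field
  names <- paste0(names)
  structure(list(
    r1 = fastq_reads(names, b1, q1),
    r2 = fastq_reads(names, b2, q2),
    truth = list(templates = templates, template_len = tl,
                 adapter = config$adapter, errors = errors,
                 polyx_pairs = sort(polyx_pairs),
                 coords = data.frame(lane = config$lane, tile = config$tile,
                                     x = xs, y = ys),
                 config = config)),
    class = "sim_pairs")
}

#' Expected overlap mismatch rate for a simulation configuration
#'
#' Every overlapped base is sequenced twice; with per-base error rate e on
#' both mates a mismatch arises when exactly one mate errs, or both err
#' differently: 2e(1-e) + (2/3)e^2 (a coincident error matches the other
#' mate's with probability 1/3). With errors on a single mate the rate is
#' simply e.
#'
#' @param config A [simulation_config()].
#' @return Expected mismatch probability per overlapped base.
#' @export
expected_mismatch_rate <- function(config) {
  e <- config$error_rate
  if (config$error_mate == "both") 2 * e * (1 - e) + (2 / 3) * e^2 else e
}

#' Plant a polyG bubble on a tile
#'
#' Adds whole-read polyG records whose header coordinates lie uniformly
#' inside the given circle — emulating the dense polyX patch an air bubble
#' leaves on a two-channel flowcell — plus Poisson-distributed background
#' polyG reads spread uniformly over the tile.
#'
#' @param reads A [fastq_reads] to append to (may be empty).
#' @param spec A list: `lane`, `tile`, `cx`, `cy`, `r`, `n_rim_reads`
#'   (reads planted in the bubble; default 150), optional `bg_rate`
#'   (Poisson mean of background polyG reads; default 50), optional
#'   `tile_width` (default 2000) and `read_len` (default 50).
#' @param seed Integer seed.
#' @return A list: `reads` (augmented), `truth` (the planted circle and
#'   the planted/background coordinates).
#' @export
plant_polyx_bubble <- function(reads = fastq_reads(), spec, seed = 1L) {
  set.seed(seed)
  n_rim <- if (is.null(spec$n_rim_reads)) 150L else spec$n_rim_reads
  bg_rate <- if (is.null(spec$bg_rate)) 50 else spec$bg_rate
  tw <- if (is.null(spec$tile_width)) 2000L else spec$tile_width
  rl <- if (is.null(spec$read_len)) 50L else spec$read_len
  # uniform in the disc: r ~ R*sqrt(u)
  th <- runif(n_rim, 0, 2 * pi)
  rr <- spec$r * sqrt(runif(n_rim))
  bx <- as.integer(round(spec$cx + rr * cos(th)))
  by <- as.integer(round(spec$cy + rr * sin(th)))
  n_bg <- rpois(1, bg_rate)
  gx <- sample.int(tw, n_bg, replace = TRUE) - 1L
  gy <- sample.int(tw, n_bg, replace = TRUE) - 1L
  xs <- c(bx, gx); ys <- c(by, gy)
  xs <- pmin(pmax(xs, 0L), tw - 1L)
  ys <- pmin(pmax(ys, 0L), tw - 1L)
  nm <- format_coord(spec$lane, spec$tile, xs, ys)
  polyg <- fastq_reads(nm, strrep("G", rl), strrep("D", rl))  # 'D' = Q35
  list(reads = rbind_reads(reads, polyg),
       truth = list(circle = spec,
                    planted = data.frame(x = bx, y = by),
                    background = data.frame(x = gx, y = gy)))
}

rbind_reads <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("fastq_reads", "data.frame")
  out
}
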