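#' Read a FASTQ file
#'
#' Reads plain or gzip-compressed FASTQ (selected transparently; `gzfile()`
#' handles both). Records are validated: a truncated record, a missing `+`
#' separator line or a bases/quality length mismatch raises an error naming
#' the offending record index. Only Phred+33 quality encoding is accepted.
#'
#' @param path Path to a FASTQ file (`.gz` or plain).
#' @param callback Optional function called with a [fastq_reads] chunk;
#'   when supplied the file is streamed in chunks of `chunk_size` records
#'   (constant memory) and `read_fastq()` returns the total record count
#'   invisibly instead of the records.
#' @param chunk_size Records per chunk in callback mode.
#' @return A [fastq_reads] data frame (or a count, in callback mode).
#' @export
read_fastq <- function(path, callback = NULL, chunk_size = 100000L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  if (is.null(callback)) {
    lines <- readLines(con)
    return(parse_fastq_lines(lines, 0L))
  }
  done <- 0L
  repeat {
    lines <- readLines(con, n = 4L * chunk_size)
    if (length(lines) == 0) break
    chunk <- parse_fastq_lines(lines, done)
    callback(chunk)
    done <- done + nrow(chunk)
    if (length(lines) < 4L * chunk_size) break
  }
  invisible(done)
}

parse_fastq_lines <- function(lines, offset) {
  n <- length(lines)
  if (n == 0) return(fastq_reads())
  if (n %% 4 != 0)
    stop("truncated FASTQ: record ", offset + n %/% 4 + 1,
         " is incomplete", call. = FALSE)
  hdr <- lines[seq(1, n, by = 4)]
  bases <- lines[seq(2, n, by = 4)]
  plus <- lines[seq(3, n, by = 4)]
  quals <- lines[seq(4, n, by = 4)]
  bad <- which(substr(hdr, 1, 1) != "@")
  if (length(bad) > 0)
    stop("record ", offset + bad[1], ": header does not start with '@'",
         call. = FALSE)
  bad <- which(substr(plus, 1, 1) != "+")
  if (length(bad) > 0)
    stop("record ", offset + bad[1], ": missing '+' separator line",
         call. = FALSE)
  bad <- which(nchar(bases) != nchar(quals))
  if (length(bad) > 0)
    stop("record ", offset + bad[1], ": bases and quality strings differ ",
         "in length", call. = FALSE)
  fastq_reads(sub("^@", "", hdr), bases, quals)
}

#' Write FASTQ records
#'
#' A `.gz` suffix on `path` selects gzip compression. Round-trips exactly:
#' `read_fastq()` of the written file reproduces the input records.
#'
#' @param reads A [fastq_reads] data frame.
#' @param path Output path; `.gz` suffix selects gzip.
#' @return The number of records written, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "fastq_reads") || is.data.frame(reads))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (nrow(reads) > 0) {
    out <- as.vector(rbind(paste0("@", reads$name), reads$bases,
                           "+", reads$quals))
    writeLines(out, con)
  }
  invisible(nrow(reads))
}

#' Discover and pair FASTQ files in a folder
#'
#' Files whose names differ only by an R1/R2 token (`R1`/`R2` anywhere, or
#' `_1`/`_2` immediately before the FASTQ extension) are matched into pairs;
#' everything else is returned as single-end. Every input file appears
#' exactly once in the output, in deterministic lexicographic order.
#'
#' @param folder Directory containing FASTQ files (`.fq`, `.fastq`,
#'   optionally `.gz`).
#' @return A list of `list(r1 =, r2 =)` entries; `r2` is `NA` for
#'   single-end files.
#' @export
pair_files <- function(folder) {
  if (!dir.exists(folder)) stop("folder not found: ", folder, call. = FALSE)
  files <- sort(list.files(folder, pattern = "\\.(fq|fastq)(\\.gz)?$"))
  if (length(files) == 0) return(list())
  mate2 <- function(f) {
    if (grepl("R1", f, fixed = TRUE))
      return(sub("R1(?!.*R1)", "R2", f, perl = TRUE))  # last R1 occurrence
    if (grepl("_1\\.(fq|fastq)(\\.gz)?$", f))
      return(sub("_1(\\.(fq|fastq)(\\.gz)?)$", "_2\\1", f))
    NA_character_
  }
  used <- character()
  out <- list()
  for (f in files) {
    if (f %in% used) next
    m2 <- mate2(f)
    if (!is.na(m2) && m2 %in% files && !(m2 %in% used)) {
      out[[length(out) + 1]] <- list(r1 = file.path(folder, f),
                                     r2 = file.path(folder, m2))
      used <- c(used, f, m2)
    } else if (grepl("R2", f, fixed = TRUE) ||
               grepl("_2\\.(fq|fastq)(\\.gz)?$", f)) {
      # might be the mate of a not-yet-visited R1; check
      m1 <- if (grepl("R2", f, fixed = TRUE))
        sub("R2(?!.*R2)", "R1", f, perl = TRUE)
      else sub("_2(\\.(fq|fastq)(\\.gz)?)$", "_1\\1", f)
      if (m1 %in% files) next  # will be paired when m1 is visited
      out[[length(out) + 1]] <- list(r1 = file.path(folder, f), r2 = NA)
      used <- c(used, f)
    } else {
      out[[length(out) + 1]] <- list(r1 = file.path(folder, f), r2 = NA)
      used <- c(used, f)
    }
  }
  out
}

#' Parse Illumina flowcell coordinates from a read name
#'
#' Understands the colon-delimited Illumina header dialect
#' `instrument:run:flowcell:lane:tile:x:y...` (at least 7 fields; anything
#' after the first whitespace is ignored). Returns `NULL` — not an error —
#' when the name does not match.
#'
#' @param name A read name (header without `@`).
#' @return A list with integer fields `lane`, `tile`, `x`, `y`, or `NULL`.
#' @seealso [parse_coords()] for the vectorised variant.
#' @export
parse_coord <- function(name) {
  df <- parse_coords(name)
  if (is.na(df$lane[1])) return(NULL)
  as.list(df[1, ])
}

#' Parse flowcell coordinates for many read names
#'
#' @param names Character vector of read names.
#' @return A data frame with integer columns `lane`, `tile`, `x`, `y`;
#'   rows are `NA` where the name is not in the Illumina dialect.
#' @export
parse_coords <- function(names) {
  first <- sub("\\s.*$", "", names)
  parts <- strsplit(first, ":", fixed = TRUE)
  take <- function(p) {
    if (length(p) < 7) return(rep(NA_integer_, 4))
    if (!all(grepl("^[0-9]+$", p[4:6])) || !grepl("^[0-9]", p[7]))
      return(rep(NA_integer_, 4))
    as.integer(sub("^([0-9]+).*$", "\\1", p[4:7]))
  }
  m <- t(vapply(parts, take, integer(4)))
  data.frame(lane = m[, 1], tile = m[, 2], x = m[, 3], y = m[, 4])
}

#' Format a flowcell coordinate as an Illumina-style read name
#'
#' Inverse of [parse_coord()]: `parse_coord(format_coord(c))` recovers `c`.
#'
#' @param lane,tile,x,y Integer coordinate fields (vectorised).
#' @param instrument,run,flowcell Leading name fields.
#' @return Character vector of read names.
#' @export
format_coord <- function(lane, tile, x, y, instrument = "sim", run = 1,
                         flowcell = "fc1") {
  sprintf("%s:%s:%s:%d:%d:%d:%d", instrument, run, flowcell,
          as.integer(lane), as.integer(tile), as.integer(x), as.integer(y))
}
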