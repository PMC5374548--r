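# Independent oracles, deliberately naive: these re-derive expected values
# by enumeration or textbook dynamic programming, never by calling the code
# paths they check.

# full-table Levenshtein DP
dp_edit_distance <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  d <- matrix(0L, la + 1, lb + 1)
  d[, 1] <- 0:la
  d[1, ] <- 0:lb
  for (i in seq_len(la)) for (j in seq_len(lb)) {
    d[i + 1, j + 1] <- min(d[i, j] + (av[i] != bv[j]),
                           d[i, j + 1] + 1L, d[i + 1, j] + 1L)
  }
  d[la + 1, lb + 1]
}

# exhaustive offset scan with the same tie rules as the engine, built on
# the DP oracle above
oracle_overlap <- function(b1, b2, min_overlap) {
  c2 <- revcomp(b2)
  la <- nchar(b1); lb <- nchar(c2)
  best <- NULL
  maxd <- max(abs(-(lb - min_overlap)), abs(la - min_overlap))
  for (d in 0:maxd) for (O in unique(c(d, -d))) {
    if (O < -(lb - min_overlap) || O > la - min_overlap) next
    a_start <- max(O, 0); a_end <- min(la, O + lb)
    L <- a_end - a_start
    if (L < 1) next
    a <- substr(b1, a_start + 1, a_end)
    b <- substr(c2, max(-O, 0) + 1, max(-O, 0) + L)
    e <- dp_edit_distance(a, b)
    if (is.null(best) || e < best$e || (e == best$e && L > best$L))
      best <- list(O = O, L = L, e = e)
  }
  best
}

# minimum enclosing circle by O(n^3) enumeration of 1-, 2- and 3-point
# support circles
oracle_mec <- function(pts) {
  n <- nrow(pts)
  best <- NULL
  contains <- function(ctr, r)
    all((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2 <= r^2 * (1 + 1e-9) + 1e-9)
  consider <- function(ctr, r)
    if (contains(ctr, r) && (is.null(best) || r < best$r))
      best <<- list(ctr = ctr, r = r)
  for (i in seq_len(n)) consider(pts[i, ], 0)
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n)
    consider((pts[i, ] + pts[j, ]) / 2, sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2)
  if (n >= 3) for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    p <- pts[i, ]; q <- pts[j, ]; s <- pts[k, ]
    den <- 2 * (p[1] * (q[2] - s[2]) + q[1] * (s[2] - p[2]) + s[1] * (p[2] - q[2]))
    if (abs(den) < 1e-12) next
    ux <- (sum(p^2) * (q[2] - s[2]) + sum(q^2) * (s[2] - p[2]) +
             sum(s^2) * (p[2] - q[2])) / den
    uy <- (sum(p^2) * (s[1] - q[1]) + sum(q^2) * (p[1] - s[1]) +
             sum(s^2) * (q[1] - p[1])) / den
    consider(c(ux, uy), sqrt((p[1] - ux)^2 + (p[2] - uy)^2))
  }
  best
}

# brute-force polyX: test every window of every length >= P for every base
oracle_polyx <- function(seq, P, L) {
  n <- nchar(seq)
  if (n < P) return(FALSE)
  v <- strsplit(seq, "")[[1]]
  for (X in c("A", "C", "G", "T")) {
    for (i in 1:(n - P + 1)) {
      w <- v[i:(i + P - 1)]
      if (w[1] == X && w[P] == X && sum(w != X) <= L) return(TRUE)
    }
  }
  FALSE
}

random_reads <- function(n, len, qual = "I", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bases <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
    character(1))
  fastq_reads(paste0("r", seq_len(n)), bases, strrep(qual, len))
}

# reads engineered to hit an exact per-cycle base composition:
# counts_by_cycle is an n_cycles x 4 matrix of per-base read counts
# (columns A, C, G, T) summing to n on every row
content_reads <- function(n, counts_by_cycle, qual_by_cycle = NULL) {
  n_cycles <- nrow(counts_by_cycle)
  if (is.null(qual_by_cycle)) qual_by_cycle <- rep(35L, n_cycles)
  cols <- vapply(seq_len(n_cycles), function(c) {
    stopifnot(sum(counts_by_cycle[c, ]) == n)
    rep(c("A", "C", "G", "T"), counts_by_cycle[c, ])
  }, character(n))
  bases <- apply(cols, 1, paste, collapse = "")
  quals <- strrep(paste(vapply(qual_by_cycle, function(q)
    rawToChar(as.raw(q + 33L)), character(1)), collapse = ""), 1)
  fastq_reads(paste0("r", seq_len(n)), bases, rep(quals, n))
}

# a uniform profile of n reads x n_cycles with one cycle's composition
# overridden; gc_pct applies at `gc_cycle` as G = C = gc/2, A = T = rest
uniform_profile_reads <- function(n = 1000, n_cycles = 100, gc_cycle = NULL,
                                  gc_pct = NULL, qual = 35L) {
  counts <- matrix(n / 4, n_cycles, 4)
  if (!is.null(gc_cycle)) {
    gc_n <- round(n * gc_pct / 100 / 2)
    counts[gc_cycle, ] <- c(n / 2 - gc_n, gc_n, gc_n, n / 2 - gc_n)
  }
  content_reads(n, counts, rep(qual, n_cycles))
}

# Ground-truth expected error statistics for a simulation, restricted to
# the accepted (profiled) pairs. Coincident errors on both mates at the
# same template position are balanced-quality by construction and cannot
# be attributed, so they are excluded from the expected transform counts.
oracle_transforms <- function(sim, accepted) {
  S <- sim$truth$config$read_len
  tl <- sim$truth$template_len
  err <- sim$truth$errors
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  counts <- setNames(integer(12), unlist(lapply(c("A", "C", "G", "T"),
    function(t) paste0(t, "->", setdiff(c("A", "C", "G", "T"), t)))))
  n_collide_diff <- 0L; n_single <- 0L
  for (i in accepted) {
    lo <- max(1L, tl[i] - S + 1L); hi <- min(tl[i], S)
    e <- err[err$pair == i & !is.na(err$template_pos) &
               err$template_pos >= lo & err$template_pos <= hi, ]
    if (nrow(e) == 0) next
    tab <- table(e$template_pos)
    for (tp in as.integer(names(tab))) {
      rows <- e[e$template_pos == tp, ]
      if (nrow(rows) == 2) {
        # both mates err at the same position: mismatch only if the
        # observed calls differ in a common orientation
        o1 <- rows$obs_base[rows$mate == 1]
        o2 <- comp[[rows$obs_base[rows$mate == 2]]]
        if (o1 != o2) n_collide_diff <- n_collide_diff + 1L
      } else {
        r <- rows[1, ]
        key <- if (r$mate == 1) paste0(r$true_base, "->", r$obs_base)
               else paste0(comp[[r$true_base]], "->", comp[[r$obs_base]])
        counts[key] <- counts[key] + 1L
        n_single <- n_single + 1L
      }
    }
  }
  list(transforms = counts, singles = n_single,
       collisions_differing = n_collide_diff)
}
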