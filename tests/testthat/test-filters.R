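test_that("polyX detection anchors on X and tolerates at most L non-X bases", {
  hit <- detect_polyx(strrep("G", 35))
  expect_true(hit$found)
  expect_equal(hit$base, "G")
  expect_equal(c(hit$start, hit$end), c(1L, 35L))

  expect_false(detect_polyx(strrep("G", 34))$found)

  # two tolerated interior non-G bases; three are too many
  two <- paste0(strrep("G", 16), "AA", strrep("G", 17))
  expect_true(detect_polyx(two)$found)
  three <- paste0(strrep("G", 16), "AAA", strrep("G", 17))
  expect_false(detect_polyx(three)$found)

  # N counts as non-X
  expect_true(detect_polyx(paste0(strrep("T", 20), "NN", strrep("T", 13)))$found)
  expect_false(detect_polyx(paste0(strrep("T", 19), "NNN", strrep("T", 13)))$found)

  # the window must start and end on X: flanking junk does not help
  expect_false(detect_polyx(paste0("AC", strrep("G", 33)))$found)

  # first qualifying X in A,C,G,T order, leftmost window
  both <- paste0(strrep("C", 35), strrep("A", 35))
  hit <- detect_polyx(both)
  expect_equal(hit$base, "A")
  expect_equal(hit$start, 36L)
})

test_that("polyX agrees with a brute-force window scan on random sequences", {
  set.seed(37)
  for (i in 1:150) {
    len <- sample(10:100, 1)
    # enrich one base so qualifying runs actually occur
    probs <- c(1, 1, 1, 1); probs[sample(4, 1)] <- sample(c(4, 10, 20), 1)
    s <- paste(sample(c("A", "C", "G", "T"), len, TRUE, probs / sum(probs)),
               collapse = "")
    P <- sample(c(10L, 20L, 35L), 1); L <- sample(0:3, 1)
    if (L >= P) next
    expect_equal(detect_polyx(s, P, L)$found, oracle_polyx(s, P, L),
                 info = sprintf("seq=%s P=%d L=%d", s, P, L))
  }
})

test_that("quality filter counts low-quality bases, N content and mean quality", {
  q40 <- fastq_reads("a", strrep("A", 50), strrep("I", 50))
  expect_true(quality_filter(q40)$passed)

  sixn <- fastq_reads("a", paste0(strrep("N", 6), strrep("A", 44)),
                      strrep("I", 50))
  v <- quality_filter(sixn, max_n = 5)
  expect_false(v$passed)
  expect_equal(v$reason, "n_count")
  expect_true(quality_filter(sixn, max_n = 6)$passed)

  # low mean quality fails with reason "quality"
  lowq <- fastq_reads("a", strrep("A", 50), strrep("0", 50))  # '0' = Q15
  v <- quality_filter(lowq, min_mean_qual = 20)
  expect_false(v$passed)
  expect_equal(v$reason, "quality")
})

test_that("quality filter matches an independent per-read recount", {
  set.seed(53)
  n <- 2000
  bases <- vapply(1:n, function(i) paste(sample(c("A", "C", "G", "T", "N"),
                                                50, TRUE,
                                                c(rep(0.23, 4), 0.08)),
                                         collapse = ""), character(1))
  quals <- vapply(1:n, function(i)
    rawToChar(as.raw(sample(33:73, 50, TRUE))), character(1))
  reads <- fastq_reads(paste0("r", 1:n), bases, quals)
  got <- quality_filter(reads, low_qual_threshold = 15, max_low_qual = 18,
                        max_n = 5, min_mean_qual = 20)
  for (i in seq_len(n)) {
    ph <- as.integer(charToRaw(quals[i])) - 33L
    nN <- sum(strsplit(bases[i], "")[[1]] == "N")
    fail_q <- sum(ph < 15) > 18 || mean(ph) < 20
    fail_n <- nN > 5
    expect_equal(got$passed[i], !(fail_q || fail_n))
    if (fail_q) expect_equal(got$reason[i], "quality")
    else if (fail_n) expect_equal(got$reason[i], "n_count")
  }
})

test_that("bubble filter removes exactly the reads strictly inside a circle", {
  circles <- structure(data.frame(lane = 1L, tile = 1101L, cx = 500,
                                  cy = 500, r = 100, support = 30L),
                       class = c("bubble_circles", "data.frame"))
  centre <- data.frame(lane = 1L, tile = 1101L, x = 500L, y = 500L)
  expect_false(bubble_filter(centre, circles)$passed)
  other_tile <- data.frame(lane = 1L, tile = 1102L, x = 500L, y = 500L)
  expect_true(bubble_filter(other_tile, circles)$passed)
  absent <- data.frame(lane = NA_integer_, tile = NA_integer_,
                       x = NA_integer_, y = NA_integer_)
  expect_true(bubble_filter(absent, circles)$passed)

  # 1000 random coordinates vs 3 planted circles: oracle point-in-circle
  set.seed(59)
  circles <- structure(data.frame(lane = 1L, tile = c(1101L, 1101L, 1102L),
                                  cx = c(300, 1500, 800),
                                  cy = c(300, 1500, 800),
                                  r = c(150, 200, 300),
                                  support = 30L),
                       class = c("bubble_circles", "data.frame"))
  coords <- data.frame(lane = 1L, tile = sample(c(1101L, 1102L, 1103L),
                                                1000, TRUE),
                       x = sample(0:1999, 1000, TRUE),
                       y = sample(0:1999, 1000, TRUE))
  got <- bubble_filter(coords, circles)
  want <- vapply(1:1000, function(i) {
    inside <- FALSE
    for (k in 1:3) {
      if (coords$tile[i] == circles$tile[k] &&
          (coords$x[i] - circles$cx[k])^2 +
          (coords$y[i] - circles$cy[k])^2 < circles$r[k]^2)
        inside <- TRUE
    }
    !inside
  }, logical(1))
  expect_equal(got$passed, want)
})

test_that("bad reads keep their name verbatim with the filter appended", {
  r <- fastq_reads("r1", "ACGT", "IIII")
  bad <- annotate_bad(r, "polyX")
  expect_equal(bad$name, "r1 qcfail:polyX")
  expect_equal(bad$bases, r$bases)
  expect_error(annotate_bad(r, ""))
  # annotation survives an I/O round trip
  p <- withr::local_tempfile(fileext = ".fq")
  write_fastq(bad, p)
  expect_equal(read_fastq(p)$name, "r1 qcfail:polyX")
})
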