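test_that("per-cycle profile counts bases and qualities at their cycle", {
  p <- profile_cycles(fastq_reads(c("a", "b"), c("AC", "AG"), c("II", "II")))
  expect_equal(p$n_cycles, 2L)
  expect_equal(unname(p$counts[1, "A"]), 2L)
  expect_equal(unname(base_content(p)[1, "A"]), 1.0)
  expect_equal(unname(p$counts[2, c("C", "G")]), c(1L, 1L))
  expect_equal(unname(base_content(p)[2, c("C", "G")]), c(0.5, 0.5))

  # 'I' decodes to Q40; N counted in its own column
  p <- profile_cycles(fastq_reads("n", "N", "I"))
  expect_equal(unname(p$counts[1, "N"]), 1L)
  expect_equal(p$mean_qual[1], 40)

  expect_equal(profile_cycles(fastq_reads())$n_cycles, 0L)
})

test_that("profile conserves every input base and matches binomial spread", {
  reads <- random_reads(300, 40, seed = 17)
  reads$bases[5] <- paste0(substr(reads$bases[5], 1, 20), strrep("N", 20))
  p <- profile_cycles(reads)
  expect_equal(sum(p$counts), sum(nchar(reads$bases)))
  expect_equal(rowSums(p$counts), as.numeric(p$total),
               ignore_attr = TRUE)

  # uniform simulated composition: every per-cycle percentage near 25%
  sim <- simulate_pairs(simulation_config(seed = 2, n_pairs = 5000,
                                          template_mean = 60))
  both <- structure(rbind(as.data.frame(sim$r1), as.data.frame(sim$r2)),
                    class = c("fastq_reads", "data.frame"))
  p <- profile_cycles(both)
  frac <- base_content(p)[, c("A", "C", "G", "T")]
  expect_true(all(abs(frac - 0.25) < 0.02))
})

test_that("discontinued base count matches its definition and symmetries", {
  expect_equal(discontinued_count("ATCGA"), 4L)
  expect_equal(discontinued_count("AAAAA"), 0L)
  expect_equal(discontinued_count("AAB"), 1L)
  expect_equal(discontinued_count(c("", "A", "AT")), c(0L, 0L, 1L))
  # invariant under reversal and complementation
  set.seed(23)
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(2:30, 1), TRUE),
               collapse = "")
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    comp_s <- chartr("ACGT", "TGCA", s)
    expect_equal(discontinued_count(rev_s), discontinued_count(s))
    expect_equal(discontinued_count(comp_s), discontinued_count(s))
  }
})

test_that("discontinuity curve averages change points over sliding windows", {
  expect_equal(discontinuity_curve(fastq_reads("a", "AAAA", "IIII"), 2),
               c(0, 0, 0))
  expect_equal(discontinuity_curve(fastq_reads("a", "ATAT", "IIII"), 4), 3)
  expect_error(discontinuity_curve(fastq_reads(), 1), "window")
  # uniform random reads: expected (window-1) * 3/4 change points
  reads <- random_reads(1000, 30, seed = 31)
  curve <- discontinuity_curve(reads, 5)
  expect_length(curve, 26)
  expect_true(all(abs(curve - 3.0) < 0.2))
  # short reads are skipped for windows they cannot cover
  mixed <- fastq_reads(c("a", "b"), c("ATATAT", "AT"), c("IIIIII", "II"))
  expect_equal(discontinuity_curve(mixed, 3), c(2, 2, 2, 2))
})

test_that("k-mer strand counts are canonical and balance on symmetric input", {
  tab <- kmer_strand_counts(fastq_reads("a", "ATCGATCG", "IIIIIIII"), k = 8)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$kmer, "ATCGATCG")  # smaller of ATCGATCG / CGATCGAT
  expect_equal(tab$fwd, 1L)
  expect_equal(tab$rev, 0L)

  tab <- kmer_strand_counts(fastq_reads(c("a", "b"), c("AAAA", "TTTT"),
                                        c("IIII", "IIII")), k = 4)
  expect_equal(tab$kmer, "AAAA")
  expect_equal(tab$fwd, 1L)
  expect_equal(tab$rev, 1L)

  expect_error(kmer_strand_counts(random_reads(1, 10), k = 7), "even")

  # total count equals the number of N-free windows scanned
  reads <- random_reads(50, 20, seed = 41)
  reads$bases[1] <- paste0(strrep("N", 10), substr(reads$bases[1], 11, 20))
  tab <- kmer_strand_counts(reads, k = 4)
  n_windows <- sum(vapply(reads$bases, function(b) {
    w <- substring(b, 1:(nchar(b) - 3), 4:nchar(b))
    sum(!grepl("N", w))
  }, numeric(1)))
  expect_equal(sum(tab$fwd + tab$rev), n_windows)

  # a read set closed under reverse complement is perfectly balanced
  base <- random_reads(200, 30, seed = 43)
  closed <- fastq_reads(c(base$name, paste0(base$name, "rc")),
                        c(base$bases, revcomp(base$bases)),
                        c(base$quals, base$quals))
  tab <- kmer_strand_counts(closed, k = 8)
  no_palin <- tab$kmer != revcomp(tab$kmer)
  expect_true(all(tab$fwd[no_palin] == tab$rev[no_palin]))
})

test_that("bias summary is 0 when balanced, 1 one-sided, 0.5 at 3x duplication", {
  bal <- kmer_strand_counts(fastq_reads(c("a", "b"), c("AAAA", "TTTT"),
                                        c("IIII", "IIII")), k = 4)
  expect_equal(bias_summary(bal), 0)
  one <- kmer_strand_counts(fastq_reads("a", "AAAA", "IIII"), k = 4)
  expect_equal(bias_summary(one), 1)
  expect_error(bias_summary(kmer_strand_counts(fastq_reads(), k = 4)),
               "empty")
  # one strand duplicated 3x: every k-mer 3 forward vs 1 reverse
  s <- "GTCAGAACGGTAGAGTCACAATTGACAAGACAGAGCTGTT"  # no revcomp palindromes
  reads <- fastq_reads(paste0("r", 1:4),
                       c(rep(s, 3), revcomp(s)),
                       rep(strrep("I", nchar(s)), 4))
  expect_equal(bias_summary(kmer_strand_counts(reads, k = 8)), 0.5)
})

test_that("strand-symmetric simulated templates show little per-k-mer bias", {
  # template set closed under reverse complement: 20 random 50-mers plus
  # their reverse complements, sampled uniformly as whole reads
  set.seed(47)
  tmpl <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = ""),
    character(1))
  pool <- c(tmpl, revcomp(tmpl))
  picks <- sample(pool, 5000, TRUE)
  reads <- fastq_reads(paste0("r", 1:5000), picks, strrep("I", 50))
  tab <- kmer_strand_counts(reads, k = 8)
  deep <- tab[tab$fwd + tab$rev >= 50, ]
  skew <- abs(deep$fwd - deep$rev) / (deep$fwd + deep$rev)
  expect_gt(mean(skew < 0.3), 0.95)
})
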