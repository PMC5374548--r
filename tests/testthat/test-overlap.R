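make_pair <- function(template, S, adapter = strrep("X", 0),
                      base_qual = 35L) {
  # X never occurs in sequences, so an accidental adapter match is impossible
  fill <- function(short) if (short > 0)
    substr(strrep(paste0(adapter, "A"), short), 1, short) else ""
  tlen <- nchar(template)
  b1 <- if (tlen >= S) substr(template, 1, S) else
    paste0(template, substr(paste0(adapter, strrep("A", S)), 1, S - tlen))
  rc <- revcomp(template)
  b2 <- if (tlen >= S) substr(rc, 1, S) else
    paste0(rc, substr(paste0(adapter, strrep("A", S)), 1, S - tlen))
  q <- strrep(rawToChar(as.raw(base_qual + 33L)), S)
  list(r1 = fastq_reads("p/1", b1, q), r2 = fastq_reads("p/2", b2, q))
}

test_that("edit distance agrees with adist trivia and a full DP oracle", {
  expect_equal(edit_distance("", "ACGT"), 4L)
  expect_equal(edit_distance("ACGT", "ACGT"), 0L)
  expect_equal(edit_distance("ACGT", "AGGT"), 1L)
  set.seed(61)
  for (i in 1:100) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(0:25, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(0:25, 1), TRUE),
               collapse = "")
    expect_equal(edit_distance(a, b), dp_edit_distance(a, b))
  }
})

test_that("the compiled capped DP is exact up to its cap", {
  set.seed(67)
  for (i in 1:100) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(1:30, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(1:30, 1), TRUE),
               collapse = "")
    true_d <- dp_edit_distance(a, b)
    for (cap in c(0L, 2L, 5L, 40L)) {
      got <- pairedqc:::lev_capped_cpp(a, b, cap)
      if (true_d <= cap) expect_equal(got, true_d)
      else expect_gt(got, cap)
    }
  }
})

test_that("a 60 bp template read at 2x50 overlaps 40 bp at offset 10", {
  set.seed(71)
  template <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  pr <- make_pair(template, 50)
  res <- find_overlap(pr$r1, pr$r2)
  expect_equal(res$offset, 10L)
  expect_equal(res$overlap_len, 40L)
  expect_equal(res$edit_dist, 0L)
  expect_equal(res$hamming_dist, 0L)
  expect_true(res$overlapped)

  # one substitution planted in r2 inside the overlap: edit distance 1
  pr2 <- pr
  pos <- 20L  # r2 position 20 maps to template position 60-20+1=41, in overlap
  old <- substr(pr2$r2$bases, pos, pos)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  substr(pr2$r2$bases, pos, pos) <- new
  substr(pr2$r2$quals, pos, pos) <- ")"  # Q8
  res2 <- find_overlap(pr2$r1, pr2$r2)
  expect_equal(res2$offset, 10L)
  expect_equal(res2$edit_dist, 1L)
  expect_equal(res2$hamming_dist, 1L)
  expect_equal(nrow(res2$mismatch), 1L)
  expect_equal(res2$mismatch$pos_r2, pos)
  expect_equal(res2$mismatch$r2_qual, 8L)
})

test_that("template-length regimes drive overlap geometry", {
  set.seed(73)
  # 2S <= T: no physical overlap
  template <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  pr <- make_pair(template, 50)
  expect_false(find_overlap(pr$r1, pr$r2)$overlapped)

  # T <= S: negative offset T - S, overlap T
  template <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  pr <- make_pair(template, 50, adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA")
  res <- find_overlap(pr$r1, pr$r2, min_overlap = 15)
  expect_equal(res$offset, -20L)
  expect_equal(res$overlap_len, 30L)
  expect_true(res$overlapped)
})

test_that("the chosen offset equals an exhaustive scan on random pairs", {
  set.seed(79)
  for (i in 1:60) {
    la <- sample(20:60, 1); lb <- sample(20:60, 1)
    r1 <- random_reads(1, la)
    r2 <- random_reads(1, lb)
    mo <- sample(5:15, 1)
    got <- find_overlap(r1, r2, min_overlap = mo)
    want <- oracle_overlap(r1$bases, r2$bases, mo)
    expect_equal(got$offset, want$O)
    expect_equal(got$overlap_len, want$L)
    expect_equal(got$edit_dist, want$e)
  }
})

test_that("adapter cutting truncates both mates to the template and is sound", {
  adapter <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"
  set.seed(83)
  for (tlen in seq(20, 49, by = 3)) {
    template <- paste(sample(c("A", "C", "G", "T"), tlen, TRUE),
                      collapse = "")
    pr <- make_pair(template, 50, adapter = adapter)
    res <- find_overlap(pr$r1, pr$r2, min_overlap = 15)
    expect_equal(res$offset, tlen - 50L)
    cut <- cut_adapters(pr$r1, pr$r2, res)
    expect_equal(nchar(cut$r1$bases), tlen)
    expect_equal(nchar(cut$r2$bases), tlen)
    expect_equal(cut$r1$bases, template)
    # the removed tail is exactly the planted adapter prefix
    expect_equal(substr(pr$r1$bases, tlen + 1, 50),
                 substr(adapter, 1, 50 - tlen))
    # self-consistency: re-running the search gives a full-length overlap
    res2 <- find_overlap(cut$r1, cut$r2, min_overlap = 15)
    expect_equal(res2$offset, 0L)
    expect_equal(res2$overlap_len, tlen)
  }
  pr <- make_pair(paste(sample(c("A", "C", "G", "T"), 49, TRUE),
                        collapse = ""), 50, adapter = adapter)
  res <- find_overlap(pr$r1, pr$r2, min_overlap = 15)
  expect_equal(res$offset, -1L)
  expect_equal(nchar(cut_adapters(pr$r1, pr$r2, res)$r1$bases), 49L)
  expect_error(cut_adapters(pr$r1, pr$r2,
                            structure(list(overlapped = TRUE, offset = 5L),
                                      class = "overlap_result")),
               "negative")
})

test_that("quality-asymmetric mismatches are corrected from the trusted mate", {
  set.seed(89)
  template <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  pr <- make_pair(template, 50, base_qual = 38L)
  # plant a low-quality error in r2's overlap region (Fig-style scenario)
  pos <- 25L
  old <- substr(pr$r2$bases, pos, pos)
  substr(pr$r2$bases, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  substr(pr$r2$quals, pos, pos) <- ")"  # Q8
  res <- find_overlap(pr$r1, pr$r2)
  expect_equal(res$edit_dist, 1L)
  fix <- correct_pair(pr$r1, pr$r2, res, high_q = 30, low_q = 15)
  expect_equal(fix$corrected, 1L)
  expect_false(fix$uncorrectable)
  expect_equal(substr(fix$r2$bases, pos, pos), old)
  expect_equal(substr(fix$r2$quals, pos, pos), substr(pr$r1$quals, 1, 1))
  expect_equal(find_overlap(fix$r1, fix$r2)$edit_dist, 0L)

  # balanced qualities (Q30 vs Q29) stay uncorrected
  pr2 <- make_pair(template, 50, base_qual = 30L)
  substr(pr2$r2$bases, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                            substr(pr2$r2$bases, pos, pos))[1]
  substr(pr2$r2$quals, pos, pos) <- ">"  # Q29
  res2 <- find_overlap(pr2$r1, pr2$r2)
  fix2 <- correct_pair(pr2$r1, pr2$r2, res2)
  expect_equal(fix2$corrected, 0L)
  expect_true(fix2$uncorrectable)
  expect_equal(fix2$r2$bases, pr2$r2$bases)

  expect_error(correct_pair(pr$r1, pr$r2,
                            structure(list(overlapped = TRUE, edit_dist = 0L),
                                      class = "overlap_result")),
               "edit_dist")
})

test_that("indel-bearing overlaps (Hamming != edit) are uncorrectable", {
  set.seed(97)
  template <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  pr <- make_pair(template, 50)
  # delete one base inside r2's copy and pad at its 3' end: the aligned
  # slices now differ by an indel, so Hamming >> edit
  b2 <- pr$r2$bases
  pr$r2$bases <- paste0(substr(b2, 1, 19), substr(b2, 21, 50), "A")
  res <- find_overlap(pr$r1, pr$r2, max_ed_fraction = 0.2)
  expect_true(res$overlapped)
  expect_gt(res$hamming_dist, res$edit_dist)
  fix <- correct_pair(pr$r1, pr$r2, res)
  expect_true(fix$uncorrectable)
  expect_equal(fix$r2$bases, pr$r2$bases)
})

test_that("correction drives planted one-mate errors to zero residual mismatch", {
  sim <- simulate_pairs(simulation_config(seed = 101, n_pairs = 300,
                                          error_rate = 0.02,
                                          error_mate = "r2"))
  for (i in seq_len(300)) {
    res <- find_overlap(sim$r1[i, ], sim$r2[i, ])
    if (!res$overlapped || res$edit_dist == 0) next
    fix <- correct_pair(sim$r1[i, ], sim$r2[i, ], res)
    expect_false(fix$uncorrectable)
    expect_equal(find_overlap(fix$r1, fix$r2)$hamming_dist, 0L)
  }
})

test_that("error statistics accumulate totals, transforms and conservation", {
  set.seed(103)
  template <- paste(sample(c("A", "C", "G", "T"), 70, TRUE), collapse = "")
  pr <- make_pair(template, 65)  # overlap 2*65-70 = 60
  res <- find_overlap(pr$r1, pr$r2)
  expect_equal(res$overlap_len, 60L)
  st <- accumulate_error_stats(res, error_stats())
  expect_equal(st$total_overlapped_bases, 60L)
  expect_equal(st$mismatched_bases, 0L)

  # an A(Q40) / C(Q5) mismatch in r1 orientation counts as A->C
  pos_r1 <- 30L  # template position 30, r2 position 70-30+1=41
  expect_equal(substr(pr$r1$bases, pos_r1, pos_r1),
               substr(template, pos_r1, pos_r1))
  substr(pr$r1$quals, pos_r1, pos_r1) <- "I"  # Q40
  truep <- substr(template, pos_r1, pos_r1)
  obs <- setdiff(c("A", "C", "G", "T"), truep)[1]
  pos_r2 <- 70L - pos_r1 + 1L
  substr(pr$r2$bases, pos_r2, pos_r2) <- chartr("ACGT", "TGCA", obs)
  substr(pr$r2$quals, pos_r2, pos_r2) <- "&"  # Q5
  res <- find_overlap(pr$r1, pr$r2)
  expect_equal(res$hamming_dist, 1L)
  st <- accumulate_error_stats(res, st)
  key <- paste0(truep, "->", obs)
  expect_equal(unname(st$transform_counts[key]), 1L)
  expect_equal(st$mismatched_bases, 1L)
  expect_equal(sum(st$transform_counts) + st$unprofiled_mismatches,
               st$mismatched_bases)

  # balanced mismatches land in unprofiled; short overlaps are skipped
  st2 <- accumulate_error_stats(res, error_stats(),
                                min_profile_overlap = 60L)
  expect_equal(st2$total_overlapped_bases, 0L)
})

test_that("merging returns the corrected overlap with max qualities", {
  set.seed(107)
  template <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  pr <- make_pair(template, 50)
  substr(pr$r1$quals, 15, 15) <- "$"  # Q3 somewhere in the overlap
  res <- find_overlap(pr$r1, pr$r2)
  m <- merge_overlap(pr$r1, pr$r2, res)
  expect_equal(m$bases, substr(template, 11, 50))
  expect_equal(nchar(m$bases), 40L)
  expect_match(m$name, " merged$")
  # the low r1 quality is replaced by the mate's higher one
  expect_equal(substr(m$quals, 5, 5), "D")  # Q35 from r2

  # fully overlapping T = S pair merges at full length
  prs <- make_pair(template, 60)
  res <- find_overlap(prs$r1, prs$r2)
  expect_equal(res$offset, 0L)
  expect_equal(nchar(merge_overlap(prs$r1, prs$r2, res)$bases), 60L)
  expect_error(merge_overlap(prs$r1, prs$r2,
                             structure(list(overlapped = FALSE),
                                       class = "overlap_result")),
               "overlapped")
})
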