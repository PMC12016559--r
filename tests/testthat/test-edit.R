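test_that("edit distance handles the textbook examples", {
  expect_equal(edit_distance("ACGT", "ACGT")$distance, 0L)
  expect_equal(edit_distance("ACGT", "AGT")$distance, 1L)
  # the classic kitten/sitting pattern under a nucleotide encoding that
  # preserves its equality structure (N never matches, standing in for the
  # three letters that match nothing): distance 3
  expect_equal(edit_distance("NATTGC", "NATTACN")$distance, 3L)
  expect_equal(wagner_fischer("NATTGC", "NATTACN"), 3L)
  # length-1 query of the same letter against a run: n-1 insertions
  expect_equal(edit_distance("A", "AAAAAA")$distance, 5L)
  expect_error(edit_distance("", "ACGT"), "non-empty")
  expect_error(edit_distance("ACGT", "ACG", limit = -1), "limit")
})

test_that("bit-vector distances equal Wagner-Fischer in whole and limit modes", {
  set.seed(30)
  for (i in 1:250) {
    m <- sample(1:300, 1); n <- sample(1:300, 1)
    q <- rand_seq(m, alphabet = c("A", "C", "G", "T", "N"))
    r <- rand_seq(n, alphabet = c("A", "C", "G", "T", "N"))
    wf <- wagner_fischer(q, r)
    expect_identical(edit_distance(q, r)$distance, wf, info = paste(q, r))
    el <- edit_distance(q, r, limit = wf)
    expect_false(el$exceeded)
    expect_identical(el$distance, wf)
    if (wf > 0) expect_true(edit_distance(q, r, limit = wf - 1)$exceeded)
    k <- sample(0:max(m, n), 1)
    ek <- edit_distance(q, r, limit = k)
    expect_identical(ek$exceeded, wf > k, info = paste(q, r, k))
    if (!ek$exceeded) expect_identical(ek$distance, wf)
  }
})

test_that("limit mode examines no more cells than whole mode", {
  set.seed(31)
  for (i in 1:40) {
    pr <- rand_pair(sample(100:400, 1), divergence = 0.1, seed = 3000 + i)
    wf <- wagner_fischer(pr$query, pr$reference)
    whole <- edit_distance(pr$query, pr$reference)
    lim <- edit_distance(pr$query, pr$reference, limit = wf)
    expect_lte(lim$cells, whole$cells)
  }
  # and the reduction is real for low-divergence long pairs
  pr <- rand_pair(2000, divergence = 0.02, seed = 77)
  wf <- wagner_fischer(pr$query, pr$reference)
  expect_lt(edit_distance(pr$query, pr$reference, limit = wf)$cells,
            0.5 * edit_distance(pr$query, pr$reference)$cells)
})

test_that("edit tracebacks consume both sequences with exactly d edit columns", {
  expect_identical(edit_distance("ACGTA", "ACGTA", want_cigar = TRUE)$cigar, "5=")
  # the extra query base aligns as one query-consuming column
  expect_identical(parse_cigar(edit_cigar("ACGT", "AGT", 1))$op,
                   c("=", "I", "="))
  set.seed(32)
  for (i in 1:80) {
    m <- sample(1:200, 1); n <- sample(1:200, 1)
    q <- rand_seq(m); r <- rand_seq(n)
    wf <- wagner_fischer(q, r)
    for (lim in list(NULL, wf)) {
      ed <- edit_distance(q, r, limit = lim, want_cigar = TRUE)
      cg <- parse_cigar(ed$cigar)
      expect_identical(sum(cg$length[cg$op %in% c("X", "I", "D")]),
                       as.integer(wf), info = paste(q, r))
      cc <- cigar_consumed(ed$cigar)
      expect_identical(c(cc$query, cc$reference), c(m, n))
    }
  }
  expect_error(edit_cigar("ACGT", "AGT", 2), "does not match")
})

test_that("edit distance is symmetric", {
  set.seed(33)
  for (i in 1:40) {
    q <- rand_seq(sample(1:150, 1)); r <- rand_seq(sample(1:150, 1))
    expect_identical(edit_distance(q, r)$distance, edit_distance(r, q)$distance)
  }
})
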