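test_that("generation is reproducible from seeds and varies across them", {
  expect_identical(random_reference(500, seed = 7), random_reference(500, seed = 7))
  expect_false(random_reference(500, seed = 7) == random_reference(500, seed = 8))
  prof <- mutation_profile(0.1, "nanopore", seed = 5)
  ref <- random_reference(300, seed = 5)
  expect_identical(as.character(mutate(ref, prof)),
                   as.character(mutate(ref, prof)))
  expect_identical(inject_indel(ref, 50, "deletion", seed = 2),
                   inject_indel(ref, 50, "deletion", seed = 2))
})

test_that("base composition of references is uniform", {
  s <- random_reference(1e5, seed = 11)
  counts <- table(strsplit(s, "")[[1]])
  expect_setequal(names(counts), c("A", "C", "G", "T"))
  # each frequency within 3 binomial sigmas of 1/4
  sigma <- sqrt(1e5 * 0.25 * 0.75)
  expect_true(all(abs(counts - 25000) < 3 * sigma))
})

test_that("the mutation process hits its divergence and ratio targets", {
  prof0 <- mutation_profile(0, "nanopore", seed = 1)
  ref <- random_reference(2000, seed = 1)
  expect_identical(as.character(mutate(ref, prof0)), ref)

  n <- 1e5
  d <- 0.05
  ref <- random_reference(n, seed = 21)
  q <- mutate(ref, mutation_profile(d, "nanopore", seed = 21))
  ev <- attr(q, "events")
  # total event count within 3 binomial sigmas of n*d
  expect_lt(abs(sum(ev) - n * d), 3 * sqrt(n * d * (1 - d)))
  # realized type counts consistent with 23:31:46 (chi-square, alpha = 0.01)
  p <- c(23, 31, 46) / 100
  chi <- stats::chisq.test(ev, p = p)
  expect_gt(chi$p.value, 0.01)
  # higher deletion than insertion rate shortens the read on average
  expect_lt(nchar(q), n)
})

test_that("structural indels land mid-sequence with the requested size", {
  ref <- random_reference(10000, seed = 31)
  del <- inject_indel(ref, 50, "deletion", seed = 31)
  expect_identical(nchar(del), 9950L)
  ins <- inject_indel(ref, 200, "insertion", seed = 31)
  expect_identical(nchar(ins), 10200L)
  # event position within [0.4 L, 0.6 L]: locate the first disagreement
  pos <- which(strsplit(ref, "")[[1]][1:9000] != strsplit(del, "")[[1]][1:9000])[1]
  expect_gte(pos, 0.4 * 10000 - 1)
  expect_lte(pos, 0.6 * 10000 + 1)
  expect_error(inject_indel(ref, 6000, "deletion", seed = 1), "half")
})

test_that("recall experiments are reproducible and full-width recall is 1", {
  prof <- mutation_profile(0.1, "nanopore", seed = 51)
  e1 <- recall_experiment(6, 300, prof, band_widths = c(32, 0))
  e2 <- recall_experiment(6, 300, prof, band_widths = c(32, 0))
  expect_identical(e1$table, e2$table)
  expect_identical(e1$replicates, e2$replicates)
  expect_equal(e1$table$recall[e1$table$band_width == 0], 1)
})

test_that("recall is non-decreasing in the band width", {
  prof <- mutation_profile(0.2, "nanopore", seed = 61)
  e <- recall_experiment(8, 800, prof,
                         indel = list(size = 60, kind = "insertion"),
                         band_widths = c(32, 64, 128, 256, 0))
  rec <- e$table$recall
  ordered <- c(rec[1:4], rec[5])  # widths ascending, full width last
  expect_true(all(diff(ordered) >= 0))
})

test_that("a band twice the indel size recovers the optimum; far smaller does not", {
  prof <- mutation_profile(0.2, "nanopore", seed = 71)
  e <- recall_experiment(8, 1200, prof,
                         indel = list(size = 100, kind = "deletion"),
                         band_widths = c(256, 64))
  expect_equal(e$table$recall[e$table$band_width == 256], 1)
  expect_equal(e$table$recall[e$table$band_width == 64], 0)
})
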