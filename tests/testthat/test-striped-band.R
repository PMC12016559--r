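test_that("band configuration enforces the width/lane relation", {
  cfg <- band_config(16, 4)
  expect_identical(cfg$segments, 4L)
  expect_error(band_config(17, 4), "multiple")
  expect_error(band_config(0, 4), "positive")
  expect_error(band_config(16, 0), "positive")
})

test_that("normal/striped coordinate maps are the expected bijection", {
  cfg <- band_config(16, 4)
  m5 <- normal_to_striped(5, cfg)
  expect_identical(m5$register, 1L)
  expect_identical(m5$lane, 1L)
  m15 <- normal_to_striped(15, cfg)
  expect_identical(m15$register, 3L)
  expect_identical(m15$lane, 3L)
  expect_identical(striped_to_normal(0, 0, cfg), 0L)
  expect_identical(striped_to_normal(1, 1, cfg), 5L)
  # round-trip over every offset is the identity
  mp <- normal_to_striped(0:15, cfg)
  expect_identical(striped_to_normal(mp$register, mp$lane, cfg), 0:15)
  expect_error(normal_to_striped(16, cfg), "offset")
  expect_error(striped_to_normal(4, 0, cfg), "register")
  expect_error(striped_to_normal(0, 4, cfg), "lane")
})

test_that("the striped row places cells register-wise as the layout demands", {
  cfg <- band_config(16, 4)
  r <- striped_row(0:15, cfg)
  # register 0 holds offsets 0, s_bar, 2 s_bar, 3 s_bar
  expect_identical(r$registers[, 1], c(0, 4, 8, 12))
  expect_identical(striped_to_normal_values(r), as.numeric(0:15))
})

test_that("shift decisions compare register sums with sentinels included", {
  expect_identical(decide_shift(c(10), c(3)), 0L)
  expect_identical(decide_shift(c(7), c(7)), 1L)
  expect_identical(decide_shift(c(3), c(10)), 2L)
  neg <- neg_inf_sentinel()
  # a sentinel drags its register's sum down
  expect_identical(decide_shift(c(neg, 100), c(0, 0)), 2L)
  expect_error(decide_shift(1:3, 1:2), "equal length")
})

test_that("striped move equals a left shift with sentinel fill, for every layout", {
  neg <- neg_inf_sentinel()
  set.seed(1)
  for (p in c(1, 2, 3, 4, 8, 16)) {
    for (sb in c(1, 2, 3, 4, 8, 16)) {
      W <- p * sb
      if (W > 256) next
      cfg <- band_config(W, p)
      vals <- sample(-100:100, W, replace = TRUE)
      row <- striped_row(vals, cfg, band_origin = 3L)
      for (sh in 0:2) {
        mv <- striped_move(row, sh)
        expect_identical(striped_to_normal_values(mv),
                         left_shift_sentinel(vals, sh),
                         info = sprintf("W=%d p=%d shift=%d", W, p, sh))
        expect_identical(mv$band_origin, 3L + sh)
      }
    }
  }
})

test_that("the worked 16-cell example moves as the figure prescribes", {
  cfg <- band_config(16, 4)
  row <- striped_row(0:15, cfg)
  mv <- striped_move(row, 1)
  # normal order reads 1..15 followed by one sentinel
  expect_identical(striped_to_normal_values(mv),
                   c(1:15, neg_inf_sentinel()))
  # the new first register holds old offsets 1, 5, 9, 13
  expect_identical(mv$registers[, 1], c(1, 5, 9, 13))
  mv2 <- striped_move(row, 2)
  expect_identical(striped_to_normal_values(mv2),
                   c(2:15, rep(neg_inf_sentinel(), 2)))
})

test_that("moving one cell twice equals moving two cells once", {
  set.seed(2)
  for (p in c(1, 2, 4)) for (sb in c(1, 2, 5)) {
    cfg <- band_config(p * sb, p)
    row <- striped_row(sample(-50:50, p * sb, replace = TRUE), cfg)
    a <- striped_move(striped_move(row, 1), 1)
    b <- striped_move(row, 2)
    expect_identical(striped_to_normal_values(a), striped_to_normal_values(b))
    expect_identical(a$band_origin, b$band_origin)
  }
})

test_that("invalid shifts are rejected", {
  cfg <- band_config(8, 2)
  row <- striped_row(1:8, cfg)
  expect_error(striped_move(row, 3), "shift")
  expect_error(striped_move(row, -1), "shift")
})
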