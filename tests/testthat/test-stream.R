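test_that("constructor enforces stream invariants", {
  t0 <- as.POSIXct("2020-03-23", tz = "UTC")
  st <- tweet_stream(c("b", "a"), c("u2", "u1"), t0 + c(10, 5), c("x", "y"))
  expect_s3_class(st, "tweet_stream")
  expect_equal(st$tweet_id, c("a", "b")) # sorted by time
  expect_equal(stream_span(st), t0 + c(5, 10), ignore_attr = "tzone")
  expect_error(tweet_stream(c("a", "a"), c("u", "u"), t0 + 1:2, c("x", "y")),
               "unique")
  expect_error(tweet_stream("a", "u", t0, ""), "non-empty")
})

test_that("JSONL round trip preserves text fields bit-identically", {
  t0 <- as.POSIXct("2020-03-23 12:00:00", tz = "UTC")
  texts <- c("plain text", "unicode ’ … café", "#tags @and urls https://x.y/z")
  st <- tweet_stream(c("1", "2", "3"), c("u1", "u2", "u1"), t0 + 1:3, texts)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_tweet_stream(st, path)
  st2 <- read_tweet_stream(path)
  expect_identical(st2$text, st$text)
  expect_identical(st2$tweet_id, st$tweet_id)
  expect_identical(st2$user_id, st$user_id)
  expect_equal(st2$timestamp, st$timestamp)
})

test_that("malformed lines are skipped and counted", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  good <- sprintf(
    '{"id":"%d","user_id":"u","created_at":"2020-03-23T0%d:00:00Z","text":"t%d"}',
    1:3, 1:3, 1:3
  )
  writeLines(c(good[1], "{not json", good[2:3]), path)
  expect_warning(st <- read_tweet_stream(path), "skipped 1")
  expect_equal(nrow(st), 3)
  expect_equal(attr(st, "skipped"), 1L)

  # unparseable timestamp counts as malformed too
  writeLines(c(good[1],
               '{"id":"9","user_id":"u","created_at":"yesterday","text":"t"}'),
             path)
  expect_warning(st <- read_tweet_stream(path), "skipped 1")
  expect_equal(st$tweet_id, "1")
})

test_that("empty file yields an empty stream with undefined span", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  file.create(path)
  st <- read_tweet_stream(path)
  expect_equal(nrow(st), 0)
  expect_null(stream_span(st))
  expect_error(time_windows(st, window_config("1d", "1d")), "span")
})

test_that("window partition reproduces the 3-day/1-day seven-window layout", {
  sp <- as.POSIXct(c("2020-03-23", "2020-04-01"), tz = "UTC")
  w <- time_windows(sp, window_config("3d", "1d"))
  expect_equal(nrow(w), 7)
  expect_equal(w$start[1], sp[1])
  expect_equal(w$end[7], sp[2])
  expect_true(all(as.numeric(diff(w$start), units = "days") == 1))
  expect_true(all(as.numeric(w$end - w$start, units = "days") == 3))
})

test_that("window starts enumerate every shift offset that fits the span", {
  origin <- as.POSIXct("2020-01-01", tz = "UTC")
  sp <- origin + c(0, 10)
  w <- time_windows(sp, window_config(4, 2))
  # oracle: every offset s = 0, 2, 4, ... with s + len <= span length
  expect_equal(as.numeric(w$start - origin, units = "secs"), c(0, 2, 4, 6))
  expect_equal(nrow(w), 4)

  # span exactly one window long: a single window regardless of shift
  w1 <- time_windows(origin + c(0, 4), window_config(4, 1))
  expect_equal(nrow(w1), 1)

  # invalid configurations
  expect_error(window_config(0, 1), "length")
  expect_error(window_config(4, 0), "shift")
  expect_error(window_config(4, 5), "shift")
})

test_that("window membership is half-open and overlap-aware", {
  origin <- as.POSIXct("2020-03-23", tz = "UTC")
  st <- make_stream(c(0, 86400 * 3 - 1, 86400 * 3, 86400 * 4))
  w <- time_windows(origin + c(0, 6 * 86400), window_config("3d", "1d"))
  w1 <- tweets_in_window(st, w[1, ])
  expect_true("id1" %in% w1$tweet_id)        # t = start included
  expect_true("id2" %in% w1$tweet_id)        # t = end - 1s included
  expect_false("id3" %in% w1$tweet_id)       # t = end excluded
  # a tweet in the overlap region appears in both overlapping windows
  w2 <- tweets_in_window(st, w[2, ])
  expect_true("id2" %in% w2$tweet_id)   # [1d, 4d) overlaps [0, 3d)
  w3 <- tweets_in_window(st, w[3, ])
  w4 <- tweets_in_window(st, w[4, ])
  expect_true("id4" %in% w3$tweet_id)   # day 4 lies in [2d, 5d) ...
  expect_true("id4" %in% w4$tweet_id)   # ... and in [3d, 6d)
})

test_that("no tweet is lost across windows; shift = len gives a disjoint partition", {
  set.seed(99)
  for (shift in c("1d", "2d", "3d")) {
    st <- make_stream(sort(runif(200, 0, 9 * 86400)))
    w <- time_windows(st, window_config("3d", shift),
                      span_end = stream_span(st)[1] + 9 * 86400)
    member <- lapply(seq_len(nrow(w)), function(i)
      tweets_in_window(st, w[i, ])$tweet_id)
    counts <- table(factor(unlist(member), levels = st$tweet_id))
    expect_true(all(counts >= 1)) # union covers the span
    if (shift == "3d") expect_true(all(counts == 1)) # disjoint partition
  }
})
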