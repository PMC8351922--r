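test_that("per-topic counts are exact and user-distinct", {
  st <- make_stream(1:7, users = c("a", "a", "b", "c", "a", "b", "c"),
                    topics = c(2L, 2L, 2L, 2L, 2L, 3L, NA))
  stats <- trend_stats(st)
  expect_equal(stats$n_tweets[stats$topic == 2], 5)
  expect_equal(stats$n_users[stats$topic == 2], 3)  # same user counted once
  expect_equal(stats$n_tweets[stats$topic == 3], 1)
  expect_true(all(stats$n_users <= stats$n_tweets))
  empty <- trend_stats(make_stream(1, topics = NA_integer_))
  expect_equal(nrow(empty), 0)
})

test_that("trending score mixes max-normalized volume and reach", {
  stats <- data.frame(topic = 1:2, n_tweets = c(10L, 6L), n_users = c(5L, 8L))
  sc <- trending_score(stats, alpha = 0.5)
  expect_equal(sc$score, c(0.5 * 1 + 0.5 * 5 / 8, 0.5 * 0.6 + 0.5 * 1))
  expect_equal(sc$score, c(0.8125, 0.8))
  expect_error(trending_score(stats, alpha = 1.5), "alpha")
  expect_error(trending_score(stats[0, ], 0.5), "no topic")
})

test_that("alpha limits reduce to count-only rankings", {
  set.seed(1)
  for (i in 1:50) {
    n <- sample(2:8, 1)
    stats <- data.frame(topic = seq_len(n),
                        n_tweets = sample(1:100, n, replace = TRUE))
    stats$n_users <- pmin(stats$n_tweets, sample(1:50, n, replace = TRUE))
    r1 <- order(-trending_score(stats, 1)$score, -stats$n_tweets)
    expect_equal(stats$n_tweets[r1], sort(stats$n_tweets, decreasing = TRUE))
    r0 <- order(-trending_score(stats, 0)$score, -stats$n_users)
    expect_equal(stats$n_users[r0], sort(stats$n_users, decreasing = TRUE))
  }
})

test_that("score is monotone in volume and reach with maxima held fixed", {
  stats <- data.frame(topic = 1:3, n_tweets = c(50L, 20L, 10L),
                      n_users = c(30L, 10L, 5L))
  base <- trending_score(stats, 0.4)$score[2]
  up_n <- stats; up_n$n_tweets[2] <- 30L
  up_u <- stats; up_u$n_users[2] <- 20L
  expect_gt(trending_score(up_n, 0.4)$score[2], base)
  expect_gt(trending_score(up_u, 0.4)$score[2], base)
})

test_that("bounded priority queue equals the full-sort prefix", {
  set.seed(2)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    stats <- data.frame(topic = seq_len(n),
                        n_tweets = sample(1:6, n, replace = TRUE))
    stats$n_users <- pmin(stats$n_tweets, sample(1:4, n, replace = TRUE))
    sc <- trending_score(stats, runif(1))
    k <- sample(1:5, 1)
    got <- top_k_topics(sc, k)
    # oracle: full sort by score desc, tweet count desc, topic asc
    ord <- order(-sc$score, -sc$n_tweets, sc$topic)
    expect_equal(got$topic, sc$topic[head(ord, k)])
    expect_equal(got$rank, seq_len(min(k, n)))
  }
})

test_that("a short query is flagged when fewer topics than k exist", {
  sc <- trending_score(data.frame(topic = 1:2, n_tweets = c(3L, 1L),
                                  n_users = c(2L, 1L)), 0.5)
  q <- top_k_topics(sc, 5)
  expect_equal(nrow(q), 2)
  expect_true(attr(q, "short_query"))
  expect_false(attr(top_k_topics(sc, 2), "short_query"))
})

test_that("explicit tie cases resolve by tweet count then topic index", {
  sc <- data.frame(topic = c(7L, 2L, 5L), n_tweets = c(4L, 6L, 6L),
                   n_users = c(2L, 2L, 2L), score = c(0.8, 0.8, 0.8))
  q <- top_k_topics(sc, 2)
  expect_equal(q$topic, c(2L, 5L)) # same score: higher N wins, then lower id
})

test_that("popularity percentages are exact ratios summing to 100", {
  st <- make_stream(1:100, users = paste0("u", 1:100),
                    topics = c(rep(1L, 19), rep(2L, 81)))
  pct <- popularity_percentages(st)
  expect_equal(unname(pct["topic_1"]), 19)
  expect_equal(sum(pct), 100)
  expect_length(popularity_percentages(make_stream(1, topics = NA_integer_)), 0)
})

test_that("the trend matrix tracks the planted schedule switch", {
  sim <- generate_stream(stream_sim_config(seed = 13, n_users = 80,
                                           tweets_per_user = 15))
  st <- sim$stream
  st$topic <- sim$truth$tweets$z_true
  w <- time_windows(st, window_config("3d", "1d"),
                    span_end = stream_span(st)[1] + 9 * 86400)
  m <- trend_matrix(st, w)
  expect_equal(dim(m), c(3, 7))
  expect_true(all(abs(colSums(m) - 100) < 1e-9))
  # planted dominance: topic 1 leads the early windows, topic 2 the late ones
  expect_true(all(apply(m[, 1:3], 2, which.max) == 1))
  expect_true(all(apply(m[, 5:7], 2, which.max) == 2))
})
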