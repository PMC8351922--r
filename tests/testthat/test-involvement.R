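test_that("kappa vectors count query-topic tweets per rank", {
  st <- make_stream(1:6, users = c("a", "a", "a", "b", "b", "c"),
                    topics = c(5L, 5L, 7L, 9L, 9L, 4L))
  kap <- kappa_counts(st, query = c(5L, 7L, 9L)) # ranks 1..3
  expect_equal(unname(kap["a", ]), c(2L, 1L, 0L))
  expect_equal(unname(kap["b", ]), c(0L, 0L, 2L))
  expect_false("c" %in% rownames(kap)) # only off-query activity
})

test_that("psi applies rank weights k+1-l", {
  expect_equal(psi_score(c(2, 1, 0)), 3 * 2 + 2 * 1 + 1 * 0)
  expect_equal(psi_score(c(2, 1, 0)), 8)
  expect_equal(psi_score(c(0, 0, 0)), 0)
  expect_equal(psi_score(5, k = 1), 5) # k = 1 reduces to the raw count
  m <- rbind(a = c(2, 1, 0), b = c(0, 0, 1))
  expect_equal(unname(psi_score(m)), c(8, 1))
})

test_that("sigma normalizes by the window maximum", {
  expect_equal(unname(sigma_score(c(a = 8, b = 4))), c(1, 0.5))
  expect_equal(unname(sigma_score(c(solo = 3))), 1)
  expect_equal(unname(sigma_score(c(a = 6, b = 6))), c(1, 1)) # tied maxima
  expect_warning(out <- sigma_score(c(a = 0, b = 0)), "undefined")
  expect_length(out, 0)
})

test_that("sigma is invariant to integer rescaling of all kappa vectors", {
  set.seed(3)
  for (i in 1:25) {
    kap <- matrix(rpois(15, 2), 5, 3)
    if (all(rowSums(kap) == 0)) next
    s1 <- sigma_score(psi_score(kap))
    s2 <- sigma_score(psi_score(kap * 7L))
    expect_equal(s1, s2)
  }
})

test_that("a tweet on a higher-ranked topic never lowers psi", {
  set.seed(4)
  for (i in 1:25) {
    kap <- rpois(3, 2)
    l <- sample(1:3, 1)
    kap2 <- kap
    kap2[l] <- kap2[l] + 1
    expect_gte(psi_score(kap2), psi_score(kap))
  }
})

test_that("the windowed ranking equals the composition of its stages", {
  sim <- generate_stream(stream_sim_config(seed = 14, n_users = 50,
                                           tweets_per_user = 10))
  st <- sim$stream
  st$topic <- sim$truth$tweets$z_true
  w <- time_windows(st, window_config("3d", "1d"),
                    span_end = stream_span(st)[1] + 9 * 86400)
  res <- rank_involved_users(st, w, k = 2, alpha = 0.5, r = 10)
  for (i in seq_len(nrow(w))) {
    wt <- tweets_in_window(st, w[i, ])
    query <- top_k_topics(trending_score(trend_stats(wt), 0.5), 2)
    kap <- kappa_counts(wt, query)
    psi <- psi_score(kap)
    sigma <- sigma_score(setNames(psi, rownames(kap)))
    ord <- order(-sigma, -rowSums(kap), rownames(kap))
    expect_equal(res[[i]]$users$user_id, rownames(kap)[head(ord, 10)])
    expect_equal(res[[i]]$users$sigma, unname(sigma[head(ord, 10)]))
    # sigma non-increasing down the list, max attains 1
    expect_true(all(diff(res[[i]]$users$sigma) <= 0))
    expect_equal(res[[i]]$users$sigma[1], 1)
  }
})

test_that("an unreachable eligibility threshold yields an empty warning result", {
  st <- make_stream(1:4, users = c("a", "a", "b", "b"), topics = rep(1L, 4))
  w <- time_windows(stream_span(st) + c(0, 1), window_config(60, 60))
  expect_warning(res <- rank_involved_users(st, w, k = 1, r = 5,
                                            min_tweets = 99), "min_tweets")
  expect_equal(nrow(res[[1]]$users), 0)
})

test_that("the planted hyper-active user tops every window", {
  sim <- generate_stream(stream_sim_config(seed = 15, n_users = 60,
                                           tweets_per_user = 10))
  st <- sim$stream
  st$topic <- sim$truth$tweets$z_true
  w <- time_windows(st, window_config("3d", "1d"),
                    span_end = stream_span(st)[1] + 9 * 86400)
  res <- rank_involved_users(st, w, k = 3, alpha = 0.5, r = 5)
  for (r in res) {
    expect_equal(r$users$user_id[1], sim$truth$hyper_user)
    expect_equal(r$users$sigma[1], 1)
  }
})
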