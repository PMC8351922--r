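#' Per-user query-topic tweet counts (kappa vectors)
#'
#' For each user with at least one tweet on a query topic in the window,
#' counts the user's tweets on the l-th ranked query topic, l = 1..k. Users
#' whose counts are all zero (only off-query activity) are excluded.
#'
#' @param wtweets topic-annotated window tweets.
#' @param query a [top_k_topics()] query (or ranked integer topic vector).
#' @return Integer matrix, users in rows (rownames = user ids), k ranked
#'   query topics in columns.
#' @export
kappa_counts <- function(wtweets, query) {
  topics <- query_topics(query)
  k <- length(topics)
  if (is.null(wtweets$topic)) stop("tweets are not topic-annotated")
  qt <- wtweets[!is.na(wtweets$topic) & wtweets$topic %in% topics, , drop = FALSE]
  users <- sort(unique(qt$user_id))
  mat <- matrix(0L, nrow = length(users), ncol = k,
                dimnames = list(users, paste0("rank_", seq_len(k))))
  if (nrow(qt) > 0) {
    for (l in seq_len(k)) {
      cnt <- table(qt$user_id[qt$topic == topics[l]])
      if (length(cnt)) mat[names(cnt), l] <- as.integer(cnt)
    }
  }
  mat
}

#' Rank-weighted involvement sum (psi)
#'
#' \deqn{\psi = \sum_{l=1}^{k} (k + 1 - l)\,\kappa_l} so a tweet on the
#' rank-1 query topic weighs k and a tweet on the rank-k topic weighs 1. With
#' k = 1 this reduces to the raw tweet count.
#'
#' @param kappa integer vector of length k (a row of [kappa_counts()]), or a
#'   matrix with k columns (one psi per row).
#' @param k number of query topics; defaults to `length(kappa)` /
#'   `ncol(kappa)`.
#' @return Numeric psi value(s).
#' @export
psi_score <- function(kappa, k = NULL) {
  if (is.matrix(kappa)) {
    if (is.null(k)) k <- ncol(kappa)
    stopifnot(ncol(kappa) == k)
    return(drop(kappa %*% (k + 1 - seq_len(k))))
  }
  if (is.null(k)) k <- length(kappa)
  stopifnot(length(kappa) == k)
  sum((k + 1 - seq_len(k)) * kappa)
}

#' Normalized involvement scores (sigma)
#'
#' \deqn{\sigma_i = \psi_i / \max_z \psi_z} over the window's eligible users,
#' so the most active user(s) score exactly 1 and all scores lie in [0, 1].
#'
#' @param psi named numeric vector of psi values for the eligible users.
#' @return Named numeric vector of sigma values; empty (with a warning) when
#'   every psi is zero, since the normalizer is undefined.
#' @export
sigma_score <- function(psi) {
  if (length(psi) == 0) return(setNames(numeric(0), character(0)))
  m <- max(psi)
  if (m <= 0) {
    warning("all psi values are zero; sigma undefined")
    return(setNames(numeric(0), character(0)))
  }
  psi / m
}

#' Top involved users per window (the query algorithm)
#'
#' For every time window: selects the top-k trending topics as the query,
#' computes each eligible user's rank-weighted involvement (kappa, psi,
#' sigma), and returns the r most involved users. Eligibility requires at
#' least `min_tweets` tweets on query topics in the window; the same eligible
#' set provides the sigma normalizer. Users sort by sigma descending, ties by
#' total query-tweet count then user id.
#'
#' @param stream topic-annotated `tweet_stream`.
#' @param windows a [time_windows()] frame.
#' @param k number of query topics per window.
#' @param alpha trending-score mixing weight, see [trending_score()].
#' @param r number of users returned per window.
#' @param min_tweets minimum query-topic tweets for eligibility.
#' @return A list with one element per window, each containing `window`
#'   (index), `query` (the [top_k_topics()] object) and `users` (data frame
#'   `rank`, `user_id`, `psi`, `sigma`, truncated to r).
#' @export
rank_involved_users <- function(stream, windows, k = 3, alpha = 0.5, r = 20,
                                min_tweets = 1) {
  stopifnot(inherits(stream, "tweet_stream"))
  out <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    wt <- tweets_in_window(stream, windows[i, ])
    st <- trend_stats(wt)
    if (nrow(st) == 0) {
      out[[i]] <- list(window = windows$index[i], query = NULL,
                       users = data.frame(rank = integer(0),
                                          user_id = character(0),
                                          psi = numeric(0), sigma = numeric(0)))
      next
    }
    query <- top_k_topics(trending_score(st, alpha), k)
    kap <- kappa_counts(wt, query)
    eligible <- rowSums(kap) >= min_tweets
    kap <- kap[eligible, , drop = FALSE]
    if (nrow(kap) == 0) {
      warning(sprintf("window %d: no user meets min_tweets = %d",
                      windows$index[i], min_tweets))
      out[[i]] <- list(window = windows$index[i], query = query,
                       users = data.frame(rank = integer(0),
                                          user_id = character(0),
                                          psi = numeric(0), sigma = numeric(0)))
      next
    }
    psi <- psi_score(kap)
    sigma <- sigma_score(setNames(psi, rownames(kap)))
    total <- rowSums(kap)
    ord <- order(-sigma, -total, rownames(kap))
    sel <- head(ord, r)
    out[[i]] <- list(
      window = windows$index[i],
      query = query,
      eligible = rownames(kap),
      users = data.frame(
        rank = seq_along(sel),
        user_id = rownames(kap)[sel],
        psi = unname(psi[sel]),
        sigma = unname(sigma[sel]),
        stringsAsFactors = FALSE
      )
    )
  }
  out
}
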