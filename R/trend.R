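#' Per-topic tweet and user counts in a window
#'
#' One record per topic with at least one tweet in the window: `n_tweets` is
#' the number of tweets on the topic, `n_users` the number of distinct users
#' who posted them (so `n_users <= n_tweets`).
#'
#' @param wtweets topic-annotated window tweets (from [tweets_in_window()]).
#' @return Data frame with columns `topic`, `n_tweets`, `n_users`; empty when
#'   the window holds no topic-annotated tweets.
#' @export
trend_stats <- function(wtweets) {
  if (is.null(wtweets$topic)) stop("tweets are not topic-annotated")
  wt <- wtweets[!is.na(wtweets$topic), , drop = FALSE]
  if (nrow(wt) == 0) {
    return(data.frame(topic = integer(0), n_tweets = integer(0),
                      n_users = integer(0)))
  }
  topics <- sort(unique(wt$topic))
  data.frame(
    topic = topics,
    n_tweets = vapply(topics, function(t) sum(wt$topic == t), integer(1)),
    n_users = vapply(topics, function(t)
      length(unique(wt$user_id[wt$topic == t])), integer(1))
  )
}

#' Trending score for each topic in a window
#'
#' The score mixes tweet volume and distinct-user reach:
#' \deqn{\Lambda_i = \alpha \frac{N_i}{\max_j N_j} +
#'       (1-\alpha) \frac{U_i}{\max_j U_j}}
#' Both components are max-normalized within the window before mixing, so
#' \eqn{\Lambda \in (0, 1]} and \eqn{\alpha} trades off the two factors on a
#' common scale. At \eqn{\alpha = 1} the ranking equals the raw tweet-count
#' ranking; at \eqn{\alpha = 0} the raw distinct-user ranking.
#'
#' @param stats output of [trend_stats()]; must be non-empty.
#' @param alpha mixing weight in `[0, 1]`.
#' @return `stats` with an added `score` column.
#' @export
trending_score <- function(stats, alpha = 0.5) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1) {
    stop("alpha must be a single value in [0, 1]")
  }
  if (nrow(stats) == 0) stop("no topic statistics to score")
  stats$score <- alpha * stats$n_tweets / max(stats$n_tweets) +
    (1 - alpha) * stats$n_users / max(stats$n_users)
  stats
}

# --- bounded priority queue -------------------------------------------------
# Binary min-heap holding at most k items, keyed by (score, n_tweets,
# -topic): the root is the weakest retained topic, so streaming all topics
# through leaves exactly the top-k. Ties break by higher tweet count, then
# lower topic index.

pq_less <- function(a, b) {
  # TRUE when item a has strictly lower priority than item b
  if (a$score != b$score) return(a$score < b$score)
  if (a$n != b$n) return(a$n < b$n)
  a$topic > b$topic
}

pq_new <- function(k) {
  env <- new.env(parent = emptyenv())
  env$items <- vector("list", 0)
  env$k <- k
  env
}

pq_sift_up <- function(pq, i) {
  while (i > 1) {
    p <- i %/% 2
    if (pq_less(pq$items[[i]], pq$items[[p]])) {
      tmp <- pq$items[[i]]; pq$items[[i]] <- pq$items[[p]]; pq$items[[p]] <- tmp
      i <- p
    } else break
  }
}

pq_sift_down <- function(pq, i) {
  n <- length(pq$items)
  repeat {
    l <- 2 * i; r <- 2 * i + 1; m <- i
    if (l <= n && pq_less(pq$items[[l]], pq$items[[m]])) m <- l
    if (r <= n && pq_less(pq$items[[r]], pq$items[[m]])) m <- r
    if (m == i) break
    tmp <- pq$items[[i]]; pq$items[[i]] <- pq$items[[m]]; pq$items[[m]] <- tmp
    i <- m
  }
}

pq_add <- function(pq, item) {
  if (length(pq$items) < pq$k) {
    pq$items[[length(pq$items) + 1]] <- item
    pq_sift_up(pq, length(pq$items))
  } else if (pq_less(pq$items[[1]], item)) {
    pq$items[[1]] <- item
    pq_sift_down(pq, 1)
  }
  invisible(pq)
}

pq_drain <- function(pq) {
  out <- vector("list", 0)
  while (length(pq$items) > 0) {
    out[[length(out) + 1]] <- pq$items[[1]]
    last <- length(pq$items)
    pq$items[[1]] <- pq$items[[last]]
    pq$items[[last]] <- NULL
    if (length(pq$items) > 0) pq_sift_down(pq, 1)
  }
  rev(out) # strongest first
}

#' Select the top-k trending topics (the query)
#'
#' Streams the scored topics through a bounded priority queue of size `k` and
#' returns the `k` highest-scoring topics, ranked. Ties break by higher tweet
#' count, then lower topic index. When fewer than `k` topics exist, all are
#' returned and the result is flagged as a short query.
#'
#' @param scored output of [trending_score()].
#' @param k number of query topics.
#' @return An object of class `topic_query`: a data frame with columns
#'   `rank`, `topic`, `score`, `n_tweets`, `n_users`, with attributes `k`,
#'   `short_query`.
#' @export
top_k_topics <- function(scored, k) {
  stopifnot(is.numeric(k), length(k) == 1, k >= 1)
  if (is.null(scored$score)) stop("run trending_score() first")
  pq <- pq_new(as.integer(k))
  for (i in seq_len(nrow(scored))) {
    pq_add(pq, list(score = scored$score[i], n = scored$n_tweets[i],
                    topic = scored$topic[i], users = scored$n_users[i]))
  }
  items <- pq_drain(pq)
  out <- data.frame(
    rank = seq_along(items),
    topic = vapply(items, function(x) as.integer(x$topic), integer(1)),
    score = vapply(items, function(x) x$score, numeric(1)),
    n_tweets = vapply(items, function(x) as.integer(x$n), integer(1)),
    n_users = vapply(items, function(x) as.integer(x$users), integer(1))
  )
  class(out) <- c("topic_query", "data.frame")
  attr(out, "k") <- as.integer(k)
  attr(out, "short_query") <- nrow(out) < k
  out
}

#' @export
print.topic_query <- function(x, ...) {
  cat(sprintf("Top-%d topic query%s:\n", attr(x, "k"),
              if (isTRUE(attr(x, "short_query"))) " (short: fewer topics than k)" else ""))
  print.data.frame(x)
  invisible(x)
}

# Ranked topic ids of a query (or pass an integer vector through).
query_topics <- function(query) {
  if (inherits(query, "topic_query")) return(query$topic)
  as.integer(query)
}

#' Popularity percentages of topics in a window
#'
#' Percentage of the window's topic-annotated tweets on each topic; the
#' percentages over all topics sum to 100 up to rounding.
#'
#' @param wtweets topic-annotated window tweets.
#' @param topics topics to report (default: all topics present).
#' @return Named numeric vector of exact percentages (see [report_round()]).
#' @export
popularity_percentages <- function(wtweets, topics = NULL) {
  wt <- wtweets[!is.na(wtweets$topic), , drop = FALSE]
  if (nrow(wt) == 0) return(setNames(numeric(0), character(0)))
  if (is.null(topics)) topics <- sort(unique(wt$topic))
  pct <- vapply(topics, function(t) 100 * sum(wt$topic == t) / nrow(wt),
                numeric(1))
  setNames(pct, paste0("topic_", topics))
}

#' Topic-by-window popularity matrix
#'
#' Heatmap-ready matrix of popularity percentages, topics in rows and windows
#' in columns.
#'
#' @param stream topic-annotated `tweet_stream`.
#' @param windows a [time_windows()] frame.
#' @param topics topics to include (default: all).
#' @return Numeric matrix, `length(topics)` x `nrow(windows)`.
#' @export
trend_matrix <- function(stream, windows, topics = NULL) {
  if (is.null(topics)) topics <- sort(unique(stream$topic[!is.na(stream$topic)]))
  mat <- matrix(0, nrow = length(topics), ncol = nrow(windows),
                dimnames = list(paste0("topic_", topics),
                                paste0("I", windows$index)))
  for (i in seq_len(nrow(windows))) {
    pct <- popularity_percentages(tweets_in_window(stream, windows[i, ]), topics)
    if (length(pct)) mat[, i] <- pct
  }
  mat
}
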