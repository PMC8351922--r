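#' Run the full window-level trend/involvement/sentiment analysis
#'
#' End-to-end driver: preprocesses the stream (if needed), fits the topic
#' model (if the stream is not yet topic-annotated), scores sentiment (if
#' needed), partitions the span into overlapping windows, and per window
#' computes the top-k trending-topic query, the top-r involved users with
#' their involvement scores, per-user aggregate sentiment, overall and
#' topic-wise sentiment clusters, and the cluster quality measures (weighted
#' entropy and semantic cohesion).
#'
#' @param stream a `tweet_stream` (annotations are computed when absent).
#' @param window_cfg a [window_config()]; default 3-day windows shifted by
#'   1 day.
#' @param K topics for the model (ignored if `stream$topic` exists).
#' @param k query size (top-k trending topics per window).
#' @param alpha trending-score mixing weight.
#' @param r users reported per window.
#' @param min_tweets eligibility threshold on query-topic tweets.
#' @param threshold sentiment classification boundary.
#' @param preprocess_cfg a [preprocess_config()].
#' @param seed seed for the topic-model fit.
#' @param ... further arguments to [tlda()] (`iters`, `burn_in`, ...).
#' @return An object of class `trend_analysis`: list with `stream` (fully
#'   annotated), `model` (the [tlda()] fit or `NULL` when topics were given),
#'   `windows`, and `window_results` (one element per window: `query`,
#'   `popularity`, `users`, `eligible`, `aggregates`, `clusters`,
#'   `main_topics`, `entropy`, `cohesion`, `dynamics_row`).
#' @export
analyze_stream <- function(stream, window_cfg = window_config("3d", "1d"),
                           K = 3, k = 3, alpha = 0.5, r = 20, min_tweets = 1,
                           threshold = 0.05,
                           preprocess_cfg = preprocess_config(),
                           seed = NULL, ...) {
  stopifnot(inherits(stream, "tweet_stream"))
  if (is.null(stream$tokens)) stream <- preprocess_stream(stream, preprocess_cfg)
  model <- NULL
  if (is.null(stream$topic)) {
    model <- tlda(stream, K = K, seed = seed, ...)
    stream <- assign_topics(model, stream)
  }
  if (is.null(stream$compound)) {
    stream <- score_stream(stream, threshold = threshold)
  }
  windows <- time_windows(stream, window_cfg)

  results <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    wt <- tweets_in_window(stream, windows[i, ])
    st <- trend_stats(wt)
    if (nrow(st) == 0) {
      results[[i]] <- list(window = windows$index[i], query = NULL)
      next
    }
    query <- top_k_topics(trending_score(st, alpha), k)
    kap <- kappa_counts(wt, query)
    kap <- kap[rowSums(kap) >= min_tweets, , drop = FALSE]
    eligible <- rownames(kap)
    users_df <- data.frame(rank = integer(0), user_id = character(0),
                           psi = numeric(0), sigma = numeric(0))
    if (nrow(kap) > 0) {
      psi <- psi_score(kap)
      sigma <- sigma_score(setNames(psi, rownames(kap)))
      ord <- order(-sigma, -rowSums(kap), rownames(kap))
      sel <- head(ord, r)
      users_df <- data.frame(rank = seq_along(sel),
                             user_id = rownames(kap)[sel],
                             psi = unname(psi[sel]),
                             sigma = unname(sigma[sel]),
                             stringsAsFactors = FALSE)
    }
    aggregates <- aggregate_user_sentiment(wt, query, users = eligible)
    clusters <- build_sentiment_clusters(aggregates, threshold = threshold)
    topic_clusters <- lapply(query$topic, function(tp) {
      build_sentiment_clusters(aggregates, score = paste0("topic_", tp),
                               threshold = threshold)
    })
    names(topic_clusters) <- paste0("topic_", query$topic)
    main_topics <- user_main_topic(wt, query)
    entropy <- cluster_entropy(clusters, main_topics, topics = query$topic)
    cohesion <- cluster_cohesion(clusters, main_topics, query)
    qt <- wt[!is.na(wt$topic) & wt$topic %in% query$topic, , drop = FALSE]
    n <- nrow(qt)
    dyn <- data.frame(
      window = windows$index[i], n = n,
      pos_pct = if (n) 100 * sum(qt$label == "positive") / n else NA_real_,
      neg_pct = if (n) 100 * sum(qt$label == "negative") / n else NA_real_,
      neu_pct = if (n) 100 * sum(qt$label == "neutral") / n else NA_real_
    )
    results[[i]] <- list(
      window = windows$index[i], query = query,
      popularity = popularity_percentages(wt),
      users = users_df, eligible = eligible, aggregates = aggregates,
      clusters = clusters, topic_clusters = topic_clusters,
      main_topics = main_topics, entropy = entropy, cohesion = cohesion,
      dynamics_row = dyn
    )
  }
  structure(list(
    stream = stream, model = model, windows = windows,
    window_results = results,
    params = list(K = K, k = k, alpha = alpha, r = r,
                  min_tweets = min_tweets, threshold = threshold)
  ), class = "trend_analysis")
}

#' @export
print.trend_analysis <- function(x, ...) {
  cat(sprintf("Trend/sentiment analysis: %d windows, k = %d, alpha = %.2f\n",
              nrow(x$windows), x$params$k, x$params$alpha))
  for (res in x$window_results) {
    if (is.null(res$query)) {
      cat(sprintf("  I%d: (no topic-annotated tweets)\n", res$window))
      next
    }
    top <- res$query
    cat(sprintf("  I%d: top topics %s | %d eligible users | clusters %s\n",
                res$window,
                paste(sprintf("%d(%.2f)", top$topic, top$score), collapse = " "),
                length(res$eligible),
                paste(sprintf("%s=%d", levels(res$clusters$cluster),
                              tabulate(res$clusters$cluster,
                                       nbins = 3)), collapse = " ")))
  }
  invisible(x)
}

#' @export
summary.trend_analysis <- function(object, ...) {
  ws <- object$window_results
  has_q <- !vapply(ws, function(r) is.null(r$query), logical(1))
  cluster_sizes <- sapply(ws[has_q], function(r)
    tabulate(r$clusters$cluster, nbins = 3))
  rownames(cluster_sizes) <- c("C_Neg", "C_Neu", "C_Pos")
  colnames(cluster_sizes) <- paste0("I", vapply(ws[has_q], `[[`, 0, "window"))
  entropy <- sapply(ws[has_q], function(r) r$entropy$per_cluster)
  colnames(entropy) <- colnames(cluster_sizes)
  dynamics <- do.call(rbind, lapply(ws[has_q], `[[`, "dynamics_row"))
  out <- list(cluster_sizes = cluster_sizes, entropy = entropy,
              dynamics = dynamics,
              queries = lapply(ws[has_q], `[[`, "query"))
  class(out) <- "summary.trend_analysis"
  out
}

#' @export
print.summary.trend_analysis <- function(x, ...) {
  cat("Sentiment cluster sizes per window:\n")
  print(x$cluster_sizes)
  cat("\nCluster entropy per window (bits):\n")
  print(round(x$entropy, 3))
  cat("\nQuery-topic sentiment dynamics (% of tweets):\n")
  dyn <- x$dynamics
  dyn[c("pos_pct", "neg_pct", "neu_pct")] <-
    lapply(dyn[c("pos_pct", "neg_pct", "neu_pct")], report_round)
  print(dyn, row.names = FALSE)
  invisible(x)
}
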