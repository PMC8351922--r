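#' Score sentiment for every tweet in a stream
#'
#' Adds `pos`, `neg`, `neu`, `compound` and `label` columns. By default the
#' scorer consumes the preprocessed token stream (`tokens` column pasted back
#' to text), matching the pipeline in which cleaned streams are passed to the
#' sentiment engine; set `text = "raw"` to score the raw tweet text instead,
#' which additionally exercises the capitalization, punctuation and emoticon
#' rules that preprocessing removes. Note that stopword removal also removes
#' negators ("not", "don't"), so negation scope is only active on raw text.
#'
#' @param stream a `tweet_stream`; must carry `tokens` unless `text = "raw"`.
#' @param text `"tokens"` (default) or `"raw"`.
#' @param lexicon valence lexicon, see [vader_scores()].
#' @param threshold classification cutoff, see [classify_sentiment()].
#' @param overwrite allow replacing existing sentiment annotations.
#' @return The stream with sentiment columns added.
#' @export
score_stream <- function(stream, text = c("tokens", "raw"),
                         lexicon = vader_lexicon(), threshold = 0.05,
                         overwrite = FALSE) {
  stopifnot(inherits(stream, "tweet_stream"))
  text <- match.arg(text)
  check_annotation(stream, "compound", overwrite)
  if (text == "tokens") {
    if (is.null(stream$tokens)) {
      stop("stream has no `tokens` column; run preprocess_stream() first or use text = \"raw\"")
    }
    input <- vapply(stream$tokens, paste, character(1), collapse = " ")
  } else {
    input <- stream$text
  }
  sc <- vader_scores(input, lexicon)
  stream$pos <- sc$pos
  stream$neg <- sc$neg
  stream$neu <- sc$neu
  stream$compound <- sc$compound
  stream$label <- classify_sentiment(sc$compound, threshold)
  stream
}

#' Aggregate user sentiment towards the query topics in a window
#'
#' For each eligible user, sums the compound scores of the user's tweets in
#' the window whose topic belongs to the query (off-query tweets are
#' excluded). The aggregate is an unweighted sum, so its magnitude can exceed
#' 1 for active users. Per-topic sums are returned alongside for topic-wise
#' clustering.
#'
#' @param wtweets window tweets (a scored, topic-annotated `tweet_stream`
#'   subset, e.g. from [tweets_in_window()]).
#' @param query a query object from [top_k_topics()] (or an integer vector of
#'   topic ids, ranked).
#' @param users optional character vector restricting to the eligible-user
#'   set; default is every user with at least one query-topic tweet in the
#'   window.
#' @return A data frame with columns `user_id`, `total`, and one
#'   `topic_<id>` column per query topic.
#' @export
aggregate_user_sentiment <- function(wtweets, query, users = NULL) {
  topics <- query_topics(query)
  if (is.null(wtweets$topic)) stop("tweets are not topic-annotated")
  if (is.null(wtweets$compound)) stop("tweets are not sentiment-scored")
  qt <- wtweets[wtweets$topic %in% topics, , drop = FALSE]
  if (is.null(users)) users <- unique(qt$user_id)
  qt <- qt[qt$user_id %in% users, , drop = FALSE]
  out <- data.frame(user_id = users, total = 0, stringsAsFactors = FALSE)
  for (tp in topics) out[[paste0("topic_", tp)]] <- 0
  if (nrow(qt) > 0) {
    tot <- tapply(qt$compound, qt$user_id, sum)
    out$total <- as.numeric(tot[match(users, names(tot))])
    out$total[is.na(out$total)] <- 0
    for (tp in topics) {
      sel <- qt[qt$topic == tp, , drop = FALSE]
      if (nrow(sel) > 0) {
        ts <- tapply(sel$compound, sel$user_id, sum)
        v <- as.numeric(ts[match(users, names(ts))])
        v[is.na(v)] <- 0
        out[[paste0("topic_", tp)]] <- v
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Per-window sentiment dynamics for a topic or query
#'
#' Percentages of positive / negative / neutral tweets among the topic's (or
#' query topics') tweets in every window. Windows where the topic does not
#' appear are dropped with a note in the `missing` attribute.
#'
#' @param stream scored, topic-annotated `tweet_stream`.
#' @param windows a [time_windows()] frame.
#' @param topic integer topic id(s) to restrict to; `NULL` means all
#'   topic-annotated tweets.
#' @return Data frame with columns `window`, `n`, `pos_pct`, `neg_pct`,
#'   `neu_pct` (exact percentages; round with [report_round()] for display).
#' @export
sentiment_dynamics <- function(stream, windows, topic = NULL) {
  stopifnot(inherits(stream, "tweet_stream"))
  if (is.null(stream$label)) stop("stream is not sentiment-scored")
  rows <- list()
  missing <- integer(0)
  for (i in seq_len(nrow(windows))) {
    wt <- tweets_in_window(stream, windows[i, ])
    if (!is.null(topic)) wt <- wt[!is.na(wt$topic) & wt$topic %in% topic, , drop = FALSE]
    n <- nrow(wt)
    if (n == 0) {
      missing <- c(missing, windows$index[i])
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      window = windows$index[i], n = n,
      pos_pct = 100 * sum(wt$label == "positive") / n,
      neg_pct = 100 * sum(wt$label == "negative") / n,
      neu_pct = 100 * sum(wt$label == "neutral") / n
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(window = integer(0), n = integer(0), pos_pct = numeric(0),
               neg_pct = numeric(0), neu_pct = numeric(0))
  if (length(missing)) {
    message("topic absent from window(s): ", paste(missing, collapse = ", "))
    attr(out, "missing") <- missing
  }
  out
}

#' Round-half-up to integer percentages for reports
#'
#' @param x numeric vector of percentages.
#' @return Integer vector, ties rounded away from zero (half-up policy).
#' @export
report_round <- function(x) {
  as.integer(floor(x + 0.5))
}
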