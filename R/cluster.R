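#' Partition users into sentiment clusters
#'
#' Users are assigned by their aggregate compound score: `C_Pos` when the
#' aggregate is at or above `threshold`, `C_Neg` at or below `-threshold`,
#' `C_Neu` otherwise. The three clusters are disjoint and exhaust the
#' eligible-user set. The same boundaries as tweet-level classification
#' (0.05) are reused so that a sizeable neutral cluster exists.
#'
#' @param aggregates data frame from [aggregate_user_sentiment()], or any
#'   data frame with `user_id` and a score column.
#' @param score name of the column holding the aggregate (default `"total"`;
#'   use a `topic_<id>` column for topic-wise clustering).
#' @param threshold positive boundary (mirrored for negative).
#' @return An object of class `sentiment_clusters`: data frame `user_id`,
#'   `score`, `cluster` (factor `C_Neg`/`C_Neu`/`C_Pos`).
#' @export
build_sentiment_clusters <- function(aggregates, score = "total",
                                     threshold = 0.05) {
  stopifnot(score %in% names(aggregates), threshold > 0)
  s <- aggregates[[score]]
  cl <- ifelse(s >= threshold, "C_Pos", ifelse(s <= -threshold, "C_Neg", "C_Neu"))
  out <- data.frame(user_id = aggregates$user_id, score = s,
                    cluster = factor(cl, levels = c("C_Neg", "C_Neu", "C_Pos")),
                    stringsAsFactors = FALSE)
  class(out) <- c("sentiment_clusters", "data.frame")
  out
}

#' @export
print.sentiment_clusters <- function(x, ...) {
  cat("Sentiment clusters:\n")
  print(table(x$cluster))
  invisible(x)
}

#' Main topic of activity of each user in a window
#'
#' The query topic on which the user posted the most tweets in the window;
#' ties go to the higher-ranked query topic. Users with no query-topic tweet
#' are excluded.
#'
#' @param wtweets topic-annotated window tweets.
#' @param query a [top_k_topics()] query (or ranked integer topic vector).
#' @return Named integer vector: user id -> topic id.
#' @export
user_main_topic <- function(wtweets, query) {
  kap <- kappa_counts(wtweets, query)
  topics <- query_topics(query)
  if (nrow(kap) == 0) return(setNames(integer(0), character(0)))
  # which.max on the kappa row returns the first (= highest-ranked) maximum
  idx <- apply(kap, 1, which.max)
  setNames(topics[idx], rownames(kap))
}

#' Weighted entropy of sentiment clusters
#'
#' Entropy of the main-topic distribution within each cluster,
#' \deqn{entropy(C_j) = -\sum_{i=1}^{n} p_{ij} \log_2 p_{ij}} with
#' \eqn{0 \log 0 := 0}, where \eqn{p_{ij}} is the fraction of cluster j's
#' users whose main topic is topic i and n is the number of query topics
#' (so each entropy lies in \eqn{[0, \log_2 n]}). The total is the
#' cluster-size-weighted sum \eqn{\sum_j |C_j|/|U| \cdot entropy(C_j)};
#' empty clusters contribute zero. Low entropy indicates topically pure
#' clusters.
#'
#' @param clusters a [build_sentiment_clusters()] partition.
#' @param main_topics named vector from [user_main_topic()]; users missing
#'   from it are ignored.
#' @param topics the n query topics defining the support of p (default: the
#'   topics present in `main_topics`).
#' @return List with `per_cluster` (named numeric), `weighted` (scalar), and
#'   `p` (n x clusters probability matrix).
#' @export
cluster_entropy <- function(clusters, main_topics, topics = NULL) {
  if (is.null(topics)) topics <- sort(unique(as.integer(main_topics)))
  n <- length(topics)
  cl_levels <- levels(clusters$cluster)
  p <- matrix(0, nrow = n, ncol = length(cl_levels),
              dimnames = list(paste0("topic_", topics), cl_levels))
  ent <- setNames(numeric(length(cl_levels)), cl_levels)
  sizes <- setNames(integer(length(cl_levels)), cl_levels)
  for (cl in cl_levels) {
    members <- clusters$user_id[clusters$cluster == cl]
    mt <- main_topics[names(main_topics) %in% members]
    sizes[cl] <- length(mt)
    if (length(mt) == 0) next # empty cluster: entropy 0, excluded from weight
    pr <- vapply(topics, function(t) mean(mt == t), numeric(1))
    p[, cl] <- pr
    nz <- pr[pr > 0]
    ent[cl] <- -sum(nz * log2(nz))
  }
  weighted <- if (sum(sizes) > 0) sum(sizes / sum(sizes) * ent) else 0
  list(per_cluster = ent, weighted = weighted, p = p, n_topics = n)
}

#' Semantic cohesion (expertness) of sentiment clusters
#'
#' For each non-empty cluster: the modal main topic of its members (ties to
#' the higher-ranked query topic) and the fraction rho of members sharing it,
#' \eqn{1/|C_j| \le \rho \le 1}. High rho marks a cluster dominated by one
#' topic's specialists.
#'
#' @param clusters a [build_sentiment_clusters()] partition.
#' @param main_topics named vector from [user_main_topic()].
#' @param query the query (used for rank-order tie-breaking); default: topic
#'   ids sorted ascending.
#' @return Data frame `cluster`, `size`, `modal_topic`, `rho`; empty clusters
#'   are reported with `NA` modal topic and rho.
#' @export
cluster_cohesion <- function(clusters, main_topics, query = NULL) {
  topics <- if (is.null(query)) sort(unique(as.integer(main_topics)))
            else query_topics(query)
  cl_levels <- levels(clusters$cluster)
  out <- data.frame(cluster = cl_levels, size = 0L,
                    modal_topic = NA_integer_, rho = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_along(cl_levels)) {
    members <- clusters$user_id[clusters$cluster == cl_levels[j]]
    mt <- main_topics[names(main_topics) %in% members]
    out$size[j] <- length(mt)
    if (length(mt) == 0) next
    counts <- vapply(topics, function(t) sum(mt == t), integer(1))
    best <- which.max(counts) # first maximum = higher-ranked query topic
    out$modal_topic[j] <- topics[best]
    out$rho[j] <- counts[best] / length(mt)
  }
  out
}
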