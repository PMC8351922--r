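# Shared fixtures and independent oracle implementations used across tests.
# Oracles are deliberately naive (enumeration / direct formula evaluation)
# and never call the code paths they check.

make_stream <- function(times, users = NULL, texts = NULL, topics = NULL,
                        origin = as.POSIXct("2020-03-23", tz = "UTC")) {
  n <- length(times)
  if (is.null(users)) users <- paste0("u", seq_len(n))
  if (is.null(texts)) texts <- paste("tweet", seq_len(n))
  st <- tweet_stream(paste0("id", seq_len(n)), users, origin + times, texts)
  if (!is.null(topics)) st$topic <- topics[match(st$tweet_id, paste0("id", seq_len(n)))]
  st
}

# entropy of a probability vector, directly from the definition
entropy_oracle <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

cosine <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))

# Greedy one-to-one matching of fitted topics to true topics by cosine of
# the topic-word distributions over the shared vocabulary; returns the
# per-true-topic matched cosines.
match_topics <- function(theta_hat, theta_true) {
  common <- intersect(colnames(theta_hat), colnames(theta_true))
  K <- nrow(theta_true)
  cs <- matrix(0, nrow(theta_hat), K)
  for (a in seq_len(nrow(theta_hat))) {
    for (b in seq_len(K)) {
      cs[a, b] <- cosine(theta_hat[a, common], theta_true[b, common])
    }
  }
  out <- numeric(K)
  for (i in seq_len(K)) {
    best <- which(cs == max(cs), arr.ind = TRUE)[1, ]
    out[best[2]] <- cs[best[1], best[2]]
    cs[best[1], ] <- -Inf
    cs[, best[2]] <- -Inf
  }
  out
}

# Collapsed joint density (up to a constant) of a Twitter-LDA state with all
# switches fixed at "topic word", evaluated by the Dirichlet-multinomial
# closed form. docs: list of 1-based word-id vectors; z: 1-based topics.
tlda_joint_oracle <- function(docs, users, z, K, V, alpha, beta) {
  U <- length(unique(users))
  uf <- match(users, sort(unique(users)))
  n_ut <- matrix(0, U, K)
  for (d in seq_along(docs)) n_ut[uf[d], z[d]] <- n_ut[uf[d], z[d]] + 1
  n_tw <- matrix(0, K, V)
  for (d in seq_along(docs)) {
    for (w in docs[[d]]) n_tw[z[d], w] <- n_tw[z[d], w] + 1
  }
  ll <- sum(lgamma(n_ut + alpha))
  for (t in seq_len(K)) {
    ll <- ll - lgamma(sum(n_tw[t, ]) + V * beta) + sum(lgamma(n_tw[t, ] + beta))
  }
  ll
}

# small convenience: a scored + topic-annotated synthetic stream
small_annotated_stream <- function(seed = 2, n_users = 40, tweets_per_user = 8) {
  sim <- generate_stream(stream_sim_config(
    seed = seed, n_users = n_users, tweets_per_user = tweets_per_user
  ))
  st <- preprocess_stream(sim$stream)
  st$topic <- sim$truth$tweets$z_true # use planted topics: no model noise
  st <- score_stream(st)
  list(stream = st, truth = sim$truth)
}
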