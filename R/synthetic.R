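#' Configuration for the synthetic stream generator
#'
#' Describes a ground-truth tweet stream: a planted topic vocabulary,
#' per-day-segment topic prevalences (the trend schedule), heterogeneous
#' (log-normal, heavy-tailed) user activity with one optional hyper-active
#' user, a background/topic word switch, and a sentiment plan injecting
#' real valence-lexicon words at controlled per-segment rates.
#'
#' Defaults emulate the study conditions exercised throughout the package:
#' 200 users with 20 tweets each over nine days (so the 3-day/1-day
#' overlapping windows give seven windows), three well-separated 50-word
#' topics (no vocabulary overlap), topic 1 dominant in days 1-4 and topic 2
#' in days 5-9, a 10x hyper-active first user, and a positive-tweet rate
#' ramping 0.2 to 0.6 across the span with a constant 0.2 negative rate.
#'
#' @param seed integer seed; the seed fully determines the stream.
#' @param n_users,tweets_per_user population size and mean activity.
#' @param n_topics,words_per_topic,topic_overlap topic vocabulary layout;
#'   `topic_overlap` is the fraction of each topic's words shared with the
#'   previous topic (the difficulty knob for recovery).
#' @param n_background_words,background_prob background vocabulary size and
#'   the probability that a word position is a background word.
#' @param doc_len_mean mean tokens per tweet (Poisson, minimum 1).
#' @param span_start UTC instant the stream starts.
#' @param n_segments,segment_len trend-schedule resolution (segments of
#'   `segment_len` starting at `span_start`).
#' @param schedule optional `n_topics` x `n_segments` prevalence matrix
#'   (columns sum to 1); `NULL` builds the default two-phase schedule.
#' @param activity_sdlog log-normal sd of user activity rates.
#' @param hyper_user plant user 1 as a hyper-active user?
#' @param hyper_factor activity multiplier of the hyper-active user.
#' @param p_pos,p_neg per-segment probabilities that a tweet gets positive /
#'   negative valence words appended (recycled to `n_segments`).
#' @param pos_pool,neg_pool valence-lexicon words used for injection; the
#'   defaults are drawn from the bundled lexicon so the rule-based scorer is
#'   exercised genuinely.
#' @return An object of class `stream_sim_config`.
#' @export
stream_sim_config <- function(seed = 1L,
                              n_users = 200L,
                              tweets_per_user = 20,
                              n_topics = 3L,
                              words_per_topic = 50L,
                              topic_overlap = 0,
                              n_background_words = 40L,
                              background_prob = 0.2,
                              doc_len_mean = 8,
                              span_start = as.POSIXct("2020-03-23", tz = "UTC"),
                              n_segments = 9L,
                              segment_len = "1d",
                              schedule = NULL,
                              activity_sdlog = 1,
                              hyper_user = TRUE,
                              hyper_factor = 10,
                              p_pos = seq(0.2, 0.6, length.out = n_segments),
                              p_neg = rep(0.2, n_segments),
                              pos_pool = c("good", "great", "happy", "hope",
                                           "safe", "love", "excellent", "win",
                                           "relief", "brave"),
                              neg_pool = c("bad", "sad", "fear", "panic",
                                           "crisis", "death", "sick", "worry",
                                           "terrible", "pain")) {
  stopifnot(n_users >= 1, tweets_per_user > 0, n_topics >= 1,
            words_per_topic >= 2, topic_overlap >= 0, topic_overlap < 1,
            background_prob >= 0, background_prob <= 1, n_segments >= 1)
  p_pos <- rep_len(p_pos, n_segments)
  p_neg <- rep_len(p_neg, n_segments)
  if (any(p_pos + p_neg > 1)) stop("p_pos + p_neg must be <= 1 per segment")
  if (is.null(schedule)) {
    schedule <- default_schedule(n_topics, n_segments)
  }
  schedule <- as.matrix(schedule)
  if (nrow(schedule) != n_topics || ncol(schedule) != n_segments) {
    stop("schedule must be n_topics x n_segments")
  }
  if (any(schedule < 0) || any(abs(colSums(schedule) - 1) > 1e-8)) {
    stop("schedule columns must be probability vectors")
  }
  structure(list(
    seed = as.integer(seed), n_users = as.integer(n_users),
    tweets_per_user = tweets_per_user, n_topics = as.integer(n_topics),
    words_per_topic = as.integer(words_per_topic),
    topic_overlap = topic_overlap,
    n_background_words = as.integer(n_background_words),
    background_prob = background_prob, doc_len_mean = doc_len_mean,
    span_start = span_start, n_segments = as.integer(n_segments),
    segment_len = parse_duration(segment_len), schedule = schedule,
    activity_sdlog = activity_sdlog, hyper_user = isTRUE(hyper_user),
    hyper_factor = hyper_factor, p_pos = p_pos, p_neg = p_neg,
    pos_pool = pos_pool, neg_pool = neg_pool
  ), class = "stream_sim_config")
}

# Two-phase trend schedule: topic 1 dominant in the first ceiling(4/9) of
# the span, topic 2 dominant afterwards, remaining mass spread evenly.
default_schedule <- function(n_topics, n_segments) {
  sched <- matrix(0, nrow = n_topics, ncol = n_segments)
  switchpoint <- ceiling(n_segments * 4 / 9)
  for (s in seq_len(n_segments)) {
    dom <- if (n_topics == 1) 1 else if (s <= switchpoint) 1 else 2
    if (n_topics == 1) {
      sched[1, s] <- 1
    } else {
      sched[, s] <- (1 - 0.7) / (n_topics - 1)
      sched[dom, s] <- 0.7
    }
  }
  sched
}

#' Generate a synthetic tweet stream with planted ground truth
#'
#' Draws a stream under the generative story of the topic model: each tweet
#' gets an author (activity-rate weighted), a uniform timestamp (its day
#' segment sets the topic prevalences), a true topic, and words mixed from
#' the topic and background distributions by the switch probability. Valence
#' words from the configured pools are appended according to the per-segment
#' sentiment plan, so the rule-based scorer is exercised on genuinely
#' sentiment-bearing text.
#'
#' @param cfg a [stream_sim_config()].
#' @return A list with `stream` (a [tweet_stream()]) and `truth`, where
#'   `truth` holds record-aligned per-tweet ground truth (`tweets`: true
#'   topic, segment, planted polarity), per-word switches `y_true`, the true
#'   distributions (`theta_true`, `theta_b_true`, `schedule`), user activity
#'   rates and the hyper-active user id.
#' @export
generate_stream <- function(cfg = stream_sim_config()) {
  stopifnot(inherits(cfg, "stream_sim_config"))
  set.seed(cfg$seed)
  K <- cfg$n_topics
  W <- cfg$words_per_topic

  # --- vocabulary and true distributions ---
  topic_words <- vector("list", K)
  topic_words[[1]] <- sprintf("t%02dw%02d", 1, seq_len(W))
  n_shared <- round(cfg$topic_overlap * W)
  for (t in seq_len(K)[-1]) {
    own <- sprintf("t%02dw%02d", t, seq_len(W - n_shared))
    shared <- if (n_shared > 0) utils::tail(topic_words[[t - 1]], n_shared) else character(0)
    topic_words[[t]] <- c(shared, own)
  }
  bg_words <- sprintf("bg%03d", seq_len(cfg$n_background_words))
  vocab <- unique(c(unlist(topic_words), bg_words))
  theta_true <- matrix(0, nrow = K, ncol = length(vocab),
                       dimnames = list(paste0("topic_", seq_len(K)), vocab))
  for (t in seq_len(K)) {
    w8 <- 1 / seq_len(W) # Zipf-like decreasing mass
    theta_true[t, topic_words[[t]]] <- w8 / sum(w8)
  }
  bw <- 1 / seq_len(cfg$n_background_words)
  theta_b_true <- setNames(numeric(length(vocab)), vocab)
  theta_b_true[bg_words] <- bw / sum(bw)

  # --- users ---
  user_ids <- sprintf("u%04d", seq_len(cfg$n_users))
  rates <- stats::rlnorm(cfg$n_users, meanlog = 0, sdlog = cfg$activity_sdlog)
  if (cfg$hyper_user) rates[1] <- max(rates) * cfg$hyper_factor
  n_tweets <- round(cfg$n_users * cfg$tweets_per_user)

  # --- tweets ---
  authors <- sample(user_ids, n_tweets, replace = TRUE, prob = rates)
  span_secs <- cfg$n_segments * cfg$segment_len
  offsets <- runif(n_tweets, 0, span_secs)
  timestamps <- cfg$span_start + offsets
  segments <- pmin(floor(offsets / cfg$segment_len) + 1L, cfg$n_segments)
  z_true <- integer(n_tweets)
  tokens <- vector("list", n_tweets)
  y_true <- vector("list", n_tweets)
  polarity <- character(n_tweets)
  for (i in seq_len(n_tweets)) {
    seg <- segments[i]
    z <- sample.int(K, 1, prob = cfg$schedule[, seg])
    z_true[i] <- z
    len <- max(1L, rpois(1, cfg$doc_len_mean))
    is_bg <- runif(len) < cfg$background_prob
    w <- character(len)
    if (any(is_bg)) w[is_bg] <- sample(bg_words, sum(is_bg), replace = TRUE,
                                       prob = theta_b_true[bg_words])
    if (any(!is_bg)) w[!is_bg] <- sample(topic_words[[z]], sum(!is_bg),
                                         replace = TRUE,
                                         prob = theta_true[z, topic_words[[z]]])
    u <- runif(1)
    pol <- if (u < cfg$p_pos[seg]) "positive"
           else if (u < cfg$p_pos[seg] + cfg$p_neg[seg]) "negative"
           else "neutral"
    extra <- character(0)
    if (pol == "positive") extra <- sample(cfg$pos_pool, sample(1:2, 1))
    if (pol == "negative") extra <- sample(cfg$neg_pool, sample(1:2, 1))
    tokens[[i]] <- c(w, extra)
    y_true[[i]] <- c(as.integer(!is_bg), rep(0L, length(extra)))
    polarity[i] <- pol
  }
  texts <- vapply(tokens, paste, character(1), collapse = " ")
  ids <- sprintf("tw%06d", seq_len(n_tweets))

  stream <- tweet_stream(ids, authors, timestamps, texts)
  ord <- match(stream$tweet_id, ids)
  truth <- list(
    tweets = data.frame(
      tweet_id = ids[ord], z_true = z_true[ord], segment = segments[ord],
      polarity = polarity[ord], stringsAsFactors = FALSE
    ),
    y_true = y_true[ord],
    theta_true = theta_true, theta_b_true = theta_b_true,
    schedule = cfg$schedule, topic_words = topic_words,
    user_rates = setNames(rates, user_ids),
    hyper_user = if (cfg$hyper_user) user_ids[1] else NA_character_,
    config = cfg
  )
  list(stream = stream, truth = truth)
}

#' Three-tweet worked-example stream
#'
#' A tiny fixture of three public-health tweets (economy, caregiving, and
#' industry-news themed) with synthetic ids and timestamps, used to
#' demonstrate and test the sentiment path end to end.
#'
#' @return A [tweet_stream()] of 3 tweets.
#' @export
worked_example_stream <- function() {
  texts <- c(
    paste("Emerging markets have limited power to tackle recession",
          "#economy #businessnews #coronavirus #emerging #emergingmarkets",
          "#healthcareindustry"),
    paste("My Mom’s a nurse and just tested positive for COVID-19.",
          "The caregiver is now the patient. Stay home for all the brave"),
    paste("Under Armour Manufacturing Face Masks For Hospital Workers Amid",
          "Coronavirus Pandemic #economy #armour #coronavir…",
          "https://t.co/J7Rkz8WMjw")
  )
  tweet_stream(
    tweet_id = c("s1", "s2", "s3"),
    user_id = c("uA", "uB", "uC"),
    timestamp = as.POSIXct("2020-03-23", tz = "UTC") + c(1, 2, 3) * 3600,
    text = texts
  )
}
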