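#' Fit a Twitter-style LDA topic model
#'
#' Fits the microblog topic model in which every tweet carries exactly one
#' latent topic z, drawn from its author's topic-interest distribution
#' \eqn{\Phi_u} (Dirichlet prior `alpha`), and every word position carries a
#' Bernoulli switch y (Beta prior `gamma`) choosing between the corpus-wide
#' background word distribution \eqn{\theta_B} (Dirichlet prior `lambda`)
#' and the tweet's topic word distribution \eqn{\theta_t} (Dirichlet prior
#' `beta`). The one-topic-per-tweet assumption reflects the shortness of
#' microblog posts; the background switch absorbs ubiquitous words that
#' carry no topical signal.
#'
#' Inference is collapsed Gibbs sampling: each sweep resamples every tweet's
#' topic from its exact full conditional (integrating out \eqn{\Phi},
#' \eqn{\theta}), then every word's switch. Point estimates are posterior
#' means averaged over the post-burn-in sweeps. The same seed yields
#' identical output.
#'
#' @param x a `tweet_stream` with a `tokens` column (see
#'   [preprocess_stream()]), or a list of character token vectors.
#' @param K number of topics (>= 1).
#' @param users character vector of authors, required when `x` is a plain
#'   token list; ignored for streams.
#' @param alpha Dirichlet prior on user-topic distributions; default `50/K`.
#' @param beta Dirichlet prior on topic-word distributions.
#' @param gamma Beta prior on the background/topic switch (the two-outcome
#'   Dirichlet).
#' @param lambda Dirichlet prior on the background word distribution.
#' @param iters total Gibbs sweeps; must exceed `burn_in`.
#' @param burn_in sweeps discarded before averaging.
#' @param min_count words occurring fewer than `min_count` times are pruned
#'   from the vocabulary (default 1 = keep all).
#' @param seed optional integer seed (applied with [set.seed()]).
#' @return An object of class `tlda` with components `phi` (user x topic),
#'   `theta` (topic x word), `theta_b` (background word distribution), `pi`
#'   (probability a word is a topic word), `z_counts` (tweet x topic
#'   post-burn-in sample counts), `loglik` (collapsed joint log-density
#'   trace), `vocab`, `users`, `doc_ids`, `dropped` (indices of documents
#'   with no usable token, never sampled), and the hyperparameters.
#' @seealso [assign_topics()], [topic_terms()], and the methods
#'   [print.tlda()], [summary.tlda()], [coef.tlda()], [logLik.tlda()],
#'   [predict.tlda()], [simulate.tlda()], [plot.tlda()].
#' @export
tlda <- function(x, K, users = NULL, alpha = 50 / K, beta = 0.01, gamma = 20,
                 lambda = 0.01, iters = 500, burn_in = 200, min_count = 1,
                 seed = NULL) {
  if (!is.numeric(K) || length(K) != 1 || K < 1) stop("K must be >= 1")
  K <- as.integer(K)
  if (iters <= burn_in) stop("iters must exceed burn_in")
  stopifnot(alpha > 0, beta > 0, gamma > 0, lambda > 0)
  if (inherits(x, "tweet_stream")) {
    if (is.null(x$tokens)) stop("stream has no `tokens`; run preprocess_stream() first")
    tokens <- x$tokens
    users <- x$user_id
    doc_ids <- x$tweet_id
  } else if (is.list(x)) {
    tokens <- x
    if (is.null(users) || length(users) != length(tokens)) {
      stop("`users` must be given (one author per document) for token-list input")
    }
    users <- as.character(users)
    doc_ids <- as.character(seq_along(tokens))
  } else {
    stop("`x` must be a tweet_stream or a list of token vectors")
  }
  if (length(tokens) == 0) stop("empty corpus")

  all_words <- unlist(tokens, use.names = FALSE)
  if (length(all_words) == 0) stop("corpus has no tokens")
  wc <- table(all_words)
  vocab <- sort(names(wc)[wc >= min_count])
  if (length(vocab) == 0) stop("vocabulary empty after min_count pruning")
  docs <- lapply(tokens, function(tok) {
    ids <- match(tok, vocab)
    as.integer(ids[!is.na(ids)] - 1L)
  })
  keep <- lengths(docs) > 0
  dropped <- which(!keep)
  if (length(dropped) > 0) {
    warning(sprintf("%d document(s) with no usable token were not sampled",
                    length(dropped)))
  }
  docs_fit <- docs[keep]
  if (length(docs_fit) == 0) stop("no document has a usable token")
  user_levels <- sort(unique(users[keep]))
  doc_user <- as.integer(match(users[keep], user_levels) - 1L)

  if (!is.null(seed)) set.seed(seed)
  res <- .tlda_gibbs(docs_fit, doc_user, length(user_levels), length(vocab),
                     K, alpha, beta, gamma, lambda, as.integer(iters),
                     as.integer(burn_in))

  z_counts <- matrix(0L, nrow = length(tokens), ncol = K)
  z_counts[keep, ] <- res$z_counts
  phi <- res$phi
  dimnames(phi) <- list(user_levels, paste0("topic_", seq_len(K)))
  theta <- res$theta
  dimnames(theta) <- list(paste0("topic_", seq_len(K)), vocab)
  theta_b <- setNames(as.numeric(res$theta_b), vocab)

  structure(list(
    K = K, vocab = vocab, phi = phi, theta = theta, theta_b = theta_b,
    pi = res$pi, z_counts = z_counts, loglik = as.numeric(res$loglik),
    users = users, user_levels = user_levels, doc_ids = doc_ids,
    dropped = dropped, n_samples = res$n_samples,
    hyper = list(alpha = alpha, beta = beta, gamma = gamma, lambda = lambda),
    iters = iters, burn_in = burn_in, seed = seed, call = match.call()
  ), class = "tlda")
}

#' @export
print.tlda <- function(x, ...) {
  cat(sprintf(
    "Twitter-LDA model: %d topics, %d documents (%d dropped), %d users, vocabulary %d\n",
    x$K, length(x$doc_ids), length(x$dropped), length(x$user_levels),
    length(x$vocab)
  ))
  cat(sprintf("  Gibbs sweeps: %d (burn-in %d, %d samples averaged)\n",
              x$iters, x$burn_in, x$n_samples))
  cat(sprintf("  P(topic word) = %.3f; final joint log-density %.1f\n",
              x$pi, x$loglik[length(x$loglik)]))
  invisible(x)
}

#' @export
summary.tlda <- function(object, n = 8, ...) {
  out <- list(model = object, top_words = topic_terms(object, n))
  class(out) <- "summary.tlda"
  out
}

#' @export
print.summary.tlda <- function(x, ...) {
  print(x$model)
  cat("\nTop words per topic:\n")
  print(x$top_words, quote = FALSE)
  invisible(x)
}

#' @describeIn tlda topic-word probability matrix \eqn{\hat\theta}.
#' @param object,... method arguments.
#' @export
coef.tlda <- function(object, ...) object$theta

#' @export
logLik.tlda <- function(object, ...) {
  val <- object$loglik[length(object$loglik)]
  structure(val,
            df = object$K * (length(object$vocab) - 1) +
              length(object$user_levels) * (object$K - 1) +
              length(object$vocab) - 1 + 1,
            class = "logLik")
}

#' @export
plot.tlda <- function(x, ...) {
  plot(seq_along(x$loglik), x$loglik, type = "l",
       xlab = "Gibbs sweep", ylab = "collapsed joint log-density",
       main = "Sampler trace", ...)
  graphics::abline(v = x$burn_in, lty = 2)
  invisible(x)
}

#' Posterior-mode topic for every tweet
#'
#' Each tweet's topic is the most frequent sampled topic across the
#' post-burn-in sweeps; ties break to the lowest topic index. Documents that
#' had no usable token get `NA`.
#'
#' @param fit a [tlda()] model.
#' @param stream optional `tweet_stream` (the one the model was fitted on) to
#'   annotate; with `stream = NULL` the integer topic vector is returned.
#' @param overwrite allow replacing an existing `topic` annotation.
#' @return Integer topic vector, or the annotated stream.
#' @export
assign_topics <- function(fit, stream = NULL, overwrite = FALSE) {
  stopifnot(inherits(fit, "tlda"))
  z <- apply(fit$z_counts, 1, which.max) # first max = lowest topic on ties
  z[rowSums(fit$z_counts) == 0] <- NA_integer_
  z <- as.integer(z)
  if (is.null(stream)) return(z)
  stopifnot(inherits(stream, "tweet_stream"))
  check_annotation(stream, "topic", overwrite)
  if (nrow(stream) != length(z)) stop("stream does not match the fitted corpus")
  idx <- match(stream$tweet_id, fit$doc_ids)
  if (anyNA(idx)) stop("stream tweet ids do not match the fitted corpus")
  stream$topic <- z[idx]
  stream
}

#' Top words of each topic
#'
#' The `n` highest-probability words of every topic word distribution, ties
#' broken lexicographically. When `n` exceeds the vocabulary the full
#' ranking is returned.
#'
#' @param fit a [tlda()] model.
#' @param n words per topic.
#' @return Character matrix, `n` rows x `K` topic columns (a Table-1-style
#'   layout when printed).
#' @export
topic_terms <- function(fit, n = 10) {
  stopifnot(inherits(fit, "tlda"), n >= 1)
  n <- min(n, length(fit$vocab))
  out <- sapply(seq_len(fit$K), function(t) {
    ord <- order(-fit$theta[t, ], fit$vocab)
    fit$vocab[ord[seq_len(n)]]
  })
  out <- matrix(out, nrow = n, dimnames = list(NULL, paste0("topic_", seq_len(fit$K))))
  out
}

#' Predict topics for new tokenized documents
#'
#' Maximum a posteriori topic under the fitted point estimates: for a
#' document by user u with tokens w, scores each topic t by
#' \eqn{\log \hat\Phi_{u,t} + \sum_w \log(\hat\pi \hat\theta_{t,w} +
#' (1-\hat\pi)\hat\theta_{B,w})}, marginalizing the background switch.
#' Unknown users fall back to the average user profile; unknown words are
#' skipped.
#'
#' @param object a [tlda()] model.
#' @param newdata list of character token vectors.
#' @param users optional character vector of authors.
#' @param ... unused.
#' @return Integer vector of topic ids (`NA` for documents with no known
#'   token).
#' @export
predict.tlda <- function(object, newdata, users = NULL, ...) {
  stopifnot(is.list(newdata))
  mean_phi <- colMeans(object$phi)
  vapply(seq_along(newdata), function(i) {
    ids <- match(newdata[[i]], object$vocab)
    ids <- ids[!is.na(ids)]
    if (length(ids) == 0) return(NA_integer_)
    phi_u <- if (!is.null(users) && users[i] %in% rownames(object$phi)) {
      object$phi[users[i], ]
    } else mean_phi
    scores <- vapply(seq_len(object$K), function(t) {
      log(phi_u[t]) + sum(log(object$pi * object$theta[t, ids] +
                                (1 - object$pi) * object$theta_b[ids]))
    }, numeric(1))
    which.max(scores)
  }, integer(1))
}

#' Simulate a corpus from a fitted model
#'
#' Posterior-predictive style draw: for each requested document, an author
#' is picked uniformly, a topic from \eqn{\hat\Phi_u}, and each word from the
#' background distribution with probability \eqn{1-\hat\pi} or the topic
#' distribution otherwise.
#'
#' @param object a [tlda()] model.
#' @param nsim number of documents.
#' @param seed optional seed.
#' @param doc_len mean document length (Poisson, minimum 1).
#' @param ... unused.
#' @return List with `tokens`, `users`, `z`.
#' @export
simulate.tlda <- function(object, nsim = 100, seed = NULL, doc_len = 8, ...) {
  if (!is.null(seed)) set.seed(seed)
  users <- sample(object$user_levels, nsim, replace = TRUE)
  z <- integer(nsim)
  tokens <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    z[i] <- sample.int(object$K, 1, prob = object$phi[users[i], ])
    len <- max(1, rpois(1, doc_len))
    bg <- runif(len) > object$pi
    w <- integer(len)
    if (any(bg)) w[bg] <- sample.int(length(object$vocab), sum(bg),
                                     replace = TRUE, prob = object$theta_b)
    if (any(!bg)) w[!bg] <- sample.int(length(object$vocab), sum(!bg),
                                       replace = TRUE, prob = object$theta[z[i], ])
    tokens[[i]] <- object$vocab[w]
  }
  list(tokens = tokens, users = users, z = z)
}
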