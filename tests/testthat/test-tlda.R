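test_that("sampler conditionals match brute-force collapsed-posterior enumeration", {
  # 2 documents, 2 topics, vocabulary of 3, all switches at "topic word":
  # enumerate the collapsed joint over all (z1, z2) states with the
  # Dirichlet-multinomial closed form and compare the implied conditionals
  # with the sampler's own conditional routine. Repeated words in doc 1
  # exercise the within-document incremental counts.
  docs <- list(c(1L, 1L, 2L), c(2L, 3L))
  users <- c("uA", "uB")
  y <- lapply(docs, function(d) rep(1L, length(d)))
  alpha <- 0.7; beta <- 0.3; K <- 2L; V <- 3L
  for (z_other in 1:2) {
    joint <- vapply(1:2, function(z1)
      tlda_joint_oracle(docs, users, c(z1, z_other), K, V, alpha, beta),
      numeric(1))
    oracle <- exp(joint - max(joint)) / sum(exp(joint - max(joint)))
    cond <- trendsent:::.tlda_z_conditional(
      lapply(docs, function(d) d - 1L), c(0L, 1L),
      z = c(1L, z_other), y_ = y, U = 2L, V = V, K = K,
      alpha = alpha, beta = beta, d = 1L
    )
    expect_equal(as.numeric(cond), oracle, tolerance = 1e-12)
  }
  # same-author documents couple through the user-topic counts
  joint <- vapply(1:2, function(z1)
    tlda_joint_oracle(docs, c("uA", "uA"), c(z1, 2L), K, V, alpha, beta),
    numeric(1))
  oracle <- exp(joint - max(joint)) / sum(exp(joint - max(joint)))
  cond <- trendsent:::.tlda_z_conditional(
    lapply(docs, function(d) d - 1L), c(0L, 0L),
    z = c(1L, 2L), y_ = y, U = 1L, V = V, K = K,
    alpha = alpha, beta = beta, d = 1L
  )
  expect_equal(as.numeric(cond), oracle, tolerance = 1e-12)
})

test_that("a single-topic model assigns every tweet to topic 1 and mixes to corpus frequencies", {
  sim <- generate_stream(stream_sim_config(seed = 5, n_users = 30,
                                           tweets_per_user = 6, n_topics = 1,
                                           p_pos = 0, p_neg = 0))
  st <- preprocess_stream(sim$stream)
  fit <- tlda(st, K = 1, iters = 60, burn_in = 20, seed = 2)
  expect_true(all(assign_topics(fit) == 1L))
  # topic + background mixture reproduces smoothed corpus word frequencies
  emp <- table(factor(unlist(st$tokens), levels = fit$vocab))
  emp <- as.numeric(emp) / sum(emp)
  mix <- fit$pi * fit$theta[1, ] + (1 - fit$pi) * fit$theta_b
  expect_lt(max(abs(as.numeric(mix) - emp)), 0.01)
})

test_that("the seed fully determines the fit", {
  sim <- generate_stream(stream_sim_config(seed = 6, n_users = 20,
                                           tweets_per_user = 5))
  st <- preprocess_stream(sim$stream)
  f1 <- tlda(st, K = 3, iters = 40, burn_in = 10, seed = 123)
  f2 <- tlda(st, K = 3, iters = 40, burn_in = 10, seed = 123)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$z_counts, f2$z_counts)
  f3 <- tlda(st, K = 3, iters = 40, burn_in = 10, seed = 321)
  expect_false(identical(f1$z_counts, f3$z_counts))
})

test_that("configuration errors are caught before sampling", {
  st <- preprocess_stream(worked_example_stream())
  expect_error(tlda(st, K = 0), "K")
  expect_error(tlda(st, K = 2, iters = 10, burn_in = 10), "exceed")
  expect_error(tlda(list(), K = 2, users = character(0)), "empty")
  expect_error(tlda(worked_example_stream(), K = 2), "tokens")
})

test_that("topic assignment breaks sample-count ties toward the lower index", {
  fake <- structure(list(
    K = 6L, z_counts = rbind(c(0L, 0L, 5L, 0L, 0L, 5L),
                             c(9L, 1L, 0L, 0L, 0L, 0L),
                             c(0L, 0L, 0L, 0L, 0L, 0L))
  ), class = "tlda")
  z <- assign_topics(fake)
  expect_equal(z[1], 3L)        # tie between topics 3 and 6 -> 3
  expect_equal(z[2], 1L)
  expect_true(is.na(z[3]))      # never-sampled document
})

test_that("topic_terms ranks by probability with lexicographic ties", {
  fake <- structure(list(
    K = 2L, vocab = c("apple", "hospital", "zebra"),
    theta = rbind(c(0.25, 0.5, 0.25), c(1 / 3, 1 / 3, 1 / 3))
  ), class = "tlda")
  dimnames(fake$theta) <- list(NULL, fake$vocab)
  tt <- topic_terms(fake, 2)
  expect_equal(tt[, 1], c("hospital", "apple"))  # max mass first
  expect_equal(unname(tt[1, 2]), "apple")        # uniform: lexicographic
  expect_equal(nrow(topic_terms(fake, 99)), 3)   # n > vocabulary
})

test_that("log density trends upward during burn-in on separable data", {
  sim <- generate_stream(stream_sim_config(seed = 9, n_users = 40,
                                           tweets_per_user = 8))
  st <- preprocess_stream(sim$stream)
  fit <- tlda(st, K = 3, iters = 80, burn_in = 40, seed = 7)
  ll <- fit$loglik
  expect_gt(mean(ll[60:80]), mean(ll[1:10]))
})

test_that("prediction recovers the planted topic of specialist documents", {
  sim <- generate_stream(stream_sim_config(seed = 10, n_users = 60,
                                           tweets_per_user = 10,
                                           p_pos = 0, p_neg = 0))
  st <- preprocess_stream(sim$stream)
  fit <- tlda(st, K = 3, iters = 120, burn_in = 60, seed = 3)
  # map model topics to true topics, then check pure-vocabulary documents
  matched <- match_topics(fit$theta, sim$truth$theta_true)
  expect_true(all(matched >= 0.9))
  newdocs <- lapply(1:3, function(t) sim$truth$topic_words[[t]][1:6])
  pred <- predict(fit, newdocs)
  expect_true(all(vapply(1:3, function(t) {
    idx <- sim$truth$tweets$z_true == t
    modal <- as.integer(names(which.max(table(assign_topics(fit)[idx]))))
    pred[t] == modal
  }, logical(1))))
})

test_that("simulate draws documents from the fitted vocabulary", {
  sim <- generate_stream(stream_sim_config(seed = 12, n_users = 15,
                                           tweets_per_user = 4))
  fit <- tlda(preprocess_stream(sim$stream), K = 2, iters = 30, burn_in = 10,
              seed = 1)
  out <- simulate(fit, nsim = 20, seed = 2)
  expect_length(out$tokens, 20)
  expect_true(all(unlist(out$tokens) %in% fit$vocab))
  expect_true(all(out$z %in% 1:2))
})
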