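test_that("threshold assignment partitions the eligible users", {
  agg <- data.frame(user_id = c("a", "b", "c"), total = c(0.3, -0.3, 0.0))
  cl <- build_sentiment_clusters(agg)
  expect_equal(as.character(cl$cluster), c("C_Pos", "C_Neg", "C_Neu"))
  # boundaries are inclusive, mirroring tweet-level classification
  agg2 <- data.frame(user_id = c("p", "n", "z"), total = c(0.05, -0.05, 0.049))
  cl2 <- build_sentiment_clusters(agg2)
  expect_equal(as.character(cl2$cluster), c("C_Pos", "C_Neg", "C_Neu"))
  expect_equal(sum(table(cl2$cluster)), nrow(agg2))
})

test_that("main topic is the kappa argmax with rank-order ties", {
  st <- make_stream(1:6, users = c("a", "a", "a", "a", "b", "b"),
                    topics = c(3L, 3L, 3L, 8L, 3L, 8L))
  mt <- user_main_topic(st, query = c(3L, 8L))
  expect_equal(unname(mt["a"]), 3L)   # 3 vs 1 tweets
  expect_equal(unname(mt["b"]), 3L)   # 1-1 tie: higher-ranked query topic
  mt2 <- user_main_topic(st, query = c(8L, 3L))
  expect_equal(unname(mt2["b"]), 8L)  # rank order decides the tie
})

test_that("cluster entropy evaluates the definition exactly", {
  # one cluster, all users on one topic -> 0 bits
  cl <- build_sentiment_clusters(
    data.frame(user_id = paste0("u", 1:4), total = rep(1, 4)))
  mt <- setNames(rep(1L, 4), paste0("u", 1:4))
  ent <- cluster_entropy(cl, mt, topics = 1:2)
  expect_equal(unname(ent$per_cluster["C_Pos"]), 0)
  # 50/50 split over two topics -> exactly 1 bit
  mt2 <- setNames(c(1L, 1L, 2L, 2L), paste0("u", 1:4))
  ent2 <- cluster_entropy(cl, mt2, topics = 1:2)
  expect_equal(unname(ent2$per_cluster["C_Pos"]), 1)
  # p = (1/2, 1/4, 1/4) -> 1.5 bits
  mt3 <- setNames(c(1L, 1L, 2L, 3L), paste0("u", 1:4))
  ent3 <- cluster_entropy(cl, mt3, topics = 1:3)
  expect_equal(unname(ent3$per_cluster["C_Pos"]), 1.5)
  # weighted total for a single non-empty cluster equals its entropy
  expect_equal(ent3$weighted, 1.5)
})

test_that("entropy and cohesion match brute-force recomputation on random tables", {
  set.seed(5)
  for (i in 1:100) {
    n_users <- sample(3:30, 1)
    k <- sample(2:4, 1)
    users <- paste0("u", seq_len(n_users))
    agg <- data.frame(user_id = users,
                      total = round(runif(n_users, -1, 1), 2))
    cl <- build_sentiment_clusters(agg)
    mt <- setNames(sample.int(k, n_users, replace = TRUE), users)
    ent <- cluster_entropy(cl, mt, topics = seq_len(k))
    coh <- cluster_cohesion(cl, mt, query = seq_len(k))
    exp_w <- 0
    for (lvl in levels(cl$cluster)) {
      members <- cl$user_id[cl$cluster == lvl]
      if (length(members) == 0) {
        expect_equal(unname(ent$per_cluster[lvl]), 0)
        expect_true(is.na(coh$rho[coh$cluster == lvl]))
        next
      }
      tab <- table(factor(mt[members], levels = seq_len(k)))
      p <- as.numeric(tab) / length(members)
      expect_equal(unname(ent$per_cluster[lvl]), entropy_oracle(p))
      exp_w <- exp_w + length(members) / n_users * entropy_oracle(p)
      # cohesion: modal-topic share, first maximum on ties
      rho <- coh$rho[coh$cluster == lvl]
      expect_equal(rho, max(tab) / length(members))
      expect_true(rho > 0 && rho <= 1)
      expect_gte(rho, 1 / length(members))
      # bounds on entropy
      expect_gte(unname(ent$per_cluster[lvl]), 0)
      expect_lte(unname(ent$per_cluster[lvl]), log2(k) + 1e-12)
    }
    expect_equal(ent$weighted, exp_w)
  }
})

test_that("cohesion hand cases: modal share, singleton, purity", {
  cl <- build_sentiment_clusters(
    data.frame(user_id = paste0("u", 1:4), total = rep(0.5, 4)))
  mt <- setNames(c(1L, 1L, 1L, 2L), paste0("u", 1:4))
  coh <- cluster_cohesion(cl, mt, query = c(1L, 2L))
  expect_equal(coh$rho[coh$cluster == "C_Pos"], 0.75)
  expect_equal(coh$modal_topic[coh$cluster == "C_Pos"], 1L)
  # singleton cluster
  cl1 <- build_sentiment_clusters(data.frame(user_id = "x", total = -1))
  expect_equal(cluster_cohesion(cl1, setNames(2L, "x"))$rho[1], 1)
  # all users sharing the main topic is maximal expertness
  mt_pure <- setNames(rep(2L, 4), paste0("u", 1:4))
  coh_pure <- cluster_cohesion(cl, mt_pure, query = c(1L, 2L))
  expect_equal(coh_pure$rho[coh_pure$cluster == "C_Pos"], 1)
  ent_pure <- cluster_entropy(cl, mt_pure, topics = 1:2)
  expect_equal(ent_pure$weighted, 0)
})

test_that("raising the specialist fraction raises cohesion and lowers entropy", {
  set.seed(6)
  make_case <- function(spec_frac) {
    n <- 300
    users <- paste0("u", seq_len(n))
    spec <- runif(n) < spec_frac
    mt <- ifelse(spec, 1L, sample.int(3, n, replace = TRUE))
    cl <- build_sentiment_clusters(
      data.frame(user_id = users, total = runif(n, -1, 1)))
    list(ent = cluster_entropy(cl, setNames(mt, users), topics = 1:3),
         coh = cluster_cohesion(cl, setNames(mt, users), query = 1:3))
  }
  lo <- make_case(0.1)
  hi <- make_case(0.9)
  expect_lt(hi$ent$weighted, lo$ent$weighted)
  expect_gt(mean(hi$coh$rho, na.rm = TRUE), mean(lo$coh$rho, na.rm = TRUE))
})
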