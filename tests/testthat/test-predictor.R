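# Predictor: neighbor index with first co-occurrence times, attention
# queries/keys/values, multi-head cross-attention (against a hand-rolled
# oracle), predictive embeddings, pair scoring, and the analytic gradients of
# the full scoring path against numerical differentiation.

test_that("neighbor index keeps first co-occurrence times symmetrically", {
  idx <- new_neighbor_index(4)
  expect_true(all(lengths(idx$nbr) == 0))
  idx <- update_neighbor_index(idx, data.frame(t = 1L, i = 1L, j = 2L))
  idx <- update_neighbor_index(idx, data.frame(t = 2L, i = 1L, j = 2L))
  expect_equal(idx$ft[[1]][match(2, idx$nbr[[1]])], 1L)   # first time kept
  idx <- update_neighbor_index(idx, data.frame(t = 2L, i = 2L, j = 3L))
  expect_equal(idx$ft[[3]][match(2, idx$nbr[[3]])], 2L)   # symmetric entry
  expect_equal(idx$ft[[2]][match(3, idx$nbr[[2]])], 2L)
})

test_that("queries and keys/values follow the state||encoding layout", {
  emb <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2, byrow = TRUE)
  st <- init_states(emb, d = 2)
  enc <- time_encoder(3, omega = c(1, 0, 0), phase = rep(0, 3))
  q <- build_query(st, enc, 1, t = 2)
  expect_equal(q, c(1, 2, 2, 1, 1))
  expect_length(q, 2 + 3)
  expect_identical(q, build_query(st, enc, 1, t = 2))

  idx <- new_neighbor_index(3)
  idx <- update_neighbor_index(idx, data.frame(t = 1L, i = 1L, j = 2L))
  idx <- update_neighbor_index(idx, data.frame(t = 4L, i = 1L, j = 3L))
  kv <- build_keys_values(st, enc, idx, 1, t = 5)
  expect_equal(dim(kv), c(2, 5))
  expect_equal(kv[1, ], c(3, 4, 1, 1, 1))    # neighbor 2, phi(1)
  expect_equal(kv[2, ], c(5, 6, 4, 1, 1))    # neighbor 3, phi(4)
  expect_equal(nrow(build_keys_values(st, enc, idx, 2, t = 5)), 1)
  # no neighbors -> empty matrix
  expect_equal(nrow(build_keys_values(st, enc, new_neighbor_index(3), 1, 5)), 0)
})

test_that("the neighbor cap keeps the latest first co-occurrences", {
  idx <- new_neighbor_index(7)
  for (k in 2:6) {
    idx <- update_neighbor_index(idx, data.frame(t = k - 1L, i = 1L, j = k))
  }
  nb <- conceptdrift:::get_neighbors(idx, 1, cap = 3)
  expect_setequal(nb$nbr, c(4L, 5L, 6L))
  expect_setequal(nb$ft, c(3L, 4L, 5L))
  full <- conceptdrift:::get_neighbors(idx, 1, cap = Inf)
  expect_length(full$nbr, 5)
})

test_that("cross_attention reduces to the forced closed forms", {
  p <- 4L
  id_block <- new_attention_block(p, p, heads = 1L, seed = 1)
  id_block$Wq <- id_block$Wk <- id_block$Wv <- id_block$Wo <- diag(p)
  v1 <- c(1, 2, 3, 4)
  # single neighbor: softmax over one key is 1, identity projections
  expect_equal(cross_attention(id_block, rnorm(p), matrix(v1, 1)), v1)
  # two identical keys, distinct values: uniform weights
  v2 <- c(4, 3, 2, 1)
  kv <- rbind(v1, v2)
  blk <- id_block
  blk$Wk <- matrix(0, p, p)    # all keys project to zero -> uniform softmax
  expect_equal(cross_attention(blk, rnorm(p), kv), 0.5 * (v1 + v2))
  # empty neighborhood yields the zero vector
  expect_equal(cross_attention(id_block, rnorm(p), matrix(0, 0, p)),
               rep(0, p))
})

test_that("cross_attention matches a hand-rolled oracle and its invariants", {
  set.seed(11)
  for (rep in 1:5) {
    p <- sample(2:5, 1)
    A <- 2 * sample(1:3, 1)
    H <- sample(c(1L, 2L), 1)
    blk <- new_attention_block(p, A, heads = H, seed = rep)
    q <- rnorm(p)
    kv <- matrix(rnorm(3 * p), 3, p)
    got <- cross_attention(blk, q, kv, weights = TRUE)
    ref <- oracle_attention(q, kv, blk$Wq, blk$Wk, blk$Wv, blk$Wo, H)
    expect_equal(as.numeric(got), ref, tolerance = 1e-6)
    # weights normalize per head
    expect_equal(rowSums(attr(got, "weights")), rep(1, H))
    # permutation invariance of the neighbor list
    perm <- sample(nrow(kv))
    expect_equal(as.numeric(cross_attention(blk, q, kv[perm, ])),
                 as.numeric(got), tolerance = 1e-12)
  }
})

test_that("predictive embeddings and scores follow their closed forms", {
  emb <- matrix(rnorm(6), 3, 2)
  st <- init_states(emb, d = 2)
  set.seed(2)
  fuse <- conceptdrift:::new_mlp2(2 + 3, 4, 4)
  zf <- lapply(fuse, function(p) p * 0)
  z0 <- predictive_embedding(zf, st, 1, 3, h = rnorm(3))
  expect_equal(z0$vector, rep(0, 4))
  z1 <- predictive_embedding(fuse, st, 1, 3, h = c(1, 2, 3))
  expect_length(z1$vector, 4)
  expect_identical(z1$vector,
                   predictive_embedding(fuse, st, 1, 3, c(1, 2, 3))$vector)

  # zero-parameter head scores 0.5 for any pair
  head0 <- lapply(conceptdrift:::new_mlp2(4, 3, 1), function(p) p * 0)
  expect_equal(score_pair(head0, z1, z0), 0.5)
  # exact symmetry
  set.seed(3)
  head <- conceptdrift:::new_mlp2(4, 3, 1)
  expect_identical(score_pair(head, z1, z0), score_pair(head, z0, z1))
  # hand-computed closed form: identity hidden layer on positive sums
  zi <- structure(list(vector = c(0.2, 0.7), concept = 1L, t = 2L),
                  class = "predictive_embedding")
  zj <- structure(list(vector = c(0.4, 0.1), concept = 2L, t = 2L),
                  class = "predictive_embedding")
  w <- c(0.3, -0.9); b <- 0.2
  head1 <- list(W1 = diag(2), b1 = c(0, 0), W2 = matrix(w), b2 = b)
  expect_equal(score_pair(head1, zi, zj),
               stats::plogis(sum(w * (zi$vector + zj$vector)) + b))
  # step mismatch is fatal
  zk <- structure(list(vector = c(1, 1), concept = 3L, t = 5L),
                  class = "predictive_embedding")
  expect_error(score_pair(head1, zi, zk), "different steps")
})

test_that("analytic gradients of the scoring path match finite differences", {
  sim <- generate_dynamic_graph(small_drift_config(6))
  emb <- generate_embeddings(sim)
  g <- sim$graph
  cfg <- conceptdrift:::resolve_config(
    model_config(state_dim = 6L, time_dim = 3L, attn_dim = 4L, heads = 2L,
                 dz = 4L, score_hidden = 3L, neighbor_cap = 4, seed = 8),
    ncol(emb), g$horizon
  )
  cfg$state_dim <- 6L
  model <- new_model(cfg)
  store <- init_states(emb, d = 6L, seed = 8)
  index <- new_neighbor_index(nrow(emb))
  for (t in 1:3) {
    ev <- events_at(g, t)
    store <- apply_graphlet(store, conceptdrift:::gru_of(model), model$enc,
                            ev, t)
    index <- update_neighbor_index(index, ev)
  }
  pairs <- pair_samples(c(1L, 2L, 5L, 7L), c(3L, 4L, 6L, 8L), 4L,
                        c(1L, 0L, 1L, 0L))
  loss_fn <- function(m) {
    fw <- conceptdrift:::forward_pairs(m, store, index, pairs, 4L)
    conceptdrift:::bce_loss(fw$prob, pairs$label)
  }
  fw <- conceptdrift:::forward_pairs(model, store, index, pairs, 4L)
  grads <- conceptdrift:::backward_pairs(
    model, fw, (fw$prob - pairs$label) / nrow(pairs)
  )
  eps <- 1e-6
  set.seed(99)
  for (grp in names(model$params)) {
    for (nm in names(model$params[[grp]])) {
      P <- model$params[[grp]][[nm]]
      for (k in sample(length(P), min(3, length(P)))) {
        m2 <- model
        m2$params[[grp]][[nm]][k] <- P[k] + eps
        up <- loss_fn(m2)
        m2$params[[grp]][[nm]][k] <- P[k] - eps
        dn <- loss_fn(m2)
        num <- (up - dn) / (2 * eps)
        expect_equal(grads[[grp]][[nm]][k], num, tolerance = 1e-4,
                     label = paste("grad", grp, nm, k))
      }
    }
  }
})
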