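# Chronological predict-then-update training and evaluation. Each epoch
# replays the graphlet sequence from re-initialized memory; at every step t
# the positives E_t plus uniformly sampled negatives are scored using only
# information from steps < t, binary cross-entropy gradients update the
# parameters, and only then is E_t integrated into the memory and the
# neighbor index. The checkpoint with the best validation AUC is kept.

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a uniformly chosen positive outranks a uniformly chosen
#' negative, with ties counted 1/2.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1 = positive).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("auc needs both classes present")
  r <- rank(scores)  # average ranks handle ties as 1/2 credit
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Average precision
#'
#' Mean over positives of the precision at each positive's rank, with scores
#' sorted descending and ties broken by stable original index order.
#'
#' @inheritParams auc
#' @return AP in `(0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  labels <- as.integer(labels)
  if (sum(labels == 1) == 0) stop("average_precision needs at least 1 positive")
  ord <- order(-scores)  # stable: ties keep original index order
  y <- labels[ord]
  prec_at <- cumsum(y) / seq_along(y)
  mean(prec_at[y == 1])
}

# Events at training steps, optionally uniformly subsampled (seeded).
training_events <- function(graph, train_end, data_fraction, seed) {
  ev <- graph$events[graph$events$t <= train_end, , drop = FALSE]
  if (data_fraction < 1 && nrow(ev) > 0) {
    set.seed(derive_seed(seed, 42L))
    keep <- sort(sample.int(nrow(ev), round(data_fraction * nrow(ev))))
    ev <- ev[keep, , drop = FALSE]
  }
  rownames(ev) <- NULL
  ev
}

# Replay one graphlet into store/index without scoring.
replay_step <- function(model, store, index, events, t) {
  store <- apply_graphlet(store, gru_of(model), model$enc, events, t,
                          raw_delta = model$cfg$raw_delta,
                          freeze_states = !model$cfg$use_integration)
  index <- update_neighbor_index(index, events)
  list(store = store, index = index)
}

# Score the (leakage-removed) positives of E_step plus 1:1 negatives with the
# given store/index, which must reflect history through step - 1.
score_step <- function(model, store, index, graph, step, seed,
                       neg_ratio = 1) {
  pos_pairs <- remove_seen_pairs(events_at(graph, step)[, c("i", "j")],
                                 graph, step)
  if (nrow(pos_pairs) == 0) {
    stop("no surviving positive pairs at step ", step,
         " after leakage removal")
  }
  pos <- pair_samples(pos_pairs$i, pos_pairs$j, step, 1L)
  neg <- sample_negatives(pos, graph, ratio = neg_ratio, seed = seed,
                          exclude_history = model$cfg$exclude_history_negatives)
  pairs <- rbind(pos, neg)
  fw <- forward_pairs(model, store, index, pairs, step)
  list(scores = fw$prob, labels = pairs$label,
       n_pos = nrow(pos), n_neg = nrow(neg))
}

eval_result <- function(scores, labels, n_pos, n_neg) {
  structure(list(auc = auc(scores, labels),
                 ap = average_precision(scores, labels),
                 n_pos = n_pos, n_neg = n_neg),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> AUC = %.4f  AP = %.4f  (%d pos / %d neg)\n",
              x$auc, x$ap, x$n_pos, x$n_neg))
  invisible(x)
}

#' Train the temporal-semantic link predictor
#'
#' @param graph A [temporal_graph()].
#' @param split A [split_spec()]; training uses steps `1..train_end`,
#'   model selection uses AUC at `val_step`.
#' @param embeddings `|V| x d_emb` matrix of pre-computed concept embeddings
#'   (rows aligned with `graph$ids`).
#' @param cfg A [model_config()].
#' @return A `conceptdrift_fit`: the trained model (best-validation
#'   checkpoint), per-epoch `history` (train loss, validation AUC/AP), the
#'   resolved config, and everything needed to re-evaluate.
#' @export
train <- function(graph, split, embeddings, cfg = model_config()) {
  stopifnot(inherits(graph, "temporal_graph"), inherits(split, "split_spec"))
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) != n_concepts(graph)) {
    stop("embedding rows (", nrow(embeddings), ") != vocabulary size (",
         n_concepts(graph), ")")
  }
  if (split$test_step > graph$horizon) stop("test step beyond horizon")
  cfg <- resolve_config(cfg, ncol(embeddings), graph$horizon)
  seed <- cfg$seed
  set_global_seed(seed)
  model <- new_model(cfg, seed = seed)
  store0 <- init_states(embeddings, d = cfg$state_dim,
                        projection = cfg$project_embeddings, seed = seed)
  train_ev <- training_events(graph, split$train_end, cfg$data_fraction, seed)
  if (nrow(train_ev) == 0) stop("no training events at steps <= train_end")

  opt <- adam_init(model$params)
  best <- list(auc = -Inf, params = model$params, epoch = 0L)
  history <- data.frame()

  for (epoch in seq_len(cfg$epochs)) {
    store <- if (cfg$epoch_memory_reset || epoch == 1) {
      reset_states(store0)
    } else store
    index <- new_neighbor_index(n_concepts(graph))
    losses <- c()
    for (t in seq_len(split$train_end)) {
      pos_ev <- train_ev[train_ev$t == t, , drop = FALSE]
      if (nrow(pos_ev) > 0) {
        pos <- pair_samples(pos_ev$i, pos_ev$j, t, 1L)
        nseed <- if (cfg$resample_negatives) {
          derive_seed(seed, 1000L * epoch + t)
        } else derive_seed(seed, 1000L + t)
        neg <- sample_negatives(pos, graph, ratio = cfg$neg_ratio,
                                seed = nseed,
                                exclude_history = cfg$exclude_history_negatives)
        pairs <- rbind(pos, neg)
        nb <- if (is.finite(cfg$batch_size)) {
          split(seq_len(nrow(pairs)),
                ceiling(seq_len(nrow(pairs)) / cfg$batch_size))
        } else list(seq_len(nrow(pairs)))
        for (rows in nb) {
          batch <- pairs[rows, , drop = FALSE]
          fw <- forward_pairs(model, store, index, batch, t)
          losses <- c(losses, bce_loss(fw$prob, batch$label))
          dlogit <- (fw$prob - batch$label) / length(rows)
          grads <- backward_pairs(model, fw, dlogit)
          step <- adam_step(model$params, grads, opt, lr = cfg$lr)
          model$params <- step$params
          opt <- step$state
        }
      }
      rs <- replay_step(model, store, index, pos_ev, t)
      store <- rs$store
      index <- rs$index
    }
    # advance memory to val_step - 1, then score the validation step
    vstore <- store
    vindex <- index
    for (t in seq(split$train_end + 1L, length.out = split$val_step - 1L -
                    split$train_end)) {
      rs <- replay_step(model, vstore, vindex, events_at(graph, t), t)
      vstore <- rs$store
      vindex <- rs$index
    }
    vs <- score_step(model, vstore, vindex, graph, split$val_step,
                     seed = derive_seed(seed, 555L))
    vres <- eval_result(vs$scores, vs$labels, vs$n_pos, vs$n_neg)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = mean(losses),
      val_auc = vres$auc, val_ap = vres$ap
    ))
    if (vres$auc > best$auc) {
      best <- list(auc = vres$auc, params = model$params, epoch = epoch)
    }
  }
  model$params <- best$params
  structure(list(
    model = model, cfg = cfg, history = history, best_epoch = best$epoch,
    embeddings = embeddings, ids = graph$ids, vocab_hash = fnv1a(graph$ids),
    split = split, train_events = train_ev
  ), class = "conceptdrift_fit")
}

#' @export
print.conceptdrift_fit <- function(x, ...) {
  h <- x$history
  cat("<conceptdrift_fit>", nrow(h), "epochs; best epoch", x$best_epoch,
      sprintf("(val AUC %.4f)\n", max(h$val_auc)))
  invisible(x)
}

# Rebuild memory and neighbor index from scratch through step `through`,
# optionally capturing a snapshot of the full state matrix after every step
# (snapshot 0 is the initial state).
replay_through <- function(fit, graph, through, capture = FALSE) {
  model <- fit$model
  store <- init_states(fit$embeddings, d = fit$cfg$state_dim,
                       projection = fit$cfg$project_embeddings,
                       seed = fit$cfg$seed)
  index <- new_neighbor_index(n_concepts(graph))
  snaps <- if (capture) stats::setNames(list(store$states), "0") else NULL
  for (t in seq_len(through)) {
    rs <- replay_step(model, store, index, events_at(graph, t), t)
    store <- rs$store
    index <- rs$index
    if (capture) snaps[[as.character(t)]] <- store$states
  }
  list(store = store, index = index, snapshots = snaps)
}

#' Capture semantic-state snapshots along a replay
#'
#' Re-initializes memory from the fit's embeddings and replays graphlets
#' chronologically with the trained parameters, recording the full state
#' matrix after every step.
#'
#' @param fit A [train()] result.
#' @param graph The [temporal_graph()].
#' @param through Last step to replay.
#' @return Named list of `|V| x d` matrices for steps `0..through`.
#' @export
replay_states <- function(fit, graph, through = graph$horizon) {
  replay_through(fit, graph, through, capture = TRUE)$snapshots
}

#' Evaluate a trained model at a time step
#'
#' Replays history through `step - 1`, removes test pairs seen at earlier
#' steps, samples 1:1 negatives uniformly, scores every candidate with the
#' trained predictor, and reports AUC and average precision.
#'
#' @param fit A [train()] result.
#' @param graph The [temporal_graph()].
#' @param step Target time step.
#' @param seed Seed for negative sampling.
#' @return An `eval_result` with `auc`, `ap`, `n_pos`, `n_neg`.
#' @export
evaluate <- function(fit, graph, step, seed = 1L) {
  if (fnv1a(graph$ids) != fit$vocab_hash) {
    stop("graph vocabulary does not match the model's vocabulary")
  }
  rp <- replay_through(fit, graph, step - 1L)
  ss <- score_step(fit$model, rp$store, rp$index, graph, step,
                   seed = derive_seed(seed, 777L))
  eval_result(ss$scores, ss$labels, ss$n_pos, ss$n_neg)
}

#' Score arbitrary candidate pairs at a time step
#'
#' @param fit A [train()] result.
#' @param graph The [temporal_graph()].
#' @param pairs Data frame with columns `i`, `j` (concept indices).
#' @param step Target step; history through `step - 1` is replayed.
#' @return Numeric vector of co-occurrence probabilities.
#' @export
predict_pairs <- function(fit, graph, pairs, step) {
  rp <- replay_through(fit, graph, step - 1L)
  pairs <- canonical_pairs(pairs)
  forward_pairs(fit$model, rp$store, rp$index, pairs, step)$prob
}

#' Frozen-embedding dot-product baseline
#'
#' Scores a pair by the inner product of the two concepts' initial embeddings
#' (no temporal information), under the same leakage removal and negative
#' sampling as [evaluate()]. Used as the reference the temporal model must
#' beat.
#'
#' @param graph The [temporal_graph()].
#' @param embeddings `|V| x d_emb` matrix.
#' @param step Target step.
#' @param seed Seed for negative sampling.
#' @return An `eval_result`.
#' @export
baseline_dot_eval <- function(graph, embeddings, step, seed = 1L) {
  pos_pairs <- remove_seen_pairs(events_at(graph, step)[, c("i", "j")],
                                 graph, step)
  if (nrow(pos_pairs) == 0) stop("no surviving positives at step ", step)
  pos <- pair_samples(pos_pairs$i, pos_pairs$j, step, 1L)
  neg <- sample_negatives(pos, graph, ratio = 1, seed = derive_seed(seed, 777L))
  pairs <- rbind(pos, neg)
  emb <- as.matrix(embeddings)
  scores <- rowSums(emb[pairs$i, , drop = FALSE] * emb[pairs$j, , drop = FALSE])
  eval_result(scores, pairs$label, nrow(pos), nrow(neg))
}
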