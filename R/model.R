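# Model assembly: configuration, parameter construction, and the batched
# forward/backward passes used by training. Stored memory states are read as
# constants; at scoring time each updated concept's state is recomputed from
# its cached last message and detached previous state, so gradients reach the
# contextual-integration cell exactly one update deep (never through the full
# history), while attention, fusion and scoring parameters receive full
# gradients.

#' Model / training configuration
#'
#' @param state_dim Semantic state dimension `d`; `NULL` = embedding dimension.
#' @param time_dim Functional time-encoding dimension.
#' @param heads Attention heads.
#' @param attn_dim Total attention dimension (divisible by `heads`).
#' @param neighbor_cap Max neighbors attended over (`Inf` = full neighborhood;
#'   a finite cap keeps the latest first co-occurrences and bounds hub cost).
#' @param dz Predictive-embedding dimension; `NULL` = `state_dim`.
#' @param score_hidden Score-head hidden width; `NULL` = `dz`.
#' @param lr Adam learning rate.
#' @param epochs Training epochs (graphlets replayed chronologically each
#'   epoch from re-initialized memory).
#' @param neg_ratio Negatives per positive (1 = the 1:1 protocol).
#' @param resample_negatives Fresh training negatives each epoch.
#' @param exclude_history_negatives Reject negatives seen at earlier steps too.
#' @param data_fraction Uniform, seeded subsample fraction of training-step
#'   events (data-scarcity experiments).
#' @param project_embeddings `"auto"`, `"on"`, or `"off"`.
#' @param epoch_memory_reset Re-initialize memory each epoch.
#' @param raw_delta Feed raw scalar `t - tp` instead of its encoding.
#' @param use_integration `FALSE` freezes states at initialization (ablation).
#' @param use_attention `FALSE` predicts from states only (ablation).
#' @param batch_size Scored pairs per gradient step within one graphlet
#'   (`Inf` = one step per graphlet).
#' @param update_bias Initial update-gate bias of the integration cell
#'   (positive favors retaining the previous state).
#' @param seed Integer seed for all stochastic components.
#' @return A list of class `cd_config`.
#' @export
model_config <- function(state_dim = NULL, time_dim = 8L, heads = 2L,
                         attn_dim = 32L, neighbor_cap = 20, dz = 32L,
                         score_hidden = 64L, lr = 1e-3, epochs = 30L,
                         neg_ratio = 1, resample_negatives = TRUE,
                         exclude_history_negatives = FALSE, data_fraction = 1,
                         project_embeddings = "auto",
                         epoch_memory_reset = TRUE, raw_delta = FALSE,
                         use_integration = TRUE, use_attention = TRUE,
                         batch_size = Inf, update_bias = 1, seed = 1L) {
  stopifnot(data_fraction > 0, data_fraction <= 1)
  structure(as.list(environment()), class = "cd_config")
}

# Resolve NULL dimensions against the embedding matrix and horizon.
resolve_config <- function(cfg, d_emb, horizon) {
  if (is.null(cfg$state_dim)) cfg$state_dim <- d_emb
  if (is.null(cfg$dz)) cfg$dz <- cfg$state_dim
  if (is.null(cfg$score_hidden)) cfg$score_hidden <- cfg$dz
  cfg$horizon <- horizon
  cfg
}

#' Construct an untrained model
#'
#' Builds the time encoder (fixed), the gated recurrent integration cell, the
#' multi-head cross-attention block, the fusion MLP and the score head.
#'
#' @param cfg Resolved [model_config()].
#' @param seed Seed for parameter initialization.
#' @return List of class `cd_model` with `params`, `enc`, `cfg`.
#' @export
new_model <- function(cfg, seed = cfg$seed) {
  d <- cfg$state_dim
  dt <- cfg$time_dim
  msg_dim <- if (cfg$raw_delta) 2L * d + 1L else 2L * d + dt
  qdim <- d + dt
  enc <- time_encoder(dt, linear_scale = max(cfg$horizon, 2))
  params <- list(
    gru = unclass(new_gru_cell(msg_dim, d, seed = derive_seed(seed, 1L),
                               update_bias = cfg$update_bias)),
    attn = attn_weights(new_attention_block(qdim, cfg$attn_dim, cfg$heads,
                                            seed = derive_seed(seed, 2L))),
    fuse = {
      set.seed(derive_seed(seed, 3L))
      new_mlp2(d + cfg$attn_dim, cfg$dz, cfg$dz)
    },
    score = {
      set.seed(derive_seed(seed, 4L))
      new_mlp2(cfg$dz, cfg$score_hidden, 1L)
    }
  )
  structure(list(params = params, enc = enc, cfg = cfg), class = "cd_model")
}

gru_of <- function(model) structure(model$params$gru, class = "gru_cell")
attn_of <- function(model) {
  structure(c(model$params$attn,
              list(heads = model$cfg$heads, attn_dim = model$cfg$attn_dim,
                   input_dim = model$cfg$state_dim + model$cfg$time_dim)),
            class = "attention_block")
}

# Numeric-parameter view of the attention block for the optimizer.
attn_weights <- function(block) block[c("Wq", "Wk", "Wv", "Wo")]

# ---- batched scoring forward/backward ---------------------------------------

# Scores candidate pairs at step t from the current store and neighbor index.
# Returns probabilities plus caches sufficient for backward_pairs().
#
# Every state read (the scored concepts' own states AND the neighbor states
# inside attention keys/values) whose concept has a cached message is
# recomputed through the integration cell from that cached message and its
# detached previous state. The recomputation reproduces the stored values
# exactly, but exposes the GRU step to the backward pass, so the cell is
# trained by both the fusion/query path and the attention path -- one update
# deep, never through history.
forward_pairs <- function(model, store, index, pairs, t) {
  cfg <- model$cfg
  d <- cfg$state_dim
  uc <- sort(unique(c(pairs$i, pairs$j)))
  M <- length(uc)
  mi <- match(pairs$i, uc)
  mj <- match(pairs$j, uc)

  nb <- NULL
  nbr_all <- integer(0)
  if (cfg$use_attention) {
    nb <- lapply(uc, function(i) get_neighbors(index, i, cfg$neighbor_cap))
    nbr_all <- unlist(lapply(nb, `[[`, "nbr"))
  }

  # gradient set: every read concept with a cached message; their states are
  # recomputed through the cell (bitwise equal to the stored values) so the
  # backward pass can reach the cell parameters
  gset <- integer(0)
  gru_fwd <- NULL
  states <- store$states
  if (cfg$use_integration) {
    gset <- sort(unique(c(uc, nbr_all)))
    gset <- gset[store$has_msg[gset]]
    if (length(gset) > 0) {
      gru_fwd <- gru_forward(gru_of(model),
                             store$msg_cache[gset, , drop = FALSE],
                             store$prev_cache[gset, , drop = FALSE])
      states[gset, ] <- gru_fwd$S
    }
  }
  S <- states[uc, , drop = FALSE]

  phi_t <- encode_time(model$enc, t)
  Q <- cbind(S, matrix(phi_t, M, length(phi_t), byrow = TRUE))

  attn_fwd <- NULL
  flat <- integer(0)
  if (cfg$use_attention) {
    cnt <- vapply(nb, function(x) length(x$nbr), 0L)
    N <- max(1L, max(cnt))
    KV <- matrix(0, M * N, d + model$enc$d_time)
    mask <- matrix(FALSE, M, N)
    if (any(cnt > 0)) {
      ft_all <- unlist(lapply(nb, `[[`, "ft"))
      flat <- unlist(lapply(seq_len(M), function(m) {
        if (cnt[m] == 0) integer(0) else (m - 1L) * N + seq_len(cnt[m])
      }))
      te <- encode_time(model$enc, ft_all)
      if (is.null(dim(te))) te <- matrix(te, nrow = length(ft_all))
      KV[flat, ] <- cbind(states[nbr_all, , drop = FALSE], te)
      mask[cbind(rep(seq_len(M), cnt),
                 unlist(lapply(cnt[cnt > 0], seq_len)))] <- TRUE
    }
    attn_fwd <- attn_forward_batch(attn_of(model), Q, KV, mask)
    Hout <- attn_fwd$Hout
  } else {
    Hout <- matrix(0, M, cfg$attn_dim)
  }

  U <- cbind(S, Hout)
  fuse_fwd <- mlp2_forward(model$params$fuse, U)
  Z <- fuse_fwd$Y
  X <- Z[mi, , drop = FALSE] + Z[mj, , drop = FALSE]
  score_fwd <- mlp2_forward(model$params$score, X)
  logits <- drop(score_fwd$Y)
  list(prob = sigmoid(logits), logits = logits, uc = uc, mi = mi, mj = mj,
       gset = gset, gru_fwd = gru_fwd, attn_fwd = attn_fwd,
       fuse_fwd = fuse_fwd, score_fwd = score_fwd, M = M,
       nbr_all = nbr_all, flat = flat)
}

# Backward pass for forward_pairs(); dlogit is dLoss/dlogit per pair.
# Returns a grads list parallel to model$params.
backward_pairs <- function(model, fw, dlogit) {
  cfg <- model$cfg
  d <- cfg$state_dim
  sb <- mlp2_backward(model$params$score, fw$score_fwd, matrix(dlogit))
  dX <- sb$dX
  dZ <- matrix(0, fw$M, cfg$dz)
  acc <- rowsum(rbind(dX, dX), group = c(fw$mi, fw$mj))
  dZ[as.integer(rownames(acc)), ] <- acc
  fb <- mlp2_backward(model$params$fuse, fw$fuse_fwd, dZ)
  dS <- fb$dX[, seq_len(d), drop = FALSE]          # M x d, indexed by uc
  dNbr <- NULL                                      # |nbr_all| x d
  if (cfg$use_attention) {
    dHout <- fb$dX[, d + seq_len(cfg$attn_dim), drop = FALSE]
    ab <- attn_backward_batch(attn_of(model), fw$attn_fwd, dHout)
    dS <- dS + ab$dQ[, seq_len(d), drop = FALSE]
    if (length(fw$flat) > 0) {
      dNbr <- ab$dKV[fw$flat, seq_len(d), drop = FALSE]
    }
    g_attn <- ab$grads
  } else {
    g_attn <- zeros_like(attn_weights(model$params$attn))
  }
  if (length(fw$gset) > 0) {
    dG <- matrix(0, length(fw$gset), d)
    own <- match(fw$uc, fw$gset)            # NA when uc has no cached message
    hit <- which(!is.na(own))
    if (length(hit) > 0) {
      dG[own[hit], ] <- dS[hit, , drop = FALSE]   # uc entries are unique
    }
    if (!is.null(dNbr)) {
      nmap <- match(fw$nbr_all, fw$gset)
      keep <- which(!is.na(nmap))
      if (length(keep) > 0) {
        dG <- dG + rowsum_into(dNbr[keep, , drop = FALSE], nmap[keep],
                               length(fw$gset))
      }
    }
    g_gru <- gru_backward(gru_of(model), fw$gru_fwd, dG)
  } else {
    g_gru <- zeros_like(model$params$gru)
  }
  list(gru = g_gru, attn = g_attn, fuse = fb$grads, score = sb$grads)
}

# rowsum() into a fixed number of rows, keeping absent groups as zero rows.
rowsum_into <- function(x, group, nrows) {
  out <- matrix(0, nrows, ncol(x))
  acc <- rowsum(x, group = group)
  out[as.integer(rownames(acc)), ] <- acc
  out
}
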