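# Prediction path: temporal multi-head cross-attention over a concept's
# neighborhood produces, together with the concept's own semantic state, a
# predictive embedding
#     z_i(t) = MLP(s_i(t) || h_i(t)),
#     h_i(t) = MultiHeadCrossAttention(q, K, V),
#     q = s_i(t) || phi(t),   K = V = [ s_n(t) || phi(t_n) ]_n,
# where t_n is the step at which neighbor n FIRST co-occurred with i, and a
# pair is scored as p(i, j | t+1) = sigmoid(MLP(z_i(t) + z_j(t))).

#' Neighbor index keyed by first co-occurrence time
#'
#' For each concept, the set of concepts it has co-occurred with and the step
#' of their first co-occurrence. First-interaction times are kept (never
#' overwritten by later repeats) because they mark potential discovery events,
#' while recency is already captured by the evolving states.
#'
#' @param n Number of concepts.
#' @return An object of class `neighbor_index`.
#' @export
new_neighbor_index <- function(n) {
  structure(list(nbr = rep(list(integer(0)), n),
                 ft = rep(list(integer(0)), n)),
            class = "neighbor_index")
}

#' Record a graphlet's events in the neighbor index
#'
#' @param index A [new_neighbor_index()].
#' @param events Data frame of events at one step (chronological processing is
#'   assumed; earlier calls hold earlier steps).
#' @return The updated index.
#' @export
update_neighbor_index <- function(index, events) {
  if (nrow(events) == 0) return(index)
  for (k in seq_len(nrow(events))) {
    i <- events$i[k]; j <- events$j[k]; t <- events$t[k]
    if (!(j %in% index$nbr[[i]])) {
      index$nbr[[i]] <- c(index$nbr[[i]], j)
      index$ft[[i]] <- c(index$ft[[i]], t)
    }
    if (!(i %in% index$nbr[[j]])) {
      index$nbr[[j]] <- c(index$nbr[[j]], i)
      index$ft[[j]] <- c(index$ft[[j]], t)
    }
  }
  index
}

# Neighbors of i with first co-occurrence times, truncated to the `cap`
# neighbors with the LATEST first co-occurrence steps (ties broken by lower
# concept index for determinism). cap = Inf keeps the full neighborhood.
get_neighbors <- function(index, i, cap = Inf) {
  nbr <- index$nbr[[i]]
  ft <- index$ft[[i]]
  if (length(nbr) > cap) {
    ord <- order(-ft, nbr)[seq_len(cap)]
    nbr <- nbr[ord]
    ft <- ft[ord]
  }
  list(nbr = nbr, ft = ft)
}

#' Attention query for a concept
#'
#' @param store A [init_states()] store.
#' @param enc A [time_encoder()].
#' @param i Concept index.
#' @param t Current step.
#' @return Length `d + d_time` vector `s_i(t) || phi(t)`.
#' @export
build_query <- function(store, enc, i, t) {
  c(store$states[i, ], encode_time(enc, t))
}

#' Attention keys/values for a concept's neighborhood
#'
#' One row per neighbor: its current semantic state concatenated with the
#' encoding of its first co-occurrence step with `i`. Keys and values are the
#' same matrix. When the neighborhood exceeds `cap`, the `cap` neighbors with
#' the latest first co-occurrence steps are kept.
#'
#' @param store A [init_states()] store.
#' @param enc A [time_encoder()].
#' @param index A [new_neighbor_index()].
#' @param i Concept index.
#' @param t Current step (unused in the vectors themselves; neighbor states
#'   are their most recent stored states).
#' @param cap Maximum neighbors used (default `Inf`).
#' @return `n x (d + d_time)` matrix (0 rows if no neighbors).
#' @export
build_keys_values <- function(store, enc, index, i, t, cap = Inf) {
  nb <- get_neighbors(index, i, cap)
  if (length(nb$nbr) == 0) {
    return(matrix(0, 0, store$d + enc$d_time))
  }
  te <- encode_time(enc, nb$ft)
  if (is.null(dim(te))) te <- matrix(te, nrow = length(nb$ft))
  cbind(store$states[nb$nbr, , drop = FALSE], te)
}

#' Multi-head cross-attention block
#'
#' Canonical scaled dot-product attention with `H` heads of dimension
#' `attn_dim / H`, per-head query/key/value projections from the input
#' dimension and an output projection; a single query attends over the
#' neighborhood keys/values.
#'
#' @param input_dim Dimension of query and key/value rows (`d + d_time`).
#' @param attn_dim Total attention dimension (divisible by `heads`).
#' @param heads Number of heads.
#' @param seed Seed for initialization.
#' @return An object of class `attention_block`.
#' @export
new_attention_block <- function(input_dim, attn_dim, heads = 2L, seed = 1L) {
  stopifnot(attn_dim %% heads == 0)
  set.seed(derive_seed(seed, 303L))
  structure(list(
    Wq = glorot(input_dim, attn_dim),
    Wk = glorot(input_dim, attn_dim),
    Wv = glorot(input_dim, attn_dim),
    Wo = glorot(attn_dim, attn_dim),
    heads = as.integer(heads), attn_dim = as.integer(attn_dim),
    input_dim = as.integer(input_dim)
  ), class = "attention_block")
}

#' Single-query multi-head cross-attention
#'
#' @param block A [new_attention_block()].
#' @param q Query vector.
#' @param kv Key/value matrix (one row per neighbor; keys and values are the
#'   same list). An empty `kv` yields the zero vector, letting prediction
#'   degrade gracefully to state-only for isolated concepts.
#' @param weights Return per-head attention weights as attribute
#'   `"weights"` (heads x neighbors matrix).
#' @return Length `attn_dim` output vector.
#' @export
cross_attention <- function(block, q, kv, weights = FALSE) {
  if (length(q) != block$input_dim) stop("query has wrong dimension")
  if (NROW(kv) == 0) return(numeric(block$attn_dim))
  kv <- as.matrix(kv)
  if (ncol(kv) != block$input_dim) stop("key/value rows have wrong dimension")
  H <- block$heads
  dh <- block$attn_dim / H
  Qp <- drop(matrix(q, 1) %*% block$Wq)
  Kp <- kv %*% block$Wk
  Vp <- kv %*% block$Wv
  out <- numeric(block$attn_dim)
  W <- matrix(0, H, nrow(kv))
  for (h in seq_len(H)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    sc <- drop(Kp[, cols, drop = FALSE] %*% Qp[cols]) / sqrt(dh)
    w <- exp(sc - max(sc))
    w <- w / sum(w)
    W[h, ] <- w
    out[cols] <- drop(crossprod(Vp[, cols, drop = FALSE], w))
  }
  res <- drop(matrix(out, 1) %*% block$Wo)
  if (weights) attr(res, "weights") <- W
  res
}

# ---- batched attention over M concepts with padded neighbor lists ----------
#
# KV is an (M * N) x p matrix in concept-major order (neighbor index fastest),
# mask an M x N logical matrix of valid rows. Rows of concepts with no valid
# neighbors get a zero output. Returns intermediates for the backward pass.
attn_forward_batch <- function(block, Q, KV, mask) {
  M <- nrow(Q)
  N <- ncol(mask)
  H <- block$heads
  dh <- block$attn_dim / H
  Qp <- Q %*% block$Wq
  Kp <- KV %*% block$Wk
  Vp <- KV %*% block$Wv
  repM <- rep(seq_len(M), each = N)
  O <- matrix(0, M, block$attn_dim)
  Wlist <- vector("list", H)
  for (h in seq_len(H)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    sc <- rowSums(Kp[, cols, drop = FALSE] * Qp[repM, cols, drop = FALSE]) / sqrt(dh)
    S <- matrix(sc, M, N, byrow = TRUE)
    S[!mask] <- -Inf
    mx <- apply(S, 1, max)
    mx[!is.finite(mx)] <- 0
    E <- exp(S - mx)
    E[!mask] <- 0
    rs <- rowSums(E)
    W <- E / ifelse(rs > 0, rs, 1)
    Wlist[[h]] <- W
    wflat <- as.vector(t(W))
    O[, cols] <- rowsum(Vp[, cols, drop = FALSE] * wflat, group = repM)
  }
  list(Hout = O %*% block$Wo, O = O, W = Wlist, Qp = Qp, Kp = Kp, Vp = Vp,
       Q = Q, KV = KV, mask = mask, repM = repM)
}

attn_backward_batch <- function(block, fwd, dH) {
  M <- nrow(fwd$Q)
  N <- ncol(fwd$mask)
  H <- block$heads
  dh <- block$attn_dim / H
  repM <- fwd$repM
  dO <- dH %*% t(block$Wo)
  gWo <- t(fwd$O) %*% dH
  dQp <- matrix(0, M, block$attn_dim)
  dKp <- matrix(0, nrow(fwd$KV), block$attn_dim)
  dVp <- matrix(0, nrow(fwd$KV), block$attn_dim)
  for (h in seq_len(H)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    W <- fwd$W[[h]]
    wflat <- as.vector(t(W))
    dOh <- dO[, cols, drop = FALSE]
    # dW[m, n] = <dOh[m, ], Vp[(m, n), ]>
    dW <- matrix(rowSums(fwd$Vp[, cols, drop = FALSE] *
                           dOh[repM, , drop = FALSE]), M, N, byrow = TRUE)
    dVp[, cols] <- dOh[repM, , drop = FALSE] * wflat
    dS <- W * (dW - rowSums(W * dW))
    dS[!fwd$mask] <- 0
    dsflat <- as.vector(t(dS))
    dQp[, cols] <- rowsum(fwd$Kp[, cols, drop = FALSE] * dsflat,
                          group = repM) / sqrt(dh)
    dKp[, cols] <- (fwd$Qp[repM, cols, drop = FALSE] * dsflat) / sqrt(dh)
  }
  list(
    grads = list(
      Wq = t(fwd$Q) %*% dQp,
      Wk = t(fwd$KV) %*% dKp,
      Wv = t(fwd$KV) %*% dVp,
      Wo = gWo
    ),
    dQ = dQp %*% t(block$Wq),
    dKV = dKp %*% t(block$Wk) + dVp %*% t(block$Wv)
  )
}

#' Predictive embedding of a concept
#'
#' Fuses the concept's current state with its attention summary through a
#' two-layer perceptron: `z_i(t) = MLP(s_i(t) || h)`.
#'
#' @param mlp_fuse A [new_mlp2()]-style parameter list (see
#'   [new_model()]; input `d + attn_dim`, output `d_z`).
#' @param store A [init_states()] store.
#' @param i Concept index.
#' @param t Step.
#' @param h Attention output vector for `i` at `t`.
#' @return List of class `predictive_embedding` with `vector`, `concept`, `t`.
#' @export
predictive_embedding <- function(mlp_fuse, store, i, t, h) {
  x <- matrix(c(store$states[i, ], h), 1)
  structure(list(vector = drop(mlp2_forward(mlp_fuse, x)$Y),
                 concept = as.integer(i), t = as.integer(t)),
            class = "predictive_embedding")
}

#' Score a candidate pair
#'
#' `sigmoid(MLP(z_i + z_j))`; the sum makes the score exactly symmetric in the
#' pair.
#'
#' @param head A [new_mlp2()]-style score head (input `d_z`, output 1).
#' @param z_i,z_j `predictive_embedding`s at a common step.
#' @return Co-occurrence probability in (0, 1).
#' @export
score_pair <- function(head, z_i, z_j) {
  if (z_i$t != z_j$t) stop("predictive embeddings are at different steps")
  x <- matrix(z_i$vector + z_j$vector, 1)
  drop(sigmoid(mlp2_forward(head, x)$Y))
}
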