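# Evolving semantic states. Each concept carries a state vector s_i(t),
# initialized from a pre-computed embedding matrix. When concepts i and j
# co-occur at step t, a context message
#     CAF_i(t) = s_i(tp_i) || s_j(tp_j) || phi(t - tp_i)
# is formed from the endpoints' states at their last update times tp and a
# functional encoding of the elapsed time, and the state is updated by a
# gated recurrent contextual-integration cell s_i(t) = GRU(CAF_i(t), s_i(tp_i)).

#' Functional time encoder
#'
#' Maps a scalar time (a step `t` or a difference `t - tp`) to a `d_time`
#' vector: component 1 is the linear term `omega_1 x + b_1`, components
#' `k >= 2` are `cos(omega_k x + b_k)`. Frequencies default to a fixed
#' geometric ladder of periods `2, 4, 8, ...` plus the linear trend scaled by
#' `1/linear_scale`, covering both within-horizon periodicities and long-range
#' elapsed time. The encoder is deterministic and is not trained.
#'
#' @param d_time Encoding dimension (>= 1).
#' @param linear_scale Scale of the linear component (roughly the horizon).
#' @param omega,phase Optional explicit frequency/phase vectors.
#' @return An object of class `time_encoder`.
#' @export
time_encoder <- function(d_time = 8L, linear_scale = 10,
                         omega = NULL, phase = NULL) {
  d_time <- as.integer(d_time)
  stopifnot(d_time >= 1)
  if (is.null(omega)) {
    omega <- c(1 / linear_scale,
               if (d_time > 1) 2 * pi / 2^seq_len(d_time - 1))
  }
  if (is.null(phase)) phase <- numeric(d_time)
  stopifnot(length(omega) == d_time, length(phase) == d_time)
  structure(list(omega = omega, phase = phase, d_time = d_time),
            class = "time_encoder")
}

#' Encode a time value (or vector of values)
#'
#' @param enc A [time_encoder()].
#' @param x Numeric scalar or vector of times / time differences.
#' @return For scalar `x` a length-`d_time` vector; for vector `x` a
#'   `length(x) x d_time` matrix (one encoding per row).
#' @export
encode_time <- function(enc, x) {
  ang <- outer(x, enc$omega) + rep(enc$phase, each = length(x))
  out <- cos(ang)
  out[, 1] <- ang[, 1]
  if (length(x) == 1) out <- drop(out)
  out
}

#' Initialize the semantic state store
#'
#' States at `t = 0` are the rows of the embedding matrix, projected to the
#' state dimension by a fixed seeded linear map when the dimensions differ
#' (`projection = "auto"`), and used verbatim otherwise. The store also keeps
#' per-concept last-update times and the cached last context message needed to
#' recompute a state with gradients at read time.
#'
#' @param embeddings `|V| x d_emb` numeric matrix (one row per concept).
#' @param d State dimension (default `ncol(embeddings)`).
#' @param projection `"auto"` (project only when `d != d_emb`), `"on"`, or
#'   `"off"` (error if dimensions differ).
#' @param seed Seed for the projection map.
#' @return An object of class `state_store`.
#' @export
init_states <- function(embeddings, d = ncol(embeddings),
                        projection = c("auto", "on", "off"), seed = 1L) {
  projection <- match.arg(projection)
  embeddings <- as.matrix(embeddings)
  d <- as.integer(d)
  nv <- nrow(embeddings)
  proj <- NULL
  if (projection == "on" || (projection == "auto" && ncol(embeddings) != d)) {
    set.seed(derive_seed(seed, 101L))
    proj <- glorot(ncol(embeddings), d)
    init <- embeddings %*% proj
  } else {
    if (ncol(embeddings) != d) {
      stop("embedding dimension ", ncol(embeddings), " != state dimension ", d,
           " with projection disabled")
    }
    init <- embeddings
  }
  structure(list(
    states = init,
    init = init,
    proj = proj,
    last_update = integer(nv),
    step = 0L,
    d = d,
    # cached inputs of each concept's most recent GRU update, enabling exact
    # recomputation of its current state at read time
    msg_cache = NULL,
    prev_cache = matrix(0, nv, d),
    has_msg = logical(nv)
  ), class = "state_store")
}

# Reset a store to its t = 0 condition (used at the start of each epoch).
reset_states <- function(store) {
  nv <- nrow(store$states)
  store$states <- store$init
  store$last_update <- integer(nv)
  store$step <- 0L
  store$msg_cache <- NULL
  store$prev_cache <- matrix(0, nv, store$d)
  store$has_msg <- logical(nv)
  store
}

#' Context aggregation for one co-occurrence
#'
#' Builds the context message for target concept `i` co-occurring with `j` at
#' step `t`: the concatenation of both endpoints' states at their last update
#' times with an encoding of the elapsed time since `i`'s last update. No
#' state is mutated.
#'
#' @param store A [init_states()] store.
#' @param enc A [time_encoder()].
#' @param i Target concept index.
#' @param j Co-occurring concept index.
#' @param t Current step (must be `>= last_update[i]`).
#' @return A `context_message`: list with `vector` (length `2d + d_time`),
#'   `target`, and `t`.
#' @export
context_aggregate <- function(store, enc, i, j, t) {
  stopifnot(t >= store$last_update[i])
  v <- c(store$states[i, ], store$states[j, ],
         encode_time(enc, t - store$last_update[i]))
  structure(list(vector = v, target = as.integer(i), t = as.integer(t)),
            class = "context_message")
}

#' Aggregate several context messages for one concept
#'
#' A concept can co-occur with several others within one step; the paper-level
#' update is defined per co-occurrence, so simultaneous messages are combined
#' by their elementwise mean, which is permutation-invariant and leaves a
#' single message unchanged.
#'
#' @param messages Nonempty list of `context_message`s with a common target
#'   and step.
#' @return One aggregated `context_message`.
#' @export
aggregate_messages <- function(messages) {
  if (length(messages) == 0) stop("cannot aggregate an empty message list")
  tgt <- vapply(messages, `[[`, 0L, "target")
  tt <- vapply(messages, `[[`, 0L, "t")
  stopifnot(all(tgt == tgt[1]), all(tt == tt[1]))
  vecs <- do.call(rbind, lapply(messages, `[[`, "vector"))
  structure(list(vector = colMeans(vecs), target = tgt[1], t = tt[1]),
            class = "context_message")
}

#' Gated recurrent contextual-integration cell
#'
#' Standard GRU gates with input size `2d + d_time` and state size `d`:
#' `r = sigmoid(W_r x + U_r h + b_r)`, `u = sigmoid(W_u x + U_u h + b_u)`,
#' `n = tanh(W_n x + r * (U_n h) + b_n)`, `s' = (1 - u) * n + u * h`.
#' The update-gate bias is initialized positive so fresh cells favor retaining
#' the previous semantic state.
#'
#' @param input_dim Message dimension `2d + d_time`.
#' @param d State dimension.
#' @param seed Seed for Glorot initialization.
#' @param update_bias Initial value of `b_u` (default 1).
#' @return An object of class `gru_cell` (a parameter list).
#' @export
new_gru_cell <- function(input_dim, d, seed = 1L, update_bias = 1) {
  set.seed(derive_seed(seed, 202L))
  structure(list(
    Wr = glorot(input_dim, d), Ur = glorot(d, d), br = numeric(d),
    Wu = glorot(input_dim, d), Uu = glorot(d, d), bu = rep(update_bias, d),
    Wn = glorot(input_dim, d), Un = glorot(d, d), bn = numeric(d)
  ), class = "gru_cell")
}

# Batched GRU forward: X (m x input_dim), H (m x d). Returns the new states
# and intermediates for the backward pass.
gru_forward <- function(cell, X, H) {
  r <- sigmoid(sweep(X %*% cell$Wr + H %*% cell$Ur, 2, cell$br, "+"))
  u <- sigmoid(sweep(X %*% cell$Wu + H %*% cell$Uu, 2, cell$bu, "+"))
  hn <- H %*% cell$Un
  n <- tanh(sweep(X %*% cell$Wn + r * hn, 2, cell$bn, "+"))
  list(S = (1 - u) * n + u * H, r = r, u = u, n = n, hn = hn, X = X, H = H)
}

# Gradients of a batched GRU step with respect to the cell parameters given
# dL/dS. Inputs X and H are treated as constants (detached), so only parameter
# gradients are returned.
gru_backward <- function(cell, fwd, dS) {
  du_pre <- dS * (fwd$H - fwd$n) * fwd$u * (1 - fwd$u)
  dn_pre <- dS * (1 - fwd$u) * (1 - fwd$n^2)
  dr_pre <- dn_pre * fwd$hn * fwd$r * (1 - fwd$r)
  list(
    Wr = t(fwd$X) %*% dr_pre, Ur = t(fwd$H) %*% dr_pre, br = colSums(dr_pre),
    Wu = t(fwd$X) %*% du_pre, Uu = t(fwd$H) %*% du_pre, bu = colSums(du_pre),
    Wn = t(fwd$X) %*% dn_pre, Un = t(fwd$H) %*% (fwd$r * dn_pre),
    bn = colSums(dn_pre)
  )
}

#' One contextual-integration step
#'
#' Integrates a context message with a concept's previous state through the
#' gated recurrent cell, returning the new state vector.
#'
#' @param cell A [new_gru_cell()].
#' @param msg A `context_message` (or a bare numeric vector).
#' @param s_prev Length-`d` previous state.
#' @return Length-`d` updated state.
#' @export
contextual_integrate <- function(cell, msg, s_prev) {
  x <- if (inherits(msg, "context_message")) msg$vector else msg
  if (length(x) != nrow(cell$Wr)) {
    stop("message length ", length(x), " != cell input size ", nrow(cell$Wr))
  }
  if (length(s_prev) != ncol(cell$Wr)) {
    stop("state length ", length(s_prev), " != cell state size ", ncol(cell$Wr))
  }
  drop(gru_forward(cell, matrix(x, 1), matrix(s_prev, 1))$S)
}

# Build the aggregated per-target message matrix for one graphlet. Both
# endpoints of every event receive a message (undirected semantics); all state
# reads use the pre-step states, so the result is independent of event order.
# Returns NULL if there are no events, else list(targets, X, H) with rows
# sorted by target index.
build_step_messages <- function(store, enc, events, t, raw_delta = FALSE) {
  if (nrow(events) == 0) return(NULL)
  targets <- c(events$i, events$j)
  partners <- c(events$j, events$i)
  ord <- order(targets, partners)
  targets <- targets[ord]
  partners <- partners[ord]
  dt <- t - store$last_update[targets]
  denc <- if (raw_delta) matrix(dt, ncol = 1) else {
    m <- encode_time(enc, dt)
    if (is.null(dim(m))) matrix(m, nrow = length(dt)) else m
  }
  msgs <- cbind(store$states[targets, , drop = FALSE],
                store$states[partners, , drop = FALSE], denc)
  agg <- rowsum(msgs, group = targets, reorder = TRUE)
  cnt <- as.vector(rowsum(rep(1, length(targets)), group = targets,
                          reorder = TRUE))
  uniq <- as.integer(rownames(agg))
  list(targets = uniq, X = agg / cnt,
       H = store$states[uniq, , drop = FALSE])
}

#' Apply one graphlet to the state store
#'
#' For every concept touched by at least one event at step `t`, builds its
#' context messages (both endpoints of each event update), mean-aggregates
#' them, integrates through the cell against the pre-step state, and advances
#' `last_update`. All reads use pre-update states (simultaneous semantics), so
#' the result is invariant to event order within the step. Untouched concepts
#' are left bitwise unchanged.
#'
#' @param store A [init_states()] store.
#' @param cell A [new_gru_cell()].
#' @param enc A [time_encoder()].
#' @param events Data frame of events, all at the same step `t`.
#' @param t The step; must exceed the last processed step.
#' @param raw_delta Use the raw scalar `t - tp` instead of its encoding.
#' @param freeze_states Advance bookkeeping but leave states at their current
#'   values (used by the contextual-integration ablation).
#' @return The updated store.
#' @export
apply_graphlet <- function(store, cell, enc, events, t, raw_delta = FALSE,
                           freeze_states = FALSE) {
  t <- as.integer(t)
  if (t <= store$step) {
    stop("graphlets must be applied chronologically: step ", t,
         " after step ", store$step)
  }
  if (nrow(events) > 0 && !all(events$t == t)) {
    stop("events passed to apply_graphlet must all be at step t = ", t)
  }
  store$step <- t
  bs <- build_step_messages(store, enc, events, t, raw_delta = raw_delta)
  if (is.null(bs)) return(store)
  if (!freeze_states) {
    fwd <- gru_forward(cell, bs$X, bs$H)
    store$states[bs$targets, ] <- fwd$S
    if (is.null(store$msg_cache)) {
      store$msg_cache <- matrix(0, nrow(store$states), ncol(bs$X))
    }
    store$msg_cache[bs$targets, ] <- bs$X
    store$prev_cache[bs$targets, ] <- bs$H
    store$has_msg[bs$targets] <- TRUE
  }
  store$last_update[bs$targets] <- t
  store
}
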