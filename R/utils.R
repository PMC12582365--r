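# Internal numeric helpers shared across modules: parameter initialization,
# small feed-forward blocks with analytic gradients, the Adam optimizer, and
# deterministic seed derivation.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Set the global random seed
#'
#' All stochastic components of the package (parameter initialization, negative
#' sampling, synthetic generation, subsampling) draw from R's global RNG stream
#' or from seeds derived deterministically from a user seed, so fixing one seed
#' makes a full run reproducible.
#'
#' @param seed Integer seed, or `NULL` for entropy-based seeding (logged via
#'   `message()` so the run can be reproduced).
#' @return The seed actually used, invisibly.
#' @export
set_global_seed <- function(seed = NULL) {
  if (is.null(seed)) {
    seed <- as.integer(Sys.time()) %% 1000000L
    message("conceptdrift: no seed supplied, using entropy-based seed ", seed)
  }
  set.seed(as.integer(seed))
  invisible(as.integer(seed))
}

# Derive a child seed from a parent seed; keeps results < 2^31 and distinct
# across small offsets.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + as.double(offset) * 9973 + 12345) %% 2147483647)
}

# Glorot/Xavier uniform initialization for a fan_in x fan_out matrix.
glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

zeros_like <- function(p) {
  if (is.list(p)) return(lapply(p, zeros_like))
  p * 0
}

# ---- two-layer perceptron (hidden ReLU, linear output) ---------------------

new_mlp2 <- function(d_in, d_hidden, d_out) {
  list(
    W1 = glorot(d_in, d_hidden), b1 = numeric(d_hidden),
    W2 = glorot(d_hidden, d_out), b2 = numeric(d_out)
  )
}

mlp2_forward <- function(p, X) {
  A <- X %*% p$W1
  A <- sweep(A, 2, p$b1, "+")
  H <- relu(A)
  Y <- sweep(H %*% p$W2, 2, p$b2, "+")
  list(Y = Y, H = H, A = A, X = X)
}

mlp2_backward <- function(p, fwd, dY) {
  dH <- dY %*% t(p$W2)
  dA <- dH * (fwd$A > 0)
  list(
    grads = list(
      W1 = t(fwd$X) %*% dA, b1 = colSums(dA),
      W2 = t(fwd$H) %*% dY, b2 = colSums(dY)
    ),
    dX = dA %*% t(p$W1)
  )
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

# params and grads are parallel (possibly nested) lists of numeric arrays.
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(
        p = lapply(out, `[[`, "p"),
        m = lapply(out, `[[`, "m"),
        v = lapply(out, `[[`, "v")
      )
    } else {
      upd(p, g, m, v)
    }
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}

# Accumulate one grads list into another (same structure).
acc_grads <- function(a, b) {
  if (is.list(a)) return(Map(acc_grads, a, b))
  a + b
}

# FNV-1a hash of a character vector; used to fingerprint vocabularies in
# saved model directories without external dependencies.
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (as.double(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

bce_loss <- function(prob, label) {
  p <- clamp_prob(prob)
  -mean(label * log(p) + (1 - label) * log(1 - p))
}
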