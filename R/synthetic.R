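# Synthetic dynamic co-occurrence graphs with planted conceptual drift.
# Concepts live in a latent space organized into clusters; positions take a
# Gaussian random walk each step, and a configurable set of planted pairs is
# additionally contracted toward each other so that, like emerging biomedical
# connections, they become close -- and only then co-occur -- late in the
# horizon. Edges are sampled with a logistic probability in latent distance,
# so concepts that are close share neighbors by construction (the
# distributional-hypothesis premise holds in the generated world).

#' Configuration of the synthetic drift generator
#'
#' @param n_concepts Number of concepts.
#' @param horizon Number of time steps `T`.
#' @param latent_dim Latent-space dimension.
#' @param n_clusters Number of latent clusters.
#' @param drift_rate Per-step, per-coordinate random-walk standard deviation.
#' @param converge_pairs Number of planted pairs (endpoints drawn from
#'   different clusters) pulled together over time; must be `<= n_concepts/2`.
#' @param converge_rate Per-step fraction each planted endpoint moves toward
#'   its partner (pair distance contracts by `1 - 2 * converge_rate` per step
#'   once the pair's onset step is reached).
#' @param converge_threshold Latent distance below which a planted pair stops
#'   being withheld and may co-occur.
#' @param edge_scale Logistic intercept: an edge `(i, j)` at step `t` appears
#'   with probability `sigmoid(edge_scale - ||x_i(t) - x_j(t)||)`. The default
#'   `NULL` calibrates the intercept analytically so the expected edge count at
#'   the initial positions matches `degree_target`.
#' @param degree_target Expected mean degree per step used to calibrate
#'   `edge_scale` when it is `NULL` (default 4, a sparse concept graph).
#' @param center_scale Std. dev. of cluster centers.
#' @param cluster_spread Std. dev. of concepts around their cluster center.
#' @param d_emb Dimension of the synthetic concept embeddings.
#' @param embedding_noise Std. dev. of embedding noise.
#' @param embedding_map `"random"` (seeded linear map from initial latent
#'   positions) or `"identity"` (requires `d_emb == latent_dim`).
#' @param seed Integer seed.
#' @return List of class `drift_config`.
#' @export
drift_config <- function(n_concepts = 300L, horizon = 12L, latent_dim = 8L,
                         n_clusters = 4L, drift_rate = 0.2,
                         converge_pairs = 30L, converge_rate = 0.12,
                         converge_threshold = 2.0, edge_scale = NULL,
                         degree_target = 4, center_scale = 1.5,
                         cluster_spread = 0.7,
                         d_emb = 16L, embedding_noise = 0.1,
                         embedding_map = c("random", "identity"), seed = 1L) {
  embedding_map <- match.arg(embedding_map)
  stopifnot(n_concepts > 0, horizon > 0, latent_dim > 0, n_clusters > 0,
            drift_rate >= 0, converge_pairs >= 0,
            converge_pairs <= n_concepts / 2)
  structure(as.list(environment()), class = "drift_config")
}

#' Generate a dynamic co-occurrence graph with planted drift
#'
#' @param cfg A [drift_config()].
#' @return List of class `drift_sim` with:
#'   * `graph`: the [temporal_graph()] (ids `C0001`, `C0002`, ...);
#'   * `trajectories`: `n_concepts x latent_dim x (horizon + 1)` array of
#'     latent positions (slice 1 is `t = 0`);
#'   * `planted`: data frame `i`, `j`, `onset` (step at which contraction
#'     starts), `converge_step` (first step with distance below threshold,
#'     `NA` if never);
#'   * `clusters`: cluster assignment;
#'   * `cfg`: the config.
#' @export
generate_dynamic_graph <- function(cfg) {
  stopifnot(inherits(cfg, "drift_config"))
  set.seed(derive_seed(cfg$seed, 11L))
  n <- cfg$n_concepts
  L <- cfg$latent_dim
  Tn <- cfg$horizon

  centers <- matrix(stats::rnorm(cfg$n_clusters * L, 0, cfg$center_scale),
                    cfg$n_clusters, L)
  clusters <- sample(rep_len(seq_len(cfg$n_clusters), n))
  X <- centers[clusters, , drop = FALSE] +
    matrix(stats::rnorm(n * L, 0, cfg$cluster_spread), n, L)

  # planted pairs: disjoint endpoints, drawn from different clusters where
  # possible so they start far apart and genuinely "emerge"
  planted <- data.frame(i = integer(0), j = integer(0), onset = integer(0))
  if (cfg$converge_pairs > 0) {
    avail <- sample.int(n)
    pi_ <- integer(cfg$converge_pairs)
    pj_ <- integer(cfg$converge_pairs)
    for (k in seq_len(cfg$converge_pairs)) {
      a <- avail[1]
      avail <- avail[-1]
      other <- which(clusters[avail] != clusters[a])
      pick <- if (length(other) > 0) other[1] else 1L
      b <- avail[pick]
      avail <- avail[-pick]
      pi_[k] <- min(a, b)
      pj_[k] <- max(a, b)
    }
    onset <- sample.int(max(1L, Tn %/% 2L), cfg$converge_pairs, replace = TRUE)
    planted <- data.frame(i = pi_, j = pj_, onset = onset)
  }

  # resolve the logistic intercept: expected edges at the initial positions
  # match the target mean degree
  if (is.null(cfg$edge_scale)) {
    D0 <- as.matrix(stats::dist(X))
    ut0 <- upper.tri(D0)
    target <- n * cfg$degree_target / 2
    cfg$edge_scale <- stats::uniroot(
      function(es) sum(sigmoid(es - D0[ut0])) - target, c(-50, 50)
    )$root
  }

  traj <- array(NA_real_, c(n, L, Tn + 1L))
  traj[, , 1] <- X
  events <- vector("list", Tn)
  planted_key <- paste(planted$i, planted$j)
  converge_step <- rep(NA_integer_, nrow(planted))

  for (t in seq_len(Tn)) {
    X <- X + matrix(stats::rnorm(n * L, 0, cfg$drift_rate), n, L)
    if (nrow(planted) > 0) {
      act <- which(planted$onset <= t)
      for (k in act) {
        i <- planted$i[k]; j <- planted$j[k]
        di <- X[j, ] - X[i, ]
        X[i, ] <- X[i, ] + cfg$converge_rate * di
        X[j, ] <- X[j, ] - cfg$converge_rate * di
      }
    }
    traj[, , t + 1L] <- X
    D <- as.matrix(stats::dist(X))
    P <- sigmoid(cfg$edge_scale - D)
    ut <- upper.tri(P)
    if (t == 1 && sum(P[ut]) < 0.5) {
      stop("drift_config yields ~zero expected edges per step ",
           "(expected ", round(sum(P[ut]), 3), " at t = 1); ",
           "increase edge_scale or reduce latent distances")
    }
    # withhold planted pairs until their distance falls below the threshold
    if (nrow(planted) > 0) {
      pd <- D[cbind(planted$i, planted$j)]
      newly <- which(is.na(converge_step) & pd < cfg$converge_threshold)
      converge_step[newly] <- t
      block <- which(pd >= cfg$converge_threshold)
      P[cbind(planted$i[block], planted$j[block])] <- 0
      P[cbind(planted$j[block], planted$i[block])] <- 0
    }
    draw <- matrix(stats::runif(n * n), n, n)
    hit <- which(ut & draw < P, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      events[[t]] <- data.frame(t = t, i = hit[, 1], j = hit[, 2])
    }
  }
  ev <- do.call(rbind, events)
  if (is.null(ev)) ev <- data.frame(t = integer(), i = integer(), j = integer())
  ids <- sprintf("C%04d", seq_len(n))
  graph <- temporal_graph(ids, Tn, ev,
                          names = sprintf("concept %04d", seq_len(n)))
  planted$converge_step <- converge_step
  structure(list(graph = graph, trajectories = traj, planted = planted,
                 clusters = clusters, cfg = cfg),
            class = "drift_sim")
}

#' @export
print.drift_sim <- function(x, ...) {
  cat("<drift_sim>", n_concepts(x$graph), "concepts, T =", x$graph$horizon,
      ",", nrow(x$graph$events), "events,", nrow(x$planted), "planted pairs\n")
  invisible(x)
}

#' Generate correlated synthetic concept embeddings
#'
#' Stands in for pre-computed language-model embeddings: the embedding of a
#' concept is a linear map of its initial latent position plus Gaussian noise,
#' so embeddings carry the (initial) semantic geometry of the world without
#' revealing its temporal evolution.
#'
#' @param sim A [generate_dynamic_graph()] result.
#' @param cfg The [drift_config()] (defaults to `sim$cfg`).
#' @return `n_concepts x d_emb` matrix with `graph$ids` as row names.
#' @export
generate_embeddings <- function(sim, cfg = sim$cfg) {
  X0 <- sim$trajectories[, , 1]
  n <- nrow(X0)
  L <- ncol(X0)
  set.seed(derive_seed(cfg$seed, 21L))
  if (cfg$embedding_map == "identity") {
    if (cfg$d_emb != L) stop("identity embedding map requires d_emb == latent_dim")
    E <- X0
  } else {
    A <- matrix(stats::rnorm(L * cfg$d_emb, 0, 1 / sqrt(L)), L, cfg$d_emb)
    E <- X0 %*% A
  }
  if (cfg$embedding_noise > 0) {
    E <- E + matrix(stats::rnorm(n * cfg$d_emb, 0, cfg$embedding_noise),
                    n, cfg$d_emb)
  }
  rownames(E) <- sim$graph$ids
  E
}

#' Write / read a dense embedding matrix as tab-separated text
#'
#' First column is the concept id, remaining columns are the embedding values;
#' row order is free (rows are joined on id against the vocabulary on read).
#'
#' @param embeddings Matrix with concept ids as row names.
#' @param path Output path.
#' @param ids Vocabulary order to return rows in.
#' @return `read_embeddings()` returns the matrix aligned to `ids`.
#' @export
write_embeddings <- function(embeddings, path) {
  df <- data.frame(id = rownames(embeddings), as.data.frame(embeddings))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path, ids) {
  df <- utils::read.table(path, sep = "\t", quote = "", comment.char = "#",
                          colClasses = c("character", rep(NA, -1 + length(
                            strsplit(readLines(path, n = 1), "\t")[[1]]))))
  m <- match(ids, df[[1]])
  if (anyNA(m)) stop("embedding file missing concept id(s): ",
                     paste(utils::head(ids[is.na(m)], 5), collapse = ", "))
  out <- as.matrix(df[m, -1, drop = FALSE])
  rownames(out) <- ids
  storage.mode(out) <- "double"
  out
}
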