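# Empirical validation of conceptual drift. Two concepts are similar at time
# t when their neighborhoods (the sets of concepts each has co-occurred with
# up to t) overlap; co-occurring pairs should therefore show higher
# neighborhood overlap than random non-co-occurring pairs, and semantic-state
# trajectories of converging pairs should approach each other in a pooled
# principal-component projection.

#' Jaccard similarity of two sets
#'
#' `|a intersect b| / |a union b|`, with the empty-sets case defined as 0.
#'
#' @param a,b Vectors interpreted as sets.
#' @return Value in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

# Adjacency sets (neighbor lists) from all events at steps <= t.
adjacency_upto <- function(graph, t) {
  adj <- rep(list(integer(0)), n_concepts(graph))
  ev <- graph$events[graph$events$t <= t, , drop = FALSE]
  if (nrow(ev) > 0) {
    for (side in 1:2) {
      a <- if (side == 1) ev$i else ev$j
      b <- if (side == 1) ev$j else ev$i
      sp <- split(b, a)
      for (k in names(sp)) {
        adj[[as.integer(k)]] <- unique(c(adj[[as.integer(k)]], sp[[k]]))
      }
    }
  }
  adj
}

#' Neighborhood-overlap report at a time step
#'
#' Compares the Jaccard overlap of the neighborhoods (history strictly before
#' `t`, so the statistic is predictive rather than circular) of pairs
#' co-occurring at `t` against uniformly sampled pairs not co-occurring at
#' `t`.
#'
#' @param graph A [temporal_graph()].
#' @param t Time step (`>= 1`).
#' @param n_samples Maximum co-occurring pairs used and number of
#'   non-co-occurring pairs sampled (must be positive).
#' @param seed Seed for sampling.
#' @return List of class `overlap_report` with mean/median Jaccard for both
#'   groups, the gap of means, sample sizes and `t`.
#' @export
overlap_report <- function(graph, t, n_samples = 500L, seed = 1L) {
  t <- as.integer(t)
  stopifnot(t >= 1, t <= graph$horizon)
  if (n_samples <= 0) stop("n_samples must be positive")
  ev <- events_at(graph, t)
  if (nrow(ev) == 0) stop("no co-occurring pairs at step ", t)
  set.seed(derive_seed(seed, 31L))
  if (nrow(ev) > n_samples) {
    ev <- ev[sort(sample.int(nrow(ev), n_samples)), , drop = FALSE]
  }
  adj <- adjacency_upto(graph, t - 1L)
  co_j <- vapply(seq_len(nrow(ev)),
                 function(k) jaccard(adj[[ev$i[k]]], adj[[ev$j[k]]]), 0)
  # uniform non-co-occurring pairs at step t
  nv <- n_concepts(graph)
  all_t <- events_at(graph, t)
  forbid <- paste(all_t$i, all_t$j)
  got <- matrix(0L, 0, 2)
  tries <- 0L
  while (nrow(got) < n_samples) {
    m <- 2L * (n_samples - nrow(got)) + 16L
    tries <- tries + m
    if (tries > 200L * n_samples + 10000L) {
      stop("could not sample non-co-occurring pairs at step ", t)
    }
    a <- sample.int(nv, m, replace = TRUE)
    b <- sample.int(nv, m, replace = TRUE)
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    ok <- lo != hi & !(paste(lo, hi) %in% forbid)
    got <- rbind(got, cbind(lo[ok], hi[ok]))
  }
  got <- got[seq_len(n_samples), , drop = FALSE]
  non_j <- vapply(seq_len(nrow(got)),
                  function(k) jaccard(adj[[got[k, 1]]], adj[[got[k, 2]]]), 0)
  structure(list(
    t = t,
    co_mean = mean(co_j), co_median = stats::median(co_j),
    non_mean = mean(non_j), non_median = stats::median(non_j),
    gap = mean(co_j) - mean(non_j),
    n_co = length(co_j), n_non = length(non_j)
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(paste0("<overlap_report> step %d: co-occurring mean Jaccard ",
                     "%.4f (n = %d) vs non-co-occurring %.4f (n = %d), ",
                     "gap %.4f\n"),
              x$t, x$co_mean, x$n_co, x$non_mean, x$n_non, x$gap))
  invisible(x)
}

#' Project semantic-state trajectories onto shared principal components
#'
#' Fits one principal-component basis on the pooled per-step states of the
#' selected concepts (so trajectories are comparable across time) and projects
#' each concept's per-step state onto the top two components. Component signs
#' follow the convention that the first nonzero loading of each component is
#' positive, making the projection deterministic.
#'
#' @param snapshots Named list of `|V| x d` state matrices (e.g. from
#'   [replay_states()]); names are capture steps.
#' @param concepts Integer vector of concept indices to track.
#' @return List of `trajectory_record`s: `concept`, `steps`, and an
#'   `n_steps x 2` coordinate matrix.
#' @export
track_trajectories <- function(snapshots, concepts) {
  if (length(snapshots) < 2) stop("need at least 2 state snapshots")
  concepts <- as.integer(concepts)
  steps <- names(snapshots)
  pooled <- do.call(rbind, lapply(snapshots, function(S) {
    S[concepts, , drop = FALSE]
  }))
  if (nrow(unique(pooled)) < 2) {
    stop("fewer than 2 distinct state vectors; nothing to project")
  }
  pc <- stats::prcomp(pooled, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  if (k < 2) rot <- cbind(rot, 0)
  for (c_ in 1:2) {
    nz <- which(abs(rot[, c_]) > 1e-12)
    if (length(nz) > 0 && rot[nz[1], c_] < 0) rot[, c_] <- -rot[, c_]
  }
  ctr <- pc$center
  lapply(seq_along(concepts), function(m) {
    coords <- t(vapply(snapshots, function(S) {
      drop((S[concepts[m], ] - ctr) %*% rot)
    }, numeric(2)))
    rownames(coords) <- steps
    structure(list(concept = concepts[m], steps = steps, coords = coords),
              class = "trajectory_record")
  })
}

#' Per-step distance between two projected trajectories
#'
#' @param record_i,record_j `trajectory_record`s over the same capture steps.
#' @return Named numeric vector of Euclidean distances per captured step.
#' @export
convergence_curve <- function(record_i, record_j) {
  if (!identical(record_i$steps, record_j$steps)) {
    stop("trajectory records cover different capture steps")
  }
  d <- sqrt(rowSums((record_i$coords - record_j$coords)^2))
  names(d) <- record_i$steps
  d
}
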