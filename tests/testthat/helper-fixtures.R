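# Shared fixtures: tiny hand-built graphs, a small annotation file, a compact
# synthetic world and a fast model configuration. Everything is generated in
# code at test time.

# Hand-built toy graph: 5 concepts, T = 4.
toy_graph <- function() {
  ev <- data.frame(
    t = c(1L, 1L, 2L, 3L, 3L),
    i = c(1L, 2L, 1L, 2L, 4L),
    j = c(2L, 3L, 3L, 4L, 5L)
  )
  temporal_graph(paste0("M", 1:5), 4L, ev)
}

# Annotation file content used by the construction tests (10 articles).
write_toy_annotations <- function(path) {
  lines <- c(
    "# PubTator-style export",
    "article_id\tyear\tconcept_id\tconcept_type\tconcept_name",
    "A1\t2001\tD001\tMeSH\talpha",
    "A1\t2001\tD002\tMeSH\tbeta",
    "A1\t2001\tD003\tMeSH\tgamma",
    "A2\t2001\tD001\tMeSH\talpha",
    "A2\t2001\tD002\tMeSH\tbeta",
    "A3\t2002\tD002\tMeSH\tbeta",
    "A3\t2002\tD004\tMeSH\tdelta",
    "A4\t2002\t\tMeSH\tmissing-id",
    "A5\t2002\tG999\tGene\tsome-gene",
    "A6\t2003\tD005\tMeSH\tepsilon"
  )
  writeLines(lines, path)
  path
}

# Small synthetic world for fast end-to-end tests (50 concepts).
small_drift_config <- function(seed = 1L, ...) {
  drift_config(n_concepts = 50L, horizon = 8L, n_clusters = 3L,
               converge_pairs = 5L, seed = seed, ...)
}

# Fast model configuration matched to the small world.
small_model_config <- function(seed = 1L, epochs = 4L, ...) {
  model_config(time_dim = 4L, heads = 2L, attn_dim = 8L, dz = 8L,
               score_hidden = 8L, epochs = epochs, neighbor_cap = 10,
               seed = seed, ...)
}

small_trained <- function(seed = 1L, mcfg = small_model_config(seed)) {
  sim <- generate_dynamic_graph(small_drift_config(seed))
  emb <- generate_embeddings(sim)
  g <- sim$graph
  split <- split_spec(g$horizon - 2L, g$horizon - 1L, g$horizon)
  list(sim = sim, graph = g, emb = emb, split = split,
       fit = train(g, split, emb, mcfg))
}

# Brute-force single-query softmax attention (independent oracle).
oracle_attention <- function(q, kv, Wq, Wk, Wv, Wo, heads) {
  if (nrow(kv) == 0) return(numeric(ncol(Wq)))
  A <- ncol(Wq)
  dh <- A / heads
  qp <- as.numeric(q %*% Wq)
  Kp <- kv %*% Wk
  Vp <- kv %*% Wv
  out <- numeric(A)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    s <- as.numeric(Kp[, cols, drop = FALSE] %*% qp[cols]) / sqrt(dh)
    w <- exp(s) / sum(exp(s))
    out[cols] <- colSums(Vp[, cols, drop = FALSE] * w)
  }
  as.numeric(out %*% Wo)
}

# Exhaustive pairwise AUC (independent oracle).
oracle_auc <- function(scores, labels) {
  ps <- scores[labels == 1]
  ns <- scores[labels == 0]
  tot <- 0
  for (p in ps) for (n in ns) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(ps) * length(ns))
}

# Rank-walk AP (independent oracle, stable tie-break by index).
oracle_ap <- function(scores, labels) {
  ord <- order(-scores)
  y <- labels[ord]
  hits <- 0
  precs <- c()
  for (k in seq_along(y)) {
    if (y[k] == 1) {
      hits <- hits + 1
      precs <- c(precs, hits / k)
    }
  }
  mean(precs)
}
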