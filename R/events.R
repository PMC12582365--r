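# Construction of the dynamic concept co-occurrence graph: annotation parsing,
# filtering, graphlet sequence assembly, neighborhoods, temporal splits,
# leakage removal, and uniform negative sampling.

#' Construct a temporal co-occurrence graph
#'
#' A temporal graph is a fixed concept vocabulary `V` plus a chronologically
#' sorted table of edge events `(t, i, j)`, one per unordered concept pair and
#' time step. Time steps are 1-based; `t = 0` is reserved for the empty
#' graphlet `E_0` (the state before any literature is observed), so events at
#' `t = 0` are rejected.
#'
#' @param ids Character vector of concept identifiers (defines node indices).
#' @param horizon Total number of time steps `T`.
#' @param events Data frame with integer columns `t`, `i`, `j` (1-based concept
#'   indices). Pairs are canonicalized to `i < j`, duplicates within a step are
#'   collapsed, and rows are sorted by `(t, i, j)`.
#' @param names Character vector of human-readable concept names.
#' @return An object of class `temporal_graph`.
#' @export
temporal_graph <- function(ids, horizon, events, names = ids) {
  stopifnot(is.character(ids), length(ids) >= 1, !anyDuplicated(ids))
  horizon <- as.integer(horizon)
  if (is.null(events) || nrow(events) == 0) {
    events <- data.frame(t = integer(), i = integer(), j = integer())
  }
  events <- data.frame(
    t = as.integer(events$t),
    i = as.integer(events$i),
    j = as.integer(events$j)
  )
  if (nrow(events) > 0) {
    if (any(events$t < 1)) {
      stop("edge events at t <= 0 are not allowed: E_0 is the empty graphlet")
    }
    if (any(events$t > horizon)) stop("edge event beyond horizon T = ", horizon)
    if (any(events$i == events$j)) stop("self-pairs (i == j) are not allowed")
    rng <- range(c(events$i, events$j))
    if (rng[1] < 1 || rng[2] > length(ids)) stop("concept index out of range")
    lo <- pmin(events$i, events$j)
    hi <- pmax(events$i, events$j)
    events$i <- lo
    events$j <- hi
    events <- unique(events)
    events <- events[order(events$t, events$i, events$j), , drop = FALSE]
    rownames(events) <- NULL
  }
  structure(
    list(ids = ids, names = names, horizon = horizon, events = events),
    class = "temporal_graph"
  )
}

#' @export
print.temporal_graph <- function(x, ...) {
  cat("<temporal_graph> |V| =", length(x$ids), " T =", x$horizon,
      " |E| =", nrow(x$events), "events\n")
  invisible(x)
}

#' Number of concepts in a graph's vocabulary
#' @param graph A [temporal_graph()].
#' @return Integer `|V|`.
#' @export
n_concepts <- function(graph) length(graph$ids)

#' Events of one graphlet
#' @param graph A [temporal_graph()].
#' @param t Time step.
#' @return The rows of `graph$events` at step `t` (the edge set `E_t`).
#' @export
events_at <- function(graph, t) {
  graph$events[graph$events$t == as.integer(t), , drop = FALSE]
}

#' Temporal train/validation/test split
#'
#' @param train_end Last training time step.
#' @param val_step Validation time step.
#' @param test_step Test time step.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_end, val_step, test_step) {
  train_end <- as.integer(train_end)
  val_step <- as.integer(val_step)
  test_step <- as.integer(test_step)
  if (!(train_end < val_step && val_step < test_step)) {
    stop("require train_end < val_step < test_step")
  }
  structure(list(train_end = train_end, val_step = val_step,
                 test_step = test_step), class = "split_spec")
}

#' Parse PubTator-style annotation records
#'
#' Reads a tab-separated file with columns `article_id`, `year`, `concept_id`,
#' `concept_type`, `concept_name`. Lines starting with `#` are comments; a
#' header line (second field non-numeric) is detected and skipped. Fields are
#' kept raw; no normalization is applied at parse time.
#'
#' @param path Path to the annotation file.
#' @return A data frame with one row per well-formed line, in file order, with
#'   attribute `skipped` listing line numbers of malformed lines (wrong column
#'   count or non-integer year), which are also reported via `warning()`.
#' @export
parse_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lineno <- seq_along(lines)[keep]
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) > 0) {
    f1 <- fields[[1]]
    if (length(f1) == 5 && is.na(suppressWarnings(as.integer(f1[2])))) {
      fields <- fields[-1]
      lineno <- lineno[-1]
    }
  }
  nfld <- lengths(fields)
  yr <- rep(NA_integer_, length(fields))
  yr[nfld == 5] <- suppressWarnings(
    as.integer(vapply(fields[nfld == 5], `[[`, "", 2))
  )
  bad <- nfld != 5 | is.na(yr)
  if (any(bad)) {
    warning("skipped ", sum(bad), " malformed annotation line(s): ",
            paste(lineno[bad], collapse = ", "))
  }
  fields <- fields[!bad]
  out <- data.frame(
    article_id = vapply(fields, `[[`, "", 1),
    year = yr[!bad],
    concept_id = vapply(fields, `[[`, "", 3),
    concept_type = vapply(fields, `[[`, "", 4),
    concept_name = vapply(fields, `[[`, "", 5),
    stringsAsFactors = FALSE
  )
  attr(out, "skipped") <- lineno[bad]
  out
}

#' Filter annotation records to usable concepts
#'
#' Applies the two record-level noise filters used when building the concept
#' graph: (i) records with a missing/blank concept id are removed; (ii) only
#' concepts of the configured controlled-vocabulary type (MeSH by default) are
#' kept. Order is preserved.
#'
#' @param records Data frame from [parse_annotations()].
#' @param mesh_tag Concept-type tag that marks MeSH terms in this PubTator
#'   dialect (default `"MeSH"`).
#' @return The filtered data frame.
#' @export
filter_annotations <- function(records, mesh_tag = "MeSH") {
  keep <- nzchar(trimws(records$concept_id)) & records$concept_type == mesh_tag
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the temporal graphlet sequence from filtered annotations
#'
#' Every unordered pair of distinct concepts annotated in the same article
#' yields one edge event at the article's time step; within-step duplicates
#' collapse to a single unweighted event. Years map to steps as
#' `t = year - first_year + 1`, leaving `t = 0` as the empty graphlet.
#'
#' @param records Filtered annotation data frame.
#' @param first_year,last_year Inclusive calendar range of the corpus; a record
#'   outside it is an error.
#' @return A [temporal_graph()].
#' @export
build_temporal_graph <- function(records, first_year, last_year) {
  if (nrow(records) == 0) stop("no annotation records to build a graph from")
  if (any(records$year < first_year | records$year > last_year)) {
    bad <- which(records$year < first_year | records$year > last_year)[1]
    stop("record year ", records$year[bad], " outside corpus range [",
         first_year, ", ", last_year, "]")
  }
  ids <- sort(unique(records$concept_id))
  name_of <- records$concept_name[!duplicated(records$concept_id)]
  names(name_of) <- records$concept_id[!duplicated(records$concept_id)]
  idx <- match(records$concept_id, ids)
  t <- records$year - as.integer(first_year) + 1L
  horizon <- as.integer(last_year) - as.integer(first_year) + 1L
  key <- split(seq_len(nrow(records)), paste(records$article_id, t))
  ev <- lapply(key, function(rows) {
    u <- sort(unique(idx[rows]))
    if (length(u) < 2) return(NULL)
    pr <- utils::combn(u, 2)
    data.frame(t = t[rows[1]], i = pr[1, ], j = pr[2, ])
  })
  ev <- do.call(rbind, ev)
  if (is.null(ev)) ev <- data.frame(t = integer(), i = integer(), j = integer())
  temporal_graph(ids, horizon, ev, names = unname(name_of[ids]))
}

#' Neighborhood of a concept up to a time step
#'
#' The neighborhood of concept `i` at step `t` is the set of concepts that
#' have co-occurred with `i` at least once at steps `1..t`. Neighborhoods are
#' monotone in `t`, and `neighborhood(graph, i, 0)` is empty since `E_0` is.
#'
#' @param graph A [temporal_graph()].
#' @param i Concept index.
#' @param t Time step in `0..T`.
#' @return Sorted integer vector of neighbor indices.
#' @export
neighborhood <- function(graph, i, t) {
  i <- as.integer(i)
  t <- as.integer(t)
  if (i < 1 || i > n_concepts(graph)) stop("concept index out of range: ", i)
  if (t < 0 || t > graph$horizon) stop("time step out of range: ", t)
  ev <- graph$events
  ev <- ev[ev$t <= t & (ev$i == i | ev$j == i), , drop = FALSE]
  if (nrow(ev) == 0) return(integer(0))
  sort(unique(as.integer(ifelse(ev$i == i, ev$j, ev$i))))
}

canonical_pairs <- function(pairs) {
  pairs <- as.data.frame(pairs)[, 1:2]
  names(pairs) <- c("i", "j")
  data.frame(i = pmin(pairs$i, pairs$j), j = pmax(pairs$i, pairs$j))
}

#' Remove candidate pairs already seen in history
#'
#' Evaluation-time leakage removal: any candidate pair with an edge event at a
#' step strictly before `before` is dropped, so only genuinely new
#' co-occurrences remain as positives.
#'
#' @param candidates Data frame (or 2-column matrix) of concept index pairs.
#' @param graph A [temporal_graph()].
#' @param before Time step; events at steps `< before` count as history.
#' @return The surviving candidate pairs (canonicalized `i < j`).
#' @export
remove_seen_pairs <- function(candidates, graph, before) {
  cand <- canonical_pairs(candidates)
  hist <- graph$events[graph$events$t < as.integer(before), , drop = FALSE]
  seen <- paste(hist$i, hist$j)
  out <- cand[!(paste(cand$i, cand$j) %in% seen), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Labeled pair samples
#'
#' @param i,j Concept indices.
#' @param t Target time step.
#' @param label 1 for an observed co-occurrence, 0 for a sampled negative.
#' @return Data frame of class `pair_samples`.
#' @export
pair_samples <- function(i, j, t, label) {
  out <- data.frame(i = as.integer(i), j = as.integer(j),
                    t = as.integer(t), label = as.integer(label))
  class(out) <- c("pair_samples", "data.frame")
  out
}

#' Uniformly sample negative (non-co-occurring) pairs
#'
#' Draws `ceiling(ratio * nrow(positives))` concept pairs uniformly from the
#' vocabulary, rejecting self-pairs, pairs present in `E_t` at the positives'
#' time step and, optionally, pairs present at any earlier step. Sampling is
#' deterministic under `seed`.
#'
#' @param positives `pair_samples` at a single time step `t`.
#' @param graph A [temporal_graph()].
#' @param ratio Negatives per positive (default 1 for the 1:1 protocol).
#' @param seed Integer seed.
#' @param exclude_history Also reject pairs with events at steps `< t`
#'   (default `FALSE`: uniform sampling rejects only current positives).
#' @return `pair_samples` with label 0.
#' @export
sample_negatives <- function(positives, graph, ratio = 1, seed = 1L,
                             exclude_history = FALSE) {
  stopifnot(ratio > 0, nrow(positives) > 0)
  nv <- n_concepts(graph)
  if (nv < 3) stop("need at least 3 concepts to sample negatives")
  t <- positives$t[1]
  stopifnot(all(positives$t == t))
  need <- as.integer(ceiling(ratio * nrow(positives)))
  ev <- events_at(graph, t)
  forbid <- paste(ev$i, ev$j)
  if (exclude_history) {
    hist <- graph$events[graph$events$t < t, , drop = FALSE]
    forbid <- c(forbid, paste(hist$i, hist$j))
  }
  set.seed(as.integer(seed))
  got_i <- integer(0)
  got_j <- integer(0)
  tries <- 0L
  max_tries <- 200L * need + 10000L
  while (length(got_i) < need) {
    m <- 2L * (need - length(got_i)) + 16L
    tries <- tries + m
    if (tries > max_tries) {
      stop("graph too dense at step ", t,
           ": could not sample ", need, " negatives")
    }
    a <- sample.int(nv, m, replace = TRUE)
    b <- sample.int(nv, m, replace = TRUE)
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    ok <- lo != hi & !(paste(lo, hi) %in% forbid)
    got_i <- c(got_i, lo[ok])
    got_j <- c(got_j, hi[ok])
  }
  pair_samples(got_i[seq_len(need)], got_j[seq_len(need)], t, 0L)
}

#' Write / read a temporal graph as plain text
#'
#' `write_edge_events()` writes two tab-separated files: `<prefix>.events.tsv`
#' (`# horizon: T` header comment, then columns `t`, `concept_id_i`,
#' `concept_id_j`) and `<prefix>.vocab.tsv` (`concept_id`, `concept_name`, one
#' per line; row order defines node indices). `read_edge_events()` inverts it;
#' round-tripping is the identity on vocabulary, horizon and events.
#'
#' @param graph A [temporal_graph()].
#' @param prefix Path prefix for the two files.
#' @return `write_edge_events()` returns the prefix invisibly;
#'   `read_edge_events()` returns a [temporal_graph()].
#' @export
write_edge_events <- function(graph, prefix) {
  evp <- paste0(prefix, ".events.tsv")
  vcp <- paste0(prefix, ".vocab.tsv")
  con <- file(evp, "w")
  on.exit(close(con))
  writeLines(paste0("# horizon: ", graph$horizon), con)
  if (nrow(graph$events) > 0) {
    writeLines(paste(graph$events$t, graph$ids[graph$events$i],
                     graph$ids[graph$events$j], sep = "\t"), con)
  }
  utils::write.table(
    data.frame(id = graph$ids, name = graph$names),
    vcp, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(prefix)
}

#' @rdname write_edge_events
#' @export
read_edge_events <- function(prefix) {
  evp <- paste0(prefix, ".events.tsv")
  vcp <- paste0(prefix, ".vocab.tsv")
  if (!file.exists(evp) || !file.exists(vcp)) {
    stop("missing edge-event or vocabulary file for prefix ", prefix)
  }
  voc <- utils::read.table(vcp, sep = "\t", quote = "", comment.char = "",
                           colClasses = "character")
  ids <- voc[[1]]
  nms <- if (ncol(voc) >= 2) voc[[2]] else ids
  lines <- readLines(evp)
  horizon <- NA_integer_
  hl <- grep("^# *horizon:", lines, value = TRUE)
  if (length(hl) > 0) horizon <- as.integer(sub("^# *horizon: *", "", hl[1]))
  data_lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(data_lines) > 0) {
    fields <- strsplit(data_lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != 3)
    if (length(bad) > 0) stop("malformed edge-event line(s): ",
                              paste(bad, collapse = ", "))
    t <- as.integer(vapply(fields, `[[`, "", 1))
    ai <- vapply(fields, `[[`, "", 2)
    aj <- vapply(fields, `[[`, "", 3)
    mi <- match(ai, ids)
    mj <- match(aj, ids)
    if (anyNA(mi) || anyNA(mj)) {
      stop("unknown concept id in event file: ",
           paste(unique(c(ai[is.na(mi)], aj[is.na(mj)])), collapse = ", "))
    }
    if (anyNA(t) || any(t < 1)) {
      stop("edge events must have integer t >= 1 (E_0 is empty)")
    }
    ev <- data.frame(t = t, i = mi, j = mj)
  } else {
    ev <- data.frame(t = integer(), i = integer(), j = integer())
  }
  if (is.na(horizon)) horizon <- if (nrow(ev) > 0) max(ev$t) else 1L
  temporal_graph(ids, horizon, ev, names = nms)
}
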