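# Graph construction: parsing, filtering, graphlet assembly, neighborhoods,
# leakage removal, negative sampling, and the text round-trip.

test_that("parse_annotations reads well-formed files and reports bad lines", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A1\t2001\tD001\tMeSH\talpha",
               "A2\t2002\tD002\tMeSH\tbeta",
               "A3\t2003\tD003\tMeSH\tgamma"), f)
  rec <- parse_annotations(f)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$concept_id, c("D001", "D002", "D003"))
  expect_equal(rec$year, 2001:2003)

  writeLines(character(0), f)
  expect_equal(nrow(parse_annotations(f)), 0)

  good <- sprintf("A%d\t2001\tD%03d\tMeSH\tx", 1:10, 1:10)
  writeLines(append(good, "BAD\t2001\tD999\tMeSH", after = 5), f)
  expect_warning(rec <- parse_annotations(f), "skipped 1")
  expect_equal(nrow(rec), 10)
  expect_equal(attr(rec, "skipped"), 6L)

  expect_error(parse_annotations(file.path(tempdir(), "nope.tsv")),
               "not found")
})

test_that("filter_annotations applies the missing-id and MeSH-type rules", {
  rec <- data.frame(
    article_id = c("A", "A", "A", "A"),
    year = 2001L,
    concept_id = c("", "D010300", "G1", "  "),
    concept_type = c("MeSH", "MeSH", "Gene", "MeSH"),
    concept_name = letters[1:4]
  )
  out <- filter_annotations(rec)
  expect_equal(out$concept_id, "D010300")
  # configurable vocabulary tag
  out2 <- filter_annotations(rec, mesh_tag = "Gene")
  expect_equal(out2$concept_id, "G1")
})

test_that("build_temporal_graph forms same-article pairwise edges per step", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_toy_annotations(f)
  rec <- filter_annotations(parse_annotations(f))
  g <- build_temporal_graph(rec, 2000, 2003)
  expect_s3_class(g, "temporal_graph")
  expect_equal(g$ids, c("D001", "D002", "D003", "D004", "D005"))
  expect_equal(g$horizon, 4L)
  # A1 {D001,D002,D003} at t=2 gives 3 edges; A2 {D001,D002} duplicates one
  e2 <- g$events[g$events$t == 2, ]
  expect_equal(nrow(e2), 3)
  expect_equal(unname(as.matrix(e2[, c("i", "j")])),
               matrix(c(1L, 2L, 1L, 3L, 2L, 3L), 3, 2, byrow = TRUE))
  # A3 {D002,D004} at t=3; A6 single concept yields no edge at t=4
  expect_equal(nrow(g$events[g$events$t == 3, ]), 1)
  expect_equal(nrow(g$events[g$events$t == 4, ]), 0)
  # year outside the configured range is fatal
  expect_error(build_temporal_graph(rec, 2002, 2003), "outside corpus range")
})

test_that("temporal_graph enforces its invariants", {
  expect_error(temporal_graph("a", 2, data.frame(t = 0L, i = 1L, j = 2L)),
               "E_0")
  expect_error(temporal_graph(c("a", "b"), 2,
                              data.frame(t = 1L, i = 1L, j = 1L)),
               "self-pairs")
  expect_error(temporal_graph(c("a", "b"), 2,
                              data.frame(t = 1L, i = 1L, j = 3L)),
               "out of range")
  # canonicalization + dedup
  g <- temporal_graph(c("a", "b"), 2,
                      data.frame(t = c(1L, 1L), i = c(2L, 1L), j = c(1L, 2L)))
  expect_equal(nrow(g$events), 1)
  expect_true(g$events$i < g$events$j)
})

test_that("neighborhood is cumulative, monotone, and empty at t = 0", {
  g <- temporal_graph(paste0("c", 1:4), 3,
                      data.frame(t = c(1L, 2L), i = c(1L, 1L), j = c(2L, 3L)))
  expect_equal(neighborhood(g, 1, 0), integer(0))
  expect_equal(neighborhood(g, 1, 1), 2L)
  expect_equal(neighborhood(g, 1, 2), c(2L, 3L))
  expect_error(neighborhood(g, 9, 1), "out of range")
  # monotonicity on a generated graph
  sim <- generate_dynamic_graph(small_drift_config(4))
  for (i in c(1L, 7L, 23L)) {
    sizes <- vapply(0:sim$graph$horizon,
                    function(t) length(neighborhood(sim$graph, i, t)), 0L)
    prev_sets <- lapply(0:sim$graph$horizon,
                        function(t) neighborhood(sim$graph, i, t))
    expect_true(all(diff(sizes) >= 0))
    for (t in seq_len(sim$graph$horizon)) {
      expect_true(all(prev_sets[[t]] %in% prev_sets[[t + 1]]))
    }
  }
})

test_that("remove_seen_pairs removes exactly the historical pairs", {
  g <- toy_graph()  # (1,2) at t=1, (2,3) t=1, (1,3) t=2, (2,4),(4,5) t=3
  cand <- data.frame(i = c(1L, 3L, 2L), j = c(2L, 4L, 4L))
  out <- remove_seen_pairs(cand, g, before = 3)
  expect_equal(out, data.frame(i = c(3L, 2L), j = c(4L, 4L)))
  # empty history keeps all candidates
  expect_equal(nrow(remove_seen_pairs(cand, g, before = 1)), 3)
  # all candidates historical
  expect_equal(nrow(remove_seen_pairs(data.frame(i = 1L, j = 2L), g, 2)), 0)
  # brute-force leakage property on a generated graph
  sim <- generate_dynamic_graph(small_drift_config(5))
  gg <- sim$graph
  t0 <- gg$horizon
  surv <- remove_seen_pairs(events_at(gg, t0)[, c("i", "j")], gg, t0)
  hist <- gg$events[gg$events$t < t0, ]
  expect_length(intersect(paste(surv$i, surv$j), paste(hist$i, hist$j)), 0)
})

test_that("sample_negatives is uniform, pure, and seed-deterministic", {
  g <- toy_graph()
  pos <- pair_samples(c(1L, 2L, 1L, 2L, 4L), c(2L, 3L, 3L, 4L, 5L), 3L, 1L)
  neg <- sample_negatives(pos, g, ratio = 1, seed = 7)
  expect_equal(nrow(neg), 5)
  expect_true(all(neg$label == 0))
  expect_true(all(neg$i != neg$j))
  e3 <- events_at(g, 3)
  expect_length(intersect(paste(neg$i, neg$j), paste(e3$i, e3$j)), 0)
  expect_identical(neg, sample_negatives(pos, g, ratio = 1, seed = 7))
  expect_equal(nrow(sample_negatives(pos[1:3, ], g, ratio = 2, seed = 7)), 6)
  # saturated graph at the target step is fatal
  dense <- temporal_graph(paste0("c", 1:3), 1,
                          data.frame(t = 1L, i = c(1L, 1L, 2L), j = c(2L, 3L, 3L)))
  posd <- pair_samples(1L, 2L, 1L, 1L)
  expect_error(sample_negatives(posd, dense, ratio = 5, seed = 1),
               "too dense")
  # optional exclusion of historical pairs
  neg_h <- sample_negatives(pos, g, ratio = 3, seed = 7,
                            exclude_history = TRUE)
  hist <- g$events[g$events$t < 3, ]
  expect_length(intersect(paste(neg_h$i, neg_h$j),
                          paste(hist$i, hist$j)), 0)
})

test_that("edge-event files round-trip the graph exactly", {
  g <- toy_graph()
  prefix <- file.path(withr::local_tempdir(), "toy")
  write_edge_events(g, prefix)
  g2 <- read_edge_events(prefix)
  expect_identical(g2$ids, g$ids)
  expect_identical(g2$horizon, g$horizon)
  expect_identical(g2$events, g$events)

  # event at t = 0 is rejected
  bad <- file.path(withr::local_tempdir(), "bad")
  write_edge_events(g, bad)
  ev_lines <- readLines(paste0(bad, ".events.tsv"))
  writeLines(c(ev_lines, "0\tM1\tM2"), paste0(bad, ".events.tsv"))
  expect_error(read_edge_events(bad), "t >= 1")

  # unknown concept id is fatal
  writeLines(c(ev_lines, "2\tM1\tZZZ"), paste0(bad, ".events.tsv"))
  expect_error(read_edge_events(bad), "unknown concept id")
})
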