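mkRecords <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(mir_id = r[[1]], target_id = r[[2]], source = r[[3]],
               score = if (length(r) > 3) as.numeric(r[[4]]) else NA_real_,
               stringsAsFactors = FALSE)))
}

test_that("interaction filtering applies strict thresholds per dialect", {
  rec <- mkRecords(
    list("m1", "t1", "validated"),
    list("m1", "t2", "predicted_score", 85.0),
    list("m1", "t3", "predicted_score", 80.0),
    list("m2", "t1", "predicted_mirsvr", -1.5),
    list("m2", "t2", "predicted_mirsvr", -1.2),
    list("m2", "t3", "predicted_mirsvr", -0.1))
  kept <- filterInteractions(rec)
  keys <- paste(kept$mir_id, kept$target_id)
  expect_setequal(keys, c("m1 t1", "m1 t2", "m2 t1"))
  expect_equal(nrow(filterInteractions(rec[0, ])), 0L)
})

test_that("duplicate records collapse with provenance union, idempotently", {
  rec <- mkRecords(
    list("m1", "t1", "validated"),
    list("m1", "t1", "predicted_score", 95),
    list("m1", "t1", "predicted_mirsvr", -2))
  kept <- filterInteractions(rec)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$sources, "predicted_mirsvr,predicted_score,validated")
  # filtering is idempotent on already-filtered records
  again <- filterInteractions(
    data.frame(mir_id = kept$mir_id, target_id = kept$target_id,
               source = "validated", score = NA_real_))
  expect_equal(again$mir_id, kept$mir_id)
  expect_equal(again$target_id, kept$target_id)
})

test_that("malformed source/score combinations are rejected", {
  expect_error(filterInteractions(mkRecords(list("m", "t", "validated", 5))),
               "malformed")
  expect_error(filterInteractions(
    mkRecords(list("m", "t", "predicted_score"))), "malformed")
  expect_error(filterInteractions(
    mkRecords(list("m", "t", "predicted_mirsvr", 1.2))), "malformed")
  expect_error(filterInteractions(mkRecords(list("m", "t", "whatever", 1))),
               "unknown")
})

test_that("network construction follows the repression weight convention", {
  inter <- data.frame(mir_id = "m1", target_id = c("t1", "t2", "t3"),
                      sources = "validated", stringsAsFactors = FALSE)
  sel <- data.frame(mir_id = "m1", direction = "up",
                    stringsAsFactors = FALSE)
  net <- buildNetwork(sel, inter)
  expect_equal(edgeTable(net)$weight, rep(-1, 3))
  lit <- buildNetwork(sel, inter, convention = "literal")
  expect_equal(edgeTable(lit)$weight, rep(1, 3))
  # selected miR absent from interactions: empty network
  none <- buildNetwork(data.frame(mir_id = "mX", direction = "down"),
                       inter)
  expect_equal(nrow(edgeTable(none)), 0L)
  expect_equal(length(mirNodes(none)), 0L)
  expect_error(buildNetwork(data.frame(mir_id = "m1",
                                       direction = NA_character_), inter),
               "direction")
})

test_that("edge restriction matches a dictionary-lookup join oracle", {
  set.seed(21)
  for (i in 1:10) {
    mirs <- paste0("m", 1:12)
    sel_n <- sample(3:9, 1)
    sel <- data.frame(mir_id = sample(mirs, sel_n),
                      direction = sample(c("up", "down"), sel_n,
                                         replace = TRUE),
                      stringsAsFactors = FALSE)
    inter <- unique(data.frame(
      mir_id = sample(mirs, 60, replace = TRUE),
      target_id = sample(paste0("t", 1:15), 60, replace = TRUE),
      stringsAsFactors = FALSE))
    inter$sources <- "validated"
    net <- buildNetwork(sel, inter)
    dict <- setNames(sel$direction, sel$mir_id)
    want <- inter[inter$mir_id %in% names(dict), ]
    want_keys <- sort(paste(want$mir_id, want$target_id,
                            ifelse(dict[want$mir_id] == "up", -1, 1)))
    got <- edgeTable(net)
    expect_equal(sort(paste(got$mir_id, got$target_id, got$weight)),
                 want_keys)
  }
})

test_that("node strength equals brute-force summation on random graphs", {
  set.seed(77)
  for (i in 1:60) {
    net <- randomNet(n_mir = sample(2:50, 1), n_target = sample(2:50, 1),
                     n_edges = sample(1:120, 1))
    s <- nodeStrength(net)
    want <- strengthOracle(edgeTable(net))
    expect_equal(setNames(s$strength, s$target_id)[names(want)],
                 want)
    # conservation, degree bound and parity invariants
    expect_equal(sum(s$strength), sum(edgeTable(net)$weight))
    expect_true(all(abs(s$strength) <= s$degree))
    expect_true(all((s$strength - s$degree) %% 2 == 0))
  }
})

test_that("strength convention and cancellation behave as specified", {
  sel <- data.frame(mir_id = c("u1", "u2", "u3", "d1", "d2"),
                    direction = c("up", "up", "up", "down", "down"),
                    stringsAsFactors = FALSE)
  inter <- data.frame(
    mir_id = c("u1", "u2", "u3", "u1", "u2", "d1", "d2"),
    target_id = c("tA", "tA", "tA", "tB", "tB", "tB", "tB"),
    sources = "validated", stringsAsFactors = FALSE)
  s <- nodeStrength(buildNetwork(sel, inter))
  expect_equal(s$strength[s$target_id == "tA"], -3L)  # 3 up-miR edges
  expect_equal(s$strength[s$target_id == "tB"], 0L)   # 2 up vs 2 down
  # adding one more down-miR edge raises strength by exactly one
  inter2 <- rbind(inter, data.frame(mir_id = "d1", target_id = "tA",
                                    sources = "validated"))
  s2 <- nodeStrength(buildNetwork(sel, inter2))
  expect_equal(s2$strength[s2$target_id == "tA"],
               s$strength[s$target_id == "tA"] + 1L)
})

test_that("ranking is by |strength|, then strength, then target id", {
  sel <- data.frame(mir_id = c("u1", "u2", "d1"),
                    direction = c("up", "up", "down"),
                    stringsAsFactors = FALSE)
  inter <- data.frame(
    mir_id = c("u1", "u2", "d1", "u1", "d1"),
    target_id = c("zz", "zz", "aa", "bb", "cc"),
    sources = "validated", stringsAsFactors = FALSE)
  s <- nodeStrength(buildNetwork(sel, inter))
  # zz: -2; aa: +1; bb: -1; cc: +1 -> order: zz, aa, cc, bb
  expect_equal(s$target_id, c("zz", "aa", "cc", "bb"))
  expect_equal(s$rank, 1:4)
})

test_that("edge-list export round-trips and empty networks are valid", {
  set.seed(9)
  net <- randomNet()
  p <- tempfile(fileext = ".tsv")
  exportNetwork(net, p, "edgelist")
  back <- readNetworkEdgeList(p)
  expect_equal(sort(paste(edgeTable(back)$mir_id, edgeTable(back)$target_id,
                          edgeTable(back)$weight)),
               sort(paste(edgeTable(net)$mir_id, edgeTable(net)$target_id,
                          edgeTable(net)$weight)))
  expect_equal(mirDirections(back)[mirNodes(net)],
               mirDirections(net)[mirNodes(net)])
  # empty network: files exist with headers, round-trip stays empty
  empty <- buildNetwork(data.frame(mir_id = "x", direction = "up"),
                        data.frame(mir_id = character(0),
                                   target_id = character(0),
                                   sources = character(0)))
  exportNetwork(empty, p, "edgelist")
  expect_equal(readLines(p),
               "mir_id\ttarget_id\tweight\tmir_direction\tsources")
  expect_equal(nrow(edgeTable(readNetworkEdgeList(p))), 0L)
  p2 <- tempfile(fileext = ".sif")
  exportNetwork(empty, p2, "sif")
  expect_equal(length(readLines(p2)), 0L)
})

test_that("SIF relations encode the edge sign", {
  sel <- data.frame(mir_id = c("u1", "d1"), direction = c("up", "down"),
                    stringsAsFactors = FALSE)
  inter <- data.frame(mir_id = c("u1", "d1"), target_id = c("t1", "t2"),
                      sources = "validated", stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".sif")
  exportNetwork(buildNetwork(sel, inter), p, "sif")
  lines <- readLines(p)
  expect_true("u1\tpredicts_down\tt1" %in% lines)
  expect_true("d1\tpredicts_up\tt2" %in% lines)
})

test_that("GraphML export is well-formed and igraph-readable", {
  skip_if_not_installed("xml2")
  sel <- data.frame(mir_id = c("m1", "m2"), direction = c("up", "down"),
                    stringsAsFactors = FALSE)
  inter <- data.frame(mir_id = c("m1", "m1", "m2", "m2"),
                      target_id = c("t1", "t2", "t1", "t2"),
                      sources = "validated", stringsAsFactors = FALSE)
  net <- buildNetwork(sel, inter)
  p <- tempfile(fileext = ".graphml")
  exportNetwork(net, p, "graphml")
  doc <- xml2::read_xml(p)   # errors if not well-formed XML
  expect_equal(xml2::xml_name(doc), "graphml")
  g <- igraph::read_graph(p, format = "graphml")
  expect_equal(igraph::gorder(g), 4L)
  expect_equal(igraph::gsize(g), 4L)
  expect_setequal(igraph::E(g)$weight, edgeTable(net)$weight)
})
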