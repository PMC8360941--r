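fig1 <- make_fig1_fixture()

test_that("constructor enforces bipartiteness and builds a clean biadjacency matrix", {
  net <- bipartite_network(data.frame(a = c("e", "e"), b = c("2", "3")))
  expect_setequal(net$v1, "e")
  expect_setequal(net$v2, c("2", "3"))
  expect_equal(n_links(net), 2)
  expect_true(all(as.matrix(net$B) %in% c(0, 1)))
  expect_equal(sum(net$B), n_links(net))
  expect_length(intersect(net$v1, net$v2), 0)
  expect_error(bipartite_network(data.frame(a = c("e", "2"), b = c("2", "e"))),
               "bipartiteness")
  # duplicate rows collapse to one link
  dup <- bipartite_network(data.frame(a = c("e", "e"), b = c("2", "2")))
  expect_equal(n_links(dup), 1)
})

test_that("edge-list loader round-trips networks and reports malformed input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("e\t2", "e\t3"), f)
  net <- read_bipartite_edgelist(f)
  expect_setequal(net$v1, "e")
  expect_setequal(net$v2, c("2", "3"))
  expect_equal(n_links(net), 2)

  # the worked-example graph as an 11-row file
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_bipartite_edgelist(fig1, f2)
  net2 <- read_bipartite_edgelist(f2)
  expect_equal(network_stats(net2)$n_nodes, 8)
  expect_equal(network_stats(net2)$n_links, 11)
  expect_identical(links_df(net2), links_df(fig1))

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("e\t2", "2\te"), f3)
  expect_error(read_bipartite_edgelist(f3), "bipartiteness")

  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("e\t2", "just-one-field"), f4)
  expect_error(read_bipartite_edgelist(f4), "line 2")
})

test_that("temporal loader parses dates and keeps the earliest duplicate", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("p1\tA\t2003-05-01", "p1\tA\t2001-02-03", "p1\tB\t2002-01-01"), f)
  net <- read_bipartite_edgelist(f, temporal = TRUE)
  expect_s3_class(net, "temporal_bipartite_network")
  expect_equal(n_links(net), 2)
  e <- net$edges
  expect_equal(e$date[e$v2 == "A"], as.Date("2001-02-03"))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("p1\tA\tnot-a-date", f2)
  expect_error(read_bipartite_edgelist(f2, temporal = TRUE), "date")
})

test_that("adjacency-matrix loader reads the drug-target benchmark dialect", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("\tdrugA\tdrugB", "t1\t1\t0", "t2\t0\t1"), f)
  net <- read_bipartite_adjacency(f)
  expect_equal(n_links(net), 2)
  expect_setequal(net$v1, c("drugA", "drugB"))
  expect_setequal(net$v2, c("t1", "t2"))
  expect_equal(neighbors(net, "drugA"), "t1")

  # all-zero 3 x 4: seven nodes, no links
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("\td1\td2\td3\td4", "t1\t0\t0\t0\t0", "t2\t0\t0\t0\t0",
               "t3\t0\t0\t0\t0"), f2)
  net2 <- read_bipartite_adjacency(f2)
  expect_equal(network_stats(net2)$n_nodes, 7)
  expect_equal(n_links(net2), 0)

  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("\td1", "t1\t2"), f3)
  expect_error(read_bipartite_adjacency(f3), "non-binary")

  f4 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("\td1\td1", "t1\t1\t0"), f4)
  expect_error(read_bipartite_adjacency(f4), "duplicate")
})

test_that("neighbourhoods on the worked example match the hand-checked structure", {
  expect_equal(neighbors(fig1, "e"), c("2", "3"))
  expect_equal(neighbors(fig1, "1"), c("a", "b", "d"))
  expect_equal(second_neighbors(fig1, "e"), c("a", "b", "c", "d", "e"))
  expect_equal(degree(fig1, "2"), 4)
  expect_equal(degree(fig1, "b"), 3)
  expect_error(neighbors(fig1, "zzz"), "unknown node")
})

test_that("isolated and degenerate nodes behave sanely", {
  net <- bipartite_network(data.frame(a = "x", b = "1"), v1 = c("x", "lonely"))
  expect_equal(neighbors(net, "lonely"), character(0))
  expect_equal(second_neighbors(net, "lonely"), character(0))
  expect_equal(degree(net, "lonely"), 0)
  # star: the second neighbourhood of the hub is the hub itself
  star <- bipartite_network(data.frame(a = c("x", "x"), b = c("1", "2")))
  expect_equal(second_neighbors(star, "x"), "x")
})

test_that("second neighbourhood matches a two-hop breadth-first oracle", {
  for (net in random_net_battery(8, seed = 7)) {
    for (v in c(net$v1, net$v2)) {
      expect_equal(second_neighbors(net, v), brute_second_neighbors(net, v))
    }
  }
})

test_that("degree sums are conserved across the two sides", {
  for (net in random_net_battery(8, seed = 19)) {
    expect_equal(sum(degrees(net, "v1")), n_links(net))
    expect_equal(sum(degrees(net, "v2")), n_links(net))
  }
})

test_that("network statistics match direct counting", {
  s <- network_stats(fig1)
  expect_equal(s$n_nodes, 8)
  expect_equal(s$n_links, 11)
  expect_equal(s$mean_degree_v1, 11 / 5)
  expect_equal(s$mean_degree_v1 * s$n_v1, s$n_links)
  expect_equal(s$mean_degree_v2 * s$n_v2, s$n_links)
  single <- bipartite_network(data.frame(a = "x", b = "1"))
  expect_equal(network_stats(single)$mean_degree_v1, 1)
  expect_equal(network_stats(single)$mean_degree_v2, 1)
})

test_that("minimum-conditions filter keeps exactly the patients a census keeps", {
  set.seed(31)
  degs <- sample(1:10, 100, replace = TRUE)
  rows <- do.call(rbind, lapply(seq_len(100), function(i) {
    data.frame(p = sprintf("p%03d", i),
               d = sprintf("D%02d", sample(20, degs[i])),
               t = as.Date("2000-01-01") + seq_len(degs[i]))
  }))
  coh <- temporal_bipartite_network(rows)
  filt <- filter_min_conditions(coh, 4)
  expect_equal(length(filt$v1), sum(degs >= 4))
  expect_true(all(degrees(filt, "v1") >= 4))
  expect_true(all(degrees(filt, "v2") >= 1))  # isolated diseases dropped
  # k = 1 keeps every patient
  expect_equal(length(filter_min_conditions(coh, 1)$v1), 100)
  # a patient with 3 diagnoses disappears at k = 4
  small <- temporal_bipartite_network(data.frame(
    p = c(rep("few", 3), rep("many", 4)),
    d = sprintf("D%d", c(1:3, 1:4)),
    t = as.Date("2000-01-01") + 1:7
  ))
  expect_false("few" %in% filter_min_conditions(small, 4)$v1)
  expect_true("many" %in% filter_min_conditions(small, 4)$v1)
})
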