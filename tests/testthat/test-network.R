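test_that("buildNetwork assembles nodes and edges deterministically", {
  pat <- data.frame(code_i = c("E11", "E78", "I10"),
                    code_j = c("I10", "I10", "K29"),
                    odds_ratio = c(2, 3, 4), p_value = rep(1e-8, 3),
                    frequency = c(10, 20, 30), selected = TRUE)
  net <- buildNetwork(pat, label = "toy")
  expect_equal(nNodes(net), 4L)
  expect_equal(nEdges(net), 3L)
  expect_equal(nodeTable(net)$code, c("E11", "E78", "I10", "K29"))
  expect_equal(nodeTable(net)$chapter, c(4L, 4L, 9L, 11L))
  et <- edgeTable(net)
  expect_true(all(et$code_i < et$code_j))
  # empty selection -> empty network
  empty <- buildNetwork(pat[0, ])
  expect_equal(nNodes(empty), 0L)
  # unselected rows violate the contract
  pat$selected[2] <- FALSE
  expect_error(buildNetwork(pat), "selected")
})

test_that("maximal cliques match hand-computed and brute-force enumerations", {
  tri <- netFromEdges(cbind(c("A00", "A00", "B00"), c("B00", "C00", "C00")))
  expect_equal(enumerateMaximalCliques(tri), list(c("A00", "B00", "C00")))
  path <- netFromEdges(cbind(c("A00", "B00"), c("B00", "C00")))
  expect_setequal(enumerateMaximalCliques(path),
                  list(c("A00", "B00"), c("B00", "C00")))
  # K4 plus pendant attached to V04
  k4p <- rbind(t(combn(sprintf("V%02d", 1:4), 2)), c("V04", "V05"))
  net <- netFromEdges(k4p)
  got <- enumerateMaximalCliques(net)
  expect_setequal(got, bruteMaximalCliques(adjFromEdges(sprintf("V%02d", 1:5), k4p)))
  expect_setequal(got, list(sprintf("V%02d", 1:4), c("V04", "V05")))
})

test_that("mcc sums (|C|-1)! over maximal cliques", {
  tri <- netFromEdges(cbind(c("A00", "A00", "B00"), c("B00", "C00", "C00")))
  expect_equal(unname(mcc(tri, "A00")), 2)          # (3-1)!
  star <- netFromEdges(cbind(rep("S00", 3), c("L01", "L02", "L03")))
  expect_equal(unname(mcc(star, "S00")), 3)         # reduces to degree
  k4p <- rbind(t(combn(sprintf("V%02d", 1:4), 2)), c("V04", "V05"))
  net <- netFromEdges(k4p)
  expect_equal(unname(mcc(net, "V04")), 7)          # 3! + 1!
  expect_equal(unname(mcc(net, "V05")), 1)
  expect_error(mcc(net, "Z99"), "not in network")
})

test_that("cliques and mcc agree with exhaustive subset search on random graphs", {
  for (s in 1:20) {
    n <- sample(4:10, 1)
    edges <- randomEdges(n, 0.4, seed = s)
    if (nrow(edges) == 0) next
    net <- netFromEdges(edges)
    nodes <- nodeTable(net)$code
    A <- adjFromEdges(nodes, edges)
    expect_setequal(Filter(function(C) length(C) >= 2, enumerateMaximalCliques(net)),
                    Filter(function(C) length(C) >= 2, bruteMaximalCliques(A)))
    for (v in nodes)
      expect_equal(unname(mcc(net, v)), bruteMCC(A, v))
  }
})

test_that("MCC equals degree on triangle-free graphs", {
  for (s in 1:10) {
    # random bipartite graph: triangle-free by construction
    set.seed(s)
    left <- sprintf("L%02d", 1:5); right <- sprintf("R%02d", 1:5)
    pairs <- expand.grid(left, right, stringsAsFactors = FALSE)
    edges <- as.matrix(pairs[runif(nrow(pairs)) < 0.3, , drop = FALSE])
    if (nrow(edges) == 0) next
    net <- netFromEdges(edges)
    m <- computeMetrics(net)
    expect_equal(m$mcc, as.numeric(m$degree))
  }
})

test_that("metrics match closed forms on the triangle and the path", {
  tri <- netFromEdges(cbind(c("A00", "A00", "B00"), c("B00", "C00", "C00")))
  m <- computeMetrics(tri)
  expect_equal(m$degree, rep(2L, 3))
  expect_equal(m$clustering_coefficient, rep(1, 3))
  expect_equal(m$closeness, rep(1, 3))
  expect_equal(m$betweenness, rep(0, 3))
  expect_equal(m$eigencentrality, rep(1, 3))
  expect_equal(sum(m$pagerank), 1, tolerance = 1e-9)

  path <- netFromEdges(cbind(c("A00", "B00"), c("B00", "C00")))
  mp <- computeMetrics(path)
  b <- mp[mp$code == "B00", ]
  expect_equal(b$betweenness, 1)
  expect_equal(b$clustering_coefficient, 0)
  expect_equal(b$closeness, 1)                    # distance 1 to both others
  expect_equal(mp$closeness[mp$code == "A00"], 2 / 3)
})

test_that("pagerank and betweenness agree with independent oracles", {
  edges <- rbind(c("A00", "B00"), c("A00", "C00"), c("B00", "C00"),
                 c("C00", "D00"), c("D00", "E00"), c("E00", "F00"),
                 c("D00", "F00"), c("F00", "G00"))
  net <- netFromEdges(edges)
  m <- computeMetrics(net)
  A <- adjFromEdges(m$code, edges)
  pr <- brutePagerank(A)
  expect_equal(m$pagerank, unname(pr[m$code]), tolerance = 1e-6)
  btw <- bruteBetweenness(A)
  expect_equal(m$betweenness, unname(btw[m$code]), tolerance = 1e-9)
  expect_equal(sum(m$pagerank), 1, tolerance = 1e-9)
  # handshake
  expect_equal(sum(m$degree), 2L * nEdges(net))
})

test_that("disconnected graphs use the declared conventions", {
  # two components: triangle + isolated edge + isolated node is impossible
  # (every network node has an edge), so: triangle + edge
  edges <- rbind(c("A00", "B00"), c("A00", "C00"), c("B00", "C00"),
                 c("X00", "Y00"))
  net <- netFromEdges(edges)
  m <- computeMetrics(net)
  n <- 5
  # Wasserman-Faust: triangle nodes (3-1)/2 * (3-1)/(n-1) = 1 * 0.5
  expect_equal(m$closeness[m$code == "A00"], (2 / 2) * (2 / 4))
  expect_equal(m$closeness[m$code == "X00"], (1 / 1) * (1 / 4))
  # eigencentrality: largest component only, max-normalized
  expect_equal(m$eigencentrality[m$code %in% c("A00", "B00", "C00")], rep(1, 3))
  expect_equal(m$eigencentrality[m$code %in% c("X00", "Y00")], rep(0, 2))
  expect_equal(sum(m$pagerank), 1, tolerance = 1e-9)
})

test_that("metrics are invariant under node relabeling", {
  edges <- randomEdges(8, 0.4, seed = 99)
  net <- netFromEdges(edges)
  nodes <- nodeTable(net)$code
  relabel <- setNames(sprintf("Z%02d", rev(seq_along(nodes))), nodes)
  edges2 <- cbind(relabel[edges[, 1]], relabel[edges[, 2]])
  net2 <- netFromEdges(edges2)
  m1 <- computeMetrics(net)
  m2 <- computeMetrics(net2)
  m2$orig <- names(relabel)[match(m2$code, relabel)]
  m2 <- m2[order(m2$orig), ]
  for (col in c("degree", "mcc", "closeness", "clustering_coefficient",
                "betweenness", "pagerank", "eigencentrality"))
    expect_equal(m1[[col]], m2[[col]], tolerance = 1e-9, label = col)
})

test_that("hubAssociatedSubnetwork keeps edges incident to hubs", {
  star <- netFromEdges(cbind(rep("S00", 3), c("L01", "L02", "L03")))
  sub <- hubAssociatedSubnetwork(star, "S00")
  expect_equal(nEdges(sub), 3L)
  expect_equal(nNodes(sub), 4L)
  tri <- netFromEdges(cbind(c("A00", "A00", "B00"), c("B00", "C00", "C00")))
  sub2 <- hubAssociatedSubnetwork(tri, "A00")
  expect_equal(nEdges(sub2), 2L)
  expect_setequal(nodeTable(sub2)$code, c("A00", "B00", "C00"))
  expect_error(hubAssociatedSubnetwork(tri, "Z99"), "not in network")
  # monotone growth with the hub set; edges always a subset
  edges <- randomEdges(9, 0.35, seed = 3)
  net <- netFromEdges(edges)
  nodes <- nodeTable(net)$code
  prev_edges <- 0L
  for (k in seq_along(nodes)) {
    sub_k <- hubAssociatedSubnetwork(net, nodes[seq_len(k)])
    expect_gte(nEdges(sub_k), prev_edges)
    key <- function(x) paste(edgeTable(x)$code_i, edgeTable(x)$code_j)
    expect_true(all(key(sub_k) %in% key(net)))
    prev_edges <- nEdges(sub_k)
  }
  expect_equal(nEdges(hubAssociatedSubnetwork(net, nodes)), nEdges(net))
})

test_that("exportNetwork writes GraphML and CSV mirrors", {
  net <- netFromEdges(cbind(c("A00", "A00"), c("B00", "C00")),
                      frequency = c(5, 7), label = "toy")
  dir <- withr::local_tempdir()
  paths <- exportNetwork(net, dir)
  expect_true(all(file.exists(paths)))
  back <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_equal(igraph::vcount(back), 3)
  expect_setequal(igraph::E(back)$frequency, c(5, 7))
  nodes_csv <- read.csv(paths[["nodes"]])
  expect_true(all(c("mcc", "pagerank", "eigencentrality") %in% names(nodes_csv)))
  edges_csv <- read.csv(paths[["edges"]])
  expect_equal(sum(edges_csv$frequency), 12)
})
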