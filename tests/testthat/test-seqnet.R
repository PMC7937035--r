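twoSongRec <- recordingFromSequences("ex", list(c("A", "B", "C"),
                                                c("A", "B", "D")))

test_that("transition counts sum per-song adjacencies, never across songs", {
  W <- weightMatrix(buildNetwork(twoSongRec))
  expect_equal(W["A", "B"], 2L)
  expect_equal(W["B", "C"], 1L)
  expect_equal(W["B", "D"], 1L)
  expect_equal(sum(W), 4L)

  disjoint <- buildNetwork(recordingFromSequences("d", list(c("A", "B"),
                                                            c("C", "D"))))
  D <- igraph::distances(asGraph(disjoint), mode = "out")
  expect_true(is.infinite(D["A", "C"]))
  expect_equal(sum(weightMatrix(disjoint) > 0), 2L)

  # weight-matrix mass equals the number of consecutive within-song pairs
  set.seed(5)
  for (i in 1:10) {
    r <- randomRecording(paste0("r", i))
    expect_equal(sum(weightMatrix(buildNetwork(r))),
                 sum(lengths(songSequences(r)) - 1L))
  }
})

test_that("self-loop flag controls the derived graph, not the counts", {
  r <- recordingFromSequences("s", list(c("A", "A", "B")))
  off <- buildNetwork(r, includeSelfLoops = FALSE)
  on <- buildNetwork(r, includeSelfLoops = TRUE)
  expect_equal(weightMatrix(off), weightMatrix(on))
  expect_equal(weightMatrix(on)["A", "A"], 1L)
  expect_equal(igraph::ecount(asGraph(off)), 1L)
  expect_equal(igraph::ecount(asGraph(on)), 2L)
})

test_that("average degree is 2E/n on the unweighted directed graph", {
  expect_equal(averageDegree(buildNetwork(twoSongRec)), 1.5)
  expect_equal(averageDegree(buildNetwork(
    recordingFromSequences("one", list("A")))), 0)
  triangle <- makeNet(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3))
  expect_equal(averageDegree(triangle), 4)
})

test_that("directed path length averages over reachable ordered pairs", {
  expect_equal(averageShortestPath(buildNetwork(twoSongRec)), 1.4)
  cyc <- makeNet(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(averageShortestPath(cyc), 1)
  empty <- makeNet(matrix(0L, 3, 3))
  expect_true(is.na(averageShortestPath(empty)))
})

test_that("clustering is transitivity of the undirected projection", {
  chain <- makeNet(matrix(c(0, 1, 0, 0, 0, 1, 0, 0, 0), 3, 3, byrow = TRUE))
  expect_equal(clusteringCoefficient(chain), 0)
  triangle <- makeNet(matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, 3, byrow = TRUE))
  expect_equal(clusteringCoefficient(triangle), 1)
})

test_that("path and clustering match brute force on random small graphs", {
  set.seed(101)
  for (i in 1:120) {
    net <- randomNet(sample(2:15, 1L), p = runif(1, 0.05, 0.5))
    expect_equal(averageShortestPath(net), bfAvgShortestPath(net))
    expect_equal(clusteringCoefficient(net), bfClustering(net))
  }
})

test_that("small-worldness matches the closed form on a complete graph", {
  k4 <- makeNet(matrix(1L, 4, 4) - diag(1L, 4))
  expected <- (1 / (3 / 4)) / (1 / (log(4) / log(3)))
  expect_equal(smallWorldness(k4), expected, tolerance = 1e-12)

  # mean degree <= 1 leaves the random-graph baseline undefined
  sparse <- makeNet(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE))
  expect_true(is.na(smallWorldness(sparse)))
  # triangle-free star: k = 1.5 > 1, C = 0, so S = 0
  star <- makeNet(rbind(c(0, 1, 1, 1), matrix(0L, 3, 4)))
  expect_equal(smallWorldness(star), 0)
})

test_that("small-worldness is 0 for triangle-free graphs with k > 1", {
  ring <- makeNet({
    W <- matrix(0L, 5, 5)
    for (i in 1:5) W[i, i %% 5 + 1] <- 1L
    W
  })
  expect_equal(smallWorldness(ring), 0)
})

test_that("monte-carlo baseline agrees with the analytic one on ER graphs", {
  set.seed(77)
  g <- igraph::sample_gnp(50, 0.08)
  W <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  net <- makeNet(W * 1L)
  sA <- smallWorldness(net, mode = "analytic")
  set.seed(78)
  sM <- smallWorldness(net, mode = "montecarlo", nRand = 200L)
  expect_lt(abs(sM - sA) / sA, 0.15)
})

test_that("computeMetrics composes the descriptors", {
  m <- computeMetrics(twoSongRec)
  expect_equal(m$repertoire_size, 4L)
  expect_equal(m$n_syllables, 6L)
  expect_equal(m$average_degree, 1.5)
  expect_equal(m$average_shortest_path, 1.4)
  expect_equal(m$clustering_coefficient, 0)

  single <- computeMetrics(recordingFromSequences("one", list("A")))
  expect_equal(single$repertoire_size, 1L)
  expect_equal(single$n_syllables, 1L)
  expect_equal(single$average_degree, 0)
  expect_true(is.na(single$average_shortest_path))
})

test_that("descriptive connection statistics match hand enumeration", {
  d <- descriptiveStats(buildNetwork(twoSongRec))
  expect_equal(d$pct_nodes_degree_lt3, 75)
  expect_equal(d$pct_edges_bidirectional, 0)
  expect_equal(d$pct_edges_weight_gt1, 100 / 3)

  cyc <- makeNet(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(descriptiveStats(cyc)$pct_edges_bidirectional, 100)

  allOnes <- makeNet(matrix(c(0, 1, 0, 0, 0, 1, 0, 0, 0), 3, 3, byrow = TRUE))
  expect_equal(descriptiveStats(allOnes)$pct_edges_weight_gt1, 0)

  empty <- makeNet(matrix(0L, 2, 2))
  expect_true(is.na(descriptiveStats(empty)$pct_edges_bidirectional))
})

test_that("metrics are invariant to relabeling syllable types", {
  set.seed(9)
  r <- randomRecording("orig", nSongs = 6L)
  perm <- setNames(sample(letters[1:6]), LETTERS[1:6])
  relabeled <- recordingFromSequences(
    "perm", lapply(songSequences(r), function(s) unname(perm[s])),
    meanFreqs = NULL)
  for (f in list(averageDegree, averageShortestPath, clusteringCoefficient,
                 smallWorldness)) {
    expect_equal(f(buildNetwork(r)), f(buildNetwork(relabeled)))
  }
})

test_that("concatenating song lists sums the weight matrices", {
  set.seed(13)
  r1 <- randomRecording("a", nSongs = 4L)
  r2 <- randomRecording("b", nSongs = 4L)
  combined <- recordingFromSequences(
    "ab", c(songSequences(r1), songSequences(r2)))
  Wc <- weightMatrix(buildNetwork(combined))
  W1 <- weightMatrix(buildNetwork(r1))
  W2 <- weightMatrix(buildNetwork(r2))
  for (a in rownames(Wc)) {
    for (b in colnames(Wc)) {
      w <- 0L
      if (a %in% rownames(W1) && b %in% colnames(W1)) w <- w + W1[a, b]
      if (a %in% rownames(W2) && b %in% colnames(W2)) w <- w + W2[a, b]
      expect_equal(Wc[a, b], w)
    }
  }
})

test_that("edge-list and GraphML exports carry the directed weights", {
  net <- buildNetwork(twoSongRec)
  csv <- tempfile(fileext = ".csv")
  writeEdgeList(net, csv)
  el <- read.csv(csv)
  expect_equal(nrow(el), 3L)
  expect_equal(el$weight[el$source == "A" & el$target == "B"], 2L)

  gml <- tempfile(fileext = ".graphml")
  writeGraphML(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), 3)
  expect_setequal(igraph::E(g)$weight, c(2, 1, 1))
})
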