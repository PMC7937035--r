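# Directed syllable networks and their descriptors.

#' @importFrom igraph graph_from_adjacency_matrix distances as_undirected
#'   simplify transitivity mean_distance vcount ecount sample_gnm
#'   write_graph degree
NULL

.METRIC_NAMES <- c("average_degree", "average_shortest_path",
                   "clustering_coefficient", "small_worldness")

# unweighted directed adjacency (logical) under the network's self-loop flag
.unweightedAdjacency <- function(net) {
  A <- weightMatrix(net) > 0
  if (!includeSelfLoops(net)) diag(A) <- FALSE
  A
}

#' Build the syllable-transition network of a recording
#'
#' Computes the first-order adjacency matrix for each song (counts of type
#' A immediately followed by type B), sums the per-song matrices into one
#' matrix for the whole recording, and wraps it as a
#' [SyllableNetwork-class]. Order matters: A-then-B and B-then-A are
#' different transitions, so the matrix is asymmetric. No transition is
#' counted across a song boundary; single-token songs contribute nothing.
#'
#' @param recording a [SyllableRecording-class].
#' @param includeSelfLoops logical; whether immediate type repetitions
#'   (diagonal counts) become edges of the derived unweighted graph. The
#'   diagonal of the weight matrix is always retained.
#' @return A [SyllableNetwork-class].
#' @examples
#' r <- recordingFromSequences("r1", list(c("A","B","C"), c("A","B","D")))
#' weightMatrix(buildNetwork(r))
#' @export
buildNetwork <- function(recording, includeSelfLoops = FALSE) {
  seqs <- songSequences(recording)
  labs <- sort(unique(unlist(seqs)))
  n <- length(labs)
  counts <- numeric(n * n)
  for (s in seqs) {
    if (length(s) < 2L) next
    i <- match(s[-length(s)], labs)
    j <- match(s[-1L], labs)
    tab <- tabulate(i + (j - 1L) * n, nbins = n * n)
    counts <- counts + tab
  }
  W <- matrix(as.integer(counts), n, n, dimnames = list(labs, labs))
  new("SyllableNetwork", nodeLabels = labs, weightMatrix = W,
      includeSelfLoops = isTRUE(includeSelfLoops))
}

#' @describeIn SyllableNetwork-class the unweighted directed graph (an
#'   igraph object) derived from the weight matrix under the network's
#'   self-loop convention.
#' @export
setMethod("asGraph", "SyllableNetwork", function(x) {
  igraph::graph_from_adjacency_matrix(.unweightedAdjacency(x) * 1L,
                                      mode = "directed")
})

.undirectedProjection <- function(net) {
  igraph::simplify(igraph::as_undirected(asGraph(net), mode = "collapse"))
}

#' Average degree of the syllable network
#'
#' Mean total (in + out) degree on the unweighted directed graph:
#' `2 * E / n`, where E is the number of distinct directed edges and n the
#' repertoire size. High values mean syllable types are found adjacent to
#' many other types across the songs.
#'
#' @param net a [SyllableNetwork-class].
#' @return A single number (0 for an edgeless network).
#' @export
averageDegree <- function(net) {
  n <- length(nodeLabels(net))
  2 * sum(.unweightedAdjacency(net)) / n
}

#' Average shortest path of the syllable network
#'
#' Mean directed graph distance over all ordered pairs of distinct nodes
#' for which a path exists; unreachable pairs are excluded from the mean
#' (syllable networks routinely contain isolated chains). Grows with the
#' length of stable runs of unique syllable types.
#'
#' @param net a [SyllableNetwork-class].
#' @return A single number, or `NA` if no ordered pair is reachable.
#' @export
averageShortestPath <- function(net) {
  g <- asGraph(net)
  D <- igraph::distances(g, mode = "out")
  diag(D) <- NA
  finite <- D[is.finite(D)]
  if (!length(finite)) return(NA_real_)
  mean(finite)
}

#' Clustering coefficient (global transitivity)
#'
#' Computed on the undirected projection of the network: three times the
#' number of triangles over the number of connected triples, i.e. the
#' relative frequency with which three syllable types are all pairwise
#' adjacent. Defined as 0 when the graph has no connected triple.
#'
#' @param net a [SyllableNetwork-class].
#' @return A number in `[0, 1]`.
#' @export
clusteringCoefficient <- function(net) {
  tr <- igraph::transitivity(.undirectedProjection(net), type = "global")
  if (is.nan(tr)) 0 else tr
}

#' Small-worldness coefficient
#'
#' `S = (C / C_rand) / (L / L_rand)` on the undirected projection, where C
#' is the global clustering coefficient, L the mean shortest path, and the
#' `_rand` baselines describe an Erdos-Renyi random graph with the same
#' number of nodes n and mean degree k. S is large when most syllable
#' types are not directly adjacent yet remain a few steps apart.
#'
#' Two baselines are available: `"analytic"` (default) uses the standard
#' closed forms `C_rand = k / n`, `L_rand = ln(n) / ln(k)`;
#' `"montecarlo"` averages C and L over `nRand` simulated G(n, m) graphs
#' with the same node and edge counts (uses the current RNG state, so seed
#' beforehand for reproducibility).
#'
#' The coefficient is undefined (NA) when mean degree k <= 1 or the
#' baselines degenerate; callers should exclude such networks downstream.
#'
#' @param net a [SyllableNetwork-class].
#' @param mode `"analytic"` or `"montecarlo"`.
#' @param nRand number of random graphs for the Monte-Carlo baseline.
#' @return A single non-negative number, or `NA` when undefined.
#' @export
smallWorldness <- function(net, mode = c("analytic", "montecarlo"),
                           nRand = 200L) {
  mode <- match.arg(mode)
  gu <- .undirectedProjection(net)
  n <- igraph::vcount(gu)
  m <- igraph::ecount(gu)
  kbar <- 2 * m / n
  if (n < 2L || kbar <= 1) return(NA_real_)
  C <- igraph::transitivity(gu, type = "global")
  if (is.nan(C)) C <- 0
  L <- igraph::mean_distance(gu, directed = FALSE)
  if (!is.finite(L) || L <= 0) return(NA_real_)
  if (mode == "analytic") {
    Crand <- kbar / n
    Lrand <- log(n) / log(kbar)
  } else {
    cs <- numeric(nRand)
    ls <- numeric(nRand)
    for (b in seq_len(nRand)) {
      gr <- igraph::sample_gnm(n, m)
      cb <- igraph::transitivity(gr, type = "global")
      cs[b] <- if (is.nan(cb)) 0 else cb
      ls[b] <- igraph::mean_distance(gr, directed = FALSE)
    }
    Crand <- mean(cs)
    Lrand <- mean(ls[is.finite(ls)])
  }
  if (!is.finite(Crand) || Crand <= 0 || !is.finite(Lrand) || Lrand <= 0)
    return(NA_real_)
  (C / Crand) / (L / Lrand)
}

#' Classical and network descriptors of one recording
#'
#' Bundles the two classical variables (repertoire size = number of
#' distinct syllable types = network nodes; number of syllables = tokens)
#' with the four network variables: [averageDegree()],
#' [averageShortestPath()], [clusteringCoefficient()] and
#' [smallWorldness()]. Undefined metrics propagate as NA.
#'
#' @param recording a [SyllableRecording-class].
#' @param includeSelfLoops passed to [buildNetwork()].
#' @param swMode small-worldness baseline, see [smallWorldness()].
#' @return One-row data.frame with recording metadata and the six
#'   variables.
#' @export
computeMetrics <- function(recording, includeSelfLoops = FALSE,
                           swMode = "analytic") {
  net <- buildNetwork(recording, includeSelfLoops)
  data.frame(recording_id = recordingId(recording),
             individual_id = individualId(recording),
             year = recordingYear(recording),
             repertoire_size = repertoireSize(recording),
             n_syllables = nSyllables(recording),
             average_degree = averageDegree(net),
             average_shortest_path = averageShortestPath(net),
             clustering_coefficient = clusteringCoefficient(net),
             small_worldness = smallWorldness(net, mode = swMode),
             stringsAsFactors = FALSE)
}

#' Metrics table for a collection of recordings
#'
#' @param recordings list of [SyllableRecording-class] objects.
#' @inheritParams computeMetrics
#' @return data.frame, one row per recording.
#' @export
metricsTable <- function(recordings, includeSelfLoops = FALSE,
                         swMode = "analytic") {
  out <- do.call(rbind, lapply(recordings, computeMetrics,
                               includeSelfLoops = includeSelfLoops,
                               swMode = swMode))
  rownames(out) <- NULL
  out
}

#' Descriptive connection statistics of a syllable network
#'
#' Three percentages summarising the texture of the network: the share of
#' nodes with total degree below 3 (types occurring next to at most two
#' other types), the share of connected unordered type pairs linked in
#' both directions, and the share of directed edges with transition count
#' above 1 (syllable pairs performed repeatedly).
#'
#' @param net a [SyllableNetwork-class].
#' @return One-row data.frame with `pct_nodes_degree_lt3`,
#'   `pct_edges_bidirectional`, `pct_edges_weight_gt1` (the latter two NA
#'   for an edgeless network).
#' @export
descriptiveStats <- function(net) {
  A <- .unweightedAdjacency(net)
  W <- weightMatrix(net)
  n <- length(nodeLabels(net))
  deg <- rowSums(A) + colSums(A)
  pctLow <- 100 * sum(deg < 3) / n
  U <- (A | t(A)) & upper.tri(A)
  B <- (A & t(A)) & upper.tri(A)
  pctBi <- if (sum(U) == 0) NA_real_ else 100 * sum(B) / sum(U)
  pctW <- if (sum(A) == 0) NA_real_ else 100 * sum(W[A] > 1) / sum(A)
  data.frame(pct_nodes_degree_lt3 = pctLow,
             pct_edges_bidirectional = pctBi,
             pct_edges_weight_gt1 = pctW)
}

#' Export a syllable network
#'
#' `writeEdgeList()` writes a `source,target,weight` CSV of the directed
#' weighted edges (under the network's self-loop convention);
#' `writeGraphML()` writes GraphML via igraph.
#'
#' @param net a [SyllableNetwork-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  A <- .unweightedAdjacency(net)
  W <- weightMatrix(net)
  idx <- which(A, arr.ind = TRUE)
  df <- data.frame(source = nodeLabels(net)[idx[, 1L]],
                   target = nodeLabels(net)[idx[, 2L]],
                   weight = W[idx])
  df <- df[order(df$source, df$target), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeEdgeList
#' @export
writeGraphML <- function(net, path) {
  W <- weightMatrix(net)
  W[!.unweightedAdjacency(net)] <- 0L
  g <- igraph::graph_from_adjacency_matrix(W, mode = "directed",
                                           weighted = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
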