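# Brute-force oracles and fixture builders shared across the suite.
# The oracles deliberately use naive algorithms (Floyd-Warshall, triple
# enumeration, substring scans) independent of the package's code paths.

makeNet <- function(W, includeSelfLoops = FALSE) {
  labs <- if (is.null(rownames(W))) {
    paste0("N", seq_len(nrow(W)))
  } else {
    rownames(W)
  }
  dimnames(W) <- list(labs, labs)
  new("SyllableNetwork", nodeLabels = labs,
      weightMatrix = matrix(as.integer(W), nrow(W), ncol(W),
                            dimnames = dimnames(W)),
      includeSelfLoops = includeSelfLoops)
}

randomNet <- function(n, p = 0.2, maxWeight = 3L) {
  W <- matrix(0L, n, n)
  on <- matrix(runif(n * n) < p, n, n)
  W[on] <- sample.int(maxWeight, sum(on), replace = TRUE)
  makeNet(W)
}

adjacencyOf <- function(net) {
  A <- weightMatrix(net) > 0
  if (!includeSelfLoops(net)) diag(A) <- FALSE
  A
}

# mean directed shortest path over reachable ordered pairs, Floyd-Warshall
bfAvgShortestPath <- function(net) {
  A <- adjacencyOf(net)
  n <- nrow(A)
  D <- ifelse(A, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  diag(D) <- NA
  v <- D[is.finite(D)]
  if (!length(v)) NA_real_ else mean(v)
}

# global transitivity by explicit triangle / connected-triple enumeration
bfClustering <- function(net) {
  A <- adjacencyOf(net)
  U <- (A | t(A))
  diag(U) <- FALSE
  n <- nrow(U)
  triples <- 0
  for (j in seq_len(n)) {
    k <- sum(U[j, ])
    triples <- triples + k * (k - 1) / 2
  }
  if (triples == 0) return(0)
  tri <- 0
  if (n >= 3) {
    for (i in 1:(n - 2)) {
      for (j in (i + 1):(n - 1)) {
        for (k in (j + 1):n) {
          if (U[i, j] && U[j, k] && U[i, k]) tri <- tri + 1
        }
      }
    }
  }
  3 * tri / triples
}

# motif types per length: substring scan with per-song membership count
bfMotifCounts <- function(songs, minLen = 2L, maxLen = 10L) {
  vapply(minLen:maxLen, function(L) {
    perSong <- lapply(songs, function(s) {
      if (length(s) < L) return(character())
      unique(vapply(seq_len(length(s) - L + 1L),
                    function(i) paste(s[i:(i + L - 1L)], collapse = "|"),
                    character(1L)))
    })
    cand <- unique(unlist(perSong))
    if (!length(cand)) return(0L)
    sum(vapply(cand, function(k)
      sum(vapply(perSong, function(ks) k %in% ks, logical(1L))) >= 2L,
      logical(1L)))
  }, integer(1L))
}

randomSongs <- function(nSongs, maxLen, nTypes) {
  lapply(seq_len(nSongs), function(i) {
    L <- sample.int(maxLen, 1L)
    LETTERS[sample.int(nTypes, L, replace = TRUE)]
  })
}

randomRecording <- function(id, nSongs = 5L, maxLen = 12L, nTypes = 6L) {
  recordingFromSequences(id, randomSongs(nSongs, maxLen, nTypes))
}
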