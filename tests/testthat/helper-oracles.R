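# Independent oracles used to cross-check the package's graph code.

# Kruskal MST total weight with union-find, on the complete Euclidean
# graph of a point set. Independent of the package's Prim implementation.
kruskalWeight <- function(pts) {
  k <- nrow(pts)
  D <- as.matrix(dist(pts))
  pairs <- t(combn(k, 2))
  w <- D[pairs]
  ord <- order(w)
  parent <- seq_len(k)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  total <- 0
  used <- 0L
  for (i in ord) {
    a <- find(pairs[i, 1])
    b <- find(pairs[i, 2])
    if (a != b) {
      parent[a] <- b
      total <- total + w[i]
      used <- used + 1L
      if (used == k - 1L) break
    }
  }
  total
}

# Decode a Pruefer sequence (length k - 2, entries in 1..k) into the edge
# list of the labeled tree it encodes.
prueferToEdges <- function(pruefer, k) {
  stopifnot(length(pruefer) == k - 2)
  degree <- rep(1L, k)
  for (s in pruefer) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, k - 1L, 2L)
  for (i in seq_along(pruefer)) {
    leaf <- which(degree == 1L)[1L]
    edges[i, ] <- c(leaf, pruefer[i])
    degree[leaf] <- 0L
    degree[pruefer[i]] <- degree[pruefer[i]] - 1L
  }
  edges[k - 1L, ] <- which(degree == 1L)
  edges
}

randomPrueferTree <- function(k) {
  trajectoryTree(prueferToEdges(sample.int(k, k - 2, replace = TRUE), k),
                 nNodes = k)
}

# Unweighted tree diameter by an independent route: all-pairs BFS
# distances through igraph.
igraphDiameter <- function(tree) {
  g <- igraph::graph_from_edgelist(treeEdges(tree), directed = FALSE)
  max(igraph::distances(g))
}

pathTree <- function(k) trajectoryTree(cbind(seq_len(k - 1), 2:k))
starTree <- function(k) trajectoryTree(cbind(rep(1L, k - 1), 2:k))

# The worked 10-node example tree: a long path 1-...-8 with two extra
# leaves hanging off nodes 3 and 5.
exampleTree10 <- function() {
  trajectoryTree(cbind(c(1, 2, 3, 4, 5, 6, 7, 3, 5),
                       c(2, 3, 4, 5, 6, 7, 8, 9, 10)))
}
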