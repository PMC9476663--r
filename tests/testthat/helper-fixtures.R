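# Shared fixtures and independent oracles for the suite.

heptaneGraph <- function() groupMolecule(generateLinearAlkane(7))
dmpGraph <- function() groupMolecule(generate24DMP())

# Brute-force oracle: every connected induced subset of `size` groups,
# checked with igraph, independent of the package's pruned enumeration.
bruteConnectedSubsets <- function(graph, size) {
  A <- adjacencyMatrix(graph)
  ng <- nrow(A)
  if (ng <= size) return(list(seq_len(ng)))
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  sets <- utils::combn(ng, size, simplify = FALSE)
  Filter(function(s)
    igraph::is_connected(igraph::induced_subgraph(ig, s)), sets)
}

setKeys <- function(sets)
  sort(vapply(sets, function(s) paste(sort(s), collapse = "+"), ""))

# A smooth centroid-distance pair potential (hartree) for closed-loop tests.
centroidPair <- function(a, b) {
  d <- sqrt(sum((colMeans(a) - colMeans(b))^2))
  -0.002 * exp(-d / 2)
}

# A three-body perimeter potential for the level-2 tests.
perimeterTriple <- function(a, b, c) {
  ca <- colMeans(a); cb <- colMeans(b); cc <- colMeans(c)
  per <- sqrt(sum((ca - cb)^2)) + sqrt(sum((cb - cc)^2)) +
    sqrt(sum((cc - ca)^2))
  1e-4 * exp(-per / 8)
}

# Random alkane trees (max degree 4) with clash-free realizations; the seed
# list below was chosen once for geometric validity of the idealized builds.
randomAlkaneTree <- function(nCarbons, seed) {
  set.seed(seed)
  repeat {
    parents <- integer(nCarbons)
    deg <- integer(nCarbons)
    ok <- TRUE
    for (k in seq_len(nCarbons)[-1L]) {
      open <- which(deg[seq_len(k - 1L)] <
                      ifelse(seq_len(k - 1L) == 1L, 4L, 3L))
      if (!length(open)) { ok <- FALSE; break }
      p <- if (length(open) == 1L) open else sample(open, 1L)
      parents[k] <- p
      deg[p] <- deg[p] + 1L
    }
    if (!ok) next
    mol <- try(generateBranchedAlkane(alkaneSpec(parents),
                                      name = "random alkane"),
               silent = TRUE)
    if (!inherits(mol, "try-error")) return(mol)
  }
}
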