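# Shared fixtures and independent oracles, all base R.

# Random Erdos-Renyi adjacency as a base dense matrix (possibly disconnected).
random_adjacency <- function(n, p = 0.5) {
  a <- matrix(0, n, n)
  up <- upper.tri(a)
  a[up] <- rbinom(sum(up), 1, p)
  a + t(a)
}

adj_connected <- function(a) {
  n <- nrow(a)
  seen <- logical(n); seen[1] <- TRUE
  repeat {
    nxt <- which(colSums(a[seen, , drop = FALSE]) > 0 & !seen)
    if (!length(nxt)) break
    seen[nxt] <- TRUE
  }
  all(seen)
}

random_connected_adjacency <- function(n, p = 0.5, max_tries = 200) {
  for (i in seq_len(max_tries)) {
    a <- random_adjacency(n, p)
    if (adj_connected(a)) return(a)
  }
  stop("could not draw a connected graph")
}

# Effective resistance between two nodes by grounding one node and solving
# the reduced Laplacian linear system (current injection oracle).
effective_resistance <- function(a, x, y) {
  n <- nrow(a)
  lap <- diag(colSums(a)) - a
  keep <- setdiff(seq_len(n), y)   # ground y
  rhs <- rep(0, n - 1)
  rhs[match(x, keep)] <- 1
  v <- solve(lap[keep, keep], rhs)
  v[match(x, keep)]
}

# Exhaustive pairwise AUC over all positive/negative score comparisons.
auc_exact <- function(pos, neg) {
  cmp <- outer(pos, neg, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Small deterministic duplex for pipeline tests: ring target + shifted aux.
ring_duplex <- function(n = 30) {
  nodes <- paste0("v", seq_len(n))
  ring <- cbind(nodes, nodes[c(2:n, 1)])
  chords <- cbind(nodes, nodes[c(3:n, 1, 2)])
  multiplex(list(target = ring, aux = rbind(ring[1:(n %/% 2), ], chords)),
            nodes = nodes)
}

# Lexicographic rank of an unordered pair (u < v) among n nodes; used to
# compare edge sets independently of the package's internal encoding.
pair_rank <- function(u, v, n) {
  (u - 1) * n - u * (u - 1) / 2 + (v - u)
}

write_temp_lines <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}

# Label-matrix form of a layer's edges, for building multiplex objects.
edges_to_labels <- function(net, e) {
  cbind(net$nodes[e[, 1]], net$nodes[e[, 2]])
}
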