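#' Generate a correlated duplex network
#'
#' Builds a two-layer network in which the layers share a controlled
#' fraction of edges, the one structural quantity the fused score exploits
#' (cross-layer link persistence). The auxiliary layer is drawn from a base
#' random-graph model; the target layer takes `ceiling(overlap * m_target)`
#' edges uniformly from the auxiliary edge set and the remainder uniformly
#' from the non-auxiliary pairs, so the realized edge overlap equals
#' `overlap` up to rounding by construction.
#'
#' @param n Number of nodes (shared across layers).
#' @param m_target,m_aux Edge counts of the target and auxiliary layers.
#' @param overlap Fraction of target edges copied from the auxiliary layer,
#'   in `[0, 1]`; requires `ceiling(overlap * m_target) <= m_aux`.
#' @param base_model `"ER"` (uniform random graph with exactly `m_aux`
#'   edges) or `"BA"` (preferential attachment, subsampled to `m_aux` edges,
#'   giving heavy-tailed degrees).
#' @param seed Optional seed.
#' @return A [multiplex()] object with layers `"target"` and `"aux"`; node
#'   labels are `"n1" ... "n<n>"` in index order.
#' @examples
#' net <- generate_duplex(50, 100, 100, overlap = 0.5, seed = 7)
#' summary(net)
#' @export
generate_duplex <- function(n, m_target, m_aux, overlap,
                            base_model = c("ER", "BA"), seed = NULL) {
  base_model <- match.arg(base_model)
  np <- n * (n - 1) / 2
  if (m_target > np || m_aux > np)
    stop_config("edge counts exceed the number of unordered pairs")
  if (overlap < 0 || overlap > 1) stop_config("'overlap' must be in [0, 1]")
  n_shared <- ceiling(overlap * m_target)
  if (n_shared > m_aux)
    stop_config("overlap * m_target exceeds the auxiliary edge count")
  if (m_target - n_shared > np - m_aux)
    stop_config("not enough non-auxiliary pairs for the unshared target edges")
  local_seed(seed, {
    g <- if (base_model == "ER") {
      igraph::sample_gnm(n, m_aux)
    } else {
      k <- max(1L, ceiling(m_aux / (n - 1)))
      ga <- igraph::sample_pa(n, m = k, directed = FALSE)
      ga <- igraph::simplify(ga)
      if (igraph::ecount(ga) < m_aux)
        stop_config("BA model produced too few simple edges for m_aux")
      igraph::subgraph_from_edges(ga, sample(igraph::ecount(ga), m_aux),
                                  delete.vertices = FALSE)
    }
    aux <- canonical_pairs(igraph::as_edgelist(g, names = FALSE))
    aux_keys <- edge_keys(aux, n)
    shared <- aux[sample(nrow(aux), n_shared), , drop = FALSE]
    fresh_keys <- sample(setdiff(seq_len(np), aux_keys),
                         m_target - n_shared)
    target <- canonical_pairs(rbind(shared, pair_unrank(sort(fresh_keys), n)))
    nodes <- paste0("n", seq_len(n))
    multiplex(list(target = cbind(nodes[target[, 1]], nodes[target[, 2]]),
                   aux = cbind(nodes[aux[, 1]], nodes[aux[, 2]])),
              nodes = nodes)
  })
}

#' Destroy cross-layer correlation by permuting one layer's node identities
#'
#' Returns a copy of the network with the node identities of one layer
#' relabelled by a uniform random permutation. The layer's degree sequence
#' (and all its within-layer structure) is preserved while any
#' correspondence with the other layers is destroyed, giving the standard
#' null model for cross-layer correlation.
#'
#' @param net A [multiplex()] object.
#' @param layer Layer to reshuffle.
#' @param seed Optional seed.
#' @return A [multiplex()] object.
#' @export
rewire_null <- function(net, layer, seed = NULL) {
  stopifnot(inherits(net, "multiplex"))
  if (!layer %in% names(net$layers)) stop_config("unknown layer: ", layer)
  n <- length(net$nodes)
  local_seed(seed, {
    perm <- sample.int(n)
    e <- net$layers[[layer]]
    net$layers[[layer]] <- canonical_pairs(cbind(perm[e[, 1]], perm[e[, 2]]))
    net
  })
}
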