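#' Base structural similarity scores on one layer
#'
#' Computes a single-layer similarity index for a set of node pairs from an
#' adjacency matrix. Available measures:
#' \describe{
#'   \item{`cn`}{Common neighbours, \eqn{|\Gamma(x) \cap \Gamma(y)|}.}
#'   \item{`ra`}{Resource allocation,
#'     \eqn{\sum_{z \in \Gamma(x)\cap\Gamma(y)} 1/|\Gamma(z)|}: each common
#'     neighbour passes on an equal share of a unit resource, so hubs
#'     contribute less.}
#'   \item{`act`}{Average commute time. The score is
#'     \eqn{1/(l^+_{xx} + l^+_{yy} - 2 l^+_{xy})} with \eqn{l^+} the
#'     pseudo-inverse of the graph Laplacian; the denominator is the
#'     effective resistance between the nodes, so closer-in-random-walk
#'     pairs score higher. On a connected graph the pseudo-inverse is
#'     computed as \eqn{(L - ee'/n)^{-1} + ee'/n}; on a disconnected graph
#'     the Moore-Penrose pseudo-inverse is used (the two coincide when the
#'     graph is connected), which keeps cross-component scores finite.}
#'   \item{`lpi`}{Local path index, \eqn{(A^2)_{xy} + \varepsilon (A^3)_{xy}}:
#'     common neighbours plus a small credit for length-3 paths. With
#'     `epsilon = 0` it reduces exactly to `cn`.}
#' }
#'
#' @param adj Symmetric adjacency matrix (as from [layer_adjacency()]).
#' @param pairs Integer matrix with two columns (`u`, `v`) of node indices.
#' @param measure One of `"cn"`, `"ra"`, `"act"`, `"lpi"`.
#' @param epsilon Length-3 path weight for `lpi` (default `1e-4`); must be
#'   non-negative.
#' @return An object of class `sim_scores`: list with `measure`, `pairs` and
#'   numeric `score` aligned with the rows of `pairs`.
#' @examples
#' net <- multiplex(list(l1 = cbind(c("a", "b"), c("b", "c"))))
#' adj <- layer_adjacency(net, "l1")
#' similarity_scores(adj, cbind(1L, 3L), "cn")$score  # a-c share b
#' @export
similarity_scores <- function(adj, pairs,
                              measure = c("ra", "cn", "act", "lpi"),
                              epsilon = 1e-4) {
  measure <- match.arg(measure)
  n <- nrow(adj)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) && (min(pairs) < 1L || max(pairs) > n))
    stop("pair contains node index outside the adjacency")
  score <- switch(measure,
    cn = {
      a2 <- Matrix::crossprod(adj)
      as.numeric(a2[pairs])
    },
    ra = {
      deg <- Matrix::colSums(adj)
      inv <- ifelse(deg > 0, 1 / deg, 0)
      w <- adj %*% Matrix::Diagonal(n, inv) %*% adj
      as.numeric(w[pairs])
    },
    act = {
      lp <- laplacian_pinv(adj)
      d <- Matrix::diag(lp)
      res <- unname(d[pairs[, 1]] + d[pairs[, 2]] - 2 * lp[pairs])
      1 / res
    },
    lpi = {
      if (epsilon < 0) stop_config("'epsilon' must be non-negative")
      a2 <- adj %*% adj
      s <- a2 + epsilon * (a2 %*% adj)
      as.numeric(s[pairs])
    })
  structure(list(measure = measure, pairs = pairs, score = score),
            class = "sim_scores")
}

#' @export
print.sim_scores <- function(x, ...) {
  cat("Similarity scores (", x$measure, "): ", nrow(x$pairs), " pairs, range [",
      format(min(x$score), digits = 4), ", ",
      format(max(x$score), digits = 4), "]\n", sep = "")
  invisible(x)
}

# Pseudo-inverse of the graph Laplacian. Connected graphs use the shifted
# inverse (L - ee'/n)^{-1} + ee'/n, which equals the Moore-Penrose
# pseudo-inverse there; disconnected graphs (where that shift is singular)
# fall back to MASS::ginv.
laplacian_pinv <- function(adj) {
  n <- nrow(adj)
  if (n < 2) stop("Laplacian pseudo-inverse needs at least 2 nodes")
  lap <- as.matrix(Matrix::Diagonal(n, Matrix::colSums(adj)) - adj)
  if (is_connected_adj(adj)) {
    j <- matrix(1 / n, n, n)
    lp <- tryCatch(solve(lap - j) + j, error = function(e)
      stop("Laplacian system numerically singular: ", conditionMessage(e),
           call. = FALSE))
    lp
  } else {
    MASS::ginv(lap)
  }
}

is_connected_adj <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = NULL)
  igraph::is_connected(g)
}

#' Min-max normalization of similarity scores
#'
#' Rescales scores linearly to `[0, 1]` over the supplied pair set. The
#' normalized score stands in for a connection probability inside the bit
#' score, so zeros must be kept off exactly 0: every normalized value
#' strictly below `floor_fraction` times the smallest positive normalized
#' value is raised to that floor, keeping `log2` finite while preserving the
#' ordering among positive scores.
#'
#' @param scores A `sim_scores` object or numeric vector.
#' @param floor_fraction Fraction of the smallest positive normalized value
#'   used as the floor (default `0.1`).
#' @return An object of class `norm_scores`: list with `value` (numeric in
#'   `(0, 1]`), `min`, `max` and `floor` used. If all scores are equal the
#'   degenerate map sends every pair to 1, with a warning.
#' @export
minmax_normalize <- function(scores, floor_fraction = 0.1) {
  s <- if (inherits(scores, "sim_scores")) scores$score else as.numeric(scores)
  if (length(s) < 2) stop("need at least two scored pairs to normalize")
  lo <- min(s); hi <- max(s)
  if (hi == lo) {
    warning("all similarity scores equal; normalized scores degenerate to 1")
    return(structure(list(value = rep(1, length(s)), min = lo, max = hi,
                          floor = 1), class = "norm_scores"))
  }
  v <- (s - lo) / (hi - lo)
  pos <- v[v > 0]
  floor_val <- floor_fraction * min(pos)
  v[v < floor_val] <- floor_val
  structure(list(value = v, min = lo, max = hi, floor = floor_val),
            class = "norm_scores")
}
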