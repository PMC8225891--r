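#' Construct a multiplex network
#'
#' A multiplex network is a set of undirected simple graphs (layers) over one
#' shared node index. Layers are edge sets; nodes isolated in a layer are kept
#' so every layer's adjacency is defined on the full node set.
#'
#' @param layers Named list. Each element gives one layer's edges as a
#'   two-column matrix or data frame of node labels (one row per undirected
#'   edge). Self-loops are dropped with a message; duplicate and reversed
#'   edges are collapsed.
#' @param nodes Optional character vector of node labels fixing the node set
#'   and its order. Defaults to the sorted union of labels seen in the layers.
#' @return An object of class `multiplex`: a list with elements `nodes`
#'   (character vector) and `layers` (named list of integer edge matrices
#'   with columns `u < v` indexing into `nodes`).
#' @examples
#' net <- multiplex(list(
#'   advice = cbind(c("a", "b"), c("b", "c")),
#'   social = cbind("a", "c")
#' ))
#' net
#' @export
multiplex <- function(layers, nodes = NULL) {
  if (!is.list(layers) || length(layers) < 1L)
    stop_config("'layers' must be a non-empty list of edge tables")
  nm <- names(layers)
  if (is.null(nm) || anyNA(nm) || any(nm == "") || anyDuplicated(nm))
    stop_config("layers must have unique non-empty names")
  lab <- lapply(layers, function(e) {
    e <- as.matrix(e)
    if (ncol(e) < 2) stop_config("each layer needs two endpoint columns")
    matrix(as.character(e[, 1:2]), ncol = 2)
  })
  if (is.null(nodes)) {
    nodes <- sort(unique(unlist(lab, use.names = FALSE)))
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop_config("duplicate node labels")
    seen <- unique(unlist(lab, use.names = FALSE))
    if (!all(seen %in% nodes))
      stop_config("edge endpoint not in supplied node set: ",
                  paste(utils::head(setdiff(seen, nodes), 3), collapse = ", "))
  }
  loops <- 0L
  edges <- lapply(lab, function(e) {
    idx <- matrix(match(e, nodes), ncol = 2)
    loops <<- loops + sum(idx[, 1] == idx[, 2])
    canonical_pairs(idx)
  })
  if (loops > 0)
    message("dropped ", loops, " self-loop(s)")
  structure(list(nodes = nodes, layers = edges), class = "multiplex")
}

#' @export
print.multiplex <- function(x, ...) {
  cat("Multiplex network: ", length(x$nodes), " nodes, ",
      length(x$layers), " layer(s)\n", sep = "")
  for (nm in names(x$layers))
    cat("  ", nm, ": ", nrow(x$layers[[nm]]), " edges\n", sep = "")
  invisible(x)
}

#' @export
summary.multiplex <- function(object, ...) {
  act <- vapply(object$layers, function(e)
    length(unique(as.vector(e))), integer(1))
  out <- data.frame(layer = names(object$layers),
                    edges = vapply(object$layers, nrow, integer(1)),
                    active_nodes = act, row.names = NULL)
  attr(out, "n_nodes") <- length(object$nodes)
  if (length(object$layers) >= 2)
    attr(out, "node_multiplexity") <- node_multiplexity(object)
  class(out) <- c("summary.multiplex", "data.frame")
  out
}

#' @export
print.summary.multiplex <- function(x, ...) {
  cat("Multiplex network over", attr(x, "n_nodes"), "nodes\n")
  print.data.frame(x)
  nm <- attr(x, "node_multiplexity")
  if (!is.null(nm)) cat("Node multiplexity:", format(nm, digits = 3), "\n")
  invisible(x)
}

#' Read a multiplex network from edge-list files
#'
#' Two layouts are supported. `"combined"` is one file with whitespace
#' separated lines `layer u v [weight]` (the CoMuNe repository layout).
#' `"per-layer"` takes a vector of paths, one two/three-column edge list per
#' layer; names of the vector become layer names (defaulting to file base
#' names). Lines starting with `#` are comments. Weights are parsed and
#' discarded with a message: the method is defined on unweighted layers.
#'
#' @param path File path (combined) or named character vector of file paths
#'   (per-layer).
#' @param format `"combined"` or `"per-layer"`.
#' @param nodes Optional node label vector passed to [multiplex()].
#' @return A [multiplex()] object.
#' @export
read_multiplex <- function(path, format = c("combined", "per-layer"),
                           nodes = NULL) {
  format <- match.arg(format)
  parse_file <- function(p, min_fields) {
    ln <- readLines(p)
    keep <- !grepl("^\\s*(#|$)", ln)
    fields <- strsplit(trimws(ln[keep]), "\\s+")
    nums <- which(keep)
    bad <- which(lengths(fields) < min_fields)
    if (length(bad))
      stop_config("malformed line ", nums[bad[1]], " in ", p, ": '",
                  ln[nums[bad[1]]], "'")
    list(fields = fields, has_weight = any(lengths(fields) > min_fields))
  }
  weighted <- FALSE
  if (format == "combined") {
    pf <- parse_file(path, 3L)
    weighted <- pf$has_weight
    lay <- vapply(pf$fields, `[`, character(1), 1)
    u <- vapply(pf$fields, `[`, character(1), 2)
    v <- vapply(pf$fields, `[`, character(1), 3)
    layers <- split(data.frame(u, v), factor(lay, unique(lay)))
    layers <- lapply(layers, as.matrix)
  } else {
    if (is.null(names(path)))
      names(path) <- sub("\\.[^.]*$", "", basename(path))
    layers <- lapply(path, function(p) {
      pf <- parse_file(p, 2L)
      weighted <<- weighted || pf$has_weight
      cbind(vapply(pf$fields, `[`, character(1), 1),
            vapply(pf$fields, `[`, character(1), 2))
    })
  }
  if (weighted) message("edge weights present in input; ignored")
  multiplex(layers, nodes = nodes)
}

#' Write a multiplex network as a combined edge list
#'
#' One line per edge, `layer u v`, the format read back by
#' [read_multiplex()] with `format = "combined"`.
#'
#' @param net A [multiplex()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_multiplex <- function(net, path) {
  stopifnot(inherits(net, "multiplex"))
  lines <- unlist(lapply(names(net$layers), function(nm) {
    e <- net$layers[[nm]]
    if (!nrow(e)) return(character(0))
    paste(nm, net$nodes[e[, 1]], net$nodes[e[, 2]])
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Fraction of nodes active in more than one layer
#'
#' A node is active in a layer if it has degree at least one there. Node
#' multiplexity is the fraction of all nodes active in two or more layers; it
#' gauges how much shared structure the layers can possibly exchange.
#'
#' @param net A [multiplex()] object with at least two layers.
#' @return A number in `[0, 1]`.
#' @export
node_multiplexity <- function(net) {
  stopifnot(inherits(net, "multiplex"))
  if (length(net$layers) < 2)
    stop_config("node multiplexity needs at least two layers")
  counts <- integer(length(net$nodes))
  for (e in net$layers) {
    act <- unique(as.vector(e))
    counts[act] <- counts[act] + 1L
  }
  sum(counts >= 2L) / length(net$nodes)
}

#' Layer adjacency matrix
#'
#' Builds the symmetric 0/1 adjacency of one layer over the full shared node
#' index (isolated nodes kept as zero rows). An `edge_subset` restricts the
#' adjacency to a subset of that layer's edges, which is how training
#' adjacencies are built without test edges.
#'
#' @param net A [multiplex()] object.
#' @param layer Layer name.
#' @param edge_subset Optional integer edge matrix (rows `u < v` indexing
#'   `net$nodes`), a subset of the layer's edges.
#' @return A sparse symmetric `dgCMatrix` with zero diagonal and node labels
#'   as dimnames.
#' @export
layer_adjacency <- function(net, layer, edge_subset = NULL) {
  stopifnot(inherits(net, "multiplex"))
  if (!layer %in% names(net$layers))
    stop_config("unknown layer: ", layer)
  e <- if (is.null(edge_subset)) net$layers[[layer]] else {
    es <- canonical_pairs(edge_subset)
    full <- net$layers[[layer]]
    n <- length(net$nodes)
    if (nrow(es) && !all(pair_rank(es[, 1], es[, 2], n) %in%
                         pair_rank(full[, 1], full[, 2], n)))
      stop_config("edge_subset contains edges not in layer '", layer, "'")
    es
  }
  n <- length(net$nodes)
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                       x = 1, dims = c(n, n),
                       dimnames = list(net$nodes, net$nodes))
}

# Ranks of a layer's edges in the unordered-pair enumeration.
edge_keys <- function(edges, n) {
  if (!nrow(edges)) return(numeric(0))
  pair_rank(edges[, 1], edges[, 2], n)
}
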