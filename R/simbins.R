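#' Fit the bin-fusion link prediction model on a duplex
#'
#' Fits the SimBins model for predicting missing links in a target layer with
#' the help of one auxiliary layer. The fit (i) builds the training pair
#' universe (training edges plus sampled non-edges), (ii) scores every
#' universe pair with the base similarity in each layer (target similarity on
#' the training adjacency only), (iii) partitions the universe into
#' equal-depth bins per layer, and (iv) estimates per-bin intra-layer and
#' trans-layer connection probabilities (the trans-layer table split by
#' auxiliary connectedness), imputing empty bins. A pair's score is then
#'
#' \deqn{SB_{xy} = \log_2 \tilde S^T_{xy} + \log_2\!\big( \tilde p_{intra}(i)
#'   + \tilde p_{trans}(j) - \tilde p_{intra}(i)\,\tilde p_{trans}(j) \big)}
#'
#' with \eqn{\tilde S^T} the min-max normalized target similarity, `i`/`j`
#' the pair's target/auxiliary bins, and the trans-layer term taken from the
#' aux-connected or aux-unconnected slice according to the pair's status in
#' the auxiliary layer. The score is a (negated) conditional surprisal in
#' bits: larger means a more likely link.
#'
#' @param net A [multiplex()] object.
#' @param target,auxiliary Layer names (distinct).
#' @param measure Base similarity: `"ra"`, `"cn"`, `"act"` or `"lpi"`.
#' @param train_edges Integer edge matrix, subset of the target layer's
#'   edges used for training (default: all edges).
#' @param b_target,b_aux Bin counts (default 10 each; 10-50 is a sensible
#'   range, more adds nothing but cost).
#' @param negative_ratio Sampled non-edges per training edge in the universe
#'   (default 2).
#' @param epsilon Length-3 path weight when `measure = "lpi"`.
#' @param floor_fraction Floor for zero normalized similarities, as a
#'   fraction of the smallest positive normalized value (default 0.1).
#' @param impute_method `"pls"` or `"linear"`, see [impute_probabilities()].
#' @param universe Optional pre-built [build_pair_universe()] result (must
#'   match `train_edges`); otherwise one is built, using `seed`.
#' @param exclude Pairs barred from the sampled non-edges (passed to
#'   [build_pair_universe()]).
#' @param seed Optional seed for the universe sample.
#' @return An object of class `simbins` with the fitted tables; use
#'   [predict.simbins()] to score pairs, `summary()`/`plot()` to inspect the
#'   probability tables.
#' @examples
#' net <- generate_duplex(n = 60, m_target = 120, m_aux = 120,
#'                        overlap = 0.6, seed = 1)
#' fit <- simbins(net, "target", "aux", measure = "ra", b_target = 5,
#'                b_aux = 5, seed = 1)
#' fit
#' cand <- rbind(c(1L, 2L), c(3L, 9L))
#' predict(fit, cand)
#' @export
simbins <- function(net, target, auxiliary,
                    measure = c("ra", "cn", "act", "lpi"),
                    train_edges = NULL, b_target = 10, b_aux = 10,
                    negative_ratio = 2, epsilon = 1e-4,
                    floor_fraction = 0.1,
                    impute_method = c("pls", "linear"),
                    universe = NULL, exclude = NULL, seed = NULL) {
  stopifnot(inherits(net, "multiplex"))
  measure <- match.arg(measure)
  impute_method <- match.arg(impute_method)
  if (!all(c(target, auxiliary) %in% names(net$layers)))
    stop_config("unknown layer name(s)")
  if (target == auxiliary)
    stop_config("target and auxiliary layers must differ")
  if (is.null(train_edges)) train_edges <- net$layers[[target]]
  train_edges <- canonical_pairs(train_edges)
  if (is.null(universe)) {
    universe <- build_pair_universe(net, target, train_edges,
                                    ratio = negative_ratio,
                                    exclude = exclude, seed = seed)
  }
  adj_t <- layer_adjacency(net, target, edge_subset = train_edges)
  adj_a <- layer_adjacency(net, auxiliary)
  s_t <- similarity_scores(adj_t, universe$pairs, measure, epsilon)
  s_a <- similarity_scores(adj_a, universe$pairs, measure, epsilon)
  part_t <- equal_depth_bins(s_t, universe, b_target)
  part_a <- equal_depth_bins(s_a, universe, b_aux)
  aux_edges <- net$layers[[auxiliary]]
  intra <- intra_layer_probability(part_t, universe)
  trans <- trans_layer_probability(part_a, universe, aux_edges)
  probs <- list(
    p_intra = impute_probabilities(intra$p, impute_method),
    p_trans = impute_probabilities(trans$p, impute_method),
    p_trans_conn = impute_probabilities(trans$p_conn, impute_method),
    p_trans_unconn = impute_probabilities(trans$p_unconn, impute_method))
  structure(list(
    nodes = net$nodes, target = target, auxiliary = auxiliary,
    measure = measure, epsilon = epsilon,
    b_target = b_target, b_aux = b_aux,
    floor_fraction = floor_fraction, impute_method = impute_method,
    train_edges = train_edges, aux_edges = aux_edges,
    adj_target = adj_t, adj_aux = adj_a,
    universe = universe, part_target = part_t, part_aux = part_a,
    raw = list(intra = intra, trans = trans), probs = probs,
    seed = seed), class = "simbins")
}

#' @export
print.simbins <- function(x, ...) {
  cat("SimBins fit: target '", x$target, "' | auxiliary '", x$auxiliary,
      "' (base measure: ", toupper(x$measure), ")\n", sep = "")
  cat("  universe: ", nrow(x$universe$pairs), " pairs (",
      nrow(x$train_edges), " training edges)\n", sep = "")
  cat("  bins: ", x$b_target, " target / ", x$b_aux, " auxiliary (",
      sum(x$raw$intra$imputed), " + ",
      sum(x$raw$trans$imputed$p_conn) + sum(x$raw$trans$imputed$p_unconn),
      " imputed entries)\n", sep = "")
  invisible(x)
}

#' @export
summary.simbins <- function(object, ...) {
  out <- list(
    call_info = object[c("target", "auxiliary", "measure",
                         "b_target", "b_aux")],
    intra = data.frame(bin = seq_len(object$b_target),
                       count = object$raw$intra$counts,
                       p_intra = object$probs$p_intra,
                       imputed = object$raw$intra$imputed),
    trans = data.frame(bin = seq_len(object$b_aux),
                       count = object$raw$trans$n,
                       p_trans = object$probs$p_trans,
                       p_conn = object$probs$p_trans_conn,
                       p_unconn = object$probs$p_trans_unconn,
                       imputed = object$raw$trans$imputed$p))
  class(out) <- "summary.simbins"
  out
}

#' @export
print.summary.simbins <- function(x, ...) {
  ci <- x$call_info
  cat("SimBins fit: '", ci$target, "' from '", ci$auxiliary, "', ",
      toupper(ci$measure), " base measure\n\n", sep = "")
  cat("Intra-layer connection probability (target bins):\n")
  print(x$intra, digits = 3, row.names = FALSE)
  cat("\nTrans-layer connection probability (auxiliary bins):\n")
  print(x$trans, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Bar plot of the fitted per-bin connection probabilities
#'
#' Left panel: intra-layer connection probability by target-similarity bin.
#' Right panel: trans-layer probability by auxiliary-similarity bin, overall
#' and split by auxiliary connectedness. Imputed bars are shaded.
#'
#' @param x A fitted `simbins` object.
#' @param ... Unused.
#' @export
plot.simbins <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2.5, 1))
  on.exit(graphics::par(op))
  dens <- ifelse(x$raw$intra$imputed, 20, NA)
  graphics::barplot(x$probs$p_intra, names.arg = seq_len(x$b_target),
                    density = dens, col = "grey40",
                    xlab = "target similarity bin", ylab = "P(link)",
                    main = "intra-layer")
  m <- rbind(all = x$probs$p_trans, connected = x$probs$p_trans_conn,
             unconnected = x$probs$p_trans_unconn)
  graphics::barplot(m, beside = TRUE, names.arg = seq_len(x$b_aux),
                    col = c("grey60", "grey20", "grey85"),
                    xlab = "auxiliary similarity bin", ylab = "P(link)",
                    main = "trans-layer",
                    legend.text = rownames(m),
                    args.legend = list(x = "topleft", bty = "n", cex = 0.8))
  invisible(x)
}

#' Low-level fused bit score
#'
#' Combines normalized target similarities with bin-indexed fused
#' probabilities into the final score,
#' `log2(s_norm) + log2(fused probability)`. Cells whose fused probability is
#' zero would give `-Inf`; they are replaced by (minimum finite score - 1) so
#' every pair stays rankable, with a message reporting the count.
#'
#' @param s_norm Normalized target similarities in `(0, 1]` (numeric or a
#'   `norm_scores` object).
#' @param bins_target,bins_aux Integer bin indices per pair.
#' @param probs Imputed probability table (as in a fitted `simbins` object).
#' @param aux_connected Logical per pair: linked in the auxiliary layer?
#' @return Numeric score vector (bits; higher = more likely link).
#' @export
simbins_score <- function(s_norm, bins_target, bins_aux, probs,
                          aux_connected) {
  v <- if (inherits(s_norm, "norm_scores")) s_norm$value else
    as.numeric(s_norm)
  fused <- estimate_connection_probability(probs, bins_target, bins_aux,
                                           aux_connected)
  sc <- log2(v) + log2(fused)
  bad <- !is.finite(sc)
  if (any(bad)) {
    message(sum(bad), " pair(s) with zero fused probability ranked below ",
            "all finite scores")
    sc[bad] <- if (all(bad)) -1 else min(sc[!bad]) - 1
  }
  sc
}

#' Score node pairs with a fitted model
#'
#' Computes the fused bit score for arbitrary node pairs. Target similarity
#' is computed on the training adjacency (test edges are never read),
#' min-max normalized over the supplied pair set; pairs are assigned to bins
#' through the boundaries stored at fit time, and their auxiliary
#' connectedness picks the trans-layer slice.
#'
#' @param object A fitted `simbins` object.
#' @param pairs Integer matrix of node-index pairs to score.
#' @param ... Unused.
#' @return Data frame with node labels `u`, `v` and `score` (bits).
#' @export
predict.simbins <- function(object, pairs, ...) {
  pairs <- orient_pairs(pairs)
  if (!nrow(pairs)) stop("no pairs to score")
  s_t <- similarity_scores(object$adj_target, pairs, object$measure,
                           object$epsilon)
  s_a <- similarity_scores(object$adj_aux, pairs, object$measure,
                           object$epsilon)
  s_norm <- minmax_normalize(s_t, object$floor_fraction)
  bt <- assign_bins(object$part_target, s_t)
  ba <- assign_bins(object$part_aux, s_a)
  n <- length(object$nodes)
  conn <- pair_rank(pairs[, 1], pairs[, 2], n) %in%
    edge_keys(object$aux_edges, n)
  sc <- simbins_score(s_norm, bt, ba, object$probs, conn)
  data.frame(u = object$nodes[pairs[, 1]], v = object$nodes[pairs[, 2]],
             score = sc)
}

#' Multi-auxiliary extension: sum of per-duplex fits
#'
#' With several auxiliary layers the simplest combination is the sum of the
#' per-duplex scores, one fit per (target, auxiliary) pair.
#'
#' @param net A [multiplex()] object.
#' @param target Target layer name.
#' @param aux_layers Character vector of at least one auxiliary layer.
#' @param ... Passed to [simbins()] for every duplex.
#' @return An object of class `simbins_multi` (list of fits); its `predict`
#'   method returns the summed scores.
#' @export
simbins_multi <- function(net, target, aux_layers, ...) {
  if (length(aux_layers) < 1) stop_config("need at least one auxiliary layer")
  fits <- lapply(aux_layers, function(a) simbins(net, target, a, ...))
  names(fits) <- aux_layers
  structure(list(target = target, fits = fits), class = "simbins_multi")
}

#' @export
predict.simbins_multi <- function(object, pairs, ...) {
  parts <- lapply(object$fits, predict, pairs = pairs)
  out <- parts[[1]]
  if (length(parts) > 1)
    out$score <- Reduce(`+`, lapply(parts, `[[`, "score"))
  out
}

#' @export
print.simbins_multi <- function(x, ...) {
  cat("SimBins multi-auxiliary fit: target '", x$target, "', ",
      length(x$fits), " auxiliary layer(s): ",
      paste(names(x$fits), collapse = ", "), "\n", sep = "")
  invisible(x)
}
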