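#' Baseline scorers
#'
#' `score_baseline_target` ranks pairs by the raw base similarity in the
#' target layer alone; `score_baseline_sum` by the elementwise sum of the raw
#' target- and auxiliary-layer similarities (no normalization). Both take
#' `sim_scores` objects or plain numeric vectors aligned on the same pairs.
#'
#' @param target_scores,aux_scores Similarity scores per pair.
#' @return Numeric score vector.
#' @export
score_baseline_target <- function(target_scores) {
  if (inherits(target_scores, "sim_scores")) target_scores$score
  else as.numeric(target_scores)
}

#' @rdname score_baseline_target
#' @export
score_baseline_sum <- function(target_scores, aux_scores) {
  st <- score_baseline_target(target_scores)
  sa <- score_baseline_target(aux_scores)
  if (length(st) != length(sa)) stop("score vectors differ in length")
  st + sa
}

#' Global overlap rate of two layers
#'
#' Edge-set overlap between two layers as a layer-relevance weight. The
#' default is the Jaccard form `|E_T n E_A| / |E_T u E_A|`; `type = "min"`
#' normalizes by the smaller layer instead.
#'
#' @param edges_target,edges_aux Integer edge matrices over a common node
#'   index of `n` nodes.
#' @param n Number of nodes in the shared index.
#' @param type `"jaccard"` (default) or `"min"`.
#' @return Overlap rate in `[0, 1]`.
#' @export
gor <- function(edges_target, edges_aux, n, type = c("jaccard", "min")) {
  type <- match.arg(type)
  et <- edge_keys(canonical_pairs(edges_target), n)
  ea <- edge_keys(canonical_pairs(edges_aux), n)
  if (!length(et) && !length(ea))
    stop("overlap rate undefined for two empty layers", call. = FALSE)
  inter <- length(intersect(et, ea))
  den <- switch(type, jaccard = length(union(et, ea)),
                min = min(length(et), length(ea)))
  inter / den
}

#' Degree-correlation layer relevance
#'
#' Pearson correlation between the per-node degree vectors of two layers
#' over the shared node index, clamped below at 0 (a negative relevance
#' would flip the auxiliary ranking in the weighted comparator, which is not
#' intended). Zero-variance degree vectors give relevance 0 with a warning.
#'
#' @param net A [multiplex()] object.
#' @param layer_target,layer_aux Layer names.
#' @return Relevance in `[0, 1]`.
#' @export
pcc_relevance <- function(net, layer_target, layer_aux) {
  stopifnot(inherits(net, "multiplex"))
  n <- length(net$nodes)
  if (n < 3) stop_config("need at least 3 shared nodes")
  deg <- function(layer) {
    e <- net$layers[[layer]]
    if (is.null(e)) stop_config("unknown layer: ", layer)
    tabulate(as.vector(e), n)
  }
  dt <- deg(layer_target); da <- deg(layer_aux)
  if (stats::sd(dt) == 0 || stats::sd(da) == 0) {
    warning("zero-variance degree vector; relevance set to 0")
    return(0)
  }
  max(0, stats::cor(dt, da))
}

#' Relevance-weighted two-layer score
#'
#' The comparator scoring schema
#' `(1 - phi) * S_T + phi * mu * S_A`, a convex combination of the raw
#' target- and auxiliary-layer similarities weighted by a scalar layer
#' relevance `mu` (overlap rate or degree correlation). `phi = 0.5` is the
#' recommended balance.
#'
#' @param target_scores,aux_scores Similarity scores per pair (`sim_scores`
#'   or numeric).
#' @param mu Layer relevance in `[0, 1]` (from [gor()] or
#'   [pcc_relevance()]).
#' @param phi Mixing weight in `[0, 1]` (default 0.5).
#' @return Numeric score vector.
#' @export
relevance_weighted_score <- function(target_scores, aux_scores, mu,
                                     phi = 0.5) {
  if (phi < 0 || phi > 1) stop_config("'phi' must be in [0, 1]")
  st <- score_baseline_target(target_scores)
  sa <- score_baseline_target(aux_scores)
  (1 - phi) * st + phi * mu * sa
}
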