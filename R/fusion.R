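#' Probabilistic fusion operators
#'
#' Combine two probabilities for the same binary event into a consensus.
#' `or_fuse(p, q) = p + q - pq` treats the inputs as independent evidence for
#' the event (the probabilistic union), so it never falls below either input
#' and is robust to one weak source; `and_fuse(p, q) = pq` is the
#' conjunction, never above either input. The link score uses the OR form:
#' either high in-layer similarity or a favourable auxiliary bin should be
#' enough to raise the connection estimate.
#'
#' @param p,q Probabilities in `[0, 1]` (vectorized).
#' @return Fused probabilities in `[0, 1]`.
#' @examples
#' or_fuse(0.5, 0.5)   # 0.75
#' and_fuse(0.5, 0.5)  # 0.25
#' @export
or_fuse <- function(p, q) {
  check_prob(p); check_prob(q)
  p + q - p * q
}

#' @rdname or_fuse
#' @export
and_fuse <- function(p, q) {
  check_prob(p); check_prob(q)
  p * q
}

check_prob <- function(x) {
  if (anyNA(x) || any(x < 0 | x > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  invisible(x)
}

#' Estimated connection probability for a 2-D bin cell
#'
#' The OR fusion of the intra-layer connection probability of target bin `i`
#' with the trans-layer probability of auxiliary bin `j`, where the
#' trans-layer side is the aux-connected slice when the pair is linked in the
#' auxiliary layer and the aux-unconnected slice otherwise.
#'
#' @param probs A fully imputed probability table, as stored in a fitted
#'   [simbins()] object (`list(p_intra, p_trans_conn, p_trans_unconn)`).
#' @param i,j Target and auxiliary bin indices (vectorized).
#' @param aux_connected Logical (vectorized): is the pair an auxiliary-layer
#'   edge?
#' @return Fused probabilities in `[0, 1]`.
#' @export
estimate_connection_probability <- function(probs, i, j, aux_connected) {
  p_int <- probs$p_intra[i]
  p_tr <- ifelse(aux_connected, probs$p_trans_conn[j], probs$p_trans_unconn[j])
  if (anyNA(p_int) || anyNA(p_tr))
    stop("probability table contains unimputed entries", call. = FALSE)
  or_fuse(p_int, p_tr)
}
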