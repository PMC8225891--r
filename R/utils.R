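# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards. A `NULL` seed leaves the
#' current stream untouched, which is how the experiment runner threads one
#' master seed through every stage of an iteration.
#' @noRd
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Lexicographic rank of unordered pairs (u < v) over n nodes, 1-based.
# rank(u, v) = (u - 1) * n - u * (u - 1) / 2 + (v - u)
pair_rank <- function(u, v, n) {
  (u - 1) * n - u * (u - 1) / 2 + (v - u)
}

# Inverse of pair_rank: vectorized unranking via the cumulative count of
# pairs with first element <= u (there are n - u pairs for each u).
pair_unrank <- function(p, n) {
  ends <- cumsum(rev(seq_len(n - 1)))  # last rank with first element u
  u <- findInterval(p - 1, ends) + 1L
  starts <- c(0, ends)[u]
  v <- u + (p - starts)
  cbind(u = u, v = as.integer(v))
}

# Canonicalize an integer edge/pair matrix: u < v per row, drop self-pairs
# and duplicates, sort rows lexicographically.
canonical_pairs <- function(m, n = NULL) {
  m <- matrix(as.integer(m), ncol = 2)
  keep <- m[, 1] != m[, 2]
  m <- m[keep, , drop = FALSE]
  if (nrow(m)) {
    swap <- m[, 1] > m[, 2]
    m[swap, ] <- m[swap, 2:1]
    m <- m[!duplicated(m), , drop = FALSE]
    m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  }
  dimnames(m) <- list(NULL, c("u", "v"))
  m
}

# Orient pairs u < v without reordering or deduplicating rows.
orient_pairs <- function(m) {
  m <- matrix(as.integer(m), ncol = 2)
  if (any(m[, 1] == m[, 2])) stop("self-pairs are not scoreable", call. = FALSE)
  swap <- m[, 1] > m[, 2]
  m[swap, ] <- m[swap, 2:1]
  dimnames(m) <- list(NULL, c("u", "v"))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(..., call. = FALSE)
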