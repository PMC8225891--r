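#' Build the training pair universe
#'
#' The training universe \eqn{U'} is the set of node pairs over which
#' connection probabilities are estimated: the training edges of the target
#' layer plus a seeded uniform sample of non-edges. Non-edges are drawn from
#' all unordered pairs minus the *full* target edge set, so no held-out test
#' edge can be mislabelled as a negative. The sample is `ratio` times the
#' number of training edges (default 2), mirroring the link imbalance of real
#' networks; if fewer non-edges exist, all are used with a warning.
#'
#' @param net A [multiplex()] object.
#' @param target Target layer name.
#' @param train_edges Integer edge matrix, a subset of the target layer's
#'   edges (default: all of them).
#' @param ratio Non-edges sampled per training edge (default 2).
#' @param exclude Optional integer pair matrix of additional pairs barred
#'   from the non-edge sample (e.g. an already drawn test negative set).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `pair_universe`: data frame fields `pairs`
#'   (integer matrix), `label` (1 = training edge, 0 = sampled non-edge),
#'   plus `n_nodes` and `target`.
#' @export
build_pair_universe <- function(net, target, train_edges = NULL, ratio = 2,
                                exclude = NULL, seed = NULL) {
  stopifnot(inherits(net, "multiplex"))
  if (!target %in% names(net$layers)) stop_config("unknown layer: ", target)
  if (ratio < 1) stop_config("'ratio' must be >= 1")
  full <- net$layers[[target]]
  n <- length(net$nodes)
  train_edges <- if (is.null(train_edges)) full else canonical_pairs(train_edges)
  np <- n * (n - 1) / 2
  barred <- c(edge_keys(full, n),
              if (!is.null(exclude)) {
                ex <- canonical_pairs(exclude)
                edge_keys(ex, n)
              })
  avail <- setdiff(seq_len(np), barred)
  need <- ratio * nrow(train_edges)
  z <- local_seed(seed, {
    if (length(avail) < need) {
      warning("only ", length(avail), " non-edges available; using all ",
              "(requested ", need, ")")
      avail
    } else {
      sample(avail, need)
    }
  })
  zp <- pair_unrank(sort(z), n)
  pairs <- rbind(train_edges, zp)
  structure(list(pairs = pairs,
                 label = rep(c(1L, 0L), c(nrow(train_edges), nrow(zp))),
                 n_nodes = n, target = target),
            class = "pair_universe")
}

#' @export
print.pair_universe <- function(x, ...) {
  cat("Pair universe for layer '", x$target, "': ", nrow(x$pairs),
      " pairs (", sum(x$label), " linked, ", sum(x$label == 0),
      " sampled non-edges)\n", sep = "")
  invisible(x)
}

#' Equal-depth (frequency) binning of similarity scores
#'
#' Partitions the universe into `b` bins of approximately equal size by
#' ascending similarity. Pairs with identical scores must land in the same
#' bin (otherwise membership would depend on sort stability); each tie block
#' is assigned the bin of its median rank. Heavily tied score distributions
#' (e.g. the many exact zeros of resource allocation) therefore produce some
#' empty bins, whose probabilities are later imputed.
#'
#' @param scores A `sim_scores` object (or numeric vector) aligned with the
#'   universe's pairs.
#' @param universe A `pair_universe` object.
#' @param b Number of bins (>= 2, at most the universe size).
#' @return An object of class `bin_partition`: `b`, integer `bin` per pair
#'   (increasing with score), per-bin `counts`, and the stored boundaries
#'   (`upper` score per non-empty bin) used to bin new pairs at prediction
#'   time.
#' @export
equal_depth_bins <- function(scores, universe, b) {
  s <- if (inherits(scores, "sim_scores")) scores$score else as.numeric(scores)
  stopifnot(inherits(universe, "pair_universe"))
  np <- nrow(universe$pairs)
  if (length(s) != np) stop("scores are not aligned with the universe")
  b <- as.integer(b)
  if (b < 2) stop_config("'b' must be at least 2")
  if (b > np) stop_config("more bins (", b, ") than pairs (", np, ")")
  ord <- order(s)
  rank <- integer(np); rank[ord] <- seq_len(np)
  # median rank of each tie block decides the whole block's bin
  grp <- match(s, sort(unique(s)))
  rmin <- tapply(rank, grp, min)
  rmax <- tapply(rank, grp, max)
  rmed <- floor((rmin + rmax) / 2)
  gbin <- as.integer(floor((rmed - 1) * b / np) + 1)
  bin <- gbin[grp]
  counts <- tabulate(bin, b)
  nonempty <- which(counts > 0)
  upper <- vapply(nonempty, function(k) max(s[bin == k]), numeric(1))
  structure(list(b = b, bin = bin, counts = counts,
                 nonempty = nonempty, upper = upper),
            class = "bin_partition")
}

#' @export
print.bin_partition <- function(x, ...) {
  cat("Equal-depth partition into", x$b, "bins (",
      sum(x$counts == 0), "empty )\n")
  print(stats::setNames(x$counts, paste0("bin", seq_len(x$b))))
  invisible(x)
}

#' Map new scores to stored bin boundaries
#'
#' Assigns pairs scored at prediction time (outside the training universe) to
#' bins using the boundaries stored by [equal_depth_bins()]: a score at or
#' below a non-empty bin's upper boundary falls in that bin; scores above the
#' highest boundary fall in bin `b`.
#'
#' @param part A `bin_partition`.
#' @param scores Numeric scores (or `sim_scores`).
#' @return Integer bin indices in `1..b`.
#' @export
assign_bins <- function(part, scores) {
  stopifnot(inherits(part, "bin_partition"))
  s <- if (inherits(scores, "sim_scores")) scores$score else as.numeric(scores)
  pos <- findInterval(s, part$upper, left.open = TRUE) + 1L
  out <- integer(length(s))
  inside <- pos <= length(part$nonempty)
  out[inside] <- part$nonempty[pos[inside]]
  out[!inside] <- part$b
  out
}

#' Intra-layer connection probability per bin
#'
#' For each target-similarity bin, the fraction of its pairs that are linked
#' in the target training edge set. Empty bins get `NA` and are flagged for
#' imputation.
#'
#' @param part A `bin_partition` built from target-layer scores of the
#'   universe.
#' @param universe The `pair_universe` the partition was built on.
#' @return List with `p` (length `b`, `NA` where empty), `counts`, and
#'   logical `imputed` flags.
#' @export
intra_layer_probability <- function(part, universe) {
  stopifnot(inherits(part, "bin_partition"), inherits(universe, "pair_universe"))
  if (length(part$bin) != nrow(universe$pairs))
    stop("partition and universe sizes differ")
  linked <- tabulate(part$bin[universe$label == 1L], part$b)
  p <- ifelse(part$counts > 0, linked / part$counts, NA_real_)
  list(p = p, counts = part$counts, imputed = is.na(p))
}

#' Trans-layer connection probability per auxiliary bin
#'
#' For each auxiliary-similarity bin, the fraction of its pairs linked in the
#' *target* training edge set: overall (`p`), and split by whether the pair
#' is connected in the auxiliary layer (`p_conn` over the aux-connected
#' pairs, `p_unconn` over the rest). Empty denominators get `NA` and are
#' flagged.
#'
#' @param part A `bin_partition` built from auxiliary-layer scores of the
#'   universe.
#' @param universe The `pair_universe` the partition was built on.
#' @param aux_edges Integer edge matrix: the full auxiliary layer edge set.
#' @return List with vectors `p`, `p_conn`, `p_unconn`, counts `n`,
#'   `n_conn`, `n_unconn`, and logical flag lists `imputed`.
#' @export
trans_layer_probability <- function(part, universe, aux_edges) {
  stopifnot(inherits(part, "bin_partition"), inherits(universe, "pair_universe"))
  if (length(part$bin) != nrow(universe$pairs))
    stop("partition and universe sizes differ")
  n <- universe$n_nodes
  aux_edges <- canonical_pairs(aux_edges)
  conn <- pair_rank(universe$pairs[, 1], universe$pairs[, 2], n) %in%
    edge_keys(aux_edges, n)
  lab <- universe$label == 1L
  tab <- function(which) tabulate(part$bin[which], part$b)
  n_all <- part$counts
  n_conn <- tab(conn)
  n_unconn <- tab(!conn)
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  p <- ratio(tab(lab), n_all)
  p_conn <- ratio(tab(lab & conn), n_conn)
  p_unconn <- ratio(tab(lab & !conn), n_unconn)
  list(p = p, p_conn = p_conn, p_unconn = p_unconn,
       n = n_all, n_conn = n_conn, n_unconn = n_unconn,
       imputed = list(p = is.na(p), p_conn = is.na(p_conn),
                      p_unconn = is.na(p_unconn)))
}

#' Impute missing bin probabilities
#'
#' Fills `NA` entries of a per-bin probability vector. The default imputes by
#' 1-D penalized least-squares smoothing over the bin-index axis, in the
#' discrete-cosine-transform formulation with the smoothing parameter chosen
#' by generalized cross-validation; `method = "linear"` is a simple fallback
#' (linear interpolation with edge extension). Observed entries are returned
#' unchanged; imputed values are clamped to `[0, 1]`.
#'
#' @param values Numeric vector with `NA`s at the missing bins.
#' @param method `"pls"` (penalized least squares, default) or `"linear"`.
#' @return Numeric vector with no `NA`s.
#' @export
impute_probabilities <- function(values, method = c("pls", "linear")) {
  method <- match.arg(method)
  miss <- is.na(values)
  if (all(miss)) stop("cannot impute: all entries missing")
  if (!any(miss)) return(values)
  nb <- length(values)
  obs <- which(!miss)
  filled <- if (method == "linear" || length(obs) < 3) {
    if (length(obs) == 1) rep(values[obs], nb)
    else stats::approx(obs, values[obs], xout = seq_len(nb), rule = 2)$y
  } else {
    smooth_pls_gcv(values, miss)
  }
  values[miss] <- pmin(pmax(filled[miss], 0), 1)
  values
}

# DCT-II matrix (orthonormal) for the penalized least squares smoother.
dct_matrix <- function(n) {
  k <- 0:(n - 1)
  i <- 0:(n - 1)
  m <- sqrt(2 / n) * cos(pi * outer(k, 2 * i + 1) / (2 * n))
  m[1, ] <- m[1, ] / sqrt(2)
  m
}

# Penalized least-squares smoothing of a 1-D grid with missing entries:
# minimizes ||w^(1/2)(z - y)||^2 + s ||D z||^2 via the DCT eigenbasis of the
# second-difference penalty, iterating on the missing entries; the smoothing
# parameter s is picked by generalized cross-validation.
smooth_pls_gcv <- function(y, miss) {
  n <- length(y)
  dct <- dct_matrix(n)
  lambda <- -2 + 2 * cos((0:(n - 1)) * pi / n)
  w <- as.numeric(!miss)
  y0 <- y
  y0[miss] <- stats::approx(which(!miss), y[!miss], xout = which(miss),
                            rule = 2)$y
  yv <- ifelse(miss, 0, y)
  smooth_once <- function(s) {
    gamma <- 1 / (1 + s * lambda^2)
    z <- y0
    for (it in 1:200) {
      znew <- as.numeric(t(dct) %*% (gamma * as.numeric(dct %*% (w * (yv - z) + z))))
      if (max(abs(znew - z)) < 1e-10) { z <- znew; break }
      z <- znew
    }
    z
  }
  gcv <- function(log10s) {
    s <- 10^log10s
    z <- smooth_once(s)
    gamma <- 1 / (1 + s * lambda^2)
    rss <- sum(w * (yv - z)^2)
    trh <- sum(gamma)
    nobs <- sum(w)
    rss / nobs / (1 - trh / n)^2
  }
  opt <- stats::optimize(gcv, interval = c(-6, 6))
  smooth_once(10^opt$minimum)
}

#' Empirical connection probability on 2-D bins
#'
#' Diagnostic grid: partition the universe simultaneously by target and
#' auxiliary similarity and report, per 2-D cell, the fraction of pairs
#' linked in the target training set. Empty cells are `NaN`. This grid
#' visualizes the cross-layer correlation the fused score exploits; the
#' scoring path itself uses the 1-D tables.
#'
#' @param part_target,part_aux `bin_partition` objects over the same
#'   universe.
#' @param universe The shared `pair_universe`.
#' @return A `b_T x b_A` matrix of probabilities with counts in attribute
#'   `"counts"`.
#' @export
twod_bin_probabilities <- function(part_target, part_aux, universe) {
  stopifnot(inherits(part_target, "bin_partition"),
            inherits(part_aux, "bin_partition"),
            inherits(universe, "pair_universe"))
  np <- nrow(universe$pairs)
  if (length(part_target$bin) != np || length(part_aux$bin) != np)
    stop("partitions were not built on this universe")
  bt <- part_target$b; ba <- part_aux$b
  idx <- (part_aux$bin - 1L) * bt + part_target$bin
  counts <- matrix(tabulate(idx, bt * ba), bt, ba)
  linked <- matrix(tabulate(idx[universe$label == 1L], bt * ba), bt, ba)
  grid <- linked / counts  # 0/0 -> NaN marks empty cells
  dimnames(grid) <- list(paste0("T", seq_len(bt)), paste0("A", seq_len(ba)))
  attr(grid, "counts") <- counts
  grid
}
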