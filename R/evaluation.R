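#' Random train/test split of a target layer
#'
#' Splits the target layer's edges uniformly at random into a training set
#' (`train_ratio`, default 90%) and a held-out test set, and samples a test
#' negative set of non-edges twice the size of the test set (from all
#' unordered pairs minus the full target edge set, so negatives are real
#' non-edges).
#'
#' @param net A [multiplex()] object.
#' @param target Target layer name (at least 10 edges).
#' @param train_ratio Fraction of edges kept for training, in `(0, 1)`.
#' @param negative_ratio Test negatives per test edge (default 2).
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return An object of class `edge_split`: integer edge matrices `train`
#'   and `test`, pair matrix `z_test`, and the settings used.
#' @export
split_edges <- function(net, target, train_ratio = 0.9, negative_ratio = 2,
                        seed = NULL) {
  stopifnot(inherits(net, "multiplex"))
  if (!target %in% names(net$layers)) stop_config("unknown layer: ", target)
  if (train_ratio <= 0 || train_ratio >= 1)
    stop_config("'train_ratio' must be in (0, 1)")
  edges <- net$layers[[target]]
  m <- nrow(edges)
  if (m < 10) stop_config("target layer has fewer than 10 edges")
  n <- length(net$nodes)
  local_seed(seed, {
    n_train <- floor(train_ratio * m)
    idx <- sample.int(m, n_train)
    train <- edges[sort(idx), , drop = FALSE]
    test <- edges[sort(setdiff(seq_len(m), idx)), , drop = FALSE]
    np <- n * (n - 1) / 2
    avail <- setdiff(seq_len(np), edge_keys(edges, n))
    need <- negative_ratio * nrow(test)
    z <- if (length(avail) < need) {
      warning("only ", length(avail), " non-edges available for the test ",
              "negative set (requested ", need, ")")
      avail
    } else sample(avail, need)
    structure(list(train = train, test = test,
                   z_test = pair_unrank(sort(z), n),
                   target = target, train_ratio = train_ratio,
                   negative_ratio = negative_ratio, n_nodes = n),
              class = "edge_split")
  })
}

#' @export
print.edge_split <- function(x, ...) {
  cat("Edge split of layer '", x$target, "': ", nrow(x$train), " train / ",
      nrow(x$test), " test edges, ", nrow(x$z_test),
      " test non-edges\n", sep = "")
  invisible(x)
}

#' Sampled AUC for a scored candidate set
#'
#' Estimates the probability that a randomly chosen missing link outscores a
#' randomly chosen non-existent link by `n` independent with-replacement
#' comparisons: `AUC = (n' + 0.5 n'') / n`, with `n'` strict wins for the
#' positive and `n''` ties. Perfect separation gives exactly 1; identically
#' distributed scores give 0.5 in expectation.
#'
#' @param scores_pos Scores of the held-out test links.
#' @param scores_neg Scores of the sampled non-links.
#' @param n Number of comparisons (default 10000).
#' @param seed Optional seed.
#' @return AUC estimate in `[0, 1]`.
#' @export
auc_sampled <- function(scores_pos, scores_neg, n = 10000, seed = NULL) {
  if (!length(scores_pos) || !length(scores_neg))
    stop("both score sets must be non-empty", call. = FALSE)
  if (n < 1) stop_config("'n' must be >= 1")
  local_seed(seed, {
    p <- scores_pos[sample.int(length(scores_pos), n, replace = TRUE)]
    q <- scores_neg[sample.int(length(scores_neg), n, replace = TRUE)]
    (sum(p > q) + 0.5 * sum(p == q)) / n
  })
}

#' Precision at the top of the ranking
#'
#' Fraction of true missing links among the top `L` scored candidates. Ties
#' at the cut are broken by a seeded uniform shuffle, which is deterministic
#' given the seed and unbiased in expectation.
#'
#' @param scores Candidate scores (test links and non-links together).
#' @param labels 0/1 labels aligned with `scores` (1 = held-out test link).
#' @param L Cut depth; defaults to the number of test links.
#' @param seed Optional seed for tie-breaking.
#' @return Precision in `[0, 1]`.
#' @export
precision_at_l <- function(scores, labels, L = NULL, seed = NULL) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  labels <- as.integer(labels)
  L <- L %||% sum(labels == 1L)
  if (L < 1 || L > length(scores)) stop_config("'L' out of range")
  local_seed(seed, {
    shuffle <- sample.int(length(scores))
    top <- order(-scores[shuffle])[seq_len(L)]
    sum(labels[shuffle][top]) / L
  })
}

#' Repeated-split evaluation of link prediction methods on a duplex
#'
#' For each iteration: draw a fresh seeded train/test split of the target
#' layer, build the training universe and fit the bin-fusion model on the
#' training edges, score the candidate set (test links plus test non-links)
#' with every requested method, and record sampled AUC and precision.
#' Methods: `"simbins"` (the fused score), `"target"` (raw target
#' similarity), `"sum"` (raw target + auxiliary similarity), `"yao_gl"` /
#' `"yao_pl"` (relevance-weighted combination with overlap-rate /
#' degree-correlation relevance). Candidates alone are scored, not all of
#' `U`; pass the full pair set to [predict.simbins()] for a complete
#' ranking.
#'
#' @param net A [multiplex()] object.
#' @param target,auxiliary Layer names.
#' @param measure Base similarity measure.
#' @param methods Subset of `c("simbins", "target", "sum", "yao_gl",
#'   "yao_pl")`.
#' @param iterations Number of repeated splits (default 10).
#' @param train_ratio,negative_ratio Split settings (defaults 0.9 and 2).
#' @param b_target,b_aux,epsilon,floor_fraction,impute_method Model settings
#'   passed to [simbins()].
#' @param phi Mixing weight of the relevance-weighted comparators.
#' @param auc_n Comparisons per AUC estimate (default 10000).
#' @param seed Master seed; per-iteration seeds are derived from it.
#' @return An object of class `mlp_eval`: long data frame `results`
#'   (iteration, method, auc, precision) plus metadata; `summary()` gives
#'   per-method means and standard errors.
#' @export
run_experiment <- function(net, target, auxiliary,
                           measure = c("ra", "cn", "act", "lpi"),
                           methods = c("simbins", "target", "sum"),
                           iterations = 10, train_ratio = 0.9,
                           negative_ratio = 2, b_target = 10, b_aux = 10,
                           epsilon = 1e-4, floor_fraction = 0.1,
                           impute_method = "pls", phi = 0.5,
                           auc_n = 10000, seed = 1) {
  stopifnot(inherits(net, "multiplex"))
  measure <- match.arg(measure)
  methods <- match.arg(methods, c("simbins", "target", "sum",
                                  "yao_gl", "yao_pl"), several.ok = TRUE)
  if (iterations < 1) stop_config("'iterations' must be >= 1")
  iter_seeds <- local_seed(seed,
    sample.int(.Machine$integer.max - 1L, iterations))
  n <- length(net$nodes)
  rows <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    rows[[it]] <- local_seed(iter_seeds[it], {
      split <- split_edges(net, target, train_ratio, negative_ratio)
      cand <- rbind(split$test, split$z_test)
      labels <- rep(c(1L, 0L), c(nrow(split$test), nrow(split$z_test)))
      fit <- simbins(net, target, auxiliary, measure = measure,
                     train_edges = split$train, b_target = b_target,
                     b_aux = b_aux, negative_ratio = negative_ratio,
                     epsilon = epsilon, floor_fraction = floor_fraction,
                     impute_method = impute_method, exclude = split$z_test)
      s_t <- similarity_scores(fit$adj_target, cand, measure, epsilon)
      s_a <- similarity_scores(fit$adj_aux, cand, measure, epsilon)
      score_method <- function(method) switch(method,
        simbins = suppressMessages(predict(fit, cand)$score),
        target = score_baseline_target(s_t),
        sum = score_baseline_sum(s_t, s_a),
        yao_gl = relevance_weighted_score(s_t, s_a,
          gor(split$train, fit$aux_edges, n), phi),
        yao_pl = relevance_weighted_score(s_t, s_a, {
          dt <- tabulate(as.vector(split$train), n)
          da <- tabulate(as.vector(fit$aux_edges), n)
          if (stats::sd(dt) == 0 || stats::sd(da) == 0) 0
          else max(0, stats::cor(dt, da))
        }, phi))
      do.call(rbind, lapply(methods, function(mth) {
        sc <- score_method(mth)
        data.frame(iteration = it, method = mth,
                   auc = auc_sampled(sc[labels == 1L], sc[labels == 0L],
                                     n = auc_n),
                   precision = precision_at_l(sc, labels))
      }))
    })
  }
  structure(list(results = do.call(rbind, rows),
                 target = target, auxiliary = auxiliary, measure = measure,
                 iterations = iterations, seed = seed,
                 settings = list(train_ratio = train_ratio,
                                 negative_ratio = negative_ratio,
                                 b_target = b_target, b_aux = b_aux,
                                 epsilon = epsilon, phi = phi,
                                 auc_n = auc_n)),
            class = "mlp_eval")
}

#' @export
summary.mlp_eval <- function(object, ...) {
  r <- object$results
  agg <- do.call(rbind, lapply(split(r, r$method), function(d) {
    data.frame(method = d$method[1], iterations = nrow(d),
               auc_mean = mean(d$auc),
               auc_se = stats::sd(d$auc) / sqrt(nrow(d)),
               precision_mean = mean(d$precision),
               precision_se = stats::sd(d$precision) / sqrt(nrow(d)))
  }))
  rownames(agg) <- NULL
  attr(agg, "header") <- sprintf(
    "%s <- %s (%s), %d iteration(s)", object$target, object$auxiliary,
    toupper(object$measure), object$iterations)
  class(agg) <- c("summary.mlp_eval", "data.frame")
  agg
}

#' @export
print.summary.mlp_eval <- function(x, ...) {
  cat("Link prediction evaluation:", attr(x, "header"), "\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' @export
print.mlp_eval <- function(x, ...) {
  print(summary(x))
  invisible(x)
}
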