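test_that("pair universe has the 2:1 negative convention and is seeded", {
  set.seed(1)
  net <- generate_duplex(40, 100, 100, overlap = 0.5)
  u1 <- build_pair_universe(net, "target", ratio = 2, seed = 9)
  expect_equal(nrow(u1$pairs), 300L)
  expect_equal(sum(u1$label), 100L)
  u2 <- build_pair_universe(net, "target", ratio = 2, seed = 9)
  expect_identical(u1, u2)
  u3 <- build_pair_universe(net, "target", ratio = 2, seed = 10)
  expect_false(identical(u1$pairs, u3$pairs))
  # sampled non-edges are disjoint from the full target edge set
  keys <- pair_rank(u1$pairs[, 1], u1$pairs[, 2], 40)
  tkeys <- pair_rank(net$layers$target[, 1], net$layers$target[, 2], 40)
  expect_length(intersect(keys[u1$label == 0], tkeys), 0)
  # excluded pairs never appear among the negatives
  excl <- u1$pairs[u1$label == 0, ][1:20, ]
  u4 <- build_pair_universe(net, "target", ratio = 2, exclude = excl,
                            seed = 9)
  k4 <- pair_rank(u4$pairs[, 1], u4$pairs[, 2], 40)
  expect_length(intersect(k4, pair_rank(excl[, 1], excl[, 2], 40)), 0)
})

test_that("universe on a near-complete layer uses all non-edges with warning", {
  nodes <- letters[1:5]
  all_e <- t(combn(nodes, 2))
  net <- multiplex(list(target = all_e[1:9, ], aux = all_e[1:3, ]),
                   nodes = nodes)
  expect_warning(u <- build_pair_universe(net, "target", ratio = 2),
                 "non-edges available")
  expect_equal(sum(u$label == 0), 1L)  # 10 pairs - 9 edges
})

test_that("equal-depth bins are balanced for distinct scores", {
  net <- generate_duplex(20, 40, 40, overlap = 0, seed = 3)
  u <- build_pair_universe(net, "target", ratio = 2, seed = 3)
  s <- seq_len(nrow(u$pairs)) / 7  # 120 distinct scores
  part <- equal_depth_bins(s, u, 2)
  expect_equal(part$counts, c(60L, 60L))
  part10 <- equal_depth_bins(s, u, 10)
  expect_equal(part10$counts, rep(12L, 10))
  # bin index is non-decreasing in score
  expect_true(all(diff(part10$bin[order(s)]) >= 0))
  expect_error(equal_depth_bins(s, u, 1), "at least 2")
  expect_error(equal_depth_bins(s, u, 1000), "more bins")
})

test_that("tied scores share a bin, producing empty bins", {
  net <- generate_duplex(20, 40, 40, overlap = 0, seed = 4)
  u <- build_pair_universe(net, "target", ratio = 2, seed = 4)
  s <- rep(0, nrow(u$pairs)); s[1] <- 5
  part <- equal_depth_bins(s, u, 10)
  expect_equal(sum(part$counts == 0), 8L)
  expect_equal(part$counts[10], 1L)       # the singleton top score
  expect_equal(sum(part$counts), nrow(u$pairs))
  # all tied pairs landed in one bin
  expect_length(unique(part$bin[s == 0]), 1L)
})

test_that("new scores map through stored boundaries", {
  net <- generate_duplex(20, 40, 40, overlap = 0, seed = 5)
  u <- build_pair_universe(net, "target", ratio = 2, seed = 5)
  s <- runif(nrow(u$pairs))
  part <- equal_depth_bins(s, u, 6)
  # training scores map back to their own bins
  expect_equal(assign_bins(part, s), part$bin)
  # below the lowest boundary -> bin 1; above the highest -> bin b
  expect_equal(assign_bins(part, min(s) - 1), 1L)
  expect_equal(assign_bins(part, max(s) + 1), 6L)
})

test_that("per-bin probabilities are exact count ratios that conserve totals", {
  set.seed(6)
  net <- generate_duplex(40, 120, 120, overlap = 0.5)
  u <- build_pair_universe(net, "target", ratio = 2, seed = 6)
  adj_t <- layer_adjacency(net, "target")
  s_t <- similarity_scores(adj_t, u$pairs, "ra")
  part <- equal_depth_bins(s_t, u, 10)
  # partition conservation
  expect_equal(sum(part$counts), nrow(u$pairs))
  intra <- intra_layer_probability(part, u)
  # weighted mean of p_intra over bins = |E_train| / |U'| = 1/3, exactly
  ne <- part$counts > 0
  expect_identical(sum(intra$p[ne] * part$counts[ne]) / sum(part$counts),
                   sum(u$label) / nrow(u$pairs))
  # hand case: a bin's probability equals its linked fraction
  b1 <- which(part$bin == part$bin[1])
  expect_equal(intra$p[part$bin[1]], mean(u$label[b1]))

  adj_a <- layer_adjacency(net, "aux")
  s_a <- similarity_scores(adj_a, u$pairs, "ra")
  part_a <- equal_depth_bins(s_a, u, 10)
  tr <- trans_layer_probability(part_a, u, net$layers$aux)
  expect_equal(sum(tr$n), nrow(u$pairs))
  expect_equal(tr$n_conn + tr$n_unconn, tr$n)
  # count conservation per populated bin, pre-imputation
  for (j in which(tr$n > 0)) {
    lhs <- (if (tr$n_conn[j]) tr$n_conn[j] * tr$p_conn[j] else 0) +
      (if (tr$n_unconn[j]) tr$n_unconn[j] * tr$p_unconn[j] else 0)
    expect_equal(lhs, tr$n[j] * tr$p[j])
  }
})

test_that("imputation fills gaps and leaves observations unchanged", {
  expect_equal(impute_probabilities(c(0.1, NA, 0.3), "linear"),
               c(0.1, 0.2, 0.3))
  expect_identical(impute_probabilities(c(0.2, 0.4), "linear"), c(0.2, 0.4))
  expect_equal(impute_probabilities(c(NA, 0.5, 0.5, NA), "linear"),
               rep(0.5, 4))
  expect_error(impute_probabilities(c(NA_real_, NA), "linear"),
               "all entries missing")
  y <- c(0.05, 0.1, NA, 0.25, 0.4, NA, 0.7, 0.85, NA, 0.95)
  z <- impute_probabilities(y, "pls")
  expect_false(anyNA(z))
  expect_identical(z[!is.na(y)], y[!is.na(y)])
  expect_true(all(z >= 0 & z <= 1))
  # smooth rising series imputes rising values
  expect_true(all(diff(z) > -0.05))
})

test_that("2-d bin grid marginals reproduce the 1-d probabilities", {
  set.seed(8)
  net <- generate_duplex(40, 120, 120, overlap = 0.6)
  u <- build_pair_universe(net, "target", ratio = 2, seed = 8)
  s_t <- similarity_scores(layer_adjacency(net, "target"), u$pairs, "ra")
  s_a <- similarity_scores(layer_adjacency(net, "aux"), u$pairs, "ra")
  pt <- equal_depth_bins(s_t, u, 5)
  pa <- equal_depth_bins(s_a, u, 5)
  grid <- twod_bin_probabilities(pt, pa, u)
  counts <- attr(grid, "counts")
  expect_equal(sum(counts), nrow(u$pairs))
  # count-weighted row means = intra-layer probabilities (brute recount)
  intra <- intra_layer_probability(pt, u)
  for (i in which(rowSums(counts) > 0)) {
    got <- sum(grid[i, ] * counts[i, ], na.rm = TRUE) / sum(counts[i, ])
    expect_equal(got, intra$p[i])
  }
  tr <- trans_layer_probability(pa, u, net$layers$aux)
  for (j in which(colSums(counts) > 0)) {
    got <- sum(grid[, j] * counts[, j], na.rm = TRUE) / sum(counts[, j])
    expect_equal(got, tr$p[j])
  }
  # empty cells are NaN
  if (any(counts == 0)) expect_true(all(is.nan(grid[counts == 0])))
})

test_that("independent layers give flat trans-layer probabilities and
           correlated layers a conn > unconn split", {
  set.seed(12)
  flat <- generate_duplex(150, 450, 450, overlap = 0)
  u <- build_pair_universe(flat, "target", ratio = 2)
  s_a <- similarity_scores(layer_adjacency(flat, "aux"), u$pairs, "ra")
  pa <- equal_depth_bins(s_a, u, 10)
  tr <- trans_layer_probability(pa, u, flat$layers$aux)
  # within binomial sampling error of the global rate 1/3
  ok <- which(tr$n >= 30)
  se <- sqrt(1 / 3 * 2 / 3 / tr$n[ok])
  expect_true(all(abs(tr$p[ok] - 1 / 3) < 4 * se))

  cor_net <- generate_duplex(150, 450, 450, overlap = 0.6)
  u2 <- build_pair_universe(cor_net, "target", ratio = 2)
  s_a2 <- similarity_scores(layer_adjacency(cor_net, "aux"), u2$pairs, "ra")
  pa2 <- equal_depth_bins(s_a2, u2, 10)
  tr2 <- trans_layer_probability(pa2, u2, cor_net$layers$aux)
  both <- which(tr2$n_conn > 0 & tr2$n_unconn > 0)
  expect_true(all(tr2$p_conn[both] > tr2$p_unconn[both]))
})

test_that("rising intra-layer pattern emerges on a structured target layer", {
  # target with strong transitivity: RA similarity predicts links
  set.seed(13)
  g <- igraph::sample_smallworld(1, 150, 4, 0.1)
  e <- igraph::as_edgelist(g, names = FALSE)
  nodes <- paste0("n", 1:150)
  net <- multiplex(list(target = cbind(nodes[e[, 1]], nodes[e[, 2]]),
                        aux = cbind(nodes[e[, 1]], nodes[e[, 2]])),
                   nodes = nodes)
  split <- split_edges(net, "target", 0.9, seed = 13)
  u <- build_pair_universe(net, "target", split$train, ratio = 2, seed = 13)
  s <- similarity_scores(layer_adjacency(net, "target",
                                         edge_subset = split$train),
                         u$pairs, "ra")
  part <- equal_depth_bins(s, u, 10)
  intra <- intra_layer_probability(part, u)
  ok <- which(!intra$imputed)
  expect_gt(cor(ok, intra$p[ok], method = "spearman"), 0)
})
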