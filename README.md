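# simbins

Link prediction in multiplex networks by information-theoretic similarity
fusion.

Many relational systems are *multiplex*: the same nodes are connected
through several kinds of ties at once (synaptic connection types in a
connectome, genetic vs. physical protein interactions, advice vs.
friendship among physicians). Layers of real multiplexes are correlated —
a pair connected or structurally similar in one layer is more likely to be
connected in another — and this package exploits that to predict missing
links in one **target** layer using an **auxiliary** layer as side
information. The intended users are network scientists and systems
biologists with a partially observed layer and at least one other layer
over the same nodes.

## The model

For node pairs (x, y), a base single-layer similarity is computed in each
layer: common neighbours (CN), resource allocation (RA), average commute
time (ACT, via the pseudo-inverse Laplacian), or the local path index
(LPI, A² + εA³). A training universe U′ is formed from the target layer's
training edges plus twice as many sampled non-edges, and is partitioned
twice into equal-depth (equal-frequency) bins: once by target-layer
similarity, once by auxiliary-layer similarity. Each bin yields empirical
connection probabilities:

- **intra-layer** p̃ᵢₙₜᵣₐ(SᵢT): the fraction of pairs in target bin i linked
  in the target training set;
- **trans-layer** p̃ₜᵣₐₙₛ(SⱼA): the fraction of pairs in *auxiliary* bin j
  linked in the target training set, split into aux-connected and
  aux-unconnected slices.

Empty bins (frequent when similarity scores tie heavily at zero) are
imputed by 1-D penalized least-squares smoothing over the bin axis. The
two probabilities are fused with the probabilistic OR,
p + q − pq, and the score of a pair in target bin i and auxiliary bin j is
the bit-valued surprisal sum

    SB(x,y) = log2( S̃T(x,y) ) + log2( p̃_intra(i) OR p̃_trans(j | aux-connectedness of (x,y)) )

where S̃T is the min–max normalized target similarity (floored so the log
is finite). Higher scores mean more likely links. Baselines (target-only
similarity, raw similarity sum) and relevance-weighted comparators
((1−φ)·ST + φ·μ·SA with overlap-rate or degree-correlation relevance μ)
are included, along with sampled AUC / precision evaluation over repeated
90/10 train-test splits, and a generator of synthetic duplexes with
controlled edge overlap for validation.

## Worked example

```r
library(simbins)

# a duplex whose layers share 75% of their edges
net <- generate_duplex(n = 300, m_target = 900, m_aux = 900,
                       overlap = 0.75, seed = 42)

res <- run_experiment(net, "target", "aux", measure = "ra",
                      methods = c("simbins", "target", "sum"),
                      iterations = 20, seed = 42)
summary(res)
#> Link prediction evaluation: target <- aux (RA), 20 iteration(s)
#>    method iterations auc_mean   auc_se precision_mean precision_se
#> 1 simbins         20   0.8165 0.004527         0.7772     0.006621
#> 2     sum         20   0.5096 0.004775         0.3378     0.008157
#> 3  target         20   0.5060 0.004209         0.3367     0.010357
```

AUC is the probability (estimated by 10,000 sampled comparisons per split)
that a held-out true link outscores a sampled non-link; precision is the
fraction of true links among the top-|E_test| ranked candidates. On a
sparse random target layer, within-layer similarity alone is nearly
uninformative (AUC ≈ 0.51), yet the fused score recovers the cross-layer
signal (AUC ≈ 0.82): held-out target edges tend to be auxiliary edges too,
which the trans-layer probability split captures.

A single fit exposes the estimated tables directly:

```r
fit <- simbins(net, "target", "aux", measure = "ra", seed = 1)
summary(fit)   # per-bin intra-/trans-layer probabilities, imputation flags
plot(fit)      # bar plots of both tables
pred <- predict(fit, rbind(c(1L, 2L), c(5L, 9L)))  # bit scores for pairs
```

A thin command-line front end over the same functions lives at
`inst/cli/simbins.R` (`score`, `evaluate`, `simulate` subcommands, YAML/JSON
configs; see `inst/extdata/example_config.yaml`).

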