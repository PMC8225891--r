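---
title: "Bin-fused link prediction in multiplex networks: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bin-fused link prediction in multiplex networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simbins)
```

## The problem

A multiplex network is a collection of edge sets ("layers") over one
shared node set. Layers of real multiplexes are not independent: a node
pair that is connected, or structurally similar, in one layer is more
often connected in another (link persistence). `simbins` turns that
regularity into a link predictor: missing links in a *target* layer are
scored using the pair's similarity in the target layer itself **and** its
similarity and connectedness in an *auxiliary* layer.

## From surprisal to the score

Write $L^T_{xy} = 1$ for the event that $(x,y)$ is linked in the target
layer. The score of a candidate pair is the negated conditional surprisal
$-I(L^T_{xy}=1 \mid S_i^T, S_j^A)$ of that event given the pair's
similarity *bins* in the two layers (all logarithms base 2, so scores are
in bits). Expanding by mutual information and dropping the pairwise
constant $I(L^T=1)$ — which shifts all scores equally and cannot change a
ranking (a property the test suite verifies via AUC/precision invariance
under constant shifts) — leaves two estimable pieces:

1. $\log_2 \tilde S^T_{xy}$, where $\tilde S^T$ is the min–max normalized
   base similarity in the target layer, standing in for the connection
   probability before any bin knowledge;
2. $\log_2 p(L^T=1 \mid S_i^T, S_j^A)$, the conditional connection
   probability given the bins, estimated by fusing two per-bin empirical
   frequencies with the probabilistic OR:
   $p_{\mathrm{intra}}(S_i^T) + p_{\mathrm{trans}}(S_j^A) -
    p_{\mathrm{intra}}(S_i^T)\, p_{\mathrm{trans}}(S_j^A)$.

The OR is chosen over the AND (both are provided as `or_fuse()` /
`and_fuse()`) because evidence for a link from either layer should be able
to act alone: the fused value never drops below either input, so a pair
that looks dissimilar in the target layer can still rank high when the
auxiliary layer vouches for it. The trans-layer probability is estimated
separately for pairs connected and unconnected in the auxiliary layer,
because auxiliary connectedness is itself a strong predictor where layers
overlap.

## The estimation pipeline

Fitting (`simbins()`) proceeds on training data only:

* **Universe.** $U'$ = target training edges plus a seeded uniform sample
  of non-edges, two per training edge. Negatives are drawn from all
  unordered pairs minus the *full* target edge set, so a held-out test
  edge can never be mislabelled as a training negative. Self-pairs and
  ordered duplicates are excluded throughout: the layers are undirected
  simple graphs, so only unordered distinct pairs are meaningful.
* **Base similarity.** CN, RA, ACT or LPI, computed per layer; target
  similarity uses the training adjacency only. ACT uses the shifted
  inverse $(L - ee'/n)^{-1} + ee'/n$ on connected graphs and the
  Moore–Penrose pseudo-inverse (identical there) on disconnected ones, so
  every score is finite even across components.
* **Equal-depth bins.** Pairs sorted by score, cut at ranks
  $k\,|U'|/b$. Tied scores must share a bin — otherwise membership would
  depend on sort stability — so each tie block is assigned the bin of its
  median rank. Score distributions with heavy ties (the many exact zeros
  of RA/CN on sparse layers) therefore leave some bins empty, by design.
* **Probability tables.** Per-bin linked fractions, exact count ratios.
* **Imputation.** Empty bins are filled by 1-D penalized least-squares
  smoothing over the bin index (discrete-cosine-transform formulation;
  the smoothing parameter is chosen by generalized cross-validation), with
  linear interpolation as a configurable fallback that is also used
  automatically when fewer than three bins are observed. Observed entries
  are never altered; imputed values are clamped to $[0,1]$. Imputation
  runs inside the scoring path — not just for display — because the score
  needs both trans-layer slices defined on every bin.

Prediction (`predict.simbins()`) scores arbitrary pairs: target similarity
on the training adjacency, normalized over the currently scored pair set,
bins assigned through the boundaries stored at fit time (scores below the
lowest boundary fall in bin 1, above the highest in bin $b$ — candidate
pairs are partly outside $U'$, and boundary reuse is the only consistent
way to bin them).

## Numerical choices

* **Zero similarities.** $\log_2 0$ would send every zero-similarity pair
  to $-\infty$ and erase the bin term — the very pairs the method is
  designed to rescue. Normalized scores are floored at `floor_fraction`
  (default 0.1) times the smallest positive normalized value: ordering
  among positive scores is preserved and zero-similarity pairs remain
  rankable by their bins.
* **Zero fused probabilities.** A fused probability of 0 (possible when
  both table entries are exactly 0) is replaced by (minimum finite score
  − 1): "worst" rank, no infinity arithmetic.
* **Degenerate normalization.** All-equal similarity maps every pair to 1
  with a warning rather than failing.
* **Ties at the precision cut.** The top-$L$ cut breaks score ties by a
  seeded uniform shuffle: deterministic given the seed, unbiased in
  expectation.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `b_target`, `b_aux` | 10 | bins per layer; 10–50 works, fewer degrades resolution, more adds cost without benefit |
| `negative_ratio` | 2 | sampled non-edges per training edge in $U'$, reflecting link imbalance |
| `train_ratio` | 0.9 | training fraction of target edges per split |
| `epsilon` | 1e-4 | LPI weight of length-3 paths |
| `floor_fraction` | 0.1 | floor for zero normalized similarity |
| `phi` | 0.5 | mixing weight of the relevance-weighted comparators |
| `auc_n` | 10000 | sampled comparisons per AUC estimate |

The relevance-weighted comparators need a scalar layer relevance $\mu$:
`gor()` defaults to the Jaccard edge-overlap
$|E^T \cap E^A| / |E^T \cup E^A|$ (a min-denominator variant is
available) and `pcc_relevance()` uses the Pearson correlation of the two
layers' degree vectors, clamped below at 0 since a negative relevance
would invert the auxiliary ranking. The original comparator publications
leave room for other feature choices; these are documented approximations.

## The synthetic generator, and what tests do (not) show

`generate_duplex()` draws the auxiliary layer from an ER (or BA) model and
builds the target layer from $\lceil \omega\, m_T \rceil$ auxiliary edges
plus $m_T - \lceil \omega\, m_T \rceil$ non-auxiliary pairs. The overlap
$\omega$ — the one quantity the fused score exploits — is thus exact by
construction and sweeping it maps out the method's operating range:
uninformative auxiliary at the chance level, strongly informative at
$\omega \ge 0.5$. `rewire_null()` permutes one layer's node identities,
preserving that layer's internal structure while destroying all
cross-layer correspondence — the uncorrelated control.

Two caveats on reading the synthetic results. First, at $\omega = 0$ the
construction *excludes* target edges from the auxiliary edge set, which is
anti-correlation, not independence; the independent control is the
permutation null. Second, ER layers lack the transitivity and degree
heterogeneity of real networks, so within-layer similarity is much weaker
here than on empirical data; passing tests demonstrate the cross-layer
machinery, not realistic single-layer baselines. The generator makes no
attempt to mimic any specific real dataset.

The test suite exercises the pipeline at deliberately modest sizes —
oracle checks on graphs of ≤ 8 nodes, conservation on 80-node duplexes,
and the overlap sweep at $n = 300$, $m_T = m_A = 900$ with 20 evaluation
splits per overlap level — chosen so the full behavioural envelope
(monotone AUC in $\omega$, significant gain over the single-layer baseline
at $\omega \ge 0.5$, gap collapse under the permutation null) is measured
in minutes on one core.

## Known limitations

* Unweighted, undirected simple layers only; weights in input files are
  parsed and discarded.
* One auxiliary layer per fit; `simbins_multi()` sums per-duplex scores
  over several auxiliaries but shares no information between them, and
  higher-dimensional bins (target × aux₁ × aux₂) are not attempted — the
  sample sparsity per cell grows too fast.
* Equal-width binning (cheaper, $O(m)$) is not implemented; the partition
  interface would accommodate it.
* ACT on large networks requires a dense $n \times n$ pseudo-inverse;
  practical to a few thousand nodes.
* Layer relevance measures are approximations of the comparator
  literature, as noted above.
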