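---
title: "Extracting resting-state networks with unsupervised GraphSAGE embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting resting-state networks with unsupervised GraphSAGE embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Resting-state fMRI measures spontaneous BOLD fluctuations without a task.
Regions whose fluctuations are correlated form intrinsic connectivity
networks; the most robust of these is the default mode network (DMN:
posterior cingulate, precuneus, medial prefrontal and inferior parietal
cortex). `rsnsage` extracts such networks from ROI-level time series — one
signal per atlas parcel — by learning graph-neural-network node embeddings
of the functional connectivity graph and clustering them. A classical
seed-based correlation (SBC) baseline is provided for comparison.

The package deliberately starts *after* image preprocessing: its input is
a cohort of per-subject matrices (time points × ROIs), read from
tab-separated text with a JSON manifest, or simulated.

## The model, stage by stage

**Connectivity graph.** For each subject the Pearson correlation
$r_{xy}$ between every pair of ROI time courses is computed; the matrices
are averaged elementwise over subjects. Starting from the complete graph
on the $n$ ROIs (every pair makes an edge, $n(n-1)/2$ edges in total —
319,600 for an 800-ROI parcellation), every edge whose group-mean
correlation falls below a cutoff (default 0.1) is dropped. The comparison
is *signed*: a strong negative correlation is also dropped. The resulting
graph is undirected and unweighted; correlation magnitudes survive only in
the node features, which are the rows of the thresholded mean-correlation
matrix (sub-threshold entries and the diagonal zeroed, so a node's feature
support coincides exactly with its edge set). A switch retains the raw
rows instead, since either reading of "the correlation is the node
feature" is defensible; thresholded is the default because it keeps
features and topology consistent.

**GraphSAGE embeddings.** A two-layer sample-and-aggregate network is
implemented from scratch. At layer $k$, each node $v$ draws a fixed-size
sample of its neighbourhood (fan-outs 50 then 10, uniformly *with*
replacement — fixed-shape batches are what fixed fan-outs are for), the
sample is summarized by an aggregator, and
$$h_v^k = \sigma\!\left(W^k \,[\,h_v^{k-1} \,\|\, h_{N(v)}^k\,]\right),
\qquad h_v^k \leftarrow h_v^k / \lVert h_v^k\rVert_2 .$$
The mean aggregator averages neighbour vectors; the pool aggregator takes
an elementwise max of $\sigma(W_{pool} h_u)$ over the sample. An LSTM
aggregator is not offered: its output depends on an arbitrary neighbour
permutation and an unstated recurrent parameterization. Isolated nodes
aggregate over themselves.

Training is unsupervised: 10 uniform random walks of length 5 start at
every node, and every walk contributes positive pairs (start node, each
other node on the walk). For a pair $(u, v)$ with $Q = 5$ uniform
negatives,
$$J = -\log\sigma(z_u^\top z_v) - Q\,\mathbb{E}_{v_n \sim P_n}
\log\sigma(-z_u^\top z_{v_n}),$$
with the expectation replaced by the sample mean over the drawn negatives
and $\sigma$ the logistic sigmoid (the layer nonlinearity, by contrast, is
ReLU; the loss is only meaningful with a sigmoid). Negatives colliding
with $u$ or $v$ are redrawn. Minibatches of 10 pairs are optimized with
Adam at learning rate 0.01 for 100 epochs, with dropout 0.15 on the input
of every weight matrix during training only. Adam is our choice of
optimizer for this loss; Glorot-uniform initialization, no biases (the
layer map has none). Weights, walks, sampling, dropout and negatives all
derive from one seed, so training is exactly reproducible.

Final embeddings are computed with dropout off and *exact* (full
neighbourhood) aggregation rather than a sampled one: inference-time
sampling would add variance and nothing else, and the exhaustive mode is
what the exhaustive-equivalence tests exercise. Every embedding row has
unit L2 norm; a row that is identically zero after the ReLU is left at
zero with a warning rather than silently rescaled.

**Network extraction.** Embeddings are centered and projected onto the
smallest number $p$ of principal axes whose cumulative explained variance
reaches 95% (minimal-$p$ is the standard reading of "95% variance"; a
2-D projection is for plotting, not clustering). Axis signs are fixed by
making each axis's largest-magnitude loading positive, so PCA is
deterministic. Lloyd k-means with k-means++ seeding, 10 restarts and a
300-iteration cap partitions the ROIs into $k = 7$ clusters by default;
an emptied cluster is re-seeded from the farthest point. All $p$ retained
components are clustered by default; `cluster_components = 2` restricts
clustering to the two leading components (the coordinates a 2-D embedding
plot shows), since grouping "in the plot" and grouping in the full
retained space are both defensible readings of the procedure. The DMN cluster is identified as
the one maximizing Jaccard overlap with a reference ROI list — the
automatable surrogate for visual identification — with ties broken toward
the lower cluster index. When planted labels are known, recovery is scored
by adjusted Rand index and normalized mutual information (via `mclust`
and `igraph`).

**Seed-based baseline.** Per subject, the seed ROI (e.g. PCC) is
correlated with every other ROI; correlations are Fisher-z transformed
(`atanh`, the usual variance stabilization before group tests; a raw-r
mode exists for comparison) and tested ROI-wise with a one-sample t
statistic against zero, $df = n_{subjects} - 1$. Significance uses the
strict two-sided threshold $|t| > t_{1-\alpha/2, df}$ at $\alpha = 10^{-4}$
— which at $df = 83$ gives the familiar 4.09 — with an optional Bonferroni
mode that divides a familywise $\alpha$ by the number of tested ROIs (the
correction method is our choice; only the FWER level is conventional).
The seed is excluded from testing; an ROI with zero across-subject
variance is flagged, not silently dropped.

## The synthetic cohort

Real multi-subject ROI data cannot ship with a package, so the simulator
plants the structure the pipeline is supposed to find. ROIs are split into
contiguous blocks; ROI $i$ in network $k$ follows
$$x_i(t) = \sqrt{\rho}\, s_k(t) + \sqrt{1-\rho}\, e_i(t),$$
with $s_k$ and $e_i$ i.i.d. standard normal over time ($e_i$ scaled by
`noise_sd`). Within-network correlation is then
$\rho / (\rho + (1-\rho)\,\sigma_e^2)$ in expectation — equal to $\rho$
at unit noise — and between-network correlation is zero. The default
configuration is 70 ROIs in 7 equal networks, 10 subjects, 180 time
points, $\rho = 0.6$: a 7-network, ~180-time-point setting at roughly
1/11 of an 800-ROI parcellation, sized so the whole pipeline (including
100 training epochs) runs in minutes on one CPU. The first block is
designated the planted DMN. One RNG stream per cohort is split per
subject by counter, so extending a cohort never changes existing
subjects.

What the simulator does *not* emulate: temporal autocorrelation and
band-limited spectra of filtered BOLD, hemodynamics, motion and
physiological artefacts, inter-subject variability in network topography,
and negative between-network coupling. The correlation and graph stages
are invariant to temporal ordering, so white latent signals exercise them
fully — but passing tests on synthetic cohorts demonstrate correctness of
the machinery, not performance on real BOLD data.

## Numerical choices and degenerate inputs

- Constant time series make the correlation undefined; they raise errors
  naming the offending ROI rather than producing `NA`.
- The graph threshold must lie in $(-1, 1)$; isolated nodes are allowed
  but warned about, and they self-aggregate.
- Zero activation vectors stay zero through L2 normalization (warned).
- `|r| >= 1` is clamped to $\pm(1 - 10^{-7})$ before `atanh`.
- t statistics with zero standard deviation become signed infinities (or
  `NaN` at mean zero) and are flagged and excluded from significance.
- k-means inertia is non-increasing across Lloyd iterations by
  construction; the per-iteration trace of the winning restart is kept so
  this is checkable.
- All tolerances in tests are absolute and stated per check; embedding
  unit norms hold to 1e-6.

## Problem sizes used in the tests

Unit tests run on 2–50 node instances against brute-force oracles
(pairwise correlation loops, elementwise mean/max, step-by-step layer
evaluation, term-by-term loss, covariance eigendecomposition, exhaustive
Jaccard scans). The end-to-end checks run the default 70-ROI cohort once
and reuse the result; the training-scale choices above keep that run to a
few minutes. Determinism is additionally exercised end-to-end at 16 ROIs.

## Known limitations

- Embeddings are nonnegative (ReLU output), so "orthogonal" clusters mean
  disjoint support rather than opposed directions; cosine separation
  between planted networks is the operative signal.
- The negative-sampling loss has a nonzero floor under nonnegative
  embeddings; its absolute value is not comparable across graphs, only
  its trend within a run.
- k is fixed (default 7), not selected; non-DMN clusters are not named.
- No per-subject graphs, partial correlations, or Fisher-z-weighted
  edges; the group graph is the single object embedded.
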