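# rsnsage

Extraction of resting-state networks — in particular the default mode
network (DMN) — from ROI-level resting-state fMRI time series, using
unsupervised **GraphSAGE** node embeddings of the functional connectivity
graph, plus a classical seed-based correlation (SBC) baseline.

`rsnsage` is for researchers who already have parcellated rs-fMRI signals
(one time course per atlas ROI, any preprocessing pipeline) and want a
reproducible, scriptable route from those signals to a partition of ROIs
into intrinsic networks.

## Method

1. **Connectivity graph.** Per subject, the Pearson correlation
   $r_{xy}$ between every pair of ROI time courses; matrices averaged
   elementwise over subjects. From the complete graph on $n$ ROIs
   ($n(n-1)/2$ edges; 319,600 at $n = 800$), edges with mean correlation
   $< 0.1$ (signed) are dropped. Node features are the thresholded
   correlation rows.
2. **GraphSAGE.** Two layers (200, 100 units), fixed fan-out neighbour
   sampling (50, 10) with mean or max-pool aggregation:
   $h_v^k = \sigma(W^k [h_v^{k-1} \| h_{N(v)}^k])$, L2-normalized per
   node. Unsupervised training on random-walk positive pairs (10 walks of
   length 5 per node) with the negative-sampling loss
   $J = -\log\sigma(z_u^\top z_v) - Q\,\mathbb{E}\log\sigma(-z_u^\top z_{v_n})$,
   $Q = 5$, minibatch Adam (batch 10, lr 0.01, 100 epochs, dropout 0.15).
3. **Extraction.** PCA keeping the minimal components reaching 95%
   variance; Lloyd k-means (k-means++ seeding, 10 restarts) into $k = 7$
   clusters; the DMN cluster identified by maximal Jaccard overlap with a
   reference ROI list; recovery scored by ARI/NMI when ground truth is
   known.
4. **SBC baseline.** Seed-to-ROI correlations per subject, Fisher z,
   one-sample group t map ($df = n_{subjects}-1$), strict two-sided
   threshold $|t| > t_{1-\alpha/2,df}$ (4.09 at $\alpha = 10^{-4}$,
   $df = 83$), optional Bonferroni FWER mode.

A synthetic cohort generator plants block-structured networks
($x_i = \sqrt{\rho}\,s_k + \sqrt{1-\rho}\,e_i$) so the whole pipeline is
testable without external data. See `vignettes/methods.Rmd` for the full
account.

## Worked example

```r
library(rsnsage)

# 70 ROIs in 7 planted networks, 10 subjects, 180 time points, rho = 0.6
res <- run_pipeline(pipeline_config(seed = 1))
res
#> <pipeline_result> 315 edges, 6 PCA components, inertia 0.0005, ARI 1.000, DMN Jaccard 1.000
str(res$metrics[c("edge_count", "p", "ari", "nmi", "dmn_jaccard")])
#> List of 5
#>  $ edge_count : int 315
#>  $ p          : int 6
#>  $ ari        : num 1
#>  $ nmi        : num 1
#>  $ dmn_jaccard: num 1
```

Reading the output: the thresholded group-mean correlation graph keeps
315 of the 2,415 possible edges (essentially the within-network pairs);
the 100-dimensional embeddings compress to 6 principal components at 95%
variance — one fewer than the number of planted networks, as expected for
7 well-separated clusters; k-means then recovers the planted partition
exactly (ARI = NMI = 1), and the cluster identified as the DMN coincides
exactly with the planted DMN block (Jaccard = 1).

The baseline, from a seed inside the planted DMN:

```r
co <- res$cohort
map <- sbc_baseline(co, "ROI_001", alpha = 0.0001)
map
#> <seed_map> seed ROI_001, 69 ROIs tested, df = 9, 9 significant at |t| > 6.59
```

All 9 other members of the planted 10-ROI DMN block exceed the threshold;
no out-of-block ROI does.

Artifacts (edge list, features, embeddings, partition, seed map, metrics
and run log) are written by `run_pipeline(cfg, out_dir = "...")`, and a
thin command-line front end lives at `inst/cli/rsnsage.R`
(`simulate` and `run` subcommands with `--config` and per-flag
overrides).

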