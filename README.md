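# scanchor

Anchor-graph clustering for paired single-cell RNA and ATAC data.

`scanchor` clusters cells measured with both scRNA-seq and scATAC-seq by
learning, instead of an `n × n` cell–cell graph, a small set of `m ≪ n`
**anchors** and `m × n` column-stochastic **anchor graphs** that tie every
cell to every anchor. Three representations cooperate:

* **omic-specific anchor graphs** `Z_1, Z_2`, one per modality, from
  `min ‖X_i − Y_i Z_i‖²_F + ρ‖Z_i‖²_F` with simplex-constrained columns;
* a **shared anchor graph** `Z_s` with orthonormal per-view projections
  `W_i`, shared anchors `Y_s` and residual-inverse view weights `α`, from
  `min Σ_i α_i² ‖X_i − W_i Y_s Z_s‖²_F + ‖Z_s‖²_F`, fit by closed-form block
  updates (orthogonal Procrustes for `W_i`, `Y_s`; column-wise simplex
  projection for `Z_s`) interleaved with a graph-convolutional estimate of
  `Z_s` trained by Adam — the objective trace is non-increasing by
  construction;
* a **high-order representation** `Z_s'` from multi-head masked graph
  attention over the cells, which completes the specific graphs by Hadamard
  product, `Z_im,i = Z_s' ⊙ Z_i`; the fused embedding
  `Z_final = θ Z_im,1 + (1−θ) Z_im,2` is clustered by k-means.

Evaluation utilities (Hungarian-matched accuracy, NMI, ARI, macro
precision/recall/F1, silhouette), MatrixMarket/dense-delimited readers and
writers, a planted-cluster paired-multiome simulator, and an end-to-end
pipeline with ablation switches are included. The methods vignette
(`vignettes/anchor-graph-clustering.Rmd`) derives every update and records
the design decisions and known limitations.

## Worked example

```r
library(scanchor)

# a paired multiome with 3 planted cell types: 300 cells, 200 genes, 500 peaks
dat <- generate_multiome(synthetic_spec(seed = 2))

cfg <- run_config(n_clusters = 3, seed = 2,
                  max_iterations = 240, validate_every = 30)
res <- run_pipeline(cfg, dat$rna, dat$atac, labels = dat$labels)

print(res)
#> <run_manifest> 300 cells -> 3 clusters (seed 2)
#> <evaluation_report> ACC 1.0000 | NMI 1.0000 | ARI 1.0000 | F1 1.0000 | P 1.0000 | R 1.0000 | S 0.4031

res$shared$alpha          # view weights: RNA, ATAC, merged
#> 0.000 1.000 0.000
res$shared$objective_trace  # one value per closed-form cycle, non-increasing
#> 27070.5 291.5 30.6 30.3 30.2 30.1 30.1 30.1 30.1
```

The report line says the k-means partition of the fused embedding matched
the planted cell types exactly (ACC/NMI/ARI/F1 all 1), with a mean
silhouette of 0.40 on the fused embedding. The near-binary ATAC view
reconstructs with much lower residual than the log-scale RNA view here, so
the residual-inverse weighting concentrates `α` on it — the weights react to
absolute residual scale, which is the model's stated behaviour. Individual
seeds vary (the attention stage is an untrained seeded propagation); the
test suite asserts recovery at ARI ≥ 0.9 in at least 8 of 10 seeds under
these conditions.

From a shell, the same run is:

```sh
Rscript inst/scripts/scanchor-run.R \
  --rna rna/matrix.mtx --atac atac/matrix.mtx --labels labels.tsv \
  --clusters 3 --seed 2 --out-dir out/
```

which writes `labels.tsv`, `embedding.csv`, `metrics.json` and a run
manifest. `--mac-only` clusters the shared graph directly and `--no-hgat`
skips the attention stage (imputation becomes the identity).

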