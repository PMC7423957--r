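# mvembed

Multi-view neighbourhood embedding and multi-objective clustering for
sample-by-feature data measured through several *views* — typically
multi-omics assays (gene expression, miRNA expression, DNA methylation)
on one patient cohort. `mvembed` is for analysts who want a single
patient stratification that uses all assays at once, weights reliable
assays more than noisy ones without hand-set weights, and copes with
samples missing from some assays.

## The method

1. **Per-view neighbour distributions.** In each view *v* a Gaussian is
   centred on every sample *i*; the probability that *i* picks *j* as a
   neighbour is

   p<sup>v</sup><sub>ij</sub> = exp(−‖x<sub>i</sub>−x<sub>j</sub>‖² / 2σ²<sub>i</sub>) / Σ<sub>k≠i</sub> exp(−‖x<sub>i</sub>−x<sub>k</sub>‖² / 2σ²<sub>i</sub>),

   with σ<sub>i</sub> calibrated so the row entropy equals log *k*
   (default *k* = 30 effective neighbours).

2. **Conflation.** The per-view distributions are merged by their
   normalized product — the conflation &(f₁, f₂) = f₁f₂ / Σ f₁f₂ — which
   minimizes the maximal Shannon-information loss and automatically
   weights each view by its precision. A case-wise extension handles
   samples present in only some views. Averaging baselines (`avgprob`,
   `avgdata`) are included for comparison.

3. **Embedding.** Low-dimensional coordinates *Y* (default dimension 80)
   are initialized by a stacked denoising autoencoder on the concatenated
   views and optimized to minimize KL(P‖Q), where Q uses a Student-t
   kernel with one degree of freedom; the gradient
   4 Σ<sub>j</sub>(p<sub>ij</sub>−q<sub>ij</sub>)(1+‖y<sub>i</sub>−y<sub>j</sub>‖²)⁻¹(y<sub>i</sub>−y<sub>j</sub>)
   is followed with momentum (0.5 → 0.9) and adaptive per-coordinate
   gains for 2000 iterations at base rate η = 200.

4. **Clustering.** Archived multi-objective simulated annealing searches
   over variable-length center sets (2 ≤ K ≤ √n), minimizing the
   Xie–Beni index while maximizing the PBM index; the archive of
   non-dominated solutions is returned and the best-PBM member reported.

External validity metrics (NMI, ARI, macro F1, accuracy after optimal
cluster-to-class mapping) and one-vs-rest signal-to-noise marker scoring
round out the toolkit, together with a synthetic multi-view
Gaussian-mixture generator used throughout the tests.

## Worked example

Generate a 4-cluster, 3-view cohort of 200 samples (separation/noise
ratio 6) and run the full pipeline:

```r
library(mvembed)

spec <- synth_spec(n_samples = 200, n_clusters = 4,
                   view_dims = c(50, 30, 50), center_separation = 6,
                   noise_sd = 1, seed = 42)
cfg <- run_config(synth = spec, k = 30, d_emb = 10, iterations = 750,
                  sae = sae_config(hidden = 64, pretrain_epochs = 20,
                                   finetune_epochs = 40),
                  seed = 42)
res <- run_pipeline(cfg)
print(res)
```

```
run_result (conflation / best_pbm)
  n         200
  K         4
  xb        0.006705
  pbm       244.78
  kl_final  0.6906
  nmi       1
  ari       1
  macro_f1  1
  accuracy  1
```

Reading the summary: the annealer's best-PBM solution recovered `K = 4`
clusters; `xb` (lower is better) and `pbm` (higher is better) are the
internal validity objectives of that solution; `kl_final` is the
divergence between the unified and embedded neighbour distributions after
optimization; and because the generator's ground truth was available, the
external agreement metrics show a perfect stratification. Setting
`missing_fraction = 0.2` in the spec exercises the incomplete-view
conflation path instead (absent samples are masked, not imputed).

A thin command-line front end with `run`, `synth` and `metrics`
subcommands is installed under `inst/scripts/mvembed`:

```sh
Rscript inst/scripts/mvembed synth --n 200 --clusters 4 --dims 50,30,50 --out demo
Rscript inst/scripts/mvembed run --views demo/view1.tsv,demo/view2.tsv,demo/view3.tsv \
    --labels demo/labels.tsv --normalize none --d-emb 10 --iterations 750 --out demo_run
```

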