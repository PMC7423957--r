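---
title: "Multi-view neighbourhood embedding: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view neighbourhood embedding: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvembed)
```

## The problem

Multi-omics studies measure the same patient cohort through several assays
(gene expression, miRNA expression, DNA methylation, ...). Each assay — each
*view* — carries partly consensual, partly complementary information about
the latent group structure of the cohort, on scales and in feature spaces
that are not directly comparable. `mvembed` integrates the views in
*probability space*: each view is summarized by the neighbour-selection
probabilities it induces among the samples, those per-view distributions are
merged into one unified distribution, and a low-dimensional embedding is fit
so that its own neighbour distribution matches the unified one. The
embedding is then clustered with a multi-objective annealer that selects the
number of clusters itself.

Working with neighbour probabilities sidesteps the incommensurability of the
raw feature spaces: probabilities are unitless, per-sample, and can be
combined with well-defined operations regardless of the dimensionality or
noise level of the view that produced them.

## Per-view neighbour distributions

Within view $v$, a Gaussian is centred on each sample $i$ and the
probability that $i$ selects $j$ as its neighbour is

$$p^v_{ij} = \frac{\exp(-\|x^v_i - x^v_j\|^2 / 2\sigma^{v\,2}_i)}
  {\sum_{k \ne i}\exp(-\|x^v_i - x^v_k\|^2 / 2\sigma^{v\,2}_i)},
  \qquad p^v_{ii} = 0,$$

with the bandwidth $\sigma^v_i$ calibrated per sample so that the Shannon
entropy of row $i$ equals $\log k$, $k$ being the effective number of
nearest neighbours (default $k = 30$). We treat each row as a conditional
distribution summing to one; this convention is what makes the conflation
denominator and the later $1/2n$ symmetrization coherent. The calibration
uses a doubling bracket followed by up to 50 bisection steps and stops when
the entropy is within $10^{-5}$ nats of the target; entropy is monotone in
$\sigma$, so the search is reliable. Rows consisting of identical points, or
targets beyond the attainable entropy range, fall back to a boundary
bandwidth with a warning rather than failing.

All distances, calibrations and probabilities are computed among the samples
*present* in the view only; absent samples are masked, not imputed.

## Conflation of the views

The conflation of probability mass functions is their normalized product,
$\&(f_1, f_2) = f_1 f_2 / \sum_y f_1(y) f_2(y)$. It is the combination rule
that minimizes the maximal loss of Shannon information, and for normal
inputs it reproduces precision-weighted least squares: a sharp (confident)
view pulls the consensus harder than a diffuse (noisy) one, with no explicit
view weights to tune. This auto-weighting is the package's reason for
preferring conflation over the two classical alternatives it also
implements as baselines: averaging the probabilities (`avgprob`, which
preserves every mode of every view and so yields multi-modal, indecisive
rows when views disagree) and averaging the distance matrices (`avgdata`,
which mixes scales before any probabilistic interpretation).

For samples present in every view the unified pairwise value is

$$p_{ij} = \frac{\prod_v p^v_{ij}}
  {\prod_v p^v_{ij} + \prod_v \sum_{k \ne j} p^v_{ik}},$$

computed in log space (products of hundreds of small probabilities underflow
otherwise). As printed, the rows of this matrix do not sum to one; because
the gradient of the embedding cost assumes a normalized joint distribution,
the default renormalizes each row before the symmetrization
$p_{ij} \leftarrow (p_{ij} + p_{ji})/2n$, after which the matrix is
symmetric, zero-diagonal and sums to one. A literal mode
(`renormalize = FALSE`) keeps the unnormalized per-pair values for
comparison.

With incomplete views the combination is case-wise: a pair present together
in several views is conflated over exactly those shared views; a sample
present in a single view keeps its single-view row; a neighbour present in a
single view contributes its probability divided by the number of views $m$;
a pair sharing no view (and fitting neither special case) gets zero. On
complete data every pair falls into the conflation case over all views, so
the incomplete path reduces — structurally, hence bit-exactly — to the
complete formula. Both paths share one engine for that reason; the engine
itself is validated against an independent, unvectorized case-by-case oracle
in the tests.

Before any Kullback–Leibler computation the unified matrix is floored at
$10^{-12}$ off the diagonal, the standard guard against $\log 0$ in
stochastic neighbour embeddings.

## Initial embedding

The concatenated matrix (views side by side, absent blocks zero) is
compressed by a stacked denoising autoencoder with the symmetric
architecture $d \to 500 \to d_\mathrm{emb} \to 500 \to d$: ReLU hidden
layers and bottleneck, linear output (inputs are z-scored, a ReLU output
would clip negatives). Each layer is first pretrained as a denoising
autoencoder — dropout corruption (rate 0.05) on its input and hidden
activations, mean-squared reconstruction error — then the stack is
fine-tuned end-to-end without corruption, and the clean encoder pass gives
$Y_\mathrm{init}$. The autoencoder is implemented directly in R (dense
matrix algebra, Adam optimizer with learning rate $10^{-3}$, minibatches of
at most 64); at cohort scale (hundreds of samples, a few hundred selected
features per view) this trains in seconds. Epoch counts default to 200 for
pretraining and 400 for fine-tuning and are fully configurable. A
deterministic PCA initializer is available behind
`initializer = "pca"` as a training-free alternative; the pipeline runs
end-to-end with either.

No optimizer, epoch count, batch size or learning rate is canonical for
this architecture; the defaults above are ordinary stacked-autoencoder
practice, and identical seeds reproduce $Y_\mathrm{init}$ exactly.

## Final embedding

In the embedding the neighbour distribution uses a Student-t kernel with one
degree of freedom,

$$q_{ij} = \frac{(1+\|y_i-y_j\|^2)^{-1}}
  {\sum_{l \ne k}(1+\|y_l-y_k\|^2)^{-1}},$$

and the coordinates minimize $C = \mathrm{KL}(P\|Q) = \sum_{i,j} p_{ij}
\log(p_{ij}/q_{ij})$ by full-batch gradient descent with the closed-form
gradient

$$\frac{\partial C}{\partial y_i} =
  4\sum_j (p_{ij}-q_{ij})(1+\|y_i-y_j\|^2)^{-1}(y_i-y_j).$$

Defaults: 2000 iterations, base learning rate $\eta = 200$, momentum 0.5
switching to 0.9 at iteration 250, and per-coordinate delta-bar-delta gains
(+0.2 on sign disagreement between gradient and velocity, ×0.8 on
agreement, floor 0.01). The gradient sums over all pairs, so the descent is
full-batch by construction. The embedding is recentred to zero mean after
every step — the cost is translation invariant, and recentring pins the
otherwise free global offset. No early exaggeration is applied by default.
The gradient implementation is checked against central finite differences
of the cost in the tests.

## Clustering

The embedding is clustered by archived multi-objective simulated annealing
with a variable-length, center-based encoding: a solution is a set of $K$
centers, $2 \le K \le \lfloor\sqrt{n}\rfloor$, and crisp labels assign each
sample to its nearest center. Two validity indices are optimized
simultaneously — the Xie–Beni index (compactness over separation, squared
Euclidean distances, minimized) and the PBM index
$(1/K)(E_1/E_K)D_K$ (Euclidean distances, maximized, no outer square). Three
mutation operators explore the space: perturbing one center with Laplace
noise (scale 1), inserting a data point as a new center, deleting a center;
the kind is drawn uniformly and redrawn if it would leave the $K$ bounds.
Candidate acceptance follows the domination relation against the current
solution and the archive; dominated candidates are accepted with probability
$1/(1+\exp(\overline{\Delta\mathrm{dom}}/T))$, where the amount of
domination is the normalized objective-difference product, so worse moves
become rare as the temperature $T$ anneals from 100 to 0.001 at cooling
rate 0.9 (110 levels, 100 proposals per level). The archive of mutually
non-dominated solutions is clustered down to 40 members (single linkage in
normalized objective space) whenever it exceeds 50. Empty clusters are
repaired by moving the offending center onto the sample farthest from its
own center.

From the final archive the default report is the solution with the largest
PBM index (fully unsupervised); a supervised selection by NMI against
provided labels is available and flagged as label-using, since benchmark
studies often report the best archive member.

## Synthetic data and what it does (not) show

`synth_spec()`/`synth_multiview()` generate the benchmark used throughout
the tests: a Gaussian mixture with a shared cluster assignment across
views, per-view cluster centers with a prescribed minimum pairwise
separation, isotropic per-view noise, and optional per-view missingness
that never leaves a sample absent from every view. Defaults mirror a
typical multi-omics cohort after feature selection: view dimensions
(400, 170, 400), $n = 200$, four clusters, separation/noise ratio 6. The
test and acceptance runs use narrower views of (50, 30, 50) features —
the affinity, conflation and embedding stages scale with $n$, not with the
view width, so narrower views exercise the same code paths at a fraction of
the autoencoder cost — together with a compact autoencoder configuration
(hidden width 64, bottleneck 10, 20 + 40 epochs) and 750 descent
iterations, which this data comfortably saturates.

The generator emulates shared structure, view-specific scale/noise and
missing samples. It does not emulate batch effects, count overdispersion,
methylation beta distributions, dropout zeros, or feature correlation
within a view; passing the synthetic recovery tests therefore demonstrates
the correctness of the machinery and its behaviour under the stated noise
model, not performance on real cohorts. `degrade_view()` adds extra noise
to one view to probe the conflation's precision weighting against the
averaging baseline.

## Numerical choices and degenerate inputs

* Feature variance (for the ranking filter) and the z-score normalization
  use the population ($1/n$) estimator; the ranking is invariant to the
  choice, fixing one keeps results deterministic. Ties rank towards the
  lower column index. Both statistics skip rows flagged absent, since the
  zero placeholders would bias the moments.
* Feature selection runs before normalization (both orders are defensible;
  selecting first means the kept features' z-scores are computed once, on
  the final feature set), and the miRNA-style fractional rule is a
  `fraction` parameter, default 0.23.
* Conflation products are `exp`/`log` with a `double.xmin` floor; the
  unified matrix is floored at $10^{-12}$ for KL only.
* Degenerate affinity rows (identical points) fall back to uniform with a
  warning; coincident cluster centers give the Xie–Beni index an `Inf`
  sentinel; a clustering request on identical points returns a flagged
  degenerate archive.
* Stage seeds derive from the master seed at fixed offsets (+1
  autoencoder, +2 annealer), so stages can be re-run in isolation and a
  full rerun with the same configuration reproduces the summary to
  machine precision.

## Known limitations

Unsupervised selection by PBM is not infallible: on some data draws —
in our experiments chiefly under per-view missingness — the archive's
largest-PBM member merges well-separated clusters into a coarser
partition (PBM's maximal-center-distance term can reward such merges),
even though a solution with the correct number of clusters sits elsewhere
in the archive. Inspecting the returned archive, or using the supervised
NMI selection when labels exist, recovers it; this is why the archive,
not just the selected solution, is part of the pipeline's output.

The embedding stage is dense in $n$ ($O(n^2)$ per iteration with no
Barnes–Hut style approximation), which is the method's intended regime —
patient cohorts of a few hundred to a few thousand samples — but not
single-cell atlas scale. The cluster-to-class mapping used by the macro-F1
and accuracy metrics enumerates one-to-one assignments and is limited to
nine mapped classes, which the $K \le \sqrt{n}$ bound keeps comfortable.
The annealer's acceptance-probability form and archive-pruning details
follow the published algorithm family but constants (initial archive size,
pruning linkage) are implementation choices, logged in the run
configuration.
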