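---
title: "Reconstructing continuous expression trajectories from snapshot data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing continuous expression trajectories from snapshot data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Single-cell RNA sequencing destroys the cells it measures, so a time-course
experiment yields a handful of unpaired cross-sectional snapshots
$P_{t_0}, \dots, P_{t_K}$ rather than continuous per-cell trajectories.
`profet` reconstructs a continuous-time picture of the dynamics from those
snapshots in two stages:

1. **Generative particle transport.** For each adjacent snapshot pair, source
   cells (as particles in a low-dimensional latent space) are transported
   toward the target distribution along the Wasserstein gradient flow of a
   *Lipschitz-regularized KL divergence*. The flow velocity is
   $v(x) = -\nabla\phi(x)$, where the dual potential $\phi$ is the maximizer
   of the variational objective
   $$\frac1N\sum_i \phi(Y_i) \;-\; \frac1M\sum_j f^*(\phi(X_j)),
     \qquad f^*(y) = e^{y-1},$$
   over $L$-Lipschitz functions ($f^*$ is the convex conjugate of
   $f(x) = x\log x$). The constraint does two things: it keeps the objective
   finite between mutually singular empirical measures, and it bounds the
   transport speed by $L$, since $\|\nabla\phi\| \le L$.
2. **Force-matching.** The transport stage emits time-labelled velocity
   samples $(x, s, v)$. A single neural velocity field $v_\theta(x, s)$ over
   the whole time course is fit to them by least squares, turning the
   per-interval Lagrangian particle paths into one Eulerian flow model that
   can be integrated from any start state and time.

The method makes no assumption about the shape of the snapshot
distributions — no Gaussian base measure, no W2-geodesic (straight-line)
interpolation. That is what lets it capture non-monotone dynamics such as a
mid-course turning point, which coupling-based linear interpolation cannot
represent by construction.

## Latent space

All transport happens in a linear latent space: expression matrices are
log-transformed (`log1p_normalize()`), optionally restricted to the
highest-variance genes (pooled sample variance across all cells;
`select_top_variance_genes()`), and projected by covariance PCA
(`fit_latent()`; genes are centered, not scaled — variance-stabilized
expression is already on a common scale). Loading-column signs are fixed so
the largest-magnitude entry is positive, making runs reproducible.
Trajectories are mapped back to gene space with the exact linear inverse
(`inverse_project()`), which yields per-gene, per-cell dynamics.

The default latent dimension is `d = 2` (visualization-scale); the transport
stage remains well-behaved up to moderate dimensions (a few tens), beyond
which dual-potential estimation from a few hundred cells becomes the
bottleneck.

## The transport stage in detail

`run_gpa()` alternates two steps: fit the dual potential on the current
particles (`fit_potential()`), then move every particle one forward-Euler
step down its gradient (`euler_step()`). The key numerical choices:

* **Lipschitz enforcement.** The potential is a 3x128 ReLU network. After
  every Adam update each weight matrix is projected to spectral norm at most
  $L^{1/4}$ (power iteration during the inner loop, an exact SVD-based
  projection at the end of each fit). Because ReLU is 1-Lipschitz, the
  product of layer norms bounds the network's global Lipschitz constant, so
  the emitted speed bound $\|v\| \le L$ holds to machine precision — it is a
  hard constraint, not a penalty.
* **Defaults.** $L = 1$ (transport speed is then interpretable in latent
  units per local time unit); $\Delta t = 0.1$; at most 150 outer
  iterations; 50 inner Adam steps per fit with warm-started weights, and a
  longer (500-step) first fit because a freshly initialized potential scores
  near $-e^{-1}$ and needs a warm-up before the stopping rule is meaningful.
* **Stopping.** The outer loop stops once the fitted divergence estimate
  falls below 0.05, a practical early-stopping point beyond which further
  iterations mostly overfit the endpoint distribution. With identical source
  and target the optimum of the objective is exactly 0, so the rule fires
  immediately.
* **Horizon guard.** In the pipeline the per-pair step size is raised, if
  necessary, so that the reachable distance (iterations x dt x L) is at
  least four times the centroid displacement of the pair: the flow needs
  headroom both to travel and to settle. This mirrors the usual CFL-style
  trade-off — larger steps move faster but follow the potential landscape
  more coarsely.

## Time alignment and force-matching

Each pair runs on its own local clock $t \in [0, H_i]$. `align_times()` maps
it affinely onto the experimental interval $[t_i, t_{i+1}]$ and — crucially —
rescales every velocity by the chain rule ($v \cdot dt_{\text{local}}/ds$),
so the aligned samples are derivatives with respect to physical time and the
integrated field reproduces the transport on the experimental clock. An
alternative `longest-horizon` mode applies one shared dilation factor (the
longest local horizon); it is provided because the proportional alignment of
unequal horizons admits both readings, and the choice only matters when
observation intervals differ in length.

`train_velocity_field()` fits a 4x64 tanh network on $(x, s) \mapsto v$ by
minibatch Adam (batch 256, 3000 updates, step-decayed learning rate).
Inputs and velocity targets are z-scored internally and the scales folded
back in at prediction time; without this the spectrally capped network
underfits intervals whose dilation makes velocities large. Layers are capped
at spectral norm 4 — the field stays Lipschitz by construction (product
bound over layers, on standardized coordinates), while a tighter cap of 1
would limit the whole field to Lipschitz constant 1 and make the constrained
fit unstable. A 10% held-out split monitors overfitting.

`integrate_trajectories()` is forward Euler with 200 steps per unit time by
default; halving the step changes endpoints at first order, and the constant
field is integrated exactly.

## Evaluation protocol

Distribution agreement is measured with the entropic OT cost
(`entropic_ot_cost()`, log-domain Sinkhorn, marginal L1 tolerance $10^{-6}$,
at most 10,000 iterations), its debiased form (`sinkhorn_divergence()`,
tested over $\varepsilon \in \{0.01, 0.1, 1, 10, 100\}$), squared RBF-kernel
MMD exactly as the V-statistic with diagonal terms ($\gamma = 1$), and
histogram TV/KL for single genes (shared equal-width bins,
$\max(10, \lceil\sqrt{n}\rceil)$ of them, KL smoothing $10^{-10}$).

Two coupling baselines serve as references: the entropic OT plan with linear
(displacement) interpolation, and a seeded uniform random pairing with
linear interpolation. When a held-out snapshot is evaluated, both baselines
interpolate between the two flanking *training* snapshots; the field-based
prediction therefore also starts from the last training snapshot before the
held-out time and integrates forward to it. This equal-information protocol
compares methods on the same inputs; the full-span trajectories from the
earliest snapshot remain the pipeline's trajectory product.

Per-gene agreement at held-out times is tested by permutation
(`permutation_test()`): pool, reshuffle into the original group sizes,
recompute the distance. The p-value uses the add-one correction
$p = (\#\{d_{\pi} \ge d_{\text{obs}}\} + 1)/(n_{\pi} + 1)$ — a deliberate
departure from the plain fraction, which can return an exact zero that
breaks downstream log-scale use. Under the null the test is calibrated to
slightly conservative (histogram ties can only inflate p).

## Downstream analyses

* `classify_fates()` — k-means on a reference snapshot (k chosen from 2..8
  by mean silhouette width), nearest-centroid assignment of predicted
  states; reference = last snapshot labels terminal fates, reference = first
  labels ancestral origins. Centroid ties resolve to the lowest index.
* `stratify_by_displacement()` — per-cell Euclidean displacement between two
  trajectory times; Gaussian KDE with Scott's bandwidth
  $h = \hat\sigma n^{-1/5}$ on a 512-point grid; local minima (prominence
  filter at $10^{-4}$ of the density maximum suppresses numerical ripples);
  the two smallest-x minima split cells into low/medium/high shift groups,
  degrading gracefully to two or one group. Summary statistics: mean, sd,
  IQR, CV (0 by convention for all-identical displacements), and Shannon
  entropy (nats) of the displacement histogram on the KDE grid.
* `normalized_divergence()` — between-group mean expression difference
  normalized by its own maximum absolute value over time, so the profile
  lives in $[-1, 1]$ and is scale-invariant; $|profile| \ge 0.5$ flags
  substantial divergence (first crossing time reported, linearly
  interpolated between grid points), a drop $> 0.5$ from the running
  maximum flags convergence.
* `deg_analysis()` — per-gene log2 fold change with a $10^{-9}$ pseudocount
  (suitable for log-normalized data), Welch two-sample t-test (the
  unequal-variance form is the safer default where group variances are not
  known to match), Benjamini-Hochberg FDR alongside raw p-values; genes
  constant in both groups get p = 1 by convention.

## The synthetic EMT generator

`simulate_emt_series()` emulates the benchmark setting: a population of
epithelial cells driven through the epithelial-mesenchymal transition. Gene
$i$ of a 26-gene regulatory network evolves by
$$dx_i = \Big(g_i \prod_{j: J_{ij}\ne 0} HS(x_j;\lambda_{ij},
\Theta_{ij}, n_{ij}) - k_i x_i\Big)dt + D\,x_i\,dW_i,$$
with the shifted Hill function
$HS(x) = \lambda + (1-\lambda)/(1 + (x/\Theta)^n)$ and multiplicative noise
of magnitude $D = 1$, integrated by Euler-Maruyama. Since the noise is
proportional to $x_i$, zero expression is absorbing in the exact dynamics;
states are clipped at zero after each step to preserve that under
discretization.

The packaged topology (`emt_grn_26_synthetic.txt`) is a constructed,
editable EMT-like circuit — core double-negative feedback between the
miR-200 family and ZEB factors, SNAIL/miR-34 mutual inhibition, epithelial
gatekeepers (GRHL2, OVOL2, KLF4) and marker outputs (CDH1, VIM, CDH2, FN1) —
*not* a published network reconstruction; tests treat it as an opaque
fixture and exercise the kinetics on small hand-built topologies.

Biological variability is emulated by an ensemble: every replicate
trajectory draws its own kinetic parameter set uniformly from documented
ranges (production 1-100 expression/time; degradation 0.1-1 per time, i.e.
lifetimes of 1-10 time units; activating fold change 1-10; inhibiting fold
change 0.1-1; threshold 2-198% of the regulator's unregulated scale
$g/k$; integer Hill coefficients 1-6) and its own uniform random initial
condition in $[0, g_i/k_i]$. Five snapshots at times 0-4 (500 cells by
default; the packaged end-to-end benchmark uses 100 for tractability on one
CPU) emulate temporally sparse sampling, with nearest-grid-point lookup
(ties toward the earlier index).

What the generator does *not* emulate: measurement noise and dropout,
library-size variation, cell-cycle structure, proliferation or death (the
population is fixed), and batch effects. Passing the synthetic benchmark
therefore demonstrates that the transport-plus-force-matching machinery
recovers nonlinear population dynamics from sparse sampling — not that it is
robust to every artifact of real scRNA-seq, which is what the optional
validation on real datasets is for.

## Problem sizes and reproducibility

The packaged tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which each property is cleanly measurable: 1-D
Gaussian transport with 200 particles per cloud; field recovery from 2,000
velocity samples; the three-snapshot turning-point toy with 200 cells per
snapshot; the end-to-end synthetic EMT benchmark with 100 replicate cells,
five time points, training on times {0, 2, 4} and holding out {1, 3}; 500
null replicates of 50 observations per group for permutation calibration
(with fewer observations the 10-bin histogram statistics are so discrete
that ties make the test visibly conservative); 600 cells for the trimodal
stratification. Every stochastic stage derives its seed deterministically
from one global seed (`stage_seed`), so a config plus a seed reproduces a
run exactly, and `run_pipeline()` writes a provenance log (config hash,
seeds, package version) into each run directory.

## Known limitations

* Transport quality is bounded by the dual-potential estimate: with ~100
  cells in more than a few dimensions the variational divergence estimator
  is biased, so the 0.05 stopping rule stops at a coarser match than it
  would with more cells.
* The gradient-flow path between two snapshots is a modelling choice, not
  ground truth; where the true intermediate distribution lies close to the
  straight-line interpolant, coupling baselines are strong competitors, and
  where it lies off both, held-out snapshots are the only arbiter.
* Euler integration error accumulates along long multi-interval spans;
  predictions anchored at the nearest training snapshot (the evaluation
  protocol above) are correspondingly more accurate than full-span rollouts.
* No growth, birth-death, or lineage branching in the population model: the
  transported mass is conserved, unlike unbalanced-OT trajectory methods.
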