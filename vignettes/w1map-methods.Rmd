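---
title: "Methods: Wasserstein-1 neural transport maps in w1map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Wasserstein-1 neural transport maps in w1map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Given unpaired samples from a control distribution $\mu$ and a perturbed
distribution $\nu$ on $\mathbb{R}^d$, we seek a map $T$ with $T_\#\mu
\approx \nu$ that moves points as little as possible in the $W_1$ sense.
The Kantorovich–Rubinstein dual,
$$W_1(\mu,\nu) \;=\; \sup_{f \in \mathrm{Lip}_1}
  \;\mathbb{E}_\mu[f(x)] - \mathbb{E}_\nu[f(y)],$$
is a maximization over a single 1-Lipschitz potential $f$. Its maximizer
determines only the *direction* of transport: optimal maps have the ray form
$$T(x) \;=\; x - \eta(x)\, \frac{\nabla f(x)}{\lVert \nabla f(x)\rVert},$$
with $\lVert\nabla f\rVert = 1$ almost everywhere at the optimum and the
scalar field $\eta(x) \ge 0$ undetermined: on collinear configurations many
maps share the optimal cost. `w1map` therefore trains in two stages:

1. **Potential.** Minimize
   $L(\theta) = -\mathbb{E}_\mu[f_\theta] + \mathbb{E}_\nu[f_\theta]$
   over a network that is 1-Lipschitz *by construction*. At convergence
   $-L$ estimates $W_1(\mu,\nu)$.
2. **Step size.** Freeze $\theta$ and parameterize
   $T_\omega(x) = x - \eta_\omega(x)\nabla f_\theta(x)$ with
   $\eta_\omega > 0$ (softplus output). Train $\eta_\omega$ against a
   discriminator $D_\xi$ with the original saturating GAN losses
   $L(\omega) = -\mathbb{E}_\mu[\log D_\xi(T_\omega(x))]$ and
   $L(\xi) = -\mathbb{E}_\nu[\log D_\xi(y)]
   -\mathbb{E}_\mu[\log(1 - D_\xi(T_\omega(x)))]$,
   alternating one discriminator and one generator step.

Note the two displacement conventions: the ray form divides by
$\lVert\nabla f\rVert$ while the trained map uses the raw gradient. The two
coincide where $\lVert\nabla f\rVert = 1$, which the trained potential
approaches, but they are not identical objects. The default follows the raw
gradient; `normalize_direction = TRUE` in `gan_training_config()` switches
to the unit direction, with zero-gradient points left in place (counted in a
warning). We deliberately expose both rather than guess a single intent.

## The 1-Lipschitz architecture

A feed-forward layer $h_{l} = \sigma(W_l h_{l-1} + b_l)$ is non-expansive
when $\lVert W_l\rVert_2 \le 1$ and $\sigma$ is 1-Lipschitz, but
norm-*contracting* layers make gradients vanish through depth, and a network
that must realize $\lVert\nabla f\rVert = 1$ cannot afford that. Both pieces
are therefore chosen norm-preserving:

* **Orthonormal weights.** The unconstrained raw matrix $M$ is mapped to
  $W = (I - A)(I + A)^{-1}$ with $A = M - M^\top$ (Cayley transform; always
  defined since $A$ is skew-symmetric). Optimizer steps act on $M$ and the
  constraint is re-applied every step — a parameterization, not a
  projection, so it is exact at all times. The alternative
  `method = "bjorck"` runs 15 first-order Björck iterations
  $W \leftarrow W(I + \tfrac12(I - W^\top W))$ after pre-scaling by the
  spectral norm; it converges to the orthogonal polar factor (verified
  against an SVD oracle in the tests) at higher cost. Backward passes
  through both parameterizations are closed-form adjoints, checked against
  finite differences; the Björck pre-scale factor is treated as a constant
  (stop-gradient), a standard simplification that leaves the constraint
  exact and only reparameterizes the raw space.
* **Rectangular layers.** Cayley yields square orthogonal matrices, but the
  first layer has shape $64 \times d$ and the last $1 \times 64$. We build a
  square orthogonal matrix of size $\max(\text{in},\text{out})$ and slice
  leading rows/columns. Because one dimension always equals the full size,
  the slice is exactly semi-orthogonal (Gram matrix of the smaller dimension
  is the identity), so non-expansiveness is preserved by the same mechanism
  for every shape. The paper-gap here is real: how the input layer of a
  $d \gg 64$ network is constrained is our choice.
* **GroupSort activation.** Features are split into contiguous groups of
  `group_size` (default 4) and sorted within each group. The Jacobian is a
  permutation matrix, preserving every vector norm. Widths not divisible by
  the group size are a construction error, not silently padded. A group
  size equal to the width degenerates toward less useful extremes (size 1
  *is* the identity), hence the moderate default. Sorting ties are resolved
  by a stable sort, so the autodiff subgradient at tie points is
  deterministic.
* **Biases are unconstrained** (translations are 1-Lipschitz), and the
  initialization draws raw entries i.i.d. normal with sd $1/\sqrt{s}$,
  which puts the Cayley transform near a mildly rotated identity.

The composition is 1-Lipschitz for *arbitrary* parameters — the tests
assert the sampled-pair bound on untrained networks — so dual training is
unconstrained optimization.

## Training defaults (and why)

| Parameter | Default | Notes |
|---|---|---|
| hidden widths (all nets) | [64, 64, 64, 64] | reference architecture |
| GroupSort group size | 4 | moderate; configurable |
| potential iterations | 10 000 | Adam(0.5, 0.5), cosine LR 1e-2 → 1e-4 |
| GAN iterations | 10 000 | Adam, one D step per G step |
| GAN learning rate | 1e-4 → 1e-6 cosine | see "GAN stabilization" below |
| batch size | 256 | unstated upstream; standard desk-scale choice |
| GAN Adam betas | (0.9, 0.999) | plain-Adam defaults; measured more stable |
| step-size init | η ≈ 0.05 (near identity) | see below |
| step penalty | 1e-3 · E[η²] | monotone tie-break, see below |
| probability clamp | 1e-7 | keeps the saturating losses finite |
| autoencoder | [512, 512] → 50 (or [32, 32] → 8) | MSE, Adam 1e-3, weight decay 1e-5 |
| autoencoder iterations | 20 000 default | full-scale recipe is 250 000; flagged down for desk runs |
| validation holdout | 10% random, seeded | unstated upstream; best-validation checkpoint kept |

Iteration counts scale down through the configs (and the CLI's
`--iterations-scale`); tests state their reduced budgets explicitly. One
master seed derives per-stage seeds; every sampler is seeded, so a fixed
seed and config reproduce loss traces bit-for-bit on one machine.

### GAN stabilization: why the stage-2 schedule deviates

Any map that pushes $\mu$ onto $\nu$ is an equilibrium of the stage-2 game:
the discriminator sees only marginals, so once the transported cloud matches
the target, nothing in the adversarial objective pins down *which* source
point went where. With a constant learning rate the updates keep wandering
through this equilibrium set, exchanging points between structures that lie
on shared transport rays. We measured this directly on the
concentric-circles data: the fraction of points transported to the wrong
ring was ~2% shortly after the distributions first matched, ~16% after
twice as long, and >90% after 10 000 constant-rate iterations — while the
MMD to the target stayed flat throughout. Three mitigations are defaults
(each a config knob, each removable):

* **Near-identity initialization** of $\eta$ ($\approx 0.05$): the
  transported cloud starts at the source and sweeps outward along the rays,
  so the first equilibrium reached tends to preserve ray order.
* **Cosine-annealed GAN learning rate** (1e-4 → 1e-6): freezes the map near
  that first equilibrium instead of letting it diffuse away.
* **Quadratic step penalty** $\lambda\,\mathbb{E}[\eta^2]$, $\lambda =$
  1e-3: all arrangements of collinear points have the same linear cost (the
  W1 degeneracy itself), but the order-preserving arrangement uniquely
  minimizes the *squared* step size — the same reason the W2 map is the
  monotone rearrangement. The penalty therefore acts as a tie-break that
  selects the monotone member of the equilibrium set without materially
  shifting which distributions match; at $\lambda =$ 1e-3 its gradient is
  below 1% of a typical adversarial gradient.

Even so, very long adversarial training on strongly collinear geometries
remains the least robust part of the procedure (a known GAN property, not
specific to transport); the toy diagnostics below are asserted at the
budgets where the solver is intended to run.

The discriminator is an ordinary (non-Lipschitz) ReLU MLP with a sigmoid
head: the stage-2 objectives are the classical saturating GAN losses, not
Wasserstein-GAN losses — stage 2 is distribution matching, and the W1
machinery lives entirely in stage 1. Discriminator gradients are computed
through the logits (numerically stable); the clamp affects reported loss
values only. For latent-space runs the whole stage-2 game is played in the
same space the transport runs in (the latent space); the alternative of an
ambient-space discriminator is unexplored upstream and not implemented.

## Synthetic data: what it emulates, what it does not

* `make_bookshelf()` — two strips, x uniform on [0,1] vs [2,3], y noise sd
  0.001: the collinear 1-D case where infinitely many optimal maps exist and
  only one is monotone. Exact $W_1 = 2$. Markers sit at the 10/30/50/70/90%
  quantiles of source x (marker placement is our choice; only "5 markers"
  is stated upstream).
* `make_circles_pair()` — two source rings (radii 0.5, 1.0) and the same
  rings scaled ×4 as target, noise sd 0.05. Radii, noise and the ×4 factor
  are unstated upstream; chosen to match the visual scale of the reference
  figures. Ring labels let cross-ring transport be measured (boundary at
  radius 3, the midpoint of the target radii).
* `make_swiss_roll_pair()` — standard 2D Gaussian source, target the (x, z)
  coordinates of the 3D swiss roll scaled by 0.1 so both clouds have
  comparable extent.
* `make_moons_pair()` — the two interleaved half-circles, one per cloud,
  noise sd 0.05.
* `make_gaussian_pair()` — unit Gaussians translated by a known vector:
  the closed-form fixture ($W_1 = \lVert\text{shift}\rVert$).
* `make_expression_matrix()` + `simulate_overexpression()` — log-normal
  positive features with per-feature dropout (fraction expressed varies
  across features, so the ≥60% expression filter has bite); the simulator
  picks 5 eligible features, splits cells 50/50 at random, and multiplies
  the chosen features by 2 in one half. True log2 fold change on
  expression-positive cells is exactly 1. The generator does **not**
  emulate scRNA-seq count noise (no negative-binomial sampling), batch
  effects, or cell-type structure — a green test establishes that the
  solver recovers multiplicative perturbations of smooth positive features,
  not performance on real counts.

The "subset of control cells" in the overexpression protocol is a 50/50
random split; log fold changes use feature means with pseudocount 1e-8.

## Evaluation choices

* **MMD** uses the biased V-statistic estimator (the unbiased variant can
  go negative, which complicates its use as a distance; the choice is
  documented because it is not stated upstream), averaged over squared-MMD
  values at six kernel scales derived from the median-pairwise-distance
  heuristic with length-scale multipliers {2, 1, 0.5, 0.1, 0.01, 0.005};
  the scales used are recorded in every report.
* **r²** is reported as *squared* Pearson correlation of the feature-mean
  vectors ("correlation coefficient r2" is ambiguous upstream; we compute
  both and attach the signed r as an attribute). Zero-variance mean vectors
  yield `NA` rather than an arbitrary number.
* **Monotonicity** (the order-preservation criterion) is sampled: violation
  means the unit vectors of $x_1 - x_2$ and $T(x_1) - T(x_2)$ sum to less
  than 1e-3 in norm; coincident pairs are skipped. The criterion is only
  violable on collinear configurations, so the rate is a diagnostic of 1-D
  order inversion.
* **DE ranking** reimplements the two-sample Wilcoxon rank-sum z-score with
  tie correction per feature (upstream used precomputed DE lists we cannot
  assume), with deterministic index tie-breaks.

## Numerical notes and degenerate inputs

* Cayley inversion is a dense solve per layer per step; at width 64 this is
  microseconds and dominates nothing.
* Non-finite dual loss aborts with a diagnostic (learning rate / input
  scale advice) rather than training on.
* `transport_apply` with a zero-gradient row under `normalize_direction`
  returns the row unchanged and warns with a count.
* A generator loss pinned at the clamp for the last 100 iterations raises a
  mode-collapse warning and flags the trace.
* Identical source and target are legitimate inputs: the dual estimate
  hovers near 0 and the learned map stays close to the identity (tested).

## Known limitations

* The GAN stage matches distributions, not the pointwise-optimal map. On a
  pure translation the *mean* step size recovers the shift length within a
  few percent and the transported cloud matches the target closely, but the
  per-sample step size does not collapse to a constant at desk-scale
  training budgets (measured coefficient of variation ≈ 0.35–0.4); claims
  that the learned $\eta$ is the constant translation are not supported and
  not asserted.
* GroupSort networks are not proven universal 1-Lipschitz approximators in
  the Euclidean norm; pathological geometries may be unreachable.
* Monotonicity of the learned map is an empirical observation on 2D data,
  asserted by diagnostics, not a theorem.
* The autoencoder is a plain MSE model: latent transport inherits its
  distortions, and decoded predictions are only as faithful as the
  reconstruction.
* Everything runs full-batch-free on CPU in base R matrix ops; it is meant
  for $d$ up to a few thousand and $n$ up to tens of thousands, not for
  atlas-scale corpora.
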