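---
title: "Unsupervised point-cloud denoising by noise doubling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised point-cloud denoising by noise doubling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

UAV and airborne LiDAR surveys of forest plots produce dense 3-D point
clouds from which individual trees are segmented. Sensor precision limits
and acquisition conditions contaminate these clouds with noise points and
outliers, which degrade every downstream product — canopy height models,
crown delineation, biomass estimates. Classical filters (statistical and
radius outlier removal) discard points; a denoiser instead *moves* points
back toward the underlying surface. The catch for supervised learning is
that no clean reference cloud exists for real acquisitions.

`pcdenoise` implements an unsupervised scheme that trains a
displacement-predicting network on the noisy data alone, using a
noise-doubling argument, together with the surrounding toolchain: file I/O,
noise simulation, classical baseline filters, evaluation metrics, and a
synthetic forest generator that provides ground truth for testing.

## The noise-doubling scheme

Let $P$ be the unknown clean cloud and $\dot P = P + N$ the observed noisy
cloud, with $N$ additive sensor noise. Injecting a second, *independent*
noise realization $M$ of the same family and level gives the double-noisy
cloud $\dot P' = \dot P + M$, and the known per-point displacement
$\dot d_i = \dot p_i - \dot p_i'$ (which equals $-M_i$).

Under the conditional-expectation argument — the estimators of $P$, $\dot
P$ and $\dot P'$ are conditional means given $\dot P'$, noise is additive,
independent, zero-mean, and of equal level in both injections — the
displacement from the double-noisy point to the *clean* position is twice
the displacement to the singly-noisy position:

$$\bar d_i' = 2 \bar d_i .$$

So a network fed $\dot P'$ and regressed onto the *realized* target
$2\dot d_i = -2M_i$ learns, in expectation, the full displacement back to
the clean surface, without ever seeing clean coordinates. The training
objective is

$$L = L_{\mathrm{mse}} + \gamma\, L_{\mathrm{rep}}, \qquad
L_{\mathrm{mse}} = \tfrac1n \sum_i \lVert \bar d_i' - 2\dot d_i \rVert_2^2 ,$$

where $L_{\mathrm{rep}}$ is a repulsion term measured against the
pseudo-clean cloud $\tilde P = \{\dot p_i' + 2\dot d_i\}$ (algebraically
$\dot P - M$): the mean over points of the *maximum* squared distance from
the denoised position to its $k_{\mathrm{rep}}$-neighborhood in $\tilde P$.
Two remarks we surface to users:

* As printed, the term minimizes a maximum distance *to* neighbors, i.e. it
  pulls denoised points toward the far edge of their pseudo-clean
  neighborhood rather than pushing points apart. We implement it exactly as
  stated; at its default weight $\gamma = 5\cdot10^{-4}$ it is a mild
  regularizer either way.
* The neighborhood definition carries no selection criterion beyond
  distance to the base point; we use the $k_{\mathrm{rep}}$ nearest
  (default 4, ties to the lower index), queried by the base (singly-noisy)
  point, which is the less noise-affected anchor. The stated
  "normalization" of the neighborhood is implemented as an optional
  translation to the query point's frame (`center_neighborhoods`), which
  provably leaves the distances unchanged — it is exposed only for
  experimentation.

Both loss reductions are means over points, which keeps $\gamma$
batch-size-independent.

## Network

Per-point local features come from a k-NN graph convolution: each point's
`k_feat` (default 16) nearest neighbors are lifted to edge features, passed
through a shared MLP (ReLU, widths `3-256-512-1024-2048` at full scale) and
mean-aggregated over the neighbors. A global descriptor — the max-pool of
per-point features over the set, the PointNet convention — is concatenated
to each per-point feature and decoded by an MLP head (`1024-512-256-3`)
into a 3-D displacement per point. The output is *additive*: `denoised =
points + displacements`, so the residual connection is the identity map at
a zero-weight head, and we zero-initialize the output layer so training
starts exactly there.

Design choices where the design was genuinely open:

* **Edge features.** Default `"relative"` (neighbor − point offsets only),
  which makes the network exactly translation-covariant — translating the
  input translates the denoised output — and matches the encoder's stated
  input width of 3. The DGCNN concat `(neighbor − point, point)` is
  available as `edge_features = "dgcnn"`; it adds positional context at the
  cost of exact covariance, which matters little once clouds are
  normalized but breaks a property we prefer to guarantee.
* **Neighbor aggregation.** Mean, not max. The regression target is built
  from local offsets, and the mean of relative neighbor offsets is the
  sufficient local statistic for it (the conditional mean of the noise
  given the observed point is, to first order, the point's offset from the
  local surface — exactly what the neighbor mean measures). Max-pooling is
  kept where it is specified: the global descriptor.
* **Optimizer.** Adam with the configured weight decay; cosine-annealed
  learning rate from `base_lr` (default 0.001) to `eta_min` (1e-5) over
  `epochs` (default 200), batches of 128 samples.
* **Samples are contiguous patches.** A training sample is a fixed-size
  point set (`patch_points`) drawn from a dataset cloud. We draw
  *spatially contiguous* k-NN patches (a seed point plus its nearest
  neighbors, `sample_fixed(strategy = "patch")`) rather than random
  subsets: a random subset dilutes local density, so its k-NN
  neighborhoods are geometrically wider than those of the full cloud the
  model denoises at inference time, and the local offset signal the target
  depends on is lost. Random and farthest-point subsampling remain
  available for other purposes.
* **Fresh noise every epoch.** $M$ is re-drawn per sample per epoch, so the
  regression sees the distribution of $M$ that the expectation argument is
  about, not one frozen realization.

## Inference

The training inputs are double-noisy, so two protocols are shipped:

* `mode = "double"` (default): inject a fresh $M$, predict on $\dot P + M$,
  output $\dot P + M + \bar d'$; average over `realizations` independent
  draws. The injected noise contributes a residual that provably shrinks
  like $1/\sqrt{R}$ (the package tests fit this slope with an oracle
  model). We use $R = 8$ in our own evaluations.
* `mode = "direct_half"`: feed the noisy cloud itself and add half the
  predicted displacement (the doubling identity read backwards). No extra
  noise, but the network sees a slightly narrower input distribution than
  it was trained on.

## Normalization and units

Clouds are normalized to the unit sphere (centroid-centered, scaled so the
maximum radius is exactly 1) before noise injection and network input; the
record is stored on the cloud and inverted exactly. Noise levels
(`sigma`, per axis) are therefore fractions of the object radius — the
tested range 0.01–0.1 reads as 1–10 % of radius, and the training default
is 0.1. Whether such levels are meters or normalized units was left open
by the source experiments; we fix normalized units, which is the only
reading under which a single default generalizes across trees of different
sizes.

## Metrics

`evaluate_denoising()` scores a noisy and a denoised cloud against a
reference with identical settings and reports all parameters used:

* **MSE** — mean squared Euclidean point distance over a correspondence
  (`paired` index-wise, or `nearest`).
* **SNR (dB)** — $10\log_{10}(P_s/P_n)$ with $P_s$ the reference's mean
  squared point norm *in the evaluation frame* and $P_n$ the MSE. Frame
  matters: raw georeferenced coordinates have enormous norms and hence
  enormous SNRs (values near 150 dB arise exactly this way), so the frame
  is recorded in every report.
* **One-way Hausdorff** — worst-case distance from the estimate into the
  reference; the symmetric variant is exposed separately.
* **3D SSIM** — a neighborhood-based structural similarity computed
  directly in 3-D: the local signal of a point is the sorted vector of its
  `k_ssim` neighbors' distances to their centroid (rotation- and
  translation-invariant, no voxelization), and matched signal vectors
  enter the standard SSIM ratio with $C_1 = (K_1 L)^2$, $C_2 = (K_2 L)^2$,
  $K_1 = 0.01$, $K_2 = 0.03$, $L$ defaulting to the reference
  bounding-box diagonal. `ssim3d(X, X) = 1` exactly, and a rigid
  translation leaves the score at 1.

## Synthetic scenes and ground truth

Because the motivating forest dataset is not public, the package generates
its own test scenes: cylinder-trunk / ellipsoid-crown trees, multi-tree
plots with minimum-spacing placement and optional ground plane, and
unit-scale primitives (sphere, plane, cylinder). All sampling is on
*surfaces*, as LiDAR returns are, which makes `distance_to_surface()` an
analytic ground-truth channel: clean fixtures are at distance 0, and
isotropic noise of level $\sigma$ produces an RMS surface distance of
about $\sigma$ (its normal component).

What passing tests on these fixtures do and do not show: they verify the
training scheme recovers smooth surfaces from noise of a known family and
level — the regime the theory covers. Real forest clouds add occlusion,
anisotropic and range-dependent noise, multi-return artifacts and genuine
outliers; the outlier channel of `noise_spec()` emulates only the last of
these, and performance there is an empirical question the synthetic suite
cannot settle. Crown points are placed on the ellipsoid surface with a
direction-uniform (not exactly area-uniform) law; for fixture purposes
only surface membership matters.

## Desk-scale preset and problem sizes

The full-scale recipe (widths to 2048, 200 epochs, batches of 128
2048-point samples) is sized for GPU training. For CPU-bound test and
demonstration runs the package defines `train_config(preset = "desk")`:
encoder `3-64-128-256`, decoder `128-64-3`, batch 8, 50 epochs, 4 steps
per epoch, 256-point contiguous patches, `sigma = 0.02`, base learning
rate `3e-3`, dropout and weight decay off. The learning rate is raised
because a 200-step schedule takes proportionally larger steps; the
regularizers are off because a 200-step run on a model this small
underfits — with them on, the run measurably fails to fit at all. The
package's own evaluation (the acceptance script and the heaviest test)
trains this preset on a single noisy 2048-point sphere and verifies that
denoising at least reduces the mean squared surface distance to 60 % of
the noisy cloud's — at desk scale the reduction is typically to ~50 %.

Numerical conventions worth knowing: k-NN ties break to the lower index
everywhere; Hausdorff distances use direct `(a-b)^2` arithmetic so results
are bit-identical to a naive scan; degenerate inputs (all-coincident
clouds, empty neighborhoods, `k >= n`) raise errors rather than returning
arbitrary values; every stochastic operation takes an explicit seed and
leaves the global RNG state untouched.

## Known limitations

* Training cost is CPU-bound dense linear algebra; the full-scale preset
  is impractical without substantial hardware — the desk preset is the
  supported CPU path.
* The repulsion term is implemented as printed (see above) and its benefit
  at $\gamma = 5\cdot10^{-4}$ is within run-to-run noise at desk scale.
* Tangential noise components are unrecoverable by any surface denoiser;
  quality gains are measured against the surface, not against per-point
  clean positions.
* LAZ files are not read (no decompressor dependency); convert to LAS.
* `direct_half` inference inherits a train/test input-distribution
  mismatch; `double` with a handful of realizations is the recommended
  default.
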