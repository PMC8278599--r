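---
title: "Hahn-moment / PCNN fusion: methods and numerical choices"
author: "HahnFusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hahn-moment / PCNN fusion: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HahnFusion)
```

# Overview

HahnFusion fuses co-registered multi-modal brain images at feature level.
The pipeline is

1. extract 64-channel features from each source with a shared
   convolutional extractor;
2. collapse each feature stack to an activity image, tile it into
   $D \times D$ blocks, and score each block by the *potential energy* of
   its discrete orthogonal Hahn moments;
3. let a simplified pulse-coupled neural network (PCNN) compete over the
   normalized block energies, with link strengths derived from a saliency
   field; copy each output block from the source that fired most;
4. map the fused features back to a 3-channel image with a convolutional
   reconstructor.

The extractor/reconstructor pair is trained as an autoencoder on phantom
images under a composite loss; the fusion rule itself has no trainable
parameters.

# Hahn moments

The regularized Hahn polynomials
$\bar h_n^{(\alpha,\beta)}(x) = h_n(x)\sqrt{\rho(x)/d_n^2}$ are
orthonormal on $x = 0,\dots,N-1$ for any shape parameters
$\alpha, \beta > -1$. Two properties matter here: the 2-D transform
$H = \bar h \, f \, \bar h^\top$ conserves energy exactly (so block
activity is measured in a lossless coordinate system), and low orders
concentrate smooth content while high orders capture texture and edges.

The block statistic is the potential energy
$$\mathrm{PE} = \sum_{u,v} \frac{|H_{uv} - H_{11}|}{\sqrt{(u-1)^2 + (v-1)^2}},$$
with the $(1,1)$ term defined as $0$ (a $0/0$ limit: zero deviation at
zero distance). Flat blocks score zero; textured blocks score high, with
distant (high-order) structure attenuated.

## Why a spectral construction

Evaluating the gamma-ratio closed form literally overflows beyond
$N \approx 20$, and the forward three-term recurrence in the order $n$ is
numerically unstable for this normalization: in double precision its Gram
deviation from the identity grows to about $4\times10^{3}$ by $N = 64$.
The production path (`hahnBasis()`) instead uses the spectral identity of
discrete orthogonal polynomials: the matrix $P[n, x] = p_n(x)\sqrt{w(x)}$
is orthogonal, and its columns are eigenvectors of the symmetric
tridiagonal Jacobi matrix of the measure with eigenvalues exactly
$0,\dots,N-1$. One LAPACK symmetric eigendecomposition therefore yields
the whole basis with machine-precision orthonormality at any practical
$N$:

```{r}
max(abs(tcrossprod(basisValues(hahnBasis(64, 0.5, 2))) - diag(64)))
```

Two conventions are pinned by tests against the closed form
(`hahnBasisDirect()`, reliable for $N \lesssim 20$): the weight pairs
$\Gamma(\beta + 1 + x)$ with the ascending side of the support — i.e. it
equals the classical Hahn weight with the roles of $\alpha$ and $\beta$
interchanged, which the Jacobi coefficients account for — and each
eigenvector is signed so the order-0 row is positive, which reproduces the
closed form's $(-1)^n$ sign at $x = 0$.

# The simplified PCNN

Per synchronous iteration, with initial pulses $Y = 0$ and threshold
$\theta_0$:
$$L = \textstyle\sum_W Y, \quad U = S\,(1 + \beta L), \quad
\theta \leftarrow e^{-\alpha_T}\theta + V_T\,Y, \quad Y = [U \ge \theta].$$
The feeding input is the stimulus itself; the linking input sums the
8-neighborhood's previous pulses through an inverse-distance kernel. The
per-neuron *firing count* over the run is the arbitration statistic: a
stronger stimulus fires earlier and more often, and linking lets salient
neighborhoods pull their members along. Defaults
($\alpha_T = 0.2$, $V_T = 20$, $\theta_0 = 1$, 200 iterations) keep each
neuron on a fire/decay cycle whose period is monotone in the stimulus.

The link strengths $\beta$ are block means of a contrast-weighted
saliency proxy: local histogram entropy (7×7 window, 32 bins) times a
Gaussian-smoothed Sobel gradient magnitude, min-max scaled. This supplies
the "salient regions recruit their blocks" behavior using only classical,
dependency-free operations.

Ties in firing counts resolve to the element-wise maximum of the tied
sources' blocks. That makes the rule symmetric under source permutation
and exactly idempotent — `fuseFeatureMaps(list(A, A))` returns `A`
bit-for-bit — both of which the suite asserts.

# Network and training

The extractor is CONV1–3 (64 kernels of 7×7 pad 3, 5×5 pad 2, 3×3 pad 1,
all stride 1 + ReLU); the reconstructor is CONV4–5 (64 kernels 3×3 pad 1
ReLU, then 3 kernels 1×1 + sigmoid). A listed stride/padding of 0 for the
final layer is read as stride 1, padding 0 — the only reading under which
a convolution is defined, and the 1×1 kernel then preserves size. Weights
start He-initialized for ReLU layers and Xavier for the sigmoid layer,
deterministically in a seed.

Training minimizes
$$L_\text{total} = L_\text{CE} + \big(1 - \text{MS-SSIM}\big) + L_\text{TV}$$
with analytic gradients throughout. The MS-SSIM gradient is the delicate
part: the Gaussian windowing operator $G$ (separable, zero-padded,
symmetric) is self-adjoint, so the per-scale gradients of the mean
contrast-structure and luminance terms reduce to a handful of $G$
applications; scales are chained coarsest-first through the adjoint of the
2×2 average pooling. Every gradient is finite-difference-checked in the
test suite.

Optimization is plain Adam (learning rate $10^{-3}$, batch 8, 50 epochs by
default) with a seeded shuffle; two runs with the same seed, data and
configuration are bit-identical, which the acceptance tests verify by
training twice. The convolution forward/backward and the separable filter
run as compiled single-precision im2col + GEMM kernels (with the whole
per-image forward/backward fused into one call during training); pure-R
double-precision references remain in the package as test oracles.

# Quality metrics

`scoreAll()` reports six standard measures, each reduced to ITU-R BT.601
luminance first: spatial frequency (RMS first differences), single-scale
SSIM (11×11 Gaussian window, $C_1 = 0.01^2$, $C_2 = 0.03^2$, interior
mean), histogram cross entropy (mean KL divergence in bits over 256
bins), the edge-transfer measure Q_AB/F (Sobel strength/orientation
through the published sigmoids, edge-strength-weighted), pixel-domain VIF
(4 Gaussian scales, noise variance 2 on a 0–255 range), and feature
mutual information on min-max-scaled gradient-magnitude features.

# Phantoms and problem sizes

The phantom generator supplies a fully offline stand-in for a clinical
corpus: a seeded elliptical brain with a bright skull ring, band-pass
noise texture, ventricle lobes and an optional lesion (structural), plus
two to four smooth activity blobs through a hot-iron colormap masked to
the same brain (functional); `makeTriModal()` adds a CT-like variant.
Default size is 256×256 to match the corpus's conventions; training
workloads in tests and scripts use 64×64 phantoms, a package-level choice
that keeps the full desk-scale study (50 epochs × 64 images, run twice
for the determinism check) under ten minutes on one CPU without touching
any algorithmic parameter. Generator parameters are fixed study
conditions, not tuning knobs.

# Coordinates and conventions

Images are numeric matrices or `H x W x C` arrays in $[0, 1]$, rows = y,
origin top-left; the mathematics uses 0-based indices, R code 1-based
ones, and the mapping is made once per function. Quantization to 8 bits
happens only at the PNG boundary.
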