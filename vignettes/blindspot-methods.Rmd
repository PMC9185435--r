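---
title: "Mask-free blind denoising with a J-invariant dilated network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mask-free blind denoising with a J-invariant dilated network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blindspot)
```

## The problem

Self-supervised denoisers train a network $f$ on noisy images $x$ alone, by
minimizing $\lVert f(x) - x \rVert^2$. Naively this collapses to the identity
map. The classical escape is a *masking scheme*: hide random pixels during
training so the network must predict them from context. Masking damages the
training signal and adds a hyperparameter (the masking rate).

This package takes the architectural route instead: it builds networks that
are **J-invariant by construction** — the output at pixel $j$ is functionally
independent of the input at pixel $j$ — so the self-supervision loss can be
used directly on the unmodified noisy image. For a J-invariant $f$ and
zero-mean per-pixel noise ($\mathbb{E}[x \mid y] = y$),

$$\mathbb{E}\lVert f(x)-x\rVert^2
  \;=\; \mathbb{E}\lVert f(x)-y\rVert^2 + \mathbb{E}\lVert x-y\rVert^2,$$

so the self-supervised objective is the supervised objective plus a constant.
`check_loss_decomposition()` estimates both sides by Monte-Carlo so this
identity is a runnable test rather than a slogan.

## The architecture and why it is invariant

The network is fully convolutional, single channel in and out:

1. **Donut front layer.** A $K \times K$ convolution ($K$ odd) whose center
   weight is structurally absent — the layer's stencil simply has no center
   offset, so no optimizer can ever reintroduce it. After this layer, the
   feature at $j$ depends on the ring around $j$ but not $j$ itself.
2. **Two dilated paths.** Each path is a stack of $3\times3$ convolutions all
   at one dilation $d$ (defaults: one path at $d=2$, one at $d=3$, depth 2
   each). The receptive-field recurrence
   $RF^{(k)} = \bigcup_{s \in \{-d,0,d\}^2} \{\,o+s : o \in RF^{(k-1)}\,\}$
   shows that a stack at dilation $d$ maps the donut ring to offsets of the
   form (ring) $+\, d\cdot\mathbb{Z}^2$; when $d > \lfloor K/2 \rfloor$ the
   zero offset can never be produced (the ring's coordinates are too small to
   be cancelled by multiples of $d$). We implement the *strict* inequality:
   $d = \lfloor K/2 \rfloor$ demonstrably fails (at $K=3$, $d=1$ the offset
   $-1 + 1 = 0$ appears after one layer), and `receptive_field()` +
   `dependency_map_bruteforce()` verify the boundary in both directions.
   The two dilations cover each other's gaps: a single-dilation stack leaves
   a lattice of unreachable offsets, and the union of the $d=2$ and $d=3$
   fields strictly contains each one.
3. **Pointwise tail.** The paths are concatenated along channels, mixed by a
   $1\times1$ layer, the donut-layer features are added back (a skip that
   preserves the first prediction), and a small head of $1\times1$ layers
   produces the output. Everything after the paths has spatial extent
   $1\times1$ on purpose: mixing the paths with any spatial kernel could
   recombine an offset $+1$ from one path with $-1$ from a later stencil and
   re-create the zero offset. Pointwise merging keeps the invariance proof
   compositional: the union of J-invariant fields, followed by pointwise
   maps, is J-invariant.

Two further choices are safety-critical rather than cosmetic:

* **Zero padding everywhere.** Reflection padding maps a border pixel's own
  value into its neighborhood and silently breaks invariance exactly at the
  border. Zero padding cannot introduce any offset. The test suite probes
  corner and edge pixels explicitly.
* **No global residual.** Adding the input to the output would trivially
  destroy invariance; the network predicts intensities from scratch.

The supervised reference (`baseline_n2c = TRUE`) swaps the donut kernel for
the full $K\times K$ kernel and trains against clean targets; it is *not*
invariant (the verifier reports a large self-dependence, as it must) and
serves as the performance upper bound for the self-supervised runs.

## The adaptive loss

Plain self-supervision assumes zero-mean noise. Impulse noise breaks the
assumption: replacing pixels with 0 or 1 shifts the conditional mean by
$d\,(0.5 - x)$ per pixel, and an L2-trained network dutifully reproduces that
shift — the brightness-shifting artifact. The adaptive self-supervision loss
down-weights exactly the pixels that look like impulses:

$$L(f,x) = \mathbb{E}_j\!\left[ w_j\,(f(x)_j - x_j)^2 \right],
  \qquad w_j = \frac{1}{1 + \lambda\,\lvert f(x)_j - x_j\rvert},$$

with focusing parameter $\lambda$ (default 10; $\lambda = 0$ recovers L2
exactly). By default the weights are **detached** — treated as constants by
differentiation — so the gradient at a pixel is the L2 gradient scaled by
$w_j \le 1$: backpropagation from outlier pixels is suppressed, not
redirected. Differentiating through $w_j$ would add a term pulling
predictions toward the noise; both readings are available via
`detach_weights`, and a test pins the detached gradient to $w_j$ times the
L2 gradient. Two relatives complete the family: an anisotropic
total-variation term $\alpha\lVert f(x)\rVert_{TV}$ ($\alpha$ tiny, default
$10^{-7}$ in published protocols, so the TV scale matches the loss scale)
that damps residual pixel-level artifacts, and a clipped loss
$\mathbb{E}_j[\min((f(x)_j-x_j)^2, \varepsilon)]$, the non-adaptive precursor
that motivates the adaptive form. TV is implemented as the sum of absolute
forward differences along both axes — the simplest convention consistent
with "total variation"; the isotropic variant is noted but not implemented.

## Training

`train()` runs mask-free self-supervised optimization: every step samples a
batch of random crops (dihedral augmentation applied per patch — one of the
8 rotations/mirrors, uniformly), evaluates the configured loss of
$f(\text{batch})$ against the *same noisy batch*, and updates with rectified
Adam under continuous exponential learning-rate decay. Published-protocol
defaults are kept where stated: batch 64, initial learning rate 0.03,
$\lambda = 10$, rotation/mirror augmentation. The remaining constants are
engineering choices recorded in every checkpoint: patch size 64, decay rate
0.9 per 2000 steps, leaky-rectifier slope 0.1, channel width 64 with path
depths 2+2 and head depth 2. J-invariance is independent of all of them —
it follows from the stencils alone — so they affect quality only.

The forward/backward passes are implemented as one BLAS matrix product per
stencil offset on `(H, W, batch, channels)` arrays; gradients are verified
against central finite differences in the test suite. Inference offers
eight-fold dihedral test-time averaging (`denoise_tta()`): apply the network
to all 8 transforms of the image, undo each transform *geometrically*, and
average — the only reading of "average of the inverse of eight outputs"
under which averaging is well-posed. Averaging J-invariant outputs is again
J-invariant, which the suite checks through the wrapper.

## Noise simulators and the synthetic generator

Four corruption models, with printed levels on the benchmark scales
($\sigma$ on 0–255, divided by 255 at application; $d$ a probability):

* **AWGN** $x + n$, $n \sim \mathcal{N}(0, (\sigma_g/255)^2)$;
* **speckle** $x + n \cdot x$ with $n$ uniform, zero mean, standard
  deviation $\sigma_s/255$ (support $\pm\sqrt{3}\,\sigma$) — the zero-mean
  uniform reading, which the prose fixes even though the symbolic notation
  $U(0,\sigma^2)$ is ambiguous;
* **salt-and-pepper**: each pixel replaced with probability $d$ by 0 or 1,
  equiprobably (the split is unstated in the literature we follow;
  equiprobable is the symmetric default);
* **fusion**: Gaussian, then speckle applied to the already-Gaussian image,
  then impulse replacement — the "unknown statistics" regime.

AWGN and speckle outputs are deliberately *not* clipped to $[0,1]$ before
training — clipping would break the zero-mean property the decomposition
relies on; clipping happens only at metric/export time. One seed expands
into independent named substreams (gaussian, uniform, mask, value), so
disabling one fusion component never shifts another's draws, and fusion
with two components off is bit-identical to the remaining single-noise
simulator.

`make_synthetic_clean()` supplies the clean material: flat fields,
gradients, piecewise-constant shapes with sharp edges (mean well below 0.5,
so impulse noise induces a measurable brightness shift), checkerboards and
band-limited texture. It emulates the piecewise-smooth structure of natural
images at small scale; it does **not** emulate natural-image self-similarity
across scales, camera processing pipelines, or spatially correlated real
sensor noise — so passing tests certify the *mechanisms* (invariance,
decomposition, bias suppression, descent), not benchmark-grade performance
on photographs.

## Metrics

`psnr()` is $20\log_{10}(\mathrm{MAX}/\sqrt{\mathrm{MSE}})$ after clipping
both images to the dynamic range. `ssim()` uses the de-facto standard
11×11 Gaussian window ($\sigma = 1.5$) with $k_1 = 0.01$, $k_2 = 0.03$; the
windowed implementation reproduces the reference scikit-image values to
$10^{-10}$ on a frozen fixture, and a whole-image `window = "global"` mode
evaluates the single-statistic form of the SSIM expression exactly as
printed in most papers.

## Numerical and design notes

* **Donut enforcement**: the center offset is absent from the first layer's
  parameterization rather than masked multiplicatively — identical
  mathematics, and standard optimizers work untouched. The `unmask_center`
  build hook exists only so tests can show the verifier catching the broken
  variant.
* **Degenerate inputs**: 1×1 images have TV 0 by convention; identical
  images give PSNR `Inf` (a sentinel, propagated through report tables);
  `steps = 0` training returns the untouched initialization.
* **Determinism**: every stochastic component (weight init, patch stream,
  noise draws, probe pixels) derives from explicit seeds and restores the
  session RNG afterwards; pipeline reports contain no timestamps, so equal
  seeds give byte-identical reports.
* **Verifier tolerances**: compliant networks must show self-dependence
  below $10^{-5}$ (observed: exactly 0 up to float rounding); the
  non-compliant controls sit orders of magnitude above $10^{-3}$.

## Problem sizes used in the checks

The test and acceptance runs use reduced study sizes chosen once: networks
of 3–8 channels with single-depth paths, 96×96 synthetic images, batches of
8 patches of 32×32, 300 optimization steps for the brightness-preservation
comparison (the effect is large and stable well before convergence) and
2000 steps for the AWGN improvement runs; the receptive-field battery spans
$K \in \{3,5\}$, $d \in 1..4$, depths 1–3. At these sizes the full suite
exercises every claim in minutes on one CPU. The defaults in `net_spec()`
and `train_config()` remain the full-scale settings.

## Known limitations

* Grayscale 2-D only; no color, volumetric or video variants.
* No attention/normalization layers; the exact layer schedule of large
  published models is not reproduced, only the invariance mechanism.
* The adaptive loss mitigates but does not remove bias under extreme
  non-zero-mean noise; the exponential weight variant is future work.
* Performance numbers at benchmark scale (large photographic corpora, long
  training) are outside the scope of the desk-scale property checks here.
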