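---
title: "Probabilistic inpainting with structured latent priors: methods"
author: "BayesInpaint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic inpainting with structured latent priors: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its model, its tunable parameters,
the design decisions that were genuinely open, and what the desk-scale tests
do and do not demonstrate.

## The inverse problem

An image is a real matrix with intensities in [0,1] (8-bit I/O scales by
255; quality metrics are reported on the 0–255 scale, which matches the
magnitudes conventional in the inpainting literature). The forward model is

$$I_{corrupt} = M \odot I_{clean} + \eta_{pixel},$$

with $M$ a binary mask (1 = observed, 0 = missing — the convention every
module shares, because the corruption is the Hadamard product and the masked
region is zeroed) and $\eta_{pixel}$ additive Gaussian noise applied only to
observed cells, clipped to [0,1]. Noise on masked cells would be discarded
by the forward operator anyway; applying it only where the mask is 1 keeps
the observation exactly zero in the holes, which the Papoulis–Gerchberg
initialization relies on.

Reconstruction inverts a differentiable generator $G$ over its latent code
$\omega \in \mathbb{R}^{L\times D}$, a stack of $L$ level vectors of shared
dimension $D$ as in style-based generators (production-scale 18×512; the
desk-scale default is 4×16–4×32). The posterior is

$$P(\omega \mid I_{corrupt}) \propto P(I_{corrupt} \mid G(\omega)) \,
P_{mean}(\omega)\, P_{cosine}(\omega)\, P_{intensity}.$$

The Jacobian change-of-variables factor that would turn a density on
$\omega$ into a density on $G(\omega)$ is intractable for deep generators
and is deliberately omitted: the prior is placed on the latent code
directly. Log-domain weighted sums absorb all normalization constants.

## The three priors

**Mean prior.** $L_{prior} = \sum_{l,d} ((\omega - \mu)/\sigma)^2$ — the
diagonal-Gaussian negative log-density up to constants. Zero iff
$\omega = \mu$. Default $\mu = 0$, $\sigma = 1$, matching the latent scale
the auto-decoder is trained to occupy (its latents carry a small L2
penalty during training).

**Cosine prior.** $L_{cosine} = \sum_{i=1}^{L-1}
\arccos\!\big(\langle\omega_i,\omega_{i+1}\rangle /
(\lVert\omega_i\rVert\,\lVert\omega_{i+1}\rVert)\big)$, adjacent pairs only
— an all-pairs coupling would be quadratic in $L$ and is not what the
enumeration of consecutive pairs suggests. The arccos sum serves as the
negative log-density surrogate of a directional distribution on $[0,2\pi]$;
a separate angular scale parameter is reserved in `LatentPrior` but unused
by default. Numerics: the cosine argument is clamped to $[-1,1]$ against
floating-point overshoot; the gradient factor $1/\sqrt{1-c^2}$ is floored at
$10^{-6}$ so exactly (anti)parallel levels do not produce infinite
gradients; a zero level vector is a contract error naming the level. The
loss is invariant to positive per-level rescaling and to one rotation
applied to all levels (tested properties).

**Intensity prior (Papoulis–Gerchberg).** The classical band-limited
extrapolation: starting from the observation with masked cells zero,
alternate (a) projection onto the centred Fourier passband holding a
fraction `passbandFraction` of coefficients and (b) resetting observed
cells to their observed values, until the max-abs change is below `pgTol`
(default 1e-7) or `pgMaxIters` (default 500) is reached. The passband is
the largest centred square of signed frequencies $|k| \le K$ per axis whose
count does not exceed the requested fraction; the set is symmetric under
negation so real images stay real. Both projections are idempotent and the
iteration is non-expansive; for observations genuinely band-limited inside
the passband it converges to the exact completion, which the tests verify
against an independent least-squares solve in an explicit trigonometric
basis. `passbandFraction = 0.2` is the default: on 32×32 phantoms it keeps
a 13×13 frequency square, enough for the smooth anatomy-like structure
while still determining the holes.

How the intensity prior enters the objective was an open design point: the
four-term loss lists prior, cosine, pixel and perceptual terms only, while
the prior product has three factors. The package implements both readings:
`lambdaIntensity = 0` (default) gives the four-term mode, with the PG image
available as a warm-start target (`warmStart = TRUE`); `lambdaIntensity > 0`
("full prior" mode) adds $\sum_{masked}(G(\omega) - I_{PG})^2$ as a fifth
term. The phantom experiments in the acceptance suite run the full-prior
mode (weight 60; any value in roughly 20–150 behaves equivalently there —
the weight sits on a plateau, chosen as its midpoint), because on heavily
masked phantoms the PG anchor resolves completions that the observed ring
alone leaves ambiguous.

## Likelihood terms

**Pixel loss.** $\lVert F(M \odot G(\omega)) - F(I_{corrupt})\rVert^2 /
(2\sigma_{pixel}^2)$, where $F$ is the forward measurement operator:
identity by default (`nf = 0`), or fractional-overlap area averaging to an
`nf`×`nf` grid. $F$ is linear, so its adjoint is exact in the gradient.
When $\sigma_{pixel} = 0$ the $1/(2\sigma^2)$ scaling is dropped rather
than dividing by zero. Defaults $\sigma_{pixel} = 0.05$ (a visible but not
overwhelming 5% noise floor), $\sigma_{percept} = 1$.

**Perceptual loss.** The published framework uses a learned perceptual
extractor; this package substitutes a deterministic, weight-free proxy so
that nothing requires pretrained downloads: a 3-level Gaussian pyramid
(5×5 binomial blur, decimation by 2) with four orientation-selective 3×3
responses (0°, 45°, 90°, 135°) per level, each response normalized by its
root-mean-square plus $\epsilon = 10^{-2}$ (the epsilon keeps flat images
well-defined and bounds the normalization gradient). Convolutions use
replicate padding so constant images give exactly zero responses — zero
padding would fabricate edges at the border. All outputs are labelled
`perceptual_proxy`, never with the name of a learned metric; the extractor
is a plain function and can be swapped. The loss is the squared stack
distance between features of $M \odot G(\omega)$ and of the observation,
scaled by $1/(2\sigma_{percept}^2)$.

## MAP estimation

Adam on the latent code, learning rate 0.001 and 500 iterations by default
(the published optimization protocol); every gradient is an exact
reverse-mode adjoint (finite-difference agreement to ~1e-4 relative is a
test). Initialization is a seeded draw $\omega \sim N(\mu, \sigma^2)$, an
explicit matrix, or — for decoder generators — `init = "nearest"`:
retrieval initialization, starting from the training latents whose decoded
images best fit the observed region (top `restarts` candidates, default 3,
keeping the run with the lowest final loss). This is the encoder-free
analogue of encoder-initialized generator inversion and is what makes
inversion reliable when a large mask hides most of an image's
distinguishing structure. The reported solution is the best iterate seen
(Adam is not monotone per-iteration), so the final reported loss never
exceeds the initial one. Observed pixels are composited back over the
generator output by default: the observed region is data, not something to
re-synthesize, and compositing is what makes observed-region fidelity a
checkable invariant. Non-finite losses abort with the iteration index and
per-term values. Optimization is joint over all latent levels; the
framework's "alternating" phrasing is not elaborated anywhere, and a
block-coordinate variant showed no advantage at this scale, so joint
optimization is the only mode.

## Variational inference

A per-image diagonal Gaussian $q(\omega) = N(m, \mathrm{diag}(s^2))$ —
"Bayes-by-Backprop" applied to the latent code of one image rather than to
network weights, which is the modification the framework describes. A full
covariance would cost $(LD)^2$ parameters and is rejected. The objective is
the negative ELBO

$$KL(q \,\|\, N(\mu, \sigma^2)) + E_q[\text{data terms}],$$

the KL in closed form (the mean prior plays its role and is therefore
excluded from the data terms; cosine and intensity priors enter through the
expectation since they have no closed-form KL), the expectation estimated
with `mcSamples` reparameterized draws $\omega = m + s\,\varepsilon$.
Defaults: 500 iterations, Adam lr 0.01, one MC sample; `log s` initialized
at $\log(0.1\,\sigma)$ so early iterations stay near the MAP regime, and
the mean at the MAP solution when one is supplied (else the prior mean).
The returned parameters are the average of the last 25% of iterates
(`tailAverage`), which removes the stationary jitter of constant-step Adam;
on the conjugate affine-Gaussian model this recovers the analytic posterior
mean to well under 2% and per-coordinate variances to within the ~15%
irreducible gap between the diagonal family and the full-covariance
posterior. A Gamma-distributed variational factor mentioned alongside the
Gaussian parameters has no stated shape, rate or role; it is not
implemented. Posterior sampling decodes independent draws and composites
observed pixels, so samples differ only where data is missing.

## Synthetic data: what it emulates, what it does not

`generatePhantom` produces brain-like phantoms: nested, jittered, rotated
ellipses (outer shell vs. inner structures) with distinct intensities,
low-amplitude band-limited texture, light blur. `generateBandlimitedPhantom`
produces exactly band-limited images for the PG oracle.
`generateMask` implements the four benchmark families at their reference
coverages — chin-region blob 15%, centred square 25%, full-height vertical
rectangle 50%, bottom half 50% — plus free-form brush strokes; bottom/vrect
are exact up to integer rounding, the stochastic families hit their target
within ±0.03 (a bisection on blob radius, respectively stroke stamping with
a small brush). The geometries are representative: the benchmark masks are
described only in prose, so shapes here are fixed by the stated coverages,
not traced from any figure.

Phantoms are smooth, grayscale, single-object and 32×32; real MRI slices
have anatomy, bias fields, acquisition noise and far higher resolution, and
face/natural-image benchmarks have texture the phantoms lack entirely.
Passing tests therefore demonstrate the *machinery* — correct losses and
gradients, correct PG completion, correct posterior recovery where a closed
form exists, and that generative inversion beats structure-free baselines
on a family the generator has actually learned — not benchmark-level
reconstruction quality on real data.

## Problem sizes and numerical choices

The test and acceptance runs use: 32×32 phantoms, a 200-image training
corpus, 40 auto-decoder epochs (~34k parameters, mini-batch Adam, small
latent L2 so latents match the standard-normal prior), 4×16 latents, 400
MAP iterations at lr 0.02 for phantom inversion, 2000/3000 iterations for
the conjugate-model oracles, 300 VI iterations per diversity image, and
100 seeded draws per mask family — sizes chosen so the whole suite runs in
minutes on one CPU while every check retains a clear margin. The linear
oracle generator maps latents through a seeded affine map scaled so outputs
stay inside (0,1) for prior-scale latents; its clamp exists for contract
safety but is essentially never active, which is what makes the closed-form
normal-equations oracle exact. All randomness is scoped: every generator,
optimizer and sampler takes a seed, seeds the R RNG locally and restores
the caller's RNG state.

## Known limitations

* The perceptual proxy is not a learned metric; its numbers are not
  comparable to published LPIPS values.
* The auto-decoder is a stand-in: it learns the phantom family, not natural
  images, and its latent space is only as smooth as 200 examples make it.
* Diagonal variational posteriors understate correlated uncertainty
  (~15% on conjugate-model variances here; more for strongly coupled
  latents).
* PG completion assumes approximate band-limitation; on images with sharp
  edges it blurs, which is exactly why it serves as a baseline rather than
  the method.
* RGB images are handled channel-wise; no cross-channel prior is
  implemented.
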