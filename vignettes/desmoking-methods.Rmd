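---
title: "Unpaired surgical desmoking: model, priors and design choices"
author: "desmokr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unpaired surgical desmoking: model, priors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Electrocautery instruments fill the laparoscopic operating cavity with
smoke, degrading the surgeon's view.  Paired training data (the same frame
with and without smoke) cannot be captured in vivo, so desmoking is posed
as *unpaired* image-to-image translation between a clear domain $X$ and a
hazy domain $Y$.  Two generators are learned jointly: $G: X \to Y$
(clear to hazy) and $F: Y \to X$ (hazy to clear, the desmoker), each with
a PatchGAN discriminator on its output domain.

## The objective

The training objective combines four terms,

$$\mathcal{L} = \mathcal{L}_{GAN} + \lambda_{cyc}\,\mathcal{L}_{cyc}
  + \alpha\,\mathcal{L}_{IC} + \beta\,\mathcal{L}_{DC},$$

with the adversarial part in least-squares form (patch scores regressed to
1 for real, 0 for fake) and the cycle term the mean L1 error of both round
trips $x \to G(x) \to F(G(x))$ and $y \to F(y) \to G(F(y))$.  The two
additional terms are smoke-specific priors evaluated *only on generator
outputs*, so their gradients flow only into the generators:

* **Inter-channel discrepancy (IC).**  Dense grey smoke is nearly
  achromatic, so the per-pixel sum of absolute pairwise channel
  differences $\Psi(P) = |P_R-P_G| + |P_G-P_B| + |P_B-P_R|$ collapses
  towards zero under smoke.  The image-level mean $I^{IC} \in [0,2]$ is
  divided by 2 (the package's reading of "normalised in the calculation",
  keeping the term in the unit range of the cycle loss) and mapped through
  the boundary value 1: the hazy-to-clear direction is penalised by
  $|v-1|$ (residual smoke, i.e. small $v$, costs most), the clear-to-hazy
  direction by its complement $1-|v-1|$.
* **Dark channel (DC).**  The dark channel
  $I^{dark}(x) = \min_{y\in\Omega(x)}\min_c I^c(y)$ of haze-free tissue is
  near zero; haze (a convex shift towards bright atmospheric light) lifts
  it.  The loss is the trimmed mean of the dark channel of each generated
  image, summed over both directions.  Trimming (1% per tail by default)
  excludes specular highlights and near-black vignette pixels, which would
  otherwise bias the average.

Defaults are $\alpha = 3$, $\beta = 0.05$, $\lambda_{cyc} = 10$.  With
$\alpha = \beta = 0$ the objective reduces *exactly* to the plain
cycle-consistent adversarial baseline — this reduction is asserted in the
test suite against an independent recomputation of the baseline loss.

The objective as printed evaluates the dark channel of the generated
*hazy* image $G(x)$ too.  That term mildly discourages $G$ from producing
haze, which is at tension with $G$'s adversarial task; it is implemented
as stated, and `train_config(dc_on_fake_hazy = FALSE)` drops it for
ablation.

## Networks and training

The generators are ResNet-style encoder/decoders (7x7 stem, two stride-2
downsamplings, residual blocks at 4x width, two upsampling stages, tanh
output) with instance normalisation; the discriminators are PatchGANs
whose default 3-layer stack has a 70x70 receptive field and yields a
30x30 score grid on 256x256 inputs.  Upsampling uses nearest-neighbour
doubling followed by a 3x3 convolution rather than a transposed
convolution: same capacity, no checkerboard artifacts, simpler adjoint.
Weights are initialised from $N(0, 0.02)$; inputs are remapped from
$[0,1]$ to $[-1,1]$ at the network boundary, while every loss operates on
$[0,1]$ values (the IC mapping's boundary at 1 presumes that range).

Because no deep-learning framework is available to R, the convolutional
stack and its backward passes are implemented in the package itself, with
im2col/GEMM convolution kernels in compiled code.  All layer gradients
are verified against central finite differences in the test suite.

Training follows the published schedule: Adam (betas 0.5/0.999), learning
rate 0.002 held for 50 epochs then decayed linearly to zero over 50 more,
batch size 4, random 256x256 crops, and a 50-image history pool feeding
each discriminator with a mix of current and older generator outputs.
The published rate of 0.002 is ten times the usual choice for this
backbone; it is implemented as printed and is overridable
(`train_config(lr0 = ...)`).  One Adam instance optimises both
generators, another both discriminators.  Every randomness source
(initialisation, shuffling, crops, pools) derives from `cfg$seed`, making
the first training step bit-reproducible, which the suite asserts.

The IC/DC losses are computed on the training crops, not on full frames,
because that is where the objective is evaluated; the dark-channel window
inside the loss defaults to 7 (a 15-pixel window at 256-crop scale would
couple a third of the crop into a single minimum, washing out locality).
At inference `translate()` runs full-resolution without crops,
reflect-padding inputs to the network's stride (4) when needed.

## Soft matting refinement

The raw dark channel is blocky at the patch scale.  The package refines
it by solving $(L + \epsilon E)\,t = \epsilon\,t_{raw}$, where $L$ is the
matting Laplacian of the guide image over 3x3 windows
(covariance-regularised with $10^{-6}$) and $\epsilon = 10^{-4}$ weights
the data term.  The system is symmetric positive definite and solved by
Jacobi-preconditioned conjugate gradients to a relative residual of
$10^{-6}$; constant maps are in the Laplacian's null space and return
unchanged.  Refinement is used for reported/evaluated dark channels (the
fog proxy refines by default); inside training steps the unrefined dark
channel carries the gradient — refining every step would add a sparse
solve per generated image, and when `dc_refine = TRUE` is requested the
*reported* DC component is refined while the gradient still flows through
the unrefined subgradient path (each output pixel routes to its window's
minimising pixel and channel, trimmed pixels contributing nothing).

## The smoke simulator

The simulator exists so every module is testable without surgical
recordings.  Clear frames are procedural phantoms: multi-octave value
noise mapped into a tissue gamut (red dominant, blue suppressed — hence a
low dark channel), a dark vignette towards the corners and a few small
specular highlights, the two features that motivate trimming the DC
average.  Smoke is overlaid with the atmospheric scattering model
$I = J\,t + A\,(1-t)$, with near-white $A = (0.95, 0.95, 0.93)$ and
$t = \exp(-d\,n(x))$, where $n$ is unit-mean positive noise, so the mean
optical thickness equals the density $d$ by construction.  Grades map to
$d =$ 0.3 (light), 0.8 (medium), 1.8 (heavy), chosen once so the grades'
dark-channel distributions are well separated, and 1.2 with 40% areal
coverage for partial smoke; all parameters are recorded per image in the
dataset manifest rather than hard-coded downstream.  Clear and hazy
domains draw *different* phantom seeds, preserving the unpaired-training
assumption.

What the simulator does not emulate: instrument motion and motion blur,
specular interreflections, depth-dependent transmission, video display
borders, and the natural-image statistics real surgical footage carries.
Passing tests therefore demonstrate the machinery — losses with correct
gradients, training that removes simulated haze, metrics that order
degradation — not clinical performance on real hysterectomy video.

## Referenceless metrics

Paired ground truth does not exist for real surgical smoke, so evaluation
is referenceless:

* **JNBM** (sharpness, higher better): 64x64 blocks are classified as
  edge blocks when more than 0.2% of their pixels are (vertical Sobel)
  edge pixels; each edge's width along its row is compared with the
  contrast-dependent just-noticeable-blur width (5 pixels at low
  contrast, 3 above 50/255) and pooled by probability summation with
  exponent 3.6 within and across blocks; the score is the processed-block
  count over the pooled distortion.  Images with no edge blocks return 0
  with a warning instead of failing, so batch evaluation never aborts.
* **REA** (edge restoration, higher better): the relative count of newly
  visible edges, $(n_{restored} - n_{original})/n_{original}$, with a
  visible edge defined as a Sobel magnitude above 5% of the local (3x3)
  mean luminance, floored at 0.1 so near-black noise is not counted.
  This variant makes an identical reconstruction score exactly 0.
* **Fog proxy** (lower better): the trimmed mean of the refined dark
  channel.  Published fog-density evaluators are corpus-trained
  natural-scene-statistics models; shipping one is out of scope, so the
  package substitutes this documented proxy, which shares the ordering
  behaviour on graded smoke and is labelled `fog_proxy` in every output.
  It is **not** the published FADE score and its absolute values are not
  comparable to published tables.

Luminance uses Rec. 601 weights throughout.

## Numerical and degenerate-input choices

* Images are H x W x 3 arrays in $[0,1]$, channel order R, G, B; 8-bit
  files are divided by 255 on load, so a save/load round trip is exact to
  $1/255$ per channel.
* Aspect-preserving resize scales by the single covering factor
  (bilinear) and centre-crops symmetrically; non-4:3 sources therefore
  lose their margins rather than being letterboxed, mirroring how display
  borders are cropped from surgical video.
* The dark-channel min filter clamps its window at image borders; padding
  with any constant would fabricate border values.  Ties in the window
  minimum break to the first pixel in scan order, making the subgradient
  deterministic.
* `trimmed_mean` trims `floor(n * trim_frac)` values per tail by rank; if
  trimming would discard everything it errors rather than returning NaN.
* Non-finite losses abort the training step with a reference to the last
  saved checkpoint rather than propagating NaN into the weights.

## Scaled-down experiment sizes

The package's validation experiment simulates 80 images per domain at
64x64, trains 10 epochs (5 constant + 5 decay) with batch size 4, and
uses width-8 generators with 2 residual blocks and width-12, 2-layer
discriminators — small enough to train on a single CPU core in a few
minutes while leaving the method itself unchanged.  On the held-out hazy
test frames the smoke-aware model must lower the trimmed-mean dark
channel relative to the inputs on at least 8 of 10 frames and beat the
$\alpha=\beta=0$ baseline trained from the same seeds.  The full-size
defaults (width 64, 9 residual blocks, 256x256 crops, 100 epochs) remain
the package defaults for real use.

## Known limitations

* Training at the published scale (thousands of frames, 256x256, 100
  epochs, width-64 networks) is far outside what a single CPU core
  delivers in reasonable time; the package is CPU-only by construction.
* The fog proxy is a stand-in, not the published fog-density evaluator;
  only orderings, not absolute values, should be compared.
* `dc_refine = TRUE` during training refines the reported loss but not
  the gradient path (see above).
* Resuming from a checkpoint restores weights, epoch and schedule but
  not optimiser momenta.
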