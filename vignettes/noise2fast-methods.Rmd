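---
title: "Chequerboard self-supervised denoising: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chequerboard self-supervised denoising: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(noise2fast)
```

## The model

A noisy image is modelled as $x = s + n$ with $s$ the signal and $n$
zero-mean noise, independent across pixels. Nothing else is assumed about
$n$ — no distribution family, no variance estimate. The denoiser is a small
fully convolutional network $f_\theta$ trained **only on the image being
denoised**, so each run is a self-contained optimization, not an
application of a pre-trained model.

### Chequerboard downsampling

The pixel lattice is split into its two chequerboard colours: pixels with
$i + j$ even and those with $i + j$ odd (0-based indices). Compressing each
colour class horizontally (each row's surviving pixels close ranks
leftward) gives the "up" pair $x_{\mathrm{even}}, x_{\mathrm{odd}}$ of
shape $m \times n/2$; compressing vertically gives the "left" pair of
shape $m/2 \times n$. `downsample_up()` realizes the parity split as

$$x_{\mathrm{even}}(i,k) = x(i,\, 2k + (i \bmod 2)), \qquad
  x_{\mathrm{odd}}(i,k) = x(i,\, 2k + ((i+1) \bmod 2)),$$

which is the unique in-range assignment that sends the even-parity class
to one image and the odd-parity class to the other while preserving row
order; `downsample_left()` is its transpose analogue. The split is exactly
invertible (`reassemble_up()`/`reassemble_left()`), and the package treats
that inversion plus value-multiset conservation as tested invariants.

### Why training on the pairs denoises

$x_{\mathrm{even}}$ and $x_{\mathrm{odd}}$ sample interleaved pixels of
the same scene: corresponding pixels are horizontally adjacent in the
original. Writing the mapping target as
$s_{\mathrm{even}} + n_{\mathrm{odd}} + (s_{\mathrm{odd}} -
s_{\mathrm{even}})$, the pairing is a Noise2Noise objective up to the
signal-difference term $s_{\mathrm{odd}} - s_{\mathrm{even}}$, which is an
adjacent-pixel difference of the *clean* image — small wherever the scene
is locally smooth. Because the target's noise is independent of the input,
the network cannot learn it; the regression converges toward the clean
signal instead.

Two package facilities quantify this argument rather than assuming it:

* `exact_correction_targets()` subtracts the signal-difference term using
  known ground truth ("cheating"). The acceptance suite shows the final
  PSNR changes by well under 0.5 dB on the blobs phantom — the null result
  that justifies ignoring the term.
* The synthetic module's `chequer_texture` phantom is an engineered
  violation: its adjacent clean pixels differ by the full intensity range,
  so $\mathbb{E}|s_{\mathrm{odd}} - s_{\mathrm{even}}|$ is 10× the noise
  scale rather than ≪ 1× (the suite checks both directions). On such
  pixel-level textures the method's core assumption fails and results
  should not be trusted.

### The stopping rule

The four-image training set is so small that the network inevitably
overfits it, so the run needs a stopping signal. The downsampled images
are laterally distorted — a pixel's neighbours come from alternating
lattice shifts, so local structure differs fundamentally from the original
image — which makes the full-size noisy image act as held-out data.
Every `validation_interval` iterations the package measures the self-map
PSNR of $f_\theta(x)$ against $x$ (data range 1, normalized space) and
snapshots the weights whenever it improves; training stops after
`patience` validations without improvement or at `max_iterations`, and
the **best snapshot** (never the final iterate) produces the output.
With a clean reference supplied, the trace records ground-truth PSNR at
each validation too; the acceptance suite requires the two traces to be
positively correlated and the selected checkpoint to sit within 1 dB of
the run's true optimum — which is what makes self-validation trustworthy.

## Architecture and training parameters

| parameter | default | units | why |
|---|---|---|---|
| `block_widths` | 32, 64, 128, 256 | channels | the method's published architecture: two 3×3 ReLU convolutions per width, widths doubling |
| `kernel_size` | 3 | px | gives a 17-px receptive field over 8 body layers |
| `final_kernel_size` | 1 | px | 1×1 sigmoid head, single-channel output |
| `learning_rate` | 0.001 | — | the published Adam setting |
| `batch_size` | 1 | pairs | pairs are fed one by one |
| `validation_interval` | 100 | iterations | schedule choice: fine enough to catch the early peak |
| `patience` | 10 | validations | stops shortly after the peak without chasing noise in the trace |
| `max_iterations` | 30000 | iterations | hard cap; patience almost always fires first |

The receptive-field extent is $1 + (k-1) \cdot c \cdot B + (k_f - 1)$
($k$ kernel size, $c$ convolutions per block, $B$ blocks, $k_f$ final
kernel) — 17 for the defaults — and `forward_pass()` is tested to have
*empirical* locality exactly matching this analytic bound.

Choices the method's description leaves open, decided here:

* **Padding**: zero ("same") padding, so every layer preserves shape;
  training pairs and validation both need shape-preserving application.
* **Initialization**: fan-in-scaled uniform weights
  ($\pm\sqrt{6/\mathrm{fan~in}}$), zero biases, drawn from a private RNG
  stream under an explicit seed — reproducibility is a package contract
  (same seed ⇒ bit-identical fit).
* **Bias terms**: present in every convolution.
* **Pair order**: one of the four pairs drawn uniformly (seeded) per
  iteration; a `cyclic` mode exists for strict-rotation studies.
* **Adam moments**: conventional $(\beta_1, \beta_2, \epsilon) =
  (0.9, 0.999, 10^{-8})$.
* **No augmentation, no schedule, no weight decay**: the four-image set is
  taken literally.
* **Gradient form**: the sigmoid+BCE gradient is computed in its fused
  stable form $(p - t)/N$; the clamp ($\varepsilon = 10^{-7}$) affects
  only the reported loss value.

## Intensity handling

The sigmoid head and BCE loss require targets in $[0,1]$, so each plane is
min–max normalized before training and the output mapped back afterwards.
Min–max (rather than a fixed 0–255 division) deliberately supports
unclipped data: raw or background-subtracted microscopy values may be
negative or exceed the nominal range, and the package never clips on read,
during training, or on float output. The map is affine and
order-preserving, with exact round-trip tested to float tolerance.
A constant image cannot be normalized (and BCE would be degenerate); it is
returned unchanged with `stopped_reason = "degenerate_input"`.

Multi-frame and multi-channel images are denoised plane by plane
(frame-major, then channel), each with its own normalization and training
run — the network's output is always single-channel.

On disk, 8/16-bit unsigned TIFF/PNG and 32-bit float TIFF are supported.
Integer output is clipped to the type range and rounded half to even;
float output is written verbatim by the package's own minimal float-TIFF
writer (uncompressed, IEEE sample format), since none of the available R
image packages emit float TIFFs. PNG output is 8-bit.

## The synthetic generator: what it does and does not emulate

`make_phantom()` + `add_gaussian_noise()`/`add_poisson_noise()` provide the
study conditions for every pipeline-level test: the `blobs` phantom (12
Gaussian bumps, SD 4–10 px, amplitudes 24–63% of range over an 8%
background on a 0–255 scale) mimics fluorescent puncta; `ramp` and
`sinusoid` (one cycle per axis) are smooth analytic controls;
`chequer_texture` is the adversarial control described above. Gaussian
noise uses the benchmark convention ($\sigma = 25$ means 25/255 of an
8-bit range) and is never clipped; Poisson noise follows
$\mathrm{Poisson}(s \cdot \mathrm{gain})/\mathrm{gain}$ with optional
Gaussian on top (the mixed model typical of confocal detectors).

What passing on these phantoms shows: the training objective, stopping
rule and scale handling work as designed under signal-independent and
shot-noise conditions with locally smooth signal. What it does not show:
performance on natural-image texture, structured/correlated noise
(fixed-pattern, banding), saturation artifacts, or real microscope data —
no synthetic fixture reproduces those, and benchmark claims on public
datasets are out of scope here.

## Problem sizes and numerical choices

The pipeline-level tests and the reproduction script run a deliberately
desk-scale configuration: 96×96 phantoms, network widths (16, 32)
(receptive field 9), iteration cap 2000, three seeds. These sizes are the
package's chosen verification conditions — large enough for the 3 dB+
denoising gains and the validation-tracking behaviour to be unambiguous,
small enough that any single run takes well under two minutes on one CPU
core. The full-size default network (widths 32–256) is exercised directly
for its parameter count, determinism and receptive-field contract.

Other numerical details:

* Validation snapshots use strict improvement (`>`), so ties keep the
  earliest best checkpoint; `best_iteration` is the argmax of the
  validation trace.
* PSNR is capped at 100 dB so identical images produce finite traces.
* SSIM uses the conventional 11×11 Gaussian window ($\sigma = 1.5$,
  $K_1 = 0.01$, $K_2 = 0.03$), population covariances, and averages over
  fully supported windows only; it reproduces an independent reference
  implementation to nine decimals on fixed fixtures. SSIM is reported on
  the standard $[-1, 1]$ scale (some published tables print these values
  ×10).
* The "split" inference variant (apply the net to the two "up"
  downsamples and reassemble) exists as an ablation; it requires an even
  number of columns and is generally inferior to full-image inference,
  which exploits the network's translation to the undistorted lattice.
* The `block2`/`block3` training modes replace the chequerboard split with
  conventional 2×2 or 3×3 block downsampling (each sub-image paired with
  its cyclic neighbour in both directions) — faster per iteration, but
  without the lattice distortion that protects the validation signal, and
  provided for comparison rather than as the recommended mode.

## Known limitations

* Pixel-level textures and any scene violating local smoothness break the
  pairing assumption (see the `chequer_texture` control).
* Spatially correlated noise violates the independence assumption on which
  the Noise2Noise argument rests; gains will degrade.
* Each image trains its own network; throughput is bounded by optimization
  speed, not inference speed. `predict()` can reuse a trained network on
  further frames from the same acquisition as a fast approximation.
* The implementation is CPU-only, double precision, single-threaded by
  design apart from BLAS; determinism is guaranteed on a fixed machine
  and BLAS configuration.
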