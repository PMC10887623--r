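---
title: "Removing CT truncation artifacts by implicit feature disentanglement in polar coordinates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Removing CT truncation artifacts by implicit feature disentanglement in polar coordinates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When a CT scan's field of view (FOV) does not cover the whole patient
cross-section — because the detector is too narrow, or because only a
region of interest was deliberately scanned — the measured projections are
laterally truncated. Reconstructing truncated projections with filtered
backprojection (FBP) produces the *truncation* or *cupping* artifact: a
radially increasing brightness bias culminating in a bright rim at the FOV
edge. The underlying inverse problem (the "interior problem") is ill-posed,
so the artifact cannot be removed exactly without prior knowledge.
Supervised networks remove it well but need paired artifact/clean images,
which clinical practice rarely provides. This package implements an
*unpaired* approach: a cycle-consistent adversarial model whose single
shared encoder is steered, by loss design alone, to make artifact features
and anatomy features separable in one latent space — an *implicit*
disentanglement, as opposed to architectures with dedicated per-factor
encoders.

## Simulation pipeline

Since real paired data are out of reach, `detrunc` manufactures its own
study conditions end to end:

* **Phantoms** (`make_ellipse_phantom`): one outer body ellipse of positive
  attenuation plus a configurable number of uniform interior ellipses,
  optionally blurred with a 0.5 px Gaussian. Piecewise-constant objects are
  deliberate: they match the assumption under which the total-variation
  comparator is strongest, so the comparison does not stack the deck
  against it. Every phantom is a pure function of an integer seed.
* **Fan-beam projection** (`forward_project`): equiangular source positions
  over a full circle (default 720 views), equidistant flat detector,
  ray-marched line integrals with bilinear sampling at half-pixel steps.
  The default geometry (`default_fan_geometry`) places the source at twice
  the image diagonal and sizes the detector to cover the object with a 10%
  margin — the paper-free choices a generic diagnostic fan would use.
* **Truncation** (`truncate_sinogram`): the stated truncation proportion is
  read as the *total* fraction of detector channels removed, split
  symmetrically; the removed channels are deleted rather than zero-filled
  so that no downstream consumer can silently treat them as measurements.
* **FBP** (`fbp_reconstruct`): cosine pre-weighting, Ram-Lak ramp filtering
  on the virtual detector through the isocenter (FFT-based), and
  distance-weighted backprojection with linear interpolation, onto a grid
  covering exactly the retained FOV disk.

`build_unpaired_dataset` assembles the two training domains from *disjoint*
phantom seeds — artifact images are truncated-data FBPs, clean images are
full-data FBPs of different phantoms restricted to the same FOV — and keeps
ground-truth pairing only in the test split, where the reference is the
phantom resampled onto the reconstruction grid.

## Polar transformation

Cupping is quasi-circular: its level sets are rings around the image
center. Resampling the image to polar coordinates `(rho, phi)` about the
center (`to_polar`) turns those rings into straight lines: the artifact
becomes a *horizontally* varying, vertically almost-constant band, which a
convolutional network can capture with small local filters. Rows index
angle, columns index radius, so "horizontal" always means radial. The
sampled radius stops at the inscribed circle: truncated-FOV images are
disk-supported and the corners carry no signal. Default grid: 360 angles
and `size/2` radii (both divisible by 8 so three stride-2 stages fit);
bilinear interpolation both ways, with wrap-around in angle.

## The model

One encoder `E` maps a polar image to latent features; two mirrored
decoders read them: `G` extracts only content (its output is the
artifact-removed image), `Gt` decodes everything (content plus artifact).
For an artifact image `I` and a clean image `J` (both polar, normalized),
one training pass computes

* `l_I = E(I)`, `I_hat = G(l_I)` — artifact removal;
* `t_I = l_I - E(I_hat)` — the *artifact code*: what the encoding of the
  artifact image carries beyond the encoding of its cleaned version. This
  short-connection subtraction is exact, not learned;
* `Gt(l_I)` and `G(E(J))` — self-reconstructions;
* `J_hat = Gt(t_I + E(J))` — a synthetic artifact image: the artifact code
  of `I` pasted onto the content of `J`;
* `G(E(J_hat))` — the cycle: removing the synthetic artifact should give
  back `J`, which provides paired supervision the raw data never had.

Two 70x70-patch discriminators close the loop: one judges cleaned images
against the real clean domain, the other judges synthetic artifact images
against the real artifact domain.

Architecture: encoder and decoders have five convolutional layers each,
exactly three of which resample (stride-2 convolutions, mirrored by their
transposed counterparts); channel widths are `base_channels * (1, 2, 4, 4,
4)`; instance normalization everywhere except output layers; ReLU in the
encoder, LeakyReLU(0.2) elsewhere; tanh output. Along the angular axis all
padding is *circular* — the polar topology has no seam, and the test suite
checks that encoding commutes with angular rolls — and reflective along
the radius. Weights start from seeded normal(0, 0.02).

## Objectives

With weights `adv = 1`, `rec = 5`, `art = 5`, `cycle = 10`, `tv = 100`:

* **Adversarial** — least-squares GAN by default. The source formulation
  prints a `1 - log D` expression that is not a proper loss as written; we
  read it as the conventional adversarial objective and provide both the
  LSGAN form (default, the de-facto stabilizer for cycle-consistent
  translation) and the logistic cross-entropy form (`adv_form = "bce"`).
* **Self-reconstruction** — mean L1 of `Gt(E(I))` vs `I` and `G(E(J))` vs
  `J`: nothing may be lost on the full pathway, and clean images must pass
  the content pathway unchanged.
* **Artifact consistency** — mean L1 between the artifact *removed* from
  `I` and the artifact *added* to `J`; this ties the synthesized artifact
  to the one actually separated, so discriminator pressure on `J_hat`
  propagates back into the separation.
* **Cycle** — mean L1 of `G(E(J_hat))` vs `J`.
* **Horizontal TV** — on the removed-artifact image `u = I - I_hat`, the
  mean squared forward difference along the radius. The continuous form is
  an integral of the squared radial derivative, so the discretization uses
  squared (not absolute) differences, normalized by the number of
  differences; normalization keeps the weight 100 meaningful across
  resolutions. All L1 terms are likewise means, not sums, for the same
  reason.

Training alternates one discriminator step and one generator step per
iteration (Adam, learning rate 1e-4, moments 0.5/0.999 — the GAN
convention; the source states only the learning rate), with independent
unpaired draws from the two domains. Backpropagation through the full
graph — the shared encoder appears four times, `G` three times — is
implemented analytically and validated against finite differences in the
test suite; transposed convolutions are the exact adjoints of the strided
convolutions (including the padding adjoint), which makes every gradient
identity hold by construction.

## Inference

`remove_artifacts` runs `G(E(.))` in polar space. By default it maps the
*artifact estimate* `I - I_hat` — a radially smooth field — back to
Cartesian coordinates and subtracts it from the original image
("residual" mode). The alternative of resampling the network output
itself ("direct" mode) passes the full-resolution anatomy through the
polar round trip, whose tangential resolution at a practical angular
sampling measurably blurs fine content; the artifact field, being smooth,
survives the same trip essentially unharmed. Both modes are exposed;
residual is the default because it preserves input detail exactly wherever
the estimated artifact is zero. Pixels outside the inscribed FOV disk are
always passed through unchanged.

## Ablation variants

`ablation_variant` reproduces the component build-up used to justify each
ingredient: Var1 adversarial only; Var2 +reconstruction; Var3 +artifact
consistency; Var4 +cycle; Var5 moves training to polar coordinates; Var6
(+TV) is the full method. Var1-Var4 train on Cartesian rasters with
reflective padding on both axes.

## Classical comparators

* **Extrapolation**: each truncated view profile is extended by mirroring
  the boundary region with a raised-cosine taper to zero (the innermost
  extrapolated channel exactly equals the boundary channel, so the
  completed profile is continuous), then reconstructed by plain FBP and
  cropped to the retained FOV. The genre is standard but no specific
  published variant is being reproduced; retained channels are never
  modified.
* **TV reconstruction**: SART-style simultaneous algebraic updates over
  the retained rays alternate with gradient descent on a smoothed
  isotropic TV penalty, from a zero start, on an *extended* grid covering
  the full object support (the measured rays traverse tissue outside the
  FOV; solving only inside the FOV would make the data inconsistent). The
  TV step length follows the common adaptive rule: a fixed fraction
  (default 0.2) of the SART update norm. Divergence (data residual growing
  tenfold from its minimum) aborts with an error.

## Evaluation

`psnr` uses the peak of the reference over the RMS error; the printed
source formula carries an `NM` factor which is algebraically consistent
with the standard definition only as `sqrt(M*N)`, and that reading is
implemented. `ssim` follows the printed global-statistics form, with
`k1 = k2 = 0.03` (the source's stated constants — note the conventional
choice elsewhere is `k1 = 0.01`) and `L` the maximum of the reference; a
windowed variant (11x11 Gaussian, sigma 1.5) is available for
cross-checking. Metrics are computed on physical-value images, restricted
to the inscribed FOV disk. `radial_bias_profile` quantifies cupping
directly as per-annulus mean residuals.

## Problem sizes used by the tests and the acceptance script

The package's own study conditions are desk-scale: 64-pixel phantoms, 240
projection views for dataset builds, 50% truncation for the end-to-end
experiment (the stronger of the two studied ratios, chosen because at this
image size it produces an unambiguous artifact), `base_channels = 16`,
batch size 1, 600 training iterations, 200 images per unpaired training
domain and 20 held-out test pairs. The success criteria are directional —
the trained network must beat its truncated-FBP input in median held-out
SSIM, and the full objective must beat the adversarial-only variant — not
reproductions of any published score, which would require clinical data
and GPU-scale training.

## What the synthetic data does and does not emulate

The generator reproduces the *mechanism* of the artifact exactly (real
fan-beam projection, real truncation, real FBP), so the cupping in these
images is physically genuine, not painted on. It does not emulate
anatomical texture, noise correlations, beam hardening, scatter, or
detector physics; phantoms are piecewise-constant ellipse assemblies.
Passing tests therefore demonstrate that the method separates and removes
reconstruction-induced cupping under unpaired training — they say nothing
about recovering fine anatomical detail in clinical images.

## Known limitations

* Global SSIM on strongly cupped images is dominated by the luminance and
  contrast of the bright rim; small-sample medians over 20 test images are
  stochastic, and individual images can regress while the median improves.
* The CPU implementation is practical at toy scale only; the architecture
  is the full design, but widths and iteration counts are far below what
  the published experiments used.
* Edge detail inside a ~2-pixel band at the FOV rim is neither trained nor
  evaluated; the rim region is where the interior problem is least
  determined.
* With only artifact-affected data available (no clean domain at all) the
  method does not apply.
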