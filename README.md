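# detrunc

Unsupervised removal of CT truncation (cupping) artifacts by implicit
feature disentanglement in polar coordinates — with the full simulation,
baseline and evaluation stack needed to exercise it on synthetic phantoms,
no external data required.

## The problem

When fan-beam projections are laterally truncated — a narrow detector, or a
deliberate region-of-interest scan — filtered backprojection (FBP)
produces the *cupping* artifact: a radially increasing brightness bias
ending in a bright rim at the field-of-view (FOV) edge, which distorts CT
values and degrades diagnosis. The interior problem behind it is
ill-posed; supervised networks fix it well but need paired
artifact-free/artifact-affected images that clinical practice cannot
provide. `detrunc` implements an unpaired alternative for researchers in
CT image correction.

## The method

Two unpaired image domains are given: artifact images `I ∈ D_t` and clean
images `J ∈ D`. Images are first resampled to polar coordinates `(ρ, φ)`
about the image centre, which turns the quasi-circular cupping into
line-shaped bands that small convolutional filters capture easily. A
single shared encoder `E` and two decoders then operate in one latent
space:

    ℓ_I = E(I),   Î = G(ℓ_I)              (artifact removal: content only)
    t_I = ℓ_I − E(Î)                      (artifact code, by subtraction)
    Ĵ  = G_t(t_I + E(J))                  (synthetic artifact image)
    L   = λ_adv(L_advD + L_advDt) + λ_rec L_rec + λ_art L_art
          + λ_cyc L_cyc + λ_tv L_tv

with two PatchGAN discriminators (one per domain), self-reconstruction and
artifact-consistency L1 terms, a cycle term `‖G(E(Ĵ)) − J‖₁` that turns
the synthetic pairs into supervision, and a *horizontal* (radial)
total-variation penalty on the removed artifact `I − Î`. Default weights:
`λ_adv = 1, λ_rec = λ_art = 5, λ_cyc = 10, λ_tv = 100`; Adam with learning
rate 1e-4. The disentanglement is *implicit*: content and artifact share
one latent space and are separated by the losses, not by dedicated
encoders. The convolutional stack (including exact-adjoint transposed
convolutions and circular padding along the angle) and its
backpropagation are implemented in this package directly.

The package also provides the fan-beam simulator that manufactures the
artifact (projection, symmetric sinogram truncation, ramp-filtered FBP),
seeded ellipse phantoms and unpaired dataset builds, the two classical
comparators (sinogram extrapolation and SART+TV iterative reconstruction),
and PSNR / SSIM / radial-bias evaluation.

## Worked example

```r
library(detrunc)

ph   <- make_ellipse_phantom(phantom_spec(seed = 7, size = 96, n_inclusions = 4))
geom <- default_fan_geometry(96, n_views = 360)
pair <- simulate_truncated_pair(ph, geom, ratio = 0.5, out_size = 96)

mk <- inscribed_mask(96)
sprintf("truncated FBP vs ground truth:  SSIM %.4f   PSNR %.2f dB",
        ssim(pair$reference, pair$artifact, mask = mk),
        psnr(pair$reference, pair$artifact, mask = mk))
radial_bias_profile(pair$artifact, pair$reference, n_bins = 5)

sino_t <- truncate_sinogram(forward_project(ph, geom), 0.5)
ex     <- extrapolate_and_reconstruct(sino_t, 96, value_range = ph$value_range)
sprintf("extrapolation baseline:         SSIM %.4f   PSNR %.2f dB",
        ssim(pair$reference, ex, mask = mk),
        psnr(pair$reference, ex, mask = mk))
```

prints

```
truncated FBP vs ground truth:  SSIM 0.2767   PSNR 9.60 dB
radial bias (centre -> FOV edge): +0.037  +0.041  +0.051  +0.077  +0.216
extrapolation baseline:         SSIM 0.7693   PSNR 17.02 dB
```

The radial bias profile is the cupping artifact itself: the mean
reconstruction error grows from +0.04 at the centre to +0.22 at the FOV
edge (the phantom body is 0.3), and classical sinogram extrapolation
already removes much of it. Training the network takes a few minutes at
toy scale:

```r
man <- build_unpaired_dataset(200, 20, phantom_spec(size = 64, n_inclusions = 4),
                              default_fan_geometry(64, n_views = 240),
                              ratio = 0.5, out_dir = "data", seed = 41)
cfg <- train_config(iterations = 600, batch_size = 1, seed = 17,
                    net = net_config(base_channels = 16),
                    n_phi = 64, n_rho = 32)
run <- train(man, cfg)
corrected <- remove_artifacts(artifact_image, run$checkpoint)
```

On the held-out pairs of that dataset the median SSIM inside the FOV rises
from 0.48 (truncated-FBP input) to 0.55 and the median PSNR from 10.6 dB
to 19.6 dB. A command-line front end mirrors the R API
(`exec/detrunc simulate|project|recon|polar|train|infer|baseline|evaluate`),
and `run_pipeline()` chains the stages with full config/seed provenance.
The methods vignette (`vignettes/polar-disentanglement.Rmd`) documents the
model, every default, and the design decisions.

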