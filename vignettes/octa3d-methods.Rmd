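---
title: "Depth-by-depth adversarial enhancement of volumetric OCTA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-by-depth adversarial enhancement of volumetric OCTA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Optical coherence tomography angiography (OCTA) reconstructs blood flow from
the dynamic signal between repeated scans. The resulting volumes are degraded
by speckle — granular multiplicative noise inherent to coherent imaging — and
by background noise that masquerades as flow. Sectioned C-scan slices (en
face planes at a single depth) are especially noisy; vessels appear broken
and deep vasculature is barely visible.

`octa3d` implements a volumetric enhancement strategy built on three ideas:

1. **Labels by registration and averaging.** Repeated acquisitions of the
   same tissue are projected to en face images, registered to a common
   reference, cropped to the jointly valid region, and averaged. Averaging
   n aligned images divides background noise variance by n while the vessel
   signal is preserved, so the average serves as a high-quality label.
2. **Inputs by synthesis.** High-quality *C-scan* labels cannot be acquired,
   so degraded inputs are synthesized instead: a single-shot en face image
   E is superimposed on an avascular C-scan noise image C as
   `S = norm(alpha * E + beta * C)` (min–max normalized), with
   `alpha = 0.25, beta = 0.75` as the operating point. Because S has the
   noise character of a single C-scan but the vascular content of E, a
   network trained on (S, label) pairs transfers to real C-scans.
3. **Depth-by-depth application.** The trained 2D generator is applied to
   every C-scan slice independently and the slices are restacked. The model
   learns lateral vascular topology — the plane where vessels mainly run —
   while depth structure is preserved exactly because slice z of the output
   depends only on slice z of the input.

## The adversarial model

The generator is U-shaped: `n_levels` encoder blocks, each a 4×4 convolution
with stride 2 and padding 1 followed by normalization and leaky ReLU
(slope 0.2), mirrored by transposed-convolution blocks with ReLU, skip
connections between mirror levels, and a tanh head. For a 256×256 input the
default `n_levels = 8` reaches a 1×1 bottleneck. Channels start at
`base_channels` and double per level up to a cap. The discriminator is one
conv + leaky ReLU, five normalized conv blocks of the same geometry, and a
final 4×4/stride-2/pad-0 convolution with a sigmoid, reducing 256×256 to a
single probability.

Losses, with images in `[0, 1]` and the tanh mapping `x -> 2x - 1` confined
to the model boundary:

* content: `mean(|label - G(input)|)` (L1),
* adversarial: `E[log(1 - D(G(input)))]`, minimized, probabilities clamped
  to `[1e-7, 1 - 1e-7]`,
* generator total: `G_loss = lambda * content + adversarial` with
  `lambda = 1e3`,
* discriminator: binary cross-entropy
  `-E[log D(label)] - E[log(1 - D(G(input)))]`.

Training alternates one discriminator and one generator Adam step
(`lr = 1e-3`, betas 0.5/0.999) per sample at batch size 1, re-augmenting
every pair each epoch, 120 epochs at full scale.

Two points were genuinely open and are decided as follows:

* **The discriminator is unconditional** — it sees only the label image or
  the generated image, exactly as the loss terms above are written, although
  image-translation GANs often condition the discriminator on the input.
  The implementation follows the written losses.
* **Normalization at batch size 1.** Batch normalization at batch 1
  degenerates to per-channel spatial (instance) statistics; the package
  implements exactly that, accumulates running statistics during training,
  and freezes them for inference, making enhancement deterministic for
  fixed weights. Blocks whose output plane is 1×1 skip normalization
  (the statistics are undefined there).
* Weight initialization is N(0, 0.02); Adam betas and the leaky-ReLU slope
  follow adversarial-training convention. All are configurable.

Every backward pass is hand-derived (the convolutions are lowered to matrix
products by `im2col`) and pinned against central-difference numerical
gradients in the test suite.

## The synthetic phantom

No public OCTA volumes accompany the method, so the package ships a phantom
that emulates the statistical structure the method assumes, and every claim
in the test suite is made against it:

* **Vessels**: biased 3D random-walk centerlines with Bernoulli
  bifurcation, dilated by a ball of the branch radius. A `lateral_bias`
  (default 0.9) damps the axial component of the walk, reproducing the
  predominantly lateral orientation of cutaneous vasculature. Voxel
  intensity decays as `exp(-attenuation_coeff * depth)`.
* **Noise**: unit-mean gamma multiplicative speckle (`speckle_shape`,
  default 3) plus exponential additive background (`background_level`,
  default 0.12), clipped to `[0, 1]`. Both fields are drawn on depth knots
  every `axial_corr = 8` voxels and linearly interpolated between, because
  speckle grains are elongated axially by the imaging point-spread
  function. This matters: were the noise independent per depth voxel, a
  maximum projection over dozens of slices would drive the en face
  background toward the noise distribution's upper tail, and the averaged
  labels would no longer be cleaner (closer to the vessel truth) than the
  inputs — contradicting the premise of the label workflow. With the
  default correlation, phantom single-shot en face images score CNR ≈ 1.9
  and VC ≈ 0.78, and 10-repeat averages score CNR ≈ 4.6 and VC ≈ 1.0, the
  qualitative ordering the method relies on.
* **Motion**: rigid in-plane drift (translation up to ±4 px, rotation up
  to ±2°) applied identically to all depths of a repeat; real tissue also
  deforms non-rigidly, which the phantom does not model.
* **Avascular C-scans**: pure background noise slices, the noise source of
  the input synthesis.

What the phantom does *not* emulate: physically accurate OCT speckle
statistics (the gamma/exponential choice is a surrogate; the papers in this
area do not characterize their noise law quantitatively), interframe
decorrelation of the flow extraction, shadowing artifacts, or non-rigid
tissue distortion. Passing tests therefore demonstrate correctness of the
algorithms and the direction and rough magnitude of their gains, not
clinical performance.

## Registration details

The registration follows the scale-invariant-feature recipe: multi-scale
difference-of-Gaussian blob keypoints with subpixel quadratic refinement,
normalized 11×11 patch descriptors, Lowe ratio-test matching (0.75), a
RANSAC similarity model (2 px reprojection threshold, scale constrained to
[0.8, 1.25] since drift is rigid), and complex-form least squares on the
inliers. Descriptors are not rotation-normalized because acquisition drift
is within a few degrees. Warping uses bilinear interpolation with
out-of-frame pixels marked invalid — never zero-filled — so averaging is
never diluted by padding; the common crop is the largest axis-aligned
rectangle of jointly valid pixels, found by greedy border trimming. Images
with fewer than 8 ratio-test matches or 6 RANSAC inliers raise an error
naming the offending image, which is also the detection path for
feature-free (pure noise) inputs. On phantom repeats the median recovery
error is ≈ 0.07 px and ≈ 0.1°.

One ambiguity in the label workflow — whether each repeat is renormalized
before averaging — is resolved by averaging raw `[0, 1]` images with no
per-image renormalization, so the average's intensity scale remains
comparable to a single shot.

## Metrics

All four metrics operate on the en face image, its global-Otsu
binarization (the "global adaptive threshold"; vessels/background
histograms are bimodal) and its Zhang–Suen skeleton:

* CNR `= (mu_s - mu_b) / sqrt(sigma_s^2 + sigma_b^2)` with **population**
  standard deviations; white pixels are the signal region, black the
  background.
* VD: white-pixel fraction of the binarized image.
* VDI: binarized vessel area / skeleton length (average caliber).
* VC: fraction of skeleton pixels in 8-connected components of ≥ 5 pixels
  ("five continuous pixels" is read as component size, not path length).

Zhang–Suen thinning shortens bar endpoints slightly (a 10×3 bar thins to a
7-pixel centerline here; other thinning algorithms give 8–10), so fixture
pixel counts in the tests are pinned to this implementation and marked
algorithm-dependent. Per-B-scan CNR binarizes each cross-section
independently and takes a stated avascular superficial depth band as
background, excluding (with a warning) any thresholded signal pixels inside
the band. Note that Otsu-splitting a pure-noise frame still yields a
positive CNR of order 2 — thresholding always separates a brighter group —
so avascular frames are flagged by being far below vascular frames, not by
CNR ≈ 0.

## Numerical choices and degenerate inputs

* Min–max normalization maps a constant weighted sum to the zero image
  (all-black inputs are a sanctioned training class, not an error).
* Constant images cannot be Otsu-thresholded and raise an error, as do
  empty skeletons in VDI/VC and overlapping or empty CNR regions.
* Augmentation rotates only by multiples of 90° (no interpolation) and
  crops a fraction in `[0.75, 1]` before resizing back; input and label
  receive the identical transform.
* Slices that do not meet the generator's `2^n_levels` divisibility are
  reflect-padded (not zero-padded, so border vessels are not attenuated at
  the seam) and cropped back exactly.
* All randomness flows from explicit integer seeds; every generator-side
  operation restores the caller's RNG state.

## Scaled study conditions

Tests and the acceptance script run the full pipeline at desk scale, chosen
once as: 64×64 slices and `n_levels = 6`, phantom volumes of 32×64×64, 50
vascular training pairs plus the method's 20 noise-only and 20 black pairs,
30 epochs, batch 1, Adam `lr = 1e-3`, `lambda = 1e3`, `base_channels = 12`.
The noise-only/black counts are kept at their full-scale values because
they are the mechanism that teaches background suppression; halving them
proportionally would change the method, not just its size. Under these
conditions training reduces the content loss by roughly half, enhancement
of held-out synthetic inputs roughly doubles their CNR (≈ 1.9 → ≈ 3),
raises VC from ≈ 0.78 to ≈ 0.95, and reduces the L1 distance to the
noise-free vessel truth; `scripts/acceptance.R` recomputes these numbers
from scratch on any seed.

## Known limitations

* The networks run on CPU in plain R (BLAS-backed im2col convolutions);
  full-scale 256×256/120-epoch training is possible but slow — the package
  is sized for methodological study, not production training throughput.
* The discriminator is unconditional by design (see above); a conditional
  variant is a one-line architectural change but is deliberately not the
  default.
* Registration assumes rigid drift; elastic tissue distortion is out of
  scope.
* Metric absolute values depend on the phantom's noise surrogate and on
  the thinning algorithm; comparisons between processing arms of the same
  data are the meaningful quantity.
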