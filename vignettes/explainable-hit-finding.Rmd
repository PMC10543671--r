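---
title: "Explainable CNN hit finding for serial crystallography: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explainable CNN hit finding for serial crystallography: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Serial femtosecond crystallography (SFX) experiments fire micro-crystals
through an X-ray free-electron laser beam and record one diffraction snapshot
per pulse. Only a small fraction of frames — often well under 1% — actually
contain crystal diffraction (Bragg peaks); everything else is detector noise
or amorphous scattering. Hit finding, the act of keeping the useful frames
and vetoing the rest, is therefore the first and most consequential data
reduction step. Convolutional neural networks classify such frames very
accurately, but on their own they are black boxes: they report *that* a frame
is a hit, not *why*.

`sfxsight` re-creates, as a tested and reusable pipeline, a study of exactly
this question. It (i) simulates labelled diffraction-like frames with known
Bragg-peak ground truth, (ii) trains compact CNN classifiers on them,
(iii) explains the classifiers' decisions with gradient-weighted class
activation mapping (Grad-CAM), guided backpropagation and their combination,
(iv) inverts layer representations to see what each layer retains of the
input, and (v) runs a classical radial-threshold spot finder as the baseline
the field would otherwise use. Because the synthetic ground truth is exact,
the usual qualitative claims ("the network looks at the Bragg peaks") become
quantitative, testable statements.

## The synthetic data generator

Frames follow the five-class structure used by synthetic diffraction
benchmarks: `Blank` (detector noise only), `NoCrystal` (amorphous rings, no
crystal), and `Weak`, `Good`, `Strong` (rings plus Bragg peaks of increasing
count and amplitude). Hit/miss labels merge the first two classes into `miss`
and the rest into `hit`.

Each frame is the clipped sum of three terms:

* **Peaks** — isotropic 2-D Gaussians (width `peak_sigma`, default 1.2 px)
  at uniformly sampled pixel-centre positions with a hard-core minimum
  separation of `min_sep_factor * peak_sigma` (default 4, making planted
  peak counts unambiguous local maxima; a scene that cannot be placed in
  1000 draws is rejected as overcrowded).
* **Rings** — Gaussian annuli at radii 10/18/26 px (scaled with the frame)
  of width 3 px, amplitude 1: the azimuthally symmetric scattering of
  amorphous carrier liquid.
* **Noise** — additive Gaussian read noise (`noise_sigma`, default 0.3),
  optionally preceded by Poisson resampling of the photon signal.

The default per-class parameters (64 x 64 frames) are:

| class | peaks | amplitude | rings |
|---|---|---|---|
| Blank | 0 | — | no |
| NoCrystal | 0 | — | yes |
| Weak | 2–6 | 2–4 | yes |
| Good | 8–14 | 5–8 | yes |
| Strong | 16–26 | 9–14 | yes |

The amplitude floors (2 < 5 < 9) are strictly ordered, which is the
defining property of the three hit classes. No published generative
parameters exist for the reference synthetic benchmark beyond its
qualitative class descriptions, so these values are this package's own
choice of a realistic, analytically checkable scene; they are stated here
once and used unchanged everywhere (tests, analysis scripts, acceptance
run). Below 64 px the peak-count ranges scale with frame area, since a
smaller crop resolves proportionally fewer peaks; above 64 px they are held
fixed, because the number of Bragg reflections is a property of the crystal,
not of the detector.

What the generator deliberately does **not** emulate: diffraction geometry
(Ewald-sphere curvature, polarization), detector panel gaps, structured
pedestal noise, saturated pixels, and the long intensity tails of real
Bragg peaks. Passing tests on these frames therefore demonstrate the
*mechanics* of the pipeline (the explanations really do concentrate on the
planted peaks; the spot finder really does count them), not performance on
any real detector. Coordinates are 1-based `(row, col)` with the frame
centre at `((H+1)/2, (W+1)/2)`, the natural convention in R.

## Classifiers and training

Two architecture families are provided, both size-parameterized:

* **AlexNet-style** — exactly five convolutional blocks followed by three
  fully connected layers, ReLU after every hidden layer, max-pooling after
  selected blocks. The desk preset uses 64 x 64 single-channel inputs with
  16/32/48/48/32 filters and 128/64/k fully connected widths (~128k
  parameters); a full-scale preset with the canonical 96/256/384/384/256 +
  4096/4096/k sizes exists as a configuration choice.
* **Residual** — stages of two-convolution residual blocks with stride-2
  projection shortcuts between stages, global average pooling, and a linear
  head. Tests use a small two-stage variant; depth is configurable.

The desk presets omit dropout and local-response/batch normalization so that
every oracle in the test suite is exactly reproducible; this is a noted
departure from the canonical architectures. Grayscale frames are replicated
to whatever channel count a spec demands. Preprocessing is per-frame
standardization (subtract mean, divide by SD + 1e-8), which makes the
synthetic intensity scale irrelevant to the network.

Training minimizes softmax cross-entropy on the raw scores with Adam and a
per-epoch exponentially decaying learning rate `lr(t) = lr0 * d^t`. The desk
preset runs 15 epochs at batch 32 with `lr0 = 1e-3`, `d = 0.95` on 500
training frames per class; the full-scale preset keeps the 50-epoch /
batch-128 / `1e-5` recipe. The desk learning rate is deliberately larger
than the full-scale one: at 64 px with ~10^5 parameters, `1e-5` barely moves
the loss in 15 epochs, and `1e-3` converges stably (the separable-toy test
drives training accuracy to 100%). Prediction is the argmax of the raw
scores with ties broken toward the lowest class index. The whole engine
(im2col convolution in C++, hand-derived backward passes) is part of the
package and is itself under test: analytic gradients agree with central
finite differences to better than 1e-4 relative error away from ReLU and
max-pool kinks, where no derivative exists.

## Evaluation metrics

Confusion matrices use rows = true class, columns = predicted. Accuracy is
`100 * trace / total`; recall and precision are one-vs-rest per class
(`TP/(TP+FN)` row-wise, `TP/(TP+FP)` column-wise). No macro averaging is
reported. Percentages in report tables are rounded half-up to one decimal;
raw fractions stay available. Classes with no true (recall) or predicted
(precision) instances yield flagged `NA`, never silent NaN. A bundled
published confusion matrix of an AlexNet classifier on the DiffraNet test
set serves as the worked example; two of its printed precision cells (Blank,
Strong) disagree with its own counts by one unit in the last decimal, and
the package reports the values computed from the counts.

## Grad-CAM, guided backpropagation, guided Grad-CAM

For a frame, a class `c` and a convolutional layer with post-ReLU feature
maps `A^k`:

1. compute `dy_c / dA^k` for the raw (pre-softmax) class score `y_c`;
2. average-pool those gradients spatially into neuron importance weights
   `alpha_k = (1/Z) sum_ij dy_c / dA^k_ij`;
3. form `L = ReLU(sum_k alpha_k A^k)` — only positively contributing
   regions survive;
4. upsample `L` bilinearly (corner-aligned) to the input size;
5. min-max normalize to [0, 1] for display and blend with the input.

One wording in the source study calls `y_c` "the raw output of the last
convolutional layer"; the canonical definition, used here, is the
pre-softmax *classifier* score, and the divergence is recorded. The
normalization and upsampling choices are likewise declared here because the
study leaves them open. An identically zero map stays zero rather than being
rescaled. The default explanation layer is the last convolutional layer
(AlexNet style) or the last residual stage, matching common practice for
deep residual networks; the default class is the predicted one.

Guided backpropagation modifies every ReLU's backward rule to pass gradient
only where the forward pre-activation *and* the incoming gradient are
positive, giving sharp signed pixel-space saliency; guided Grad-CAM is the
elementwise product of the upsampled heat map with those gradients. The
construction follows the method's original definition, since the source
study names but does not define it.

Because the generator provides exact peak coordinates, the package scores
localization quantitatively: `localization_score = sum(heat[mask]) /
sum(heat)` over a peak mask dilated by 3 px. A heat map with no preference
for peaks scores exactly the mask's area fraction, so "the network focuses
on Bragg peaks" becomes the inequality `mean score > mean area fraction`,
which the study-level test checks over >= 50 hit frames, alongside the
companion trend that total (unnormalized) heat grows from Blank to Strong
frames.

## Representation inversion

To see what a layer retains, the package reconstructs an image from the
layer's representation `Phi_0` of an original frame `x_0` by minimizing

```
||Phi(sigma * x) - Phi_0||^2 / ||Phi_0||^2
  + lambda_alpha * sum_i |x_i - mean(x)|^alpha
  + lambda_tv * sum_ij (dx_h^2 + dx_v^2)^(beta/2)
```

from a seeded random-noise start. The first term is the normalized Euclidean
representation distance; the alpha-norm prior (alpha = 6, `lambda_alpha =
1e-5` by default) keeps the pixel spread narrow; the total-variation prior
(beta = 1, `lambda_tv = 1e-3`) favours piecewise-smooth images. `sigma` is
the average Euclidean norm of the (preprocessed) training images, so the
optimization variable stays O(1) while the network sees natural-range
inputs. The alpha exponent and the normalization of the distance follow the
inversion method this construction descends from, since the study itself
fixes only `beta = 1`.

Numerical choices: forward differences with zero boundary for TV; a
`beta = 1` TV gradient stabilized with `eps = 1e-8` inside the square root
(the objective value itself is exact); gradient descent with momentum 0.9
and step halving every `ceil(iterations/3)` as the default optimizer, Adam
as the configurable alternative (and the better choice through deep
networks); best-iterate bookkeeping so the returned reconstruction attains
the smallest recorded total loss. Box clipping of the iterate is available
(`clip_mult`) but **off by default**: diffraction frames are sparse, their
peak pixels legitimately sit far outside 1.5 standard deviations of the
pixel distribution, and clipping there would bias exactly the structures
under study. Degenerate configurations fail loudly: a non-finite objective
aborts and names the diverging component.

Two closed-form anchors pin the implementation down: with the identity
"network" and zero priors the minimizer is `x_0` itself (recovered to
`rep_distance < 1e-3` and max deviation < 5% of range), and the priors match
hand-evaluated values on constant and 2 x 2 inputs. The study-level trend —
conv1 reconstructions correlate with the input more strongly than conv5
reconstructions — is asserted over 10 frames with shared seeds.

## The spot-finder baseline

The classical alternative to a CNN scores each pixel against a radially
dependent threshold `median(r) + snr_min * scale(r)` computed in equal-width
annuli (2 px by default) around the beam centre. Candidates are grouped into
connected components (8-connectivity by default, 4 available); components
with more than `n_min` but fewer than `n_max` pixels — strict inequalities,
following the algorithm's usual wording — count as peaks; a frame with at
least `n_peaks` peaks is a hit. Peaks carry intensity-weighted centroids,
integrated background-subtracted intensity and an SNR estimate.

The robust scale is the upper-quartile estimator `(q75 - median)/0.6745`
rather than the MAD: annuli whose intensities are clipped at zero are
zero-inflated, which collapses the MAD to zero and floods dark regions with
false candidates, while the upper quartile is untouched by the zero mass and
still ignores bright peak outliers. The background is estimated per frame
(frames are independent here), with no iterative re-estimation — full
Peakfinder8 fidelity is out of scope. On noise-free frames with fully
isolated planted peaks (hard-core separation 12 peak widths) the recovered
count equals the planted count on every frame of a 50-frame batch; on the
default noisy study frames the finder essentially never calls a miss a hit
but does discard a minority of weak hits — the qualitative signature
expected of threshold-based spot finding.

## Problem sizes and reproducibility

The bundled study runs at desk scale by design: 64 x 64 frames, 500
training + 100 test frames per class, 15 training epochs (10 for the binary
problem), 60–250 inversion iterations. These sizes make the full pipeline —
simulation through inversion — reproducible in minutes on one CPU core while
leaving every scientific claim testable; 512 x 512 frames and full-scale
architectures remain configuration choices, not tested paths. Determinism
is end-to-end: every stochastic stage draws its seed from the global seed by
fixed offsets, and identical configurations reproduce identical metrics on a
fixed BLAS.

## Known limitations

* Synthetic frames are far easier than real detector data; accuracy numbers
  here quantify the pipeline, not expected performance on experimental
  frames with weak peaks, panel artefacts, or jet streaks.
* The CNN engine is plain R + C++ matrix code: correct and adequate at desk
  scale, but not a GPU framework; full-scale presets exist and are slow.
* Max-pool gradient ties route to the first maximum; guided backpropagation
  on architectures without ReLU would degenerate to plain backpropagation.
* The spot finder estimates its background per frame and therefore needs a
  frame to be mostly background, which holds for SFX data.
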