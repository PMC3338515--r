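---
title: "Inferring chemoattractant fields from cell tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring chemoattractant fields from cell tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemofield)
```

## The problem

Directed cell migration is driven by chemical gradients that are, for most
systems of interest, invisible: the net chemoattractant landscape acting on a
neutrophil in living tissue is a superposition of signals that cannot all be
imaged at once. What *can* be observed is the cells' response. `chemofield`
treats the cells as distributed sensors and inverts their motion: from
time-lapse centroid tracks it reconstructs the scalar field whose gradient
best explains the observed velocities.

The pipeline has four stages, each usable on its own:

1. **simulate** — an agent-based generator of ground-truth fields, tracks and
   rendered image stacks (for validation);
2. **track** — segmentation of fluorescent cells and keyhole linking into
   centroid tracks;
3. **kinematics** — Kalman-filter/RTS-smoother estimation of positions and
   velocities from the noisy centroids;
4. **field** — Bayesian inference of the field on a multiscale
   squared-exponential basis.

## Model and assumptions

### Velocity–gradient proportionality

The Keller–Segel view of chemotaxis motivates the working assumption

$$\mathbf v(t) = \chi \, \nabla f(\mathbf s(t)),$$

with $\chi$ an unknown positive constant. This is deliberately the simplest
relation consistent with gradient-directed motion: no receptor saturation, no
velocity cap, no memory. Consequences worth keeping in mind:

* the inferred field is identified only up to a positive affine
  transformation ($\chi$ and an additive constant are absorbed into the
  parameters), so all outputs are in arbitrary units and comparisons must be
  made after normalisation (`normalize_field()`);
* where the true velocity–gradient relation saturates, the inferred field
  will flatten relative to the true one — the reconstruction is of the field
  *as sensed and acted on by the cells*.

### From tracks to a linear model

Integrating $\nabla f$ along one track step and assuming the velocity is
approximately constant over a sampling interval gives a field *difference*
per consecutive sample pair $(k, k+1)$:

$$f(\mathbf s_{k+1}) - f(\mathbf s_k) \;\approx\;
  \tfrac{1}{\chi}\,\hat{\mathbf v}_k \cdot (\mathbf s_{k+1} - \mathbf s_k).$$

Expanding $f$ on basis functions
$\phi_i(\mathbf s) = \exp\!\big(-\lVert \mathbf s - \mathbf c_i \rVert^2 /
(2\sigma_i^2)\big)$ turns each step into one row of a linear system: response
$\hat{\mathbf v}_k \cdot \Delta\mathbf s_k$, design row
$\phi_i(\mathbf s_{k+1}) - \phi_i(\mathbf s_k)$. Two details are design
choices rather than forced:

* **Response orientation.** With the proportionality model the response can
  be written either as $\hat{\mathbf v}_k\cdot\Delta\mathbf s_k$ or as
  $\hat{\mathbf v}_k\cdot\hat{\mathbf v}_k\,\Delta t$; the two coincide when
  the velocity really is constant over the step. We use
  $\hat{\mathbf v}\cdot\Delta\mathbf s$, which stays meaningful when the
  smoothed displacement and velocity disagree slightly.
* **Steps across tracker gaps.** Rows are built from consecutive *retained*
  samples whatever the frame gap: both the response and the design are
  displacement-based, so a longer step is still a valid (if noisier) field
  difference. Steps touching a velocity sample flagged as an outlier are
  skipped instead.

The same parameters $\theta_i$ describe the step differences *and* the field
itself, so estimating them from the step equations immediately yields the
field everywhere — that dual use is what makes the scheme work.

### Bayesian ridge posterior

The parameters get a zero-mean Gaussian prior with variance
$\sigma_\theta^2$; the response noise is i.i.d. Gaussian with variance
$\sigma_e^2$. The posterior is Gaussian with

$$\Sigma = \big(X^\top X/\sigma_e^2 + I/\sigma_\theta^2\big)^{-1},
  \qquad \hat\theta = \Sigma X^\top y / \sigma_e^2,$$

solved by Cholesky factorisation of the regularised normal matrix (the
unregularised $X^\top X$ may be numerically singular — fine-scale functions
far from any track contribute near-zero columns, and the prior is what keeps
the solve well-posed). Only the ratio $\sigma_\theta^2/\sigma_e^2$ affects
the posterior mean. The predictive surface and its pointwise variance come
from `predict_field()`; regions outside a user mask are marked invalid.

Non-identifiability of scale is exact in this formulation: the posterior mean
is linear in the responses, so scaling every velocity by $c>0$ scales the
mean field pointwise by $c$ and leaves the unit-range-normalised field
unchanged to machine precision (this is asserted in the test suite).

### Multiscale basis

`multiscale_basis()` places four coarse functions at the domain corners plus
a regular fine grid centred in the domain. Reference configurations:

| configuration | fine grid | spacing | fine width | total functions |
|---|---|---|---|---|
| in-vitro-style chamber | 3 × 3 | 320 px | = spacing | 13 |
| whole-larva field of view | 6 × 6 | 100 px | spacing / 2 | 40 |

The exponent convention is $1/(2\sigma^2)$ throughout, and all width rules
are interpreted in it. The coarse width defaults to half the larger domain
dimension: the coarse scale exists to carry the domain-wide trend, and a
corner function must still respond appreciably at the domain centre
($\phi \approx 0.6$ at one width). Both choices are exposed as arguments.

### Velocity estimation

Each track is smoothed with the Taylor-series state-space model: per axis the
state holds position and its first $n-1$ derivatives, the transition matrix
is the upper-triangular Taylor matrix $F_{ij} = \Delta t^{(j-i)}/(j-i)!$, and
the state noise is the integrated-white-noise covariance
$Q_{ij} = q\,\Delta t^{\,2n+1-i-j} / \big((n-i)!\,(n-j)!\,(2n+1-i-j)\big)$,
i.e. white noise of power $q$ driving the highest derivative. A standard
Kalman filter plus RTS backward pass yields smoothed positions, velocities
and covariances; frame gaps are handled exactly by propagating $F$ and $Q$
over the elapsed interval without an update. The smoother is verified in the
tests against an independent batch MAP solve of the same joint Gaussian model
(agreement to ~1e-13).

## Parameters, defaults and units

| parameter | default | unit | role |
|---|---|---|---|
| `dt` / `sample_interval` | 1.5 | min | frame interval (90 s acquisition) |
| `n_derivatives` | 3 | — | position, velocity, acceleration per axis |
| `q` | 0.5 | px² min⁻⁵ | state-noise power; smaller = smoother velocities |
| `r` | 1 | px² | centroid measurement noise variance |
| `init_state_cov_scale` | 100 | — | diffuse initial state uncertainty |
| `min_length` | 5 | samples | shortest track used for velocities |
| `outlier_speed` | 20 | px/min (µm/min with pixel size) | velocity-magnitude exclusion |
| `prior_var` ($\sigma_\theta^2$) | 100 | a.u.² | parameter prior variance |
| `noise_var` ($\sigma_e^2$) | 1 | a.u.² | response noise variance |
| `wedge_angle` / `circle_angle` | 60 / 300 | deg | keyhole acceptance regions |
| `wedge_length_factor` | 3 | × predicted displacement | wedge reach |
| `circle_radius` | 20 | px | fallback acceptance radius |
| `chi` | 1 | px² min⁻¹ per a.u. | simulator proportionality constant |

`q` deserves a note. It is a tuning parameter expressing how erratic the
motion is believed to be, and the right value is dataset-dependent. The
default 0.5 is conservative (mild smoothing, minimal distortion of genuinely
erratic paths). A calibration grid on simulated wound-recruitment data
(q × prior/noise ratio, several seeds) showed downstream field recovery is
insensitive to `q` over 0.02–0.5, so the conservative value is kept. For
validation data generated with *no* velocity diffusion — deterministic drift
plus centroid noise — the matched model is a much stronger prior, and the
velocity-recovery analysis in the acceptance suite accordingly uses
`q = 0.002`; there the smoothed velocities reach roughly 4–5× lower RMSE than
central differencing of the raw centroids, whereas `q = 0.5` attenuates
frame-to-frame jitter only mildly (ratio ≈ 0.76). Per-dataset tuning of this
kind — inspecting the data and setting the smoothing strength — is the normal
use of the method.

Velocities are reported in px/min unless a `pixel_size` (µm/px) is given, in
which case they are converted to µm/min; positions always stay in pixels.

## The synthetic generator: what it does and does not emulate

`simulate_tracks()` runs the *assumed* generative model forward: forward
Euler at `dt_integrate` (0.1 min default; the scheme matches the
proportionality model, which specifies no higher-order dynamics), velocity =
`chi * grad f` plus Gaussian velocity noise each integration step, sampling
every 1.5 min with Gaussian centroid noise, and truncation of a track when
the cell leaves the masked domain (mirroring real tracks that end at the
image edge). `render_frames()` draws cells as Gaussian-profile blobs with
additive background noise. Closed-form fields are differentiated
analytically; gridded fields by central differences with bilinear
interpolation.

Emulated features of real data: static spatial gradient, per-frame centroid
noise, finite track lengths, cells entering/leaving, image rendering for
tracker testing. **Not** emulated: time-evolving fields, attractant
production/diffusion/decay, receptor saturation and adaptation, cell–cell
interactions, shape changes, uneven illumination, z-drift. Passing the
synthetic validations therefore demonstrates correctness of the inference
machinery *under the model's own assumptions* — it does not by itself
establish that a particular biological dataset satisfies those assumptions.

Study conditions used throughout the tests and the acceptance script (chosen
once, as realistic for a wound-recruitment field of view on the reduced
500 × 500 modelling grid): 50 cells × 40 frames at 90 s, centroid noise 1 px,
velocity noise 0.5 px/min, χ = 1; wound field = Gaussian peak of amplitude
400 a.u. and width 80 px at (350, 250); linear-gradient analogue on a
640 × 640 domain with slope 2 a.u./px. At these sizes the full suite runs in
well under a minute.

## Numerical choices and degenerate inputs

* Posterior solve: Cholesky of the regularised normal matrix; never an
  explicit inverse of the unregularised system. Zero regression rows return
  the prior.
* Kalman update: Joseph-form covariance update and symmetrisation each step;
  a singular innovation (r = 0 with degenerate geometry) is reported as a
  numerical error rather than propagated.
* Hysteresis thresholds: Otsu on the intensity data (high) and on
  `log(x + 1)` (low; the `+1` avoids `log(0)`), with the low threshold capped
  at the high one. A constant frame yields zero detections, not an error.
* Keyhole ties: wedge beats circle; within a class, nearest candidate wins,
  with deterministic tie-breaks — linking is invariant to detection order.
* `unit_range` normalisation of a constant field is a degenerate-input error;
  `fixed_range` only clips the *displayed* values.
* Odd image dimensions are edge-replicated before 2 × 2 pyramid averaging
  (reported via a message).
* TIFF output: samples must lie in [0, 1], so field TIFFs are written
  unit-range normalised; exact values go to CSV and the value range to the
  run manifest.

## Known limitations

* **Scale and offset are not identifiable.** Only normalised fields are
  comparable; the colourbars say "arbitrary units" for a reason.
* **Field recovery quality is seed-dependent at moderate data sizes.** With
  50 noisy tracks the correlation between inferred and true wound fields
  ranges roughly 0.87–0.94 across simulation seeds; the peak location is far
  more stable (always within ~60 px ≈ half a fine spacing). The binding
  constraint is the information content of the tracks, not the basis (which
  can represent the true field to r ≈ 0.99) nor the hyperparameters.
  Counter-intuitively, *noise-free* trajectories are worse: deterministic
  paths run radially up the gradient, constraining the field only along
  flow lines, whereas motility noise makes cells explore transverse
  directions.
* **Static fields only.** Tracks from different times are pooled; a field
  evolving during acquisition is blurred into a time-average.
* **2-D only.** Z-stacks are collapsed by max/mean projection before
  tracking; genuinely three-dimensional migration violates the model.
* **Tracking is designed for sparse, well-separated bright cells.** Dense
  fields of touching cells will under-segment (hysteresis merges bridged
  objects deliberately), and the keyhole linker does not model division or
  long occlusions (only single-frame junctions are repaired).
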