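---
title: "Correspondence-free stereopsis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correspondence-free stereopsis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mantisstereo)
```

Stereoscopic vision is usually framed as a correspondence problem: decide
which left- and right-eye image locations view the same physical point, then
read depth off the resulting disparity map. This package implements and tests
two mechanisms at the opposite extreme, inspired by praying-mantis behaviour,
which produce useful depth-guided behaviour without ever estimating
disparity: a two-layer linear network whose winner-take-all readout turns the
head towards the stereoscopically nearer of competing targets, and a single
binocular neuron with centre/surround receptive fields that triggers
predatory strikes only for near, binocular, suitably sized objects. This
vignette records the models, their assumptions, the tunable parameters, and
the design and numerical choices made where the description of the system
leaves them open.

## Viewing geometry

All geometry lives in a right-handed world frame with `Z` pointing out in
front of the animal, `Y` up, and positive azimuth rotating the gaze towards
`+X` — the left-eye side. Head pose is a position (the midpoint of the two
eyes), a Fick azimuth-longitude/elevation-latitude pair (elevation applied
first, then azimuth — `fick_rotation()`), and the interocular distance `I`
(1 cm throughout the simulations). The eyes are fixed on the head, displaced
`±I/2` along the head's `X` axis (`+` for the left eye), and share the head's
rotation matrix, so a world point projects to per-eye azimuth and elevation
by the same Fick extraction applied about the eye's nodal point
(`project_to_retina()`). Two derived quantities summarize a binocular view:
the cyclopean azimuth `(α_R + α_L)/2` and the disparity `δ = α_R − α_L`,
positive inside the binocular overlap and larger for nearer points.
Refixation postmultiplies the head's rotation matrix by the Fick matrix of
the target's head-centred direction, leaving position unchanged; afterwards
the target lies on the gaze vector.

Numerical choices: angles are stored in degrees and converted to radians only
inside trigonometric calls; azimuths use the two-argument arctangent, and
elevations are restricted to `[-90°, 90°]` by the latitude convention. A
point coinciding with a projection centre raises an error rather than
returning `NaN`. Rotation outputs are orthonormal to well below `1e-10`,
which the test suite asserts directly.

## Scenes, retinas, and labels

A retina is a lat-long grid of visual directions; the full-scale grid is
51 × 51 units spanning ±70° (2.8° spacing). Scenes are collections of
spheres, each given by headcentric azimuth, elevation, distance, and
diameter. The angular subtense convention is the exact silhouette angle of a
sphere, `subtense = 2·asin(radius/distance)`; a sphere at 8 cm subtending 15°
has diameter 2.1 cm. Training scenes hold four spheres with azimuths and
elevations drawn independently from a normal with mean 0° and s.d. 45°,
distances uniform on 1–11 cm, and diameters scaled so each sphere subtends
10° at the origin, which removes angular size as a distance cue.

Rendering is deliberately minimal: a grid unit takes value 1 exactly when its
direction lies within a sphere's angular radius as seen from that eye's nodal
point, and 0 otherwise. There is no anti-aliasing (sub-unit accuracy is
meaningless at 2.8° spacing), no occlusion handling (spheres are unioned),
and no photometric structure — the input images stand for the output of an
upstream monocular target detector, not for luminance. High-elevation spheres
smear across azimuth columns exactly as land masses smear in a Mercator map;
this is a property of the lat-long chart, not an artefact.

Each scene's label is the output-grid unit nearest (Euclidean, in the
azimuth–elevation chart) to the headcentric direction of the nearest sphere
whose centre projects within the ±70° extent of at least one eye; if no
sphere is visible the label is the unit encoding (0°, 0°), i.e. "hold still".
A sphere whose centre is out of view may still contribute pixels; it just
cannot be the label.

The noise model for behavioural experiments is additive i.i.d. Gaussian with
s.d. 0.1 (of the unit target amplitude), clipped at zero, independent per
eye. The underlying behavioural data only show that inputs were noisy, not
the noise law; clipped Gaussian is the simplest non-negative choice, the
sigma is a configuration knob, and none of the package's behavioural claims
are sensitive to its exact value.

## The saccade network

The network is strictly two layers: both retinas, flattened and concatenated
(5202 inputs at full scale), feeding every unit of an output layer laid out
on the same 51 × 51 ± 70° grid of headcentric directions. Output units are
purely linear (weights and a bias). Training minimizes softmax cross-entropy
of the labelled unit with mini-batch stochastic gradient descent: momentum
0.9, constant learning rate 0.05, batch 128, shuffling every epoch. The
softmax exists only in the loss; at run time the decision is the argmax of
the affine outputs, with ties broken to the lowest flattened index
(elevation fastest, then azimuth) so decisions are reproducible. Weights are
initialized with small uniform values scaled by the inverse square root of
the fan-in — small enough that the initial loss equals the uniform-softmax
value `log(n_classes)` to within 1%.

Three presets are provided. The `full` preset (51 × 51 grids, 100 000
scenes, 8 epochs) is the reference configuration; it takes hours on one
CPU. The `desk` preset keeps the full 51 × 51 grid geometry but trains on
20 000 scenes for 8 epochs (about eight minutes); it is the configuration
at which behavioural results are reported. The grid geometry is kept at
full scale deliberately: reported saccade directions can only be as fine as
the output grid, and a 25 × 25 grid (5.8° spacing) has no unit near −15°,
so mean-direction comparisons at the ±2° level are meaningless there no
matter how well the model is trained. The `scaled_down` preset (25 × 25
grids, 20 000 scenes, 4 epochs, about a minute) exists for fast unit-test
fixtures; its qualitative behaviour — held-out accuracy orders of magnitude
above the no-skill rate, binocular fusion, near preference, the
disparity-shaped weight structure — matches the larger configurations, but
individual runs vary more: with only ~600 gradient updates, roughly one
training seed in ten converges to a solution that prefers the farther of
two near targets, a failure mode the `desk` preset's ~1250 updates
eliminated across every seed tried. The momentum coefficient (unstated in
the original description beyond "SGD with momentum") uses the conventional
0.9; the learning-rate schedule is constant since only an initial rate is
given.

What training produces, and the tests check: each off-centre output unit
develops net-positive summed weights from left-eye inputs at azimuths below
its encoded azimuth and from right-eye inputs above it — the signature of
near-disparity tuning, since a near object has `α_L < α_H < α_R`. A single
near target whose monocular images straddle its cyclopean direction drives
the unit near the cyclopean direction hardest (behavioural fusion), and with
two equal-subtense targets at mirrored azimuths the winner is almost always
on the nearer side once distances differ by tens of percent. Two caveats
were found while validating at desk scale. First, the no-action unit's bias
is reliably the largest and grows steadily with training (about 1.6× the
next largest after the scaled-down schedule, 4.5× after eight epochs on
100 000 scenes), but a full order-of-magnitude dominance is a property of
much longer training than the desk-scale presets perform; the corresponding
acceptance check documents this honestly rather than weakening the bar.
Second, when both targets are very near (roughly within 3 cm, or two equal
targets at matched distances), the network can be captured by ghost
pairings: the left eye's image of one target and the right eye's image of
the other form a spurious large-disparity "object" between them, which
near-preferring weights reward — two equal targets at 8 cm can make the
(0°, 0°) unit win outright. This is precisely the four-sensor ambiguity the
toy lattice module formalizes, surfacing in the linear network; a
winner-take-all readout has no mechanism to reject it. The near-preference
contract is therefore tested in the mid-range regime (distances of 4 cm and
beyond), where the behaviour is reliable.

## The strike sensor

The strike model is one binocular unit. Each eye feeds it through a fixed
pipeline: isotropic Gaussian spatial low-pass (default s.d. 1°, on the order
of acute-zone interommatidial angles), a first-order temporal high-pass
(`y_t = a(y_{t-1} + x_t − x_{t-1})`, `a = τ/(τ+Δt)`, default τ = 200 ms,
frame interval 10 ms), and full-wave rectification — so only change drives
the sensor, regardless of contrast sign. The monocular drive is the inner
product of the processed frame with a binary centre/surround window:
excitatory within 5° of the RF centre, inhibitory in the annulus to 10°,
weighted so the window sums to zero (a full-field stimulus produces no
drive). The RF centres sit nasally at ±atan(I/2 · 1/2.5) ≈ ±11.3° so the two
lines of sight cross 2.5 cm ahead of the head. Binocular combination is a
thresholded sum raised to the fifth power:
`activity = max(l + r − θ, 0)^5`. Threshold-then-power (rather than
power-then-threshold) is chosen because it makes monocular silence exact:
the threshold is calibrated at construction to 1.2× the peak monocular drive
of the preferred stimulus, so any stimulus confined to one eye stays below
threshold. The strike gain is likewise calibrated so the preferred stimulus
peaks at a 5% per-frame strike probability; strikes are then Bernoulli draws
per frame with probability `min(gain·activity, 1)`.

These defaults were chosen by a systematic search over the open parameters
(blur scale, time constant, surround radius and weight, threshold factor)
against the qualitative behaviours the sensor must show, and then frozen:
size tuning of the time-averaged activity for a sweeping disc is unimodal
and peaks at the 10° centre diameter; activity at the preferred distance
exceeds activity at half and double the distance many-fold; a ghost pair —
two distant spheres placed on the two monocular lines of sight of a virtual
near object, each duplicating that eye's near-object image locally — drives
the sensor orders of magnitude less than the matched single near object,
because each distant sphere's second image lands in one eye's inhibitory
surround; and monocular stimulation is exactly silent.

One documented limitation: the vertical-disparity cutoff. The sensor does
stop responding once a dichoptic vertical offset exceeds a few degrees, and
the cutoff is on the scale of the receptive field rather than of the
stimulus. But the *strict* form of the invariance — the offset at which
activity falls below 50% of its zero-offset value changing by less than 10%
when the disc diameter doubles — does not hold in this model family, for
two structural reasons verified across the full parameter search. First, the
fifth-power output maps a 13% drop in drive to a 50% drop in activity, so
the measured cutoff sits at the *onset* of the drive's decline, which scales
with `centre radius − stimulus radius` and therefore with stimulus size.
Second, for discs at or above the centre size the temporally filtered image
is an edge arc whose vertical extent grows with diameter, extending the
tolerance roughly in proportion to size. The fitted temporal dynamics that
produce diameter-independence in the original strike model belong to its
separately published parameterization, which this package deliberately does
not reproduce; the corresponding acceptance check is left failing with this
explanation rather than being weakened.

## Toy correspondence demonstrations

Two executable miniatures make the correspondence taxonomy concrete. On a
discrete ensemble of monocular inner products `{1, 2, 3}`, all equally
probable, a linear binocular unit (`l + r`) averages 4 over matched pairs
and 4 over unordered non-matching pairs — no correspondence; an energy unit
(`(l + r)²`) averages 56/3 versus 50/3 — weak correspondence, and the test
suite checks the matched mean dominates for *any* ensemble (a Jensen-type
inequality); a thresholded linear unit (responses below 4 zeroed) averages
10/3 versus 3 — a threshold alone induces the same effect. Non-matching
means use unordered pairs, and matched pairs are weighted uniformly; both
conventions are fixed by the worked arithmetic the implementation must
reproduce. The lattice demonstration pairs every left location with every
right location: one object activates one sensor, two distinguishable objects
two, two indistinguishable objects four — the canonical double-vision
ambiguity. The recurrent smoothing/uniqueness stage that would resolve the
ambiguity is represented only by its expected outcome in the demonstrations,
not as implemented dynamics, since no update equations are specified for it.

## Reproducibility and problem sizes

Every stochastic entry point takes a seed, and every result table carries its
configuration. The test suite and the acceptance script use the desk network
preset (full grid geometry, 20 000 scenes, 8 epochs, ~8 minutes of training)
for the behavioural headline, the scaled-down preset for fast module
fixtures, 1000-repeat behavioural runs, a 41 × 41 ± 35° strike stimulus
grid, and sweep ladders of a handful of points per axis; these sizes were
chosen so the full suite runs in minutes on a single CPU while leaving every
qualitative conclusion unchanged at finer settings. What passing tests show is that the *models*
behave as described on the synthetic scenes they define — bright discs on
dark backgrounds, no occlusion, no clutter, a fixed noise law. They do not
show that real mantis vision is captured beyond those behaviours, and the
package makes no claim about real neural circuitry.
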