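---
title: "Quantifying intracellular motion in gliding diatoms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intracellular motion in gliding diatoms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glidekymo)
```

## The measurement problem

Raphid diatoms glide over surfaces along their long axis at up to a few
micrometres per second, driven by an actomyosin system associated with the
raphe, the slit in the silica cell wall through which adhesive mucilage is
secreted. To ask how intracellular myosin motion relates to whole-cell
motion, two things must be measured simultaneously from dual-channel TIRF
time-lapse movies:

1. the **cell's own kinematics** — centre, long-axis orientation, speed —
   obtained by tracking the two chloroplasts visible in the
   autofluorescence channel, and
2. the **motion of GFP-labelled spots relative to the cell**, obtained by
   registering the GFP channel into the co-moving cell frame and reading
   trace slopes off kymographs.

`glidekymo` implements this pipeline end to end, together with a
population-scale motility assay at low magnification and the closed-form
drag estimates used in the force-balance argument. Because the raw movies
behind the original measurements are not available at desk scale, the
package ships a first-class synthetic-movie generator with exact ground
truth; every stage is validated against it.

## Cell tracking from chloroplast landmarks

The two chloroplasts are bright, stable blobs of roughly 4.5–6.0 µm
diameter, one in each half of the cell. Detection uses a fixed-scale,
scale-normalised Laplacian-of-Gaussian response matched to a single
user-chosen spot diameter (default 5.6 µm, constrained to 4–8 µm), keeps
the two strongest non-overlapping maxima per frame, and refines each
centre by an iterated intensity-weighted centroid inside the bounding
circle. The centroid window is Gaussian-apodised (σ = radius/2): a
hard-edged discrete disc whose boundary still carries substantial blob
intensity would bias the sub-pixel estimate by up to a few tenths of a
pixel, while the apodised window converges to the true centre. On
noise-free synthetic movies the centre error is below 0.25 px and the
axis-angle error below 1°.

Frames with fewer than two accepted detections become *gaps*, not
errors. Linking assigns each frame's detections to the two tracks by the
cheaper of the two possible pairings and raises an error (naming the
frame) if the pairing is ambiguous within tolerance — identity swaps are
treated as data corruption, not as something to silently survive. Gap
runs up to `max_gap` (default 5) frames are closed by linear
interpolation and flagged; longer runs are an error.

Pose per frame: the centre is the coordinate midpoint of the two
landmark centres, and the axis angle is the angle of their connecting
vector. Angles are reported counter-clockwise positive in the
mathematical (y-up) sense although image rows increase downward, and are
wrapped to (−90°, 90°] since a cell axis has no preferred end. The
*leading* label goes to the track whose mean projection onto the cell's
net displacement is larger; for an essentially stationary cell
(net displacement < 1 px) the rightmost track is labelled leading as a
deterministic fallback.

Instantaneous speed divides the frame-to-frame centre displacement by
the frame interval (100 ms at the default 10 fps); the final value is
repeated so the trace has one entry per frame. Smoothing is a centred
moving average of nominally 20 samples with symmetric shrinking windows
at the ends, the behaviour of the classic MATLAB `smooth` function —
which also means an even window acts as the next smaller odd window
(20 → 19). One subtlety worth recording: symmetric shrinking end-windows
do *not* conserve the mean of an arbitrary trace (a unit impulse at the
first sample, window 5, has smoothed sum 23/15). Conservation holds
exactly whenever the trace is constant within two half-windows of each
end, and that is the property the test suite asserts.

## Registration into the cell frame

A reference frame is chosen to mimic the manual convention of picking a
frame where the cell lies horizontal near the image centre: the valid
frame minimising `|angle|/90 + dist(centre, FOV centre)/(diagonal/2)`,
earliest frame on ties. Every other frame is then translated so its cell
centre lands on the reference centre and rotated about that centre by
the pose-angle difference; the order (translate, then rotate about the
reference centre) is fixed and verified by the motion-cancellation
invariant — re-tracking a registered synthetic movie leaves the cell
centre constant to < 0.5 px. Resampling is bilinear with zero fill; the
canvas keeps the input size, so content rotated or translated out of
view is lost, matching the cropped-single-cell workflow the pipeline is
built for. Frames with an invalid pose are emitted all-zero and flagged
rather than dropped, keeping row indices aligned with time.

## Kymographs and stripe removal

The kymograph collapses a band of registered rows by maximum projection:
`K[t, x] = max over y in band of I[t, y, x]`. Maximum projection over
the cell's width keeps a trace visible even when a spot wanders off the
centreline. Columns are micrometres along the cell axis, rows are frame
intervals.

Interference patterns and abrupt changes of the cell's height above the
coverslip leave full-width horizontal stripes. Rows of constant offset
carry energy only at zero spatial frequency, so the filter zeroes a
narrow vertical strip (default width 2 frequency pixels) of the centred
2D spectrum across all temporal frequencies, with two deliberate
choices:

* the DC coefficient is preserved, so overall brightness is unchanged —
  a strip that included DC would shift the image mean;
* the strip is applied together with its conjugate mirror. The spectrum
  of a real image is conjugate-symmetric; editing it asymmetrically and
  taking the real part of the inverse transform would silently re-create
  half of the masked energy at the mirrored frequencies. With the
  symmetric closure the output is exactly real and provably carries zero
  energy at every masked frequency (an even width therefore behaves like
  the next odd width).

A pure-stripe image (each row constant) collapses to its global mean to
numerical precision, while a diagonal-trace image keeps > 0.95
correlation with its stripe-free original — both are asserted in the
test suite.

## Orientation-histogram velocimetry

A straight kymograph trace of orientation α (measured from the space
axis toward increasing time) corresponds to velocity
`v = (pixel_size / frame_interval) · cot(α)`: vertical traces (α = 90°)
are stationary, α < 90° moves toward +x. Orientations within 2° of the
space axis are rejected as "too fast to resolve" — at 130 nm/px and
10 fps that cutoff is ≈ 37 µm/s, far above the ≤ 12 µm/s spot speeds of
interest, and the cot() divergence makes anything beyond it meaningless.

The batch estimator computes a Fourier-components orientation histogram
of a rectangular ROI: mean-subtracted, 2D-Hann-windowed, zero-padded to
a square power of two; the power spectrum is integrated over an annulus
of 0.1–0.9 of the Nyquist radius (excluding the DC neighbourhood, which
carries no orientation, and the aliased corners) into 90 bins of 2°, and
frequency orientations are rotated by 90° to structure orientations.
ROIs must span 5–15 s: long enough that a trace crosses many bins of the
spectrum, short enough that cell speed is approximately constant within
the window.

Estimation follows a three-tier hierarchy. A Gaussian-with-baseline is
fitted (Levenberg–Marquardt) to the circularly unwrapped histogram
around the strongest *off-vertical* mode; if the goodness of fit reaches
R² ≥ 0.5 the fitted peak is used (`gaussian-peak`), otherwise the raw
local maximum (`local-max`); manually measured straight segments
(`measure_segment`) are the third tier and always available. Structure
within ±5° of vertical is excluded from the mode search because the
registered cell body itself — static in the cell frame — contributes a
strong stationary (vertical) mode; if no off-vertical bin exceeds 1.5×
the uniform level the ROI is declared to contain no moving traces. On
synthetic kymographs with trace families at 0.5–12 µm/s and SNR 5 the
batch estimate stays within 10% of truth across the whole range.

ROIs are anchored in windows of smooth, sustained gliding (smoothed
speed > 0.5 µm/s for ≥ 5 s), and each measurement is paired with the
mean smoothed cell speed over the same window; the reported `ratio` is
cell speed over myosin speed. In the reference scenario — cell gliding
at +2 µm/s, spots at −6 µm/s in the cell frame — the recovered myosin
velocity is negative while the cell velocity is positive, reproducing
the opposite-direction signature of the fast myosins.

## Population motility assay

Low-magnification brightfield movies (defaults 0.91 µm/px, 1 fps) show
cells as dark elongated bodies on a bright background. Frames are
inverted and normalised, lightly Gaussian-smoothed (σ = 1 px), Otsu
thresholded, and connected components above 100 µm² are reduced to
centroids weighted by the *above-threshold* excess — weighting by raw
intensity would let boundary-noise flicker dominate the centroid of so
large an object. Nearest-neighbour linking within 30 µm per frame with a
2-frame gap tolerance yields per-cell traces.

"Distance moved" is the cumulative path length, not the net
displacement: the assay's filters (duration strictly > 30 s, distance
strictly > 50 µm ≈ one cell length) are meant to discard brief or
essentially stationary tracks, and back-and-forth gliding should count
as movement. Mean velocity is path length over duration, computed at
1 fps without trace smoothing — centroid jitter therefore biases the
mean velocity of a *stationary* cell upward to roughly 0.03 µm/s at the
generator's default noise, which is the measured noise floor of the
assay and is asserted to stay below 0.05 µm/s in the tests. Summaries
report median and IQR with the linear-interpolation percentile rule
(R's type 7), making boxplot statistics bit-reproducible.

## Hydrodynamic drag

The force argument needs the viscous drag on a gliding cell. The cell is
modelled as a cylinder with half-sphere ends, evaluated with the
prolate-spheroid axial-translation closed form of equal diameter and
length (a standard approximation, accurate to a few percent and
conservative); the spec of the formula and its small-eccentricity series
(used below e = 0.01, where the closed form loses precision to
cancellation) are in `?stokes_drag`. The claim this supports:
a 6 µm diameter capsule at 4 µm/s in water stays below 1 pN drag for any
length from 6 to 50 µm — the computed maximum (at 50 µm) is ≈ 0.54 pN,
and a single myosin motor can generate forces of that order.

```{r drag}
lengths <- seq(6, 50, by = 0.5)
f <- stokes_drag(drag_model("capsule", diameter = 6, length = lengths,
                            velocity = 4, viscosity = 1.0))
max(f)
```

## The synthetic-movie generator

`generate_gliding_movie()` renders what the analysis assumes: an
elongated cell (default 40 µm × 8 µm — the cell length is only loosely
constrained by the observation that ~50 µm is "about one cell length",
so it is configurable) gliding along its axis on a piecewise-constant
velocity trajectory (|v| ≤ 4 µm/s by convention), two Gaussian
chloroplast blobs (FWHM equal to the stated 4.5–6.0 µm diameters) at
fixed offsets along the axis, a low-intensity anisotropic Gaussian ridge
as the GFP cell body, diffraction-limited spots (FWHM 0.4 µm)
translocating at constant cell-frame velocities (±12 µm/s max by
convention) between the poles, additive Gaussian noise (Poisson shot
noise behind a flag), and optional full-width horizontal stripes added
to the GFP channel — the channel the kymographs are built from; the
tracking channel never sees them. Rendering is analytic Gaussian
evaluation at pixel centres (no supersampling), so blob mass is
conserved to ≪ 0.1% as the cell moves sub-pixel distances. Ground truth
(pose, signed along-axis velocity, per-spot positions, trajectory
events) is integrated in closed form, exact to machine precision, and a
fixed seed gives bit-identical movies without disturbing the caller's
RNG stream.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: evanescent-field depth falloff
(intensities are independent of z, as nothing downstream uses z),
photobleaching and blinking, frustule optics, non-rigid cell motion,
intensity variation between the two chloroplasts' shapes, and spot
crowding/passing dynamics beyond linear superposition. Registration and
velocimetry accuracies quoted here are accuracies *under rigid-body
motion with Gaussian blobs*; real movies add model mismatch the pipeline
is not tested against.

`generate_population_movie()` renders dark elongated cells on a bright
background (defaults 0.91 µm/px, 1 fps, 300 s). Cells glide at assigned
constant speeds along gently curving paths and reverse direction at the
field margins — raphid diatoms reverse frequently, and reversal keeps
every path inside the field so ground-truth path length is exactly
speed × duration. The default background noise is 0.5% of the background
level, representative of a well-exposed 10 ms LED brightfield exposure.

## Reference problem sizes

The validation scenarios the test-suite runs are deliberately desk-sized:
a 25 s, 10 fps movie at 130 nm/px (120 × 800 px) with twelve −6 µm/s
spots at SNR 5 for the full pipeline; a 20 s movie with a 0.4 s
stop-and-reverse for event localisation; 100 × 256 px drawn kymographs
for the velocimetry sweep; and 3–4 cells over 50–60 s for the population
assay. These sizes were chosen so the whole suite exercises every stage
in about a minute while leaving all accuracy criteria comfortably
resolvable.

## Numerical and I/O choices

* Image coordinates: x = column, y = row, y down, origin at the centre
  of pixel (0, 0); angles are converted to the mathematical y-up sense
  at the pose boundary so users reason in standard orientation.
* "Geometric mean between the centre positions" of the landmark circles
  is implemented as the coordinate midpoint — a literal geometric mean
  of signed coordinates is ill-defined.
* Local-maxima plateaus (possible in noise-free synthetic images when a
  blob centre falls exactly between pixels) are broken in raster order,
  so detection stays deterministic.
* TIFFs are plain multi-page 16-bit (frame-major, channel-interleaved)
  with calibration, channel labels and page layout in a JSON sidecar;
  `read_stack()` falls back to explicit overrides and errors if neither
  source provides calibration. Every `write_results()` run emits a
  manifest with an MD5 hash of the canonical configuration and of every
  written file, so a run is reproducible bit-for-bit from config + seed.

## Known limitations

* Linking assumes exactly two landmarks; cells with a third bright
  autofluorescent body would need masking first.
* The orientation histogram reports one dominant velocity per ROI; ROIs
  containing two comparable trace families yield whichever mode is
  stronger (the manual-segment tier exists for exactly that case).
* Velocities within the ±5° vertical exclusion zone (|v| ≲ 0.11 µm/s at
  default calibration) are indistinguishable from stationary background
  in the batch estimator.
* Population tracking has no collision handling: cells that touch merge
  into one component for the frames involved and their tracks terminate
  or restart depending on the gap tolerance.
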