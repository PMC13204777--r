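---
title: "The msod model: a fly-inspired small-moving-object detector"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The msod model: a fly-inspired small-moving-object detector}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(msod)
```

# The problem

Small moving objects — a handful of pixels, blurred texture, luminance close
to background clutter — are notoriously hard to detect in video, and the
hardest part is not finding them but rejecting *pseudo-objects*: small,
high-contrast background features that translate rigidly with a moving
background and look exactly like genuine targets to any local motion
detector. The fly visual system solves this problem with a compact layered
circuit, and `msod` implements a computational model of that circuit with
four stages:

1. **Retina** — grayscale conversion and optical blur.
2. **Lamina** — temporal band-pass filtering (large monopolar cells),
   spatio-temporal lateral inhibition, and decomposition into rectified ON
   (luminance-increase) and OFF (luminance-decrease) channels; in parallel,
   an amacrine/T1 branch computes local contrast.
3. **Medulla and lobula** — second-order surround inhibition (Tm3/Tm2)
   giving small-size selectivity, gamma-kernel delays (Mi1/Tm1), and a
   feedback Hassenstein–Reichardt correlator whose signed output models the
   small-object-selective LC11 neuron.
4. **Mushroom body** — thresholded LC11 responses are linked into motion
   trajectories, local contrast is sampled along each trajectory, and a
   trajectory is confirmed as a genuine mover only when the running
   standard deviation of its contrast series exceeds a threshold.

The confirmation logic is the scientific heart of the model. A
background-locked pseudo-object travels *with* its surroundings, so the
local contrast it carries is the same in every frame and the standard
deviation of its contrast trajectory stays near zero. An independent mover
crosses ever-changing background, so its contrast trajectory fluctuates and
its standard deviation grows past the threshold within a few frames.

# Model equations

With $P(x, y, t)$ the blurred luminance, the stages are:

* **Band-pass:** $LMC = P * H$ in time, with
  $H(t) = \frac{n_2!\,t^{n_1} - n_1!\,t^{n_2}}{n_1!\,n_2!}\,e^{-t}$,
  $n_2 > n_1$. $H(0) = 0$, $\int_0^\infty H = 0$, and the single sign
  change sits at $t^* = (n_2!/n_1!)^{1/(n_2-n_1)}$ (about $3.728$ at the
  defaults $n_1 = 1$, $n_2 = 6$).
* **Lateral inhibition:** $LMCI = LMC * W_I$ with the separable kernel
  $W_I = W_{SP} W_{TP} + W_{SN} W_{TN}$, where
  $W_{SP} = [G_{\sigma_2} - G_{\sigma_3}]^+$,
  $W_{SN} = [G_{\sigma_2} - G_{\sigma_3}]^-$ are the rectified halves of a
  difference of Gaussians and $W_{TP}, W_{TN}$ are fast/slow exponentials
  ($\lambda_1 < \lambda_2$). The separable form is evaluated as a temporal
  filter followed by a spatial convolution; a brute-force spatio-temporal
  convolution oracle in the test suite confirms the equivalence.
* **ON/OFF:** $S_{ON} = [LMCI]^+$, $S_{OFF} = [-LMCI]^-$ read as
  $\max(-LMCI, 0)$, the unique non-negative reading.
* **Contrast branch:** centre and annulus box sums over $\Psi$ (11×11) and
  $\Pi$ (31×31) windows give
  $T1 = \overline{L}_{\text{annulus}} - \overline{L}_{\text{centre}}$,
  with divisors $31^2 - 11^2 = 840$ and $11^2 = 121$ — the only reading in
  which each divisor counts the pixels actually summed.
* **Medulla:** $S_{Tm3} = [S_{ON} * W_1]^+$,
  $S_{Tm2} = [S_{OFF} * W_1]^+$ with
  $W_1 = A\,W_{SP} + B\,W_{SN}$, $B > A$, so the kernel is net-inhibitory
  and extended activity dies while isolated blobs survive. Mi1/Tm1 are
  gamma-delayed copies:
  $\Gamma_{n,\tau}(t) = \frac{n^n t^n}{(n-1)!\,\tau^{n+1}} e^{-nt/\tau}$,
  a unit-integral kernel peaking at $t = \tau$.
* **Lobula (LC11):**
  $LC11_1 = (S_{Tm3} + kF_1)(S_{Tm1} + kF_1)$,
  $LC11_2 = (S_{Tm2} + kF_2)(S_{Mi1} + kF_2)$,
  $LC11 = LC11_1 - LC11_2$, where $F_i$ is a gamma-weighted sum of that
  pathway's own outputs at strictly past lags. Strict causality keeps each
  frame an explicit function of the history (no fixed-point equation), and
  with $k = 0$ the recursion reduces exactly to the feedforward product
  correlator; both properties are asserted in the tests.

# Discretization: the decisions that matter

The model's continuous kernels must be realized on a 30 FPS frame grid,
and the constants above do not share one coherent time unit. Three
decisions, made once, define the package's reading:

**All 1-D kernels are bin-integrated, not point-sampled.** Tap $j$
integrates the continuous kernel over a frame-period bin (centred bins for
the band-pass and gamma kernels, forward bins for the monotone
exponentials). This preserves total kernel mass under any sampling step —
in particular, a delay of less than one frame period does not vanish but
splits its mass between lags 0 and 1.

**The band-pass is calibrated so its discrete step response is a
single-frame transient.** The filter models sensitivity to luminance
*change* — operationally, a consecutive-frame difference. Point-sampling
$H$ at one time-unit per frame stretches its excitatory phase over ~4
frames; a small target moving faster than its own width then occupies each
pixel for a single frame *inside* the excitatory phase, and the ON response
to the target's departure cancels against the lingering memory of its
presence. The package therefore samples $H$ at $2t^*$ time-units per frame
(`bandpass_step()`), which puts the whole excitatory phase in the lag-0 tap
and the inhibitory rebound almost entirely in lag 1: a luminance step
produces one strong transient frame followed by a residue below 12% of the
peak. The lamina exponentials $\lambda_1, \lambda_2$ share this time base.
After bin integration the negative taps are rescaled so the discrete sum is
exactly zero — a temporally constant input is annihilated exactly, which
the null-propagation tests rely on.

**The delay constants $\tau_3 = \tau_4 = 25$ are read as milliseconds.**
These model physiological Mi1/Tm1 latencies, tens of milliseconds; at
30 FPS they become 0.75 frames. Read as *frames* instead, 25 frames
exceeds the entire 21-frame benchmark sequence: the "delayed" channel then
carries the stimulus-onset transient for the whole sequence and the
correlator pairs current signals with the positions objects occupied at
frame 0 (we verified this failure mode empirically before fixing the
unit). A `time_unit = "frame"` switch retains the literal reading for
sensitivity studies.

**Correlator latency.** The pointwise product $S_{Tm3}\cdot S_{Tm1}$
fires where an OFF event (object covers a pixel) is followed by an ON
event (object reveals it) — an event that completes one frame after the
object has left. The response at frame $t$ therefore marks the object's
position at $t - 1$; at 250 px/s and 30 FPS that is a systematic trailing
offset of $v/\text{fps} = 8.3$ px, which we measured exactly. The mushroom
body compensates by assigning detections to their *event frame*
$t - \texttt{latency}$ (default 1), which also makes the contrast sample
$T1(x, y, t_{\text{event}})$ refer to the place and time the object
actually occupied.

# Detection, trajectories, confirmation

The response scale of the correlator is not meaningful in absolute terms,
so the detection threshold $Th = 0.2$ is applied to a normalized map. The
normalizer is the mean of the 100 largest positive response values of the
frame (about four 5×5 object footprints): it tracks the strength of the
strongest few candidate objects, unlike a max-normalizer, under which a
single strong distractor silences every weaker genuine object, and unlike
a fixed quantile of all pixels, which falls below the noise floor when
strong pixels are sparse. Surviving pixels are reduced to local maxima by
greedy non-maximum suppression over a 5×5 window (ties resolved toward
smaller $y$, then $x$).

Trajectories are built by greedy nearest-neighbour linking with a distance
budget of `link_radius` (10 px) *per elapsed frame* and a tolerance of one
missed frame (`gap_max = 1`): the strength of a revelation event depends on
the luminance of the background patch being revealed, so single-frame
dropouts are expected for a real mover. Ties go to the earliest-created
trajectory, making linking deterministic. Each trajectory accumulates the
contrast series $CT_i = T1(x_i, y_i, t_i)$ and its running *sample*
standard deviation from the trajectory start ($SD_1 = 0$; cumulative, not
windowed, so evidence accumulates monotonically in time). A point is
confirmed when its trajectory has at least `min_length = 3` points and
$SD > Th_2 = 4$ gray levels. Confirmation is monotone in $Th_2$: raising
the threshold never adds confirmations.

# The synthetic stimulus generator

`scene_config()` / `render_sequence()` emulate the benchmark stimuli: a
wide textured panorama translating horizontally behind a 500×250 viewport
at 250 px/s, three background-locked 5×5 luminance-0 pseudo-objects
painted *into* the panorama (rigid with the background by construction),
and one independent 5×5 luminance-0 object crossing at −250 px/s, with
exact per-frame ground-truth centres. Rendering is a pure function of the
configuration: identical seeds give bit-identical frames.

The default background is a smoothed Gaussian field with a correlation
length of 12 px, normalized to mean 127.5 and standard deviation 40 gray
levels and clipped to [0, 255] — the luminance statistics of a typical
outdoor photograph. This matters: a full-range, fine-grained noise
background is a field of small high-contrast objects in its own right, and
no small-target model (this one included) can operate on it. What the
generator does *not* emulate: photographic spatial structure (edges,
occlusions, perspective), illumination changes, sensor noise beyond an
optional additive Gaussian term, and sub-pixel rendering — objects are
hard-edged rectangles painted at the nearest pixel. Passing tests on these
scenes therefore demonstrate the mechanism — size selectivity, background
suppression, pseudo-object rejection — not performance on real footage.

Positions in the baseline scene (pseudo-objects at (50, 60), (65, 125),
(80, 190); mover from (430, 125)) were chosen once so that no two
trajectories approach within the link radius during the 21 frames.

# Evaluation conventions

* **Detection rate**: fraction of evaluated frames with a confirmed
  detection within 5 px (Euclidean) of the true target centre.
* **Pixel precision/recall/F1**: object-sized boxes stamped at confirmed
  detections versus the true target boxes; pseudo-objects count as
  background.
* **SNR/VN**: house conventions, labelled as such — SNR is the mean over
  frames of (peak response inside the 5-px-dilated target region) / (RMS
  response outside); VN is the percentage of total response energy outside
  the target region. Only *comparisons within one pipeline* (e.g. raw LC11
  versus confirmed output) are meaningful; the absolute values are not
  comparable across publications because no canonical definition exists.
* **Warm-up**: the first 8 frames are excluded from all metrics. The
  start-up transient of the band-pass decays below a third of its peak
  within 8 frames and trajectories have had time to accumulate the 3
  points confirmation requires; excluding the *complete* temporal depth of
  all filters (17 frames) would leave almost nothing of a 21-frame
  sequence to evaluate. The last evaluated frame is $T - 1 -$`latency`,
  since later events cannot be observed.

# Numerical choices and degenerate inputs

* Spatial borders use replicate padding everywhere (convolutions and box
  sums), so unit-sum kernels preserve constants up to the edge.
* Temporal filters start from zero history (the model's zero initial
  state); the warm-up exclusion covers the transient.
* The spatial convolution engine is a compiled direct convolution; the
  test suite holds it to below $10^{-9}$ maximum absolute error against a
  pure-R nested-loop oracle on 100 random inputs, and the box-sum integral
  images and the separable inhibition are checked against brute-force
  oracles the same way.
* Sample SD of fewer than two points is 0; an all-zero response yields
  SNR = VN = 0 by convention; frames with no positive response produce no
  detections; an empty prediction gives precision 0.
* All linking and NMS tie-breaks are deterministic (documented above), so
  the entire pipeline is bit-reproducible.

# Problem sizes used by the test suite

Unit tests run on small synthetic stacks (16×16 to 160×100 px, 6–21
frames) where brute-force oracles are affordable. The end-to-end property
tests run the full benchmark geometry — 500×250 px, 21 frames — over five
seeds for the pseudo-object-rejection check and over the full 11-point
luminance grid × five seeds for the luminance trend, sizes chosen so the
whole suite completes in a few minutes on one CPU while still exercising
the exact study conditions.

# Known limitations

* The trailing-offset compensation assumes the dominant delay mass sits at
  lag 1; at much higher frame rates (occupancy spread over many frames)
  the latency parameter should be 0.
* Very slow targets (moving less than their own width per frame) violate
  the cover-then-reveal event model that the calibrated band-pass is built
  around; the model is tuned to the fast-target regime of the benchmark.
* A bright target on a dark background drives the $LC11_2$ pathway and
  appears with negative sign; detection uses the positive part by default
  (`use_abs = TRUE` treats both polarities symmetrically).
* The contrast-SD test rejects background-locked distractors but cannot
  reject an independent mover that happens to traverse perfectly uniform
  background (its contrast series is then flat); on natural panoramas such
  paths are rare.

```{r example, eval = FALSE}
scene <- baseline_scene(seed = 1)
seq1 <- render_sequence(scene)
result <- msod_detect(seq1$frames)
evaluate_detections(result, seq1$truth)
autoplot(result)
plot_contrast_sd(result)
```
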