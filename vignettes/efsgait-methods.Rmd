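---
title: "Electrostatic gait sensing: models, detectors and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrostatic gait sensing: models, detectors and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efsgait)
```

`efsgait` studies a non-contact gait measurement principle: a charged
walking body drives a displacement current through a nearby passive
electrode, and the timing structure of that current encodes the foot
events that segment the gait cycle. This vignette documents the models the
package implements, the parameters that matter, what the bundled simulator
does and does not emulate, and the design decisions taken where the
problem was genuinely open.

## The electrostatic forward model

The body is treated as a good conductor carrying a quasi-static charge
$Q_B$. Its capacitance to the environment is dominated by the feet: each
sole is a plate capacitor to ground, jointly
$C_f = 2\,\varepsilon_s S_s / d_e$ with $\varepsilon_s$ the sole
permittivity, $S_s$ the equivalent sole–ground area and $d_e$ the sole
thickness. When one foot is airborne at height $h(t)$, the air gap acts in
series and the body potential becomes

$$
U_B(t) \;=\; Q_B\,\frac{\varepsilon_a S_s + h(t)\,C_f}
                       {C_f\,\varepsilon_a S_s}
\;=\; Q_B\left(\frac{1}{C_f} + \frac{h(t)}{\varepsilon_a S_s(t)}\right),
$$

a standing offset $Q_B/C_f$ plus a motion term. An electrode coupled to
the body through capacitance $C$ carries the displacement current
$I = C\,\mathrm{d}U_B/\mathrm{d}t$, so, expanding the motion term,

$$
I(t) \;\propto\; \frac{1}{S_s}\frac{\mathrm{d}h}{\mathrm{d}t}
 \;-\; \frac{h}{S_s^2}\frac{\mathrm{d}S_s}{\mathrm{d}t}.
$$

Two modelling simplifications are made. First, the electrode's own induced
potential is neglected in the charge balance: the electrode sits at
virtual ground behind the huge sampling resistor, so its potential is
orders of magnitude below $U_B$. Second, the absolute amplitude of the
simulated signal is explicitly *uncalibrated*: $Q_B$, $C$ and the noise
levels of a real room are not measurable constants, so only the timing
structure of the waveform is treated as physically meaningful, and every
detector in the package is amplitude-normalised (thresholds are fractions
of the observed peak-to-peak excursion).

## Gait timing generator

Ground truth is a per-foot event schedule: alternating initial contacts
(IC) and foot-offs (SE). Cycle durations are drawn from truncated normals
calibrated to metronome-paced walking at three speeds — fast
$990 \pm 120$ ms (clipped to 870–1153 ms), normal $1198 \pm 110$ ms
(1088–1398 ms), slow $1498 \pm 75$ ms (1358–1697 ms) — and the stance
phase occupies a truncated-normal fraction of each cycle with mean 0.60.
The stance-fraction spread (sd 0.025, clipped to (0.4, 0.8)) is our own
choice of a realistic healthy-gait variability, matching the few-percent
spread reported for stance ratios in healthy adults. The distribution
family is likewise our choice: only mean, sd and range are externally
given, and a rejection-sampled truncated normal reproduces all three.

## Foot kinematics

The forward model needs $h(t)$ and $S_s(t)$, for which no measured form is
available; the package synthesizes them from the schedule:

* **Height** is identically zero on stance. Over each swing it is a
  piecewise raised-cosine bump: a fast lift to 85% of `h_max` over
  `lift_s` (default 0.05 s), a gentle dome peaking at `h_max`
  (default 0.15 m) at mid-swing, and a symmetric fast landing over
  `land_s`. The fast lift/landing is deliberate and load-bearing: in human
  gait the vertical foot velocity peaks just after toe-off and just before
  heel strike, and it is exactly this property that places the extrema of
  $I(t)$ at the SE and IC instants — the premise of the electrostatic
  detector. A single symmetric cosine over the whole swing would instead
  put the velocity peak a quarter-swing (~120 ms) away from the events and
  would misrepresent the physics the detector relies on. With the default
  50 ms lift, the current extremum sits ~25 ms inside the swing, a known,
  cycle-constant offset.
* **Area** is `s_max` (0.025 m², an adult sole) while the foot is flat,
  rolls off smoothly to `s_min` (0.002 m²) over the last `roll_fraction`
  (0.15) of stance — the toe roll-off — and ramps back after contact.
  `s_min > 0` keeps $U_B$ finite. Before the first contact the foot is
  taken to be just landing out of swing ($h = 0$, $S_s = s_\min$), which
  keeps both series continuous. Because $h = 0$ throughout stance, the
  area ramps inside stance do not move the potential; the area's role is
  to set the swing-phase gain $1/(\varepsilon_a S_s)$.

All amplitudes are configurable; none is validated against measured
kinematics (a stated non-goal). What *is* validated, by construction and
by test, is that the zeros of $h$ coincide with the schedule's stance
intervals and the bump peaks at mid-swing.

## Acquisition chains

**Electrostatic channel.** The current is simulated on an internal 4 kHz
grid (a finer grid keeps the central-difference derivative clean before
any filtering), white input-referred current noise (sd $10^{-7}$ A) and a
50 Hz mains sinusoid (amplitude $5\times10^{-8}$ A) are added, the sum is
converted to volts across $R_s = 10\,\mathrm{G\Omega}$ (10 mV/pA), low-pass
filtered with an order-4 Butterworth at 20 Hz, and decimated to 1 kHz. The
filter is applied forward–backward (zero phase) so filtering never biases
event times, with odd-reflection padding so the filter's edge transients
do not leak into the trace (and a DC input passes at exactly the DC gain).
The noise defaults are our fixed study conditions: large enough that the
mains line and broadband floor are visible in the raw trace, small enough
that a quiet laboratory's signal-to-noise ratio is preserved. No ADC
quantisation is modelled. The attenuation of the 50 Hz line by the 20 Hz
corner (≥ 20 dB required, ~64 dB achieved by the doubled-order zero-phase
pass) is asserted by test.

**Pressure channel.** The FSR insole output rises with foot load within a
0–2.5 V conditioning range. Per stance the simulator emits a trapezoid:
baseline (0.1 V) to full scale (2.5 V) over an 80 ms loading ramp from IC,
and back over 80 ms ending at SE, plus a slow sinusoidal baseline drift
(0.05 V, 20 s period — unloaded FSR drift during movement) and Gaussian
noise (10 mV), clipped to the output range. The trapezoid's ramp time and
drift are our choices of plausible FSR behaviour; the output range is the
conditioning circuit's specification.

## Event detection

**Pressure (three steps).** (1) Stance zones are found from rising and
falling edges of the smoothed signal through the fixed 1 V threshold —
comfortably above the unloaded output and below full load. Threshold
crossings closer than `min_event_gap` (0.3 s) are treated as noise
chatter and cancelled pairwise. (2) Because the unloaded level drifts, the
contact/separation reference is the *local* minimum adjacent to each edge,
found by differentiating the smoothed signal and walking from the
derivative's extremum to its zero crossing. (3) The minima are corrected
by an offset of 3% of the cycle's local max-to-min excursion: IC is the
first instant after the pre-rise minimum at which the signal exceeds
(min + offset) — i.e. the minimum is shifted *later*, onto the rising
limb — and SE is the last instant before the post-fall minimum still
exceeding it, shifted *earlier*. The offset direction is not externally
fixed; this choice makes IC/SE bracket the loaded interval, and on a clean
linear ramp it lands the corrected event `offset_frac × ramp` after the
true contact, a closed form the tests assert at one-sample accuracy.

**Electrostatic.** The trace is smoothed with a 50 ms moving average;
positive peaks are foot-offs and negative troughs are contacts, extracted
with a topographic-prominence floor of 20% of the trace's peak-to-peak
amplitude and a 0.3 s minimum separation within each kind, then merged
with alternation enforced by dropping the less prominent member of any
same-kind adjacent pair (ties keep the earlier event). The peak→SE /
trough→IC polarity follows the physics above; because a reversed electrode
wiring flips it exactly, an optional auto-detection compares the median
peak→trough gap (the ~40% swing) with the trough→peak gap (the ~60%
stance) and swaps labels when the phase structure is inverted. It is off
by default since the rule is a heuristic, not an identity.

Both detectors are translation-equivariant by construction (all decisions
are made on sample indices; times are `t0 + index/fs`), which the tests
check exactly.

## Temporal parameters and agreement statistics

Per cycle: $T_g = IC_{m+1} - IC_m$, $T_s = SE_n - IC_m$,
$T_w = T_g - T_s$ (an exact identity in the code, not a recomputation),
cadence $120000 / T_g[\mathrm{ms}]$ steps/min, and the stance/swing ratios.
Partial cycles at either end are dropped, never extrapolated.

Validation statistics mirror standard concurrent-validity practice:
greedy nearest-neighbour event matching within a 100 ms window; error
summaries with a 5 ms-bin histogram spanning ±50 ms; gait-cycle accuracy
$100 - \overline{|\%\,\mathrm{error}|}$ over paired cycles; Pearson $r$
with the conventional grading (excellent > 0.90, good 0.80–0.89, fair
0.70–0.79, poor below); and ICC(2,1) — the single-measures,
absolute-agreement form of the two-way random-effects model — computed
from the explicit ANOVA mean squares,
$\mathrm{ICC} = (MS_R - MS_E)/(MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E))$,
with significance from $F = MS_R/MS_E$ on $(n-1, (n-1)(k-1))$ degrees of
freedom (the model is named in the reliability literature without a fixed
significance test; the row-effect F test is the standard choice). The
tests verify the implementation against an independent `aov()`-based
mean-squares route to $10^{-10}$.

## Numerical choices

* Derivatives are central differences; the forward model's derivative is
  taken on the 4 kHz grid *before* filtering and decimation. At 4 kHz the
  truncation error of a central difference on the 50 ms cosine lift is
  ~$4\times10^{-5}$ relative, so the analytic-derivative agreement test
  runs at 20 kHz with a slower lift, where the $O(\Delta t^2)$ error drops
  below $10^{-6}$.
* The moving average shrinks its window at the ends (stays zero-phase
  everywhere); a cumulative-sum implementation makes it $O(n)$, and the
  EFS flatness guard therefore tolerates the cumsum's float dust when
  deciding a trace has no structure.
* Tie-breaks: equal-prominence same-kind neighbours keep the earlier
  event; plateau maxima resolve to their first sample.
* Degenerate inputs error early with classed conditions
  (`efsgait_insufficient_signal`, `efsgait_malformed_signal`,
  `efsgait_format_error`, …) so pipelines can react programmatically.

## End trimming and pipeline

Walkers need an adjustment period before a steady rhythm, so
`run_pipeline()` removes 2 s from the beginning and end of every recording
before detection; truth events inside the trimmed windows are dropped,
interior events untouched. Everything downstream of one seed is
deterministic: the schedule, both noise draws and all derived reports are
byte-identical across runs.

## What the simulator shows — and what it cannot

The validation suite runs the full chain at 100 cycles per pace (about
two minutes of gait at 1 kHz per run, a size chosen to match the scale of
a typical per-subject recording session) and reproduces the behaviour a
correct implementation should show under these conditions: EFS event
timing within ±40 ms of truth, paired-cycle accuracy above 97%, and
cross-method $T_g$ correlation above 0.99 over mixed paces.

These are statements about the simulator's study conditions, not about
real rooms: the generator does not emulate double support mechanics,
inter-subject kinematic variability, electrode-angle and distance
sensitivity, humidity/temperature effects on body charge, bystander
motion, or pathological gait beyond parameter changes. The EFS event
offset (~25 ms at the defaults) is an honest consequence of peak-velocity
timing; it inflates stance-ratio estimates by ~4 percentage points while
leaving cycle durations unbiased — which is precisely why cycle-level
quantities are the method's most reliable output, and why the stance/swing
means of the two channels should not be expected to coincide.
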