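---
title: "Methods: joint-angle movement analysis for nap-session monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint-angle movement analysis for nap-session monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(napscope)
```

## The measurement model

napscope analyses contactless sleep recordings through a single chain:
a pose-estimation backend (BlazePose-class models, or the bundled
simulator) emits, per video frame, up to 12 named body landmarks —
left/right shoulder, elbow, wrist, hip, knee, ankle — as normalized
image coordinates in $[0,1]$ with a visibility score. For an angle with
vertex triplet $(A, B, C)$, coordinates are first converted to pixels by
multiplying with the frame dimensions, then the two limb vectors
$\overline{AB} = B - A$ and $\overline{BC} = C - B$ are formed and the
joint angle is

$$\theta \;=\; \arccos\!\left(
  \frac{\overline{AB}\cdot\overline{BC}}
       {\lVert\overline{AB}\rVert\,\lVert\overline{BC}\rVert}
  \right)\cdot\frac{180}{\pi}.$$

Two consequences of this definition are worth internalizing:

* $\theta$ is the angle *between* the limb vectors, so a straight limb
  scores $0^\circ$ and a fully folded one $180^\circ$; the anatomical
  interior angle is $180^\circ - \theta$. We keep the between-vectors
  convention throughout because it is what the pixel-space formula above
  computes.
* The conversion to pixels happens *before* the angle: on non-square
  frames the aspect ratio distorts angles relative to normalized space.
  The property suite documents this deliberately — it is part of the
  measurement definition, not an artifact.

The $\arccos$ argument is clamped to $[-1, 1]$ to absorb floating-point
overshoot. Zero-length limb vectors raise a structured error rather than
returning $0^\circ$: a silent zero would masquerade as a straight limb
and corrupt every downstream movement index. At the stream level,
missing or low-visibility landmarks yield missing angle samples — frames
are never fabricated.

### The triplet convention

Only the elbow triplet (shoulder–elbow–wrist) is canonical. We complete
the table same-side: knee = hip–knee–ankle, hip = shoulder–hip–knee,
shoulder = hip–shoulder–elbow. Wrists and ankles are terminal joints with
no distal neighbour among the 12 points, so no within-set triplet can
measure their anatomical flexion; we define their angle as the chord back
to the same-side hip (wrist = elbow–wrist–hip, ankle = knee–ankle–hip).
This keeps all 12 labelled angles computable from the 12 points alone.
The full table ships as `inst/extdata/topology.yaml`; deployments that
track extended landmark sets (e.g. heels or finger points) can substitute
their own third points via `read_topology()` without touching code. The
chord convention is ours — the measurement literature this pipeline
follows names only the shoulder–elbow–wrist example — and results for
wrist/ankle angles should be interpreted as chord angles, not flexion.

## Movement indices

Each angle series is summarised per session by:

* **number of changes** — posture-change count,
* **maximum change** — the range $\max - \min$ over present samples,
* **maximum / minimum stable time** — longest and shortest held posture,
* **duration** — the session length.

"Change" and "stable" need operational definitions; ours are explicit
parameters of `index_params()`:

| parameter | default | meaning |
|---|---|---|
| `tolerance_deg` | 5° | stability band half-width around the segment median |
| `delta_deg` | 10° | minimum level shift counted as a change |
| `min_duration_s` | 2 s | minimum stable-segment length |
| `gap_fill_s` | 1 s | longest missing run to interpolate linearly |

A *stable segment* is a maximal interval of at least `min_duration_s` in
which every sample lies within `tolerance_deg` of the interval median;
a *change* is a transition between consecutive stable segments whose
median levels differ by at least `delta_deg`. The defaults are chosen so
that frame-level measurement noise (about 1° for pose backends on static
scenes) is an order of magnitude below the stability band, while genuine
repositioning events (tens of degrees) are an order of magnitude above
the change threshold. `delta_deg >= tolerance_deg` is enforced;
segmentation uses the running range $\le 2\cdot$`tolerance_deg` as its
scan criterion, which coincides with the change threshold at the
defaults, so a shift large enough to split segments is also large enough
to count.

Numerical details that matter:

* Segment level is the **median**, robust to transient spikes.
* Segmentation is a greedy left-to-right scan: grow while the running
  range permits, then verify the median criterion and trim from the
  right on the (rare) bimodal-within-band violation. On
  piecewise-constant signals with well-separated levels this recovers
  boundaries to within one frame.
* Missing runs longer than `gap_fill_s` are *not* interpolated; they
  split the segmentation, so occlusions can never fabricate stability.
* Segment duration counts whole frames (the last frame contributes one
  frame period), making a constant 300 s series yield exactly 300 s.
* `max_change` is the raw series range, so with noise $\sigma$ it
  overshoots the true level range by roughly the expected extreme
  deviation ($\approx 2 \times 3.5\sigma$ for a 460 s session at
  30 fps). Tests compare it against ground truth with that allowance;
  the per-event alternative (largest single between-segment shift) is
  exported alongside as `max_event_change_deg`.

## The statistical design

Movement indices are ordinal-ish, small-sample (10 subjects), and
repeated within subject, hence the nonparametric repeated-measures
toolkit:

* **Friedman tests** across the 3 conditions separately per angle, and
  across the 12 angles separately per condition, with Kendall's
  $W = \chi^2 / (n(k-1))$ as effect size. The tie correction is **off by
  default** so every reported $(\chi^2, W)$ pair satisfies that identity
  exactly (the identity is asserted in the test suite); the corrected
  statistic is available behind `tie_correct = TRUE` and then matches
  `stats::friedman.test()`.
* **Wilcoxon signed-rank post hocs** where an omnibus is significant,
  Bonferroni-corrected within the family of pairwise comparisons of that
  omnibus (3 condition pairs, or 66 angle pairs). The exact p-value is
  used for up to 12 non-zero pairs — computed from the full null
  distribution of the rank sum via generating-function convolution, so
  ties are handled exactly — and a continuity-corrected normal
  approximation with tie-corrected variance beyond. Effect size
  $r = |z|/\sqrt{n}$ counts non-zero pairs in $n$; zero differences are
  dropped before ranking. At $n = 12$ the normal approximation deviates
  from the exact symmetric-tail p by at most $\approx 0.014$ (worst in
  mid-range p-values; verified exhaustively over the untied support), a
  bound the property suite pins at 0.015.
* **Spearman correlations** of body weight against each per-angle index
  within each condition (rank-then-Pearson, t approximation for p).
* Two-sided p-values throughout; $\alpha = 0.050$; effect sizes are
  attached to significant results only, mirroring the reporting
  convention of the study design this package serves.

`condition_comparison()` requires a complete subject × condition × angle
crossing per index and refuses incomplete designs rather than silently
dropping cells.

## The synthetic-session generator

Real nap recordings are rarely shareable; the simulator makes the whole
pipeline testable with known ground truth. A session is:

1. a duration drawn from $N(460, 50^2)$ s truncated above 60 s —
   the magnitude of a typical 7–8 minute
   midday nap in this study design;
2. a whole-body repositioning schedule: event count $\sim$
   Poisson(5) by default, event times uniform subject to a minimum dwell
   of 10 s between events and to the session edges (twice the dwell that
   guarantees detectability at the default `min_duration_s`);
3. per-angle piecewise-constant levels: at every event each angle draws
   a new level from its class range (hip 5–50°, knee 50–120°, shoulder
   90–160°, elbow 30–120°) at least `min_shift` away (15–20°) from the
   effective previous level, so every event is detectable by
   construction;
4. per-frame Gaussian noise (default $\sigma = 1^\circ$) added in angle
   space, so `noise_sigma_deg` is directly comparable to
   `tolerance_deg`;
5. inverse-geometry landmark placement (below), then optional occlusion
   gaps (Poisson gap starts, exponential lengths) that drop landmarks
   and propagate to missing angle cells.

### Inverse geometry

Hips and shoulders are fixed anchors of a canonical supine skeleton in
an abstract plane. Knees and elbows are placed by rotating about their
proximal joint, which realizes the hip/shoulder and knee/elbow angles
exactly. The terminal chord angles cannot be set by rotation alone —
their triplet's third point (the hip) is already fixed — but they *can*
be set exactly by solving the distal limb length: for shank direction
$u$, knee position $V$ and hip anchor $C$, the ankle chord angle as a
function of the shank length $t$ sweeps monotonically from its geometric
lower bound (at $t \to 0$) to $180^\circ$, and the required $t$ has a
closed form from a quadratic. The ankle bound is exactly
$180^\circ - \theta_{\text{knee}}$; the wrist bound depends on the
shoulder/elbow configuration and is computed per segment. Ankle and
wrist schedules are therefore parameterized as *offsets* above their
bound (default 12–48°), which guarantees reachability with a margin of
at least $12^\circ \approx 8.5$ noise SDs at the default
$\sigma = 1^\circ$; targets that still fall below the bound (extreme
noise, or user-configured offset ranges) raise a configuration error
rather than being clamped. Offsets start above zero by a wide margin and
stay below the knee-range minimum so chord angles remain inside
$(0, 180)$.

Finally the whole session is mapped isotropically (translation + single
scale factor) into the pixel frame with a 5% margin. Isotropic maps
preserve angles, so the recomputed pixel-space angles equal the schedule
to floating-point precision — the zero-noise round trip asserts
agreement to $10^{-6}$ degrees, the worst case observed over thousands
of random configurations being $\sim 10^{-8}$ near-degenerate ones.

Because repositioning events are whole-body, chord angles inherit level
shifts from their proximal joints; the offset sampler compensates by
drawing the next offset at least `min_shift` from the *effective*
previous value, so realized shifts stay detectable. Ground truth is
always the *realized* level matrix, never the requested one.

### Studies and effects

`generate_study()` crosses subjects with conditions (one session each).
Condition effects are multiplicative: on the event rate, and on event
magnitudes (shifts contracted toward the previous level — shrinking both
the count of supra-threshold changes and the range). Body weight is
drawn from $N(75, 12^2)$ kg truncated to $[45, 120]$ and couples to the
log event rate with a configurable coefficient; negative coupling makes
heavier subjects move less, reproducing the negative weight–movement
correlation structure the analysis is designed to detect. With all
multipliers 1 and zero coupling the three conditions are exchangeable —
the null configuration used for calibration.

### What the simulator does and does not emulate

It emulates: the landmark/angle measurement chain, piecewise-stable
posture with abrupt repositioning, angle-space noise, landmark dropout,
session-length variability, condition and body-weight effect structures.
It does **not** emulate: gradual drifts or slow postural sway,
correlated multi-joint noise, blanket-induced structured occlusion,
backend-specific bias, or any actual sleep physiology. Passing tests
therefore certify the *computational* pipeline — geometry, indices,
statistics — under the stated movement model, not claims about real
sleep recordings.

## Calibration and problem sizes

The test and acceptance suites run at sizes chosen to make their
statistical claims meaningful while staying desk-scale:

* geometry invariances over 1000 randomized triplets (tolerance
  $10^{-9}$ degrees);
* statistic-vs-oracle equivalence on 100 seeded Friedman matrices and
  full $2^n$ Wilcoxon sign enumerations up to $n = 12$;
* schedule recovery over 100 full sessions at study conditions
  (5 events/angle, $\sigma = 1^\circ$): the change count must be exact
  and stable times within one frame in at least 99% of the 1200 angle
  series;
* type-I calibration over 500 null studies (10 subjects × 3
  conditions): the per-angle Friedman rejection rate on the
  maximum-change index must lie in $[0.03, 0.07]$ at $\alpha = 0.05$.
  The maximum-change index is used because it is continuous — change
  *counts* under the null are small tied integers, for which the
  uncorrected Friedman test is conservative by construction.

The chi-square reference for the Friedman statistic is itself slightly
conservative at $n = 10, k = 3$ (empirical size $\approx 0.044$), which
the calibration band accommodates; this is a property of the classic
approximation, not of the implementation.

## Known limitations

* Wrist/ankle angles are chord angles by convention; they are not
  anatomical flexion and their feasible range is coupled to the
  proximal joints.
* `max_change` on noisy series is biased upward by the noise extremes;
  prefer `max_event_change_deg` when a level-shift interpretation is
  needed.
* The exact Wilcoxon path enumerates the full rank-sum distribution and
  is intended for the small within-subject samples of this design
  ($n \le 12$ by default).
* Angles are 2D projections: out-of-plane motion changes projected
  angles without a posture change. The pipeline measures what a single
  overhead camera sees.
* The CLI covers batch processing only; live capture, pause/resume and
  on-screen overlays of interactive recording tools are out of scope.
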