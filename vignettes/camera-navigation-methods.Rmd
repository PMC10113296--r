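---
title: "Methods: simulating and assessing oblique-endoscope camera navigation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and assessing oblique-endoscope camera navigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scopeskill)
```

`scopeskill` is an in-silico counterpart of a dry-lab hysteroscopy trainer:
a passive measurement arm holds a real 30-degree endoscope that enters a
uterine phantom through a fixed entrance orifice, and trainees practise
pointing the oblique optic at ten ring targets on the cavity wall. The
package simulates the full measurement chain — encoders, pose recovery,
image formation, focus scoring, trial protocol — plus a synthetic cohort of
improving "surgeons", and then runs the learning-curve statistics a
validation study of such a trainer reports. This vignette documents the
models, the tunable parameters and the numerical choices.

## Fulcrum-constrained pose recovery

The tracker arm has six passive rotational joints but only four encoders:
three on the positioning chain (yaw–pitch–pitch) and one on the scope roll.
The missing two degrees of freedom are recovered from the *fulcrum*
(remote-center-of-motion) constraint: the endoscope shaft must pass through
the fixed entrance point $F$. With $A(\theta_1,\theta_2,\theta_3)$ the scope
attachment point from the chain's forward kinematics and $L$ the scope
length, the shaft direction is $u = (F-A)/\lVert F-A\rVert$, the tip is
$p = A + L\,u$, and the insertion depth is $d = L - \lVert F-A\rVert$. The
unencoded gimbal angles $\theta_4,\theta_5$ follow as the rotation aligning
the chain's distal frame with $u$; of the two gimbal branches we keep the
one with $|\theta_4| \le 90^\circ$, matching a physically mounted arm and
making the reconstruction deterministic.

The device this emulates does not publish link lengths or joint axes, so
the chain here is a stand-in, not a claim about any hardware: an
articulated 3R arm with $l_1 = 150$, $l_2 = 200$, $l_3 = 200$ mm, base
300 mm behind the fulcrum on the insertion axis, scope length 350 mm — all
configurable. Any geometry satisfying the reachability invariants
demonstrates the method; the kinematic tests run against an independent
homogeneous-transform oracle and enforce a fulcrum residual below
$10^{-9}$ mm and forward/inverse round trips below $10^{-6}$ mm.
A withdrawn scope ($d<0$) raises a `retracted` condition rather than being
clamped; the trial engine treats such samples as out-of-cavity rather than
failing a whole trial.

Conventions: right-handed cavity frame with origin at $F$, $+z$ into the
cavity, $+y$ superior; millimetres and degrees at every API surface,
radians internally. Roll zero points the optic toward $+y$; positive roll
is clockwise seen from the eyepiece.

## The oblique optic and the focus score

A 30-degree endoscope's optical axis is tilted $30^\circ$ from the shaft;
rolling the scope sweeps the view over a cone, which is precisely the skill
the exercise trains. The camera is a pinhole with a $70^\circ$ horizontal
field of view at $640\times480$ px (focal length $\approx 457$ px); the
optical coupler keeps the image horizon gravity-aligned, so the image
up-vector is the projection of $+y$.

Each target is a black annulus (outer radius 6 mm, inner 4 mm) around a
2 mm LED. The on-screen reticle is an ellipse fixed at the principal point
(semi-axes 40 and 28 px by default — the difficulty knob). The focus
accuracy is the percentage of the reticle's area lying inside the ring:
both curves are approximated by polygons (the projection of a circle is an
exact conic; 64 vertices for ring boundaries, 128 for the reticle), and the
overlap is computed by Sutherland–Hodgman clipping against the convex ring
polygon followed by the shoelace area. A Monte-Carlo rasterization oracle
(uniform sampling inside the reticle, even-odd point-in-polygon test) is
kept in the test suite only, and the two agree within ±0.5 percentage
points over randomized configurations. Whether "inside the black ring"
means the outer or the inner boundary of the annulus is ambiguous; the
outer boundary is the default and the choice is a parameter.

A target counts as *focused* when the overlap is 100% (boundary
inclusive). Targets seen at less than $5^\circ$ to the ring plane, partly
behind the image plane, or outside a $120^\circ$ viewing cone are reported
as degenerate/not visible and score zero at the press.

## Target layout and ideal focusing poses

The cavity is a simplified triangular prism: 60 mm deep from the internal
os to the fundus, 40 mm between the cornua, 25 mm anteroposterior. The ten
markers sit at the standard anatomical stations (fundus, both cornua, both
tubal ostia, anterior/posterior/lateral walls, isthmus), left/right pairs
mirrored in the sagittal plane, normals tilted toward the entrance as real
cavity walls funnel toward the os.

No per-target scope orientations are published, so each target's *nominal
roll* is derived geometrically: find a tip pose whose view ray passes
through the marker centre at the working distance (30 mm, capped at 55% of
the marker's distance from the fulcrum so near-entrance targets remain
viewable by a forward-oblique optic), with shaft through the fulcrum and
the view ray, shaft and insertion axis coplanar. That closure is a 1-D root
find; the roll realising the resulting view is the nominal roll. For an
*arbitrary* roll the shaft direction is re-solved by a damped fixed-point
iteration started from the coplanar solution. This is what lets a simulated
(or real) user hold a target focused with an imperfect roll — and it is why
large orientation errors can coexist with high focus accuracy, a pattern
these studies report.

## The trial protocol

A trial presents the ten targets in one of five randomised orders (fixed
by the master seed, assigned round-robin over trials so every trial block
sees each order equally — reproducible, and no order is memorisable). Each
target allows 30 s; the first pedal press is binding and the accuracy is
evaluated at exactly the logged press sample; on timeout the target scores
0 and the trial advances — this keeps the per-trial mean accuracy
well-defined, which the protocol description leaves open. The encoder
stream is sampled at 100 Hz, fine enough that path-length discretisation
error stays below 0.1%.

## The synthetic cohort

Each synthetic subject carries five skill channels: per-trial time budget
(s), path jitter (mm of tip wobble), roll error (deg), terminal aiming
error (deg), and self-assessment noise (score points). Channel $m$ on
trial $i$ follows an exponential approach
$\mathrm{level}_m(i) = c_m + (a_m - c_m)e^{-k_m (i-1)}$. The *analysis*
fits $a + b\ln(\mathrm{trial})$; using a different generative family than
the fitted one avoids validating the fit against itself.

A reach is a minimum-jerk profile in shaft space (tilt about the fulcrum,
insertion depth, roll) toward the focusing pose solved at that approach's
roll error, corrupted by smooth low-frequency jitter (sum of three random
sinusoids, 0.4–1.6 Hz, windowed to vanish at both ends) and a terminal
aiming offset. Fixation then alternates looking and correcting: every
0.1 s the agent compares a *perceived* score — true score plus an
overconfidence bias equal to one noise SD plus Gaussian noise — against
100, and either presses or moves 45% of the way to the exact pose. Early
trials therefore show the small exploratory movements around the target
that disappear with training, and presses at imperfect focus; late trials
are direct and steady. Perception noise decaying with practice produces
the accuracy learning curve without modelling vision.

Default priors define three experience classes (novice/intermediate/
expert, mixed 40/40/20) with lognormal subject-level spread (σ = 0.18).
The class means were chosen once so that the cohort's initial and final
levels sit at the scale such validation studies report (initial trial
times around 2.5 min falling toward ~1.3 min; path lengths around 2 m
falling toward ~0.9 m; orientation error improving least; accuracy
improving toward saturation). Two departures from real cohorts are known
and deliberate: simulated accuracy saturates higher than real trainees'
(high 90s rather than high 80s — the perception model is still too honest),
and economy-of-movement ratios are normalised by a straight-tip-path
baseline whose published counterpart is undefined, so only their trends,
not magnitudes, are comparable. Passing tests therefore show the pipeline
reproduces the *qualitative* structure of real learning curves — signs,
orderings, shrinking dispersion, inter-metric correlation — never the
proprietary numbers.

The straight-tip baseline itself is a strict lower bound: pivoting through
a fulcrum makes tip paths arcs, so even the noiseless agent's translation
economy is ~1.2, not 1.0. The rotation baseline and the translation
baseline both include the entry leg from the home pose.

## The statistical battery

Per-trial metrics (execution time, mean accuracy, mean wrapped orientation
error, trajectory length, total rotation, two economy ratios) are reduced
to one value per subject over the initial (1–3), middle (14–16) and final
(28–30) trial subsets; pairing is by subject, so the subset comparisons
use per-subject means, not pooled trials — the published tables do not say
which; this choice is declared, not inferred. Each comparison reports
means, SDs, gain ratio and difference, a two-sided paired t-test with 95%
CI, post-hoc power from the noncentral-t distribution at the observed
standardized effect, and the smallest n reaching 80% power at that effect
(integer bisection on the same formula). No multiple-testing correction is
applied across the seven metric rows by default (a Holm option exists),
matching how such tables report raw p per row. Degenerate paired data
(identical differences) yield t = 0, p = 1 rather than an error. Learning
curves report per-trial mean/median/quartiles and the log fit; Pearson
correlations are computed over all subject × trial rows.

## Problem sizes and reproducibility

The shipped study size is 80 subjects × 30 trials × 10 targets at 100 Hz
(about two minutes of compute for the full cohort); tests exercise scaled
versions of every property and the full cohort once. Every stochastic
function takes an explicit seed and uses an isolated RNG scope; a run is
bit-reproducible from (configuration, seed), and the configuration's MD5
fingerprint is stored in every session log header. Session logs are JSON
Lines with doubles printed at 17 significant digits, so write → read →
write is byte-identical.

```{r, eval = FALSE}
cfg <- default_config(n_subjects = 8, n_trials = 30, seed = 1)
res <- run_pipeline(cfg, out_dir = "run")
res$analysis$ini_vs_fin
plot(res$analysis$curves$exec_time_s)
```

## Known limitations

* The arm geometry is illustrative; results about the *method* (pose
  recovery, scoring, statistics) transfer, dimensions do not.
* No encoder noise, backlash or calibration error; no lens distortion; no
  biomechanical tremor or fatigue model.
* The reticle's eccentricity and its relation to the oblique optic are
  conventions, as is the outer-boundary reading of the ring.
* Orientation scoring uses a single nominal roll per target; a per-target
  band of valid orientations would be the natural refinement.
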