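---
title: "The HPBU model: hierarchical belief updating for handwriting perception, production, and sense of agency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The HPBU model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model in one page

`hpbu` implements a four-level active-inference hierarchy over 2D pen
trajectories.  From the top down:

* **Schema level (C)** — clusters of similar action sequences (one cluster
  per way of writing a digit, under the packaged corpus).
* **Sequence level (S)** — stored sequences of discrete stroke events, each
  event a relative polar angle, a stroke length, and an inter-event delay.
  The same representations serve recognition and production.
* **Vision level (V)** — converts the incoming trajectory into a belief
  over 16 discrete writing angles at every sample and segments the stream
  into *surprise events* wherever the current heading is improbable under
  the recent past.
* **Motor Control (M)** — a single-joint damped-spring plant whose
  equilibrium point is set to the next stroke subgoal.  It has **no**
  direct feedback connection to the Sequence level: when it reaches a
  subgoal it notifies the Vision level over a long-range connection, and
  only visually confirmed movement is forwarded upward.  This is what
  makes the model easy to fool with substituted visual feedback, which is
  the point of the study design.

Every belief level holds a normalized distribution over its hypothesis set
and is updated by the same rule.  With a top-down signal $P_{td}$ and a
bottom-up signal $P_{bu}$, the level free energy is the cross entropy

$$F = H(P) + D_{KL}(P\,\|\,Q) = -\sum_i P_i \ln Q_i ,$$

where in perception $P = P_{td}$, $Q = P_{bu}$ and in production the roles
are swapped (the driving signal inverts with the mode).  The new level
posterior is a Kalman mix,

$$K = \frac{F}{F + \pi}, \qquad
  P_t = P_{bu} + K\,(P_{td} - P_{bu}) \;\; \text{(perception)},$$

with the roles again swapped in production, and $P_t$ becomes the next
step's empirical prior.  Note the direction of the gain: *high* free
energy shifts weight onto the top-down prediction.  This is the reverse of
the usual predictive-coding convention; it is implemented deliberately as
stated in the source formulation, and the consequences for the agency
estimator are discussed below.

## Event segmentation and the oculocentric frame

The Vision level computes the heading of every displacement and spreads it
over 16 circular bins with a von Mises kernel ($\kappa = 8$, chosen so
that roughly 90% of the kernel mass falls on the true bin and its two
neighbours).  A predictive distribution over bins is maintained as an
exponentially discounted mixture of past angle beliefs (decay
$\lambda = 0.8$).  The surprise of a new sample is
$-\ln P_{pred}(\text{mode bin})$; when it exceeds 2.5 nats (after a 3-sample
burn-in, with a 3-sample refractory period after each event) an event is
emitted, anchored at the current pen position, and the gaze anchor is reset
there.  Events are coded *oculocentrically* — relative polar coordinates
with the previous event's anchor at the origin — so recognition is
invariant to translation and uniform scaling of the trajectory.

Two conventions the formulation leaves open are fixed as follows:

* The first event of a trajectory uses the trajectory start as its anchor
  and has `dt = 0`.
* Pen-up is treated as a maximally surprising boundary: a terminal *flush*
  event closes the final stroke.  Without it, straight single-stroke
  characters (the 1- and 7-analogues) would yield one event at most and
  could never be represented as sequences.

## Sequence comparison and temporal binding

An observed event prefix $s'$ is compared with a stored sequence $s_i$ by
aligning positions and taking the geometric mean of per-event Gaussian
kernels on the circular angle difference ($\sigma_a = 2\pi/16$) and the
length difference ($\sigma_l = 0.25$ of the stored event length);
observations that overrun a shorter hypothesis pay $e^{-0.5}$ per extra
event.  The geometric mean keeps the score $\iota \in [0,1]$ and
independent of prefix length.  The full likelihood adds the
temporal-binding factor on the newest event's delay,

$$P(s'|s_i) = \iota(s', s_i)\;
  e^{-(s'_{\Delta t}-s_{i,\Delta t})^2 / (2\pi_S^2)},$$

with $\pi_S = 0.15$ s.  As $\pi_S \to \infty$ timing becomes irrelevant;
as $\pi_S \to 0$ any timing error annihilates the likelihood.

For **schema clustering** (an implementation concern, not part of the
inference machinery) the package uses a gap-tolerant global alignment of
the same kernels (`elastic_iota`, gap cost $e^{-1}$ per skipped event,
normalised over the longer sequence) with single-linkage clustering cut at
similarity 0.6.  The reason is robustness: segmentation occasionally drops
a marginal corner in roughly one exemplar in fifty, and under strict
positional alignment one missing event shifts every later comparison and
splinters that digit's cluster.  Online recognition keeps the strict
prefix score, which is cheap and causal.

## Intention gating and production

Production is licensed only by an intention: a gating signal that marks a
target schema, multiplies its posterior by a boost factor (3.0) at *every*
schema update while active — a maintained boost, required to suppress
spontaneous switches to momentarily better-explaining schemas — and
selects the member sequence with the highest current posterior as the
intended sequence $s_I$.  During production $s_I$ may hand over to a
sibling within the same schema if that sibling's posterior exceeds twice
its own.  Without an intention no motor goal is ever emitted.

The Motor Control plant integrates

$$\varphi = \varphi_{x_i} - \varphi_{\dot y}, \quad
  \dot\varphi = \gamma\,\varphi\,e^{-\mu|\varphi|}, \quad
  g = (x_i - y)\,\dot\varphi, \quad
  \ddot y = \alpha(\beta(x_{i+3} - y) - \dot y) + g,$$

with $\alpha = 25$, $\beta = 6.25$ (critical damping of the linear part),
$\gamma = 10$, $\mu = 1/\pi$, semi-implicit Euler at 1 ms, and pen samples
emitted at 100 Hz.  $\varphi$ is the bearing to the active subgoal minus
the velocity heading (wrapped to $(-\pi,\pi]$); at zero velocity the
heading is undefined and $g = 0$ for that step.  A config switch
(`phi_mode = "bearing"`) exposes the alternative reading of $\varphi$ as
the absolute bearing.

Two consequences of these constants shaped the implementation:

* **Goal densification.**  With one subgoal per stroke corner, the
  lookahead target $x_{i+3}$ lies several strokes ahead and the
  goal-forcing term (bounded by $\gamma/(e\mu) \approx 11.6\,\mathrm{s^{-1}}$
  times the distance) is an order of magnitude weaker than the core spring
  ($\alpha\beta = 156\,\mathrm{s^{-2}}$); the pen then heads straight for
  the lookahead and provably never visits intermediate corners.  The plant
  therefore upsamples each stroke into a train of goals spaced 0.05 canvas
  units apart, which the 3-goal lookahead tracks locally; the lookahead is
  clamped at the stroke's event subgoal so corners are planted before the
  next stroke begins.  Intermediate goals advance on arrival (within half
  the spacing) or on their share of the stroke's timing goal, whichever
  comes first; the event subgoal itself must be reached within 5% of the
  stroke length (timeout 2 s).
* **Timing goals are honoured.**  The Sequence level sends position *and*
  timing goals.  The plant holds at the subgoal attractor until the
  stroke's $\Delta t$ has elapsed (the done signal fires at
  `max(arrival, schedule)`).  If the plant instead ran free, its arrival
  times would systematically disagree with the learned delays and Eq.-4
  binding would penalise even perfectly congruent self-produced actions —
  the congruent production scenario would then show the same low agency as
  the incongruent one, which inverts the phenomenon the model exists to
  reproduce.

When a subgoal is done, the Vision level checks whether the visual stream
confirms the movement: the most recent visual surprise event within 2
sampling periods of the done time if one exists, otherwise the visual pen
position at the done time, must lie within 25% of the stroke length of the
subgoal.  Confirmed events are forwarded to the Sequence level as if
perceived; failed confirmations forward nothing and leave the free energy
unexplained.  The position fallback matters because spring-produced
corners are smoother than corpus corners, so their surprise can fire a few
samples late; without the fallback even veridical feedback would
frequently fail its own confirmation.

## The sense-of-agency estimator

Once per done signal, the agency estimate is updated from the intended
sequence's likelihood:

$$K_t = \frac{F_S}{F_S + \pi_S}, \qquad
  \hat a_t = \hat a_{t-1} + K_t\,(P(s'|s_I) - \hat a_{t-1}),$$

with $\hat a_0 = 0$ and the likelihood taken as 0 on steps whose
confirmation failed (the predicted outcome was not observed).  The $\pi_S$
in this gain is the Sequence level's belief-update precision (default 8,
dimensionless in nats), not the temporal-binding width in seconds; the
source formulation uses one symbol for both quantities, but only the
former is commensurable with $F_S$.  The update is convex, so the trace is
bounded by its inputs and the one-step change never exceeds $K_t$ —
fluctuations are dampened.  There is a genuine tension in this estimator:
*higher* $F_S$ (worse prediction) raises $K_t$ and therefore the speed at
which the estimate tracks the likelihood, in both directions.  It is
implemented exactly as stated; in practice the low likelihoods that
accompany high free energy dominate, so incongruent trials still end low.

## Per-level precision

The precisions $\pi$ are the model's only free constants; the source
formulation never states how they are set.  The gain baseline matters: at
near-uniform beliefs the sequence-level free energy is already
$\approx \ln 90 \approx 4.5$ nats simply because the hypothesis space is
large, so with $\pi_S = 1$ the gain sits at $\approx 0.82$ and the
posterior stays glued to the top-down prediction — bottom-up evidence can
never accumulate and even noiseless known digits are not recognised.  The
package defaults scale the precision to roughly twice the level's baseline
entropy: vision 1.0 (16 bins), sequence 8.0 (90 sequences), schema 2.0
(9–10 schemas).  All three are configuration entries, and sensitivity to
$\pi_S$ is the first thing to explore when adapting the model.

## The synthetic corpus

The demonstration corpus the original study used (ten handwritten
exemplars of each digit, recorded on a tablet) is not deposited, so the
package generates a synthetic analogue: ten parametric single-stroke digit
templates — control polygons on a unit canvas with stylised, angular
shapes — jittered per exemplar by rotating each polygon segment by
$\mathcal N(0, 0.1\,\mathrm{rad})$, scaling each segment length by
$\mathcal N(1, 0.05)$, and scaling the duration by $\mathcal N(1, 0.05)$,
then sampled at 100 Hz with a minimum-jerk (bell-shaped) speed profile
along a lightly smoothed path.  Child seeds derive from the master seed
with a counter, so corpora are exactly reproducible.

Three generator choices are deliberate and worth knowing about:

* **Angularity.**  Template corners turn by at least ~65°, because the
  surprise segmenter (threshold 2.5 nats over 16 bins) fires reliably only
  for heading jumps of two to three bins within a couple of samples.
  Gently curved digits would segment unstably, which is a property of the
  segmentation model, not of handwriting.  The corpus is therefore
  *stylised* handwriting: it emulates the structure of the original corpus
  (10 digits × 10 exemplars, per-sample timing, controllable noise), not
  its curvature statistics.
* **Tempo.**  Durations are 1.9–4.5 s per digit, matched to the plant's
  intrinsic writing speed (about 0.5–0.7 canvas units/s given
  $\alpha, \beta$).  A corpus written much faster than the plant can move
  would make the learned timing goals unproducible and temporal binding
  meaningless in production.
* **Single strokes.**  The hierarchy has no pen-up concept, so 4 and 5 use
  one-stroke cursive-style forms.

Consequently, passing tests show that the *mechanisms* work — surprise
segmentation, oculocentric coding, likelihood-driven belief updating,
gating, equilibrium-point control, agency accumulation — on data with the
study's structure.  They do not show that the pipeline handles natural
curvature, pen lifts, co-articulation, or writer-to-writer variability.

## Scenarios and standard conditions

The scenario runner reproduces the four study conditions: (a) perceive a
known digit (5-analogue), (b) perceive a digit unknown to the repertoire
(4-analogue; the standard training corpus excludes the fours), (c) produce
a digit with veridical visual feedback (9-analogue), (d) produce the
1-analogue while the Vision level replays a 3-analogue (proprioception,
internal to the plant, stays correct).  One hierarchy update runs per
vision sample, levels updated top-down (Schema, then Sequence, then
Vision) with one-step-lagged upward messages; production updates once per
done signal.

Problem sizes used throughout the tests and the acceptance script: 90–100
training trajectories (10 per digit), 2–7 events per sequence, 10–11
schemas, trajectories of 200–450 samples; training takes a few seconds and
a scenario under a second on one core.

## Numerical choices and degenerate inputs

* Probabilities are floored at $10^{-10}$ before any logarithm and
  renormalized; surprise is capped correspondingly.
* Zero displacement yields a uniform angle belief ("no motion"), which can
  never fire an event; zero velocity sets the forcing term to zero; a
  zero-length stroke event has angle 0 by convention.
* Ties in the intended-sequence selection break toward the lowest id;
  schema ids are assigned in order of first member appearance, making
  clustering deterministic for a given input order.
* All randomness flows through explicit seeds (master seed, per-exemplar
  child seeds, per-scenario stimulus seeds); identical seeds reproduce
  corpora, repertoires, and trial logs byte for byte.

## Known limitations

* Online learning of new sequences or schemas is out of scope; perceiving
  an unknown digit leaves free energy high (by design) but nothing is
  added to the repertoire.
* The corpus is stylised and single-stroke, as discussed above.
* Recognition of *self-produced* trajectories can occasionally
  mis-attribute a digit whose produced corners are smoother than its
  corpus corners (about one digit at two of seven corpus seeds tried
  during development); the standard-seed conditions are stable.
* The agency estimator inherits the gain tension noted above; with very
  high sequence precision it would become sluggish in both directions.
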