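---
title: "Models and methods behind satkit"
author: "satkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind satkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satkit)
```

# The experiment being modeled

In automated homecage sensory association training (SAT), a singly housed
mouse initiates trials by breaking an infrared beam at a nosepoke. After a
uniform random delay of 200–800 ms — there so the animal associates the
reward with the stimulus rather than with its own operant act — a 500 ms
multiwhisker air puff is delivered; 500 ms after puff offset, water flows
for 75 ms (about 15 µL at the 0.2 µL/ms calibration). A 925 ms break
follows, and no trial can begin until 2 s after the previous (virtual) puff
onset. On 80% of initiated trials (50% in the reduced-contingency variant)
the stimulus and reward are delivered; the remaining trials are *blanks*:
a sham relay clicks at stimulus time but nothing is delivered, so auditory
relay cues are matched across trial types. The lick sensor and IR beam are
polled every 100 ms.

Learning is read out as *anticipatory licking*: licks in the 700–1000 ms
window after the (virtual) puff onset, i.e. the 300 ms directly before
water delivery. The per-condition metrics are the mean anticipatory rate on
stimulus trials ($L_w$), on blank trials ($L_b$), and the performance
$L_w - L_b$, binned in 4-hour intervals; an animal counts as a learner when
$L_w > L_b$ over the last 20% of its trials.

satkit reproduces this pipeline end to end without animals or hardware: a
discrete-event controller simulator, a parametric synthetic mouse, the lick
analysis, a whisker motion-energy module, and the group statistics.

# The controller simulator

`runSession()` runs the event loop. The agent proposes nosepoke times; the
controller accepts one as a trial only when the lockout since the previous
(virtual) puff onset has elapsed and any post-water break is over (it
enforces the maximum of the two constraints — under the default timings the
2 s lockout exactly equals puff + gap + water + break, so neither
dominates). Trial types are assigned i.i.d. Bernoulli per trial; no
balancing blocks are used, matching a controller that only fixes marginal
percentages.

**Blank-trial timeline.** Whether blank trials run the same internal
schedule as stimulus trials is not observable from outside the apparatus.
satkit has blank trials sample a delay and defines a *virtual* puff onset
at nosepoke + delay, where the sham relay clicks; lick alignment uses that
time. This choice makes blank and stimulus trials exactly comparable in the
analysis, and the 2 s lockout is enforced from the virtual onset so pacing
is identical across trial types. The convention is recorded in every log
header.

**Time base.** The controller works in integer milliseconds. Actuation
events (puff, water, relay) are logged at exact times — they are
relay-driven. Sensor events (nosepokes, licks) are quantized to the 100 ms
polling grid: an event is stamped at the polling update that *follows* it,
as a polled sensor reports. The direction of that rounding matters: stamping
at the preceding tick would drag early consummatory licks backward across
the water-onset boundary into the anticipatory window and inflate $L_w$ by
roughly 0.7 Hz on every rewarded trial; stamping at the following tick
leaves the measured rate of any stationary lick stream unchanged. The exact
nosepoke time is additionally carried in the event payload so per-trial
delays can be reconstructed from a log alone.

**Seeding.** Each session derives independent child streams (Lehmer-mixed
32-bit seeds) for trial type, delay, initiation and within-trial agent
behavior. Replaying a seed reproduces the log bit-exactly, and changing the
agent cannot perturb the trial-type or delay sequences.

# The synthetic mouse

The agent is a generative stand-in for the behavioral regularities the
paradigm elicits; it makes no claim about the animal's learning mechanism.

* **Associative state.** A single association strength $a \in [0,1]$
  follows an exponential-approach update: after each *detected and
  rewarded* pairing, $a \leftarrow a + \eta(1-a)$. This is the simplest
  monotone rule with an asymptote; after $k$ such pairings
  $a = 1-(1-\eta)^k$. Default $\eta = 0.01$.
* **Anticipatory rate.** On stimulus trials the expected lick rate is
  $r = [b + a(A-b)]\,[1 - s_0 e^{-n/\tau}]$ with baseline $b = 2$ Hz,
  asymptote $A = 8$ Hz, novelty suppression $s_0 = 0.5$ decaying over
  $\tau = 50$ trials. Blank trials always run at baseline. The
  multiplicative novelty term makes naive animals lick *less* on stimulus
  than on blank trials at training onset — the habituation dip — after
  which performance rises smoothly.
* **Why 8 Hz.** Anticipatory licking is rhythmic at roughly 8–10 Hz. The
  100 ms polling sensor cannot count above 10 Hz, and for Poisson emission
  the measured rate is $10(1-e^{-r/10})$ Hz: an 8 Hz asymptote reads out
  near 5.5 Hz, the scale real learners show. Note the consequence tested in
  the suite: Poisson licking at 10 Hz is *measured* at $\approx 6.3$ Hz,
  and only a perfectly regular 10 Hz stream saturates the ceiling.
* **Lick emission.** Licks are an inhomogeneous Poisson process,
  piecewise-constant per trial: baseline from nosepoke to puff onset, the
  anticipatory rate from onset to water time, a consummatory rate (8 Hz)
  after water. The learned rate is expressed only on stimulus trials the
  agent actually *detected* (and, in discrimination mode, only for the
  rewarded direction); an undetected puff is behaviorally a blank. Without
  this gating, a barbered (whiskerless) or low-intensity agent could not
  fail to learn, which is the phenomenon those conditions exist to show.
* **Detection and dropout per intensity.** `agentDefaults()` maps the psi
  label to detection probability (2 psi → 0.4, 6 psi → 0.9, 9 psi → 0.95)
  and a per-trial dropout hazard (0, 0, 8×10⁻⁴). These are configuration,
  not claims: they are chosen to reproduce the qualitative ordering — weak
  stimuli are missed, the aversive high intensity makes a substantial
  fraction of animals stop initiating during a 48 h session — and every
  value is overridable. At 8×10⁻⁴ per trial, about half the simulated
  9 psi animals drop out within a ~900-trial session.
* **Trial initiation.** Nosepokes are an inhomogeneous Poisson process
  (default 20/hr) with sinusoidal diurnal modulation (default amplitude
  0.5) peaking at 01:00, mid-dark-phase for a 7:00–19:00 light cycle.
  Homecage initiation counts visibly oscillate across light and dark, but
  no quantitative diurnal statistics are available to fit, so the
  amplitude is an arbitrary but fixed default.

# The lick analysis

All licks are re-expressed relative to their trial's (virtual) puff onset;
a lick belongs to the trial whose `[nosepoke, next nosepoke)` span contains
it. Debouncing keeps at most one lick per 100 ms period on a grid anchored
at the puff onset, so the scoring window spans exactly three periods and
the measurable rate is capped at 10 Hz. The window is half-open
`[700, 1000)` ms after onset: the description "after the random delay" and
"300 ms directly before water delivery" coincide exactly under this
reading, since water arrives 1000 ms after puff onset.

Choices where the source description is ambiguous:

* **Empty bins are missing, not zero.** Zero is a meaningful lick rate; a
  4-h bin with no blank trials carries `NA` for $L_b$.
* **Last 20% over the full training phase,** all trial types in time
  order, acclimation excluded — not per day. The convention is recorded in
  the log header.
* **Trial-boundary licks.** Consummatory licking after water can in
  principle bleed toward the next trial; the interval-assignment rule plus
  the 2 s lockout means such licks land before the next trial's onset and
  can never enter its scoring window.
* **Discrimination mode** treats unrewarded-direction trials as the blanks
  for $L_b$.

# Whisker motion energy and bouts

`motionEnergy()` convolves each frame with a quadrature Gabor bank
(default 4 orientations × 3 spatial frequencies, 15×15 kernels,
zero-mean), applies two small temporal derivative filters across frames
(first and centered difference — two temporal scales), and averages the
squared quadrature magnitude over pixels and filters per frame. The bank
size is a small standard default; the source procedure names no
parameters, and every element is configurable. Temporal filter outputs are
aligned to their last tap (frame *t* carries the energy of the change
arriving at *t*) and edges are replicated so the trace keeps the video's
length.

Normalization subtracts the mean of the values at or below the 20th
percentile of the 1.2 s pre-stimulus window ("low 20th percentile ...
averaged" is read as averaging that subset). The whisking threshold is
mean + 3 SD of the *normalized* pre-stimulus baseline. Bouts are maximal
strictly-supra-threshold runs of at least 0.5 s, at sample resolution (a
run of $k$ frames lasts $k/f$ s; no sub-frame interpolation). Percent
whisking counts trials with a bout overlapping the 1–2 s post-onset window
by at least 0.5 s — the window is exposed as a parameter because the puff
itself lasts only 0.5 s and the 1 s offset excludes passive resonance.

The synthetic video generator renders a bright ~2-px filament whose tip
follows a prescribed deflection, with optional Gaussian pixel noise, and
returns the ground-truth tip track. It emulates one dominant moving
structure on a dark background — the situation after cropping to the
whisker field — and deliberately not whisker identity, occlusion, fur
texture or illumination drift; end-to-end tests passing on it show the
filter chain recovers known motion epochs, not that tracking real video is
solved.

# Statistics

`pairedSignedRank()` wraps the two-sided Wilcoxon signed-rank test on
per-animal $L_w - L_b$ pairs: zero differences are dropped before ranking
(the count is always reported; all-zero input returns $p = 1$ with zero
effective pairs), the exact null distribution is used for $n \le 25$
without ties, and the continuity-corrected normal approximation otherwise.
Fewer than 5 pairs is refused outright — the exact two-sided test cannot
reach $p < 0.05$ below that. The test is applied across animals (one pair
per animal), recorded in the output metadata, since applying it across
trials within an animal would pseudo-replicate.

`groupCompare()` runs the Kruskal–Wallis omnibus test, then Dunn z
contrasts on the pooled ranks with tie-corrected variance and Šidák
adjustment $p_\mathrm{adj} = 1-(1-p)^m$. Contrasts default to
each-group-versus-a-reference (the medium-intensity group in intensity
comparisons) rather than all pairs, which keeps $m$ small; all pairs are
available. A pooled zero-variance input is reported as degenerate rather
than tested.

# Verification strategy and problem sizes

The test suite checks every operation against an independent oracle where
one exists: bout detection against a brute-force run-length scan, the
signed-rank p against full enumeration of the $2^n$ sign assignments,
baseline subtraction against explicit percentile-subset averaging, motion
energy against a frame-difference oracle (rank correlation), displacement
areas against closed-form integrals, and the associative update against
its closed form.

Cohort-level checks run at these sizes, chosen to finish in minutes on one
core while keeping each per-animal estimate well conditioned:

* contingency fractions: 10,000 assignments per condition, judged at the
  99% binomial CI;
* null preservation: 1,000 non-learner animals, 8 h sessions at
  40 trials/hr with flat diurnal modulation, so each last-20% subset has
  ~64 trials and a defined $L_b$; mean performance must sit inside the
  99% CI of 0 and the learner fraction at chance;
* parameter recovery: 20 replicate cohorts of 15 learner animals, 48 h
  sessions; the signed-rank test must reject in ≥90% of cohorts and
  >80% of animals must satisfy $L_w > L_b$;
* bout rule: 1,000 randomized 10 s traces against the oracle.

Monotonicity of the learning trace is assessed on the cohort-mean binned
performance via the isotonic-regression fit: the best non-decreasing fit
must capture >90% of the trace's variance, alongside a net-rise check. A
fixed additive slack would misstate the noise, which is heteroscedastic
because diurnal modulation concentrates trials in night bins (roughly
520–1430 stimulus trials per 4-h bin across a 15-animal cohort).

What passing these tests shows — and what it does not: the pipeline
recovers the structure its generative model puts in (rates, orderings,
null behavior) under Poisson licking and i.i.d. trial assignment. Real
lick streams are rhythmic and autocorrelated, real dropout is not a
constant hazard, and real whisker videos contain far more than one moving
filament; conclusions about live-animal data rest on the shared analysis
conventions, not on these simulations.

# Known limitations

* The associative update, novelty decay and detection gating are the
  simplest rules with the right asymptotics; trajectories other than
  smooth saturating curves (relapses, overnight consolidation steps) are
  out of reach.
* Low-intensity training that succeeds over 72 h cannot be attributed to
  slower learning versus fewer detections — the parameterization makes
  the two indistinguishable by construction.
* The 100 ms sensor model is a hard ceiling: any comparison of measured
  rates above ~8 Hz compresses severely, exactly as in the real apparatus.
* Pixel-to-mm scale for whisker displacement is a user input; without it,
  outputs are in pixels.

# A worked session

```{r quick-session}
cfg <- SessionConfig(session_duration_hr = 8)
log <- runSession(cfg, agentDefaults(6, init_rate_per_hr = 40), seed = 1)
log
ana <- analyzeLog(log)
head(ana$bins)
ana$result
```
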