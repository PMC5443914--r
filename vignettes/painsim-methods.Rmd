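---
title: "painsim: model, scoring and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{painsim: model, scoring and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painsim)
```

`painsim` is a headless re-implementation of the computational core of a
serious game that teaches surgical patients how to manage postoperative
pain at home: a simulated avatar whose pain the player manages over
three in-game days with medication, rest, distraction and household
activity, followed by an after-action review, plus the questionnaire
scoring and pre/post statistics used to evaluate such a game. This
vignette is the package's own account of the model, its parameters, and
the design choices that were genuinely open.

## The pain model

Pain lives on the 0-10 numeric rating scale (NRS). Time advances in
steps of `dt` in-game minutes (default 5; 288 steps per 24-hour day,
which runs 09:00 to 09:00). At each step pain relaxes toward an
attractor,

$$\mathrm{target}(t) = \mathrm{clamp}\big(b(t) - \min(c, \textstyle\sum_i r_i(t)) + a(t),\; 0,\; 10\big),$$

$$p_{t+\Delta} = \mathrm{clamp}\big(p_t + (1 - e^{-\lambda \Delta})(\mathrm{target}(t) - p_t),\; 0,\; 10\big),$$

where $b(t)$ is the baseline (no-intervention) pain, $r_i(t)$ the relief
of dose $i$, $c$ the relief cap, $a(t)$ the summed offset of transient
activity effects (negative while resting), and $\lambda$ the per-minute
relaxation rate (default 0.05, i.e. roughly a 20-minute time constant).
The clamp guarantees the invariant that pain never leaves $[0, 10]$,
for any policy and any seed.

**Baseline.** $b(t)$ interpolates piecewise-linearly between per-day
anchor values declining across the three postoperative days (9:00
anchors 7 → 6 → 5, with mild intra-day variation; adjoining days share
their boundary anchor so $b$ is continuous). The recovery context
implies decline; the exact trajectory is configuration
(`model_params.json`), not a claim about any published parametrisation.

**Dose relief.** Each dose contributes a triangular curve: zero until
`onset`, linear rise to `tablets × peak_relief` at `time_to_peak`,
linear decay to zero at `effect_duration`. This is the simplest
continuous shape with the required "relief begins after an onset time
and wears off" behaviour, and its area ($\tfrac12\,\mathrm{peak}\,
(\mathrm{duration}-\mathrm{onset})$ per tablet) is available in closed
form, which the tests exploit as an oracle against trapezoidal
integration. Summed relief is capped (default 8 NRS points) so that
stacking all four medications cannot trivially pin pain at 0.
Compartment models and plasma concentrations are deliberately out of
scope: the contract is qualitative.

**Medications.** Four defaults — paracetamol, ibuprofen,
paracetamol+codeine, tramadol — with conventional adult limits
(`medications.json`). All kinetics and limits are configuration; none
are claims about the original game's numbers. Over-limit doses
(per-dose, per-day, or inside the minimum interval) are *refused and
logged*, not simulated as overdose: the artifact targets education, and
limits are surfaced through refusals and side effects. Side-effect
rules fire at dose time when a trigger count is reached (e.g. nausea
when ≥ 3 codeine tablets are "loaded"). The trigger counts tablets
swallowed and not yet worn off — including the just-swallowed dose,
which a literal "in effect since onset" count would miss — while the
medication-board query `tablets_in_effect()` keeps the literal
`[onset, effect_duration)` window shown to the player. The codeine
dosing interval (240 min) is deliberately shorter than its wash-out
(360 min): if the interval equalled the wash-out, no legal sequence of
doses could ever stack tablets, and the nausea mechanism would be dead
code.

**Mobility.** Mobility falls linearly from 1.0 at pain 0 to 0.2 at
pain 10. Movement activities take `duration / mobility` minutes
(mobility sampled at the start of the activity and held, a
simplification), and are refused outright at pain ≥ 9. Rest and
distraction apply their negative `pain_effect` through the same
relaxation dynamics as medication — one dynamical mechanism, one set of
tests.

**Unmanageable-pain events.** Once per day, with configured probability
(default 0.3), an episode is scheduled at a uniformly drawn minute.
While active, pain is floored at NRS 8 and medication relief is
ignored. The help-line consult clears the episode and sets pain to
exactly 5 when it is above 5 — and never raises it when below, since
advice should not harm. A transient "advice" relief offset then holds
the attractor near 5 for 180 min (configurable): without it the
post-consult pain of 5 would relax back toward baseline within a step
or two, which would contradict the consult's stated effect in any
observable sense. Whether an episode still active at 09:00 should carry
into the next day was open; it does (no new draw can double it), since
ending it silently would reward ignoring the help line.

## Goals and stars

The three printed day goals are: day 1, take as little medication as
possible; day 2, keep pain under 3 whatever the side effects; day 3,
keep pain under 5 all day. "Under" is read strictly — a day pinned
exactly at the threshold achieves a fraction of 0. For threshold goals
the achieved fraction is the fraction of sampled steps strictly under
the threshold; for day 1 it falls linearly from 1 at zero tablets to 0
at a configurable ceiling (12 tablets). Stars: 3 at ≥ 0.95, 2 at ≥ 0.6,
else 1. The source material fixes only the 1-3 range and the goal
texts; the fraction-to-star map is declared configuration
(`goals.json`). Task completion is reported separately and does not
enter the rating, because the printed goals concern only medication and
pain.

## Telemetry and the after-action review

The log is append-only, non-decreasing in time (several entries may
share a step's timestamp; insertion order is preserved), and samples
pain every step, so the review's curve is dense rather than
event-driven. The review classifies each dose as a `dose` node and each
activity by the sign of its pain effect (`relieving` / `impairing`;
zero-effect activities produce no node — the legend defines only three
classes). Nodes falling inside a side-effect window carry an outline
flag. The log is a sufficient statistic of the day: replaying its
actions under the same seed regenerates the identical pain curve, which
is tested.

All randomness flows through a single Mersenne-Twister state owned by
the simulation, and every step consumes a fixed number of draws whether
or not anything random becomes visible. That costs a few wasted draws
but buys two properties the tests rely on: byte-identical replays under
a fixed seed, and aligned streams across counterfactual pairs (the
dose-monotonicity property compares two trajectories that differ by one
dose and nothing else).

## Instruments and statistics

Instrument definitions are JSON, not code. The packaged files enforce
the structural facts of the four instruments — AttrakDiff2: 28
seven-step semantic-differential items in 4 × 7 subscales scored
−3..+3; POP-MGS: 12 Likert items, 0-5; BQ-II: 27 Likert items, 0-5, in
four subscales; the knowledge test: 15 six-option multiple-choice items
with exactly one correct answer and a "do not know" option scored
incorrect, reported as percent correct. Item wording, pole orientation
(reverse keys) and BQ-II subscale membership are *not* derivable from
the source material; the packaged defaults are synthetic, flagged as
such in each file, and overridable — scores computed with them are
structurally correct but not comparable against any licensed form.
Missing items: excluded from subscale means with a warning
(questionnaires), counted incorrect with a flag (knowledge test),
pairwise-complete covariances (alpha), listwise (KR-20, signed-rank).

Descriptive summaries use the median and a Tukey-hinge IQR (`fivenum`);
the quantile convention was unstated, and hinges are the conservative
classical choice (a type-7 alternative is exposed). The Wilcoxon
signed-rank test discards zero differences by default (the classical
treatment; Pratt's method is available), ranks by absolute value with
average ranks for ties, and computes the p-value by full enumeration of
all $2^n$ sign assignments when the effective $n \le 15$ — exact even
under ties — switching to a normal approximation with tie-corrected
variance $\sum_i r_i^2/4$ (no continuity correction) above that.
Cronbach's alpha uses sample variances; KR-20 applies the matching
$n/(n-1)$ correction to its $p(1-p)$ item variances so that on a
complete binary matrix KR-20 and alpha agree exactly, which the tests
assert as an identity rather than an approximation.

## Synthetic agents

Policies operationalise the strategies the game teaches: no medication;
PRN dosing that waits for severe pain (NRS ≥ 7); scheduled within-limit
dosing; rest-and-distraction only; and a uniform random fuzzer over
legal actions. Synthetic respondents answer the knowledge test as
item-independent Bernoulli draws with per-item pre-test probability
0.54 and a post-test uplift of 0.17 on the probability scale — the
stated world's group-level pre/post proportions used as generator
defaults, not a reproduction of any human sample. (The model's uplift
field also accepts a log-odds scale.) Likert generators draw a rounded,
truncated Gaussian. What a green test establishes is therefore
calibration of the *pipeline* — type-I error near nominal under the
null model and high power under a +0.3 uplift at $n = 20$ — not realism
of human response styles (no acquiescence, fatigue or item
correlation).

## Numerical and degenerate-input conventions

* Activity durations round up to whole `dt` steps and truncate at the
  day boundary; the day always ends after exactly 1440 minutes.
* A policy action that does not advance the clock is followed by one
  idle step, so a day terminates for any policy.
* All-zero difference vectors make the signed-rank test degenerate:
  `W = NA`, `p = 1`, with a warning. Zero total variance makes
  alpha/KR-20 `NA` with a warning.
* Exact-test enumeration is refused above $n = 25$ (a contract error,
  not silence).
* Unknown medication, activity or instrument ids raise configuration
  errors; malformed policy actions raise scripting errors carrying the
  step index.

## Known limitations

The model is qualitative: no pharmacokinetics, no inter-individual
variability, no pain sources beyond the declining baseline and activity
offsets. Mobility is held constant within an activity. The instrument
definitions are structural stand-ins. The star thresholds, event
probability and all medication numbers are defaults of *this* artifact;
none should be quoted as properties of the original game.
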