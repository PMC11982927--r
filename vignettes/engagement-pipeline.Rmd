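---
title: "Quantifying social engagement in multiparty group sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying social engagement in multiparty group sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupengage)
```

## The problem

Group socialization sessions for older adults with Alzheimer's disease and
related dementias (ADRD) are a candidate intervention against the isolation
that accelerates cognitive decline. To tell which facilitation strategies
actually raise engagement, recorded sessions are decomposed into *events* —
self-contained interaction segments, typically opened by a facilitator
question and closed by the last response — and each event is scored by
trained raters on a 1–5 Likert engagement scale. The analytical task is to
relate those scores to what can be measured about the group: who spoke and
for how long, how many people joined in, which facilitator behaviors
occurred, and how prosodically similar consecutive speakers were.

`groupengage` implements that pipeline end to end:

1. **I/O** — Praat `PitchTier`/`IntensityTier` text files (both the long and
   the short dialect), diarization logs (Praat TextGrid interval tier or
   3-column TSV), and coded event sheets (CSV with the standard column
   layout).
2. **Turn structure** — speaker markers `H` (host), `C` (younger control),
   `F1..F9`/`M1..M7` (participants); `N` (noise) and `SO` (significant
   over-speak) spans are excluded everywhere. Intervals become turns;
   same-speaker intervals separated by at most `merge_gap` seconds merge.
3. **Prosody** — per-speaker, per-session Z-normalization of pitch and
   intensity, then six turn-level features (mean/max/min of each signal).
4. **Entrainment proximity** — mean absolute difference of each feature
   across sequential cross-speaker turn pairs, averaged within an event:
   one value per feature per event, smaller meaning interlocutors sit closer
   in prosodic space. Single-speaker events are excluded: they have no
   interlocutor pair.
5. **Time budget** — per-event speaker-group speech time, participant
   fraction of speech, and silence fraction; session-level speech shares;
   turn-length percentiles.
6. **Statistics** — individual-plus-joint linear model reports for the
   host, behavior, acoustic, time and general predictor families; one-way
   ANOVA with $\eta^2 = SS_{between}/SS_{total}$ and Tukey HSD after
   balanced downsampling; inter-rater percent agreement (exact, within-one,
   and their sum).
7. **Synthesis** — a generator that emits sessions in exactly the on-disk
   formats above with a planted linear engagement model, so every stage is
   testable without any recording.

## The engagement model

For event $i$ with predictor vector $x_i$ (eight binary behavior codes,
host one-hot with Host 4 as the all-zero reference, number speaking, and
the time-budget features), the engagement score is modelled as

$$ s_i = \beta_0 + x_i^\top \beta + \varepsilon_i, $$

fit by ordinary least squares. Each predictor is also fit alone
(`individual_and_total()`), reproducing the two-row-per-predictor report
layout used in this literature: an "individual" coefficient/SE/$R^2$/p and a
"total" (joint-model) coefficient/SE/t/p, with one shared total $R^2$, F
statistic against the constant model, and error degrees of freedom.
Likert scores are treated as a continuous response and events as
independent observations — both assumptions inherited from the modelling
tradition this package follows; neither a mixed-effects structure nor an
ordinal link is attempted (see Limitations). All p values are unadjusted
for multiple testing.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `merge_gap` (`build_turns`) | 0 | s | No published turn-boundary rule exists; 0 means only exactly adjacent same-speaker intervals merge. Bridged gaps widen a turn's span but never count as speech. |
| event–turn assignment | overlap > 50% of turn | — | A turn straddling an event boundary belongs to the event holding the strict majority of it; an exact 50% tie is excluded. |
| `sd_type` (`zscore_by_speaker`) | sample (n−1) | — | The convention matters only for tiny point counts; a population-SD switch is provided for sensitivity checks. |
| turn span membership | closed interval | — | Points at exactly `start` or `end` belong to the turn. Arbitrary but fixed and tested. |
| `pairs` (`sequential_pairs`) | cross-speaker | — | Entrainment is a between-interlocutor quantity; a same-speaker adjacent pair measures self-consistency. `pairs = "all"` retains them for sensitivity analyses. |
| `fraction_denominator` | speech | — | Participant fraction is participant time over *speech* time by default; a window-duration denominator is available since the phrase "percentage of time" does not pin one down. |
| silence definition | window not covered by H/C/F\*/M\* turns | — | Noise and over-speak spans are excluded from analysis upstream, so they count as silence, not speech. |

Normalization is computed over a speaker's **in-turn** points only: whether
the source analyses normalized over all of a speaker's audio is not
documented, and in-turn points are the only ones attributable to a speaker
from a diarization log alone. Speakers with fewer than two points or zero
spread cannot be normalized; their points are marked missing, and turns with
no voiced points yield missing pitch features that drop pairwise (per
feature, not per event) from proximity.

## The synthetic generator

`synthetic_config()` defaults emulate the kind of study this pipeline
targets: 30 sessions of 1800 s; one of four hosts per session (weights
0.40/0.31/0.22/0.07, following the hosts' shares of events, with every host
guaranteed to appear so the one-hot design stays full rank); a younger
control present in 28 of 30 sessions; 2–9 participants drawn from the
F/M pool. Events tile each session with lognormal durations
(median 20 s, `sdlog` 0.6, ≈60 events/session ≈ 1800 events per study);
within an event, 1–8 speakers rotate through a renewal process (lognormal
turn lengths, median 2 s; exponential gaps, mean 0.5 s). The host is
weighted 3:1 into event rosters and the control 0.5:1 with turn lengths
scaled by 0.4 — she joined conversations only occasionally and briefly.
Pitch baselines are ~190/210/200/120 Hz (host/control/female/male) with
20 Hz between-turn and 10 Hz within-turn spread; intensity ~65 dB with
4/2 dB spreads; tiers are sampled at `dt` = 0.1 s (coarser than Praat's
10 ms default — the statistics operate on turn summaries, which converge
long before that resolution matters).

Engagement is scored as $s = \mathrm{clip}(\mathrm{round}(\beta_0 +
x^\top\beta + \varepsilon),\,1,\,5)$ with planted $\beta$ defaulting to
magnitudes representative of published engagement-model fits and noise SD
0.6. Two numerical
constraints shaped the noise choice:

* **Dither.** The rounding step introduces a systematic sawtooth bias of
  amplitude $\sim e^{-2\pi^2\sigma^2}$ in coefficient recovery; at
  $\sigma = 0.6$ it is $\sim 10^{-3}$ and irrelevant, while at
  $\sigma \lesssim 0.45$ it is visible at $n = 2000$.
* **Clipping.** With the full-scale default magnitudes, a few percent
  of latent scores exceed the 1–5 range and are clipped — exactly as real
  Likert data saturate — which attenuates the largest coefficients by a
  fraction of a standard error. This is a property of Likert-clipped
  responses, not of the estimator. Estimator-calibration experiments
  therefore use `calibration_beta()`: half magnitudes, intercept 2.0
  (latent mean ≈3, clip active for <0.3% of events), and an exact zero
  planted on `game` for null-bias checks.

Entrainment strength `delta` pulls each turn's prosodic offset toward the
previous turn's within an event: offsets follow
$o_i = \delta\, o_{i-1} + (1-\delta)\, u_i$, $u_i \sim N(0, \tau^2)$.
At `delta = 0` the expected cross-speaker mean-feature proximity has the
closed form $2\tau/(\sqrt{\pi}\sqrt{\tau^2+\sigma_w^2})$
(`expected_proximity_delta0()`); at `delta = 1` consecutive turns share
one offset and proximity collapses toward the within-turn sampling floor.
One subtlety: empirical per-speaker Z-normalization estimates each
speaker's mean from $O(T)$ turns, leaving an $O(1/\sqrt{T})$ proximity
floor in multiparty sessions that masks the `delta = 1` limit. The dial is
therefore validated on dyadic calibration sessions (host + one
participant, both speaking in every event, `dt` = 0.02 s), where the two
speakers share every event's offset chain, the estimated baselines cancel,
and the limit is exact up to within-turn noise.

What the generator deliberately does **not** emulate: extreme-duration
events lasting tens of minutes (their per-second time features saturate
the score scale), real voicing structure and
octave errors in pitch tracking, overlapping speech (over-speak is emitted
only as excluded `SO` spans), topic content, and rater disagreement beyond
a memoryless discrete perturbation (exact/±1/±2 with probabilities
0.546/0.385/0.069). Passing tests therefore demonstrate that the pipeline
measures what it claims on schema-faithful data with known structure — not
that substantive findings about real groups generalize.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle: tier and
sheet readers against write-then-read identity; turn/event assignment
against brute-force overlap enumeration; normalization against direct
per-speaker mean/SD arithmetic; proximity against loop-free recomputation;
time features against a 1 ms grid-occupancy counter; OLS against the
closed-form normal-equations solution; Tukey HSD against a hand-computed
studentized-range probability. Statistical contracts run at fixed seeds:
coefficient recovery uses 200 replicates of ≈2000 events (29 sessions,
tiers off), checking per-coefficient ±2 SE coverage and null bias;
root-mean-square error scaling is checked by doubling the corpus size
(10 vs 20 sessions of 600 s, 80 replicates each); the entrainment dial
uses 3 dyadic sessions of 600 s per `delta`. These sizes were chosen so
the full suite completes in minutes while leaving Monte-Carlo error well
inside the asserted tolerances. `scripts/acceptance.R` recomputes the same
quantities from scratch at an arbitrary seed.

## Known limitations

* Events are modelled as independent; in real data they nest within
  sessions and share participants, so reported SEs understate uncertainty
  at the session level.
* The Likert response is treated as continuous; near the scale ends the
  linear model saturates (visible in the clipping analysis above).
* Proximity is the only entrainment measure implemented; convergence and
  synchrony variants are out of scope.
* The readers target the plain-text Praat dialects; binary Praat files and
  spreadsheet (.xlsx) sheets must be exported to text/CSV first.
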