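# groupengage

Quantitative analysis of social engagement in recorded multiparty group
sessions, built for studies of group interventions for older adults with
Alzheimer's disease and related dementias (ADRD). Sessions are decomposed
into coded *events* (self-contained interaction segments) scored on a 1–5
Likert engagement scale; the package turns diarized audio annotations into
the predictors of those scores and fits the associated models.

The pipeline:

* **Read** Praat `PitchTier`/`IntensityTier` text files (long and short
  dialects), diarization logs (TextGrid interval tier or `start↹end↹label`
  TSV with markers `H`, `C`, `F1..F9`, `M1..M7`, `N`, `SO`), and coded
  event sheets (CSV: topic, times, eight binary behavior codes, number
  speaking, host one-hot, per-rater scores).
* **Build turns** from intervals (noise/over-speak excluded, optional gap
  merging) and assign them to events by strict majority overlap.
* **Prosody**: per-speaker, per-session Z-normalization
  `z = (v − mean_speaker)/sd_speaker`, then six turn-level features
  (mean/max/min of pitch and intensity).
* **Entrainment proximity** per event: for each feature, the mean of
  `|f(t_{i+1}) − f(t_i)|` over sequential cross-speaker turn pairs —
  smaller values mean interlocutors converge in prosodic space.
  Single-speaker events are excluded.
* **Time budget** per event and session: speaker-group speech time,
  participant fraction of speech, silence fraction, turn-length
  percentiles.
* **Statistics**: individual + joint OLS reports
  (`score ~ predictors`, per-family: hosts / behaviors / acoustic / time /
  general), one-way ANOVA with `η² = SS_between/SS_total` and Tukey HSD
  after balanced downsampling, and inter-rater percent agreement.
* **Synthesize**: `generate_study()` emits complete sessions (tiers,
  diarization, event sheets) from a planted linear engagement model with a
  tunable entrainment strength `delta`, so the whole pipeline is testable
  without recordings.
* **Visualize**: color-coded turn-at-talk timelines (host red, female
  participants blue, male participants green, control black) with optional
  pitch traces.

## Worked example

```r
library(groupengage)

cfg   <- synthetic_config(n_sessions = 4, session_length = 900, seed = 2026)
study <- generate_study(cfg, dir = tempfile("study"))

s     <- study[[1]]
turns <- build_turns(s$intervals)
#> session S01: 39 events, 268 turns

tp   <- turn_prosody(turns, zscore_by_speaker(s$pitch, turns),
                     zscore_by_speaker(s$intensity, turns))
prox <- event_proximity_table(s$events, tp)
filter_entrainment_events(prox)$counts
#>                    kept excluded_single_speaker        excluded_missing
#>                      36                       3                       0

session_speech_share(turns, span = c(0, cfg$session_length))
#>   host_pct control_pct participant_pct silence_pct
#> 1     18.4       0.673            80.9        32.6
```

Three of 39 events had a single speaker and are excluded from entrainment
modelling; participants held ~81% of speech time in this session and a
third of the session was silent. Fitting the behavior-code model over all
four sessions:

```r
feats <- pipeline_features(study)
fit_engagement_model(feats$events, feats$time_features, model = "behaviors")
#>   predictor individual_coef individual_p total_coef  total_p
#> 1    social         0.03335      0.81284     0.0397 7.61e-01
#> 5    affirm         0.40340      0.00377     0.5579 6.64e-05
#> 8 nonverbal         0.63919      0.00581     0.9000 8.68e-05
#> ...
#> total R2 0.206, F = 4.2, error df 130, n 139
```

Each row reports the predictor fit alone (individual) and inside the joint
model (total); affirmation and notable non-verbal responses carry the
signal here, matching what was planted. Agreement and host effects:

```r
agr <- interrater_agreement(feats$events$score_r1, feats$events$score_r2)
#> agreement: 58.3% exact, 40.3% within one, 98.6% approximate (n=139)

host_anova(feats$events, seed = 1)
#> host ANOVA: eta2 = 0.106, p = 0.00243, balanced n = 33 per host
```

`host_anova()` first downsamples every host's events to the smallest
host's count (seeded), so the η² effect size compares balanced groups.

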