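---
title: "Methods: task engine, simulated subjects and behavioural analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task engine, simulated subjects and behavioural analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autoprt)
```

This vignette is the package's own account of its science: what the task
engine computes, how the simulated subjects behave, which parameters
matter, and where the design was genuinely open and a choice had to be
made.

## The task

Automated positive-reinforcement trainers for macaques present a panel of
buttons with coloured LED cues. While a cue is lit, pressing the cued
button **continuously for the hold time** (default 50 ms) is scored
`SUCCESS` and rewarded; pressing another button is `WRONG_BUTTON`; holding
the right button too briefly is `EARLY_RELEASE`. Either error switches all
cues off for a **time-out** (default 3 s) in which no reward is available;
presses attempted during the time-out are scored `TIMEOUT_PRESS` and
prolong it, discouraging random hammering. After an error the *same* cue
re-illuminates until it is correctly pressed, which prevents a stereotyped
single-button strategy. Task variants differ in cue semantics: the
1-button task rewards any button (used for first contact with the device),
the 2- and 4-button tasks reward only the cued one.

### Engine semantics and numerical choices

* Time is integer milliseconds from session start; button ids are 1-based.
* A success registers at hold completion; release is not required. This
  follows from reading the hold criterion as a hold, not a release rule —
  a device sampling button state can reward while the finger is still
  down.
* An error's time-out starts at the press's release. A `TIMEOUT_PRESS`
  under the default `restart` policy restarts the full period from its own
  release (`extend` appends one period instead). Either way the cue cannot
  re-illuminate earlier than one full time-out after the last offending
  press.
* The cue after a success is drawn uniformly over the active buttons,
  immediate repeats allowed; the task constrains cue behaviour only after
  errors (persistence), so uniform resampling is the neutral choice.
* All engine randomness (cue draws) comes from a private stream seeded by
  `rng_seed`; identical configuration and press script give a
  byte-identical session log. The engine never disturbs the caller's RNG.
* The refractory period between a reward and the next cue is exposed as
  `refractory_ms` (default 0; the physical devices' behaviour here is
  undocumented). A press inside the refractory window is scored against
  the already-selected next cue.
* Whether a press was made with hand or mouth is not modelled; the log
  format carries a free-text annotation field for such observations.

One property deserves a caution. "Raising the hold time never increases
the success count" is a theorem on the 1-button task: a longer hold can
only turn successes into errors, and the induced time-outs only remove
further successes (the time-out state under the longer hold dominates,
press by press). On the cued variants it is **not** a theorem: a success
resamples the cue, so the two runs diverge after the first flipped press
and the longer-hold run — whose cue then persists — can occasionally
finish with more successes (about 1 % of random scripts in our
experiments). The property suite therefore exercises hold monotonicity on
the 1-button task, where it is exact.

## Training protocol

Progression between stages fires when a session reaches the threshold of
**100 successful presses** (`should_progress()`); the per-session basis is
the default because that is how the criterion is operationally described,
with a successes-per-hour basis available by configuration (both compared
with ≥). The research facility progresses 1-button → 4-button, the
laboratory 1-button → 2-button. The laboratory's first session always uses
the 1-button task and the second stage follows immediately afterwards
(`lab_progress_after_first = TRUE`), since lab progression is
trainer-driven rather than criterion-gated; setting it to `FALSE` applies
the same success criterion as elsewhere. The criterion is evaluated after
every session. Laboratory session caps ramp linearly 10 → 36 min over 8
sessions, rounded half-up to whole minutes (`lab_session_cap()`); only the
endpoints are prescribed, so linearity is the package's interpolation
choice. "Week" means 5 working days; simulated sessions are scheduled on
working days only.

## Simulated subjects

No per-animal data from the original study are available, so the package
ships a generative cohort model whose *structure* mirrors the study: 16
female rhesus macaques in small housing groups; 8 classified Users, 5
Non-Users, and 3 subjects never exposed to the breeding-facility device; a
week of shared group access plus two weeks of individual sessions at the
breeding facility; at least 27 research-facility and 8 laboratory sessions
each.

An agent is three exponential-approach laws in cumulative rewards $r$:

* **cue-following** $p(r) = p_\infty - (p_\infty - p_0)\,e^{-r/\tau}$,
  with $p_0 = 0.25$ on the 4-button task by symmetry;
* **engagement**: both the per-session probability of interacting at all
  and the press rate while engaged ramp from naive to asymptotic values
  with their own time-constant;
* **hold durations**: truncated normal (minimum 1 ms), fixed per subject.

While engaged, the agent presses at exponential inter-press intervals,
aims at the cued button with probability $p(r)$ (uniform among the others
otherwise, and uniform over all buttons while cues are off during a
time-out), and learns only from rewards. All archetype defaults live in
one calibration table (`archetype_defaults()`); per-subject heterogeneity
is log-normal jitter on rates and time-constants and clamped additive
jitter on probabilities, drawn deterministically from
`(master_seed, subject_id)`.

Two modelling decisions are worth explaining:

* **Non-Users carry a breeding-facility context factor** (engagement
  multiplied by 0.18 there). Without it no parameter set can keep a
  subject under the 30-success classification bar across fifteen
  breeding-facility sessions *and* let it reach the 100-success
  progression criterion at the research facility, which all real animals
  eventually did. The factor encodes the reading that Non-Users failed to
  *engage* in the group-housing context (competition, social rank) rather
  than failed to learn; whether that reading or low learning ability is
  correct cannot be decided from group summaries, and the package takes
  the engagement reading.
* **Group-exposure sessions attribute only a fraction (0.3) of an agent's
  engagement** to its own log: presses at a shared device cannot be fully
  attributed to one subject, and the original analyses discarded early
  group data for exactly that reason. Social dynamics themselves
  (dominance, observational learning) are not modelled.

Calibration: archetype defaults were set by forward simulation so that the
default cohort's group summaries land near the study's printed group means
(research facility, sessions 5–27: Users ≈ 200, Unexposed ≈ 145,
Non-Users ≈ 58 correct/h against printed 194 ± 49, 119 ± 66, 71 ± 40;
laboratory, first 8 sessions: ≈ 215 / 159 / 52 against 195 ± 33,
138 ± 18, 39 ± 28) with the correct ordering in every window. What passing
cohort-level tests shows is therefore that the *pipeline* recovers a
planted group structure — classification concordance and group ordering —
not that real macaques behave like these agents. Known gaps: simulated
agents transfer between facilities without the context-novelty cost real
animals showed (simulated Users reach the research-facility criterion in
~1 session versus the reported 6 ± 1), hold-duration competence does not
itself improve with practice, and one simulated Non-User may not reach
criterion within 27 sessions (the real range extended to 33).

## Analysis pipeline

* `session_metrics()` — successful presses per *realised* hour (not the
  scheduled cap) and % correct. The percentage's denominator counts **all
  recorded presses including time-out presses** (switchable), and is
  undefined — `NA`, never 0 — for a session without presses.
* `classify_bf()` — Users performed ≥ 30 successes in at least one
  breeding-facility session; exposed subjects that never did are
  Non-Users; subjects with no breeding-facility history are Unexposed.
* `sessions_to_criterion()` — first session with ≥ 100 successes
  regardless of task variant; `NA` when never reached.
* `select_window()` — inclusive, anchored slices: research-facility
  sessions 5–27 (the first four are discarded as unattributable), the
  first 13 sessions after 4-button onset, sessions 5–12, and laboratory
  sessions 1–8.
* `group_summary()` — per-subject across-session means first, then group
  mean ± SE **over subjects** (each animal one independent observation);
  single-subject groups get `SE = NA`, empty groups are dropped with a
  warning. Per-session group means form the learning curves (`plot()`).
* `mann_whitney_exact()` — $U = \min(U_x, U_y)$ on mid-ranks; the
  two-sided p-value is the exact share of all
  $\binom{n_x+n_y}{n_x}$ assignments with $\min(U_x,U_y)$ at most the
  observed value (full enumeration up to $10^6$ assignments, then a
  tie-corrected, continuity-corrected normal approximation; the result
  records which route ran). The min-U convention matches how small
  behavioural samples are conventionally reported.
* `kruskal_wallis()` — tie-corrected H against a chi-square reference with
  $k-1$ df; with a handful of animals per group this reference is
  approximate. All-tied input returns $H = 0$, $p = 1$.
* `ols_regression()` — simple OLS via `stats::lm()`, reporting slope,
  intercept, $R^2$ and the slope's two-sided t-test p-value; a constant
  response returns slope 0 and $R^2 = 0$ by convention.
* p-values are two-sided throughout and no multiple-testing correction is
  applied, matching the analysis style the pipeline mirrors.

## Reproducibility and problem sizes

Everything stochastic descends from one integer seed: sessions derive
sub-seeds by hashing `(master_seed, subject, facility, session)` into the
31-bit range, so any single session can be regenerated in isolation. The
default cohort (16 subjects, ~750 sessions, ~2×10⁵ scored presses)
simulates in a few seconds; the property suites run the engine over a
thousand random press scripts and round-trip several hundred randomized
logs, sizes chosen to exercise the semantics thoroughly while keeping the
full test run around a minute.

## File format

Session logs are UTF-8 CSV: `#key=value` header lines (subject, facility,
1-based session index, ISO-8601 start, the full task-parameter echo,
realised duration, annotation) and one row per scored press
(`timestamp,cued_button,pressed_button,t_down_ms,duration_ms,outcome,reward`).
The reader is strict — unknown outcome tokens, inconsistent reward flags
and non-monotone times are errors with line numbers — but preserves
unknown header keys in the annotation and tolerates a trailing newline.
Trial timestamps are derived from the session start plus `t_down_ms` at
write time, which is what makes write∘read an exact identity. A cohort
bundle is a directory of `<subject>_<facility>_<index>.csv` files plus a
`subjects.csv` (id, housing group, age, weight, social rank — synthetic
metadata in simulated cohorts) and a `provenance.json` with the master
seed and spec checksum.
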