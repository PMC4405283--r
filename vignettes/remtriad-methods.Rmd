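---
title: "Relational event models for proximity-logger triads: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relational event models for proximity-logger triads: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remtriad)
```

## The problem

Collar-mounted proximity loggers record every close-proximity encounter
between tagged animals as a contact with a start, an end, and a duration at
one-second resolution. For a triad — two familiar animals (coded 1 and 2)
and a newly introduced unfamiliar animal (coded 3) — this yields a
continuous stream of tie *onsets* and *offsets* on the three possible dyads.
Aggregating such data into daily association indices discards the timing
and ordering that carry the social signal: whether recent contact begets
future contact, and whether group contact differs from dyadic contact.

`remtriad` keeps the sequence. Every onset is modelled *ordinally*: given
that some onset happened at time $t$, which of the possible onsets was it?

## The model

Write $A_t = (a_m : m \le t)$ for the history of events up to $t$. Each
candidate event $a$ carries a rate

$$\lambda_a = \exp\Big(\sum_h \theta_h\, s_h(a, A_{t^-})\Big),$$

and the probability that the realized onset is $a$ rather than any other
possible onset $a'$ at that moment is

$$p(a) = \frac{\lambda_a}{\sum_{a'} \lambda_{a'}}.$$

This is a stratified conditional (multinomial) logit: one stratum per
observed onset, containing the realized event and its *risk set* of
potential events. Per-stratum constants — including any baseline rate and
the inter-event waiting times — cancel from the likelihood, which is why
the model has no intercept and why only the ordering of events matters.

Onsets are classified by the triad configuration active at that instant:

* **pair** — an onset from the empty configuration (risk set: all three
  dyads);
* **group** — the third, unconnected animal joins one member of an existing
  pair (risk set: the two dyads containing the unconnected animal);
* **triangle** — two ties are active, so the only possible onset closes the
  triad with probability 1; triangles are classified and counted but carry
  no information and are never modelled.

Two models are fitted per day: one for pair onsets (3-row strata) and one
for group onsets (2-row strata).

## The five statistics

Each candidate dyad in each stratum carries:

1. `unfam` — 1 if the dyad involves animal 3. Binary, left unscaled so the
   estimate reads as a familiar-versus-unfamiliar contrast.
2. `pair_hour`, `pair_day` — counts of the dyad's own prior *pair* onsets
   in the past hour and in the current day.
3. `group_hour`, `group_day` — counts of prior *group* onsets in whose
   resulting two-tie configuration the dyad was one of the ties (the newly
   formed tie or the pre-existing one). The co-present but untied dyad is
   **not** credited: we read a group event as the two tied dyads having
   encountered each other as part of a group. This is one defensible
   reading of group participation; crediting the untied dyad as well would
   be another, and the choice is localised in one place
   (`build_strata` / `compute_statistics`) should a user prefer it.

Windows are defined on the analysis clock (integer seconds since
introduction). The daily window is $[d_0, t)$, where $d_0$ is the start of
the current day; the hourly window is $(t - 3600, t)$, open on the left, so
an onset exactly one hour old has just left the window, and truncated at
$d_0$. Hourly counts are therefore nested within daily counts, and nothing
recorded on a previous day is ever counted: each day is modelled as a
self-contained sequence. On the introduction day the daily window simply
starts at time zero.

Day boundaries default to calendar midnights of the logger clock, with day
1 the (partial) day of introduction; a fixed 24-hour block convention is
available (`day_start_times(mode = "fixed")`).

## Normalisation

Within each fitted (day × model) dataset the four count statistics are
centred and scaled to unit sample standard deviation; constant columns map
to zeros. This makes hourly and daily effects comparable in scale within a
dataset. Because centring is a per-dataset affine map and the conditional
likelihood is invariant to per-stratum constants, fitting on the normalised
scale estimates $\theta_h \cdot \mathrm{sd}_h$; simulation-based recovery
therefore compares against the truth rescaled by the realized column
standard deviations.

## Estimation

The log-likelihood
$\ell(\theta) = \sum_s [\theta \cdot s_{\text{actual}} -
\log \sum_r \exp(\theta \cdot s_r)]$
is concave. It is maximised by Newton–Raphson with analytic gradient and
Hessian, a step-halving safeguard that keeps $\ell$ non-decreasing, and
log-sum-exp stabilisation. Convergence is declared when the score max-norm
falls below $10^{-8}$ or the step below $10^{-10}$.

Numerical edge cases are reported, never silenced:

* effects with no within-stratum variation anywhere (e.g. `unfam` in a
  group-model dataset whose strata all derive from a familiar base pair)
  are inestimable under the conditional likelihood and returned as `NA`;
* complete or quasi-complete separation is flagged as non-convergence when
  a coefficient passes $|\theta_h| > 15$ with a still one-signed score,
  naming the effect;
* a singular Hessian raises an error naming the collinear columns.

Standard errors come from the inverse negative Hessian; Wald $z$ ratios use
the normal reference with stars at $P < 0.05$ (`*`) and $P < 0.01$ (`**`).
The null log-likelihood is $-n \log 3$ (pair) or $-n \log 2$ (group) in
closed form. A cross-check against `survival::coxph(method = "exact")`
lives in the test suite; the fitter itself is self-contained so that the
likelihood is the tested artifact.

## Data cleaning defaults

* **Minimum contact length 2 s** (`filter_short_contacts`): one-second
  detections arise spuriously at the edge of the detection zone and are
  dropped.
* **Reciprocal compression** (`compress_reciprocal`): both collars of a
  dyad may report one encounter with differing boundaries; per dyad we take
  the union of reported intervals, merging overlapping *or abutting*
  half-open intervals $[\text{onset}, \text{offset})$. The union is the
  most permissive contact definition; keeping only the longer of two
  discrepant reports would be the conservative alternative.
* **Time zero** is the introduction time from the manifest; records ending
  before it are dropped and straddling records are clipped to start at 0.
* **Simultaneous onsets** are separated by shifting the 2nd..kth onset in a
  tied second by +1..+(k−1) s, ordering ties by ascending dyad code
  (1,2) < (1,3) < (2,3). The ordinal likelihood needs *some* strict order;
  the dyad-code rule makes it deterministic and reproducible. Offsets move
  only if a shift would otherwise produce an empty interval.
* At an equal second, offsets are processed before onsets, so a tie ending
  exactly when another begins does not inflate the configuration the new
  onset sees — "group" means truly contemporaneous ties.

## The simulator

`simulate_triad()` generates the process the model describes: candidate
onsets at rates $\exp(\beta_0 + \theta \cdot s_d(t))$ with $s_d$ computed
from the realized history exactly as the fitting side defines it
(unnormalized counts, day resets, hour-window expiries); covariate-free
exponential dissolution of active ties; and the forced triangle closure at
rate $\exp(\beta_{0,\text{group}})$. Rates are piecewise constant between
breakpoints (events, hour-window expiries, day boundaries), so sampling
uses competing exponentials with re-sampling at each breakpoint, which is
exact for piecewise-constant hazards.

The baseline log-rates $\beta_0$ exist only in the generator: the
conditional likelihood is invariant to them, which the recovery tests
exploit.

Event times are recorded on the integer-second logger grid under the
constraints clean logger data satisfies — strictly increasing event times
within a triad, contacts at least 2 s long, at least 1 s between successive
same-dyad contacts, no onsets in the final 2 s of the horizon — so that
writing the study in the logger dialect and re-ingesting it through the
full cleaning pipeline reproduces the true event stream *exactly*. Rounding
a sampled time up to its recording second can shift an hour-window
membership by at most one second relative to the continuous-time rate; this
slightly perturbs the generative process near window boundaries but not the
fitted likelihood, which always uses the recorded times.

**Default conditions.** The defaults emulate a cattle introduction study:
36 triads, 5 observation days with day 1 a partial day starting at midday,
mean contact length about a minute (`offset_hazard = 1/60`), baseline
log-rates ($\beta_{0,\text{pair}} = -8$, $\beta_{0,\text{group}} = -7$) and
modest positive history effects chosen to yield on the order of 60–90 pair
onsets and a handful of group onsets per triad per full day, with triangles
rare — the event-count profile such logger deployments report. A negative
unfamiliarity effect (−0.5) in the pair model and a positive one (+0.5) in
the group model mirror the qualitative pattern of interest: the unfamiliar
animal is avoided dyadically but is the predominant creator of group
events. With self-exciting history effects the process can in principle run
away; the generator guards the log-rate at ±30 and caps events per triad,
erroring rather than silently truncating.

**What the simulator does not emulate:** spatial movement, detection error
beyond optional ±2 s reciprocal boundary jitter, logger dropout, or groups
larger than three. Passing recovery tests therefore demonstrates the
correctness of the inferential machinery under the model's own assumptions,
not robustness of the model to real-world detection artefacts.

## Validation and problem sizes

The test suite validates each stage against an independent oracle:
second-by-second coverage for interval union; hand-traced state machines
for classification; exhaustive rescans for windowed counts; brute-force
enumeration of stratum probabilities for the likelihood (agreement to
1e−10); a dense grid search for tiny MLEs; and `survival` for a full fit.

Parameter recovery uses 150 replicate studies of 200 triads × 5 days and
checks that the 95% Wald interval covers the rescaled truth for each of the
ten effects (five per model) at an empirical rate in [0.90, 0.99]. The
replicate count was fixed by a design-time power calculation: with exactly
nominal coverage, a [0.90, 0.99] acceptance band is met jointly by ten
effects with probability ≈ 0.93 at 150 replicates but only ≈ 0.30 at 50,
because 50/50 successes already violates the upper bound. The whole
recovery experiment runs in roughly a quarter of an hour on one core.

## Known limitations

* Offsets (dissolutions) are classified and counted but not modelled; the
  simulator's covariate-free dissolution is a placeholder for a future
  onset–offset model.
* Only triads are supported; larger groups need additional configuration
  statistics and a richer risk-set enumeration.
* Statistics are event *counts*; durations are not weighted.
* The ordinal likelihood discards waiting times, so the model says nothing
  about rates per unit time, only about which event came next.
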