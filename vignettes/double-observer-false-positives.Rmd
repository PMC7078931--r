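---
title: "Simulating and scoring false positives in double-observer auditory surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and scoring false positives in double-observer auditory surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddosurvey)
```

## The problem

Point-count surveys of vocalizing birds suffer two kinds of detection
error: false negatives (a bird sings, nobody records it) and false
positives (a detection is recorded for a species that did not vocalize —
in multispecies auditory surveys, almost always a misidentification).
A misidentification is doubly damaging: it is simultaneously a false
positive for the reported species and a false negative for the true one,
so it distorts the whole community's totals, not one species' count.

The dependent double-observer (DDO) method is a capture–recapture removal
design: a primary observer announces detections to a secondary observer,
who records them and silently adds anything the primary missed; each
individual is "removed" once counted, so at most one record exists per
individual. Because two people hear every cue and may confer on an
identification (as long as the detection stays attributed to whoever made
it), the design is expected to suppress false positives relative to the
standard independent single-observer (ISO) design.

This package implements the complete in-silico machinery for studying
that question: truth-list generation for simulated auditory surveys,
stochastic ISO/DDO observer models, a detection-scoring rule, and the
scenario-level statistics. The published summary counts of the motivating
playback experiment (ten prairie species, expert and naive volunteers)
are packaged so its headline tables can be recomputed from counts alone.

## Truth-list generation

A simulated survey is a 180-s timeline on a 3-s recording grid
(60 intervals). Each of the 10 roster species vocalizes a
discrete-uniform `1..4` number of times; each vocalization is a 4-s clip;
everything else is white noise. `generate_schedule()` draws the counts,
shuffles the clips into uniformly random order, and distributes the
white-noise slack `180 - 4 n` seconds across the `n + 1` gaps by uniform
stick-breaking (the gaps are the spacings of `n` uniform order statistics
on `[0, slack]`). Consequences:

* clips never overlap, but can be played back-to-back (zero gap);
* the last clip always ends by 180 s;
* the truth interval of a clip is the grid interval containing its
  *onset*. A 4-s clip can spill into the next 3-s interval; the onset is
  the unambiguous single "true interval", and the ±1-interval scoring
  window (below) absorbs the spillover.

One root seed drives everything; surveys in a batch or campaign use
substreams derived from (seed, survey counter), so any single survey can
be regenerated in isolation and batches are order-independent.

**A documented inconsistency.** The stated occurrence rule (uniform 1–4
per species, 10 species) implies a mean of 25 clips per survey with range
10–40. The reference experiment reports an empirical mean of 18.4 clips
(SD 2.7, range 12–25) without reconciling the two. The generator follows
the stated rule and exposes `count_low`/`count_high` rather than hiding a
calibration; the empirical values are stored in `reference_totals()` for
comparison only and are **not** a generator target.

## The observer model

The reference experiment used human volunteers, for which no quantitative
error model exists. The simulated observer is therefore the package's own
synthetic stand-in — the minimal stochastic model that produces every
error category the scoring rule must classify:

| parameter | meaning | default used in validation |
|---|---|---|
| `p_detect[i]` | probability a played clip of species *i* is detected | 0.85–0.95 |
| `confusion[i, j]` | probability a detected clip of *i* is reported as *j* (row-stochastic; diagonal = correct-ID probability) | diagonal 0.75 (naive) – 0.97 (expert) |
| `jitter` | distribution of the recorded interval's offset from the truth interval, on \{−1, 0, +1\} | point mass at 0, or 80–90 % at 0 |
| `collaboration` (κ) | probability a primary misidentification is corrected when the secondary independently detected *and* correctly identified the clip | 0.5–0.7 |

Jitter is clamped at the grid edges rather than wrapped (timers do not
wrap). There are no spurious, clip-less detections: the false-positive
definition under study covers misidentification and mistiming of real
clips, and the reference protocol gives observers nothing to hallucinate
from but white noise.

`simulate_ddo()` enumerates the per-clip outcome tree: primary detects →
one record with role `primary` (possibly corrected via κ as above);
primary misses, secondary detects → one record with role `secondary`;
both miss → nondetection. At most one record per clip, which is the
removal design. Role pairs swap primary/secondary on alternating surveys
in `simulate_campaign()`, as in the field protocol. The closed-form
misidentification fraction implied by the tree,

$$\frac{p_1(1-c_1)\,(1-\kappa p_2 c_2) + (1-p_1)\,p_2\,(1-c_2)}
       {p_1 + (1-p_1)p_2},$$

is strictly below the ISO fraction $1-c$ for equal profiles whenever
κ > 0; the test suite verifies the simulator against this expression by
Monte Carlo.

## Scoring: the 9-s allowable window

A detection is **correct** when a clip of the reported species lies in
the same grid interval or one interval to either side (the clip's 3-s
truth interval plus its two neighbours: a 9-s allowable window — one
interval back for observers running behind, one forward for reaction
time), *and* that clip is assigned to it. Assignment is one-to-one: each
clip absorbs at most one correct detection, so a surplus same-species
detection near an already-credited clip is a false positive. This removal
logic keeps the arithmetic `detections = correct + false positives`
exact.

`match_survey()` processes detections in increasing interval order and
assigns each the *earliest* unmatched same-species clip in its window
(ties by clip id). For windows one interval wide this left-to-right,
earliest-clip greedy provably attains the maximum number of correct
matches of any one-to-one assignment (the classical exchange argument).
Seemingly natural alternatives do not: preferring the exact interval
first strands a detection in instances like clips at intervals
\{*t*−1, *t*\} with detections at \{*t*, *t*+1\}, and the package's test
suite checks the implemented rule against a brute-force maximum-matching
oracle on an exhaustive sweep of small instances. Because ties are broken
on interval and id, scoring is invariant to detection input order.

Unassigned detections are false positives with a cause:
`misidentification` when an unmatched clip of a *different* species lies
in the window — the detection is attributed to the nearest such clip
(smaller absolute offset, then earlier clip), one attribution per clip —
otherwise `out_of_window`. The reference experiment asserts that
misidentified clips could be determined but not how; this
nearest-unmatched-clip reconstruction is the package's declared rule, and
it is exact whenever timing is unjittered (the attributed clip sits at
offset 0). Per-survey scores carry `nondetections` (clips with no correct
detection — the definition used for the reference experiment's
nondetection total) and the attributed subset `misid_clip_ids`, so both
tabulations are available.

The accounting identity
`observed − truth = FP − FN` holds exactly per species, where a species'
false negatives are its truth clips without a correct detection
(nondetections plus clips reported as something else).

## Scenario statistics

* **Rates.** The false-positive rate is `n_fp / n_detections`; its
  uncertainty is the binomial standard error
  $\sqrt{\hat p(1-\hat p)/n}$. The reference experiment's summary-table
  "SD" column is numerically this standard error (all five printed values
  reproduce at 3 decimals), and is documented as such.
* **Saturated logit.** With all four experience × method cells, the
  binomial logit with full interaction is saturated, so
  `fit_saturated_logit()` computes it in closed form from the cell odds
  `n_fp / (n_detections − n_fp)`: the intercept is the reference-cell
  (expert DDO) odds, each main effect is a cross-product odds ratio, and
  the interaction is the ratio of the fourth cell's odds ratio to the
  product of the main effects. Standard errors use the classical
  log-odds-ratio formula $\sqrt{\sum 1/k}$ over the 2, 4, or 8 counts in
  each term and are reported exponentiated (the scale the reference table
  prints). An iteratively fitted `stats::glm` agrees to better than
  10⁻⁶ relative error (property-tested on random four-cell tables); the
  closed form is preferred so every reported number is an explicit
  function of the counts.
* **Intervals.** Wald intervals on the log-odds scale by default.
  The reference experiment's printed CIs (e.g. 2.082–4.876 for the ISO
  effect) are slightly wider than Wald (2.06–4.81) and consistent with
  profile likelihood; `ci = "profile"` reproduces that behaviour but
  printed CI bounds are not treated as reproduction targets.
* **Percent reduction.** `100 (r_{ISO} − r_{DDO}) / r_{ISO}`, computed
  after rounding the rates to 3 decimals. The headline 66.3 % is only
  reproducible from the printed-precision rates (unrounded counts give
  66.0 %), so printed-precision arithmetic is the default, with
  `digits = Inf` available.
* **Zero cells.** A scenario cell with zero false positives (or zero
  correct detections) has undefined odds; `fit_saturated_logit()` refuses
  with guidance instead of applying a silent continuity correction.
* **Per-species rates** use the same estimator with a normal-approximation
  CI truncated to [0, 1]; a species with zero detections is `NA`
  (undefined), not 0, and a zero-FP species degenerates to [0, 0] — a
  known weakness of the Wald interval at the boundary, flagged rather than
  patched.

## What the validation shows — and what it cannot

The test suite validates the machinery at these problem sizes (chosen to
give the distributional checks real power while keeping the default run
fast): 1,000 schedules for the occurrence-count goodness of fit
(chi-square against uniform \{1..4\} at α = 0.01), ≥ 10⁴ ISO clips for
confusion-matrix parameter recovery (within 3 Monte-Carlo SEs of the
planted off-diagonals), a 200-survey equal-profile campaign for the
DDO-below-ISO comparison (one-sided two-proportion z at α = 0.01), and an
exhaustive ≤ 6-clip/≤ 6-detection sweep for matching optimality.

Passing these tests shows the generator, observer models, scoring rule
and statistics are internally correct and mutually consistent. It does
*not* show that the observer model describes human listeners: real
observers fatigue, learn across surveys, and respond to distance, volume
and ambient noise — none of which is modeled, and all of which the
reference experiment's design also deliberately excluded. Species-level
published values (per-species rates, similar-pair confusion bar heights,
the bias totals) depend on the human observers' actual confusion
structure and are therefore exercised qualitatively (asymmetry
directions, monotonicity in the confusion diagonal), not reproduced
numerically. The printed scenario counts, by contrast, are reproduced
exactly, because they are pure functions of the published table.

## Reproducing the headline tables

```{r}
reproduce_tables()
```
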