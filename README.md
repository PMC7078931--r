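# ddosurvey

Simulation and false-positive scoring of dependent double-observer
auditory surveys.

## The scientific problem

Multispecies auditory point counts are riddled with detection error.
Besides false negatives (a bird sings, nobody records it), observers make
**false positives** — almost always misidentifications, which corrupt two
species at once: the reported species gains a phantom observation and the
true species loses a real one. The **dependent double-observer (DDO)**
method is a capture–recapture removal design: a primary observer reports
detections to a secondary observer, who records them and silently adds
anything the primary misses, so each individual yields at most one
record; the pair may confer on identifications as long as the detection
stays attributed to whoever made it. Because two people hear every cue,
the design should suppress false positives relative to the standard
**independent single-observer (ISO)** method.

`ddosurvey` provides the full in-silico machinery for studying this:

* **Truth lists** — randomized 3-minute simulated surveys on a 3-s
  interval grid: each of 10 prairie-songbird species (a community with
  two similar-sounding pairs) vocalizes a discrete-uniform 1–4 times as a
  4-s clip; white-noise slack is spread over the gaps by uniform
  stick-breaking; clips never overlap.
* **Observer models** — a stochastic stand-in for human listeners with
  per-species detection probability `p_detect[i]`, a row-stochastic
  misidentification confusion matrix `confusion[i, j]`, ±1-interval
  timing jitter, and DDO collaboration probability κ (a primary
  misidentification is corrected when the secondary independently
  detected and correctly identified the clip).
* **Scoring** — each detection is correct iff a same-species clip lies
  within the 9-s allowable window (truth interval ±1) and is assigned to
  it one-to-one; assignment is an optimal left-to-right greedy (verified
  against a maximum-matching oracle). Unassigned detections are false
  positives, classified as `misidentification` (attributed to the nearest
  unmatched different-species clip in window) or `out_of_window`.
* **Statistics** — the false-positive rate `p̂ = n_fp / n_detections`
  with binomial standard error `sqrt(p̂(1−p̂)/n)`; the saturated
  logistic regression of the FP indicator on experience × method in
  closed form from the four cell odds `n_fp/(n − n_fp)` (odds-scale
  estimates, exponentiated SEs `exp(√Σ1/k)`, Wald or profile CIs); and
  percent reductions computed at printed precision.

The published scenario counts of the motivating playback experiment ship
as a fixture (`reference_scenario_counts()`), so its headline tables are
recomputed from counts alone — no external data needed.

## Worked example

A four-scenario campaign (expert/naive × ISO/DDO, 50 surveys each) with
calibrated observer profiles:

```r
library(ddosurvey)
roster <- study_roster()$code
profiles <- list(
  expert1 = observer_profile("expert", 0.95, uniform_confusion(roster, 0.97),
                             jitter = c(0.05, 0.9, 0.05)),
  expert2 = observer_profile("expert", 0.95, uniform_confusion(roster, 0.97),
                             jitter = c(0.05, 0.9, 0.05)),
  naive1  = observer_profile("naive", 0.85, uniform_confusion(roster, 0.75),
                             jitter = c(0.1, 0.8, 0.1)),
  naive2  = observer_profile("naive", 0.85, uniform_confusion(roster, 0.75),
                             jitter = c(0.1, 0.8, 0.1)))
scenarios <- data.frame(
  scenario   = c("expert_ddo", "expert_iso", "naive_ddo", "naive_iso"),
  experience = c("expert", "expert", "naive", "naive"),
  method     = c("DDO", "ISO", "DDO", "ISO"),
  n_surveys  = 50L,
  observer_a = c("expert1", "expert1", "naive1", "naive1"),
  observer_b = c("expert2", NA, "naive2", NA))
ex <- run_experiment(scenarios, profiles, ddo = ddo_config(0.6), seed = 2026)
ex
#> ddo_experiment
#>   experience method n_surveys n_detections n_fp       rate          se
#> 1     expert    DDO        50         1230   15 0.01219512 0.003129508
#> 2     expert    ISO        50         1218   36 0.02955665 0.004852763
#> 3      naive    DDO        50         1268  213 0.16798107 0.010498739
#> 4      naive    ISO        50         1073  282 0.26281454 0.013437337
#> 5      Total              200         4789  546 0.11401128 0.004592674
#>
#> saturated logit (odds scale):
#>          term    estimate   exp_se      ci_low     ci_high      p_value
#> 1   intercept  0.01234568 1.296655 0.007419646  0.02054219 3.456820e-64
#> 2       naive 16.35355450 1.310528 9.625464179 27.78450368 4.979672e-25
#> 3         ISO  2.46700508 1.363455 1.343627898  4.52961274 3.583023e-03
#> 4 naive x ISO  0.71577321 1.386032 0.377489338  1.35720730 3.056734e-01
```

Reading the output: within both experience levels the DDO false-positive
rate sits well below the ISO rate (0.012 vs 0.030 for experts, 0.168 vs
0.263 for naive observers). The saturated logit quantifies the same
pattern as odds ratios against the expert-DDO reference cell: a naive
observer's odds of committing a false positive are ~16× an expert's, the
ISO method multiplies the odds by ~2.5, and the interaction below 1 says
the double-observer benefit is proportionally larger for experts. Rerun
with the same seed and every number — and every file written via
`out_dir` — reproduces exactly.

Recomputing the reference experiment's tables from its printed counts:

```r
reproduce_tables()
#> Scenario false-positive rates (computed vs printed):
#>   experience method rate_computed rate_printed rate_match ...
#> 1     expert    DDO       0.03233        0.032       TRUE
#> ...  (all rate, SD, odds-ratio, SE and percent-reduction cells match)
```

## Further reading

The methods vignette
(`vignettes/double-observer-false-positives.Rmd`) documents the
generator and observer models, the optimality of the matching rule, the
closed-form regression arithmetic, all numerical conventions, and the
limits of what the synthetic validation can show about real surveys.
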