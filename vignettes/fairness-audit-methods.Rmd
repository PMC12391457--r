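---
title: "Auditing a remote motor-assessment classifier: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing a remote motor-assessment classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motorfair)
```

## The problem

Remote digital assessments of Parkinson's disease (PD) infer diagnostic
status from how a person moves a mouse and presses keys during a short
structured battery. Such tools promise accessibility, but a classifier
trained on an unbalanced cohort can behave very differently across sex,
race, device type and handedness — device type in particular can proxy for
socioeconomic status, and handedness interacts directly with pointing
dynamics. `motorfair` provides the full audit chain for this setting as a
reproducible synthetic pipeline: a session simulator with controllable
group effects, a 79-feature extractor, classical classifiers, and a
fairness audit with group-balanced bootstrap error bars.

Because the pipeline is synthetic end-to-end, every bias it reports was
*injected by configuration*, which is what makes it useful: the audit
machinery can be validated against ground truth (null configurations must
produce no findings; injected effects must be recovered) before it is
pointed at real data of the same shape.

## Cohort model

`cohort_config()` fixes the marginal structure of the simulated study
population: 251 participants, 99 labelled PD (39.4%; diagnosed and
suspected cases merged into one category) and 152 controls; 212 male /
39 female; 202 Windows, 41 Mac, 8 Linux; 176 right- and 75 left-handed;
and a race-by-status joint table whose White (51 PD / 134 non-PD) and
Black (33 PD / 6 non-PD) cells match the published two-way counts. Two of
the published one-way margins (race, device) sum to 250 rather than 251;
the defaults place the missing participant in the American-Indian/Alaska-
Native group and in the Windows group respectively, the least disruptive
completion. `generate_cohort()` reproduces every one-way margin *exactly*
(attribute vectors with the configured counts are permuted by seed), while
joints beyond race-by-status are left random: the published device-by-race
table is internally inconsistent with its own margins, so we do not force
it.

## Session simulator

The battery mirrors a browser assessment: three tracing tasks (straight
line, sine wave, Archimedean spiral), three timed key-press tasks
(constant key, two-letter, random sequence), each at three difficulty
levels, plus one clicking task and one digit-span memory run. Coordinates
are CSS-pixel, origin top-left, y downward; the default window is
1280 x 800.

The pointer model is deliberately minimal. The trace offset from the task
centerline is a stationary AR(1) Gaussian process (lag-1 autocorrelation
0.9, sampled at 60 Hz, pinned to zero at the first sample so every trace
starts on the path), vertical for straight/sine paths and radial for the
spiral. PD participants additionally carry a sinusoidal tremor term
(default 5 Hz, amplitude 4 px) and have their offset s.d. and task
durations multiplied by `pd_deviation_scale` (1.6) and `pd_time_scale`
(1.25). Device effects add response latency and scale pointer noise;
left-dominant participants incur a noise penalty (1.15) on the assumption
of a right-configured pointing device. Key-press response times are
Gaussian around a dilated base RT with a 50 ms floor; false-press
probability is multiplied for PD. Recall in the memory task is Bernoulli
with a logistic success curve around a capacity of 7 items.

Two modelling choices deserve emphasis:

* **Between-subject traits.** Each participant draws a lognormal speed
  multiplier (log-s.d. 0.18), a lognormal motor-noise multiplier
  (log-s.d. 0.35) and a Gaussian RT offset (s.d. 50 ms), once per session.
  Without them every control shares one expected duration and the
  classification problem collapses to a trivially separable one; with
  them, held-out AUROC under the default effects sits near 0.95 — the
  regime a well-performing remote assessment reports — rather than at
  1.0. The traits are independent of every group attribute, so they do
  not perturb the null-exchangeability property.
* **Device attenuation of the PD signal.** `device_pd_attenuation`
  multiplies the PD effect magnitude per device. It is the mechanism for
  bias injection experiments: setting it near 0 for Windows makes PD
  users of that device look like controls, which a correct audit must
  surface as a device disparate impact below 1.

The **null configuration** (`null_effects()`) sets every group-linked
multiplier to 1 and every group-linked additive term to 0, leaving the
baseline noise terms in place: the data stay noisy but are exchangeable
across label, sex, race, device and hand. This is tested by a two-sample
Kolmogorov–Smirnov check on feature statistics across devices (350
replicates per group, alpha 0.01).

What the simulator does **not** emulate: input-method differences (mouse
vs trackpad), browser frame-rate and latency dynamics, learning and
fatigue across the session, medication cycles, and the heavy-tailed or
saccadic structure of real pointer streams. Passing tests therefore
validate the *audit machinery* under a known generative model; they say
nothing about whether real PD motor signatures are detectable.

## Feature registry

The extractor emits exactly 79 named features across five categories:
50 mouse-movement, 6 mouse-click, 17 keyboard, 2 memory and 4
demographic. The ~20 features named in published importance tables are
implemented under their exact names (lower-snake-cased, including their
inconsistent articles, e.g. `time_to_trace_a_spiral` vs
`time_to_trace_the_spiral_normalized`); the remainder is a systematic
grid — the same deviation, timing, band-count and kinematic statistics
across the three paths, and the same response-time/accuracy statistics
across the three key tasks — so that every feature's semantics are
derivable from its name. The registry ships as
`inst/extdata/feature_registry_v1.csv` and a self-test asserts the file
matches the in-code registry.

Conventions: deviations are measured vertically for straight/sine and
radially for the spiral (matching the percentage-of-screen-height units);
"net" deviation is the absolute value of the signed sum; "mean" deviation
stays a signed *fraction* of screen height, as the emulated study
reports them; the points-inside band half-width defaults to 15 px; the
click-game "reaction" time subtracts a fixed 200 ms perception allowance
because no pointer stream is recorded for that game; per-path times sum
the three levels, while `average_tracing_time_for_all_tasks` averages the
nine individual traces. The memory task can be excluded from analysis
(`include_memory = FALSE`, features flagged missing) since the emulated
study is ambiguous about whether it analysed this task; it is included
by default. Missing features are median-imputed from the training split
only, with rows above 20% missingness dropped.

## Preprocessing and resampling

The order of operations is: stratified 70/30 split by label, then — on
the training partition only — random upsampling of the Non-White non-PD
subgroup to parity with the White non-PD subgroup, min–max scaling and
one-hot encoding fitted on training rows, then SMOTE (k = 5) to balance
the classes, with the 8 Linux participants excluded from balancing. The emulated
study's protocol is ambiguous about whether resampling preceded the split;
`resample_scope = "all"` reproduces the whole-dataset reading, but the
default confines every data-dependent transformation to the training
partition because the leakage-free reading is the only one whose held-out
metrics are interpretable. That protocol is likewise ambiguous about whether the PD
or the non-PD side of the Non-White group was upsampled; the default
follows the reading consistent with its reported group counts (non-PD), and `race_upsample(..., status = "PD")` gives the
other.

## Models

Six classical classifiers: random forest, depth-wise gradient-boosted
trees, a leaf-wise histogram GBDT (31 leaves), logistic regression,
RBF-kernel SVM and k-nearest neighbours; only the first three are named
by the emulated study, so the registry's completion is a reconstruction of "six
classical models". Hyperparameters are library defaults with pinned
seeds; the decision threshold is 0.5 on calibrated scores. Selection
takes the top three by mean F1 over shared stratified 5-fold CV, ties
broken by mean AUROC then lexicographically. AUROC is computed by the
rank formulation (ties counted one half) and is property-tested against
a pair-enumeration oracle.

## Fairness audit

Privileged groups default to male, White, Mac and right-handed (Mac
despite its smaller sample, for hardware homogeneity). Disparate impact
is the positive-prediction-rate ratio (unprivileged / privileged), equal
opportunity the TPR ratio, and equalized odds the worst-case TPR/FPR gap.
The printed equalized-odds formula is a *signed* max even though 0 is
called ideal; the default here is the standard absolute convention
`max(|dTPR|, |dFPR|)`, with the literal signed form behind
`convention = "signed"` — both are tested.

Error bars come from a group-balanced bootstrap: each of B = 100
replicates draws m rows with replacement from each group (m = the smaller
group size, so both groups contribute equally), recomputes every metric,
and the report gives means and standard deviations across replicates,
with undefined replicate metrics counted and reported rather than
dropped. Significance flags use the percentile bootstrap interval of the
unprivileged-minus-privileged difference at alpha = 0.05, no multiplicity
correction, and are left undefined below 30 valid replicates; the
procedure is a reconstruction, since the emulated study never names its test.
Stratified feature importance refits a random forest on the subgroup's
rows and reports impurity importance normalized to sum 1 (a
permutation-importance alternative on a global model was considered and
rejected as answering a different question: which features *that
subgroup's own model* relies on).

Audits of the bias-injection experiments use out-of-fold cross-validated
predictions over the whole cohort rather than the 30% held-out table:
the emulated study reports its bias tables from cross-validation with
bootstrap sampling, and the held-out Mac subset (about 12 participants) is too
small to audit stably.

## Calibration experiments and problem sizes

Three statistical experiments validate the audit chain end-to-end, all on
the default 251-participant cohort with a 100-tree random forest:

* **Bias recovery.** With the PD signal nearly removed on Windows
  (`device_pd_attenuation` 0.05) and the PD effect raised
  (deviation scale 2.5, time scale 1.5, tremor 8 px) so that the
  unsuppressed groups are classified cleanly, the device DI must fall
  below 1 with a bootstrap CI excluding 1 in at least 18 of 20 seeds.
  The injection is strong by design: the experiment checks that the
  audit *finds* a planted effect, not its detection threshold.
* **Null coverage.** Under `null_effects()` the device DI interval must
  cover 1 in at least 90% of 50 seeds.
* **Flag calibration.** Across 100 null-configuration runs, the
  significance-flag rate over sensitivity/specificity/precision and all
  four attributes must not exceed twice the nominal alpha.

These run sizes (20/50/100 seeds, B = 100) are the package's chosen
design points for its test suite; the Monte-Carlo recovery checks of the
simulator itself (noise-s.d. ratio within 15%, device latency gap within
10 ms) use 200 seeds with paired common random numbers across the
compared groups, which removes the between-subject nuisance variance
from the contrast.

## Power analysis

`min_sample_size()` reproduces the post-hoc sample-size argument: the
smallest n for which a two-sided 95% normal CI for AUROC 0.91 at
prevalence 0.39 has width at most 0.125, with the Hanley–McNeil (1982)
variance evaluated at fractional group sizes (0.39 n, 0.61 n) without
rounding. The emulated study cites a web calculator rather than a formula; the
inferred method reproduces its reported minimum of 111 exactly, and the
implementation is bisection over a monotone criterion, verified minimal
(n passes, n-1 fails) and against a linear-scan oracle.

```{r power}
min_sample_size(auc = 0.91, prevalence = 0.39, ci_width = 0.125,
                confidence = 0.95)
```

## Known limitations

* The simulator's realism is unvalidated by construction: no public raw
  sessions of this battery exist to fit it to. Its role is to give the
  audit machinery a ground truth.
* The 79-feature registry reproduces the published categories, counts and
  every published feature name, but the unpublished remainder of the
  original feature list is a systematic completion, not a reconstruction.
* Significance flags are per-metric and uncorrected; with 12 flags per
  attribute table, occasional null findings are expected by design.
* `run_pipeline()` audits the held-out partition, whose smaller subgroup
  sizes make single-run fairness numbers noisy; the bootstrap standard
  deviations in the report are the honest description of that noise.
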