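---
title: "Measuring diagnostic confidence from repeated model outputs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring diagnostic confidence from repeated model outputs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A large language model asked a multiple-choice diagnostic question returns
an answer and, if prompted, a verbalized confidence ("confidence: 85%").
Neither is a calibrated probability: generation is stochastic, and models
are known to verbalize high confidence on answers they get wrong.  When
the same prompt is sent repeatedly, however, the *distribution* of answers
carries information of its own — a model that returns the same option 20
times out of 20 is in a different epistemic state from one that splits
12/8 over two options, even if both verbalize "85%".

`repconf` implements the measurement and evaluation machinery for this
setting.  The unit of data is a *response set*: one case (with `k`
answer options and a designated ground truth) crossed with one model,
holding `n` repeated answers ordered by generation.  From a response set
truncated to any repetition depth `d` it computes five confidence
metrics, each paired with a *representative answer* whose correctness it
is taken to predict:

| metric | definition | representative answer |
|---|---|---|
| first self-reported | verbalized confidence of repetition 1 | the first response |
| mean self-reported | mean confidence over responses voting with the majority | majority-vote option |
| Shannon entropy H / relative entropy score | `H = -sum p_i log2 p_i`; `R_H = 1 - H / log2 k` | majority-vote option |
| majority-vote percentage | `100 * max count / d` | majority-vote option |
| Top Weighted Score (TWS) | `max over options of count * mean conf / d` | highest-weighted option |

`R_H` is 1 for unanimity, 0 for a uniform spread over all `k` options,
and — unlike the majority percentage — rewards concentration of dissent:
the pattern AAABB scores higher than AAABC although both have a 60%
mode.  TWS hybridizes the two signal families: an option must be both
frequent and confidently chosen to score highly.

## Assumptions

* Repetitions are exchangeable draws from the model's answer
  distribution for that case (same prompt, fixed sampling settings).
  "First response" is a positional convention (repetition index 1), not
  a quality judgement.
* Correctness is binary against a single designated ground-truth option;
  partial credit and free-text answers are out of scope.
* A confidence metric is evaluated through the correctness of *its own*
  representative answer.  This matters: two metrics with identical values
  can differ in what they are predicting.

## The evaluation stack

`evaluate_model()` relates each metric to correctness across cases three
ways:

* **Discrimination** — ROC AUC by the midrank estimator with DeLong
  variance; 95% normal CI truncated to [0, 1]; two-sided p against
  AUC = 0.5.  Raw entropy enters with its sign flipped so that higher
  always means more confident; because `R_H` is a strictly decreasing
  transform of `H`, their AUCs are identical by construction, and the
  package reports both rows deliberately.
* **Association** — Spearman rho on midranks against binary correctness,
  with a Fisher-z CI (`SE = 1/sqrt(n - 3)`), a t-approximation p value,
  and the conventional interpretation bands (negligible <= 0.10 < weak
  <= 0.39 < moderate <= 0.69 < strong <= 0.89 < very strong).  The
  pairing of a continuous score with a binary outcome makes this a
  rank-biserial-type association; it is reported as plain Spearman
  without reinterpretation.
* **Calibration** — expected calibration error over 10 fixed equal-width
  bins on [0, 1] (half-open, last bin right-closed so a confidence of
  exactly 1 is counted) and the binary Brier score.  Percent-valued
  metrics are divided by 100 and `R_H` is used as is, so every metric is
  judged on a common probability-like domain; ECE against binary
  correctness is meaningless on a 0-100 scale.  CIs come from a
  percentile bootstrap resampling *cases* — the only exchangeable unit —
  with 1000 iterations by default; a resample on which a statistic is
  undefined (e.g. single-class) is redrawn and counted.

Group differences between correct and incorrect cases use the
Mann-Whitney U test: exact enumeration of all group assignments when both
groups have at most 8 members (valid under ties), otherwise the
tie-corrected normal approximation.

Repetition-depth analyses truncate every response set to its first `d`
repetitions in generation order — never a random subsample — and
recompute everything, majority option included, at that depth.  Accuracy
across the depth conditions {first output, majority at 5, 10, 15, 20} is
compared with the Cochran Q test (for two conditions Q reduces to the
McNemar chi-square without continuity correction).  Within-model
repeatability is Fleiss kappa on the case-by-option count table, with
the usual bands (> 0.8 almost perfect, 0.61-0.80 substantial, ...).  A
temporal holdout splits cases at a training-cutoff date and compares
majority-vote correctness between strata with a two-sided Fisher exact
test; it probes whether pre-cutoff material might have leaked into
training.

## Numerical conventions and degenerate inputs

* `0 * log 0 = 0`; entropy is in bits throughout.
* Frequency or weighted-score ties are broken by canonical option order
  (the first label in the case's option list) and *flagged* in the
  profile (`majority_tie`, `tws_tie`), so downstream analyses can drop
  or inspect tied cases.  No tie-breaking convention is hidden.
* Zero-count options carry a missing mean confidence, never 0, so they
  cannot win the Top Weighted Score spuriously; if no option has a mean
  confidence, TWS fails loudly rather than guessing.
* Missing confidences are legal at the I/O layer (the rejects mechanism
  counts malformed values instead of dropping records silently); metrics
  that need them propagate NA (first self-reported) or error (TWS with no
  usable option).
* A metric constant across all cases has AUC computable (0.5) but no
  defined rank association; `evaluate_model()` reports NA for the
  Spearman fields in that event rather than aborting the other metrics.
* All-constant correctness rows give Cochran Q = 0, p = 1 by convention;
  an agreement table with all mass in one category makes Fleiss kappa
  undefined and errors.
* At depths below the full log, the majority option is recomputed within
  the truncated window (the majority can change with depth).  The
  full-depth alternative is available via `majority_at = "full"` in
  `self_reported()` / `build_profile()`.

## The synthetic generator

No raw model responses are deposited for this kind of study, so the
package carries its own test bed.  `simulate_model()` draws, per case:
a uniform ground truth; a latent modal option equal to the truth with
probability `accuracy`; an answer-probability vector from a Dirichlet
with weight `concentration` on the modal option (and 1 elsewhere) when
the modal answer is correct, `concentration_incorrect` when it is not;
then `n_reps` i.i.d. answers.  Verbalized confidences are normal draws
(SD `conf_sd`) around `conf_mu_correct` for responses choosing the
modal option and `conf_mu_incorrect` otherwise, shifted by
`overconfidence_shift` and clamped to [0, 100].

Defaults — 94 cases, k = 5, 20 repetitions, accuracy 0.6, concentrations
70/22, confidence means 85/72, SD 8 — were chosen once, by Monte-Carlo
calibration, to reproduce the regime this methodology is aimed at: high
but imperfect within-model repeatability (Fleiss kappa about 0.75-0.80),
model accuracy in the 44-74% range, verbalized confidences clustered
high relative to accuracy (overconfidence), and *more dissent on wrong
cases*.  That last property is the design decision that matters most:
with a single shared concentration, consistency would be statistically
independent of correctness and consistency-based metrics could not
discriminate at all, which is not the phenomenon of interest.  Tying
confidence to the latent modal option (not the truth) keeps the
generator confidently wrong on wrong-modal cases, as real models are.

Two switches support oracle tests: `conf_mode = "calibrated"` sets every
confidence to 100 times the case's probability mass on the true option
(a perfectly calibrated signal for the first response by construction),
and `conf_link = "truth"` makes the verbalized channel independently
informative.  Resource fields are log-normal draws on arbitrary,
documented scales (about 20 s, 4000 input and 800 output tokens per
call); they exercise the accounting, nothing more.

What the generator does *not* emulate: per-case difficulty correlated
with covariates, option-position biases, prompt-format sensitivity,
drift over repetitions (its draws are exchangeable by construction), or
confidence distributions with the heavy point masses at 80/90/95 that
real verbalized outputs show.  Tests passing on this bed therefore
validate the *measurement machinery* — that each statistic computes what
its definition says and recovers planted structure — not any claim about
how a particular real model family behaves.

## Parameter-recovery harness

`recovery_suite()` pushes canonical generator regimes through the whole
pipeline: a zero-information null (uniform answers, constant
confidence), a calibrated cell, an overconfident cell (+20-point shift),
an informative cell where both signal families carry information, and a
three-point concentration ladder.  The expectations are qualitative and
planted: null cells must show no discrimination, calibrated cells near-zero
self-reported ECE, the overconfidence shift must inflate it, the hybrid
must at least match the best single signal when both are informative, and
realized kappa must track the ladder and its Monte-Carlo target
(`kappa_target()`).

## Problem sizes

The test suite runs the worked examples and oracle equivalences at
desk scale (30-case DeLong instances, 50-instance oracle batches), the
recovery suite at 300-500 cases x 20 repetitions per cell, and the
convergence checks at up to 2000 repetitions; the analysis scripts use
the 94-case, 4-model, 20-repetition layout.  These sizes were chosen so
every stochastic check is decently powered while the whole suite stays
comfortably interactive.

## Known limitations

* The Spearman CI uses the Fisher-z normal approximation, which is
  mildly anticonservative for heavily tied (binary-outcome) data at
  small n; the p value uses the t approximation for the same reason.
* Fixed 10-bin ECE is unstable when confidences cluster into few bins —
  at 94 cases several bins are often nearly empty; the bootstrap CI makes
  that visible rather than fixing it.
* The bootstrap treats cases as the only exchangeable unit; repetition-
  level resampling (which would propagate within-case sampling noise
  into the metric values themselves) is not implemented.
* No multiple-testing correction is applied across the metric-by-model
  grid; p values are reported raw with alpha = 0.05 conventions.
* Majority and TWS ties are resolved deterministically but arbitrarily;
  analyses of datasets with frequent ties should use the tie flags.
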