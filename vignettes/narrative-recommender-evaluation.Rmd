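---
title: "Recommending recovery narratives: models, evaluation, and synthetic trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recommending recovery narratives: models, evaluation, and synthetic trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`narrarec` implements a hybrid recommender for mental-health recovery
narratives and the offline evaluation machinery used to compare its
content-based and collaborative subsystems. This vignette is the package's
account of the science: the models and their assumptions, the evaluation
conventions, the synthetic-data generator, and the choices made where the
design was genuinely open.

## Rating data

Each feedback event carries a compulsory hopefulness answer on −1…2 and,
all-or-none, four optional answers on 0…3. Three invariants shape
everything downstream:

* **Normalization.** Hopefulness is shifted by +1 so all streams live on
  the shared 0…3 scale; every prediction is clipped to [0, 3] before use.
* **Rerating overrides.** Only the latest event per (participant,
  narrative) pair contributes to a stream. Timestamps decide; exact ties
  fall back to file order (last row wins). The tie rule is our choice — the
  override semantics do not specify one — and is documented here so runs
  are reproducible.
* **Three streams.** Recommendation and evaluation use hopefulness and the
  two similarity questions only. Learning and empathy answers are parsed,
  validated and summarised, but excluded from prediction: the first three
  questions were the validated instrument when the serving system was
  designed, and keeping the evaluated surface identical to the served
  surface avoids a silent scope change.

The cold-start inclusion rule — only participants and narratives with at
least one rating are usable — is applied per training fold, so held-out
entries whose participant or narrative is absent from the training fold are
unpredictable (`NA`) rather than silently imputed.

## The three algorithms

**Content kNN.** Narrative characteristics are categorical codes of fixed
width *d* (77 by default, with 2–4 categories per item). They are one-hot
encoded before any similarity computation — cosine needs numeric vectors,
and one-hot encoding makes "same category" the unit of agreement.
`sim(i, j)` is the cosine of the one-hot vectors; a prediction is the
similarity-weighted mean of the participant's ratings over the up-to-*k*
most similar rated items with strictly positive similarity. `k = 40` with a
minimum neighbourhood of one mirrors the convention of the library family
this design descends from; the fallback ladder (participant mean, then
global mean) keeps every in-catalog pair predictable for any participant
with ratings. All-zero characteristic vectors get similarity 0 with a
warning rather than NaN.

**SVD and SVD++.** Biased matrix factorization trained by per-observation
SGD in data order (no shuffling), so a fit is bit-reproducible given the
seed. Hyperparameter defaults are the conventional library defaults this
class of system ships with: SVD f = 100, SVD++ f = 20, 20 epochs,
learning rate γ = 0.005, L2 regularization λ = 0.02, and N(0, 0.1²)
initialization for factors (biases start at zero). All are exposed as
arguments; the per-observation update applies shrinkage to every learned
term. The SGD inner loops are the package's one compiled component (Rcpp);
initialization randomness stays in R so seeds behave like any other R
seed.

**Serving.** The serving path combines each pair's latest answers into one
score with hopefulness weighted double — (2h + s₁ + s₂)/4, which keeps the
0…3 scale; hope creation is the mechanism the underlying intervention
theory treats as primary, hence the 2:1:1 weights. The combined value
drives serving only; evaluation always scores the three raw streams.
Each algorithm yields a top-10 list over candidates the participant has not
requested or blocked (blocking is modelled at two levels: individual
narrative ids, and banned characteristic codes — a "type" is interpreted as
a characteristic category since no finer definition exists). The single
highest-scoring entry of the ≤30 is served. Ties are deterministic
everywhere: within lists, ascending narrative id; across lists,
collaborative (svd, then svdpp) before content, then ascending id.

## Evaluation conventions

Cross-validation splits each stream's entries into 4 random folds; each
fold serves once as the 25% test set and the factor models are
re-initialized each time. Medians and IQRs over folds are reported, with
interpolated quartiles (R's default type-7 quantiles) — the reporting
convention is ours, as only "median and IQR" is specified upstream.

* **NMAE** is the plain mean absolute error on the normalized, clipped 0…3
  scale, no square root. The largest attainable error on this scale is 3;
  we deliberately do not rescale by a hypothetical scale width of 4, and
  note that one published account of this metric family states a 0…4 range
  without reproducing the defining equation. Computing plain MAE on the
  actual scale is the interpretation that keeps the metric meaningful.
* **MAP per participant** scores each participant's top-10 list against
  their held-out ratings, relevance meaning a normalized test rating ≥ 1
  ("a bit" / "no change" or better). Listed items without a test rating
  count as nonrelevant — internal lists mostly contain unrated items, which
  is consistent with the characteristically low precision values this
  design produces. AP divides by min(#relevant test items, 10);
  participants with test entries but no relevant one score 0 by default
  (`no_relevant = "exclude"` drops them instead; both modes exist because
  published precision conventions differ on exactly this point).
* **ILD** is the permutation-insensitive mean pairwise cosine similarity of
  the characteristic vectors within a list, averaged over lists. Tables of
  results are per algorithm, so lists are per algorithm rather than pooled
  across the three subsystems. Lists shorter than 2 carry no pair and are
  skipped with a warning.
* **ISC** is the share of rated narratives appearing in at least one
  participant's top-10 list. Feature-based metrics (ILD, ISC) use the
  entire stream as the training set; prediction-based metrics never do.
* **Overestimation unfairness** follows the Yao–Huang family: per narrative
  rated in the test fold by both the disadvantaged group and its
  complement, compare max(0, mean predicted − mean actual) between groups
  and average the absolute differences. Restricting to items rated by both
  groups is required for the group means to be estimable; with no such
  item the metric is "not computable" (NA with a warning), never 0.
  Partitions: gender (female or other vs male) and ethnicity (other
  ethnicity vs White British), derived deterministically from the profile
  categories.

The accuracy-over-time analysis reruns the cross-validated NMAE on
cumulative monthly prefixes (default grid June 2020 – July 2022, the
window the package emulates; the grid is configurable). A constant seed
across months means two months with identical prefixes report identical
values, and months with fewer than 20 ratings are skipped with a warning.

## The synthetic trial generator

No rating logs from the real trials are deposited, so the generator is a
first-class module: it emulates the *structure* the evaluation relies on,
not any real joint distribution.

What it emulates, and the defaults:

* 739 enrolled participants, ~38% of whom ever rate; a long-tailed
  per-rater activity distribution (negative binomial, mean 7, size 0.6,
  plus one) yielding ≈2300 live ratings.
* A catalog growing from 348 to 659 narratives, the remainder released in
  equal monthly batches over a March 2020 – September 2022 window; events
  only rate narratives available at the event time.
* Log-normal narrative exposure weights, giving the long-tailed
  ratings-per-narrative distribution (median ≤ mean) real request logs
  show.
* An optional-answer probability of 0.25 (the published share is 23.5%),
  optional values tied to the event's score through added noise
  (sd 0.8) — the inter-question correlation is an assumption, recorded in
  the ground-truth file, because no real correlation is published.
* Occasional reratings (3% of events) and a labeled pre-trial
  "feasibility" batch of 465 ratings from 25 separate raters, which the
  evaluation excludes.

Ratings arise from a latent model: score = b(u) + b(i) +
w_latent · p(u)ᵀq(i) + w_content · ⟨taste(u), v(i)⟩/√d + noise(σ), with the
rank-5 interaction scaled to unit variance before weighting. The continuous
score is discretized at cut points placed at the quantiles matching the
published marginal hopefulness distribution (8.83 / 39.38 / 36.63 / 15.17%,
entered as their underlying counts), because the marginals are the only
published description of the rating distribution. The defaults
(bias_sd = 0.25, w_latent = 0.3, w_content = 0.25, σ = 0.5) put the
explainable share of rating variance near 50%, within the range sparse
explicit-rating logs typically show.

**The oracle and the noise floor.** The generator stores, per pair, the
noiseless score discretized with the same cut points. Since the noise is
symmetric, that discretized value is the conditional median of the
observed rating, i.e. the MAE-optimal predictor; its MAE against the
realized ratings is the *noise floor*, the bound any fitted model is
compared against in recovery tests.

**The group-bias knob.** `w_group` is the probability that a rating by a
gender-disadvantaged participant of a *group-sensitive* narrative (a fixed
random half of the catalog) is shocked one point downward — occasional
disappointment concentrated on particular narrative types. The
item-dependence is essential: a constant additive group effect would be
absorbed into per-participant biases during training and produce no
overestimation unfairness at all, whereas type-linked shocks make measured
unfairness increase monotonically in the knob.

What the generator does **not** emulate: real INCRESE item content or
inter-characteristic structure, exposure bias from the recommender's own
feedback loop, participant attrition dynamics, or the true joint
distribution across questions. Passing tests on synthetic data therefore
show that the pipeline measures what it claims under a known generative
process — not that any algorithm would attain particular values on real
trial logs.

## Problem sizes and numerical choices

The test and acceptance workloads use trials of 200 participants × 300
narratives with ≈3000 ratings (σ = 0.5; bias_sd = 0.2 and w_latent = 0.15
in the recovery regime, w_latent = 0 with w_content = 0.5 in the
characteristic-driven regime), 20 simulated trials for stochastic
comparisons and 10 for the growing-log analysis — sizes at which the
latent signal is statistically recoverable from ~15 ratings per
participant while a full run stays comfortably interactive. Degenerate
inputs are contracts, not accidents: empty streams error on fitting, an
empty inclusion-filter result warns, folds with no testable entries are
skipped with a warning, and "no recommendation" is a typed empty result
distinct from an error.

## Known limitations

* The kNN neighbourhood size and all SGD hyperparameters are conventional
  defaults, not tuned values; the package deliberately ships no tuning
  loop.
* Unfairness is measured for two fixed binary partitions; intersectional
  and item-side fairness are out of scope, as are ranking-order metrics
  (NDCG/MRR), novelty and serendipity.
* The generator's correlation between optional answers and hopefulness is
  an assumption knob, not an estimate.
* Offline evaluation of a system that influenced its own training data
  inherits exposure bias; the package measures the algorithms on the log
  it is given and cannot correct for how the log was collected.
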