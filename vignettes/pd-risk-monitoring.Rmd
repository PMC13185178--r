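---
title: "Methods: site-level protocol deviation risk monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: site-level protocol deviation risk monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdsentinel)
```

## The problem

Protocol deviations (PDs) — departures from an approved clinical-trial
protocol — are recorded at investigator sites as structured counts and
free-text narratives. Their reporting rate is a quality signal in both
directions: a site reporting suspiciously few deviations may be
under-reporting (masking operational problems), while an unusually high
rate may indicate training or process failures. pdsentinel combines a
statistical detector for *which* sites deviate from their study's norm
with a content pipeline for *what* is being deviated from, and joins the
two into per-site risk profiles. All outputs are signals warranting
investigation, never definitive compliance determinations.

## The visit-matched bootstrap null

Let participant $j$ at site $i$ of a study attend $v_{ij}$ protocol
visits and accumulate $y_{ij}$ deviations. The site statistic is the
mean cumulative deviation count

$$T_i = \frac{1}{n_i}\sum_j y_{ij}.$$

The null hypothesis is *participant exchangeability across sites
conditional on visit count*: a site's participants should look like a
random draw from the study's participants with the same exposure. The
detector builds the null distribution of $T_i$ by resampling: in each of
$B$ iterations every participant is replaced by a participant drawn
uniformly (with replacement) from all same-study participants with
exactly the same visit count — site memberships stay fixed, only
deviation counts are transplanted — and all site means are recomputed.
The empirical tail probabilities are

$$p^{lo}_i = \frac{\#\{b: T_i^{(b)} \le T_i\} + 1}{B + 1},\qquad
  p^{hi}_i = \frac{\#\{b: T_i^{(b)} \ge T_i\} + 1}{B + 1},$$

both tails including equality (so $p^{lo}_i + p^{hi}_i \ge 1$) and with
an add-one correction so probabilities are never zero and remain valid
p-values under multiplicity adjustment (toggle `pseudo_count` off to
compare against exact enumeration).

**Why means of counts rather than per-visit rates.** Step descriptions
of this family of algorithms mix "PDs per visit" with "mean cumulative
PD count". We use the mean cumulative count and let the visit-matched
resampling itself carry the exposure adjustment: because every
replacement has the identical visit count, the resampled distribution of
$T_i$ is automatically conditioned on the site's exposure profile, and
no division by visits (which would need per-visit timing data the schema
lacks) is required.

**Resampling pool.** The pool for a participant always contains the
participant themselves and their site mates. This guarantees a non-empty
pool (a participant with a unique visit count maps to themselves) and
makes the null mildly conservative, which is the safe direction for a
screening tool. Participants at sites excluded as too small still feed
the pools — they are real exposure — but no probabilities are reported
for those sites.

**Multiplicity and flagging.** Within one study and one tail direction,
the included sites form one Benjamini–Hochberg family at level
$\alpha = 0.05$ (default): `under_reporter` if the adjusted lower-tail
probability is $\le \alpha$, `high_rate` for the upper tail. Per-study
families keep flags interpretable relative to the study's own context; a
pooled-portfolio family is available via `bh_scope = "portfolio"`. The
per-study medians of the site probabilities are reported as descriptive
reference context and never alter flags. In the pathological case where
a tie rejects both tails, the smaller adjusted value wins and the
tie-break is recorded in the output.

**Eligibility.** Studies with three or fewer sites are excluded whole;
sites with fewer than two participants are listed with flag
`insufficient_data` and excluded from both the bootstrap read-out and
the BH family. Every exclusion is logged with its reason.

**Convergence.** The running estimate after $k$ iterations is
$p_k = c_k / k$. The diagnostic is the coefficient of variation
(population SD / mean) of $p_k$ over a trailing window, by default
iterations 800–$B$, with the convention CV $= 0$ when the window mean is
zero (an estimate pinned at zero has stabilised; this happens for
strongly signalled sites whose observed mean no resample reaches).
Estimates are considered stable when CV $< 1\%$.

**Determinism.** Each study draws from an RNG stream seeded by a hash of
(study id, root seed), so identical inputs give bitwise-identical
results and adding or removing a study never perturbs the others.

## Topic pipeline

Narratives are processed per study by three pluggable stages.

1. **Extraction.** A backend maps narratives to short topic labels under
   a fixed prompt-template contract (task specification, context slot,
   structured output format, temperature pinned to 0). The shipped
   default is a deterministic keyphrase-rule mock; anything the backend
   cannot label goes to a manual-review list with the raw response
   retained. Every topic record keeps full provenance (the narrative ids
   it came from).
2. **Embedding.** A backend maps label texts to fixed-dimension vectors.
   The default is a hashed bag-of-tokens projection (feature hashing,
   64 dimensions): deterministic, offline, and sufficient for the
   token-overlap geometry the tests rely on. It captures no semantics
   beyond shared vocabulary — a deliberate limitation; live embedding
   models plug in through the same contract.
3. **Merging.** Average-linkage agglomerative clustering on cosine
   distance $1 - \cos(\theta)$. One dendrogram is cut at two heights:
   `t_topic` (default 0.3) yields specific merged topics, `t_category`
   (default 0.6) broad categories, so nesting is guaranteed by
   construction. Alternatively target counts (`n_topics`,
   `n_categories`) can be requested. The linkage rule is configurable
   (`average`, `complete`); average linkage is the default for its
   robustness on cosine distances. Each cluster is labelled by its
   medoid (highest mean similarity to peers; ties broken
   lexicographically), labels are de-duplicated per level, inputs are
   sorted by label before clustering so results are order-invariant, and
   clusters holding under 1% of narratives are tagged `rare` but never
   dropped — rare deviation types are exactly where automated pipelines
   are weakest.

Cluster separation is summarised by the silhouette score under cosine
distance: the mean over points of $(b - a)/\max(a, b)$, singletons
scoring 0. The default cut heights were chosen once against the
synthetic generator's geometry (tight keyphrase families well below 0.3
apart, distinct families well above 0.6) and are configuration, not
fitted constants.

## Validation harness

A uniform, seed-reproducible sample of classified narratives is judged
by a pluggable backend; the shipped mock compares the assigned topic
with the generator's ground truth and, for errors, applies transparent
rules for the four-way error typing (boundary / ambiguous / rare /
straightforward). The report gives accuracy $\hat p = x/n$ with a
Wilson score interval computed from the closed form at full double
precision (z-quantile never hard-coded); a Clopper–Pearson exact
interval is available as an option since published intervals for
proportions are sometimes of that family even when labelled otherwise.
Items the backend fails on are excluded from the denominator and kept
for inspection, so $n$ counts judged items only. Backends are called on
the whole batch (the mock's rare-topic rule needs sample frequencies);
if a batch call throws, items are retried singly so one failure costs
one item.

## Integration and scope classification

Per-site risk profiles join the statistical flag with the site's topic
distribution. A topic is *dominant* at a site when its site share is at
least twice its study share with at least 5 site narratives (both
configurable). Flagged sites sort first by smallest adjusted tail
probability.

No published decision rule exists for calling a deviation pattern
site-specific, country-specific or study-systemic, so the package
defines one and documents it as its own construction: per topic, a
cascade of heterogeneity tests on topic-versus-other counts
(chi-square without continuity correction, Fisher's exact test whenever
an expected cell is below 5), BH-adjusted across topics.
Site-within-country heterogeneity (per-country tests combined by
Fisher's method) is tested *first*: a spike at one site also inflates
its country's aggregate, and attributing it to the site is the correct
reading. Country heterogeneity is tested second. A topic homogeneous
everywhere but elevated study-wide (share at least twice the uniform
reference share, at least 5 narratives) is study-systemic; everything
else, including all single-site studies and zero-count topics, is
indeterminate.

## Synthetic data generator

The generator emulates exactly the structure the null assumes:
participants draw visit counts uniformly from a discrete range (default
4–10) and deviation counts from Poisson with mean
$v \cdot \lambda \cdot e_i \cdot m_i$, where $\lambda$ is the base rate
per visit (default 0.5), $e_i$ an optional lognormal benign site effect
(default off, so the null is exact by construction), and $m_i$ a class
multiplier: 1 for null sites, 0.25 for injected under-reporters, 3 for
injected high-rate sites. A negative-binomial option (`dispersion`)
exists because real deviation counts are over-dispersed. Narratives are
rendered from keyphrase templates over a packaged synthetic two-level
vocabulary (5 categories × 15 topics styled after common deviation
themes: sample collection and laboratory, informed consent and
documentation, visit scheduling, medication administration, adverse
event reporting), drawn per country from a configurable category
mixture (default uniform). Every narrative's text contains its topic's
keyphrase, so the mock extractor recovers the planted truth exactly —
closing the end-to-end test loop.

What the generator does *not* emulate: realistic clinical language,
visit calendars, correlated deviations within participants, or
drifting site behaviour over time. Green tests therefore demonstrate
the statistical machinery and the pipeline contracts, not performance
on operational narratives.

## Numerical choices and problem sizes

- Tail probabilities use non-strict inequalities in both directions and
  the $(c+1)/(B+1)$ correction by default; exact-enumeration
  comparisons switch the correction off.
- The test suite verifies Monte-Carlo tails against exhaustive
  enumeration of all visit-matched replacement assignments on toy
  studies (up to $4^4$–$6^6$ assignments), the silhouette against an
  $O(n^2)$ brute-force oracle on random instances up to 50 points, and
  the Wilson interval against its closed form.
- Calibration runs use the documented study conditions: 200
  exchangeable-null studies of 20 sites × 10 participants, $\lambda =
  0.5$, $B = 500$; the empirical false discovery rate of flagging sits
  near 0.04, under the nominal 0.05. Power runs (100 studies, one
  injected under-reporter at multiplier 0.25) flag the injected site in
  essentially every replicate. Convergence runs use $B = 1000$ with the
  window 800–1000 over 20 seeds.
- All randomness flows from one root seed through per-study hashed
  streams; no global RNG state leaks between components.

## Known limitations

The detector is a signal-detection screen, not a predictive model; it
has no site-level covariate adjustment (investigator experience,
monitoring intensity), assumes one visit count per participant (no
per-visit evaluation grid), and inherits the conservativeness of
self-inclusive resampling. The mock backends are contracts plus
plausible behaviour, not models; accuracy numbers computed on synthetic
narratives say nothing about accuracy on operational free text.
Single-site studies cannot be scope-classified, and rare topics are
flagged as such precisely because inference about them is fragile.
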