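---
title: "Quantifying discourse coherence: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying discourse coherence: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semcoh)
```

## The problem

Incoherent speech — discourse that drifts off topic, connects poorly from
sentence to sentence, or is hard to follow — is a clinically salient sign
across the psychosis spectrum. A long line of work has tried to quantify it
by the semantic similarity of adjacent words in an embedding space, but
whether any given computational measure actually tracks *human-rated*
coherence, and does so consistently across languages, is an empirical
question. This package implements a deliberately broad battery of candidate
measures, an evaluation protocol for testing them against ordinal human
ratings in several languages at once, ordinal regression models for clinical
cohorts, and the connectivity-gradient dispersion statistics used to relate
coherence to whole-cortex functional organization.

## Unit levels and the minimum-unit rule

Every document is analyzed at three levels of meaningful units:

* **lexical** — content words (nouns, verbs, adjectives; proper nouns count
  as nouns by default, because picture descriptions and clinical narratives
  name entities — configurable via `include_propn`);
* **token** — subword tokens from the tokenizer paired with the contextual
  embedding backend;
* **sentence** — sentences of written text, or the pre-marked utterances of
  clinical transcripts, which are never merged or re-split.

Segmentation, tagging and tokenization are *injected contracts*: plain
functions passed into `segment_sentences()`, `extract_lexical_units()` and
`tokenize_subwords()`. The package ships rule-based defaults (a
terminal-punctuation splitter covering Latin and CJK scripts, a whitespace
tokenizer) and the test suite uses small lexicon-based fixtures, so no
pretrained model is ever required for the machinery to be exercised; any
production tagger or tokenizer plugs into the same seam. Text is
NFC-normalized and whitespace-collapsed on construction; case is left to the
backends.

A level enters the analysis only with **at least 4 units**; otherwise all of
its measures are missing. The boundary case (exactly four units) is treated
as usable; `min_units` makes the rule explicit and adjustable.

## The 131-measure battery

Let `u_1 … u_n` be one level's embeddings and
`s_t = cos(u_t, u_{t+1})` the first-order similarity series. Per level the
battery computes 43 measures (see `battery_names()` for the canonical
naming), and two probability measures complete the set: 43 × 3 + 2 = 131.
The count works out because the distribution descriptors and wave dynamics
are computed on the *first-order* series only (not on MeanK2's series), and
each centroid mode contributes its own mean + 6 descriptors + 6 dynamics.

Estimator choices that the battery fixes, with rationale:

* **Population moments** for Var/Skew/Kurt (`m2`, `m3/m2^1.5`,
  `m4/m2^2 − 3`). These are the common default in scientific
  signal-processing stacks and remain defined for very short series; a
  zero-variance series has undefined standardized moments and yields `NA`.
* **Mean-crossing rate** counts strict sign changes of `s_t − mean(s)`
  divided by `N − 1`; a point exactly on the mean is no crossing (sign 0
  never multiplies to a negative).
* **ApEn** uses embedding dimension `m = 2` and tolerance `r = 0.2 × SD`
  (population SD), the field-standard defaults for short physiological
  series, with self-matches included; both are configurable (`apen_m`,
  `apen_r`). A constant series scores 0 by convention.
* **ACF/AcfZcr**: ACF is the biased lag-1 autocorrelation estimator (the
  `stats::acf` convention); AcfZcr counts sign changes of the ACF over all
  estimable lags `1 … N − 2`, divided by the number of adjacent lag pairs.
  Series too short to yield two lags leave AcfZcr missing — visible in
  practice for 4-unit documents, where the cumulative-centroid series has
  only 3 points.
* **Graph threshold**: the document's own mean pairwise similarity at that
  level. This is parameter-free, adapts to each backend's similarity scale,
  and guarantees a non-trivial edge set for non-degenerate documents; a
  fixed scalar can be supplied instead. Edges are binary — weighted variants
  are a different measure family, not a drop-in.
* **Closeness on disconnected graphs** uses Wasserman–Faust component
  scaling, `((n_i − 1)/(n − 1)) · ((n_i − 1)/Σd)`, so small disconnected
  fragments are penalized rather than inflated; isolated nodes score 0 for
  both closeness and clustering.
* **Centroids** are computed on raw (unnormalized) embeddings; the
  cumulative series starts at the second unit (the first has no
  predecessors).
* **Natural logs everywhere**; perplexities are base-e.
* Cosines involving an all-zero (out-of-vocabulary) embedding row are
  missing, never 0 — a zero vector has no direction, and coding it as
  similarity 0 would fabricate signal.

The battery never raises on degenerate text: it always returns 131 named
values with `NA` where a measure is undefined, and a `missing_reason`
attribute saying why.

## Cross-language evaluation

For each feature and corpus, `spearman()` computes the rank correlation with
the human rating (average ranks for ties, two-sided t-approximation
p-values, pairwise-complete deletion — the missing-data handling is the
package's choice). The three languages' p-values of one feature form one
Benjamini–Hochberg family (`fdr_bh()`), and `classify_consistency()` applies
the verdict rule with significance at q < 0.05 and near-significance at
q < 0.1. Two readings in the rule were genuinely open and are resolved as
follows: "coefficients identical" for the Uncertain class is read as
*identical signs* (coefficients cannot be numerically identical across
corpora), and the third language's sign in the Uncertain class is left
unconstrained. A feature missing in more than half a corpus Fails with
reason `"insufficient data"` rather than risking a verdict from a biased
subsample.

## Clinical models

Subjects carry three per-sample coherence ratings; their mean is thresholded
at 1.8 and 2.2 into low/medium/high (`ordinal_coherence_label()`, boundary
values falling to the lower class). Ordered probit models are fit by maximum
likelihood through `MASS::polr(method = "probit")`, whose internal optimizer
is BFGS; z-statistics and two-sided normal p-values come from the
Hessian-based standard errors, and unstable fits (huge standard errors, the
signature of separation) are turned into errors instead of silently
reported. The healthy-control group is always the reference category.
Features entering probit models are z-scored first so main-effect and
interaction coefficients are per-SD and comparable across features.

`partial_spearman()` rank-transforms all variables and residualizes on the
rank-transformed covariates — the standard construction of partial Spearman
correlation — with `n − 2 − k` degrees of freedom. `rater_agreement()`
computes ICC(2,k) from the two-way ANOVA decomposition (two-way random
effects, absolute agreement, average measures) and Cohen's weighted κ
averaged over rater pairs; linear weights are the default (the choice is
exposed, and quadratic weights are available) because coherence is a short
ordinal scale where a two-step disagreement is not four times as bad as a
one-step one.

## Gradient dispersion

`fc_matrix()` is Fisher-z-transformed Pearson correlation with `r` clipped
at `±(1 − 1e−7)` (identical series would otherwise give infinite z) and a
zero diagonal. `diffusion_gradients()` is a compact diffusion-map embedding:
row-wise sparsification keeping the strongest 10% of each connectivity
profile (`sparsity = 0.9`), a cosine affinity between profiles mapped
through the strictly positive normalized-angle kernel `1 − acos(ρ)/π` (this
keeps the diffusion graph connected — a hard-thresholded cosine kernel can
disconnect unrelated parcel groups and degenerate the leading eigenspace),
anisotropic normalization with `alpha = 0.5`, and the leading non-trivial
eigenvectors of the symmetrized diffusion operator, ordered and scaled by
eigenvalue. These are the standard published defaults of this method family;
numerical parity with any specific gradient toolbox is explicitly not a
goal, and analyses depending on its exact kernel settings should not expect
value-level reproduction. Alignment of subject maps to a template is plain
orthogonal Procrustes (rotation/reflection, no scaling).

The dispersion statistics are deliberately elementary: between-network
dispersion is the absolute difference of network means on the principal
gradient; within-network dispersion is the sum of squared deviations from
the network centroid. Both are computed on component 1 only; further
components are retained in the `GradientMap` but unused by default.

## The synthetic-data generator

The generator emulates the *statistical structure the analyses assume*, not
natural language:

* **Documents** are random walks on the unit sphere:
  `u_i = normalize(α·t + β·u_{i−1} + ε_i)` with a document topic vector `t`,
  topic adherence `α`, persistence `β` (`α + β ≤ 1`), and spherical noise.
  Latent coherence is *defined* as `α` — a modeling choice: coherent
  discourse stays near its topic, which is what the centroid measures
  quantify. The first unit is a random direction, so limits like
  "MeanK1 → 1 as α → 1" hold asymptotically in document length.
* **Ratings** arise by standardizing `α` under its generating distribution,
  adding Gaussian noise, and cutting at fixed thresholds — an ordered-probit
  link, i.e. exactly the measurement model the clinical stage assumes.
* **Cohorts** shift the latent per group on the probit scale (defaults: CHR
  −0.2, FEP −0.9, CS −0.5, matching the qualitative ordering such studies
  report, with group sizes 29/18/29/18 typical of deeply phenotyped clinical
  samples); symptom scores are noisy monotone transforms of the latent.
  With `sample_noise_sd = 0` the label-generating process *is* the ordered
  probit model, which is the right regime for estimator-recovery studies.
* **Token log-probabilities** are `−|N(mean_nll, sd)|`, so the expected
  perplexity is `exp(mean_nll)` as the spread vanishes and
  `exp(mean_nll + sd²/2)` otherwise (lognormal correction).
* **Gradient data** draw parcel values around specified network means, or
  parcel time series from a block covariance so the diffusion embedding has
  a real block structure to find.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: lexical semantics and syntax, rater
idiosyncrasies beyond exchangeable noise, non-spherical embedding anisotropy
(real embedding spaces are famously anisotropic), document-length
confounding, medication and demographic structure beyond simple covariates,
and BOLD physiology. The synthetic results validate the *machinery*
(formulas, error control, estimator calibration), not the empirical claims
one would make on real corpora.

Simulation sizes used by the test suite and the acceptance script — corpora
of 100–150 documents of 8–28 units in 32 dimensions, cohorts of 400 for
recovery studies (200 HC / 200 FEP, so the planted contrast is estimated at
full precision), 50 simulated three-language studies for the end-to-end
check, 100 repetitions of 200-feature null families for error rates — were
chosen as the smallest sizes at which the planted effects are
unambiguous and Monte-Carlo margins small; they are the package's own
defaults and scale up freely.

## Interfaces

The package is a library: functions composed in R scripts (plus
`read_corpus()`, `write_features()`, `read_timeseries()` for the standard
file formats) are the intended interface, and the acceptance script shows an
end-to-end composition. Real embedding, language-model and
next-sentence backends are supplied by the user through the backend
contracts; the package ships only the deterministic synthetic backend, and
no pretrained weights are downloaded, selected or bundled.

## Known limitations

* The verdict rule's "identical coefficients" clause is interpreted as
  identical signs; other readings would change the Uncertain class only.
* The diffusion embedding is a simplified reimplementation; component values
  are comparable in structure, not numerically, to other toolboxes.
* ICC and κ are closed-form implementations validated against their ANOVA
  definitions and null/identity fixtures in the test suite, not against an
  external agreement package.
* Perplexity averaging is per scored token of the supplied series; whether a
  backend scores whitespace words or subwords is the backend's contract.
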