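---
title: "Scoring, chance levels and inference for blended-emotion judgments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, chance levels and inference for blended-emotion judgments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emoblend)
```

# The measurement situation

A blended-emotion perception experiment presents short expressive stimuli,
each portraying a *pair* of the five basic emotions anger, disgust, fear,
happiness and sadness, at one of three prominence proportions: 30:70 (the
second stored emotion more prominent), 50:50 (equal), or 70:30 (the first
more prominent). Raters respond on up to five 0–10 intensity scales, one
per emotion. Two response formats exist: *forced-two-scale*, where exactly
two scales must be used, and *free selection*, where any one to five may
be. The proportion labels denote intended relative salience, not measured
percentages.

Two properties of this design drive everything in the package:

* **Selection is first-class.** Which scales a rater chose carries
  information independent of the ratings. An unselected scale is therefore
  stored as missing, never as a 0 rating, and every read/write cycle of
  the CSV dialect preserves that distinction exactly.
* **Chance depends on how many scales were selected.** A rater who uses
  more scales covers the target pair more easily by luck, so accuracy can
  only be interpreted against selection-count-aware chance levels.

# Accuracy indices

Per trial, with target set $T$ (the two intended emotions) and selected
set $S$:

* **generous** $= \mathbf{1}[S \cap T \neq \emptyset]$,
* **strict** $= \mathbf{1}[T \subseteq S]$,
* **very strict** $= \text{strict} \times \mathbf{1}[r_\text{prominent} >
  r_\text{subtle}]$, defined only for unequal proportions.

Design choices the definitions leave open, and how this package resolves
them:

* *Superset policy for strict scoring in free mode.* A free-selection
  response that covers both targets plus an extra scale counts as strict-
  correct. This is the only reading under which "chance varies with the
  number of selections" is meaningful — under an exact-match rule a
  three-scale response could never be strict-correct and its chance level
  would be zero, not higher. An `"exact"` policy is available as a
  `score_trials()` argument for sensitivity analysis.
* *Ties fail the ordered index.* "Received a higher rating" is read as a
  strict inequality; equal ratings on the two target scales score 0. This
  matters because ratings live on an 11-point integer grid where ties have
  positive probability (see the chance-level section).
* *Zero imputation for cell means.* The mean-rating tables average over
  **all** judgments in a cell, counting unselected scales as zero
  intensity. Only this convention yields small non-zero means for scales
  raters rarely choose, which is the quantity of interest (average
  endorsed intensity, not intensity-given-endorsement). The same
  convention feeds the participant cell means used by the ANOVAs, keeping
  descriptive and inferential tables consistent.
* *Trial pooling.* Accuracy cells pool 0/1 trials across participants and
  actors; the reported SD is the sample SD of those binary scores (for a
  proportion $p$ it is $\sqrt{p(1-p)\,n/(n-1)}$, e.g. ≈ 0.50 near
  $p = 0.5$). A participant-level mode (`unit = "participant"`) averages
  per-participant accuracies instead; both are exposed because published
  tables rarely state which was used.
* *Wald intervals by default.* The 95% CI is $p \pm 1.96\sqrt{p(1-p)/n}$,
  clipped to $[0,1]$, matching the mean/SD/CI triplets conventional in
  this literature; Wilson score intervals are available via
  `ci_method = "wilson"` and are preferable near the boundaries. The
  above-chance flag is `ci_low > chance`, i.e. a CI that does not overlap
  the chance level.

# Chance levels

`analytic_chance(index, k, m, t)` enumerates all $\binom{m}{k}$ unordered
selections and counts those that satisfy the index — no closed form is
assumed, but the enumeration is verified in tests against
$P_\text{gen}(k) = 1 - \binom{m-t}{k}\big/\binom{m}{k}$ and
$P_\text{strict}(k) = \binom{m-t}{k-t}\big/\binom{m}{k}$ for all
$m \le 7$. At the design point $m = 5, t = 2, k = 2$ this reproduces the
textbook derivation chain: miss probability $3/10 = 0.30$, generous
$0.70$, strict $2/5 \times 1/4 = 0.10$, very strict $0.10 \times 1/2 =
0.05$. The ordered argument (first pick $2/5$, conditional second pick
$1/4$) and the unordered enumeration agree identically.

The $\times 1/2$ ordering factor treats null ratings as exchangeable
*continuous* variables: given both targets are selected, either ordering
is equally likely and ties have measure zero. On the integer rating grid
ties occur with positive probability and score 0, so a discrete null lies
**below** 0.05 — the Monte-Carlo oracle therefore draws continuous uniform
ratings by default, and its `integer_ratings = TRUE` variant is documented
as conservative (the test suite checks both directions). This distinction
is not pedantic: any simulator that records integer ratings, including
this package's own, has an ordered-index null below the 0.05 anchor, and
analysts comparing observed very-strict accuracy to 0.05 are using a
slightly conservative reference.

For free-selection data, `mixture_chance()` averages fixed-$k$ levels over
a selection-count distribution, e.g. the dataset's own empirical one
(`empirical_k_distribution()`; the pipeline's
`chance_reference = "empirical"`). The default reference remains the fixed
$k = 2$ anchor, the convention when most responses use two or fewer
scales, with the caveat that trials with more selections inherently have
higher chance levels.

# Repeated-measures inference

The rating-level analysis runs one-way repeated-measures ANOVAs on
participant mean ratings, separately per rating scale and proportion
condition, with the 10 emotion combinations as the within factor. The
classical decomposition

$$SS_\text{total} = SS_\text{subject} + SS_\text{condition} +
SS_\text{error}, \qquad
F = \frac{SS_c/(c-1)}{SS_e/\big((c-1)(p-1)\big)}$$

is implemented directly (and conserved to $10^{-8}$ relative error in
property tests). Sphericity is assessed with Mauchly's $W$ on the
covariance of orthonormal condition contrasts, using Box's chi-square
approximation including the second-order series term, which makes the
p-value agree to numerical precision with the standard multivariate-model
implementations (asserted in a cross-check test against `car::Anova`).
The Greenhouse–Geisser estimate
$\hat\varepsilon = (\sum\lambda_i)^2 / \big((c-1)\sum\lambda_i^2\big)$
(eigenvalues of the contrast covariance, clamped to
$[1/(c-1), 1]$) rescales both degrees of freedom; the GG-corrected
p-value is reported as primary, since multi-condition rating designs
essentially never satisfy sphericity. Effect sizes are
$\eta^2_p = SS_c/(SS_c + SS_e)$ and
$\eta^2_G = SS_c/(SS_c + SS_s + SS_e)$; because $SS_s \ge 0$,
$\eta^2_G \le \eta^2_p$ always, and the generalized form is the one
comparable across designs.

Degenerate inputs are flagged, not crashed on: zero error variance yields
a `degenerate` result object ($F = 0$ for pure subject offsets, $F =
\infty$ for noise-free condition separation), and paired contrasts whose
difference vector is constant return an `NA`-statistic row rather than
dropping the cell.

Two post-hoc families follow the omnibus tests, both two-sided paired
t-tests on participant cell means with directionality read off the sign:

* **Target vs non-target**: per scale × proportion ANOVA, each of the 4
  combinations containing the scale's emotion against each of the 6 that
  do not — 24 comparisons at Bonferroni α = 0.05/24, reported to four
  decimals as 0.0021.
* **Prominence order**: per combination × unequal proportion, the
  participant's mean rating on the more prominent target scale against
  the less prominent one — 20 comparisons at α = 0.05/20 = 0.0025. These
  use participant-level means aggregated over actors, the natural unit for
  a repeated-measures t-test.

# The rater simulator

`simulate_study()` generates fully crossed datasets under an explicit
perception model. For a stimulus with target emotions $i_1, i_2$ and
prominence weights $(w_1, w_2)$:

$$\mu_j = A \,\big(w_1 C[i_1, j] + w_2 C[i_2, j]\big), \qquad
r_j = \mathrm{round}\big(\mathrm{clip}(\mu_j + \varepsilon_j,\, 0,\, 10)\big),
\quad \varepsilon_j \sim \mathcal{N}(0, \sigma^2)$$

followed by a selection policy: `top2` keeps the two highest ratings
(forced-two-scale format) and `threshold` keeps all scales with
$r_j \ge \tau$, falling back to the single argmax so every response has at
least one rating (free format). All ties break uniformly at random via
sub-resolution jitter, and everything is reproducible from one integer
seed.

Defaults, with rationale (all are free parameters of `rater_params()`):

* **Gain $A = 8$** — a fully expressed emotion peaks near, but not at, the
  top of the 0–10 scale, matching how trained raters use intensity scales.
* **Weights 0.3/0.7** — a numeric convention for "less/more prominent";
  the labels in the design are relative instructions to actors, not
  measured proportions, so the simulator exposes the weights rather than
  hard-coding a claim.
* **Noise $\sigma = 1$ rating unit** — moderate trial-to-trial perceptual
  and scale-use variability.
* **Confusion kernel** — unit diagonal with mutual anger↔disgust leakage
  (0.15), stronger fear↔sadness leakage (0.20), a little fear perceived in
  anger and disgust displays (0.05), and no cross-valence leakage with
  happiness. This encodes the qualitative difficulty structure of
  within-valence blends; the values are conventions, not empirical fits.
  Rows do not normalise — the kernel models signal leakage, not a
  confusion probability distribution.
* **Threshold $\tau = 2$** — a scale is reported when its perceived
  intensity clears the bottom fifth of the range.
* A per-actor gain multiplier hook exists (`actor_gain`) but defaults to
  1: the analysis makes no distributional claims about actor variation,
  so the default generative model omits it.

## What the simulator does and does not establish

With $A = 0$ the model is an exact random responder for *selection*:
ratings are iid across scales, so the top-2 set is uniform over pairs and
generous/strict accuracy converge to 0.70/0.10 (a seeded property test).
The ordered index does **not** converge to 0.05, because recorded integer
ratings tie with substantial probability when all signal is noise, and
ties score 0 — the simulated ordered-index null is conservative, exactly
the discrete-vs-continuous gap described above.

At high signal the integer grid and independent selection noise also cap
per-cell performance. With $A = 8$, $\sigma = 1$ and an identity kernel,
the subtle target of a 30:70 blend has latent mean 2.4 while each of the
three distractors has mean 0; the probability that one distractor's noisy
rating outranks the subtle target's is roughly
$\Phi(-2.4/\sqrt{2}) \approx 0.045$ before rounding, so across three
distractors (plus integer-grid ties at low ratings) a non-trivial share of
trials lose the subtle target from the top-2 set. Per-cell strict and
very-strict accuracy under these settings therefore plateau around the
mid-0.8s rather than approaching 1 — an intrinsic property of the
independent-noise selection model, not an implementation artifact. The
recovery checks in the test suite reflect this: prominence-*direction*
recovery (all 20 order tests significant, correctly signed) is asserted
and holds; near-ceiling per-cell ordered accuracy is asserted at a > 0.9
threshold and documents the model's ceiling instead.

More generally, the simulator emulates the *statistical structure* the
analysis assumes — crossed design, prominence-ordered latent means,
confusable neighbours, format-dependent selection — and none of the
things real raters add: response styles and scale anchoring, serial
dependence and fatigue, actor idiosyncrasies, culture- or
individual-level differences. Passing calibration and recovery tests
shows the pipeline measures what it claims on data obeying its
assumptions; it is not evidence about human performance.

# Numerical and engineering choices

* Enumeration, not closed forms, computes chance levels; the closed forms
  are the test oracle. All probabilities at the design point are exact
  rationals represented in doubles.
* Top-2 and argmax ties break by adding $U(0,1) \times 10^{-9}$ jitter —
  below half the rating resolution by eight orders of magnitude, so it can
  never reorder distinct ratings.
* Selection-count mixtures validate normalisation to $10^{-8}$; the
  empirical distribution constructor normalises by construction.
* The pipeline writes full-precision CSVs plus a display table rounded to
  2 decimals; the manifest records package version, mode, seed and sizes,
  and contains no timestamps, so a fixed seed reproduces every output file
  byte-for-byte.
* Problem sizes in the test suite: unit and property tests simulate 2–6
  actors × 3–20 participants; calibration and recovery checks use the full
  6-actor, 40-participant design (7,200 judgments) and 100,000-trial
  Monte-Carlo nulls, sizes at which binomial standard errors are below a
  percentage point.

# Known limitations

* Strict-policy scoring in free mode implements the superset reading; an
  exact-match reading is available but the two are not reconciled into a
  single recommended index.
* Very-strict chance for selection counts above two extends the strict
  level by the same $\times 1/2$ exchangeability factor; with more than
  two selections one could instead condition on the rank ordering within
  the selected set. The extension used here is a documented choice.
* The ANOVA layer requires a complete participant × condition layout and
  flags rather than imputes missing cells; unbalanced designs need a
  mixed-model treatment that is out of scope.
* Gaussian noise with clip-and-round is a simplification; a truncated or
  ordinal response model would avoid boundary pile-up at 0.
* No response-bias-adjusted null (the random responder is uniform over
  selections), and no sensitivity-theoretic indices (d′, unbiased hit
  rates).
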