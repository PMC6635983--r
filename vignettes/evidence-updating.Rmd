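---
title: "Half-normal Bayes factors and evidence updating for factorial trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Half-normal Bayes factors and evidence updating for factorial trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(factorialBF)
```

## The problem

A 2^5 factorial trial randomises each participant to an 'enhanced' or
'minimal' version of each of five intervention components (here, modules of
an alcohol-reduction app for adult UK drinkers screening positive for
excessive drinking, AUDIT >= 8). The analysis questions are whether each
component, pairs of components, or a promising subset of components reduce
past-week alcohol consumption (PWAC, UK units/week) or the full AUDIT score
at one-month follow-up.

Frequentist analysis of such a trial is locked to its pre-specified stopping
rule: once the planned sample is analysed, recruiting further and
re-testing inflates the type-I error without bound. Bayes factors do not
have this defect — under a true null they are driven towards zero as data
accumulate — so a trial whose data collection continued past the planned
stopping point can be *topped up*: the evidence is simply recomputed on the
pooled dataset. This package implements that workflow end to end, together
with a synthetic-trial generator so every stage can be exercised and tested
without access to any participant-level data.

## The Bayes factor model

Each contrast is reduced to a mean difference $d$ between two groups with a
standard error $s$. The difference is signed so that **positive means the
predicted direction**: for change scores (follow-up minus baseline;
negative = reduction), $d$ = minimal-group change − enhanced-group change,
so a greater reduction under enhanced is positive; for LOCF consumption
levels, $d$ = minimal level − enhanced level. The standard error is the
Welch (unpooled) formula $s = \sqrt{s_a^2/n_a + s_b^2/n_b}$.

The null hypothesis is a point mass at zero effect. The alternative models
the predicted effect $\delta$ with a **half-normal prior** $H(0, \tau)$:
peaked at 0, scale $\tau$ equal to the expected effect size, support
restricted to the predicted direction. This is deliberately conservative —
it says the intervention has at least some positive effect, smaller effects
being more plausible than larger ones. The Bayes factor is

$$
\mathrm{BF}_{10} = \frac{\int_0^\infty N(d;\,\delta, s)\,
\mathrm{HN}(\delta;\,\tau)\, d\delta}{N(d;\,0, s)} ,
$$

with the closed form

$$
m_1 = 2\, N\!\left(d;\, 0, \sqrt{s^2+\tau^2}\right)
\Phi\!\left(\mu_p/\sigma_p\right),\qquad
\mu_p = \frac{d\,\tau^2}{\tau^2+s^2},\quad
\sigma_p = \sqrt{\frac{\tau^2 s^2}{\tau^2+s^2}} .
$$

A normal (not t) likelihood is used for the observed difference: it is the
convention of the standard online calculators for this method, and it
reproduces the published reference rows (below) to well within their
printed precision. The closed form is evaluated in log space, so extreme
scale ratios do not underflow; an independent adaptive-quadrature route is
retained in the package and the two are held to 1e-8 relative agreement by
the test suite. An observed difference *opposite* to the prediction is
allowed — the prior's support stays on the predicted side, so such data
push the BF below 1.

Two limits anchor the interpretation: as $\tau \to 0$ the alternative
collapses onto the null and BF $\to$ 1; as $\tau \to \infty$ the
alternative spreads over implausible effects and BF $\to$ 0. At $d = 0$
the BF collapses analytically to $s/\sqrt{s^2+\tau^2}$.

### Prior scales

The primary consumption analysis uses $\tau = 5$ units/week (a large,
brief-intervention-sized effect, $d \approx 0.22$ with SD 23); robustness
scans add $\tau = 3$ (medium) and $\tau = 0.5$ (small) for relative
judgment. For the AUDIT outcome the consumption effect is translated
through Cohen's d: $0.22 \times 6.56 = 1.4432$ AUDIT points (`translate_effect()`
keeps full precision; published reports round this to 1.45 — the package
does not hard-code the rounded value).

### Evidential categories

`interpret_bf()` maps a BF to nine conventional labels, from "Very strong
evidence for H1" (BF > 30) through "No evidence" (BF = 1) to "Very strong
evidence for H0" (BF < 0.03). The printed bands of such tables touch
(0.33–1, 1–3, ...); the package resolves them left-closed/right-open on
the null side and left-open/right-closed on the alternative side, so every
BF lands in exactly one band. The coarse sensitivity rule is preserved:
BF < 1/3 supports the null, 1/3–3 means the data are insensitive, > 3
supports the alternative.

## Contrasts

* **Main effect** — everyone with the component enhanced vs everyone with
  it minimal, pooled over the other four components (n/2 vs n/2 in a
  balanced design).
* **Two-way interaction** — enhanced/enhanced vs minimal/minimal cells for
  a pair; mixed cells are excluded, and no model-based interaction term is
  fitted (n/4 vs n/4).
* **Synergy** — all components of a chosen subset enhanced vs all minimal,
  components outside the subset unconstrained (n/2^k per side for a
  k-component subset). The four-component synergy contrast, with the
  fifth component left free, is the package's worked reference example.

Each contrast also reports the pooled-variance one-way F (the square of
the pooled t) and its two-tailed p on $F(1, n_a+n_b-2)$ for the
frequentist report columns, while the **Welch** SE feeds the Bayes factor.
No multiplicity adjustment is applied across the 5 main and 10 interaction
contrasts; the run log records how many contrasts were computed.

## Missing outcomes

Analyses are run among *responders* — participants who completed the
follow-up primary outcome. A record with follow-up consumption but no
follow-up AUDIT is a responder for consumption analyses only. The LOCF
sensitivity set instead uses consumption **levels** for everyone:
follow-up for responders, baseline carried forward for non-responders.
LOCF maintains the variability in the data; a full intention-to-treat
assumption (non-responders drink at baseline, i.e. zero change) is *not*
offered as a change-score analysis, because assuming no change in ~87% of
the sample crushes the variance and mechanically manufactures support for
the null — the one situation in which these Bayes factors are known to
mislead.

## Topping up

`topup()` recomputes the chosen contrast at each recruitment-phase
boundary (original end, extended end), always from the pooled raw records
up to that point. Bayes factors are never chained by multiplying
per-batch factors: the half-normal prior is a model of the effect, not a
posterior to be updated per batch, so the honest update is a fresh
computation on more data. The final snapshot is therefore identical, field
for field, to a single-pass analysis of the concatenated dataset (a
property the test suite asserts exactly).

## Planning

`two_sample_power()` implements the normal-approximation power of a
two-sample two-tailed test,
$\Phi\!\left(|\delta|/(\sigma\sqrt{2/n}) - z_{1-\alpha/2}\right)$.
Under the package's default planning assumptions (control 27 units/week at
follow-up, intervention 22, common SD 23, $\alpha = 0.05$, 1:1 allocation;
d = 0.22) the power at 336 per group is 0.804 — the 80% that sized the
original 672-participant phase. At these sample sizes the normal
approximation is within 0.002 of the noncentral-t answer (asserted against
`power.t.test` in the tests); at $\delta = 0$ it returns $\alpha/2$, the
rejection rate on the predicted side.

## The synthetic-trial generator

`simulate_trial()` emulates the study conditions the analysis assumes, so
that every pipeline stage is testable without any external data:

* **Sample structure** — 672 original-phase + 1914 extended-phase
  participants by default; permuted-block randomisation with blocks of 32
  (every cell of the 2^5 design once per block), giving exact cell and
  margin balance at block boundaries. The published design states block
  randomisation without a block size; one cell per block is the natural
  choice for a 2^5 design.
* **Baselines** — consumption mean 39.0 SD 26.93 units (support [0, ∞));
  AUDIT mean 19.1 SD 6.66 (support [8, 40], so eligibility holds by
  construction). Naive truncation of normals at these bounds would inflate
  the consumption mean by ~10%, so the generator solves for the parent
  normal whose *truncated* distribution matches the target mean and SD
  (moment-matched truncated normals); the simulated moments then agree
  with the targets to Monte-Carlo error.
* **Response** — Bernoulli per phase (26.6% original, 8.5% extended),
  missing completely at random; the real response mechanism is unknown,
  and MCAR is a stated simplification.
* **Change scores** — overall mean change −12.5 units/week (the level of
  reduction seen across arms in this population), plus additive
  per-component effects and optional pairwise interaction effects
  (negative = greater reduction), plus noise with SD 23. The noise is
  anti-correlated with baseline (correlation −0.935): with independent
  noise, the floor at zero follow-up consumption would censor roughly a
  fifth of responders, biasing the mean change by several units and
  attenuating the very effects the recovery tests measure. The coupling —
  heavy drinkers regress further towards a common follow-up level — keeps
  the configured change mean/SD exact and makes the floor a <0.5% event
  (a `max(0, ·)` clamp remains as a guard). Follow-up consumption is held
  to 0.1 units so CSV round trips are lossless.
* **AUDIT follow-up** — a noisy linear companion of the consumption change
  (scaled by the SD ratio 6.56/23, own noise SD 5.8, clamped to [0, 40]).
  This is a testing device to exercise the secondary-outcome pipeline,
  not a claim about the real joint distribution.

What passing tests on this generator do **not** show about real data: real
non-response is almost certainly informative, real change scores are not
exactly normal, and the true baseline–change dependence is unknown. The
generator's role is to verify the *analysis machinery* (directionality,
pooling, balance, recovery, evidence consistency), not to certify field
effectiveness.

## Numerical and design choices

* BFs are computed and stored at full precision; report tables round BFs
  to 2 decimals, F and p to 3, means/SDs to 2 (the conventional published
  rounding).
* Degenerate inputs (non-positive SE or prior scale, groups below n = 2,
  empty contrast cells, unknown phase labels, duplicated ids across
  phases) are rejected with the offending field or id named.
* Problem sizes used by the test suite were chosen to make Monte-Carlo
  error small relative to the assertions: moment checks at n = 100,000,
  parameter recovery at n = 50,000 (3 Monte-Carlo SEs ≈ 0.6 units), and
  evidence-consistency at 500 replicates of the default 2586-participant
  cohort.
* All simulation is seed-pinned; identical configs give byte-identical
  CSV output.

## Known limitations

* Per-arm responder counts for the main-effect and interaction tables are
  not published, so those rows are validated by property-based tests
  rather than bit reproduction; only the four-component synergy table is
  fully self-contained and is reproduced exactly (to its printed input
  precision) by `summary_mode()`.
* The AUDIT-C frequency × quantity → weekly-units mapping is not
  specified in the source material; consumption is consumed as a provided
  numeric column and the mapping is left to callers.
* Three-way and higher interactions, covariate-adjusted models,
  credible intervals and formal sequential stopping designs are out of
  scope.
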