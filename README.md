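# factorialBF

Bayes-factor analysis and sequential evidence updating for
multi-component (2^k) factorial trials, built around the half-normal
prior on a directional effect.

## The problem

Factorial trials of multi-component interventions — here the motivating
case is a five-module alcohol-reduction app evaluated in a 2^5 design
among adult UK drinkers with AUDIT ≥ 8 — often end with non-significant
results that cannot distinguish "no effect" from "not enough data".
Frequentist inference is also locked to the pre-specified stopping rule:
data that keep accruing after the planned sample is reached cannot be
re-analysed. Bayes factors solve both problems: they quantify support for
the null as well as the alternative, and they may be recomputed on a
dataset "topped up" with extended recruitment, because under a true null
they are driven towards zero as data accumulate.

`factorialBF` is for trialists and methodologists who want that workflow
as tested, reusable code: factorial contrasts, half-normal-prior Bayes
factors with robustness scans, evidential categorisation, responders-only
and last-observation-carried-forward analysis sets, phase-wise evidence
trajectories, planning power calculations, and a synthetic-trial
generator so the whole pipeline runs and is tested without any
participant-level data.

## The statistic

Each contrast is summarised by a predicted-direction mean difference *d*
(positive = greater reduction under the 'enhanced' condition) and its
Welch standard error *s*. The alternative hypothesis is a half-normal
prior H(0, τ) on the true effect — peaked at zero, scale τ equal to the
expected effect size, support on the predicted side only. The Bayes
factor against the point null is

    BF10 = [ ∫₀^∞ N(d; δ, s) · HN(δ; τ) dδ ] / N(d; 0, s)
         = 2 · N(d; 0, √(s²+τ²)) · Φ(μp/σp) / N(d; 0, s),

with μp = dτ²/(τ²+s²) and σp = √(τ²s²/(τ²+s²)). The consumption analyses
scan τ = 5, 3, 0.5 units/week (large/medium/small expected effects); the
AUDIT analysis uses the d-translated τ = 0.22 × 6.56 = 1.4432 points.
BF < 1/3 supports the null, 1/3–3 means the data are insensitive, > 3
supports the alternative; `interpret_bf()` refines this into nine
conventional bands.

Contrasts supported: per-component **main effects** (enhanced vs minimal,
pooled over the rest), **two-way interactions** (enhanced/enhanced vs
minimal/minimal, mixed cells excluded) and **synergy** contrasts (all of
a 2–5 component subset enhanced vs all minimal, other components free),
each with pooled-variance F and p for the frequentist report columns.

## Worked example

Reproduce a published synergy row from its printed group summaries alone
(responders only, four components all-enhanced n=27, mean change −21.6,
SD 20.36 vs all-minimal n=12, mean change −12.1, SD 26.82):

```r
library(factorialBF)
summary_mode(27, -21.6, 20.36, 12, -12.1, 26.82, scales = c(5, 3, 0.5))
#>  mean_diff   se     F     p bf_h0_5 bf_h0_3 bf_h0_0.5                  category
#>        9.5 8.68 1.484 0.231    1.42    1.29      1.05 Anecdotal evidence for H1
```

The 9.5-unit greater reduction under the enhanced combination is
anecdotal (insensitive) evidence for a synergistic effect: BF = 1.42 at
the 5-unit prior scale, decaying towards 1 as the expected effect
shrinks.

A full synthetic top-up run:

```r
recs <- simulate_trial(sim_config(seed = 42))   # 672 + 1914 participants
phase_accounting(recs)
#>      phase    n responders response_rate_pct
#> 1 original  672        183              27.2
#> 2 extended 1914        151               7.9
#> 3  overall 2586        334              12.9

traj <- topup(recs[recs$phase == "original", ],
              recs[recs$phase == "extended", ],
              contrast_spec("synergy", c("nf", "cbr", "smf", "ap")))
as.data.frame(traj)
#>      phase n_cumulative n_analysed mean_diff   se      F     p bf_h0_5 bf_h0_3 bf_h0_0.5                  category
#> 1 original          672        183     -2.05 8.24 0.0683 0.796   0.774   0.879     0.986 Anecdotal evidence for H0
#> 2 extended         2586        334     -1.78 5.94 0.0874 0.769   0.660   0.804     0.977 Anecdotal evidence for H0
```

This null cohort behaves as the method promises: topping up moves the
Bayes factors towards the null. Planning arithmetic:

```r
two_sample_power(5, 23, 336)   # 5-unit effect, SD 23, 336/group
#> 0.8044846
```

`run_analysis(run_config(...))` wraps reading, eligibility filtering,
contrast selection and report/trajectory/log writing; a thin CLI with
`analyze`, `summary`, `simulate` and `topup` subcommands is installed at
`inst/scripts/factorial-bf.R`.

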