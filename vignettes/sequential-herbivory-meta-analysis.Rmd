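---
title: "Methods: multilevel meta-analysis of sequential-herbivory experiments"
author: "seqherb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multilevel meta-analysis of sequential-herbivory experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqherb)
```

## The problem and the data model

A sequential-herbivory experiment exposes a plant to an inducing herbivore
and later measures a response — performance or preference of a subsequent
herbivore, or performance of the plant itself — against a control in which
the subsequent herbivore attacks a previously undamaged plant. A synthesis
of this literature collects, per experimental comparison, the raw arm
summaries (means, SDs, sample sizes, or event counts for survival/choice
outcomes) together with moderators describing the herbivores (feeding
guild, diet breadth, feeding location, conspecificity), the plant (life
cycle, growth form, cultivation status) and the design (setting, inducer
removal, feeding durations, publication year).

Two features of such tables drive the entire statistical design:

* **Nesting.** A publication (study) contributes many comparisons, and
  several induction treatments within a study are compared against the
  *same* control. Effect sizes are therefore dependent at two levels, and
  the package's canonical record model keys every row by `study_id` and a
  globally unique `treatment_id` nested within it.
* **Mixed metrics.** Most records are mean-based and yield Hedges' g; a
  minority report individual survival or choice counts and yield log odds
  ratios. These are analyzed separately (the LOR subset serves as a
  validation arm), never pooled on one scale.

## Effect sizes

For mean-based records the package computes the standardized mean
difference with small-sample correction,

$$g = J\,\frac{\bar{x}_t - \bar{x}_c}{\sigma_p},\qquad
\sigma_p = \sqrt{\frac{(n_t-1)\sigma_t^2 + (n_c-1)\sigma_c^2}{n_t+n_c-2}},\qquad
J = 1 - \frac{3}{4(n_t+n_c-2)-1},$$

with the standard large-sample sampling variance
$(n_t+n_c)/(n_t n_c) + g^2/\{2(n_t+n_c)\}$. For two outcomes a larger raw
value means *worse* performance — herbivore development time and plant
damage — so the sign of g is reversed exactly once at computation time and
the reversal recorded on the row. The resulting convention is uniform:
negative g = lower herbivore/plant performance after induction (induced
resistance), positive g = induced susceptibility.

Binary records use the log odds ratio of the treatment arm against the
control arm with variance $1/a + 1/b + 1/c + 1/d$; when any cell of a 2×2
table is zero, 0.5 is added to all four cells of that table only (the usual
continuity correction). Tables with both arms all-events or all-nonevents
carry no information about the odds ratio and are excluded with a warning.

Records lacking an SD or sample size for a mean-based outcome are excluded
at effect-size computation time with a warning naming them; no imputation
is attempted, because none can be justified from the summaries alone.
Choice experiments are treated as independent two-group comparisons; if the
underlying design was paired, the computed sampling variances are
conservative approximations — a known limitation.

## The multilevel model

All models have the form

$$y = X\beta + Z_s u_s + Z_t u_t\,(+\,Z_p u_p) + \varepsilon,\qquad
u_s \sim N(0, \sigma^2_{study} I),\;
u_t \sim N(0, \sigma^2_{trt} I),\;
u_p \sim N(0, \sigma^2_{taxon} R),\;
\varepsilon_i \sim N(0, v_i),$$

with the sampling variances $v_i$ known from the effect-size step. The
three-level structure (sampling error, treatment-within-study,
between-study) is used for the overall models as well as the moderator
models: the high multilevel I² values typical of this literature are only
meaningful under that decomposition, and overall and moderator fits should
differ only in $X$.

**Estimation.** Variance components are estimated by REML. The restricted
log-likelihood is evaluated through a sparse Cholesky factorization of the
marginal covariance $V = \Sigma_j \sigma^2_j G_j + \mathrm{diag}(v)$ whose
symbolic analysis is computed once and reused across optimizer steps; for
the nested-only models $V$ is block-diagonal in studies, so one evaluation
costs the sum of cubed block sizes rather than $k^3$. Components are
optimized on the log scale — which keeps the optimizer away from the
boundary — by a quasi-Newton method with three starts (a moment-based
profile start, a small start of 0.001, a moderate start of 0.5) and
relative tolerance 1e-10. Any component driven below 1e-7 is re-tested
against the fit with that component constrained to exactly zero, and the
constrained fit is adopted when it is not worse; this reproduces the exact
zeros a profiled non-negative parameterization would report. The reported
log-likelihood includes the $+\tfrac12\log|X'X|$ constant so values are
directly comparable with the standard multilevel meta-analytic tooling.

**Inference.** Fixed effects are GLS at the optimum with Wald-z intervals;
the omnibus moderator test is the Wald chi-square $b'V_b^{-1}b$ on all
non-intercept coefficients (treatment coding, so a categorical moderator
with L levels has df = L−1). No small-sample t/F correction is applied —
the convention of the standard tooling for this model class, and the
appropriate default at the k in the hundreds typical here. Heterogeneity is
summarized by the multilevel I²,
$100\,\Sigma\sigma^2/(\Sigma\sigma^2+\tilde v)$ with
$\tilde v = (k-1)\Sigma w_i/\{(\Sigma w_i)^2-\Sigma w_i^2\}$, and
intercept-only fits also report the 95% prediction interval
$\hat\beta \pm 1.96\sqrt{se^2+\Sigma\sigma^2}$ — the interval for the true
effect of a *new* study, which in this heterogeneous literature is far
wider than the CI and is the honest statement about any single
plant–herbivore system.

**Degenerate inputs.** A single observation returns its own value and
sampling SE (no random structure is estimable). Rank-deficient moderator
designs error naming the aliased levels rather than silently dropping them.
Continuous duration moderators enter linearly in days, untransformed.

## Phylogenetic correlation

Taxon-level dependence is modeled as one additional crossed random
intercept whose correlation matrix comes from a user-supplied (or
simulated) phylogeny under Brownian motion: `VCV[i,j]` is the shared
root-to-MRCA path length and the correlation scales it to unit diagonal by
$\sqrt{d_i d_j}$, which is exact for ultrametric trees and remains a valid
correlation otherwise. Covariance scaling is available behind a flag, but
correlation is the default: it keeps $\sigma^2_{taxon}$ interpretable on
the same scale as the other components. Only one phylogeny is included per
model — plant, inducer and subsequent-herbivore trees are fitted as three
separate sensitivity models, since multiple crossed correlated terms are
poorly identified on data of this shape.

Pruning keeps the path from the original root to the retained tips' most
recent common ancestor as a root edge, so the correlation among retained
taxa is unchanged by pruning (prune-then-convert equals
convert-then-select). Taxon names are matched case- and
underscore-insensitively; taxa absent from the tree are returned as an
exclusion list and their records dropped from phylogeny-augmented fits —
no genus-level substitution is attempted.

## Publication-bias battery

* **Cumulative meta-analysis** refits the full three-level model on each
  publication-year-closing prefix (ties broken by study then record id, so
  the series is invariant to within-year row order). Prefixes too small to
  identify a component have it estimated at the zero boundary and flagged.
* **Funnel coordinates** are emitted as plot-ready tables (effect vs SE,
  with pseudo-CI rails meeting at the pooled estimate).
* **Egger-type asymmetry** comes in the two variants used in large
  syntheses, and they answer slightly different questions: a
  random-effects metaregression of the effect on its standard error (Wald
  z; applied per response category), and an unweighted OLS regression of
  the effect on its inverse variance (slope F on (1, k−2); applied to the
  pooled mean-based effects).

One behavior deserves emphasis: because the sampling variance of Hedges' g
contains a $g^2$ term, effect and SE are intrinsically correlated whenever
the true mean effect is away from zero. On synthetic data generated with
*no* selection bias but a negative true mean, the weighted SE-regression
reliably reports a negative z — the same signature as a genuinely negative
funnel skew. Per-category asymmetry statistics for SMD outcomes should
therefore be read as descriptions of funnel shape, not as proof of
selective publication; the package's calibration tests establish uniform
null p-values only under effects whose variances are independent of their
values.

## Sensitivity analyses

Leave-one-species-out refits remove every record involving a named species
in a named role (host plant, inducing herbivore, subsequent herbivore) —
the three most-studied species per role by default — and report the share
of observations removed, the estimate shift, and whether the refit CI
excludes the full-data estimate (the criterion for calling an exclusion
consequential). The binary-outcome validation recomputes the analysis on
the LOR subset, fitting survival and choice classes separately plus a
class-contrast QM test.

## The synthetic-data generator

The generator is first-class, tested code: it emits *raw summaries*, not
effect sizes, so the full pipeline is exercised end to end. Each record's
true effect is $\theta = \mu + \delta_{cat} + u_{study} + u_{trt}
(+ u_{taxon})$; mean-based arms then draw a control mean $N(0,
\sigma^2/n_c)$, a treatment mean $N(\theta\sigma, \sigma^2/n_t)$ and
observed SDs from the scaled-chi sampling distribution, so computed g
values are centered on $\theta$ with realistically varying sampling
variances. Records with sign-reversed outcomes draw the treatment mean at
$-\theta$, so the downstream sign convention recovers $\theta$. Binary
records draw counts from proportions whose logit offset is the target LOR
plus the same study/treatment deviates.

Default configuration (chosen once, as the generator's definition of the
study conditions it emulates): 161 studies with 1–4 treatments of 1–7
records (≈1500 effects); mean-based response categories in proportions
834:339:172 with true means −0.326 (herbivore performance), −0.142
(preference) and −0.013 (plant performance); a binary fraction of 160/1505
with true survival LOR −0.80; per-arm group sizes 10–30; publication years
1985–2023; heavily skewed species pools (top plant ≈13.5% of records) with
rare mammalian inducers and none as subsequent herbivore; and
$\sigma^2_{study} = 0.55$, $\sigma^2_{trt} = 0.35$, which at the default
group sizes put the multilevel I² near 88%. A single global pair of
components cannot reproduce three different per-category I² values at
once; the generator prioritizes the overall heterogeneity level. What the
generator does *not* emulate: publication selection, correlated moderators
beyond the annual/cultivated association, non-normal raw outcomes, and
paired-choice dependence — so passing recovery tests demonstrate the
pipeline's correctness under its own assumptions, not robustness to those
violations.

Reproducibility is per-study: each study's draws come from a seed stream
hashed from (global seed, study index), so enlarging a simulation never
perturbs existing studies. Simulated phylogenies are ultrametric pure-birth
trees.

## Validation strategy and problem sizes

The test suite checks, at sizes chosen to keep the default run in minutes:
effect-size arithmetic against step-by-step hand evaluation (25 randomized
instances, 1e-10) and an established implementation; the REML fitter
against an independent dense grid-search oracle (25 instances, k ≤ 12,
1e-4 per component), against closed forms (inverse-variance GLS with
components pinned; the balanced equal-variance $\hat\tau^2 =
\max(0, s^2_y - v)$), and against the standard multilevel tooling on random
instances; Monte-Carlo recovery of intercept and both variance components
(200 replicates of the full default configuration, |bias| < 0.05, CI
coverage within binomial tolerance of 95%); Egger null-p uniformity and
power against an injected small-study effect of 1.5 SE units (200
replicates at k = 200); and end-to-end reproduction runs whose outputs are
byte-identical across repeated invocations.

## Design choices that were genuinely open

* Overall per-category models keep the full nested random structure rather
  than collapsing to a two-level model: the multilevel I² reported for
  such syntheses implies the decomposition, and consistency between
  overall and moderator models is worth more than parsimony.
* The guild/diet/location moderators are *ordered* pairs
  (inducer→subsequent): cross-resistance hypotheses are directional.
* The pooled Egger regression is unweighted OLS on inverse variance; the
  per-category tests are weighted SE-metaregressions. Both are implemented
  and labeled because both conventions are in active use, and they are not
  interchangeable.
* Cumulative refits reuse the full three-level structure, fixing
  unidentifiable components at zero with a flag, rather than silently
  switching model class mid-series.
* The package ships no shell CLI: the exported functions, the numbered
  scripts under `analysis/`, and `scripts/acceptance.R` are the intended
  interfaces for interactive, scripted and automated use respectively.

## Known limitations

Wald-z inference can be mildly anticonservative for moderators with very
few levels represented by few studies; paired-choice designs are treated
as independent groups; the LOR and g arms are never combined; and
phylogeny-augmented models assume the Brownian correlation is correct
rather than estimating a signal-strength parameter.
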