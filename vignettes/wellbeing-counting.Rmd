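---
title: "Dual-cutoff counting of multi-dimensional wellbeing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-cutoff counting of multi-dimensional wellbeing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wellcount)
```

## The measurement model

`wellcount` measures wellbeing (and its complement, multi-dimensional
ill-being) with the Alkire-Foster dual-cutoff counting method, in the
configuration used for the 2020 South Australia COVID-19 wellbeing survey:
six domains — Psychological and Emotional Health, Physical Health, Standard
of Living, Family and Community Vitality, Governance, and Ecological
Diversity and Resilience — each composed of binary sufficiency indicators.

Identification uses two cutoffs, both instances of a *two-thirds rule*:

1. **Within a domain.** Let $x_{ij} \in \{0, 1\}$ be respondent $i$'s
   achievement on variable $j$, and $m_d$ the number of variables in domain
   $d$. The domain score is $s_{id} = \sum_{j \in d} x_{ij}$, and the
   respondent is *sufficient* in the domain ($z_{id} = 1$) iff
   $s_{id} \ge \lceil 2 m_d / 3 \rceil$. For the nine-variable Ecology
   domain the threshold is 6.
2. **Across domains.** The composite Wellbeing Index is
   $W_i = \sum_d z_{id} \in \{0, \dots, D\}$. A respondent *maintained
   overall wellbeing* iff $W_i \ge k$ with $k = \lceil 2D/3 \rceil$, i.e.
   4 of the 6 domains. The deprivation count is $c_i = D - W_i$.

The ceiling convention is forced by the published worked instances
(9 variables → threshold 6; 6 domains → cutoff 4): a strictly-greater-than
two-thirds rule would give 7 of 9 and is therefore rejected.

Population aggregates follow the standard counting measures. With $q$
respondents deprived out of $n$:

* headcount ratio $H = q/n$;
* intensity $A_\text{raw} = \frac{1}{q}\sum_{i \,\text{deprived}} c_i$
  (in domain units; also reported as the share $A = A_\text{raw}/D$);
* adjusted headcount $M_0 = H \times A$;
* censored per-domain deprivation shares — the fraction of the *deprived*
  group deprived in each domain, the "drivers" table — and their
  uncensored counterparts over everyone.

Under the $k$-of-$D$ rule every deprived respondent misses at least
$D - k + 1$ domains, so $A_\text{raw} \ge 3$ when $k = 4$, $D = 6$; the
published intensity of 3.6 sits just above that floor. The API also accepts
per-domain weights and an arbitrary cross-domain cutoff $k$ (the general
Alkire-Foster formulation); the equal-weight, $k = 4$-of-6 configuration is
the frozen default, and the weighted form reduces to it exactly when all
weights are equal.

## Recoding and its conventions

Raw answers are mapped to indicators by a declarative codebook
(JSON/YAML): category-set rules ("Yes" achieves), ordinal/numeric
thresholds, or binary passthrough. Conventions that matter:

* **Missing answers** default to `as_zero` (non-achievement). The published
  counting arithmetic classifies every one of the 579 respondents
  (167 deprived + 412 maintained), which requires a policy that never drops
  a row; `as_missing` is available for sensitivity analysis.
* **Hopefulness** is rated 1–8 (1 = not positive/hopeful). The source
  never states which points count as "highly positive"; the default cutoff
  is ≥ 7 (the top quarter of the scale) and is configurable everywhere it
  is used.
* **Income** is regrouped at "$600 or less" per week, read as *inclusive*
  of exactly \$600, because that boundary splits the sample nearly in half.
  Respondents reporting no income are grouped LOW but carry a separate
  flag, since that group (largely older, pension-supported respondents) is
  discussed separately.
* **Gender** "Other/Not disclosed" is kept as its own category and is
  excluded from female–male gap statistics; its sample is too small and
  heterogeneous to support conclusions.

## Subgroup reports and gaps

`stratified_rates()` decomposes classification rates by any covariate;
respondents missing the stratifier are excluded from that stratification's
denominator (as done for the 56 respondents of unknown region), never
imputed, unless an explicit label is requested. The decomposability
property — the overall headcount is the group-size-weighted mean of group
headcounts for *any* partition — is enforced by construction and tested on
random partitions.

`gap_statistic(a, b)` reports the point differential $a - b$ and the
percent difference $100(a-b)/a$ **relative to the first (female) group**.
The denominator choice is inferred from the published arithmetic
($12/98 = 12.2\%$, $11/72 = 15.3\%$) and is stated prominently because
"percent difference" is ambiguous in general.

Two printed-value discrepancies are documented rather than resolved: the
overall maintained share prints as 71.2% while $412/579 = 71.16\%$ (we
treat $412/579$ as the reference computation), and the regional/metro rates
print as 65.5%/70.2% where $53/81$ and $310/442$ give 65.4%/70.1% (we
report the recomputed values). Reported percentages are rounded half-up to
one decimal place, matching the printed precision.

## The covariate model

`fit_maintenance_model()` fits a binomial logistic regression of the
maintained classification on income group, hopefulness, age group and
gender by maximum likelihood, and reports the conventional table: $B$,
SE, Wald $= (B/\mathrm{SE})^2$ for single-df terms, df, p, odds ratio
$\exp(B)$ with $\exp(B \pm 1.96\,\mathrm{SE})$ intervals, plus Nagelkerke's
pseudo-$R^2$

$$R^2_N = \frac{1 - \exp\{2(\ell_0 - \ell_1)/n\}}{1 - \exp\{2\ell_0/n\}}$$

and the share of cases correctly classified at a 0.5 probability cutoff.
Gender enters as a three-level categorical with reference "Man", so its
joint Wald test has 2 df; hopefulness enters as the 1–8 scale treated as
numeric (a binary coding via `recode_hopefulness()` is equally possible).
Perfect or quasi-complete separation is reported with an explicit warning
and flag. The published coefficient table itself is not a reproduction
target — the raw survey microdata are not deposited — so validation is by
formula-level oracles and parameter recovery on synthetic data.

## The synthetic generator: what it emulates, and what it does not

`generator_config()`/`simulate_survey()` generate raw survey tables with
the structure the analysis assumes, at the published study conditions:
$n = 579$; gender 74.8% women / 17.6% men / 7.6% other-undisclosed; region
76% Greater Adelaide / 14% regional / 10% missing; weekly income split
evenly at \$600 (with a no-income subgroup); six domains with variable
counts (9, 8, 8, 8, 7, 9); marginal per-domain sufficiency calibrated to
the published shares (44.0, 65.0, 83.5, 87.6, 82.0, 64.8 percent).

Only the Ecology count ($m = 9$) and the 56-question total are published;
the remaining counts are this package's documented reconstruction and the
default codebook is labelled as such. The hopefulness-during distribution
applies a downward shift to the pre-period rating calibrated so the
highly-positive share falls by about 28 points, the published fall.

Dependence between domains is induced by a single shared respondent latent
$u_i \sim N(0, 1)$ scaled by `sigma_u` (default 1): each indicator is
Bernoulli with logit $b_d + \beta^\top (x_i - \bar x) + \sigma_u u_i$. One
shared latent is enough to make deprivations cluster in the same people —
which the intensity statistic requires — while keeping calibration
tractable; a full copula would add parameters the published marginals
cannot identify. Default effect sizes on the indicator logit (income 0.6,
hopefulness 0.22 per point, age 0.19 per band, small gender offsets) mirror
the order of magnitude of the published odds ratios.

Baselines $b_d$ are calibrated by **deterministic inversion**, not
stochastic search: `uniroot` solves
$\Pr\{\mathrm{Bin}(m_d, \mathrm{logit}^{-1}(b_d + s\,u)) \ge t_d\} =
\text{target}$ with the mixture over $u$ evaluated by numerical
integration, where the scale $s$ absorbs both $\sigma_u$ and — the small
bias correction — the variance of the centered covariate effects under a
normal approximation. The residual calibration error is within about one
percentage point per domain.

The generator does **not** emulate item-nonresponse patterns beyond a
single missingness rate, free-text answers, panel structure, or real
response-style artefacts (straight-lining, acquiescence). Passing tests on
generated data therefore demonstrate the correctness of the counting and
modelling machinery under the stated stochastic model, not the substantive
findings one would obtain from real microdata.

A separate deterministic fixture, `sa2020_fixture()`, reproduces the
published deprivation-count breakdown exactly (4 respondents deprived in
6 domains, 16 in 5, 61 in 4, 86 in 3; 412 maintained) with domain
identities assigned greedily against the published driver shares so the
drivers ranking comes out Psychological > Physical > Ecology > Governance >
Living standard > Community. The maintained group's split across
$c \in \{0, 1, 2\}$ (215/117/80) is not published; it is an arbitrary
documented choice on which no computation depends.

### Known-truth validation and its design rationale

In the full generator, covariate effects act on *indicator* logits and then
pass through domain thresholds and the counting rule; their marginal effect
on the maintained outcome is attenuated and non-logit-linear, so the
generating coefficients are not identified from the classification alone.
Parameter recovery is therefore validated with `simulate_known_truth()`:
the same covariate marginals, but the outcome drawn directly from the
logistic model being fitted. Under that design the income coefficient 0.6
is recovered within its own 95% CI at $n = 5000$, estimator bias shrinks
from $n = 500$ to $n = 5000$, and a zero-effect term's CI covers 1 at the
nominal rate over 200 replicates ($n = 600$ each — sizes chosen so the
whole suite runs in seconds).

## Numerical choices and degenerate inputs

* Thresholds are exact integer ceilings; no floating-point two-thirds
  comparison is ever made.
* Percentages are rounded half away from zero (`round_half_up()`), one
  decimal place by default; all printed percentages re-derive from the
  underlying counts.
* `summarize_wellbeing()` reports intensity as absent when nobody is
  deprived (and $M_0 = 0$); an empty profile set is an error, as are empty
  groups in driver and multiple-response tables.
* The margin-of-error calculator uses the maximum-variance normal
  approximation $z_{(1+\gamma)/2}\sqrt{0.25/n}$, optionally with the
  finite-population correction — the convention consistent with all three
  published representativeness claims. For $n = 579$ at 99% confidence it
  evaluates to about 5.35%, not the claimed "within 5%"; the calculator
  reports the computed value and does not force agreement.
* Pipeline runs write a manifest (config, seed, package version, no
  timestamp) sufficient to reproduce the bundle byte-for-byte.

## Known limitations

No survey weighting or post-stratification to census margins (the source
reports raw percentages); no inequality-adjusted $M_1/M_2$ variants; no
statistical inference (standard errors) on $H$ and $A$; no small-area
estimation below the region level. The default codebook's per-question
recode rules are a reconstruction, suitable for synthetic data and as a
template for real deployments, not a certified transcription of the
original instrument.
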