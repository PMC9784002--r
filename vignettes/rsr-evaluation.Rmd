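---
title: "Rank Sum Ratio evaluation of regional health services"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank Sum Ratio evaluation of regional health services}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsreval)
```

## The problem

Health administrations routinely ask whether a region's health-service
*resources* and the population's *utilization* of services are matched to the
population's *needs*. A region can be under-funded, over-supplied, or
balanced, and the answer differs by region and changes over time. rsreval
implements a complete comprehensive-evaluation pipeline for this question:
a panel of regions-by-indicators, grouped into the three WHO dimensions
(needs, utilization, resource allocation), is reduced to one score per
region per dimension, graded into three levels, and mapped to a policy
category. The packaged worked example is the Chinese provincial
maternal-services panel (31 provinces, 12 indicators, observed in 2009 and
2019), whose published per-province tables ship with the package as
plain-text fixtures.

## The RSR method

**Non-integer ranks.** For each indicator column $X$ with $n$ regions,
classical integer ranking discards the quantitative distances between
regions. The non-integer rank interpolates instead:

$$R = 1 + \frac{(n-1)(X - X_{\min})}{X_{\max} - X_{\min}}$$

for a *high-quality* indicator (larger is better), and

$$R = 1 + \frac{(n-1)(X_{\max} - X)}{X_{\max} - X_{\min}}$$

for a *low-quality* indicator such as a mortality rate. Either way the worst
region gets rank 1, the best rank $n$, and
$R_{\text{low}} = n + 1 - R_{\text{high}}$ exactly. Note the low-quality
formula is the reflection of the high-quality one; writing the numerator as
the constant $(X_{\max}-X_{\min})$ — a slip that sometimes appears in print —
would send every region to rank $n$ and break the reflection identity, which
the test suite asserts.

**RSR score.** Within one dimension with $m$ indicators,

$$RSR_i = \frac{1}{mn} \sum_{j=1}^{m} R_{ij},$$

a dimensionless score in $[1/n, 1]$ (a region ranked 1 on everything scores
$1/n$; for $n = 31$ that is $0.032$). All indicators are weighted equally
and dimensions are never pooled into a single grand score: the three
dimensions only meet again in the classification step.

**Probit distribution.** The RSR values are sorted ascending; each region's
tie-averaged rank $\bar R$ gives the downward cumulative frequency
$P = \bar R / n \times 100\%$, and the classical probit
$\Phi^{-1}(P/100) + 5$, so $P = 50\%$ sits at probit 5. The top region's
$P = 100\%$ has an infinite probit and is replaced by the standard
correction $100(1 - \tfrac{1}{4n})$; for $n = 31$ the corrected maximum is
$99.19\%$ (probit $7.406$).

**Grading line.** An ordinary least-squares line
$\widehat{RSR} = a + b \cdot \text{probit}$ is fitted with RSR as the
response. Substituting the probit cut-offs — by default 4 and 6, one
standard deviation either side of the probit mean — into the
*unrounded* fitted line gives the critical RSR values that separate three
grades: Low ($\text{probit} \le 4$), Medium, High ($\text{probit} \ge 6$).
Working from rounded published coefficients can shift a critical value in
the third decimal ($0.136 \times 4 - 0.029 = 0.515$ while the unrounded fit
gives $0.514$), which is why `rsr_fit()` always grades from its own
full-precision coefficients.

With no ties, the grade-group sizes are a structural function of $n$ alone:
Low collects the regions with $P \le \Phi(-1) = 15.87\%$ and High those with
$P \ge 84.13\%$, so every continuous 31-region dimension grades 4/22/5 —
the pattern seen in all six packaged year-dimension panels.

**Validation.** `validate_grades()` checks that the grading separates the
fitted values: one-way ANOVA across grade groups, a homogeneity-of-variance
check, and Student–Newman–Keuls (SNK) stepwise studentized-range pairwise
comparisons at $\alpha = 0.05$. Because the fitted RSR is an affine
transform of the probit, the F statistic is identical whether computed on
fitted values or probits (also asserted by tests). The homogeneity check is
Levene's test centred at the group median (the Brown–Forsythe variant, via
`car::leveneTest`); this is a design choice — robust to the skewness that
truncated probit groups can show — since "variance consistency" admits
several tests. SNK is implemented directly on `stats::qtukey`/`ptukey`
with the ANOVA error mean square, stepwise: a pair nested inside a
non-significant wider span is declared non-significant without testing.

## WHO classification

Each region's grade triple (needs, utilization, resources) is mapped to one
of eight evaluation types. The original WHO model is two-level
(`who_type_2level()`): with grades H/L in the order needs–utilization–
resources, (H,H,H)→A, (H,H,L)→B, (H,L,H)→C, (H,L,L)→D, (L,H,H)→E,
(L,H,L)→F, (L,L,H)→G, (L,L,L)→H. The three-level China extension
(`who_type_3level()`) is a 27-cell table whose restriction to the Low/High
corners equals the two-level map (asserted by enumeration). It ships as
editable JSON (`extdata/who_map_3level.json`) rather than code, so a
corrected reading of the table can be swapped in without touching the
package. Types group into five policy categories: **relative balance**
(A, H, F), **low input** (B), **resource shortage** (D), **overutilization**
(E) and **resource waste** (C, G).

Two-timepoint comparisons (`transitions()`) are reported purely
descriptively — a 5×5 category cross-tabulation and the list of movers. No
"improvement" ordering of categories is imposed, because none is defined:
whether moving from low input to overutilization is an improvement is a
policy judgement, not arithmetic.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cuts` | `c(4, 6)` | probit cut-offs; 4/6 are $\mu \pm \sigma$ on the probit scale and give the common three-grading scheme. More cuts give more grades, but classification requires exactly two. |
| `ties` | `"average"` | tie handling in the probit step. Averaging is the method's definition: exactly tied RSR values share a rank, hence a probit. `"first"` breaks ties by table order, useful for reproducing published tables computed from unrounded data (below). |
| `noise_sd` | 0.1 | synthetic generator: per-indicator observation noise, on the scale of the unit-variance latent quality. |

## Rounded fixtures and ties

The packaged fixtures store the published per-province values at their
printed precision (RSR to 3 decimals). Rounding creates a handful of exact
ties between provinces whose unrounded values differed — six provinces in
2009 needs, six in 2009 utilization, two each in the three other panels.
Within such a tie group the published per-province $P$ values cannot be
recovered from the fixture: identical inputs cannot map to distinct
outputs, and the published tables themselves resolve these ties in more
than one way (the 2009 needs tie at 0.253 carries descending ranks 16/17 in
the score table but $P$ values implying the opposite order in the
distribution table). The acceptance tests therefore compare tied provinces
as a group — as a set of values under `ties = "first"`, as the group mean
under averaging — and compare every untied province exactly (±0.05 on $P$,
±0.001 on probit). All downstream published quantities are insensitive to
the tie rule at their printed precision: the six regression equations, the
twelve critical values, all 186 grade memberships, both years' category
counts, and the transition count are reproduced under either rule.

One more convention recovered from the published tables: the
goodness-of-fit figure printed beside each regression equation is the
**adjusted $R^2$** of the fit, not the Pearson correlation (for the 2009
needs panel, $r = 0.897$, $R^2 = 0.805$, adjusted $R^2 = 0.799$, published
$0.798$; the same identification holds for all six equations).
`rsr_fit()` reports both as `$r` and `$r_adj`.

## The synthetic generator

`synth_indicators()` emulates the structure the analysis assumes: one
latent standard-normal quality per region per dimension, each indicator
observing it through additive Gaussian noise, sign-flipped for low-quality
indicators. The default panel mirrors the maternal study: 31 regions,
3/5/4 indicators, one low-quality indicator. With `noise_sd = 0` every
indicator is a strictly monotone transform of its dimension's latent
quality, so RSR recovers the latent ordering exactly (Spearman 1); at
`noise_sd = 0.1` and $n = 200$ the mean Spearman correlation stays above
0.9 across replicates. What the generator does *not* emulate: real
indicator panels are cross-correlated between dimensions, heteroscedastic,
and bounded (rates near 100% compress). Passing tests on synthetic data
therefore demonstrate correctness of the pipeline's mechanics, not
robustness of the RSR method to real-world indicator pathologies.

## Numerical choices and degenerate inputs

- Top-rank correction $100(1 - 1/(4n))$, the standard finite-probit device;
  its value at $n = 31$ (99.19%, printing as 99.2) is what the published
  distribution tables contain, confirming the convention.
- Probit means $\Phi^{-1}(P/100) + 5$; plain normal quantiles without the
  +5 offset are never used.
- Grade boundaries are closed: Low iff probit $\le$ `cuts[1]`, High iff
  probit $\ge$ `cuts[2]`.
- A constant indicator column carries no information; every region receives
  the midpoint rank $(1+n)/2$ (the unique orientation-symmetric choice) with
  a warning, so one degenerate indicator does not abort a batch run.
- Ranks are clamped to $[1, n]$ against last-ulp floating-point overshoot.
- Grade groups with fewer than two members stay in the ANOVA but are
  excluded from SNK, with a warning.
- Validation inputs (missing cells, duplicate region ids, unknown
  indicators) fail fast with the offending region and indicator named.

## Problem sizes

The test suite runs entirely on the 31-region published panels, synthetic
panels of 5–31 regions, and a recovery benchmark of 25 replicates at
$n = 200$; the whole suite completes in a few seconds, and a single full
pipeline run on a 31-region panel takes well under a second.

## Worked example

```{r}
ev09 <- rsr_evaluate(2009)
ev19 <- rsr_evaluate(2019)
ev09
ev19
transitions(ev09$classification, ev19$classification)
summary(ev09$fits$needs)
```

## Limitations

- Equal indicator weights within a dimension are assumed throughout, as the
  method prescribes; there is no weighting interface.
- The three-level type map is taken as given (editable JSON); the package
  does not derive it from first principles.
- The method grades *relative* standing within the analysed set of regions:
  adding or removing a region changes everyone's ranks, $P$, and potentially
  grades. Scores are not comparable across panels with different region
  sets.
- Classification requires the three-grading scheme; other cut vectors grade
  but do not classify.
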