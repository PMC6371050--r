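# mateperm

Permutation tests, relocation-based effect sizes, and father/non-father
contrasts for **mate-choice consistency**: do individuals repeatedly choose
long-term partners with similar characteristics?

The package is built for questionnaire-style data in which each respondent
describes all of her long-term partners on a set of traits — demographic
(residence, education, age difference), physical (ordinal image scales such
as eye colour 1–5 or hair colour 1–9, plus weight, height and Likert
ratings) and personality (TIPI domain scores, 2–14). Because such datasets
are rarely shareable, a synthetic-cohort generator with controllable
respondent-level clustering is a first-class part of the package: every
analysis can be exercised, calibrated and stress-tested without any real
data.

## The statistics

**Consistency index.** For respondent *i* with partner trait values
*t*<sub>*i*1</sub>, …, *t*<sub>*i p<sub>i</sub>*</sub>, her consistency on a
trait is the mean absolute difference over all unordered partner pairs:

&nbsp;&nbsp;&nbsp;&nbsp;Δ<sub>i</sub> = Σ<sub>j&lt;k</sub> |t<sub>ij</sub> − t<sub>ik</sub>| / (p<sub>i</sub>(p<sub>i</sub>−1)/2)

The population index Δ̄ is the unweighted mean of Δ<sub>i</sub> over all
informative respondents (those with ≥ 2 non-missing partner values), so
every respondent counts equally. Lower Δ̄ = more consistent choice.

**Permutation test.** Partners are reshuffled across respondents, keeping
each respondent's partner count; the one-tailed p-value is the fraction of
random pairings whose Δ̄ falls below the observed one.

**Relocation effect size.** Starting from the observed data, random
partner exchanges between respondents — accepted only when they raise Δ̄ —
are applied until Δ̄ reaches its random-pairing expectation. The mean
percentage of partners relocated (each exchange relocates two) is the
effect size, bounded by ≈ 50%.

**Shared and cumulative effects.** For two traits A and B, the residual
effect of B after A is measured by first randomizing A and then continuing
on B; the shared effect is E<sub>A</sub> + E<sub>B</sub> − union. Pairwise
shared effects are accumulated over all traits — apportioning higher-order
overlaps proportionally — into the *maximal cumulative effect size*: the
proportion of partners that must be relocated to erase consistency on every
trait at once.

**Companion measures.** The respondent-attributable variance percentage
from a random-intercept mixed model (the ICC, ≈ 2 × the relocation effect
size) and the double-entry within-pair Pearson correlation.

**Father contrasts.** A permutation test of whether partners who fathered
the respondent's children are exceptional or typical within her partner set
(change in Δ̄ when fathers are excluded vs. when randomly relabelled
"fathers" are excluded), plus mixed-model contrasts of father vs.
non-father group means and — via absolute deviations from group means,
Levene-style — variances.

## Worked example

```r
library(mateperm)

reg  <- default_trait_registry()
reg4 <- reg[reg$trait %in% c("residence", "weight",
                             "relative_height", "extraversion"), ]
gen <- generate_cohort(
  cohort_config(n_respondents = 200, registry = reg4,
                icc = c(residence = 0.44, weight = 0.34,
                        relative_height = 0.31, extraversion = 0.09),
                missing_rate = 0.01),
  seed = 2025)

res <- run_mate_choice_analysis(gen$cohort, n_perm = 2000,
                                n_effect_runs = 300, n_resid_runs = 150,
                                seed = 1)
res
#> Mate-choice consistency analysis
#>   cohort: 200 respondents, 668 partners, 4 traits
#>   traits with adjusted consistency p < 0.05: 4 / 4
#>   maximal cumulative effect size: 40.35%

tidy(res)[, c("trait", "observed_delta", "expected_delta", "p_adj",
              "effect_pct", "icc_pct", "pearson_r")]
#>             trait observed_delta expected_delta p_adj effect_pct icc_pct pearson_r
#> 1       residence          0.454          0.583 0.000     11.518  29.767     0.268
#> 2          weight         15.656         19.645 0.000     24.981  38.503     0.406
#> 3 relative_height          0.780          0.918 0.000     12.145  22.131     0.213
#> 4    extraversion          2.059          2.201 0.014      7.585  11.426     0.104
```

Reading the `weight` row: the average within-respondent partner difference
is 15.7 kg where random pairing would give 19.6 kg (adjusted p < 0.001);
25% of partners would have to change respondents to erase the effect, and
respondent identity accounts for 38.5% of partner weight variance. The
cumulative accumulation (`res$cumulative`) orders traits by unique
contribution (weight 24.98, relative height 7.39, residence 5.68,
extraversion 2.30) for a maximal cumulative effect size of 40.35%.

`autoplot(res)`, `autoplot(res$cumulative)` and
`autoplot(res$father_exclusion)` draw the standard visualizations;
`glance(res)` gives a one-row summary; `write_results_tables(res, "out/")`
writes the four customary CSV tables plus a run manifest.

A command-line front end with `simulate`, `consistency`, `effect`,
`shared`, `cumulative`, `fathers` and `run` subcommands is installed at
`system.file("scripts", "mateperm.R", package = "mateperm")`.

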