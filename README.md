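# delphicos

Consensus analysis for core outcome set (COS) development Delphi surveys.

A COS is the minimum set of outcomes to be measured and reported in every
study of a health condition. It is typically agreed through a multi-round
Delphi survey: stakeholder panels rate the importance of candidate outcomes,
rounds filter the list under a pre-registered consensus rule, and the
surviving outcomes go to a consensus meeting. `delphicos` implements this
pipeline for analysts of such studies:

* **Consensus engine** — the a priori criterion used in the PGP-COS (pelvic
  girdle pain) project: an outcome is "in" when ≥ 70% of a stakeholder group
  rates it important (4+ on a 5-point scale, 7+ on a 9-point scale) in at
  least 3 of 5 groups, *necessarily including the patient group*; plus round
  transitions (carry-all into round 2, filter into round 3), merging of
  adjudicated round-1 suggestions, preliminary-COS construction and
  source-tag tracking (e.g. how patient-interview-derived outcomes fared).
* **Scale comparison** — the pooled two-proportion z-test used to compare
  the randomised 5-point and 9-point arms,

  $$Z = \frac{(p_1 - p_2) - 0}{\sqrt{p(1-p)\left(\tfrac{1}{n_1} + \tfrac{1}{n_2}\right)}},
  \qquad p = \frac{x_1 + x_2}{n_1 + n_2},$$

  with two-sided normal p-values and no continuity correction; per-group and
  overall attrition rates; closed-category feedback tallies.
* **Panel simulator** — a latent-trait model of ordinal rating: each
  (outcome, group) has a mean importance θ on a canonical [0, 1] axis, each
  rating adds Gaussian noise σ and is discretised through a scale's
  cutpoints; panels have five unequal stakeholder groups, 1:1 arm
  randomisation and monotone dropout, so scale-granularity effects can be
  explored end to end.
* **Bundled study tables** — the PGP-COS study's published summary tables
  (interview-outcome ratings, suggestion adjudications, panel demographics,
  the In/Out decision grid, attrition) ship as plain-CSV fixtures
  (`pgp_fixture()`), so every reported statistic can be recomputed offline.

## Worked example

```r
library(delphicos)

# round 1: 41/53 outcomes reached consensus on the 5-point arm vs 29/53
two_proportion_z(41, 53, 29, 53)
#> <prop_comparison> 41/53 (0.774) vs 29/53 (0.547)
#>   z = 2.4611  |z| = 2.46  p = 0.01 (two-sided)

# overall attrition per arm, from the panel headcounts
subset(attrition_rates(pgp_round_counts()), group == "overall")
#>   group   arm   transition n_start n_end percent
#> 1 overall 5pt   r1_to_r2       101    76      25
#> 2 overall 5pt   r2_to_r3        76    69       9
#> 3 overall 5pt   overall        101    69      32
#> 4 overall 9pt   r1_to_r2       104    71      32
#> 5 overall 9pt   r2_to_r3        71    63      11
#> 6 overall 9pt   overall        104    63      39

# the two preliminary COS lists share 10 outcomes
pc <- preliminary_cos(pgp_fixture("round_decisions"))
overlap_count(pc$per_arm[["5pt"]], pc$per_arm[["9pt"]])
#> [1] 10
```

The z of 2.46 (p = 0.01) says the 5-point arm admitted a significantly
larger share of outcomes than the 9-point arm in round 1; the attrition grid
shows similar drop-out in both arms (32% vs 39% overall); and the two arms'
final outcome lists overlap in 10 outcomes. A synthetic panel runs through
the identical pipeline:

```r
sim <- simulate_panel(simulation_config(seed = 1))
tally_decisions(evaluate_delphi(sim$ratings))
#>   arm   round possible_n  in_n
#> 1 5pt       1         53    16
#> 2 5pt       2         53    21
#> 3 5pt       3         21     9
#> 4 9pt       1         53    10
#> 5 9pt       2         53     6
#> 6 9pt       3          6     2
```

With equally spaced cutpoints the 5-point "important" region (top 2/5 of the
latent axis) is wider than the 9-point one (top 3/9), and the simulated
5-point arm accordingly admits more outcomes — the measurement-artefact
mechanism discussed in the methods vignette
(`vignettes/delphi-cos-methods.Rmd`).

`replay_study()` recomputes every published statistic from the bundled
tables and reports expected vs computed values; see the vignette for the one
documented inconsistency inside the published decision grid.

A command-line front-end over the same functions is installed at
`inst/scripts/delphicos` (subcommands `validate`, `evaluate`, `compare`,
`simulate`, `replay`).

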