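---
title: "Methods: Delphi consensus analysis for core outcome sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Delphi consensus analysis for core outcome sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delphicos)
```

## The consensus model

A core outcome set (COS) Delphi presents a longlist of candidate outcomes
to panels of stakeholders over several rounds. `delphicos` implements the
design of the PGP-COS study: five stakeholder groups (patients, clinicians,
researchers, dual-role clinician researchers, service providers / policy
makers), panellists randomised 1:1 between a 5-point and a 9-point rating
scale, and three rounds.

The a priori criterion is parameterised by `consensus_rule()`:

* `importance_threshold` (default 0.70): the minimum share of a group
  rating the outcome "important" — 4+ on the 5-point scale, 7+ on the
  9-point scale (`delphi_scales()`).
* `min_groups` (default 3 of `total_groups = 5`): how many groups must
  reach the threshold.
* `mandatory_groups` (default `patient`): groups that must individually
  qualify. Consensus can never be declared against the patient group.

Comparisons are inclusive: a group at exactly 70% qualifies. This is not a
convention chosen for convenience — replaying the published percentages
shows patient-group cells of exactly 70 on included outcomes (e.g. sexual
functioning, round 3, 5-point arm), so the strict alternative would
contradict the published decisions.

Round transitions are explicit: everything rated in round 1 is re-rated in
round 2 together with newly merged suggestions (`carry_all`), and only
outcomes reaching consensus in round 2 continue to round 3 (`filter`).
Both modes are exposed (`next_round_outcomes()`, the `transitions` argument
of `simulate_panel()`) so other COS designs can be expressed. Each arm is
evaluated strictly independently; the per-arm round-3 survivors form the
per-arm preliminary COS and their union goes to the consensus meeting
(`preliminary_cos()`).

### Numerical conventions

* From raw records, the exact rational proportion (count over group
  denominator) is compared to the threshold; display rounding never changes
  a decision. A tiny epsilon (1e-9 on counts) guards only against binary
  representation of thresholds like 0.7, so 7 of 10 raters meet 0.70.
* From a printed percentage table, the integer percentages are compared as
  given — no re-rounding — because the underlying counts were never
  published.
* A group with zero respondents has an `NA` proportion, which is distinct
  from 0%, never meets the threshold, and fails any mandatory-group
  requirement.
* The denominator of a group's proportion is the number of that group's
  members who rated that specific outcome in that round. The source study
  did not state how skipped items were handled; this per-outcome-denominator
  convention is our choice, and it reduces to the obvious one when everyone
  rates everything.
* Integer percentages are displayed with half-up rounding
  (`round_half_up()`): all 36 published attrition cells recompute exactly
  under it (e.g. 24.75 → 25, 39.42 → 39), where base `round()` would
  disagree on exact halves.
* Outputs are ordered by outcome id, arm and round, so repeated runs are
  byte-identical.

## The two-arm comparison

`two_proportion_z()` implements the pooled-variance two-proportion z-test
with no continuity correction and a two-sided standard normal p-value;
`compare_round_consensus()` applies it to per-round consensus counts and to
the preliminary-COS sizes (each arm's round-3 "In" count over its full
round-2 candidate list). Both the signed statistic and its magnitude are
kept: the study reports magnitudes throughout, including for attrition
where the 9-point proportion is the larger. No multiplicity adjustment is
applied — the analysis is exploratory, as in the source study. Internally
p-values keep full precision; only display is rounded.

## Replaying the published tables

The bundled fixtures (`pgp_fixture()`) transcribe the study's printed
tables verbatim; `replay_study()` recomputes every statistic from them.
Three data notes, all preserved rather than corrected:

1. **The decision grid is internally inconsistent at round 3 of the 5-point
   arm.** The published per-row In/Out statuses sum to 26 "In" of 36 rated,
   while the same table's totals row (and the accompanying z-scores 0.73
   and 2.55) use 24 of 37. One outcome ("Outcomes from functional tests")
   is marked In at round 2 but not rated at round 3, accounting for the
   36 vs 37; the two extra "In" rows cannot be identified from the
   published information. The fixtures therefore ship both faces of the
   table: `round_decisions` (the rows) and `round_summary` (the printed
   totals). Tallies computed from rows honestly give 26/36;
   statistics that the study derived from its totals are replayed from
   `round_summary`. `replay_study()` reports the mismatch explicitly.
2. **Two displayed values are truncations.** The overall attrition
   statistic is 1.1570, printed as 1.15; the 9-point ease-of-use share is
   33/64 = 51.56%, printed as 51%. The replay accepts a value that matches
   the print under either display convention and says so in its `note`
   column.
3. **Two percentage cells in the interview-outcome table are digit-run
   ambiguous in transcription** (researcher row of "Perceived body
   imbalance"; clinician-researcher row of "Frustration"). They were
   resolved by feasibility against the known group denominators — e.g. 32%
   must be 6/19 because 3% cannot arise from 19 raters — and neither
   resolution affects any decision.

The interview-derived outcomes replay cleanly: running the rule over their
published percentages reproduces all 48 published In/Out/not-rated cells,
and exactly four of the eight (sexual functioning, family life impact,
social life impact, emotional symptoms) reach the preliminary COS.

## The panel simulator

`simulation_config()` / `simulate_panel()` generate synthetic panels with
the study's structure. The measurement model: each (outcome, group) pair
has a latent mean importance θ on a canonical [0, 1] axis; a rating draws
`latent = θ + N(0, σ)`, clamps to [0, 1], and maps to a scale point as one
plus the number of cutpoints strictly below it. Gaussian noise is the
minimal symmetric unimodal choice that gives a closed-form importance
probability, `P(latent > cutpoint[cutoff − 1]) = Φ((θ − c)/σ)`
(`importance_probability()`), used by the parameter-recovery tests.

Defaults are the study's conditions wherever the study states them, chosen
once:

* 53 round-1 outcomes; group totals 91/38/42/23/11 (the two arms' round-1
  enrolments combined), with each panellist randomised 1:1 to an arm by
  simple randomisation — the study's actual allocation, rather than fixed
  per-arm quotas;
* per-group dropout probabilities equal to the study's pooled observed
  transition rates (`default_dropout()`), applied independently between
  rounds, so attrition is monotone by construction;
* equally spaced cutpoints, under which the 5-point cutoff (4+) spans the
  top 2/5 of the latent axis while the 9-point cutoff (7+) spans the top
  3/9 — a built-in asymmetry that makes the coarser scale admit more
  outcomes. This offers a measurement-artefact reading of the study's
  headline finding (the 5-point preliminary COS was about twice the size
  of the 9-point one); the simulator makes the hypothesis explorable, it
  does not prove it.
* θ has no data to calibrate against (the study published only aggregated
  percentages), so the default draws each θ once per configuration from a
  Beta(3, 1.5) — most outcomes moderately-to-highly important, as in real
  outcome longlists — and σ defaults to 0.2 on the unit axis. These are
  illustrative, not estimates.
* The middle "unsure" option is not modelled specially: it simply falls
  below the cutoff, matching the engine's binary importance dichotomy.

What the simulator deliberately does not emulate: the between-round
feedback shown to panellists (the study describes it but provides no
mechanism for its effect), free-text suggestion generation, and
item-skipping. Passing simulation-based tests therefore demonstrates that
the pipeline's mechanics are correct under the stated generative model, not
that real panels behave like it.

## Problem sizes and runtime choices

The test suite favours many small seeded panels: oracle-equivalence checks
use panels of up to 6 outcomes × 5 groups; parameter recovery uses 100
replicates of a 5000-rater group (empirical importance within two binomial
standard errors of the analytic value in ≥ 90/100 replicates);
matched-cutpoint equivalence and cutoff monotonicity use 200 replicates of
a 50-rater, 6-outcome panel with paired Monte-Carlo error bounds. The
acceptance script's simulation summary uses 20 replicates of the full
study-sized default configuration. All sizes are the package's own choices
balancing statistical resolution against a suite that runs in well under a
minute per file.

## Known limitations

* Table-derived replays inherit the print: no raw counts exist behind the
  percentage table, so fixture-driven decisions are exactly as precise as
  the published integers.
* The final PGP-COS's five outcomes are not identified in the source
  tables, so final-COS containment checks require the user to supply the
  list (`track_source_outcomes(..., final_cos = )`).
* The consensus-meeting vote, qualitative interview analysis and free-text
  content analysis are out of scope; the engine accepts their outputs
  (adjudications, final lists) as inputs.
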