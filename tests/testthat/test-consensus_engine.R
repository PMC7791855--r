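test_that("importance proportions count ratings at or above the cutoff", {
  s5 <- delphi_scales()[["5pt"]]
  all5 <- make_records("pain", "patient", 1, "5pt", rep(5, 5))
  expect_equal(importance_proportion(all5, "pain", "patient", 1, s5), 100)
  mix <- make_records("pain", "patient", 1, "5pt", c(4, 4, 3, 2))
  expect_equal(importance_proportion(mix, "pain", "patient", 1, s5), 50)
  # empty group is NA, not 0
  expect_true(is.na(importance_proportion(mix, "pain", "clinician", 1, s5)))
  # 7 of 10 raters at the cutoff meet a 0.70 threshold under >=
  ten <- make_records("pain", "patient", 1, "5pt", c(rep(4, 7), rep(3, 3)))
  p <- importance_proportion(ten, "pain", "patient", 1, s5)
  expect_equal(p, 70)
  expect_true(group_consensus(
    c(clinician = 70, clinician_researcher = 70, patient = p,
      researcher = 0, service_provider_policy_maker = 0)))
})

test_that("the a priori rule needs 3/5 groups including patients", {
  rule <- consensus_rule()
  # family life impact, round 3, 5-point: unanimous consensus
  expect_true(group_consensus(
    c(clinician = 93, clinician_researcher = 95, patient = 100,
      researcher = 100, service_provider_policy_maker = 100), rule))
  # pain character/type, round 3, 5-point: patient at exactly 70 counts,
  # but only two groups qualify
  expect_false(group_consensus(
    c(clinician = 82, clinician_researcher = 42, patient = 70,
      researcher = 30, service_provider_policy_maker = 67), rule))
  # need for a mobility aid, round 3, 5-point: two qualifying groups but
  # the mandatory patient group is below threshold
  expect_false(group_consensus(
    c(clinician = 75, clinician_researcher = 58, patient = 60,
      researcher = 20, service_provider_policy_maker = 100), rule))
  # an empty group never qualifies, even as a non-mandatory group
  expect_false(group_consensus(
    c(clinician = 100, clinician_researcher = NA, patient = 100,
      researcher = NA, service_provider_policy_maker = NA), rule))
  expect_error(group_consensus(c(clinician = 100), rule), "mandatory")
  expect_error(consensus_rule(min_groups = 6), "total_groups")
  expect_error(consensus_rule(mandatory_groups = c("patient", "clinician"),
                              min_groups = 1), "min_groups")
})

test_that("replaying the printed percentages reproduces the published grid", {
  t1 <- pgp_fixture("interview_ratings")
  dec4 <- pgp_fixture("round_decisions")
  replayed <- evaluate_delphi(t1)
  published <- dec4[dec4$outcome_id %in% unique(t1$outcome_id), ]
  cmp <- dplyr::inner_join(replayed, published,
                           by = c("outcome_id", "arm", "round"),
                           suffix = c("_new", "_pub"))
  expect_equal(nrow(cmp), 8 * 2 * 3)
  expect_equal(cmp$status_new, cmp$status_pub)
  # exactly the four marked outcomes reach the preliminary COS
  expect_equal(preliminary_cos(replayed)$union,
               c("emotional_symptoms", "family_life_impact",
                 "sexual_functioning", "social_life_impact"))
})

test_that("a threshold of 1.0 leaves only outcomes with unanimous groups", {
  t1 <- pgp_fixture("interview_ratings")
  strict <- consensus_rule(importance_threshold = 1.0)
  dec <- evaluate_round(t1, 3, "5pt", strict)
  # brute force over the eight rows: patient (mandatory) and >= 3 groups at 100
  cells <- t1[t1$round == 3 & t1$arm == "5pt", ]
  manual <- vapply(split(cells, cells$outcome_id), function(d) {
    rated <- !all(is.na(d$percent))
    if (!rated) return("not_rated")
    at100 <- d$group[!is.na(d$percent) & d$percent == 100]
    if (length(at100) >= 3 && "patient" %in% at100) "in" else "out"
  }, character(1))
  expect_equal(dec$status, unname(manual[dec$outcome_id]))
  expect_equal(dec$outcome_id[dec$status == "in"], "family_life_impact")
})

test_that("the engine agrees with a brute-force oracle on random panels", {
  rule_sets <- list(
    consensus_rule(),
    consensus_rule(importance_threshold = 0.5, min_groups = 2),
    consensus_rule(min_groups = 4,
                   mandatory_groups = c("patient", "clinician"))
  )
  set.seed(421)
  for (rep in 1:10) {
    panel <- random_panel(n_outcomes = sample(2:6, 1))
    rule <- rule_sets[[sample.int(length(rule_sets), 1)]]
    for (arm in c("5pt", "9pt")) {
      got <- evaluate_round(panel, 1, arm, rule)
      expect_equal(got, oracle_evaluate(panel, 1, arm, rule,
                                        delphi_scales()))
    }
  }
})

test_that("tightening the rule never turns an Out into an In", {
  set.seed(99)
  for (rep in 1:60) {
    p <- stats::setNames(round(stats::runif(5, 0, 100), 1),
                         stakeholder_groups())
    thr <- stats::runif(1, 0.3, 0.9)
    v0 <- group_consensus(p, consensus_rule(importance_threshold = thr))
    tightened <- list(
      consensus_rule(importance_threshold = min(1, thr + 0.1)),
      consensus_rule(importance_threshold = thr, min_groups = 4),
      consensus_rule(importance_threshold = thr,
                     mandatory_groups = c("patient", "researcher"),
                     min_groups = 3)
    )
    for (rule in tightened) {
      expect_lte(group_consensus(p, rule), v0)
    }
  }
})

test_that("each arm's decisions ignore the other arm's data", {
  set.seed(7)
  panel <- random_panel(4)
  base <- evaluate_round(panel, 1, "9pt")
  # scramble the 5-point arm's ratings entirely
  mangled <- panel
  idx <- mangled$arm == "5pt"
  mangled$rating[idx] <- sample(mangled$rating[idx])
  mangled$rating[idx][1] <- 1L
  expect_equal(evaluate_round(mangled, 1, "9pt"), base)
})

test_that("round transitions carry all or filter to consensus outcomes", {
  dec <- pgp_fixture("round_decisions")
  filt <- next_round_outcomes(dec, 2, "filter")
  carry <- next_round_outcomes(dec, 2, "carry_all")
  expect_length(filt[["5pt"]], 37)
  expect_length(filt[["9pt"]], 20)
  expect_length(carry[["5pt"]], 68)
  for (a in names(filt)) expect_true(all(filt[[a]] %in% carry[[a]]))
})

test_that("adjudicated suggestions merge into the registry", {
  reg <- pgp_fixture("outcomes")
  round1 <- reg[reg$first_round == 1, ]
  expect_equal(nrow(round1), 53)
  sugg <- pgp_fixture("suggested_outcomes")

  merged <- merge_suggestions(sugg, round1)
  expect_equal(nrow(merged), 57)  # four new patient-suggested outcomes
  minted <- setdiff(merged$outcome_id, round1$outcome_id)
  expect_setequal(minted, c("likelihood_of_planning_subsequent_pregnancies",
                            "symptoms_during_menstruation",
                            "need_for_additional_supports",
                            "pain_duration_pain_pattern"))
  expect_true(all(merged$first_round[merged$outcome_id %in% minted] == 2))

  # identity on an empty suggestion list
  expect_equal(merge_suggestions(sugg[0, ], round1), round1)
  # a new outcome colliding with an existing id demands adjudication
  clash <- sugg[sugg$decision == "include_new", ][1, ]
  clash$mapped_outcome_id <- "pain_location"
  expect_error(merge_suggestions(clash, round1), "adjudicate")
  # with all stakeholders' suggestions merged, round 2 presents 68 outcomes
  expect_equal(sum(reg$first_round <= 2), 68)
})

test_that("preliminary COS lists and overlap follow the round-3 decisions", {
  dec <- pgp_fixture("round_decisions")
  pc <- preliminary_cos(dec)
  expect_length(pc$per_arm[["9pt"]], 11)
  ov <- overlap_count(pc$per_arm[["5pt"]], pc$per_arm[["9pt"]])
  expect_equal(ov, 10)
  # the sole 9-point-only outcome
  expect_equal(setdiff(pc$per_arm[["9pt"]], pc$per_arm[["5pt"]]),
               "patient_expectations_of_treatment")
  # inclusion-exclusion for the union
  expect_length(pc$union, length(pc$per_arm[["5pt"]]) +
                  length(pc$per_arm[["9pt"]]) - ov)
  expect_equal(overlap_count(pc$union, pc$union), length(pc$union))
  expect_equal(overlap_count(pc$per_arm[["5pt"]], pc$per_arm[["9pt"]]),
               overlap_count(pc$per_arm[["9pt"]], pc$per_arm[["5pt"]]))
})

test_that("source tracking summarises tagged outcomes per round", {
  dec <- pgp_fixture("round_decisions")
  reg <- pgp_fixture("outcomes")
  tr <- track_source_outcomes(dec, reg, "interview")
  expect_length(tr$outcomes, 8)
  expect_equal(tr$n_preliminary, 4)
  r1_5 <- tr$summary[tr$summary$arm == "5pt" & tr$summary$round == 1, ]
  expect_equal(r1_5$n_in + r1_5$n_out, 8)
  # a tag matching nothing gives an all-zero summary
  none <- track_source_outcomes(dec, reg, "no_such_tag")
  expect_length(none$outcomes, 0)
  expect_true(all(none$summary[c("n_in", "n_out", "n_not_rated")] == 0))
  expect_equal(none$n_preliminary, 0)
  # with a user-supplied final COS, overlap is counted
  tr2 <- track_source_outcomes(dec, reg, "interview",
                               final_cos = c("pain_intensity_severity",
                                             "family_life_impact"))
  expect_equal(tr2$n_final, 1)
})
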