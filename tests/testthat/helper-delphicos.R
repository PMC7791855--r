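# shared builders and independent oracles for the test suite

# compact builder: one rater per rating value
make_records <- function(outcome, group, round, arm, ratings,
                         id_prefix = paste0(arm, "_", group)) {
  tibble::tibble(
    participant_id = sprintf("%s_%02d", id_prefix, seq_along(ratings)),
    arm = arm, group = group, round = as.integer(round),
    outcome_id = outcome, rating = as.integer(ratings)
  )
}

# random small panel of rating records for both arms (fixed seed supplied by
# the caller), unequal group sizes, every group rates every outcome
random_panel <- function(n_outcomes, scales = delphi_scales(),
                         max_group = 6, round = 1) {
  outcomes <- sprintf("o%02d", seq_len(n_outcomes))
  pieces <- list()
  for (arm in names(scales)) {
    np <- scales[[arm]]$n_points
    for (g in stakeholder_groups()) {
      n <- sample.int(max_group, 1)
      for (oc in outcomes) {
        pieces[[paste(arm, g, oc)]] <-
          make_records(oc, g, round, arm, sample.int(np, n, replace = TRUE))
      }
    }
  }
  dplyr::bind_rows(pieces)
}

# brute-force consensus oracle: enumerates groups and counts directly,
# independent of the vectorised engine
oracle_evaluate <- function(records, round, arm, rule, scales) {
  records <- records[records$round == round & records$arm == arm, ]
  cutoff <- scales[[arm]]$importance_cutoff
  out <- lapply(sort(unique(records$outcome_id)), function(oc) {
    n_ok <- 0
    mandatory_ok <- TRUE
    for (g in stakeholder_groups()) {
      r <- records$rating[records$outcome_id == oc & records$group == g]
      ok <- length(r) > 0 &&
        (sum(r >= cutoff) / length(r)) >= rule$importance_threshold - 1e-12
      if (ok) n_ok <- n_ok + 1
      if (g %in% rule$mandatory_groups && !ok) mandatory_ok <- FALSE
    }
    tibble::tibble(
      outcome_id = oc, arm = arm, round = as.integer(round),
      status = if (n_ok >= rule$min_groups && mandatory_ok) "in" else "out")
  })
  dplyr::bind_rows(out)
}

# the study's printed round totals, used across tests
printed_round_summary <- function() pgp_fixture("round_summary")
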