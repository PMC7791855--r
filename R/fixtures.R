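#' Bundled PGP-COS Delphi study tables
#'
#' Plain-text transcriptions of the summary tables of the PGP-COS embedded
#' methodology study, shipped so that every reported statistic can be
#' recomputed offline. Cells are stored exactly as printed; dashes (an outcome
#' not carried into a round) are encoded as missing / `not_rated`, never as
#' zero. Available fixtures:
#'
#' * `interview_ratings` (`table1`): per stakeholder group, per round and per
#'   arm, the integer percentage that rated each of the eight
#'   interview-derived outcomes "important". Denominators were not published;
#'   percentages are stored as given.
#' * `suggested_outcomes` (`table2`): free-text outcomes suggested by patients
#'   in round 1 with the steering committee's adjudication
#'   (`include_new` / `already_included` / `not_an_outcome`).
#' * `participants` (`table3`): per-round, per-arm panellist counts by
#'   stakeholder group, gender, age band and country.
#' * `round_decisions` (`table4`): per-outcome In/Out/not-rated status per
#'   round and arm, under the a priori rule (>= 70% "important" in at least
#'   3/5 stakeholder groups including patients).
#' * `round_summary`: the same table's printed per-round totals (possible and
#'   "In" outcome counts per arm). Kept separately because the printed
#'   round-3 totals for the 5-point arm (24 "In" of 37) disagree with the sum
#'   of the printed row statuses (26 of 36); see the methods vignette.
#' * `outcomes`: the outcome registry (identifier, display name, source tag
#'   among systematic_review / interview / round1_suggestion, first round).
#' * `attrition` (`table5`): printed per-group attrition percentages.
#' * `feedback`: end-of-study scale ease-of-use and clarity tallies.
#'
#' @param name Fixture name (above); `table1`..`table5` aliases accepted.
#' @return A tibble.
#' @examples
#' pgp_fixture("round_summary")
#' @export
pgp_fixture <- function(name) {
  files <- c(
    interview_ratings = "interview_ratings.csv",
    suggested_outcomes = "suggested_outcomes.csv",
    participants = "participant_counts.csv",
    round_decisions = "round_decisions.csv",
    round_summary = "round_summary.csv",
    outcomes = "outcomes.csv",
    attrition = "attrition.csv",
    feedback = "feedback.csv",
    table1 = "interview_ratings.csv",
    table2 = "suggested_outcomes.csv",
    table3 = "participant_counts.csv",
    table4 = "round_decisions.csv",
    table5 = "attrition.csv"
  )
  if (!name %in% names(files)) {
    stop("unknown fixture '", name, "'; valid names: ",
         paste(sort(unique(names(files))), collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", files[[name]], package = "delphicos",
                      mustWork = TRUE)
  x <- readr::read_csv(path, show_col_types = FALSE)
  if ("round" %in% names(x)) x$round <- as.integer(x$round)
  x
}

#' Per-round stakeholder headcounts of the study panel
#'
#' Convenience accessor for the stakeholder-group block of the participants
#' fixture, in the shape expected by [attrition_from_counts()] and
#' [roster_from_counts()].
#'
#' @return Tibble with columns `group`, `arm`, `round`, `n`.
#' @examples
#' sum(subset(pgp_round_counts(), round == 1 & arm == "5pt")$n)  # 101
#' @export
pgp_round_counts <- function() {
  x <- pgp_fixture("participants")
  x <- x[x$block == "stakeholder", c("category", "arm", "round", "n")]
  names(x)[1] <- "group"
  x
}

#' Synthetic roster reproducing the study's per-round headcounts
#'
#' Expands the stakeholder-group counts into an individual-level roster with
#' synthetic identifiers (the study's individual-level roster was never
#' published). All count-based statistics — attrition rates and the attrition
#' z comparison — are invariant to this reconstruction.
#'
#' @return A roster tibble.
#' @export
pgp_roster <- function() {
  roster_from_counts(pgp_round_counts())
}
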