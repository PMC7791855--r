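#' The a priori consensus criterion
#'
#' An outcome reaches consensus in a round when at least
#' `min_groups` of the `total_groups` stakeholder groups rate it "important"
#' at or above `importance_threshold`, and every mandatory group (by default
#' the patient group) is among the groups meeting the threshold. The
#' comparison is inclusive: a group at exactly the threshold qualifies.
#' A group with no respondents in a round never meets the threshold and
#' cannot satisfy a mandatory-group requirement — consensus cannot be claimed
#' from absent voices.
#'
#' @param importance_threshold Proportion in (0, 1]; default 0.70.
#' @param min_groups Minimum number of qualifying groups; default 3.
#' @param total_groups Number of canonical groups; default 5.
#' @param mandatory_groups Groups that must individually qualify; default
#'   `"patient"`.
#' @return An object of class `consensus_rule`.
#' @examples
#' consensus_rule()
#' @export
consensus_rule <- function(importance_threshold = 0.70, min_groups = 3L,
                           total_groups = 5L, mandatory_groups = "patient") {
  stopifnot(importance_threshold > 0, importance_threshold <= 1)
  min_groups <- as.integer(min_groups)
  total_groups <- as.integer(total_groups)
  mandatory_groups <- as.character(mandatory_groups)
  if (!all(mandatory_groups %in% stakeholder_groups())) {
    stop("mandatory_groups must be canonical stakeholder groups",
         call. = FALSE)
  }
  if (length(mandatory_groups) > min_groups || min_groups > total_groups) {
    stop("need |mandatory_groups| <= min_groups <= total_groups",
         call. = FALSE)
  }
  structure(
    list(importance_threshold = importance_threshold,
         min_groups = min_groups, total_groups = total_groups,
         mandatory_groups = mandatory_groups),
    class = "consensus_rule"
  )
}

#' @export
print.consensus_rule <- function(x, ...) {
  cat(sprintf(
    "<consensus_rule> >=%.0f%% important in >=%d/%d groups, mandatory: %s\n",
    100 * x$importance_threshold, x$min_groups, x$total_groups,
    paste(x$mandatory_groups, collapse = ", ")))
  invisible(x)
}

#' Read a consensus rule from a YAML file
#'
#' Fields: `importance_threshold`, `min_groups`, `total_groups`,
#' `mandatory_groups` (all optional, defaulting as in [consensus_rule()]).
#'
#' @param path YAML file.
#' @return A `consensus_rule`.
#' @export
read_rule <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(consensus_rule, y[intersect(names(y),
    c("importance_threshold", "min_groups", "total_groups",
      "mandatory_groups"))])
}

# Inclusive threshold comparisons. Raw-record decisions compare the exact
# count against threshold * n (never a rounded display percentage); the tiny
# epsilon only guards binary representation of thresholds like 0.7, so that
# e.g. 7/10 raters meet a 0.70 threshold.
meets_count <- function(n_important, n, threshold) {
  !is.na(n) & n > 0 & n_important >= threshold * n - 1e-9
}
meets_percent <- function(percent, threshold) {
  !is.na(percent) & percent >= 100 * threshold - 1e-7
}

#' Share of a stakeholder group rating an outcome important
#'
#' Returns `100 * (# ratings >= importance_cutoff) / (# ratings)` for one
#' (outcome, group, round) cell within the scale's arm. The denominator is
#' the number of the group's members who rated that specific outcome in that
#' round. With no raters the result is `NA` — an empty group, which is
#' distinct from 0% and never meets the consensus threshold.
#'
#' @param records Rating-record tibble (see [read_ratings()]).
#' @param outcome Outcome identifier.
#' @param group Stakeholder group identifier.
#' @param round Delphi round (1..3).
#' @param scale The arm's [rating_scale()].
#' @return Percentage in \[0, 100\], or `NA` for an empty group.
#' @examples
#' rec <- tibble::tibble(
#'   participant_id = paste0("p", 1:4), arm = "5pt", group = "patient",
#'   round = 1L, outcome_id = "pain", rating = c(4L, 4L, 3L, 2L))
#' importance_proportion(rec, "pain", "patient", 1, delphi_scales()[["5pt"]])
#' @export
importance_proportion <- function(records, outcome, group, round, scale) {
  r <- records[records$outcome_id == outcome & records$group == group &
                 records$round == round & records$arm == scale$scale_id, ]
  if (nrow(r) == 0) return(NA_real_)
  100 * sum(r$rating >= scale$importance_cutoff) / nrow(r)
}

#' Apply the consensus criterion to one outcome's group percentages
#'
#' @param proportions Named numeric vector of per-group percentages in
#'   \[0, 100\], covering all canonical groups; `NA` marks an empty group.
#' @param rule A [consensus_rule()].
#' @return `TRUE` if the outcome reaches consensus.
#' @examples
#' p <- c(clinician = 93, clinician_researcher = 95, patient = 100,
#'        researcher = 100, service_provider_policy_maker = 100)
#' group_consensus(p, consensus_rule())
#' @export
group_consensus <- function(proportions, rule = consensus_rule()) {
  if (is.null(names(proportions)) ||
      !all(rule$mandatory_groups %in% names(proportions))) {
    stop("`proportions` must be named and cover the mandatory groups",
         call. = FALSE)
  }
  ok <- meets_percent(proportions, rule$importance_threshold)
  sum(ok) >= rule$min_groups && all(ok[rule$mandatory_groups])
}

#' Per-group importance percentages for every outcome in a round
#'
#' Vectorised form of [importance_proportion()]: tabulates, for one round and
#' arm, each (outcome, group) cell's rater count, important-rating count and
#' percentage.
#'
#' @inheritParams importance_proportion
#' @param arm Arm (scale) identifier.
#' @param scales Named list of [rating_scale()] objects.
#' @return Tibble with columns `outcome_id`, `group`, `n`, `n_important`,
#'   `percent`.
#' @export
group_percentages <- function(records, round, arm,
                              scales = delphi_scales()) {
  scales <- stats::setNames(scales, scale_ids(scales))
  cutoff <- scales[[arm]]$importance_cutoff
  r <- records[records$round == round & records$arm == arm, ]
  out <- dplyr::summarise(
    dplyr::group_by(r, .data$outcome_id, .data$group),
    n = dplyr::n(),
    n_important = sum(.data$rating >= cutoff),
    .groups = "drop"
  )
  out$percent <- 100 * out$n_important / out$n
  out
}

#' Evaluate the consensus criterion for one round of one arm
#'
#' Accepts either raw rating records (columns `participant_id`, `arm`,
#' `group`, `round`, `outcome_id`, `rating`) or a percentage table (columns
#' `outcome_id`, `group`, `round`, `arm`, `percent`) such as the
#' `interview_ratings` fixture. From raw records the exact rational
#' proportion is compared to the threshold; from a percentage table the
#' printed values are compared as given, with no re-rounding — display
#' rounding must never change a decision on raw data.
#'
#' Candidates default to the outcomes with any data in that round and arm
#' (in a percentage table, a missing cell row is a dash — not a candidate).
#' A supplied candidate with no ratings at all is flagged with a warning and
#' marked `not_rated`, excluding it from the possible-outcome count.
#'
#' @param x Rating records or percentage table.
#' @param round Delphi round (1..3).
#' @param arm Arm identifier.
#' @param rule A [consensus_rule()].
#' @param scales Named list of [rating_scale()] objects (records input only).
#' @param candidates Optional character vector of candidate outcomes.
#' @return Tibble with columns `outcome_id`, `arm`, `round`, `status`
#'   (`"in"` / `"out"` / `"not_rated"`), ordered by `outcome_id`.
#' @export
evaluate_round <- function(x, round, arm, rule = consensus_rule(),
                           scales = delphi_scales(), candidates = NULL) {
  if ("percent" %in% names(x)) {
    cells <- x[x$round == round & x$arm == arm, ]
    rated <- unique(cells$outcome_id[!is.na(cells$percent)])
    qualifies <- meets_percent(cells$percent, rule$importance_threshold)
  } else {
    cells <- group_percentages(x, round, arm, scales)
    rated <- unique(cells$outcome_id)
    qualifies <- meets_count(cells$n_important, cells$n,
                             rule$importance_threshold)
  }
  if (is.null(candidates)) {
    candidates <- rated
  } else if (length(setdiff(candidates, rated))) {
    warning("candidate outcome(s) with no ratings in round ", round, " (",
            arm, "): ", paste(setdiff(candidates, rated), collapse = ", "),
            "; marked not_rated", call. = FALSE)
  }

  qual_by_outcome <- split(qualifies, cells$outcome_id)
  grp_by_outcome <- split(cells$group, cells$outcome_id)
  status <- vapply(candidates, function(oc) {
    if (!oc %in% rated) return("not_rated")
    ok <- qual_by_outcome[[oc]]
    grp <- grp_by_outcome[[oc]]
    mand <- rule$mandatory_groups %in% grp[ok]
    if (sum(ok) >= rule$min_groups && all(mand)) "in" else "out"
  }, character(1))

  out <- tibble::tibble(outcome_id = candidates, arm = arm,
                        round = as.integer(round), status = unname(status))
  dplyr::arrange(out, .data$outcome_id)
}

#' Evaluate all rounds of a multi-arm Delphi
#'
#' Runs [evaluate_round()] for every round and arm present in the data,
#' treating each arm's survey independently, and completes the grid with
#' `not_rated` entries so every (outcome, arm, round) has a status. The
#' candidate set of each round is the set of outcomes actually rated in it:
#' round 1 to 2 re-rates everything plus merged suggestions (carry-all) and
#' round 2 to 3 keeps only outcomes that reached consensus (filter), which is
#' how upstream data generation (or the study itself) shapes the per-round
#' data.
#'
#' @inheritParams evaluate_round
#' @param rounds Rounds to evaluate; default `1:3`.
#' @param arms Arms to evaluate; default all arms in the data.
#' @return A decisions tibble (`outcome_id`, `arm`, `round`, `status`).
#' @export
evaluate_delphi <- function(x, rule = consensus_rule(),
                            scales = delphi_scales(), rounds = 1:3,
                            arms = NULL) {
  if (is.null(arms)) arms <- sort(unique(x$arm))
  pieces <- list()
  for (a in arms) {
    for (r in rounds) {
      pieces[[paste(a, r)]] <- evaluate_round(x, r, a, rule, scales)
    }
  }
  dec <- dplyr::bind_rows(pieces)
  all_outcomes <- sort(unique(dec$outcome_id))
  grid <- tidyr::expand_grid(outcome_id = all_outcomes, arm = arms,
                             round = as.integer(rounds))
  dec <- dplyr::left_join(grid, dec, by = c("outcome_id", "arm", "round"))
  dec$status[is.na(dec$status)] <- "not_rated"
  dplyr::arrange(dec, .data$outcome_id, .data$arm, .data$round)
}

#' Outcomes carried into the next round
#'
#' `carry_all` returns every outcome rated in the round regardless of status
#' (the round 1 to 2 transition); `filter` returns only outcomes that reached
#' consensus (the round 2 to 3 transition). Per-arm lists may differ because
#' each survey is treated independently.
#'
#' @param decision Decisions tibble from [evaluate_delphi()] or the
#'   `round_decisions` fixture.
#' @param round The round whose decisions feed the transition.
#' @param mode `"carry_all"` or `"filter"`.
#' @return Named list of outcome-id vectors, one per arm, sorted.
#' @export
next_round_outcomes <- function(decision, round,
                                mode = c("filter", "carry_all")) {
  mode <- match.arg(mode)
  d <- decision[decision$round == round, ]
  keep <- if (mode == "carry_all") d$status != "not_rated" else
    d$status == "in"
  d <- d[keep, ]
  lapply(split(d$outcome_id, d$arm), function(x) sort(unique(x)))
}

#' Merge adjudicated round-1 suggestions into the outcome registry
#'
#' Panellists may suggest additional outcomes in round 1; a steering
#' committee adjudicates each free-text suggestion. `include_new`
#' suggestions mint outcomes entering round 2 on both arms;
#' `already_included` and `not_an_outcome` leave the registry unchanged.
#' The engine never classifies free text itself — adjudications are inputs.
#'
#' @param suggestions Tibble with columns `raw_text`, `outcome_name`,
#'   `decision` (`include_new` / `already_included` / `not_an_outcome`) and
#'   `mapped_outcome_id` (the target id for `already_included`; for
#'   `include_new` the id to mint, minted from `outcome_name` when empty).
#' @param registry Outcome registry tibble (`outcome_id`, `name`, `sources`,
#'   `first_round`), e.g. `pgp_fixture("outcomes")`.
#' @return The updated registry.
#' @export
merge_suggestions <- function(suggestions, registry) {
  stopifnot(all(c("decision") %in% names(suggestions)))
  bad <- setdiff(unique(suggestions$decision),
                 c("include_new", "already_included", "not_an_outcome"))
  if (length(bad)) stop("unknown decision(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  ai <- suggestions[suggestions$decision == "already_included", ]
  if (any(is.na(ai$mapped_outcome_id) | ai$mapped_outcome_id == "")) {
    stop("already_included suggestions must name a mapped_outcome_id",
         call. = FALSE)
  }
  new <- suggestions[suggestions$decision == "include_new", ]
  if (nrow(new) == 0) return(registry)
  ids <- ifelse(is.na(new$mapped_outcome_id) | new$mapped_outcome_id == "",
                outcome_slug(new$outcome_name), new$mapped_outcome_id)
  clash <- ids %in% registry$outcome_id & !duplicated(ids)
  already <- ids %in% registry$outcome_id
  if (any(already)) {
    stop("include_new suggestion duplicates existing outcome(s): ",
         paste(ids[already], collapse = ", "),
         "; adjudicate explicitly as already_included", call. = FALSE)
  }
  minted <- tibble::tibble(outcome_id = ids, name = new$outcome_name,
                           sources = "round1_suggestion", first_round = 2L)
  dplyr::bind_rows(registry, minted)
}

# canonical identifier from a display name
outcome_slug <- function(name) {
  s <- tolower(name)
  s <- gsub("[^a-z0-9]+", "_", s)
  gsub("^_|_$", "", s)
}

#' Preliminary core outcome set after the final round
#'
#' The preliminary COS of each arm is the set of outcomes that reached
#' consensus in round 3 of that arm; the combined preliminary COS is their
#' union (deduplicated by outcome id), as carried to the face-to-face
#' consensus meeting.
#'
#' @param decision Decisions tibble covering round 3 of every arm.
#' @return List with `per_arm` (named list of sorted id vectors) and `union`.
#' @export
preliminary_cos <- function(decision) {
  d <- decision[decision$round == 3 & decision$status == "in", ]
  per_arm <- lapply(split(d$outcome_id, d$arm),
                    function(x) sort(unique(x)))
  list(per_arm = per_arm,
       union = sort(unique(unlist(per_arm, use.names = FALSE))))
}

#' Count outcomes shared by two lists
#'
#' @param list_a,list_b Character vectors of outcome ids (deduplicated).
#' @return `|a intersect b|`.
#' @export
overlap_count <- function(list_a, list_b) {
  length(intersect(unique(list_a), unique(list_b)))
}

#' Per-round In/Out tallies of a decision set
#'
#' @param decision Decisions tibble.
#' @return Tibble with `arm`, `round`, `possible_n` (outcomes rated) and
#'   `in_n` (outcomes reaching consensus).
#' @export
tally_decisions <- function(decision) {
  dplyr::summarise(
    dplyr::group_by(decision, .data$arm, .data$round),
    possible_n = sum(.data$status != "not_rated"),
    in_n = sum(.data$status == "in"),
    .groups = "drop"
  )
}

#' Track how outcomes from one source fared across rounds
#'
#' Summarises, per round and arm, the decision statuses of the outcomes
#' carrying a given source tag (e.g. `"interview"` for the patient
#' interview-derived outcomes, or `"round1_suggestion"` for outcomes
#' suggested during round 1), and counts how many reached the preliminary
#' COS on at least one arm. If the final COS (agreed at the consensus
#' meeting, outside this engine) is supplied, its overlap with the tagged
#' outcomes is counted too.
#'
#' @param decision Decisions tibble.
#' @param registry Outcome registry with a `sources` column
#'   (semicolon-separated tags).
#' @param source Source tag to track.
#' @param final_cos Optional character vector of final-COS outcome ids.
#' @return List with `outcomes` (tagged ids), `summary` (per arm and round
#'   counts of in/out/not_rated), `n_preliminary`, and `n_final` (`NA` when
#'   `final_cos` is not supplied).
#' @export
track_source_outcomes <- function(decision, registry, source,
                                  final_cos = NULL) {
  tags <- strsplit(registry$sources, ";", fixed = TRUE)
  tagged <- registry$outcome_id[vapply(tags, function(s) source %in% s,
                                       logical(1))]
  d <- decision[decision$outcome_id %in% tagged, ]
  grid <- tidyr::expand_grid(arm = sort(unique(decision$arm)),
                             round = sort(unique(decision$round)))
  summ <- dplyr::summarise(
    dplyr::group_by(d, .data$arm, .data$round),
    n_in = sum(.data$status == "in"),
    n_out = sum(.data$status == "out"),
    n_not_rated = sum(.data$status == "not_rated"),
    .groups = "drop"
  )
  summ <- dplyr::left_join(grid, summ, by = c("arm", "round"))
  summ[is.na(summ)] <- 0L
  prelim <- preliminary_cos(decision)$union
  list(
    outcomes = sort(tagged),
    summary = summ,
    n_preliminary = overlap_count(tagged, prelim),
    n_final = if (is.null(final_cos)) NA_integer_ else
      overlap_count(tagged, final_cos)
  )
}
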