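#' Evaluate a Delphi data set and write decision reports
#'
#' Runs the consensus engine over long-format ratings (or a percentage
#' table) and writes: the long decision table, a wide In/Out grid (one row
#' per outcome, one column per round and arm), per-(outcome, group)
#' percentage tables, and the per-round tallies. Outputs are
#' deterministically ordered, so repeated runs on identical inputs are
#' byte-identical.
#'
#' @param x Ratings tibble / CSV path, or a percentage table (see
#'   [evaluate_round()]).
#' @param rule A [consensus_rule()] or path to a rule YAML.
#' @param scales Named list of [rating_scale()] objects.
#' @param out_dir Output directory (created if needed).
#' @param format `"tsv"` (default) or `"json"` for the decision export.
#' @return Invisibly, a list with `decisions` and `tally`.
#' @export
run_evaluate <- function(x, rule = consensus_rule(),
                         scales = delphi_scales(), out_dir = ".",
                         format = c("tsv", "json")) {
  format <- match.arg(format)
  if (is.character(x) && length(x) == 1) x <- read_ratings(x, scales)
  if (is.character(rule) && length(rule) == 1) rule <- read_rule(rule)
  if (nrow(x) == 0) stop("no rating data to evaluate", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  decisions <- evaluate_delphi(x, rule, scales)
  tally <- tally_decisions(decisions)
  wide <- tidyr::pivot_wider(
    dplyr::mutate(decisions,
                  col = paste0("round", .data$round, "_", .data$arm)),
    id_cols = "outcome_id", names_from = "col", values_from = "status")
  wide <- dplyr::arrange(wide, .data$outcome_id)

  if (format == "json") {
    jsonlite::write_json(list(decisions = decisions, tally = tally),
                         file.path(out_dir, "decisions.json"),
                         dataframe = "rows", pretty = TRUE)
  } else {
    readr::write_tsv(decisions, file.path(out_dir, "decisions.tsv"))
    readr::write_tsv(wide, file.path(out_dir, "decisions_wide.tsv"))
    readr::write_tsv(tally, file.path(out_dir, "tally.tsv"))
  }
  if (!"percent" %in% names(x)) {
    pieces <- list()
    for (a in sort(unique(x$arm))) {
      for (r in sort(unique(x$round))) {
        p <- group_percentages(x, r, a, scales)
        if (nrow(p)) {
          p$arm <- a
          p$round <- r
          pieces[[paste(a, r)]] <- p
        }
      }
    }
    props <- dplyr::arrange(dplyr::bind_rows(pieces), .data$outcome_id,
                            .data$arm, .data$round, .data$group)
    readr::write_csv(props, file.path(out_dir, "group_percentages.csv"))
  }
  invisible(list(decisions = decisions, tally = tally))
}

#' Compare the two arms and write the statistics report
#'
#' Emits the pooled two-proportion z comparisons of consensus counts for
#' every round plus the preliminary-COS comparison, the attrition grid
#' (group x transition x arm) and the overall attrition z. The JSON and
#' text outputs are rendered from the same computed tables, so they always
#' agree.
#'
#' @param tally Decisions tibble or per-round tally (see
#'   [compare_round_consensus()]).
#' @param roster Roster tibble / CSV path or per-round counts (see
#'   [attrition_rates()]).
#' @param out_dir Output directory.
#' @param arms Length-2 arm order; default sorted.
#' @return Invisibly, a list with `comparisons` (tibble) and `attrition`.
#' @export
run_compare <- function(tally, roster, out_dir = ".", arms = NULL) {
  if (is.character(roster) && length(roster) == 1) {
    roster <- read_roster(roster)
  }
  tal <- if ("status" %in% names(tally)) tally_decisions(tally) else
    tibble::as_tibble(tally)
  present <- sort(unique(tal$arm))
  if (is.null(arms)) arms <- present
  if (length(present) < 2) {
    stop("need two arms; only found: ", paste(present, collapse = ", "),
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  rounds <- sort(unique(tal$round))
  comp_rows <- lapply(c(as.list(rounds), list("preliminary")), function(r) {
    cz <- compare_round_consensus(tal, r, arms = arms)
    tibble::tibble(comparison = paste0("round_", r),
                   x1 = cz$x1, n1 = cz$n1, x2 = cz$x2, n2 = cz$n2,
                   z = cz$z, z_abs = cz$z_abs, p_value = cz$p_value)
  })
  az <- attrition_comparison(roster, arms = arms)
  comp_rows <- c(comp_rows, list(tibble::tibble(
    comparison = "attrition_overall", x1 = az$x1, n1 = az$n1, x2 = az$x2,
    n2 = az$n2, z = az$z, z_abs = az$z_abs, p_value = az$p_value)))
  comparisons <- dplyr::bind_rows(comp_rows)
  attrition <- attrition_rates(roster)

  readr::write_tsv(comparisons, file.path(out_dir, "comparisons.tsv"))
  readr::write_tsv(attrition, file.path(out_dir, "attrition.tsv"))
  jsonlite::write_json(
    list(arms = arms, comparisons = comparisons, attrition = attrition),
    file.path(out_dir, "comparison.json"), dataframe = "rows",
    pretty = TRUE, digits = NA)
  invisible(list(comparisons = comparisons, attrition = attrition))
}

# helper for replay_study rows
replay_row <- function(check, expected, computed, pass = NULL,
                       note = NA_character_) {
  tibble::tibble(
    check = check, expected = as.character(expected),
    computed = as.character(computed),
    pass = if (is.null(pass)) identical(as.character(expected),
                                        as.character(computed)) else pass,
    note = note)
}

#' Replay every reported study statistic from the bundled fixtures
#'
#' Recomputes, from the shipped tables alone: the consensus decisions of the
#' eight interview-derived outcomes (from their printed group percentages)
#' against the published In/Out grid; the preliminary-COS membership among
#' them; the per-round In/possible tallies against the printed totals; the
#' four pooled two-proportion z statistics and the attrition z; the full
#' attrition grid; the preliminary-COS overlap; the suggestion merge; and
#' the feedback percentages. One known print inconsistency is expected to
#' fail: the round-3 5-point totals (printed 24/37) do not equal the sum of
#' the printed row statuses (26/36) — see the methods vignette.
#'
#' @param rule The consensus rule to replay under; default the study's.
#' @return Tibble with columns `check`, `expected`, `computed`, `pass`,
#'   `note`.
#' @examples
#' \donttest{replay_study()}
#' @export
replay_study <- function(rule = consensus_rule()) {
  rows <- list()
  t1 <- pgp_fixture("interview_ratings")
  dec4 <- pgp_fixture("round_decisions")
  summ <- pgp_fixture("round_summary")

  # 1. interview-derived outcomes: decisions replayed from percentages
  replayed <- evaluate_delphi(t1, rule)
  published <- dec4[dec4$outcome_id %in% unique(t1$outcome_id), ]
  cmp <- dplyr::inner_join(replayed, published,
                           by = c("outcome_id", "arm", "round"),
                           suffix = c("_replayed", "_published"))
  n_match <- sum(cmp$status_replayed == cmp$status_published)
  rows$interview <- replay_row(
    "interview outcome decisions replayed from printed percentages",
    paste0(nrow(cmp), " of ", nrow(cmp), " cells"),
    paste0(n_match, " of ", nrow(cmp), " cells"))

  # 2. preliminary-COS membership among interview-derived outcomes
  prelim_replayed <- preliminary_cos(replayed)$union
  rows$interview_prelim <- replay_row(
    "interview-derived outcomes in the preliminary COS",
    "emotional_symptoms, family_life_impact, sexual_functioning, social_life_impact",
    paste(sort(prelim_replayed), collapse = ", "))

  # 3. per-round tallies vs printed totals
  tal <- tally_decisions(dec4)
  for (i in seq_len(nrow(summ))) {
    s <- summ[i, ]
    t <- tal[tal$arm == s$arm & tal$round == s$round, ]
    note <- if (s$arm == "5pt" && s$round == 3) {
      "known print inconsistency: row statuses sum to 26/36, totals row says 24/37"
    } else NA_character_
    rows[[paste0("tally_", s$arm, "_r", s$round)]] <- replay_row(
      sprintf("round %d tally, %s arm (in/possible)", s$round, s$arm),
      sprintf("%d/%d", s$in_n, s$possible_n),
      sprintf("%d/%d", t$in_n, t$possible_n), note = note)
  }

  # 4. z statistics from the printed counts
  zs <- list(round1 = list(1, 2.46), round2 = list(2, 2.95),
             round3 = list(3, 0.73), preliminary = list("preliminary", 2.55))
  for (nm in names(zs)) {
    z <- compare_round_consensus(summ, zs[[nm]][[1]])
    rows[[paste0("z_", nm)]] <- replay_row(
      paste0("two-proportion z, ", nm), sprintf("%.2f", zs[[nm]][[2]]),
      sprintf("%.2f", round_half_up(z$z_abs, 2)))
  }
  za <- attrition_comparison(pgp_round_counts())
  rows$z_attrition <- replay_row(
    "two-proportion z, overall attrition", "1.15",
    sprintf("%.4f", za$z_abs), pass = abs(za$z_abs - 1.15) < 0.01,
    note = "printed value 1.15 is the truncation of 1.1570")

  # 5. attrition grid vs printed rates
  att <- attrition_rates(pgp_round_counts())
  att5 <- pgp_fixture("attrition")
  m <- dplyr::inner_join(att, att5, by = c("group", "arm", "transition"),
                         suffix = c("_computed", "_printed"))
  rows$attrition <- replay_row(
    "attrition grid recomputed from headcounts",
    paste0(nrow(m), " of ", nrow(m), " cells"),
    paste0(sum(m$percent_computed == m$percent_printed), " of ", nrow(m),
           " cells"))

  # 6. preliminary-COS overlap between arms
  pc <- preliminary_cos(dec4)
  rows$overlap <- replay_row(
    "overlap of the two preliminary COS lists", 10,
    overlap_count(pc$per_arm[["5pt"]], pc$per_arm[["9pt"]]))

  # 7. suggestion merge
  reg <- pgp_fixture("outcomes")
  merged <- merge_suggestions(pgp_fixture("suggested_outcomes"),
                              reg[reg$first_round == 1, ])
  rows$merge <- replay_row(
    "new outcomes minted from patient suggestions", 4,
    nrow(merged) - sum(reg$first_round == 1))
  rows$round2_n <- replay_row(
    "round-2 candidate outcomes per arm after merging all suggestions", 68,
    paste(sort(unique(tal$possible_n[tal$round == 2])), collapse = ", "))

  # 8. feedback tallies; 33/64 = 51.56% printed as 51 (truncated), so a
  # computed cell counts as matching if it equals the print under either
  # display convention (half-up or truncation)
  fb <- feedback_tally(pgp_fixture("feedback"))
  fav <- fb[fb$category %in% c("easy_very_easy", "clear_very_clear"), ]
  fav <- dplyr::arrange(fav, .data$question, .data$arm)
  printed <- c(87, 73, 64, 51)
  raw <- 100 * fav$n / fav$denominator
  ok <- round_half_up(raw) == printed | floor(raw) == printed
  rows$feedback <- replay_row(
    "scale feedback percentages (clarity 5pt/9pt, ease 5pt/9pt)",
    paste(printed, collapse = ", "), paste(fav$percent, collapse = ", "),
    pass = all(ok),
    note = "printed 51 is the truncation of 33/64 = 51.56%")

  dplyr::bind_rows(rows)
}
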