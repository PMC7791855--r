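#' Read long-format Delphi rating records
#'
#' One row per (participant, outcome, round) rating. Records are validated
#' against the scale of the participant's arm: unknown arms or stakeholder
#' groups, out-of-range ratings, rounds outside 1..3 and duplicate
#' (participant, outcome, round) rows are rejected with messages naming the
#' offending rows.
#'
#' @param path CSV file with columns `participant_id`, `arm`, `group`,
#'   `round`, `outcome_id`, `rating` (header required).
#' @param scales Named list of [rating_scale()] objects keyed by arm;
#'   default [delphi_scales()].
#' @param strict If `TRUE` (default) any invalid row is an error; if `FALSE`
#'   invalid rows are dropped with a warning reporting how many and which.
#' @return A tibble of validated rating records.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines("participant_id,arm,group,round,outcome_id,rating", f)
#' read_ratings(f)          # empty file with valid header -> 0 rows
#' @export
read_ratings <- function(path, scales = delphi_scales(), strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    arm = readr::col_character(),
    group = readr::col_character(),
    round = readr::col_integer(),
    outcome_id = readr::col_character(),
    rating = readr::col_integer()
  ))
  validate_ratings(x, scales, strict = strict)
}

#' Write rating records to CSV
#'
#' Inverse of [read_ratings()]; the round trip is lossless.
#'
#' @param x Tibble of rating records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(x, path) {
  cols <- c("participant_id", "arm", "group", "round", "outcome_id", "rating")
  stopifnot(all(cols %in% names(x)))
  readr::write_csv(x[cols], path)
  invisible(path)
}

#' Validate a tibble of rating records
#'
#' @inheritParams read_ratings
#' @param x Tibble with the rating-record columns.
#' @return The validated tibble (invalid rows removed when `strict = FALSE`).
#' @export
validate_ratings <- function(x, scales = delphi_scales(), strict = TRUE) {
  needed <- c("participant_id", "arm", "group", "round", "outcome_id",
              "rating")
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0) return(x)

  st <- scale_table(scales)
  probs <- character(0)
  bad <- rep(FALSE, nrow(x))

  mark <- function(idx, what) {
    if (any(idx)) {
      probs <<- c(probs, sprintf("row %d: %s", which(idx), what[idx]))
      bad <<- bad | idx
    }
  }
  mark(!x$arm %in% st$arm, sprintf("unknown arm '%s'", x$arm))
  mark(!x$group %in% stakeholder_groups(),
       sprintf("unknown group '%s'", x$group))
  mark(!x$round %in% 1:3, sprintf("round %s outside 1..3", x$round))
  np <- st$n_points[match(x$arm, st$arm)]
  bad_rating <- !bad & (is.na(x$rating) | x$rating < 1 | x$rating > np)
  mark(bad_rating,
       sprintf("rating %s outside 1..%s for arm '%s'", x$rating, np, x$arm))
  dup <- duplicated(x[c("participant_id", "outcome_id", "round")])
  mark(dup, rep("duplicate (participant, outcome, round)", nrow(x)))

  if (length(probs)) {
    msg <- paste0(length(probs), " invalid rating row(s):\n  ",
                  paste(utils::head(probs, 10), collapse = "\n  "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    x <- x[!bad, , drop = FALSE]
  }
  x
}

#' Read a participant roster
#'
#' One row per panellist with the arm they were randomised to, their
#' stakeholder group and `last_round`, the last Delphi round they completed.
#' Attrition is monotone by construction: completing round r implies
#' completing all earlier rounds, so `last_round` fully encodes
#' `rounds_completed`.
#'
#' @param path CSV with columns `participant_id`, `arm`, `group`,
#'   `last_round` and optionally `gender`, `age_band`, `country`.
#' @param scales Named list of [rating_scale()] objects (for arm validation).
#' @return A tibble roster.
#' @export
read_roster <- function(path, scales = delphi_scales()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_csv(path, show_col_types = FALSE)
  validate_roster(x, scales)
}

#' Write a participant roster to CSV
#' @param x Roster tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' Validate a participant roster
#' @inheritParams read_roster
#' @param x Roster tibble.
#' @return The validated tibble.
#' @export
validate_roster <- function(x, scales = delphi_scales()) {
  needed <- c("participant_id", "arm", "group", "last_round")
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  x$last_round <- as.integer(x$last_round)
  if (any(!x$arm %in% scale_ids(scales))) {
    stop("unknown arm(s): ",
         paste(setdiff(unique(x$arm), scale_ids(scales)), collapse = ", "),
         call. = FALSE)
  }
  if (any(!x$group %in% stakeholder_groups())) {
    stop("unknown group(s): ",
         paste(setdiff(unique(x$group), stakeholder_groups()),
               collapse = ", "), call. = FALSE)
  }
  if (any(!x$last_round %in% 0:3)) {
    stop("`last_round` must be in 0..3", call. = FALSE)
  }
  if (anyDuplicated(x$participant_id)) {
    stop("duplicate participant_id(s)", call. = FALSE)
  }
  x
}

#' Expand a per-round count table into a synthetic roster
#'
#' Builds the smallest roster consistent with monotone per-round headcounts:
#' for each (group, arm) with counts `n1 >= n2 >= n3`, `n3` participants have
#' `last_round = 3`, `n2 - n3` have `last_round = 2`, `n1 - n2` have
#' `last_round = 1`. Participant identifiers are synthetic.
#'
#' @param counts Tibble with columns `group`, `arm`, `round`, `n`.
#' @return A roster tibble as from [read_roster()].
#' @examples
#' roster_from_counts(pgp_round_counts())
#' @export
roster_from_counts <- function(counts) {
  stopifnot(all(c("group", "arm", "round", "n") %in% names(counts)))
  wide <- tidyr::pivot_wider(counts[c("group", "arm", "round", "n")],
                             names_from = "round", values_from = "n",
                             names_prefix = "r", values_fill = 0L)
  for (r in c("r1", "r2", "r3")) if (is.null(wide[[r]])) wide[[r]] <- 0L
  if (any(wide$r1 < wide$r2 | wide$r2 < wide$r3)) {
    stop("counts must be weakly decreasing over rounds", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(wide)), function(i) {
    w <- wide[i, ]
    last <- rep(c(3L, 2L, 1L), c(w$r3, w$r2 - w$r3, w$r1 - w$r2))
    if (!length(last)) return(NULL)
    tibble::tibble(
      participant_id = sprintf("%s_%s_%03d", w$arm, w$group,
                               seq_along(last)),
      arm = w$arm, group = w$group, last_round = last
    )
  })
  dplyr::bind_rows(rows)
}
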