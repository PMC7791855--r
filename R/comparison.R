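#' Round half away from zero
#'
#' Commercial rounding (0.5 always rounds up), the convention used for the
#' integer percentages in the study tables (e.g. 24.75 -> 25, 39.42 -> 39);
#' base R's `round()` rounds half to even. Only defined here for
#' non-negative inputs.
#'
#' @param x Numeric vector (>= 0).
#' @param digits Decimal places; default 0.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(24.75)  # 25
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Pooled two-proportion z-test
#'
#' Tests equality of two binomial proportions with the normal approximation
#' and pooled variance:
#' \deqn{Z = \frac{(p_1 - p_2) - 0}{\sqrt{p(1-p)(1/n_1 + 1/n_2)}}}
#' where \eqn{p = (x_1 + x_2)/(n_1 + n_2)} is the pooled proportion. No
#' continuity correction is applied. The p-value is the two-sided standard
#' normal tail. Both the signed `z` and its magnitude `z_abs` are reported:
#' the statistic is antisymmetric in the order of the arms, its magnitude is
#' not.
#'
#' @param x1,n1 Successes and trials in the first arm.
#' @param x2,n2 Successes and trials in the second arm.
#' @return Object of class `prop_comparison`: a list with `x1`, `n1`, `x2`,
#'   `n2`, `p1`, `p2`, `pooled_p`, `z`, `z_abs`, `p_value`.
#' @examples
#' two_proportion_z(41, 53, 29, 53)  # |z| = 2.46
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  v <- c(x1 = x1, n1 = n1, x2 = x2, n2 = n2)
  if (any(is.na(v)) || any(v < 0) || any(v != round(v))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (n1 == 0 || n2 == 0) stop("n1 and n2 must be positive", call. = FALSE)
  if (x1 > n1 || x2 > n2) stop("need x <= n in each arm", call. = FALSE)
  p1 <- x1 / n1
  p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1) {
    stop("degenerate comparison: pooled proportion is ", pooled,
         " so the pooled variance is zero", call. = FALSE)
  }
  z <- (p1 - p2) / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  structure(
    list(x1 = x1, n1 = n1, x2 = x2, n2 = n2, p1 = p1, p2 = p2,
         pooled_p = pooled, z = z, z_abs = abs(z),
         p_value = 2 * stats::pnorm(-abs(z))),
    class = "prop_comparison"
  )
}

#' @export
print.prop_comparison <- function(x, ...) {
  cat(sprintf("<prop_comparison> %d/%d (%.3f) vs %d/%d (%.3f)\n",
              x$x1, x$n1, x$p1, x$x2, x$n2, x$p2))
  cat(sprintf("  z = %.4f  |z| = %.2f  p = %.2f (two-sided)\n",
              x$z, x$z_abs, x$p_value))
  invisible(x)
}

#' Compare consensus proportions between arms for one round
#'
#' For a given round, the proportion of candidate outcomes reaching
#' consensus is compared between the two arms with [two_proportion_z()].
#' `round = "preliminary"` compares the preliminary-COS sizes (round-3 "In"
#' counts) against the full round-2 candidate list of each arm, mirroring
#' how the study compared its preliminary core outcome sets.
#'
#' @param x Either a decisions tibble (tallied with [tally_decisions()]) or
#'   a tally/summary tibble with columns `arm`, `round`, `possible_n`,
#'   `in_n` (e.g. `pgp_fixture("round_summary")`, the study's printed
#'   totals).
#' @param round 1, 2, 3 or `"preliminary"`.
#' @param arms Length-2 character vector giving the arm order; the first is
#'   `p1`. Default: sorted arm names (so `"5pt"` before `"9pt"`).
#' @return A `prop_comparison`.
#' @examples
#' compare_round_consensus(pgp_fixture("round_summary"), 1)  # |z| = 2.46
#' @export
compare_round_consensus <- function(x, round, arms = NULL) {
  tal <- if ("status" %in% names(x)) tally_decisions(x) else
    tibble::as_tibble(x)
  stopifnot(all(c("arm", "round", "possible_n", "in_n") %in% names(tal)))
  if (is.null(arms)) arms <- sort(unique(tal$arm))
  if (length(arms) != 2) stop("need exactly two arms", call. = FALSE)
  pick <- function(a, r, col) {
    v <- tal[tal$arm == a & tal$round == r, ][[col]]
    if (length(v) != 1) stop("no tally for arm ", a, ", round ", r,
                             call. = FALSE)
    v
  }
  if (identical(round, "preliminary")) {
    two_proportion_z(pick(arms[1], 3, "in_n"), pick(arms[1], 2, "possible_n"),
                     pick(arms[2], 3, "in_n"), pick(arms[2], 2, "possible_n"))
  } else {
    two_proportion_z(pick(arms[1], round, "in_n"),
                     pick(arms[1], round, "possible_n"),
                     pick(arms[2], round, "in_n"),
                     pick(arms[2], round, "possible_n"))
  }
}

# per-round headcounts from a roster: n at round r = participants whose
# last completed round is >= r
counts_from_roster <- function(roster) {
  grid <- tidyr::expand_grid(
    dplyr::distinct(roster[c("group", "arm")]), round = 1:3)
  grid$n <- mapply(function(g, a, r) {
    sum(roster$group == g & roster$arm == a & roster$last_round >= r)
  }, grid$group, grid$arm, grid$round)
  grid
}

#' Per-group and overall attrition rates
#'
#' Attrition over a transition is `(n_start - n_end) / n_start * 100`,
#' rounded to the nearest integer percent (half up); `overall` compares
#' round-1 with round-3 headcounts. Rates are computed per stakeholder group
#' and overall, per arm. A group with no round-1 members has undefined
#' rates, reported as `NA` rather than 0.
#'
#' @param x A roster tibble (`participant_id`, `arm`, `group`,
#'   `last_round`), or a counts tibble (`group`, `arm`, `round`, `n`) such
#'   as [pgp_round_counts()].
#' @return Tibble with columns `group` (including `"overall"`), `arm`,
#'   `transition` (`r1_to_r2`, `r2_to_r3`, `overall`), `n_start`, `n_end`,
#'   `percent`.
#' @examples
#' a <- attrition_rates(pgp_round_counts())
#' subset(a, group == "overall" & arm == "5pt")$percent  # 25 9 32
#' @export
attrition_rates <- function(x) {
  counts <- if ("last_round" %in% names(x)) counts_from_roster(x) else
    tibble::as_tibble(x)
  stopifnot(all(c("group", "arm", "round", "n") %in% names(counts)))
  overall <- dplyr::summarise(dplyr::group_by(counts, .data$arm, .data$round),
                              n = sum(.data$n), .groups = "drop")
  overall$group <- "overall"
  counts <- dplyr::bind_rows(counts, overall)
  wide <- tidyr::pivot_wider(counts[c("group", "arm", "round", "n")],
                             names_from = "round", values_from = "n",
                             names_prefix = "r", values_fill = 0L)
  rate <- function(n_start, n_end) {
    ifelse(n_start > 0, round_half_up(100 * (n_start - n_end) / n_start),
           NA_real_)
  }
  out <- dplyr::bind_rows(
    tibble::tibble(group = wide$group, arm = wide$arm,
                   transition = "r1_to_r2", n_start = wide$r1,
                   n_end = wide$r2, percent = rate(wide$r1, wide$r2)),
    tibble::tibble(group = wide$group, arm = wide$arm,
                   transition = "r2_to_r3", n_start = wide$r2,
                   n_end = wide$r3, percent = rate(wide$r2, wide$r3)),
    tibble::tibble(group = wide$group, arm = wide$arm,
                   transition = "overall", n_start = wide$r1,
                   n_end = wide$r3, percent = rate(wide$r1, wide$r3))
  )
  dplyr::arrange(out, .data$arm,
                 match(.data$group, c(stakeholder_groups(), "overall")),
                 match(.data$transition,
                       c("r1_to_r2", "r2_to_r3", "overall")))
}

#' Compare overall attrition between arms
#'
#' The dropouts of each arm (round-1 enrolees absent at round 3) over its
#' round-1 enrolment, compared with [two_proportion_z()]. The statistic
#' depends only on headcounts, so it is invariant to participant
#' relabelling.
#'
#' @inheritParams attrition_rates
#' @param arms Length-2 arm order (first arm is `p1`); default sorted.
#' @return A `prop_comparison`.
#' @examples
#' attrition_comparison(pgp_round_counts())$z_abs  # ~1.16 (printed as 1.15)
#' @export
attrition_comparison <- function(x, arms = NULL) {
  counts <- if ("last_round" %in% names(x)) counts_from_roster(x) else
    tibble::as_tibble(x)
  tot <- dplyr::summarise(dplyr::group_by(counts, .data$arm, .data$round),
                          n = sum(.data$n), .groups = "drop")
  if (is.null(arms)) arms <- sort(unique(tot$arm))
  if (length(arms) != 2) stop("need exactly two arms", call. = FALSE)
  n_at <- function(a, r) {
    v <- tot$n[tot$arm == a & tot$round == r]
    if (length(v) != 1 || v == 0) stop("arm ", a, " empty at round ", r,
                                       call. = FALSE)
    v
  }
  n1 <- n_at(arms[1], 1); n2 <- n_at(arms[2], 1)
  two_proportion_z(n1 - n_at(arms[1], 3), n1,
                   n2 - n_at(arms[2], 3), n2)
}

#' Tally closed-category feedback responses
#'
#' End-of-study feedback (scale ease of use, clarity) is tallied per arm and
#' question: counts, denominators and integer percentages (half-up). No text
#' analysis is performed — responses must already be coded into closed
#' categories. Questions were optional, so denominators may differ between
#' questions.
#'
#' @param x Either response records (columns `arm`, `question`, `category`,
#'   one row per response) or pre-aggregated counts (columns `arm`,
#'   `question`, `category`, `n`) such as `pgp_fixture("feedback")`.
#' @return Tibble with `arm`, `question`, `category`, `n`, `denominator`,
#'   `percent`. Zero rows in, zero rows out (no division by zero).
#' @examples
#' fb <- feedback_tally(pgp_fixture("feedback"))
#' subset(fb, category == "easy_very_easy")$percent  # 64 (5pt), 51 (9pt)
#' @export
feedback_tally <- function(x) {
  stopifnot(all(c("arm", "question", "category") %in% names(x)))
  if (nrow(x) == 0) {
    return(tibble::tibble(arm = character(), question = character(),
                          category = character(), n = integer(),
                          denominator = integer(), percent = numeric()))
  }
  counts <- if ("n" %in% names(x)) {
    dplyr::summarise(dplyr::group_by(x, .data$arm, .data$question,
                                     .data$category),
                     n = sum(.data$n), .groups = "drop")
  } else {
    dplyr::summarise(dplyr::group_by(x, .data$arm, .data$question,
                                     .data$category),
                     n = dplyr::n(), .groups = "drop")
  }
  counts <- dplyr::mutate(dplyr::group_by(counts, .data$arm, .data$question),
                          denominator = sum(.data$n))
  counts <- dplyr::ungroup(counts)
  counts$percent <- round_half_up(100 * counts$n / counts$denominator)
  dplyr::arrange(counts, .data$question, .data$arm, .data$category)
}
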