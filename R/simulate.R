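#' Configuration of a synthetic Delphi panel
#'
#' The simulator mirrors the study design: five stakeholder groups of
#' unequal size, participants randomised 1:1 between two rating-scale arms,
#' three rounds with monotone dropout, and a latent importance value per
#' (outcome, group) driving the ordinal ratings. Each rating draws
#' `latent = theta[outcome, group] + noise`, with Gaussian noise of spread
#' `sigma`, clamps it to `[0, 1]`, and discretises it through the arm
#' scale's cutpoints.
#'
#' Defaults reproduce the study's shape: 53 outcomes; group totals 91
#' clinicians, 38 clinician researchers, 42 patients, 23 researchers and 11
#' service providers / policy makers (the two arms' round-1 enrolments
#' combined); per-group dropout probabilities equal to the study's pooled
#' observed transition rates; `theta` drawn once per configuration from a
#' Beta(3, 1.5) (most outcomes moderately-to-highly important, as in real
#' outcome longlists).
#'
#' @param n_outcomes Number of outcomes presented in round 1.
#' @param group_sizes Named integer vector: panellists per stakeholder group
#'   (totals across arms; each panellist is randomised to an arm).
#' @param theta Optional matrix (`n_outcomes` x groups) of latent mean
#'   importance on `[0, 1]`; drawn from Beta(3, 1.5) under `seed` when
#'   `NULL`.
#' @param sigma Rater noise standard deviation on the latent axis (>= 0).
#' @param scales Named list of [rating_scale()] objects (the arms).
#' @param dropout Tibble with columns `group`, `transition`
#'   (`r1_to_r2` / `r2_to_r3`), `prob`; default the study's pooled rates.
#' @param rounds Number of rounds (default 3).
#' @param seed Integer seed; every random draw of the simulation is
#'   reproducible from it.
#' @return Object of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(n_outcomes = 6, seed = 42)
#' @export
simulation_config <- function(n_outcomes = 53,
                              group_sizes = c(
                                clinician = 91L, clinician_researcher = 38L,
                                patient = 42L, researcher = 23L,
                                service_provider_policy_maker = 11L),
                              theta = NULL, sigma = 0.2,
                              scales = delphi_scales(),
                              dropout = default_dropout(), rounds = 3L,
                              seed = 1L) {
  stopifnot(n_outcomes >= 1, sigma >= 0, rounds >= 1)
  if (is.null(names(group_sizes)) ||
      !all(names(group_sizes) %in% stakeholder_groups())) {
    stop("`group_sizes` must be named with canonical stakeholder groups",
         call. = FALSE)
  }
  if (any(group_sizes < 0)) stop("`group_sizes` must be >= 0", call. = FALSE)
  stopifnot(all(c("group", "transition", "prob") %in% names(dropout)),
            all(dropout$prob >= 0 & dropout$prob <= 1))
  scales <- stats::setNames(scales, vapply(scales, function(s) s$scale_id,
                                           character(1)))
  groups <- names(group_sizes)
  if (is.null(theta)) {
    set.seed(seed)
    theta <- matrix(stats::rbeta(n_outcomes * length(groups), 3, 1.5),
                    nrow = n_outcomes, dimnames = list(NULL, groups))
  }
  theta <- as.matrix(theta)
  if (nrow(theta) != n_outcomes || !all(groups %in% colnames(theta))) {
    stop("`theta` must be n_outcomes x groups with group column names",
         call. = FALSE)
  }
  if (is.null(rownames(theta))) {
    rownames(theta) <- sprintf("outcome_%02d", seq_len(n_outcomes))
  }
  if (any(theta < 0 | theta > 1)) {
    stop("`theta` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_outcomes = as.integer(n_outcomes), group_sizes = group_sizes,
         theta = theta, sigma = sigma, scales = scales, dropout = dropout,
         rounds = as.integer(rounds), seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Study-informed default dropout probabilities
#'
#' Pooled per-group transition dropout rates observed in the study panel
#' (both arms combined), e.g. 32/91 clinicians lost between rounds 1 and 2.
#'
#' @return Tibble with columns `group`, `transition`, `prob`.
#' @export
default_dropout <- function() {
  tibble::tibble(
    group = rep(stakeholder_groups(), each = 2),
    transition = rep(c("r1_to_r2", "r2_to_r3"), 5),
    prob = c(32 / 91, 7 / 59,    # clinician
             5 / 38, 0,          # clinician_researcher
             16 / 42, 8 / 26,    # patient
             2 / 23, 0,          # researcher
             3 / 11, 0)          # service_provider_policy_maker
  )
}

#' Map a latent importance value to a discrete rating
#'
#' The rating is one plus the number of cutpoints strictly below the latent
#' value, so the range is `1..(length(cutpoints) + 1)`. A latent value
#' exactly on a cutpoint falls in the lower category.
#'
#' @param latent_value Numeric vector on the canonical `[0, 1]` axis.
#' @param cutpoints Strictly increasing interior boundaries in (0, 1).
#' @return Integer ratings.
#' @examples
#' discretize(0.5, c(0.2, 0.4, 0.6, 0.8))  # 3
#' @export
discretize <- function(latent_value, cutpoints) {
  if (any(diff(cutpoints) <= 0)) {
    stop("`cutpoints` must be strictly increasing", call. = FALSE)
  }
  findInterval(latent_value, cutpoints, left.open = TRUE) + 1L
}

#' Simulate a full multi-round, two-arm Delphi panel
#'
#' Generates a roster (simple 1:1 randomisation of each panellist to an arm)
#' and rating records for every round. Between rounds, each active
#' panellist independently drops out with their group's transition
#' probability, so attrition is monotone. Round 1 presents all outcomes to
#' both arms; subsequent transitions follow `transitions` (by default the
#' study's design: carry everything into round 2, then keep only outcomes
#' reaching a priori consensus under `rule`, per arm independently). Each
#' rating redraws the rater noise, so a panellist's ratings vary across
#' rounds around the same latent mean.
#'
#' @param config A [simulation_config()].
#' @param rule [consensus_rule()] used for filtering transitions.
#' @param transitions Character vector naming the mode of each inter-round
#'   transition (`"carry_all"` or `"filter"`), length `rounds - 1`.
#' @return List with `roster`, `ratings` (both in the package CSV schemas,
#'   so simulated data flow through the pipeline unchanged), `candidates`
#'   (per arm, per round outcome lists) and `config`.
#' @examples
#' sim <- simulate_panel(simulation_config(n_outcomes = 4, seed = 7,
#'   group_sizes = c(clinician = 6, patient = 6)))
#' nrow(sim$roster)
#' @export
simulate_panel <- function(config, rule = consensus_rule(),
                           transitions = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(transitions)) {
    transitions <- if (config$rounds >= 2) {
      c("carry_all", rep("filter", config$rounds - 2))
    } else character(0)
  }
  stopifnot(length(transitions) == config$rounds - 1,
            all(transitions %in% c("carry_all", "filter")))
  set.seed(config$seed)
  arms <- scale_ids(config$scales)
  groups <- names(config$group_sizes)
  outcomes <- rownames(config$theta)

  # roster: simple randomisation to an arm, then monotone dropout
  roster <- tibble::tibble(
    group = rep(groups, times = config$group_sizes)
  )
  n <- nrow(roster)
  roster$participant_id <- sprintf("sim_%04d", seq_len(n))
  roster$arm <- sample(arms, n, replace = TRUE)
  last <- rep(1L, n)
  drop_prob <- function(group, trans) {
    i <- config$dropout$group == group & config$dropout$transition == trans
    if (any(i)) config$dropout$prob[which(i)[1]] else 0
  }
  trans_names <- c("r1_to_r2", "r2_to_r3")
  for (r in seq_len(config$rounds - 1)) {
    tn <- if (r <= 2) trans_names[r] else trans_names[2]
    p <- vapply(roster$group, drop_prob, numeric(1), trans = tn)
    active <- last == r
    stays <- stats::runif(n) >= p
    last[active & stays] <- r + 1L
  }
  roster$last_round <- last
  roster <- roster[c("participant_id", "arm", "group", "last_round")]

  # per-round candidate lists per arm, filtering via the consensus engine
  candidates <- stats::setNames(
    rep(list(stats::setNames(vector("list", config$rounds),
                             paste0("round", seq_len(config$rounds)))),
        length(arms)), arms)
  for (a in arms) candidates[[a]][[1]] <- outcomes

  ratings <- list()
  for (r in seq_len(config$rounds)) {
    active <- roster[roster$last_round >= r, ]
    pieces <- lapply(arms, function(a) {
      cand <- candidates[[a]][[r]]
      ra <- active[active$arm == a, ]
      if (nrow(ra) == 0 || length(cand) == 0) return(NULL)
      grid <- tidyr::expand_grid(participant_id = ra$participant_id,
                                 outcome_id = cand)
      grid$group <- ra$group[match(grid$participant_id, ra$participant_id)]
      mu <- config$theta[cbind(match(grid$outcome_id, outcomes),
                               match(grid$group, colnames(config$theta)))]
      latent <- mu + stats::rnorm(nrow(grid), 0, config$sigma)
      latent <- pmin(pmax(latent, 0), 1)
      grid$arm <- a
      grid$round <- r
      grid$rating <- discretize(latent, config$scales[[a]]$cutpoints)
      grid[c("participant_id", "arm", "group", "round", "outcome_id",
             "rating")]
    })
    round_ratings <- dplyr::bind_rows(pieces)
    ratings[[r]] <- round_ratings
    if (r < config$rounds) {
      for (a in arms) {
        cand <- candidates[[a]][[r]]
        if (transitions[r] == "carry_all" || length(cand) == 0) {
          candidates[[a]][[r + 1]] <- cand
        } else {
          dec <- evaluate_round(round_ratings, r, a, rule, config$scales,
                                candidates = cand)
          candidates[[a]][[r + 1]] <- dec$outcome_id[dec$status == "in"]
        }
      }
    }
  }
  list(roster = roster, ratings = dplyr::bind_rows(ratings),
       candidates = candidates, config = config)
}

#' Empirical importance probability of a simulated cell
#'
#' The observed share of a group's ratings at or above the arm scale's
#' importance cutoff, for one outcome (optionally one round). Used to check
#' parameter recovery against the analytic tail probability
#' [importance_probability()].
#'
#' @param records Simulated rating records.
#' @param outcome,group Cell to estimate.
#' @param scale The arm's [rating_scale()].
#' @param round Optional round filter (default: all rounds pooled).
#' @return Proportion in `[0, 1]`, or `NA` with no ratings.
#' @export
estimate_importance_probability <- function(records, outcome, group, scale,
                                            round = NULL) {
  r <- records[records$outcome_id == outcome & records$group == group &
                 records$arm == scale$scale_id, ]
  if (!is.null(round)) r <- r[r$round == round, ]
  if (nrow(r) == 0) return(NA_real_)
  mean(r$rating >= scale$importance_cutoff)
}

#' Analytic importance probability under the noise model
#'
#' Probability that a rating is "important": the latent value
#' `theta + N(0, sigma)` exceeds the cutpoint below the scale's importance
#' cutoff. Clamping to `[0, 1]` does not change this tail because the
#' cutpoint is interior.
#'
#' @param theta Latent mean(s) on `[0, 1]`.
#' @param sigma Noise standard deviation (>= 0).
#' @param scale A [rating_scale()].
#' @return Probability vector.
#' @examples
#' importance_probability(0.7, 0.2, delphi_scales()[["5pt"]])
#' @export
importance_probability <- function(theta, sigma, scale) {
  cut <- scale$cutpoints[scale$importance_cutoff - 1]
  if (sigma == 0) return(as.numeric(theta > cut))
  stats::pnorm((theta - cut) / sigma)
}

#' Monte-Carlo experiment over rating-scale granularity
#'
#' Repeatedly simulates a panel and runs the full per-arm consensus
#' pipeline, recording how many outcomes reach consensus in each round of
#' each arm. This is the synthetic analogue of the study's headline
#' comparison: with equally spaced cutpoints, the 5-point cutoff (4+) spans
#' the top 2/5 of the latent axis while the 9-point cutoff (7+) spans the
#' top 3/9, so the coarser scale is expected to admit more outcomes — a
#' measurement-artefact hypothesis this harness lets one probe.
#'
#' @param config A [simulation_config()].
#' @param rule [consensus_rule()] applied in every round.
#' @param replicates Number of simulated panels; each gets a seed derived
#'   from `config$seed`.
#' @return List with `draws` (one row per replicate, arm and round:
#'   `replicate`, `arm`, `round`, `possible_n`, `in_n`) and `summary`
#'   (per arm and round mean and standard deviation of the "In" count).
#'   Zero replicates give empty tibbles.
#' @export
run_scale_experiment <- function(config, rule = consensus_rule(),
                                 replicates = 100) {
  stopifnot(inherits(config, "simulation_config"), replicates >= 0)
  if (length(config$scales) < 2) {
    stop("need at least two scales to compare", call. = FALSE)
  }
  draws <- vector("list", replicates)
  for (i in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- (config$seed + 104729L * i) %% .Machine$integer.max
    sim <- simulate_panel(cfg, rule = rule)
    tal <- tally_decisions(
      evaluate_delphi(sim$ratings, rule, config$scales,
                      rounds = seq_len(config$rounds)))
    tal$replicate <- i
    draws[[i]] <- tal
  }
  draws <- dplyr::bind_rows(draws)
  if (nrow(draws) == 0) {
    return(list(draws = tibble::tibble(), summary = tibble::tibble()))
  }
  summary <- dplyr::summarise(
    dplyr::group_by(draws, .data$arm, .data$round),
    mean_in = mean(.data$in_n), sd_in = stats::sd(.data$in_n),
    mean_possible = mean(.data$possible_n), .groups = "drop")
  list(draws = draws[c("replicate", "arm", "round", "possible_n", "in_n")],
       summary = summary)
}
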