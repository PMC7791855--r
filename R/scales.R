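#' Define an ordinal importance rating scale
#'
#' A rating scale is the instrument a Delphi panellist uses to score how
#' important an outcome is. It has `n_points` ordered response options, an
#' `importance_cutoff` (the lowest option counted as an "important" rating),
#' and, for simulation, `cutpoints`: the `n_points - 1` interior boundaries
#' that map a latent importance value on the canonical `[0, 1]` axis to a
#' discrete option.
#'
#' @param scale_id Short identifier, e.g. `"5pt"`; used as the arm label.
#' @param n_points Number of response options (>= 2).
#' @param importance_cutoff Minimum rating counted as "important"
#'   (`1 <= importance_cutoff <= n_points`).
#' @param labels Optional character vector of option texts, one per point.
#' @param cutpoints Optional strictly increasing interior boundaries in
#'   `(0, 1)`, length `n_points - 1`. Default: equally spaced.
#' @return An object of class `rating_scale`.
#' @examples
#' rating_scale("5pt", 5, 4)
#' @export
rating_scale <- function(scale_id, n_points, importance_cutoff,
                         labels = NULL, cutpoints = NULL) {
  stopifnot(is.character(scale_id), length(scale_id) == 1, nzchar(scale_id))
  n_points <- as.integer(n_points)
  importance_cutoff <- as.integer(importance_cutoff)
  if (n_points < 2) stop("`n_points` must be at least 2", call. = FALSE)
  if (importance_cutoff < 1 || importance_cutoff > n_points) {
    stop("`importance_cutoff` must lie in 1..n_points", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("option_", seq_len(n_points))
  if (length(labels) != n_points) {
    stop("`labels` must have exactly `n_points` entries", call. = FALSE)
  }
  if (is.null(cutpoints)) cutpoints <- seq_len(n_points - 1) / n_points
  cutpoints <- as.numeric(cutpoints)
  if (length(cutpoints) != n_points - 1 ||
      any(diff(cutpoints) <= 0) ||
      any(cutpoints <= 0) || any(cutpoints >= 1)) {
    stop("`cutpoints` must be strictly increasing within (0, 1) and have ",
         "length `n_points - 1`", call. = FALSE)
  }
  structure(
    list(scale_id = scale_id, n_points = n_points,
         importance_cutoff = importance_cutoff, labels = labels,
         cutpoints = cutpoints),
    class = "rating_scale"
  )
}

#' @export
print.rating_scale <- function(x, ...) {
  cat(sprintf("<rating_scale '%s'> %d points, important at %d+\n",
              x$scale_id, x$n_points, x$importance_cutoff))
  invisible(x)
}

#' The two randomised PGP-COS Delphi rating scales
#'
#' The study randomised panellists 1:1 to a fully labelled 5-point scale
#' ("important" = 4+) or a 9-point scale ("important" = 7+). Both carried a
#' middle "unsure unimportant or important" option. Cutpoints default to
#' equally spaced boundaries, under which the 5-point cutoff spans the top
#' 2/5 of the latent axis and the 9-point cutoff the top 3/9.
#'
#' @return A named list of two [rating_scale()] objects, `"5pt"` and `"9pt"`.
#' @examples
#' delphi_scales()[["9pt"]]$importance_cutoff
#' @export
delphi_scales <- function() {
  lab5 <- c("very unimportant", "unimportant",
            "unsure unimportant or important", "important", "very important")
  list(
    `5pt` = rating_scale("5pt", 5, 4, labels = lab5),
    `9pt` = rating_scale("9pt", 9, 7)
  )
}

#' Canonical stakeholder groups
#'
#' The five panellist categories whose ratings are aggregated separately:
#' patients, clinicians, researchers, dual-role clinician researchers, and
#' service providers / policy makers. The patient group is the default
#' mandatory group of the consensus rule.
#'
#' @return Character vector of the five group identifiers.
#' @export
stakeholder_groups <- function() {
  c("clinician", "clinician_researcher", "patient", "researcher",
    "service_provider_policy_maker")
}

# arms present in a list of scales
scale_ids <- function(scales) {
  vapply(scales, function(s) s$scale_id, character(1))
}

# lookup table: arm -> cutoff / n_points, used for vectorised validation
scale_table <- function(scales) {
  tibble::tibble(
    arm = scale_ids(scales),
    n_points = vapply(scales, function(s) s$n_points, integer(1)),
    importance_cutoff = vapply(scales, function(s) s$importance_cutoff,
                               integer(1))
  )
}
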