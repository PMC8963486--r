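#' Baseline statistics per experimental group and behavioural item
#'
#' Computes the mean and sample standard deviation of each (group, item) pair
#' over the designated baseline window, pooling all animal-day values. The
#' group SD defines the deficit thresholds of the frailty rubric; each
#' animal's own baseline mean is the reference its later decreases are
#' measured from (see [fi_decrease()]).
#'
#' @param data Long-format behavioural measurements: a data frame with columns
#'   `animal_id`, `group`, `item`, `day`, `value`. Items follow the four-item
#'   convention `BW` (body weight, g), `MS` (grip force), `WS` (fall speed,
#'   rpm), `EE` (distance at fall).
#' @param baseline_days Numeric vector of baseline measurement days
#'   (default `0:2`, the three consecutive pre-treatment days). At least two
#'   days are required.
#' @return A tibble with one row per (group, item): columns `group`, `item`,
#'   `mean`, `sd` (sample SD, `n - 1` denominator), `n_animals`.
#' @details Every animal must have a value on every baseline day; a missing
#'   value is a hard error naming the animal, item and day. A zero baseline SD
#'   leaves the rubric thresholds undefined and is also a hard error.
#' @examples
#' bl <- data.frame(
#'   animal_id = "m1", group = "control_saline", item = "BW",
#'   day = 0:2, value = c(20, 21, 22)
#' )
#' compute_baseline(bl)
#' @seealso [score_item()], [fi_table()]
#' @export
compute_baseline <- function(data, baseline_days = 0:2) {
  check_cols(data, c("animal_id", "group", "item", "day", "value"), "behavioural data")
  if (length(baseline_days) < 2) {
    abort("`baseline_days` must contain at least two days.")
  }
  if (any(!is.finite(data$value)) || any(data$value <= 0)) {
    abort("behavioural values must be finite and strictly positive.")
  }
  base <- dplyr::filter(data, .data$day %in% baseline_days)

  # every animal x item must be complete over the baseline window
  completeness <- base |>
    dplyr::distinct(.data$animal_id, .data$item) |>
    tidyr::expand_grid(day = baseline_days) |>
    dplyr::anti_join(base, by = c("animal_id", "item", "day"))
  if (nrow(completeness) > 0) {
    m <- completeness[1, ]
    abort(sprintf(
      "missing baseline value for animal '%s', item '%s', day %s (%d missing in total).",
      m$animal_id, m$item, format(m$day), nrow(completeness)
    ))
  }

  out <- base |>
    dplyr::group_by(.data$group, .data$item) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = sd(.data$value),
      n_animals = dplyr::n_distinct(.data$animal_id),
      .groups = "drop"
    )
  if (any(out$sd == 0)) {
    bad <- out[out$sd == 0, ]
    abort(sprintf(
      "baseline SD is zero for group '%s', item '%s'; rubric thresholds are undefined.",
      bad$group[1], bad$item[1]
    ))
  }
  out
}

#' Per-animal decrease from its own baseline mean
#'
#' For every post-baseline observation, returns the animal's baseline mean
#' minus the observed value, so a positive number is a decrease (worsening)
#' for all four items.
#'
#' @inheritParams compute_baseline
#' @param days Optional vector restricting which post-baseline days are
#'   returned; an unmeasured requested day is an error.
#' @return A tibble `animal_id`, `group`, `item`, `day`, `value`, `decrease`.
#' @export
fi_decrease <- function(data, baseline_days = 0:2, days = NULL) {
  check_cols(data, c("animal_id", "group", "item", "day", "value"), "behavioural data")
  own <- data |>
    dplyr::filter(.data$day %in% baseline_days) |>
    dplyr::group_by(.data$animal_id, .data$item) |>
    dplyr::summarise(baseline_mean = mean(.data$value), .groups = "drop")
  post <- dplyr::filter(data, !(.data$day %in% baseline_days))
  if (!is.null(days)) {
    missing_days <- setdiff(days, unique(post$day))
    if (length(missing_days) > 0) {
      abort(sprintf("day %s was not measured.", paste(missing_days, collapse = ", ")))
    }
    post <- dplyr::filter(post, .data$day %in% .env$days)
  }
  post |>
    dplyr::inner_join(own, by = c("animal_id", "item")) |>
    dplyr::mutate(decrease = .data$baseline_mean - .data$value) |>
    dplyr::select("animal_id", "group", "item", "day", "value", "decrease")
}

#' Score a deficit decrease against the group-SD rubric
#'
#' Maps a decrease from baseline onto the five-level item score using the
#' baseline group SD as the threshold unit: 0 for no decrease, then 0.25,
#' 0.5, 0.75 at successive half-SD bins, and 1 for a decrease of at least
#' 3/2 SD. Boundary values fall in the higher bin, matching the closed lower
#' bound of the top rule.
#'
#' @param decrease Numeric vector of decreases (baseline mean minus observed
#'   value; positive = worsening).
#' @param group_sd Baseline group SD (single positive number, or vector
#'   recycled against `decrease`).
#' @return Numeric vector of item scores in `{0, 0.25, 0.5, 0.75, 1}`.
#' @examples
#' score_item(c(-0.3, 0.3, 0.7, 1.2, 2.0), group_sd = 1)
#' @export
score_item <- function(decrease, group_sd) {
  if (any(!is.finite(decrease)) || any(!is.finite(group_sd))) {
    abort("`decrease` and `group_sd` must be finite.")
  }
  if (any(group_sd <= 0)) {
    abort("`group_sd` must be strictly positive.")
  }
  d <- decrease / group_sd
  dplyr::case_when(
    d <= 0 ~ 0,
    d < 0.5 ~ 0.25,
    d < 1 ~ 0.5,
    d < 1.5 ~ 0.75,
    TRUE ~ 1
  )
}

#' Composite frailty index from four item scores
#'
#' @param scores Numeric vector of exactly four item scores, each in
#'   `{0, 0.25, 0.5, 0.75, 1}` (order: BW, MS, WS, EE by convention).
#' @return The arithmetic mean of the four scores, a value in `[0, 1]` on the
#'   sixteenths grid.
#' @examples
#' composite_fi(c(0.25, 0.5, 0, 1))
#' @export
composite_fi <- function(scores) {
  if (length(scores) != 4) {
    abort("`scores` must contain exactly four item scores.")
  }
  if (!all(scores %in% c(0, 0.25, 0.5, 0.75, 1))) {
    abort("item scores must each be one of 0, 0.25, 0.5, 0.75, 1.")
  }
  mean(scores)
}

#' Frailty-index table for a cohort
#'
#' Scores every animal on every post-baseline day: each of the four items is
#' binned by [score_item()] against the animal's own baseline mean and its
#' group's baseline SD, and the composite index is their mean. Animal-days
#' missing any of the four items are skipped with a warning.
#'
#' @inheritParams compute_baseline
#' @param baselines Baseline statistics from [compute_baseline()]; computed
#'   from `data` when `NULL`.
#' @return A tibble with one row per scored animal-day: `animal_id`, `group`,
#'   `day`, `fi_bw`, `fi_ms`, `fi_ws`, `fi_ee`, `fi_total`.
#' @seealso [fi_group_summary()], [fi_item_shares()], [compare_groups_fi()]
#' @export
fi_table <- function(data, baselines = NULL, baseline_days = 0:2) {
  if (is.null(baselines)) baselines <- compute_baseline(data, baseline_days)
  items <- c("BW", "MS", "WS", "EE")
  missing_items <- setdiff(items, unique(data$item))
  if (length(missing_items) > 0) {
    abort(sprintf("data lacks item(s): %s", paste(missing_items, collapse = ", ")))
  }
  dec <- fi_decrease(data, baseline_days) |>
    dplyr::inner_join(
      dplyr::select(baselines, "group", "item", group_sd = "sd"),
      by = c("group", "item")
    ) |>
    dplyr::mutate(score = score_item(.data$decrease, .data$group_sd))

  wide <- dec |>
    dplyr::select("animal_id", "group", "day", "item", "score") |>
    tidyr::pivot_wider(names_from = "item", values_from = "score")
  for (it in setdiff(items, names(wide))) wide[[it]] <- NA_real_

  incomplete <- !stats::complete.cases(wide[, items])
  if (any(incomplete)) {
    skipped <- wide[incomplete, ]
    warn(sprintf(
      "skipping %d animal-day record(s) with a missing item (first: animal '%s', day %s).",
      nrow(skipped), skipped$animal_id[1], format(skipped$day[1])
    ))
    wide <- wide[!incomplete, ]
  }
  wide |>
    dplyr::transmute(
      .data$animal_id, .data$group, .data$day,
      fi_bw = .data$BW, fi_ms = .data$MS, fi_ws = .data$WS, fi_ee = .data$EE,
      fi_total = (.data$BW + .data$MS + .data$WS + .data$EE) / 4
    ) |>
    dplyr::arrange(.data$group, .data$animal_id, .data$day)
}

#' Group-level frailty-index summary (mean +/- SEM per day)
#'
#' @param fi_records Output of [fi_table()].
#' @return A tibble `group`, `day`, `mean_fi`, `sem`, `n`.
#' @export
fi_group_summary <- function(fi_records) {
  check_cols(fi_records, c("group", "day", "fi_total"), "fi_records")
  fi_records |>
    dplyr::group_by(.data$group, .data$day) |>
    dplyr::summarise(
      mean_fi = mean(.data$fi_total),
      sem = sem(.data$fi_total),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Per-item contribution shares to the group-mean frailty index
#'
#' Each item's group-mean score divided by the group-mean total score,
#' per group and day. Days where the group-mean total is zero yield `NA`
#' shares (nothing to apportion).
#'
#' @param fi_records Output of [fi_table()].
#' @return A tibble `group`, `day`, `item`, `share`; shares of a (group, day)
#'   sum to 1 where defined.
#' @export
fi_item_shares <- function(fi_records) {
  check_cols(fi_records, c("group", "day", "fi_bw", "fi_ms", "fi_ws", "fi_ee"),
             "fi_records")
  fi_records |>
    tidyr::pivot_longer(
      cols = c("fi_bw", "fi_ms", "fi_ws", "fi_ee"),
      names_to = "item", values_to = "score"
    ) |>
    dplyr::group_by(.data$group, .data$day, .data$item) |>
    dplyr::summarise(mean_score = mean(.data$score), .groups = "drop_last") |>
    dplyr::mutate(
      total = sum(.data$mean_score),
      share = dplyr::if_else(.data$total > 0, .data$mean_score / .data$total, NA_real_)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("group", "day", "item", "share")
}
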