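#' Compare frailty-index groups per timepoint
#'
#' At each post-baseline day, fits an ANOVA on the composite index and runs
#' all pairwise group comparisons with Bonferroni adjustment (pooled-SD
#' t-tests, the classical "ANOVA followed by Bonferroni" convention).
#'
#' With `design = "two_way"` the group labels are decomposed into a treatment
#' factor (`control`/`tmao`) and a challenge factor (`saline`/`lps`) parsed
#' from labels of the form `treatment_challenge`, and the per-day ANOVA
#' includes their interaction; pairwise comparisons remain between the four
#' groups.
#'
#' @param fi_records Output of [fi_table()] (needs `group`, `day`, `fi_total`).
#' @param design `"one_way"` or `"two_way"`.
#' @param alpha Significance level for flags (default 0.05, applied to the
#'   Bonferroni-adjusted p-values).
#' @return An object of class `fi_anova` with [tidy()] (pairwise table) and
#'   [glance()] (per-day ANOVA table) methods.
#' @examples
#' set.seed(1)
#' rec <- data.frame(
#'   animal_id = rep(1:12, 2), day = rep(c(4, 6), each = 12),
#'   group = rep(rep(c("a", "b", "c"), each = 4), 2),
#'   fi_total = round(runif(24, 0, 4)) / 4
#' )
#' fit <- compare_groups_fi(rec)
#' tidy(fit)
#' @export
compare_groups_fi <- function(fi_records, design = c("one_way", "two_way"),
                              alpha = 0.05) {
  design <- match.arg(design)
  check_cols(fi_records, c("group", "day", "fi_total"), "fi_records")
  groups <- unique(fi_records$group)
  if (length(groups) < 2) {
    abort("at least two groups are required for a group comparison.")
  }
  n_per <- dplyr::count(fi_records, .data$group, .data$day)
  if (any(n_per$n < 2)) {
    abort("every group needs at least two animals per timepoint.")
  }

  per_day <- split(fi_records, fi_records$day)

  anova_tbl <- purrr::map_dfr(per_day, function(d) {
    df <- data.frame(fi = d$fi_total, group = factor(d$group))
    if (design == "two_way") {
      parts <- strsplit(as.character(df$group), "_", fixed = TRUE)
      if (any(lengths(parts) != 2)) {
        abort("two_way design needs group labels of the form 'treatment_challenge'.")
      }
      df$treatment <- factor(vapply(parts, `[`, "", 1))
      df$challenge <- factor(vapply(parts, `[`, "", 2))
      fit <- aov(fi ~ treatment * challenge, data = df)
    } else {
      fit <- aov(fi ~ group, data = df)
    }
    s <- summary(fit)[[1]]
    tibble::tibble(
      day = d$day[1],
      term = trimws(rownames(s)),
      df = s$Df, sumsq = s$`Sum Sq`, meansq = s$`Mean Sq`,
      statistic = s$`F value`, p.value = s$`Pr(>F)`
    )
  })

  pairwise_tbl <- purrr::map_dfr(per_day, function(d) {
    pt <- pairwise.t.test(d$fi_total, factor(d$group),
                          p.adjust.method = "bonferroni", pool.sd = TRUE)
    pm <- pt$p.value
    raw <- pairwise.t.test(d$fi_total, factor(d$group),
                           p.adjust.method = "none", pool.sd = TRUE)$p.value
    idx <- which(!is.na(pm), arr.ind = TRUE)
    tibble::tibble(
      day = d$day[1],
      group1 = rownames(pm)[idx[, 1]],
      group2 = colnames(pm)[idx[, 2]],
      p.value = raw[idx],
      p.adjusted = pm[idx],
      significant = pm[idx] < alpha
    )
  })

  structure(
    list(anova = anova_tbl, pairwise = pairwise_tbl,
         design = design, alpha = alpha),
    class = "fi_anova"
  )
}

#' @export
print.fi_anova <- function(x, ...) {
  cat(sprintf("Frailty-index group comparison (%s ANOVA, Bonferroni pairwise, alpha = %g)\n",
              gsub("_", "-", x$design), x$alpha))
  cat(sprintf("%d timepoint(s); %d pairwise comparison(s), %d significant\n",
              length(unique(x$pairwise$day)), nrow(x$pairwise),
              sum(x$pairwise$significant)))
  invisible(x)
}

#' @rdname compare_groups_fi
#' @param x An `fi_anova` object.
#' @param ... Unused.
#' @export
tidy.fi_anova <- function(x, ...) x$pairwise

#' @rdname compare_groups_fi
#' @export
glance.fi_anova <- function(x, ...) x$anova
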