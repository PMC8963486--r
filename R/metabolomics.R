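# Targeted-metabolomics analysis: control-referenced Z-scores, class-level
# aggregation with arm comparisons, and the VIP-gated volcano screen.

#' Control-referenced Z-scores
#'
#' Expresses every observation as the number of control-group standard
#' deviations above or below the control-group mean of that metabolite,
#' including for the control samples themselves (whose scores therefore have
#' sample mean 0 and SD 1). Metabolites with zero control SD are excluded
#' with a warning.
#'
#' @param conc Long-format concentrations: a data frame with columns
#'   `sample_id`, `metabolite`, `concentration` (non-negative).
#' @param metadata Sample table with `sample_id`, `arm`.
#' @param control_arm The reference arm (default `"control_saline"`).
#' @return A tibble `sample_id`, `arm`, `metabolite`, `concentration`,
#'   `zscore`.
#' @export
zscore_vs_control <- function(conc, metadata, control_arm = "control_saline") {
  check_cols(conc, c("sample_id", "metabolite", "concentration"), "conc")
  check_cols(metadata, c("sample_id", "arm"), "metadata")
  if (any(conc$concentration < 0)) abort("concentrations must be non-negative.")
  dat <- dplyr::inner_join(conc, metadata, by = "sample_id")
  ctrl <- dplyr::filter(dat, .data$arm == control_arm)
  if (dplyr::n_distinct(ctrl$sample_id) < 2) {
    abort(sprintf("control arm '%s' needs at least two samples.", control_arm))
  }
  ref <- ctrl |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::summarise(
      ctrl_mean = mean(.data$concentration),
      ctrl_sd = sd(.data$concentration),
      .groups = "drop"
    )
  degenerate <- ref$metabolite[ref$ctrl_sd == 0]
  if (length(degenerate) > 0) {
    warn(sprintf(
      "excluding %d metabolite(s) with zero control SD: %s",
      length(degenerate), paste(head(degenerate, 3), collapse = ", ")
    ))
    ref <- ref[ref$ctrl_sd > 0, ]
  }
  dat |>
    dplyr::inner_join(ref, by = "metabolite") |>
    dplyr::mutate(zscore = (.data$concentration - .data$ctrl_mean) / .data$ctrl_sd) |>
    dplyr::select("sample_id", "arm", "metabolite", "concentration", "zscore")
}

#' Class-level aggregates with arm comparisons
#'
#' Sums (or averages) the member metabolites of each chemical class per
#' sample and compares the aggregates between arm pairs with the Wilcoxon
#' rank-sum test, starring significance at the three-tier
#' 0.05 / 0.01 / 0.005 convention.
#'
#' @inheritParams zscore_vs_control
#' @param class_map Data frame `metabolite`, `class`.
#' @param statistic `"sum"` (default) or `"mean"` across class members.
#' @param comparisons A list of length-2 character vectors of arms to
#'   compare; default: all arm pairs present in `metadata`.
#' @param alpha Significance level for the `significant` flag (first tier).
#' @return An object of class `class_summary`: list with `aggregates`
#'   (tibble `sample_id`, `arm`, `class`, `value`) and `tests` (tibble
#'   `class`, `arm1`, `arm2`, `p.value`, `stars`, `significant`).
#' @export
class_aggregate <- function(conc, class_map, metadata,
                            statistic = c("sum", "mean"),
                            comparisons = NULL, alpha = 0.05) {
  statistic <- match.arg(statistic)
  check_cols(class_map, c("metabolite", "class"), "class_map")
  check_cols(metadata, c("sample_id", "arm"), "metadata")
  unmapped <- setdiff(unique(conc$metabolite), class_map$metabolite)
  if (length(unmapped) > 0) {
    abort(sprintf("metabolite(s) without a class: %s",
                  paste(head(unmapped, 3), collapse = ", ")))
  }
  empty <- setdiff(unique(class_map$class),
                   class_map$class[class_map$metabolite %in% conc$metabolite])
  if (length(empty) > 0) {
    warn(sprintf("skipping empty class(es): %s", paste(empty, collapse = ", ")))
  }
  fun <- if (statistic == "sum") sum else mean
  agg <- conc |>
    dplyr::inner_join(class_map, by = "metabolite") |>
    dplyr::group_by(.data$sample_id, .data$class) |>
    dplyr::summarise(value = fun(.data$concentration), .groups = "drop") |>
    dplyr::inner_join(metadata, by = "sample_id") |>
    dplyr::select("sample_id", "arm", "class", "value")

  arms <- unique(agg$arm)
  if (is.null(comparisons)) {
    comparisons <- utils::combn(arms, 2, simplify = FALSE)
  }
  tests <- purrr::map_dfr(comparisons, function(pair) {
    purrr::map_dfr(sort(unique(agg$class)), function(cl) {
      x <- agg$value[agg$arm == pair[1] & agg$class == cl]
      y <- agg$value[agg$arm == pair[2] & agg$class == cl]
      tibble::tibble(class = cl, arm1 = pair[1], arm2 = pair[2],
                     p.value = wilcox_p(x, y))
    })
  })
  tests$stars <- p_stars(tests$p.value)
  tests$significant <- !is.na(tests$p.value) & tests$p.value < alpha

  structure(list(aggregates = agg, tests = tests, statistic = statistic),
            class = "class_summary")
}

#' @export
print.class_summary <- function(x, ...) {
  cat(sprintf("Class aggregates (%s over members): %d classes, %d arm comparisons, %d significant\n",
              x$statistic, dplyr::n_distinct(x$aggregates$class),
              nrow(x$tests), sum(x$tests$significant)))
  invisible(x)
}

#' @rdname class_aggregate
#' @param x A `class_summary` object.
#' @param ... Unused.
#' @export
tidy.class_summary <- function(x, ...) x$tests

# Gate the univariate test on per-arm Shapiro-Wilk normality at 0.05:
# t-test when both arms look normal, Wilcoxon rank-sum otherwise.
univariate_p <- function(x, y) {
  normal <- function(v) {
    if (length(unique(v)) < 3) return(FALSE)
    shapiro.test(v)$p.value >= 0.05
  }
  if (normal(x) && normal(y)) {
    t.test(x, y)$p.value
  } else {
    wilcox_p(x, y)
  }
}

#' PLS-DA variable importance in projection (VIP)
#'
#' Fits a two-class PLS-DA by NIPALS latent-variable extraction on
#' column-standardised concentrations against a centred class indicator, and
#' returns the VIP score of every metabolite:
#' \deqn{VIP_j = \sqrt{p \, \sum_a w_{ja}^2 \, SSY_a / \sum_a SSY_a}}
#' with \eqn{p} metabolites, component weights \eqn{w} and per-component
#' explained class variance \eqn{SSY_a}. By construction the mean squared
#' VIP equals 1, so VIP >= 1 marks an above-average contributor.
#'
#' @inheritParams zscore_vs_control
#' @param arms Character vector of the two arms defining the contrast.
#' @param n_components Number of latent components (default 2, capped at
#'   `min(n_samples - 1, n_metabolites)`).
#' @return An object of class `plsda_vip`: list with `vip` (tibble
#'   `metabolite`, `vip`), `weights`, `scores`, `ssy` (explained class
#'   variance per component), `n_components`, `arms`, `dropped`
#'   (constant metabolites removed). [tidy()] returns the VIP table,
#'   [glance()] a one-row model summary.
#' @export
pls_vip <- function(conc, metadata, arms, n_components = 2) {
  check_cols(conc, c("sample_id", "metabolite", "concentration"), "conc")
  check_cols(metadata, c("sample_id", "arm"), "metadata")
  if (length(arms) != 2) abort("`arms` must name exactly two arms.")
  meta <- dplyr::filter(metadata, .data$arm %in% arms)
  if (any(table(factor(meta$arm, levels = arms)) < 3)) {
    abort("both arms need at least three samples.")
  }
  dat <- dplyr::inner_join(conc, meta, by = "sample_id")
  X <- long_to_matrix(dat, "metabolite", "concentration")
  y_arm <- meta$arm[match(rownames(X), as.character(meta$sample_id))]
  y <- ifelse(y_arm == arms[2], 1, -1)

  constant <- apply(X, 2, function(v) sd(v) == 0)
  dropped <- colnames(X)[constant]
  if (any(constant)) {
    warn(sprintf("dropping %d constant metabolite(s): %s",
                 sum(constant), paste(head(dropped, 3), collapse = ", ")))
    X <- X[, !constant, drop = FALSE]
  }
  Xs <- scale(X)
  yc <- y - mean(y)
  p <- ncol(Xs)
  A <- min(n_components, nrow(Xs) - 1, p)

  W <- matrix(0, p, A)
  Tm <- matrix(0, nrow(Xs), A)
  ssy <- numeric(A)
  Xr <- Xs; yr <- yc
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xr, yr))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { A <- a - 1L; break }
    w <- w / nw
    t_a <- drop(Xr %*% w)
    tt <- sum(t_a^2)
    q <- sum(yr * t_a) / tt
    p_a <- drop(crossprod(Xr, t_a)) / tt
    Xr <- Xr - tcrossprod(t_a, p_a)
    yr <- yr - q * t_a
    W[, a] <- w; Tm[, a] <- t_a; ssy[a] <- q^2 * tt
  }
  if (A < 1) abort("no class separation signal; PLS-DA cannot be fitted.")
  W <- W[, seq_len(A), drop = FALSE]
  Tm <- Tm[, seq_len(A), drop = FALSE]
  ssy <- ssy[seq_len(A)]

  vip <- sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
  structure(
    list(
      vip = tibble::tibble(metabolite = colnames(Xs), vip = vip),
      weights = W, scores = Tm, ssy = ssy, ssy_total = sum(yc^2),
      n_components = A, arms = arms,
      dropped = dropped
    ),
    class = "plsda_vip"
  )
}

#' @export
print.plsda_vip <- function(x, ...) {
  cat(sprintf("PLS-DA (%d component%s) on %s vs %s: %d metabolites, %d with VIP >= 1\n",
              x$n_components, if (x$n_components > 1) "s" else "",
              x$arms[1], x$arms[2], nrow(x$vip), sum(x$vip$vip >= 1)))
  invisible(x)
}

#' @rdname pls_vip
#' @param x A `plsda_vip` object.
#' @param ... Unused.
#' @export
tidy.plsda_vip <- function(x, ...) dplyr::arrange(x$vip, dplyr::desc(.data$vip))

#' @rdname pls_vip
#' @export
glance.plsda_vip <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    n_metabolites = nrow(x$vip),
    mean_sq_vip = mean(x$vip$vip^2),
    prop_y_explained = sum(x$ssy) / x$ssy_total
  )
}

#' Volcano screen: fold change, univariate p and the VIP rule
#'
#' Per metabolite: log2 fold change of arithmetic arm means (treatment over
#' reference), a normality-gated univariate p-value (t-test when both arms
#' pass Shapiro-Wilk at 0.05, Wilcoxon rank-sum otherwise), the VIP score
#' from [pls_vip()], and the significance flag
#' `VIP >= vip_threshold AND p < alpha`.
#'
#' Metabolites whose reference-arm mean is zero have an undefined fold
#' change and are excluded with a warning; metabolites that are all-zero in
#' exactly one arm get a fold change from a half-minimum pseudo-value and
#' are marked `fc_imputed`.
#'
#' @inheritParams pls_vip
#' @param contrast Length-2 character vector `c(treatment, reference)`.
#' @param class_map Optional `metabolite`/`class` map joined onto the result.
#' @param alpha Univariate significance level (default 0.05).
#' @param vip_threshold VIP cut-off (default 1).
#' @return A tibble of class `volcano_tbl`: `metabolite` (+ `class`),
#'   `log2fc`, `p.value`, `vip`, `significant`, `fc_imputed`.
#' @export
volcano <- function(conc, metadata, contrast, class_map = NULL,
                    alpha = 0.05, vip_threshold = 1, n_components = 2) {
  if (length(contrast) != 2) {
    abort("`contrast` must be c(treatment_arm, reference_arm).")
  }
  treatment <- contrast[1]; reference <- contrast[2]
  fit <- pls_vip(conc, metadata, arms = c(reference, treatment),
                 n_components = n_components)
  dat <- dplyr::inner_join(conc, metadata, by = "sample_id") |>
    dplyr::filter(.data$arm %in% contrast, .data$metabolite %in% fit$vip$metabolite)

  half_min <- min(dat$concentration[dat$concentration > 0]) / 2

  res <- purrr::map_dfr(unique(dat$metabolite), function(mb) {
    x <- dat$concentration[dat$metabolite == mb & dat$arm == treatment]
    y <- dat$concentration[dat$metabolite == mb & dat$arm == reference]
    mx <- mean(x); my <- mean(y)
    imputed <- FALSE
    if (xor(mx == 0, my == 0)) {
      if (mx == 0) mx <- half_min else my <- half_min
      imputed <- TRUE
    }
    if (my == 0) {
      return(tibble::tibble(metabolite = mb, log2fc = NA_real_,
                            p.value = NA_real_, fc_imputed = imputed))
    }
    tibble::tibble(
      metabolite = mb,
      log2fc = log2(mx / my),
      p.value = univariate_p(x, y),
      fc_imputed = imputed
    )
  })
  undefined <- is.na(res$log2fc)
  if (any(undefined)) {
    warn(sprintf("excluding %d metabolite(s) with undefined fold change: %s",
                 sum(undefined),
                 paste(head(res$metabolite[undefined], 3), collapse = ", ")))
    res <- res[!undefined, ]
  }
  out <- res |>
    dplyr::inner_join(fit$vip, by = "metabolite") |>
    dplyr::mutate(
      significant = .data$vip >= vip_threshold & .data$p.value < alpha
    ) |>
    dplyr::select("metabolite", "log2fc", "p.value", "vip",
                  "significant", "fc_imputed")
  if (!is.null(class_map)) {
    out <- dplyr::left_join(out, class_map, by = "metabolite") |>
      dplyr::relocate("class", .after = "metabolite")
  }
  class(out) <- c("volcano_tbl", class(out))
  out
}
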