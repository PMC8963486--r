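# Genus-level count-table statistics: composition, diversity, F/B ratio,
# and the directional challenge-response ("response breadth") screen.

lineage_ranks <- c("phylum", "class", "order", "family", "genus")

# Aggregate long counts to a lineage rank; taxa lacking the rank are pooled
# into "unclassified_<parent>" bins so per-sample proportions stay closed.
aggregate_rank <- function(counts, lineage, rank) {
  if (identical(rank, "taxon")) {
    return(dplyr::rename(counts, taxon = "taxon_id"))
  }
  if (!rank %in% lineage_ranks) {
    abort(sprintf("unknown rank '%s' (use one of: taxon, %s).",
                  rank, paste(lineage_ranks, collapse = ", ")))
  }
  if (is.null(lineage)) abort("`lineage` is required for rank aggregation.")
  check_cols(lineage, c("taxon_id", lineage_ranks[seq_len(match(rank, lineage_ranks))]),
             "lineage")
  ranks_up_to <- lineage_ranks[seq_len(match(rank, lineage_ranks))]
  lin <- lineage
  # fill gaps from the nearest classified ancestor
  lin$label <- lin[[rank]]
  for (i in rev(seq_along(ranks_up_to))) {
    missing <- is.na(lin$label) | lin$label == ""
    if (!any(missing)) break
    parent <- if (i > 1) lin[[ranks_up_to[i - 1]]] else "root"
    lin$label[missing] <- paste0("unclassified_", parent[missing])
  }
  counts |>
    dplyr::inner_join(dplyr::select(lin, "taxon_id", "label"), by = "taxon_id") |>
    dplyr::group_by(.data$sample_id, taxon = .data$label) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
}

#' Relative abundances at a lineage rank
#'
#' Aggregates counts to the requested rank and divides by per-sample totals,
#' so each sample's proportions sum to one. Taxa without an assignment at the
#' rank are pooled as `unclassified_<parent>`.
#'
#' @param counts Long-format counts: a data frame with columns `sample_id`,
#'   `taxon_id`, `count` (non-negative integers).
#' @param lineage Per-taxon lineage table with columns `taxon_id`, `phylum`,
#'   `class`, `order`, `family`, `genus`. Not needed for `rank = "taxon"`.
#' @param rank One of `"taxon"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @return A tibble `sample_id`, `taxon`, `count`, `proportion`.
#' @export
relative_abundance <- function(counts, lineage = NULL, rank = "genus") {
  check_cols(counts, c("sample_id", "taxon_id", "count"), "counts")
  if (any(counts$count < 0)) abort("counts must be non-negative.")
  agg <- aggregate_rank(counts, lineage, rank)
  totals <- agg |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  if (any(totals$total <= 0)) {
    abort(sprintf("sample '%s' has zero total count.",
                  totals$sample_id[totals$total <= 0][1]))
  }
  agg |>
    dplyr::left_join(totals, by = "sample_id") |>
    dplyr::mutate(proportion = .data$count / .data$total) |>
    dplyr::select("sample_id", "taxon", "count", "proportion")
}

#' Shannon diversity per sample
#'
#' The Shannon index \eqn{H = -\sum_i p_i \ln p_i} (natural log) over taxa
#' with non-zero proportion in the sample.
#'
#' @inheritParams relative_abundance
#' @return A tibble `sample_id`, `shannon`.
#' @export
shannon_index <- function(counts) {
  check_cols(counts, c("sample_id", "taxon_id", "count"), "counts")
  relative_abundance(counts, rank = "taxon") |>
    dplyr::filter(.data$proportion > 0) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      shannon = -sum(.data$proportion * log(.data$proportion)),
      .groups = "drop"
    )
}

#' Firmicutes/Bacteroidetes ratio per sample
#'
#' Ratio of the Firmicutes to the Bacteroidetes relative abundance in each
#' sample, a widely used gut-dysbiosis marker. Samples with zero
#' Bacteroidetes have an undefined ratio and are dropped with a warning.
#'
#' @inheritParams relative_abundance
#' @param metadata Optional sample table (`sample_id`, `arm`, ...) joined
#'   onto the result.
#' @return A tibble `sample_id`, `fb_ratio` (plus metadata columns when
#'   supplied).
#' @seealso [fb_ratio_test()]
#' @export
fb_ratio <- function(counts, lineage, metadata = NULL) {
  phyla <- relative_abundance(counts, lineage, rank = "phylum") |>
    dplyr::filter(.data$taxon %in% c("Firmicutes", "Bacteroidetes")) |>
    tidyr::pivot_wider(
      id_cols = "sample_id", names_from = "taxon",
      values_from = "proportion", values_fill = 0
    )
  for (ph in c("Firmicutes", "Bacteroidetes")) {
    if (!ph %in% names(phyla)) phyla[[ph]] <- 0
  }
  undefined <- phyla$Bacteroidetes == 0
  if (any(undefined)) {
    warn(sprintf(
      "dropping %d sample(s) with zero Bacteroidetes (F/B ratio undefined): %s",
      sum(undefined), paste(head(phyla$sample_id[undefined], 3), collapse = ", ")
    ))
    phyla <- phyla[!undefined, ]
  }
  out <- phyla |>
    dplyr::transmute(
      .data$sample_id,
      fb_ratio = .data$Firmicutes / .data$Bacteroidetes
    )
  if (!is.null(metadata)) {
    out <- dplyr::left_join(out, metadata, by = "sample_id")
  }
  out
}

#' Compare the F/B ratio between two arms
#'
#' Wilcoxon rank-sum comparison of per-sample Firmicutes/Bacteroidetes
#' ratios between two arms, with group medians.
#'
#' @inheritParams fb_ratio
#' @param metadata Sample table with `sample_id` and `arm`.
#' @param arms Character vector of the two arms to compare.
#' @param timepoint Optional timepoint filter (needs a `timepoint` column in
#'   `metadata`).
#' @return A one-row tibble `arm1`, `arm2`, `median1`, `median2`, `n1`, `n2`,
#'   `p.value`.
#' @export
fb_ratio_test <- function(counts, lineage, metadata, arms, timepoint = NULL) {
  check_cols(metadata, c("sample_id", "arm"), "metadata")
  if (length(arms) != 2) abort("`arms` must name exactly two arms.")
  fb <- fb_ratio(counts, lineage, metadata)
  if (!is.null(timepoint)) {
    check_cols(fb, "timepoint", "metadata")
    fb <- dplyr::filter(fb, .data$timepoint == .env$timepoint)
  }
  x <- fb$fb_ratio[fb$arm == arms[1]]
  y <- fb$fb_ratio[fb$arm == arms[2]]
  if (length(x) == 0 || length(y) == 0) {
    abort("both arms need at least one sample with a defined F/B ratio.")
  }
  tibble::tibble(
    arm1 = arms[1], arm2 = arms[2],
    median1 = median(x), median2 = median(y),
    n1 = length(x), n2 = length(y),
    p.value = wilcox_p(x, y)
  )
}

#' Bray-Curtis dissimilarity between samples
#'
#' Computed on per-sample relative abundances (so sequencing depth cancels),
#' via [vegan::vegdist()].
#'
#' @inheritParams relative_abundance
#' @return A `dist` object labelled by `sample_id`.
#' @export
bray_curtis <- function(counts) {
  check_cols(counts, c("sample_id", "taxon_id", "count"), "counts")
  rel <- relative_abundance(counts, rank = "taxon")
  m <- long_to_matrix(rel, "taxon", "proportion")
  if (nrow(m) < 2) abort("at least two samples are required.")
  vegan::vegdist(m, method = "bray")
}

#' Principal co-ordinate analysis (classical scaling)
#'
#' Classical metric scaling of a dissimilarity matrix: double-centering of
#' the squared dissimilarities followed by eigendecomposition. Coordinates
#' are returned for axes with positive eigenvalues; negative eigenvalues
#' (possible for non-Euclidean dissimilarities such as Bray-Curtis) are
#' reported, not dropped.
#'
#' @param d A `dist` object or square symmetric dissimilarity matrix.
#' @param k Number of axes to return (default: all positive-eigenvalue axes).
#' @return An object of class `frailty_pcoa`: a list with `coordinates`
#'   (tibble `sample_id`, `axis1`, `axis2`, ...), `eigenvalues` (all of them,
#'   descending), and `prop_explained` (relative to the sum of positive
#'   eigenvalues).
#' @export
pcoa <- function(d, k = NULL) {
  if (is.matrix(d)) {
    if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8)) {
      abort("`d` must be a symmetric square matrix or a dist object.")
    }
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  # cmdscale warns when fewer than k eigenvalues are positive; expected for
  # non-Euclidean dissimilarities, and we report the full spectrum anyway
  fit <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE))
  pos <- sum(fit$eig > sqrt(.Machine$double.eps))
  if (is.null(k)) k <- pos else k <- min(k, pos)
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("axis", seq_len(k))
  structure(
    list(
      coordinates = dplyr::bind_cols(
        tibble::tibble(sample_id = labels(d) %||% as.character(seq_len(n))),
        tibble::as_tibble(coords)
      ),
      eigenvalues = fit$eig,
      prop_explained = fit$eig[seq_len(k)] / sum(fit$eig[fit$eig > 0])
    ),
    class = "frailty_pcoa"
  )
}

#' @export
print.frailty_pcoa <- function(x, ...) {
  cat(sprintf("PCoA of %d samples: %d positive axes", nrow(x$coordinates),
              sum(x$eigenvalues > 0)))
  if (length(x$prop_explained) >= 2) {
    cat(sprintf(" (axis1 %.1f%%, axis2 %.1f%%)",
                100 * x$prop_explained[1], 100 * x$prop_explained[2]))
  }
  cat("\n")
  invisible(x)
}

#' Directional challenge-response screen within one arm
#'
#' For one arm, tests every taxon at the chosen rank for a pre- vs
#' post-challenge shift in relative abundance (Wilcoxon rank-sum; exact when
#' tie-free, tie-corrected normal approximation otherwise) and counts how
#' many taxa moved in each direction. The breadth of this response is the
#' study's proxy for how actively the community reacts to the stressor.
#'
#' Directions follow the sign of the median difference (mean difference as a
#' tie-break). P-values are reported raw by default, mirroring per-figure
#' annotation practice; set `p_adjust = "BH"` for a
#' Benjamini-Hochberg-corrected screen.
#'
#' @inheritParams relative_abundance
#' @param metadata Sample table with `sample_id`, `arm`, `timepoint`
#'   (`pre_challenge` / `post_challenge`).
#' @param arm The arm to screen.
#' @param alpha Per-taxon significance level (default 0.05).
#' @param p_adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @return An object of class `response_breadth`: list with `per_taxon`
#'   (tibble `taxon`, `p.value`, `p.used`, `effect`, `direction`, `flagged`),
#'   counts `n_increased` / `n_decreased`, and `arm`. [tidy()] returns the
#'   per-taxon table.
#' @seealso [response_ratio()]
#' @export
challenge_response <- function(counts, lineage = NULL, metadata, arm,
                               rank = "genus", alpha = 0.05,
                               p_adjust = "none") {
  check_cols(metadata, c("sample_id", "arm", "timepoint"), "metadata")
  meta <- dplyr::filter(metadata, .data$arm == .env$arm)
  pre_ids <- meta$sample_id[meta$timepoint == "pre_challenge"]
  post_ids <- meta$sample_id[meta$timepoint == "post_challenge"]
  if (length(pre_ids) < 3 || length(post_ids) < 3) {
    abort(sprintf("arm '%s' needs at least 3 pre- and 3 post-challenge samples.", arm))
  }
  rel <- relative_abundance(
    dplyr::filter(counts, .data$sample_id %in% c(pre_ids, post_ids)),
    lineage, rank
  )
  m <- long_to_matrix(rel, "taxon", "proportion")
  pre <- m[as.character(pre_ids), , drop = FALSE]
  post <- m[as.character(post_ids), , drop = FALSE]

  keep <- colSums(pre) + colSums(post) > 0
  pre <- pre[, keep, drop = FALSE]
  post <- post[, keep, drop = FALSE]

  res <- purrr::map_dfr(colnames(pre), function(tx) {
    x <- pre[, tx]; y <- post[, tx]
    eff <- median(y) - median(x)
    if (eff == 0) eff <- mean(y) - mean(x)
    tibble::tibble(taxon = tx, p.value = wilcox_p(x, y), effect = eff)
  })
  res$p.used <- p.adjust(res$p.value, method = p_adjust)
  res$direction <- dplyr::case_when(
    res$effect > 0 ~ "increased",
    res$effect < 0 ~ "decreased",
    TRUE ~ "none"
  )
  res$flagged <- !is.na(res$p.used) & res$p.used < alpha & res$direction != "none"

  structure(
    list(
      per_taxon = dplyr::select(res, "taxon", "p.value", "p.used",
                                "effect", "direction", "flagged"),
      n_increased = sum(res$flagged & res$direction == "increased"),
      n_decreased = sum(res$flagged & res$direction == "decreased"),
      n_tested = nrow(res),
      arm = arm, alpha = alpha, p_adjust = p_adjust
    ),
    class = "response_breadth"
  )
}

#' @export
print.response_breadth <- function(x, ...) {
  cat(sprintf(
    "Challenge response in arm '%s': %d taxa increased, %d decreased (of %d tested, alpha = %g%s)\n",
    x$arm, x$n_increased, x$n_decreased, x$n_tested, x$alpha,
    if (x$p_adjust != "none") paste0(", ", x$p_adjust, "-adjusted") else ""
  ))
  invisible(x)
}

#' @rdname challenge_response
#' @param x A `response_breadth` object.
#' @param ... Unused.
#' @export
tidy.response_breadth <- function(x, ...) x$per_taxon

#' Response-breadth ratio between two arms
#'
#' The "effective diversity" contrast: total responsive-taxon count of one
#' arm divided by that of another.
#'
#' @param a,b `response_breadth` objects from [challenge_response()].
#' @return A one-row tibble `arm1`, `arm2`, `breadth1`, `breadth2`, `ratio`.
#' @export
response_ratio <- function(a, b) {
  stopifnot(inherits(a, "response_breadth"), inherits(b, "response_breadth"))
  b1 <- a$n_increased + a$n_decreased
  b2 <- b$n_increased + b$n_decreased
  tibble::tibble(
    arm1 = a$arm, arm2 = b$arm,
    breadth1 = b1, breadth2 = b2,
    ratio = if (b2 > 0) b1 / b2 else NA_real_
  )
}
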