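# Internal helpers shared across modules.

# Column presence check with a readable error.
check_cols <- function(data, cols, what) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s must contain column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

# Two-sample Wilcoxon rank-sum p-value.
#
# Exact distribution when the pooled sample is tie-free; otherwise the
# tie-corrected normal approximation without continuity correction. The
# continuity-corrected approximation is markedly conservative at n = 8 per
# side (two-sided size ~0.038 instead of 0.05), which would distort the
# null calibration of per-taxon and per-metabolite screens.
wilcox_p <- function(x, y) {
  if (all(is.na(x)) || all(is.na(y))) return(NA_real_)
  suppressWarnings(
    wilcox.test(x, y, exact = TRUE, correct = FALSE)$p.value
  )
}

# Three-tier significance stars: 0.05 / 0.01 / 0.005.
p_stars <- function(p, tiers = c(0.05, 0.01, 0.005)) {
  vapply(p, function(pp) {
    if (is.na(pp)) return("")
    if (pp < tiers[3]) "***" else if (pp < tiers[2]) "**" else if (pp < tiers[1]) "*" else ""
  }, character(1))
}

# Standard error of the mean.
sem <- function(x) sd(x) / sqrt(length(x))

# Draw one Dirichlet vector by gamma normalisation.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s <= 0) {
    # pathologically tiny shapes can underflow; fall back to point mass on max
    g[which.max(alpha)] <- 1
    s <- sum(g)
  }
  g / s
}

# Long (sample_id, <key>, <value>) -> samples x key numeric matrix.
long_to_matrix <- function(data, key, value) {
  wide <- tidyr::pivot_wider(
    data,
    id_cols = "sample_id", names_from = dplyr::all_of(key),
    values_from = dplyr::all_of(value), values_fill = 0
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  m
}
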