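# End-to-end orchestration: frailty scoring -> microbiome statistics ->
# metabolite screen, from simulated or file inputs, with TSV + JSON output.

#' Run the full analysis pipeline
#'
#' Executes the three analysis stages in order — frailty-index scoring with
#' group comparisons, microbiome composition / diversity / F/B /
#' challenge-response statistics, and the metabolite class and volcano
#' screens — on either simulated data (default) or the three file-backed
#' input tables, writing per-stage TSVs plus a machine-readable
#' `summary.json` into `out_dir`. Re-running with the same config and seed
#' into a clean directory reproduces the outputs exactly.
#'
#' @param config A named list, or the path to a YAML file holding one.
#'   Recognised fields (all optional): `seed` (default 1), `out_dir`
#'   (default `"frailtykit_run"`), `alpha` (default 0.05), `n_per_group`
#'   (default 8), `simulate` (default `TRUE`), and, when `simulate` is
#'   `FALSE`, the input paths `behavior`, `counts`, `lineage`,
#'   `micro_metadata`, `concentrations`, `classes`, `metab_metadata`.
#'   `baseline_days` (default `0:2`) and `contrast` (default
#'   `c("tmao_saline", "control_saline")`) tune the stages.
#' @return Invisibly, the run report: a list with the per-stage result
#'   objects and the paths written.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(
    list(
      seed = 1L, out_dir = "frailtykit_run", alpha = 0.05,
      n_per_group = 8, simulate = TRUE, baseline_days = 0:2,
      contrast = c("tmao_saline", "control_saline")
    ),
    config
  )
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(stage, fmt, ...) {
    inform(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }

  if (isTRUE(cfg$simulate)) {
    design <- synthetic_design(n_per_group = cfg$n_per_group, seed = cfg$seed)
    log_msg("simulate", "generating synthetic cohort (seed %d)", design$seed)
    behavior <- gen_behavior(design)
    micro <- gen_microbiome(design)
    metab <- gen_metabolites(design)
  } else {
    for (f in c("behavior", "counts", "lineage", "micro_metadata",
                "concentrations", "classes", "metab_metadata")) {
      if (is.null(cfg[[f]])) abort(sprintf("config field '%s' is required when simulate is FALSE.", f))
    }
    log_msg("input", "reading input tables")
    behavior <- read_behavior(cfg$behavior)
    micro <- read_abundance(cfg$counts, cfg$lineage, cfg$micro_metadata)
    metab <- read_metabolites(cfg$concentrations, cfg$classes, cfg$metab_metadata)
    metab <- list(concentrations = metab$concentrations,
                  class_map = metab$class_map, metadata = metab$metadata)
  }

  # --- frailty stage -------------------------------------------------------
  log_msg("fi", "scoring frailty index")
  baselines <- compute_baseline(behavior, cfg$baseline_days)
  records <- fi_table(behavior, baselines, cfg$baseline_days)
  fi_summary <- fi_group_summary(records)
  fi_tests <- compare_groups_fi(records, alpha = cfg$alpha)

  # --- microbiome stage ----------------------------------------------------
  log_msg("micro", "computing composition, diversity and response breadth")
  shannon <- shannon_index(micro$counts)
  fb <- fb_ratio(micro$counts, micro$lineage, micro$metadata)
  micro_arms <- unique(micro$metadata$arm)
  fb_test <- if (length(micro_arms) >= 2) {
    fb_ratio_test(micro$counts, micro$lineage, micro$metadata,
                  arms = micro_arms[1:2], timepoint = "pre_challenge")
  } else NULL
  ord <- pcoa(bray_curtis(micro$counts), k = 2)
  breadth <- lapply(micro_arms, function(a) {
    challenge_response(micro$counts, micro$lineage, micro$metadata,
                       arm = a, alpha = cfg$alpha)
  })
  names(breadth) <- micro_arms

  # --- metabolite stage ----------------------------------------------------
  log_msg("metab", "running Z-scores, class aggregates and volcano screen")
  zs <- zscore_vs_control(metab$concentrations, metab$metadata)
  classes <- class_aggregate(metab$concentrations, metab$class_map,
                             metab$metadata, alpha = cfg$alpha)
  vol <- volcano(metab$concentrations, metab$metadata,
                 contrast = cfg$contrast, class_map = metab$class_map,
                 alpha = cfg$alpha)

  # --- outputs -------------------------------------------------------------
  paths <- list(
    fi_records = file.path(cfg$out_dir, "fi_records.tsv"),
    fi_summary = file.path(cfg$out_dir, "fi_group_summary.tsv"),
    fi_pairwise = file.path(cfg$out_dir, "fi_pairwise_tests.tsv"),
    shannon = file.path(cfg$out_dir, "shannon.tsv"),
    fb = file.path(cfg$out_dir, "fb_ratio.tsv"),
    ordination = file.path(cfg$out_dir, "pcoa_coordinates.tsv"),
    breadth = file.path(cfg$out_dir, "response_breadth.tsv"),
    zscores = file.path(cfg$out_dir, "zscores.tsv"),
    class_tests = file.path(cfg$out_dir, "class_tests.tsv"),
    volcano = file.path(cfg$out_dir, "volcano.tsv"),
    summary = file.path(cfg$out_dir, "summary.json")
  )
  readr::write_tsv(records, paths$fi_records)
  readr::write_tsv(fi_summary, paths$fi_summary)
  readr::write_tsv(tidy(fi_tests), paths$fi_pairwise)
  readr::write_tsv(shannon, paths$shannon)
  readr::write_tsv(fb, paths$fb)
  readr::write_tsv(ord$coordinates, paths$ordination)
  readr::write_tsv(
    purrr::map_dfr(breadth, function(b) dplyr::mutate(tidy(b), arm = b$arm)),
    paths$breadth
  )
  readr::write_tsv(zs, paths$zscores)
  readr::write_tsv(tidy(classes), paths$class_tests)
  readr::write_tsv(tibble::as_tibble(vol), paths$volcano)

  summary_list <- list(
    seed = cfg$seed,
    alpha = cfg$alpha,
    fi = list(
      n_records = nrow(records),
      groups = sort(unique(records$group)),
      significant_pairs = sum(tidy(fi_tests)$significant)
    ),
    microbiome = list(
      mean_shannon = mean(shannon$shannon),
      fb_test = if (!is.null(fb_test)) as.list(fb_test) else NULL,
      response_breadth = lapply(breadth, function(b) {
        list(arm = b$arm, n_increased = b$n_increased,
             n_decreased = b$n_decreased, n_tested = b$n_tested)
      }),
      pcoa_prop_explained = ord$prop_explained
    ),
    metabolites = list(
      contrast = cfg$contrast,
      n_significant_volcano = sum(vol$significant),
      significant_class_tests = sum(tidy(classes)$significant)
    )
  )
  jsonlite::write_json(summary_list, paths$summary, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  log_msg("done", "outputs written to %s", cfg$out_dir)

  invisible(list(
    baselines = baselines, fi_records = records, fi_summary = fi_summary,
    fi_tests = fi_tests, shannon = shannon, fb = fb, fb_test = fb_test,
    ordination = ord, breadth = breadth, zscores = zs, classes = classes,
    volcano = vol, paths = paths
  ))
}
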