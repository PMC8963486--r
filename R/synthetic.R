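# Synthetic cohorts with planted ground truth for all three data streams:
# behavioural trajectories, Dirichlet-multinomial genus counts, and
# lognormal targeted-metabolite panels.

behavior_defaults <- function() {
  list(
    # per-item baseline mean and per-observation Gaussian SD; the SD doubles
    # as the baseline group SD that defines the rubric thresholds
    items = list(
      BW = c(mean = 25, sd = 0.8),    # body weight, g
      MS = c(mean = 150, sd = 12),    # grip force, arbitrary units
      WS = c(mean = 30, sd = 3),      # fall speed, rpm
      EE = c(mean = 250, sd = 25)     # distance at fall, arbitrary units
    ),
    baseline_days = 0:2,
    model_days = seq(4, 28, by = 2),
    post_days = c(29, 30, 31),        # 24 / 48 / 72 h after challenge
    challenge_day = 28,
    drift_sd = 0.4,                   # TMAO-arm decline by day 28, in SD units
    drop_sd = list(                   # post-challenge drop at 24/48/72 h, SD units
      control_saline = c(0, 0, 0),
      tmao_saline = c(0, 0, 0),
      control_lps = c(0.5, 0.3, 0.1),
      tmao_lps = c(1.6, 1.6, 1.6)
    )
  )
}

microbiome_defaults <- function() {
  list(
    n_genera = 120,
    logseries_x = 0.999,     # log-series weights x^r / r over abundance ranks
    concentration = 50,      # Dirichlet precision (sum of alphas)
    depth = 50000,           # sequencing depth per sample
    fb_fold = 2,             # Bacteroidetes alpha multiplier in the TMAO arm
    fold = 4,                # responder fold (up = x fold, down = / fold)
    responders = list(
      control = c(up = 41, down = 22),
      tmao = c(up = 15, down = 10)
    )
  )
}

metabolite_defaults <- function() {
  list(
    classes = c("imidazoles", "carnitines", "SCFAs", "fatty_acids",
                "benzoic_acids", "peptides", "phenylpropanoids"),
    per_class = 9,
    sdlog = 0.25,            # lognormal noise (CV ~ 25%)
    effects = NULL           # NULL -> default_metabolite_effects()
  )
}

#' Default planted class-by-arm fold-change matrix for metabolite panels
#'
#' Encodes the planted pattern: imidazoles and carnitines elevated in both
#' TMAO arms; SCFAs, fatty acids and benzoic acids depressed in both
#' LPS-challenged arms; peptides depressed only under TMAO + LPS; and
#' phenylpropanoids elevated only under control + LPS. Folds are
#' multiplicative on the lognormal median; unlisted combinations are 1.
#'
#' @return A tibble `class`, `arm`, `fold`.
#' @export
default_metabolite_effects <- function() {
  tibble::tribble(
    ~class, ~arm, ~fold,
    "imidazoles", "tmao_saline", 2.5,
    "imidazoles", "tmao_lps", 2.5,
    "carnitines", "tmao_saline", 2.0,
    "carnitines", "tmao_lps", 2.0,
    "SCFAs", "control_lps", 0.5,
    "SCFAs", "tmao_lps", 0.5,
    "fatty_acids", "control_lps", 0.5,
    "fatty_acids", "tmao_lps", 0.5,
    "benzoic_acids", "control_lps", 0.5,
    "benzoic_acids", "tmao_lps", 0.5,
    "peptides", "tmao_lps", 0.5,
    "phenylpropanoids", "control_lps", 2.0
  )
}

#' Construct a validated synthetic-study design
#'
#' Collects the tunable parameters of the three generators. Per-block lists
#' override the defaults element-wise; anything unspecified keeps its
#' default. The defaults emulate the study conditions: four arms of 8
#' animals, a sub-threshold TMAO drift with an acute sustained post-LPS
#' decline in the TMAO arm, a doubled Bacteroidetes share under TMAO with
#' 41 up / 22 down challenge-responsive genera in the control arm versus
#' 15 up / 10 down under TMAO, and the class-level metabolite pattern of
#' [default_metabolite_effects()].
#'
#' @param n_per_group Animals (or samples) per arm and timepoint (default 8).
#' @param seed Integer seed; identical design + seed gives identical outputs.
#' @param behavior,microbiome,metabolites Named lists of overrides for the
#'   respective generator blocks.
#' @return A validated list of class `synthetic_design`.
#' @seealso [gen_behavior()], [gen_microbiome()], [gen_metabolites()]
#' @export
synthetic_design <- function(n_per_group = 8, seed = 1,
                             behavior = list(), microbiome = list(),
                             metabolites = list()) {
  d <- list(
    n_per_group = n_per_group,
    seed = as.integer(seed),
    behavior = utils::modifyList(behavior_defaults(), behavior),
    microbiome = utils::modifyList(microbiome_defaults(), microbiome),
    metabolites = utils::modifyList(metabolite_defaults(), metabolites)
  )
  if (d$n_per_group < 1) abort("`n_per_group` must be positive.")
  mb <- d$microbiome
  if (mb$concentration <= 0 || mb$depth < 1 || mb$fold <= 0 || mb$fb_fold <= 0) {
    abort("microbiome concentration, depth and folds must be positive.")
  }
  for (arm in names(mb$responders)) {
    if (sum(mb$responders[[arm]]) > mb$n_genera) {
      abort(sprintf("responder set for arm '%s' exceeds the genus panel size.", arm))
    }
  }
  eff <- d$metabolites$effects %||% default_metabolite_effects()
  bad <- setdiff(unique(eff$class), d$metabolites$classes)
  if (length(bad) > 0) {
    abort(sprintf("effect matrix names unknown class(es): %s",
                  paste(bad, collapse = ", ")))
  }
  if (any(eff$fold <= 0)) abort("effect folds must be positive.")
  d$metabolites$effects <- eff
  structure(d, class = "synthetic_design")
}

#' Null variant of the synthetic design
#'
#' All planted effects removed (no drift, no post-challenge drops, no
#' Bacteroidetes expansion, zero responders, unit metabolite folds); used
#' for type-I-error calibration.
#'
#' @inheritParams synthetic_design
#' @export
synthetic_design_null <- function(n_per_group = 8, seed = 1) {
  synthetic_design(
    n_per_group = n_per_group, seed = seed,
    behavior = list(
      drift_sd = 0,
      drop_sd = list(control_saline = c(0, 0, 0), tmao_saline = c(0, 0, 0),
                     control_lps = c(0, 0, 0), tmao_lps = c(0, 0, 0))
    ),
    microbiome = list(
      fb_fold = 1,
      responders = list(control = c(up = 0, down = 0), tmao = c(up = 0, down = 0))
    ),
    metabolites = list(effects = default_metabolite_effects()[0, ])
  )
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat(sprintf(
    "Synthetic study design: %d per group, seed %d\n  behaviour: drift %.2f SD, LPS drops %s / %s SD\n  microbiome: %d genera, concentration %g, responders control %d up/%d down, tmao %d up/%d down\n  metabolites: %d classes x %d, %d planted class effects\n",
    x$n_per_group, x$seed, x$behavior$drift_sd,
    paste(x$behavior$drop_sd$control_lps, collapse = "/"),
    paste(x$behavior$drop_sd$tmao_lps, collapse = "/"),
    x$microbiome$n_genera, x$microbiome$concentration,
    x$microbiome$responders$control["up"], x$microbiome$responders$control["down"],
    x$microbiome$responders$tmao["up"], x$microbiome$responders$tmao["down"],
    length(x$metabolites$classes), x$metabolites$per_class,
    nrow(x$metabolites$effects)
  ))
  invisible(x)
}

arms4 <- c("control_saline", "tmao_saline", "control_lps", "tmao_lps")

#' Generate a synthetic behavioural cohort
#'
#' Four arms of `n_per_group` animals measured on all four items over three
#' baseline days, every second day through the four-week model, and 24/48/72
#' h after the challenge. Observations are the item mean minus the planted
#' deterioration (linear TMAO drift plus arm-specific post-challenge drop,
#' both in units of the item SD) plus Gaussian noise with that same SD.
#'
#' @param design A [synthetic_design()].
#' @return A long tibble `animal_id`, `group`, `item`, `day`, `value` with
#'   attribute `challenge_day`.
#' @export
gen_behavior <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  b <- design$behavior
  days <- c(b$baseline_days, b$model_days, b$post_days)
  withr::with_seed(design$seed + 101L, {
    grid <- tidyr::expand_grid(
      group = arms4,
      animal = seq_len(design$n_per_group),
      item = names(b$items),
      day = days
    )
    item_mean <- vapply(b$items, `[[`, 0, "mean")[grid$item]
    item_sd <- vapply(b$items, `[[`, 0, "sd")[grid$item]
    ramp_from <- max(b$baseline_days)
    drift <- ifelse(
      grepl("^tmao", grid$group) & grid$day > ramp_from,
      b$drift_sd * (pmin(grid$day, b$challenge_day) - ramp_from) /
        (b$challenge_day - ramp_from),
      0
    )
    post_idx <- match(grid$day, b$post_days)
    drop <- ifelse(
      is.na(post_idx), 0,
      mapply(function(g, i) b$drop_sd[[g]][i], grid$group, post_idx)
    )
    value <- item_mean - (drift + drop) * item_sd +
      rnorm(nrow(grid), 0, item_sd)
    out <- tibble::tibble(
      animal_id = sprintf("%s_%02d", grid$group, grid$animal),
      group = grid$group,
      item = grid$item,
      day = grid$day,
      value = pmax(value, item_mean * 1e-3)  # keep strictly positive
    )
  })
  attr(out, "challenge_day") <- b$challenge_day
  out
}

# Deterministic genus panel: abundance ranks get log-series weights and a
# fixed interleaved phylum assignment.
genus_panel <- function(mb) {
  G <- mb$n_genera
  r <- seq_len(G)
  w <- mb$logseries_x^r / r
  p <- w / sum(w)
  # fixed interleaved phylum assignment over abundance ranks
  # (11 Firmicutes, 5 Bacteroidetes, 4 Proteobacteria, 2 Actinobacteria,
  #  2 Verrucomicrobia per cycle of 24, Bacteroidetes spread high and low
  #  so the baseline F/B ratio lands near 3)
  pattern <- c(
    "Firmicutes", "Bacteroidetes", "Firmicutes", "Firmicutes",
    "Proteobacteria", "Firmicutes", "Bacteroidetes", "Firmicutes",
    "Firmicutes", "Proteobacteria", "Firmicutes", "Bacteroidetes",
    "Firmicutes", "Firmicutes", "Proteobacteria", "Firmicutes",
    "Bacteroidetes", "Actinobacteria", "Firmicutes", "Proteobacteria",
    "Verrucomicrobia", "Bacteroidetes", "Actinobacteria", "Verrucomicrobia"
  )
  tibble::tibble(
    taxon_id = sprintf("g%03d", r),
    rank = r,
    base_alpha = mb$concentration * p,
    phylum = rep_len(pattern, G)
  )
}

#' Generate a synthetic genus-level abundance table
#'
#' Counts are Dirichlet-multinomial: each sample draws its composition from
#' a Dirichlet whose parameters are log-series base weights scaled to the
#' design's concentration, then draws `depth` reads multinomially. The TMAO
#' arm's Bacteroidetes parameters are multiplied by `fb_fold` at both
#' timepoints (the planted F/B shift); post-challenge samples of each arm
#' multiply the planted responder genera's parameters by `fold` (up) or
#' `1/fold` (down). Decliners occupy the most abundant ranks and expanders
#' the mid-abundance ranks, so the planted sets are detectable at the
#' design's noise level; post-challenge samples are independent draws, not
#' paired trajectories.
#'
#' @param design A [synthetic_design()].
#' @return A list with `counts` (long tibble `sample_id`, `taxon_id`,
#'   `count`), `lineage` (`taxon_id`, `phylum`, `class`, `order`, `family`,
#'   `genus`), `metadata` (`sample_id`, `arm`, `timepoint`), and `truth`
#'   (planted responder taxa per arm and direction).
#' @export
gen_microbiome <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  mb <- design$microbiome
  panel <- genus_panel(mb)
  G <- nrow(panel)

  # responder placement: down = most abundant ranks, up = next ranks
  resp_sets <- lapply(mb$responders, function(rs) {
    down <- panel$taxon_id[seq_len(rs["down"])]
    up <- panel$taxon_id[rs["down"] + seq_len(rs["up"])]
    list(up = up, down = down)
  })

  n <- design$n_per_group
  meta <- tidyr::expand_grid(
    arm = names(mb$responders),
    timepoint = c("pre_challenge", "post_challenge"),
    rep = seq_len(n)
  ) |>
    dplyr::mutate(sample_id = sprintf("%s_%s_%02d", .data$arm,
                                      ifelse(.data$timepoint == "pre_challenge", "pre", "post"),
                                      .data$rep)) |>
    dplyr::select("sample_id", "arm", "timepoint")

  withr::with_seed(design$seed + 202L, {
    counts <- purrr::map_dfr(seq_len(nrow(meta)), function(i) {
      alpha <- panel$base_alpha
      if (meta$arm[i] == "tmao") {
        alpha <- alpha * ifelse(panel$phylum == "Bacteroidetes", mb$fb_fold, 1)
      }
      if (meta$timepoint[i] == "post_challenge") {
        rs <- resp_sets[[meta$arm[i]]]
        alpha <- alpha *
          ifelse(panel$taxon_id %in% rs$up, mb$fold,
                 ifelse(panel$taxon_id %in% rs$down, 1 / mb$fold, 1))
      }
      x <- rmultinom(1, mb$depth, rdirichlet1(alpha))[, 1]
      tibble::tibble(sample_id = meta$sample_id[i],
                     taxon_id = panel$taxon_id, count = x)
    })
  })

  lineage <- panel |>
    dplyr::transmute(
      .data$taxon_id,
      phylum = .data$phylum,
      class = paste0(.data$phylum, "_c1"),
      order = paste0(.data$phylum, "_o1"),
      family = paste0(.data$phylum, "_f", 1 + .data$rank %% 3),
      genus = paste0("genus_", sub("^g", "", .data$taxon_id))
    )

  list(counts = counts, lineage = lineage, metadata = meta, truth = resp_sets)
}

#' Generate a synthetic targeted-metabolite table
#'
#' Lognormal concentrations for four arms of `n_per_group` samples: each
#' metabolite has a fixed baseline median (log-spaced across the panel) and
#' multiplicative class-by-arm fold effects from the design's effect matrix,
#' with lognormal noise of the design's `sdlog`.
#'
#' @param design A [synthetic_design()].
#' @return A list with `concentrations` (long tibble `sample_id`,
#'   `metabolite`, `concentration`), `class_map` (`metabolite`, `class`) and
#'   `metadata` (`sample_id`, `arm`).
#' @export
gen_metabolites <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  mt <- design$metabolites
  class_map <- tidyr::expand_grid(class = mt$classes,
                                  idx = seq_len(mt$per_class)) |>
    dplyr::transmute(
      metabolite = sprintf("%s_%02d", .data$class, .data$idx),
      class = .data$class
    )
  M <- nrow(class_map)
  base_median <- exp(seq(log(1), log(100), length.out = M))

  meta <- tidyr::expand_grid(arm = arms4, rep = seq_len(design$n_per_group)) |>
    dplyr::transmute(sample_id = sprintf("%s_m%02d", .data$arm, .data$rep),
                     arm = .data$arm)

  eff <- mt$effects
  fold_of <- function(cls, arm) {
    hit <- eff$fold[eff$class == cls & eff$arm == arm]
    if (length(hit) == 0) 1 else prod(hit)
  }

  withr::with_seed(design$seed + 303L, {
    conc <- purrr::map_dfr(seq_len(nrow(meta)), function(i) {
      folds <- vapply(class_map$class, fold_of, 0, arm = meta$arm[i])
      tibble::tibble(
        sample_id = meta$sample_id[i],
        metabolite = class_map$metabolite,
        concentration = rlnorm(M, meanlog = log(base_median * folds),
                               sdlog = mt$sdlog)
      )
    })
  })

  list(concentrations = conc, class_map = class_map, metadata = meta)
}
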