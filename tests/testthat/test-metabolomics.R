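make_panel <- function(n = 8, p = 10, shift = NULL, seed = 1, sdlog = 0.25) {
  set.seed(seed)
  arms <- rep(c("ref", "trt"), each = n)
  ids <- sprintf("%s_%d", arms, rep(seq_len(n), 2))
  base <- exp(seq(log(2), log(50), length.out = p))
  m <- matrix(rlnorm(2 * n * p, rep(log(base), each = 2 * n), sdlog),
              nrow = 2 * n, dimnames = list(ids, paste0("met", seq_len(p))))
  if (!is.null(shift)) {
    for (j in names(shift)) m[arms == "trt", j] <- m[arms == "trt", j] * shift[[j]]
  }
  list(conc = make_conc(m), meta = tibble::tibble(sample_id = ids, arm = arms))
}

test_that("control-referenced Z-scores match their definition", {
  m <- matrix(c(10, 12, 14, 16), ncol = 1,
              dimnames = list(paste0("s", 1:4), "met1"))
  conc <- make_conc(m)
  meta <- tibble::tibble(sample_id = paste0("s", 1:4),
                         arm = c("ctrl", "ctrl", "ctrl", "trt"))
  zs <- zscore_vs_control(conc, meta, control_arm = "ctrl")
  # control mean 12, sample SD 2
  expect_equal(zs$zscore[zs$sample_id == "s2"], 0)
  expect_equal(zs$zscore[zs$sample_id == "s4"], 2)

  # control self-normalisation: mean 0, SD 1 per metabolite
  pan <- make_panel(seed = 9)
  zs2 <- zscore_vs_control(pan$conc, pan$meta, control_arm = "ref")
  ctrl <- zs2[zs2$arm == "ref", ]
  stats <- ctrl |>
    dplyr::group_by(metabolite) |>
    dplyr::summarise(m = mean(zscore), s = sd(zscore))
  expect_equal(stats$m, rep(0, nrow(stats)), tolerance = 1e-9)
  expect_equal(stats$s, rep(1, nrow(stats)), tolerance = 1e-9)
})

test_that("degenerate control metabolites are excluded with a warning", {
  m <- matrix(c(5, 5, 5, 7, 1, 2, 3, 4), ncol = 2,
              dimnames = list(paste0("s", 1:4), c("flat", "ok")))
  conc <- make_conc(m)
  meta <- tibble::tibble(sample_id = paste0("s", 1:4),
                         arm = c("c", "c", "c", "t"))
  expect_warning(zs <- zscore_vs_control(conc, meta, "c"), "zero control SD")
  expect_setequal(unique(zs$metabolite), "ok")
  expect_error(zscore_vs_control(conc, meta[c(1, 4), ], "c"), "at least two")
})

test_that("class aggregates equal their members and flag planted effects", {
  m <- matrix(c(1, 2, 3, 4, 10, 20, 30, 40), ncol = 2,
              dimnames = list(paste0("s", 1:4), c("a1", "b1")))
  conc <- make_conc(m)
  cmap <- tibble::tibble(metabolite = c("a1", "b1"), class = c("A", "B"))
  meta <- tibble::tibble(sample_id = paste0("s", 1:4),
                         arm = rep(c("x", "y"), 2))
  ca <- class_aggregate(conc, cmap, meta)
  # single-member class: aggregate equals the metabolite
  agg <- ca$aggregates
  expect_equal(agg$value[agg$class == "A"],
               unname(m[match(agg$sample_id[agg$class == "A"], rownames(m)), "a1"]))

  # planted 3x imidazole elevation in the TMAO arm is flagged
  d <- synthetic_design(
    seed = 13,
    metabolites = list(effects = tibble::tibble(
      class = "imidazoles", arm = "tmao_saline", fold = 3
    ))
  )
  mt <- gen_metabolites(d)
  tests <- tidy(class_aggregate(
    mt$concentrations, mt$class_map, mt$metadata,
    comparisons = list(c("control_saline", "tmao_saline"))
  ))
  expect_true(tests$significant[tests$class == "imidazoles"])
  expect_false(any(tests$significant[tests$class != "imidazoles"]))
})

test_that("the default design plants the peptide asymmetry", {
  # peptides drop only under TMAO + LPS
  mt <- gen_metabolites(synthetic_design(seed = 17))
  tests <- tidy(class_aggregate(
    mt$concentrations, mt$class_map, mt$metadata,
    comparisons = list(c("control_saline", "control_lps"),
                       c("tmao_saline", "tmao_lps"))
  ))
  pep <- tests[tests$class == "peptides", ]
  expect_false(pep$significant[pep$arm2 == "control_lps"])
  expect_true(pep$significant[pep$arm2 == "tmao_lps"])
})

test_that("VIP satisfies its normalisation identity and symmetry", {
  pan <- make_panel(shift = list(met3 = 4, met7 = 4), seed = 21)
  fit <- pls_vip(pan$conc, pan$meta, arms = c("ref", "trt"))
  expect_equal(mean(fit$vip$vip^2), 1, tolerance = 1e-6)

  # two identically informative metabolites get equal VIPs
  m <- make_panel(seed = 22)$conc |>
    tidyr::pivot_wider(names_from = metabolite, values_from = concentration)
  mm <- as.matrix(m[, -1]); rownames(mm) <- m$sample_id
  mm[, "met2"] <- mm[, "met1"]
  arms <- sub("_\\d+$", "", rownames(mm))
  mm[arms == "trt", c("met1", "met2")] <- mm[arms == "trt", c("met1", "met2")] * 4
  fit2 <- pls_vip(make_conc(mm),
                  tibble::tibble(sample_id = rownames(mm), arm = arms),
                  arms = c("ref", "trt"))
  v <- fit2$vip
  expect_equal(v$vip[v$metabolite == "met1"], v$vip[v$metabolite == "met2"],
               tolerance = 1e-6)
  # a constant metabolite is dropped with a warning
  mm[, "met5"] <- 1
  expect_warning(
    fit3 <- pls_vip(make_conc(mm),
                    tibble::tibble(sample_id = rownames(mm), arm = arms),
                    arms = c("ref", "trt")),
    "constant"
  )
  expect_false("met5" %in% fit3$vip$metabolite)
})

test_that("a lone informative metabolite dominates the VIP ranking", {
  pan <- make_panel(p = 20, shift = list(met11 = 4), seed = 23)
  fit <- pls_vip(pan$conc, pan$meta, arms = c("ref", "trt"))
  top <- tidy(fit)
  expect_equal(top$metabolite[1], "met11")
  expect_gt(top$vip[1], 1)
})

test_that("VIP ranks agree with an independent PLS-DA implementation", {
  pan <- make_panel(p = 12, shift = list(met2 = 3, met9 = 0.3), seed = 25)
  fit <- pls_vip(pan$conc, pan$meta, arms = c("ref", "trt"), n_components = 1)

  wide <- tidyr::pivot_wider(pan$conc, names_from = metabolite,
                             values_from = concentration)
  X <- as.matrix(wide[, -1])
  y <- factor(pan$meta$arm[match(wide$sample_id, pan$meta$sample_id)])
  mo <- mixOmics::plsda(X, y, ncomp = 1)
  vip_ref <- mixOmics::vip(mo)[, 1]

  ours <- fit$vip$vip[match(names(vip_ref), fit$vip$metabolite)]
  expect_gt(cor(ours, vip_ref, method = "spearman"), 0.95)
  expect_equal(names(which.max(vip_ref)),
               fit$vip$metabolite[which.max(fit$vip$vip)])
})

test_that("volcano applies the VIP-and-p rule and its invariances", {
  pan <- make_panel(p = 20, shift = list(met1 = 4, met2 = 4, met3 = 4), seed = 27)
  v <- volcano(pan$conc, pan$meta, contrast = c("trt", "ref"))
  expect_true(all(v$significant == (v$vip >= 1 & v$p.value < 0.05)))
  expect_true(all(c("met1", "met2", "met3") %in% v$metabolite[v$significant]))
  # planted shifts have log2fc near 2
  expect_equal(v$log2fc[v$metabolite == "met1"], 2, tolerance = 0.5)

  # identical arms: nothing significant
  m0 <- make_panel(seed = 28)
  v0 <- volcano(m0$conc, m0$meta, contrast = c("trt", "ref"))
  expect_lte(sum(v0$significant), 1) # chance flags only

  # metabolite reordering leaves flags unchanged
  shuffled <- pan$conc[sample(nrow(pan$conc)), ]
  v_sh <- volcano(shuffled, pan$meta, contrast = c("trt", "ref"))
  expect_equal(dplyr::arrange(tibble::as_tibble(v_sh), metabolite),
               dplyr::arrange(tibble::as_tibble(v), metabolite))

  # rescaling one metabolite's units: FC and flags unchanged
  rescaled <- dplyr::mutate(
    pan$conc,
    concentration = ifelse(metabolite == "met4", concentration * 1000, concentration)
  )
  v_rs <- volcano(rescaled, pan$meta, contrast = c("trt", "ref"))
  expect_equal(v_rs$log2fc, v$log2fc, tolerance = 1e-9)
  expect_equal(v_rs$significant, v$significant)
})

test_that("volcano handles zero-mean reference metabolites", {
  pan <- make_panel(p = 6, seed = 29)
  conc <- pan$conc
  # met6 all-zero in the reference arm only -> half-minimum imputed FC
  conc$concentration[conc$metabolite == "met6" &
                       grepl("^ref", conc$sample_id)] <- 0
  v <- volcano(conc, pan$meta, contrast = c("trt", "ref"))
  expect_true(v$fc_imputed[v$metabolite == "met6"])
  expect_true(is.finite(v$log2fc[v$metabolite == "met6"]))
})
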