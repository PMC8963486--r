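test_that("relative abundances divide by sample totals and close to 1", {
  counts <- make_counts(list(s1 = c(A = 50, B = 50)))
  rel <- relative_abundance(counts, rank = "taxon")
  expect_equal(sort(rel$proportion), c(0.5, 0.5))

  # aggregation: two genera of one phylum with 30 + 20 of 100 reads
  counts2 <- make_counts(list(s1 = c(g1 = 30, g2 = 20, g3 = 50)))
  lin <- make_lineage(c("g1", "g2", "g3"),
                      phylum = c("Firmicutes", "Firmicutes", "Bacteroidetes"))
  ph <- relative_abundance(counts2, lin, rank = "phylum")
  expect_equal(ph$proportion[ph$taxon == "Firmicutes"], 0.5)

  # brute-force oracle on a random table, all ranks close to 1
  set.seed(7)
  taxa <- paste0("t", 1:15)
  counts3 <- purrr::map_dfr(paste0("s", 1:6), function(s) {
    tibble::tibble(sample_id = s, taxon_id = taxa,
                   count = rpois(15, 40))
  })
  lin3 <- make_lineage(taxa, phylum = rep_len(c("P1", "P2", "P3"), 15))
  for (rk in c("taxon", "phylum", "genus")) {
    rel3 <- relative_abundance(counts3, lin3, rank = rk)
    sums <- as.numeric(tapply(rel3$proportion, rel3$sample_id, sum))
    expect_equal(sums, rep(1, 6), tolerance = 1e-9)
  }
  # explicit-loop recomputation at taxon rank
  rel3 <- relative_abundance(counts3, rank = "taxon")
  for (s in c("s2", "s5")) {
    sub <- counts3[counts3$sample_id == s, ]
    for (i in seq_len(nrow(sub))) {
      got <- rel3$proportion[rel3$sample_id == s & rel3$taxon == sub$taxon_id[i]]
      expect_equal(got, sub$count[i] / sum(sub$count))
    }
  }
})

test_that("taxa without a rank assignment pool as unclassified bins", {
  counts <- make_counts(list(s1 = c(g1 = 40, g2 = 60)))
  lin <- make_lineage(c("g1", "g2"))
  lin$genus[2] <- NA
  rel <- relative_abundance(counts, lin, rank = "genus")
  expect_setequal(rel$taxon, c("genus_g1", "unclassified_f1"))
  expect_equal(sum(rel$proportion), 1)
  expect_error(relative_abundance(counts, lin, rank = "species"), "unknown rank")
})

test_that("Shannon index matches closed forms and is label-invariant", {
  counts <- make_counts(list(
    uniform4 = c(a = 25, b = 25, c = 25, d = 25),
    single = c(a = 99),
    mixed = c(a = 10, b = 10, c = 20)
  ))
  h <- shannon_index(counts)
  expect_equal(h$shannon[h$sample_id == "uniform4"], log(4))
  expect_equal(h$shannon[h$sample_id == "single"], 0)
  p <- c(0.25, 0.25, 0.5)
  expect_equal(h$shannon[h$sample_id == "mixed"], -sum(p * log(p)))

  relabeled <- dplyr::mutate(counts, taxon_id = paste0("x_", taxon_id))
  expect_equal(shannon_index(relabeled)$shannon, h$shannon)
  # bounded by log richness
  richness <- c(mixed = 3, single = 1, uniform4 = 4)
  expect_true(all(h$shannon <= log(richness[h$sample_id]) + 1e-12))
})

test_that("F/B ratio is the phylum proportion quotient and depth-invariant", {
  counts <- make_counts(list(s1 = c(f1 = 60, b1 = 20, p1 = 20),
                             s2 = c(f1 = 30, b1 = 30, p1 = 40)))
  lin <- make_lineage(c("f1", "b1", "p1"),
                      phylum = c("Firmicutes", "Bacteroidetes", "Proteobacteria"))
  fb <- fb_ratio(counts, lin)
  expect_equal(fb$fb_ratio[fb$sample_id == "s1"], 3)
  expect_equal(fb$fb_ratio[fb$sample_id == "s2"], 1)

  scaled <- dplyr::mutate(counts, count = count * 10)
  expect_equal(fb_ratio(scaled, lin)$fb_ratio, fb$fb_ratio)

  # zero Bacteroidetes -> excluded with warning
  counts$count[counts$sample_id == "s2" & counts$taxon_id == "b1"] <- 0
  expect_warning(fb2 <- fb_ratio(counts, lin), "undefined")
  expect_equal(fb2$sample_id, "s1")
})

test_that("planted Bacteroidetes expansion lowers the TMAO-arm F/B ratio", {
  d <- synthetic_design(seed = 19)
  mb <- gen_microbiome(d)
  fb <- fb_ratio(mb$counts, mb$lineage, mb$metadata) |>
    dplyr::filter(timepoint == "pre_challenge")
  med <- tapply(fb$fb_ratio, fb$arm, median)
  expect_lt(med[["tmao"]], med[["control"]])
  tst <- fb_ratio_test(mb$counts, mb$lineage, mb$metadata,
                       arms = c("control", "tmao"),
                       timepoint = "pre_challenge")
  expect_lt(tst$p.value, 0.05)
})

test_that("Bray-Curtis matches hand arithmetic and its metric range", {
  counts <- make_counts(list(
    s1 = c(a = 10, b = 30, c = 60),
    s2 = c(a = 10, b = 30, c = 60),
    s3 = c(d = 50, e = 50)
  ))
  d <- as.matrix(bray_curtis(counts))
  expect_equal(d["s1", "s2"], 0)
  expect_equal(d["s1", "s3"], 1)
  expect_equal(diag(d), c(s1 = 0, s2 = 0, s3 = 0))
  expect_equal(d, t(d))

  # hand computation on proportions for a non-trivial pair
  counts2 <- make_counts(list(x = c(a = 40, b = 60), y = c(a = 10, b = 40, c = 50)))
  px <- c(0.4, 0.6, 0); py <- c(0.1, 0.4, 0.5)
  expect_equal(as.matrix(bray_curtis(counts2))["x", "y"],
               sum(abs(px - py)) / sum(px + py))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("PCoA recovers planted configurations", {
  # two samples at dissimilarity d -> one axis at +/- d/2
  m <- matrix(c(0, 0.6, 0.6, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ord <- pcoa(m)
  expect_equal(sort(ord$coordinates$axis1), c(-0.3, 0.3))

  # Euclidean distances of known 2-D points: recovered up to rotation
  set.seed(11)
  pts <- matrix(rnorm(20), ncol = 2,
                dimnames = list(paste0("s", 1:10), NULL))
  ord2 <- pcoa(dist(pts), k = 2)
  proc <- vegan::procrustes(pts, as.matrix(ord2$coordinates[, c("axis1", "axis2")]),
                            symmetric = FALSE)
  expect_lt(sum(proc$residuals^2), 1e-12)

  # eigenvalue sum equals the trace of the centred Gower matrix
  D2 <- as.matrix(dist(pts))^2
  J <- diag(10) - matrix(1 / 10, 10, 10)
  G <- -0.5 * J %*% D2 %*% J
  expect_equal(sum(ord2$eigenvalues), sum(diag(G)), tolerance = 1e-8)

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("challenge_response counts directional shifts within an arm", {
  set.seed(23)
  taxa <- paste0("g", 1:12)
  base <- rpois(12, 200) + 50
  samples <- list()
  for (i in 1:8) {
    v <- rpois(12, base); names(v) <- taxa
    samples[[paste0("pre_", i)]] <- v
  }
  # post: same process but taxon g1 shifted 10x
  for (i in 1:8) {
    lam <- base; lam[1] <- lam[1] * 10
    v <- rpois(12, lam); names(v) <- taxa
    samples[[paste0("post_", i)]] <- v
  }
  counts <- make_counts(samples)
  meta <- tibble::tibble(
    sample_id = names(samples), arm = "control",
    timepoint = rep(c("pre_challenge", "post_challenge"), each = 8)
  )
  rb <- challenge_response(counts, make_lineage(taxa), meta, arm = "control")
  tt <- tidy(rb)
  expect_true(tt$flagged[tt$taxon == "genus_g1"])
  expect_equal(tt$direction[tt$taxon == "genus_g1"], "increased")

  # identical pre and post values -> nothing flagged
  same <- samples[1:8]
  names(same) <- paste0("post_", 1:8)
  counts0 <- make_counts(c(samples[1:8], same))
  rb0 <- challenge_response(counts0, make_lineage(taxa), meta, arm = "control")
  expect_equal(rb0$n_increased + rb0$n_decreased, 0L)

  expect_error(
    challenge_response(counts, make_lineage(taxa), meta[c(1:2, 9:16), ], "control"),
    "at least 3"
  )
})

test_that("response breadth recovers a planted control/TMAO contrast", {
  d <- synthetic_design(seed = 31)
  mb <- gen_microbiome(d)
  rb_c <- challenge_response(mb$counts, mb$lineage, mb$metadata, "control")
  rb_t <- challenge_response(mb$counts, mb$lineage, mb$metadata, "tmao")
  expect_gt(rb_c$n_increased + rb_c$n_decreased,
            rb_t$n_increased + rb_t$n_decreased)
  rr <- response_ratio(rb_c, rb_t)
  expect_gt(rr$ratio, 1)
  # BH switch is monotone: adjusted screen flags a subset
  rb_bh <- challenge_response(mb$counts, mb$lineage, mb$metadata, "control",
                              p_adjust = "BH")
  expect_lte(rb_bh$n_increased, rb_c$n_increased)
  expect_lte(rb_bh$n_decreased, rb_c$n_decreased)
})
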