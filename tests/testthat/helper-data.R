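# Small fixtures built in code.

# Behavioural cohort with hand-set values: `post` maps day -> named list of
# per-animal multipliers of the animal's baseline mean decrease (in raw units).
make_behavior <- function(animals = c("m1", "m2"),
                          group = "control_saline",
                          items = "BW",
                          baseline = list(m1 = c(20, 21, 22), m2 = c(24, 25, 26)),
                          post = list()) {
  rows <- list()
  for (a in animals) {
    for (it in items) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        animal_id = a, group = group, item = it,
        day = 0:2, value = baseline[[a]]
      )
      for (d in names(post)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          animal_id = a, group = group, item = it,
          day = as.numeric(d), value = mean(baseline[[a]]) - post[[d]][[a]]
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

# Long counts from a named list sample -> named count vector.
make_counts <- function(samples) {
  purrr::imap_dfr(samples, function(v, s) {
    tibble::tibble(sample_id = s, taxon_id = names(v), count = unname(v))
  })
}

# Minimal lineage table: every taxon in its own genus under a given phylum.
make_lineage <- function(taxa, phylum = "Firmicutes") {
  tibble::tibble(
    taxon_id = taxa,
    phylum = rep_len(phylum, length(taxa)),
    class = "c1", order = "o1", family = "f1",
    genus = paste0("genus_", taxa)
  )
}

# Long metabolite table from a samples x metabolites matrix.
make_conc <- function(m) {
  tibble::tibble(
    sample_id = rep(rownames(m), ncol(m)),
    metabolite = rep(colnames(m), each = nrow(m)),
    concentration = as.vector(m)
  )
}
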