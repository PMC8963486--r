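# Readers for the TSV dialects the analysis functions consume.

#' Read a long-format behavioural table
#'
#' Expects a TSV/CSV with header `animal_id,group,item,day,value`.
#'
#' @param path File path; delimiter inferred from the extension
#'   (`.csv` -> comma, otherwise tab).
#' @return A tibble suitable for [compute_baseline()] / [fi_table()].
#' @export
read_behavior <- function(path) {
  out <- read_table_auto(path)
  check_cols(out, c("animal_id", "group", "item", "day", "value"), path)
  out
}

#' Read a genus-level count table with lineage and sample metadata
#'
#' `counts_path` is a taxa-by-samples TSV (first column `taxon_id`, one
#' column per sample); `lineage_path` maps `taxon_id` to a
#' semicolon-separated `phylum;class;order;family;genus` lineage string (or
#' already-split rank columns); `metadata_path` has
#' `sample_id,arm,timepoint`.
#'
#' @param counts_path,lineage_path,metadata_path File paths.
#' @return A list `counts` (long tibble), `lineage`, `metadata` as consumed
#'   by [relative_abundance()] and friends.
#' @export
read_abundance <- function(counts_path, lineage_path, metadata_path) {
  wide <- read_table_auto(counts_path)
  check_cols(wide, "taxon_id", counts_path)
  counts <- tidyr::pivot_longer(wide, -"taxon_id",
                                names_to = "sample_id", values_to = "count") |>
    dplyr::select("sample_id", "taxon_id", "count")

  lin <- read_table_auto(lineage_path)
  check_cols(lin, "taxon_id", lineage_path)
  if ("lineage" %in% names(lin)) {
    lin <- tidyr::separate_wider_delim(
      lin, "lineage", delim = ";",
      names = c("phylum", "class", "order", "family", "genus"),
      too_few = "align_start"
    )
  }
  meta <- read_table_auto(metadata_path)
  check_cols(meta, c("sample_id", "arm", "timepoint"), metadata_path)
  list(counts = counts, lineage = lin, metadata = meta)
}

#' Read a targeted-metabolite table with class map and sample metadata
#'
#' `conc_path` is a samples-by-metabolites TSV (first column `sample_id`);
#' `class_path` maps `metabolite` to `class`; `metadata_path` has
#' `sample_id,arm`.
#'
#' @param conc_path,class_path,metadata_path File paths.
#' @return A list `concentrations` (long tibble), `class_map`, `metadata`.
#' @export
read_metabolites <- function(conc_path, class_path, metadata_path) {
  wide <- read_table_auto(conc_path)
  check_cols(wide, "sample_id", conc_path)
  conc <- tidyr::pivot_longer(wide, -"sample_id",
                              names_to = "metabolite",
                              values_to = "concentration")
  cls <- read_table_auto(class_path)
  check_cols(cls, c("metabolite", "class"), class_path)
  meta <- read_table_auto(metadata_path)
  check_cols(meta, c("sample_id", "arm"), metadata_path)
  list(concentrations = conc, class_map = cls, metadata = meta)
}

read_table_auto <- function(path) {
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}
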