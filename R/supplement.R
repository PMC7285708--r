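# Recomputation of the published per-sample statistics from the study's
# supplementary tables. The tables ship with the article as spreadsheets
# and are not redistributed here; export them as TSV in the layout below
# and point `supplement_stats()` at the directory.
#
#   table_s1.tsv            sample_id, core, depth_cm, pH, EC, TOC, TP, TS,
#                           Fe2_TFe, SO4_TS, <metal columns...>,
#                           votu_richness, otu_richness
#   table_s3_coverage.tsv   votu_id, family ("unclassified" when
#                           unaffiliated), one normalized-coverage column
#                           per sample_id
#   table_s4_otus.tsv       otu_id, phylum, one count column per sample_id
#   table_s5_prophages.tsv  viral_id (one row per prophage; ids must match
#                           the votu_id / member ids used in table S3)

#' Recompute the published supplementary-table statistics
#'
#' Given TSV exports of the study's supplementary tables (layout in the
#' source file header), recomputes with this package's own machinery:
#' the Pearson correlation between per-layer vOTU and prokaryotic OTU
#' richness; the Mantel correlations of the viral Bray-Curtis matrix with
#' the prokaryotic Bray-Curtis and the geochemical Euclidean matrices;
#' the between-core group statistic on the viral Bray-Curtis matrix
#' (reported as both ANOSIM R and PERMANOVA R-squared — the published
#' label conflates the two, so both are returned); the Euryarchaeota
#' fraction of sample A1; the maximum per-layer summed relative abundance
#' of classified vOTUs; and the Pearson correlation between summed
#' prophage relative abundance and pH.
#'
#' @param dir Directory holding the four TSV files.
#' @param permutations Permutations for the Mantel tests.
#' @param seed Seed for the permutation streams.
#' @return Named list of statistics (fractions reported as percentages,
#'   matching the article's units): `richness_pearson_r`,
#'   `mantel_viral_prok_r`, `mantel_viral_geochem_r`, `core_anosim_R`,
#'   `core_permanova_R2`, `euryarchaeota_A1_percent`,
#'   `max_classified_percent`, `prophage_ph_pearson_r`, plus the
#'   associated p-values.
#' @export
supplement_stats <- function(dir, permutations = 999, seed = 1L) {
  need <- c("table_s1.tsv", "table_s3_coverage.tsv", "table_s4_otus.tsv",
            "table_s5_prophages.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0) {
    abort(sprintf(paste(
      "supplementary tables not found: %s.",
      "Export the article's supplementary spreadsheets as TSV",
      "(layout documented in ?supplement_stats) into %s."),
      paste(missing, collapse = ", "), dir))
  }
  s1 <- readr::read_tsv(file.path(dir, "table_s1.tsv"),
                        show_col_types = FALSE)
  s3 <- readr::read_tsv(file.path(dir, "table_s3_coverage.tsv"),
                        show_col_types = FALSE)
  s4 <- readr::read_tsv(file.path(dir, "table_s4_otus.tsv"),
                        show_col_types = FALSE)
  s5 <- readr::read_tsv(file.path(dir, "table_s5_prophages.tsv"),
                        show_col_types = FALSE)
  sample_ids <- s1$sample_id

  rp <- pearson_cor(s1$votu_richness, s1$otu_richness)

  vir_m <- t(as.matrix(s3[sample_ids])); colnames(vir_m) <- s3$votu_id
  rownames(vir_m) <- sample_ids
  d_vir <- bray_curtis(vir_m)
  prok_m <- t(as.matrix(s4[sample_ids])); colnames(prok_m) <- s4$otu_id
  rownames(prok_m) <- sample_ids
  d_prok <- bray_curtis(prok_m)
  geo_cols <- setdiff(names(s1), c("sample_id", "core", "depth_cm",
                                   "votu_richness", "otu_richness"))
  d_geo <- euclidean_env(s1 |> select("sample_id", all_of(geo_cols)))

  m_vp <- mantel_test(d_vir, d_prok, permutations,
                      seed = child_seed(seed, "mantel_vp"))
  m_vg <- mantel_test(d_vir, d_geo, permutations,
                      seed = child_seed(seed, "mantel_vg"))
  an <- anosim_test(d_vir, s1$core, permutations,
                    seed = child_seed(seed, "anosim_core"))
  pm <- permanova_test(d_vir, s1$core, permutations,
                       seed = child_seed(seed, "permanova_core"))

  a1 <- s4[["A1"]]
  eury <- 100 * sum(a1[s4$phylum == "Euryarchaeota"]) / sum(a1)

  cov_long <- s3 |>
    pivot_longer(all_of(sample_ids), names_to = "sample_id",
                 values_to = "norm_cov") |>
    rename(entity_id = "votu_id")
  classified <- s3$votu_id[s3$family != "unclassified"]
  class_ra <- relative_abundance(cov_long, classified)
  pro_ra <- relative_abundance(cov_long,
                               intersect(s5$viral_id, s3$votu_id))
  pro_ra <- pro_ra[match(sample_ids, pro_ra$sample_id), ]
  pp <- pearson_cor(pro_ra$rel_abundance, s1$pH)

  list(
    richness_pearson_r = rp$statistic,
    richness_pearson_p = rp$p_value,
    mantel_viral_prok_r = m_vp$statistic,
    mantel_viral_prok_p = m_vp$p_value,
    mantel_viral_geochem_r = m_vg$statistic,
    mantel_viral_geochem_p = m_vg$p_value,
    core_anosim_R = an$statistic,
    core_permanova_R2 = pm$r_squared,
    euryarchaeota_A1_percent = eury,
    max_classified_percent = 100 * max(class_ra$rel_abundance, na.rm = TRUE),
    prophage_ph_pearson_r = pp$statistic,
    prophage_ph_pearson_p = pp$p_value)
}
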