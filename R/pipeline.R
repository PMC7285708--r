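# End-to-end orchestration: identify -> cluster -> abundance -> hosts ->
# functions -> stats, with a machine-readable manifest.

GEOCHEM_COLS <- c("pH", "EC", "TOC", "TP", "TS", "Fe2_TFe", "SO4_TS",
                  "Pb", "Zn", "Cu")

#' Read a full input bundle from a directory
#'
#' Loads the files written by [write_bundle()] (or assembled by hand in
#' the same layout) with the package readers: `assembly.fasta`,
#' `genes.tsv`, `detector_calls.tsv`, `samples.tsv`,
#' `coverage_scaffolds.tsv`, `coverage_genes.tsv`, `bins.tsv`,
#' `bin_taxonomy.tsv`, `otu_table.tsv`.
#'
#' @param dir Directory containing the bundle.
#' @return A `tv_bundle` list (without ground truth).
#' @export
read_bundle <- function(dir) {
  need <- c("assembly.fasta", "genes.tsv", "detector_calls.tsv", "samples.tsv",
            "coverage_scaffolds.tsv", "coverage_genes.tsv", "bins.tsv",
            "bin_taxonomy.tsv", "otu_table.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0) {
    abort(sprintf("input bundle incomplete, missing: %s",
                  paste(missing, collapse = ", ")))
  }
  scaffolds <- read_fasta(file.path(dir, "assembly.fasta"))
  structure(list(
    scaffolds = scaffolds,
    genes = read_gene_table(file.path(dir, "genes.tsv"),
                            known_scaffolds = scaffolds$id),
    calls = read_detector_calls(file.path(dir, "detector_calls.tsv")),
    samples = read_sample_table(file.path(dir, "samples.tsv")),
    coverage = read_coverage_table(file.path(dir, "coverage_scaffolds.tsv")),
    gene_coverage = read_coverage_table(file.path(dir, "coverage_genes.tsv")),
    bins = read_bin_table(file.path(dir, "bins.tsv")),
    bin_taxonomy = read_bin_taxonomy(file.path(dir, "bin_taxonomy.tsv")),
    otus = read_otu_table(file.path(dir, "otu_table.tsv")),
    truth = NULL, config = NULL), class = "tv_bundle")
}

# Coverage rows for catalogue entries: use the entity named by viral_id
# when the coverage table carries it (e.g. reads re-mapped to the trimmed
# prophage region), falling back to the parent scaffold otherwise.
catalogue_coverage <- function(catalogue, coverage) {
  have <- unique(coverage$entity_id)
  purrr::map(seq_len(nrow(catalogue)), function(i) {
    key <- if (catalogue$viral_id[i] %in% have) catalogue$viral_id[i]
    else catalogue$parent_scaffold_id[i]
    coverage |>
      filter(.data$entity_id == key) |>
      mutate(entity_id = catalogue$viral_id[i])
  }) |> bind_rows()
}

surface_groups <- function(samples, surface_layers_per_core = 2L) {
  if ("surface" %in% names(samples)) {
    return(samples |>
             mutate(group = ifelse(.data$surface, "surface", "deep")) |>
             select("sample_id", "group"))
  }
  samples |>
    group_by(.data$core) |>
    arrange(.data$depth_cm, .by_group = TRUE) |>
    mutate(group = ifelse(row_number() <= surface_layers_per_core,
                          "surface", "deep")) |>
    ungroup() |>
    select("sample_id", "group")
}

#' Run the full depth-stratified viral community analysis
#'
#' Executes the pipeline stages in order on an input bundle: viral
#' identification and curation, vOTU clustering, normalized coverage /
#' relative abundance / richness, virus-host linking, indicator-COG and
#' AMG analysis, and the community statistics (ordination, ANOSIM,
#' PERMANOVA, Mantel, Pearson correlations with geochemistry). All
#' randomness (permutation tests) derives from `cfg$rng_seed`, so reruns
#' are reproducible.
#'
#' @param bundle A `tv_bundle` ([simulate_bundle()] or [read_bundle()]).
#' @param cfg A [pipeline_config()].
#' @param groups Optional `sample_id`/`group` tibble for the surface-deep
#'   split; defaults to the bundle's `surface` flag, or to the top two
#'   layers of each core.
#' @param taxonomy Optional tibble `id`, `family` with viral taxonomy for
#'   family-level relative abundance.
#' @param outdir Optional directory; when given, [write_outputs()] is
#'   called on the result.
#' @return A `tv_results` list; see the elements written by
#'   [write_outputs()], plus `tests` (the fitted statistic objects) and
#'   `manifest`.
#' @export
run_tailings_pipeline <- function(bundle, cfg = pipeline_config(),
                                  groups = NULL, taxonomy = NULL,
                                  outdir = NULL) {
  stopifnot(inherits(bundle, "tv_bundle") || is.list(bundle))
  samples <- bundle$samples
  if (is.null(groups)) groups <- surface_groups(samples)

  ## stage 1: identify ---------------------------------------------------
  catalogue <- identify_viruses(bundle$scaffolds, bundle$genes, bundle$calls, cfg)
  accepted <- catalogue |> filter(.data$accepted)

  if (nrow(accepted) == 0) {
    empty_cov <- tibble(entity_id = character(), sample_id = character(),
                        norm_cov = numeric())
    counts <- list(n_candidates = nrow(catalogue), n_accepted = 0L,
                   n_both_detectors = 0L, n_single_detector = 0L,
                   n_votus = 0L, n_links_spacer = 0L, n_links_prophage = 0L,
                   n_links_shared = 0L, n_indicator_cogs = 0L,
                   n_amg_scaffolds = 0L)
    results <- structure(list(
      catalogue = catalogue,
      votus = cluster_votus(accepted |> select(id = "viral_id", "seq")),
      coverage = empty_cov, scaffold_coverage = empty_cov,
      gene_coverage = empty_cov,
      relative_abundance = tibble(sample_id = character(),
                                  prophage_rel_abundance = numeric()),
      prophage_ra = tibble(sample_id = character(),
                           prophage_rel_abundance = numeric()),
      family_ra = NULL,
      richness = tibble(sample_id = character(), richness = integer()),
      host_links = tibble(virus_id = character(), host_bin_id = character(),
                          evidence = character()),
      cog_coverage = tibble(cog_id = character(), sample_id = character(),
                            norm_cov = numeric()),
      indicator_cogs = tibble(cog_id = character(), p_value = numeric(),
                              q_value = numeric(), direction = character(),
                              indicator = logical()),
      amg_report = tibble(viral_id = character()),
      ordination = tibble(sample_id = character()),
      stats = tibble(test = character(), method = character(),
                     statistic = numeric(), r_squared = numeric(),
                     p_value = numeric()),
      tests = list(), groups = groups,
      manifest = run_manifest(cfg, counts = counts)), class = "tv_results")
    if (!is.null(outdir)) write_outputs(results, outdir)
    return(results)
  }

  ## stage 2: cluster ----------------------------------------------------
  votus <- cluster_votus(accepted |> select(id = "viral_id", "seq"),
                         ani_threshold = cfg$ani_threshold,
                         af_threshold = cfg$af_threshold)

  ## stage 3: abundance --------------------------------------------------
  vcov_raw <- catalogue_coverage(accepted, bundle$coverage)
  vlen <- accepted |> select(entity_id = "viral_id", "length")
  scaffold_cov <- normalized_coverage(vcov_raw, vlen, samples)
  va <- votu_coverage(vcov_raw, vlen, votus)
  votu_cov <- normalized_coverage(va$coverage, va$lengths, samples)
  rich <- richness(votu_cov, cfg$presence_threshold)
  classified_genes <- classify_genes(bundle$genes, cfg)
  viral_genes <- purrr::map(seq_len(nrow(accepted)), function(i) {
    classified_genes |>
      filter(.data$scaffold_id == accepted$parent_scaffold_id[i],
             .data$start >= accepted$region_start[i],
             .data$end <= accepted$region_end[i]) |>
      mutate(viral_id = accepted$viral_id[i])
  }) |> bind_rows()
  gcov_raw <- bundle$gene_coverage |>
    filter(.data$entity_id %in% viral_genes$gene_id)
  glen <- viral_genes |>
    mutate(length = .data$end - .data$start) |>
    select(entity_id = "gene_id", "length")
  gene_cov <- normalized_coverage(gcov_raw, glen, samples)
  prophage_ra <- relative_abundance(
    scaffold_cov, accepted$viral_id[accepted$is_prophage]) |>
    rename(prophage_rel_abundance = "rel_abundance")
  family_ra <- NULL
  if (!is.null(taxonomy)) {
    fam <- accepted |>
      left_join(taxonomy, by = c(viral_id = "id")) |>
      mutate(family = dplyr::coalesce(.data$family, "unclassified"))
    family_ra <- purrr::map(unique(fam$family), function(f) {
      relative_abundance(scaffold_cov, fam$viral_id[fam$family == f]) |>
        mutate(family = f)
    }) |> bind_rows()
  }

  ## stage 4: hosts ------------------------------------------------------
  links <- predict_hosts(catalogue, bundle$scaffolds, bundle$bins, cfg) |>
    left_join(accepted |> select(virus_id = "viral_id", "parent_scaffold_id"),
              by = "virus_id") |>
    filter(!(.data$evidence == "spacer" &
               .data$host_scaffold_id == .data$parent_scaffold_id)) |>
    select(-"parent_scaffold_id")

  ## stage 5: functions --------------------------------------------------
  cogs <- cog_coverage(viral_genes, gene_cov)
  carriers <- viral_genes |>
    filter(!is.na(.data$cog_id), .data$cog_id != "") |>
    select("cog_id", "viral_id")
  indicators <- indicator_cogs(cogs, groups, alpha = cfg$alpha,
                               carriers = carriers)
  amg <- amg_report(catalogue, classified_genes, scaffold_cov, gene_cov,
                    groups = groups)

  ## stage 6: community statistics ---------------------------------------
  votu_mat <- votu_cov |>
    pivot_wider(names_from = "entity_id", values_from = "norm_cov") |>
    as.data.frame()
  d_vir <- bray_curtis(votu_mat)
  ord <- pcoa_ord(d_vir)
  grp_vec <- groups$group[match(attr(d_vir, "Labels") %||% votu_mat$sample_id,
                                groups$sample_id)]
  core_vec <- samples$core[match(votu_mat$sample_id, samples$sample_id)]
  seed0 <- cfg$rng_seed
  tests <- list(
    anosim_depth = anosim_test(d_vir, grp_vec, cfg$permutations,
                               seed = child_seed(seed0, "anosim_depth")),
    permanova_depth = permanova_test(d_vir, grp_vec, cfg$permutations,
                                     seed = child_seed(seed0, "permanova_depth")),
    anosim_core = anosim_test(d_vir, core_vec, cfg$permutations,
                              seed = child_seed(seed0, "anosim_core")),
    permanova_core = permanova_test(d_vir, core_vec, cfg$permutations,
                                    seed = child_seed(seed0, "permanova_core")))
  prok_rich <- NULL
  if (!is.null(bundle$otus)) {
    otu_mat <- bundle$otus |>
      select("otu_id", "sample_id", "count") |>
      pivot_wider(names_from = "otu_id", values_from = "count") |>
      as.data.frame()
    otu_mat <- otu_mat[match(votu_mat$sample_id, otu_mat$sample_id), ]
    d_prok <- bray_curtis(otu_mat)
    tests$mantel_viral_prok <- mantel_test(
      d_vir, d_prok, cfg$permutations,
      seed = child_seed(seed0, "mantel_viral_prok"))
    prok_rich <- bundle$otus |>
      group_by(.data$sample_id) |>
      summarise(prok_richness = sum(.data$count > 0), .groups = "drop")
  }
  geo_cols <- intersect(GEOCHEM_COLS, names(samples))
  if (length(geo_cols) >= 2) {
    geo <- samples |> select("sample_id", all_of(geo_cols))
    geo <- geo[match(votu_mat$sample_id, geo$sample_id), ]
    d_geo <- euclidean_env(geo)
    tests$mantel_viral_geochem <- mantel_test(
      d_vir, d_geo, cfg$permutations,
      seed = child_seed(seed0, "mantel_viral_geochem"))
  }
  corr <- list()
  ord_rich <- rich[match(votu_mat$sample_id, rich$sample_id), ]
  if (!is.null(prok_rich)) {
    pr <- prok_rich$prok_richness[match(votu_mat$sample_id,
                                        prok_rich$sample_id)]
    corr$richness_viral_prok <- pearson_cor(ord_rich$richness, pr)
  }
  if ("pH" %in% names(samples)) {
    ph <- samples$pH[match(votu_mat$sample_id, samples$sample_id)]
    corr$richness_ph <- pearson_cor(ord_rich$richness, ph)
    pra <- prophage_ra$prophage_rel_abundance[
      match(votu_mat$sample_id, prophage_ra$sample_id)]
    if (sd(pra, na.rm = TRUE) > 0) {
      corr$prophage_ra_ph <- pearson_cor(pra, ph)
    }
  }
  tests <- c(tests, corr)
  stats_tbl <- purrr::imap(tests, function(t, nm) {
    tibble(test = nm, method = t$method, statistic = t$statistic,
           r_squared = t$r_squared %||% NA_real_,
           p_value = t$p_value)
  }) |> bind_rows()

  counts <- list(
    n_candidates = nrow(catalogue),
    n_accepted = nrow(accepted),
    n_both_detectors = sum(accepted$detectors == "both"),
    n_single_detector = sum(accepted$detectors != "both"),
    n_votus = dplyr::n_distinct(votus$votu_id),
    n_links_spacer = sum(links$evidence == "spacer"),
    n_links_prophage = sum(links$evidence == "prophage"),
    n_links_shared = sum(links$evidence == "shared_content"),
    n_indicator_cogs = sum(indicators$indicator),
    n_amg_scaffolds = nrow(amg))

  results <- structure(list(
    catalogue = catalogue,
    votus = votus,
    coverage = votu_cov,
    scaffold_coverage = scaffold_cov,
    gene_coverage = gene_cov,
    relative_abundance = if (is.null(family_ra)) prophage_ra else
      family_ra |> left_join(prophage_ra, by = "sample_id"),
    prophage_ra = prophage_ra,
    family_ra = family_ra,
    richness = rich |> left_join(prok_rich, by = "sample_id"),
    host_links = links,
    cog_coverage = cogs,
    indicator_cogs = indicators,
    amg_report = amg |> select(-any_of(c("genome_coverage", "gene_coverage"))),
    amg_full = amg,
    ordination = ord$coordinates,
    ordination_obj = ord,
    stats = stats_tbl,
    tests = tests,
    groups = groups,
    manifest = run_manifest(cfg, counts = counts)),
    class = "tv_results")
  if (!is.null(outdir)) write_outputs(results, outdir)
  results
}

#' @export
print.tv_results <- function(x, ...) {
  cat("<tv_results>\n")
  m <- x$manifest$counts
  cat(sprintf("  catalogue: %d accepted of %d candidates (%d both-detector)\n",
              m$n_accepted, m$n_candidates, m$n_both_detectors))
  cat(sprintf("  vOTUs: %d; host links: %d spacer / %d prophage / %d shared\n",
              m$n_votus, m$n_links_spacer, m$n_links_prophage, m$n_links_shared))
  cat(sprintf("  indicator COGs: %d; AMG scaffolds: %d\n",
              m$n_indicator_cogs, m$n_amg_scaffolds))
  invisible(x)
}

# Compare two partitions given as id -> label maps; TRUE when the induced
# equivalence classes are identical.
same_partition <- function(labels_a, labels_b) {
  ids <- names(labels_a)
  if (!setequal(ids, names(labels_b))) return(FALSE)
  key_a <- split(ids, labels_a[ids])
  key_b <- split(ids, labels_b[ids])
  setequal(lapply(key_a, sort), lapply(key_b, sort))
}

#' One-command demonstration on a synthetic community
#'
#' Generates a synthetic bundle, runs the full pipeline, scores every
#' stage against the planted ground truth, and renders a plain-text
#' report of the headline statistics (richness gradients, prophage-pH
#' correlation, indicator COGs, AMG enrichment). Idempotent per seed.
#'
#' @param seed Integer seed for both the generator and the pipeline.
#' @param outdir Optional results directory.
#' @param permutations Permutations for the community statistics.
#' @return A `tv_demo` list: `bundle`, `results`, `metrics` (named list of
#'   ground-truth comparison numbers), `report` (character lines).
#' @export
demo_run <- function(seed = 0L, outdir = NULL, permutations = 999) {
  scfg <- sim_config(seed = seed)
  bundle <- simulate_bundle(scfg)
  cfg <- pipeline_config(rng_seed = seed, permutations = permutations)
  res <- run_tailings_pipeline(bundle, cfg, taxonomy = bundle$truth$taxonomy,
                               outdir = outdir)
  truth <- bundle$truth

  acc <- res$catalogue |> filter(.data$accepted)
  recall <- mean(truth$planted_viral_ids %in% acc$viral_id)
  false_pos <- setdiff(acc$viral_id, truth$planted_viral_ids)

  truth_part <- setNames(truth$votu_partition$cluster, truth$votu_partition$id)
  found_part <- setNames(res$votus$votu_id, res$votus$member_id)
  partition_exact <- same_partition(truth_part, found_part)
  ari <- if (requireNamespace("mclust", quietly = TRUE)) {
    ids <- names(truth_part)
    mclust::adjustedRandIndex(truth_part[ids], found_part[ids])
  } else as.numeric(partition_exact)

  sp <- res$host_links |> filter(.data$evidence == "spacer")
  truth_sp_keys <- paste(truth$spacer_links$virus_id,
                         truth$spacer_links$bin_id)
  sp_keys <- paste(sp$virus_id, sp$host_bin_id)
  spacer_recall <- mean(truth_sp_keys %in% sp_keys)
  decoy_sources <- unique(truth$decoy_spacers$source_virus_id)
  decoy_hits <- sum(!(sp_keys %in% truth_sp_keys))

  ind <- res$indicator_cogs
  planted <- truth$indicator_cogs
  ind_hit <- vapply(names(planted), function(cg) {
    row <- ind |> filter(.data$cog_id == cg)
    nrow(row) == 1 && row$indicator && row$direction == planted[[cg]]
  }, logical(1))
  null_fp <- ind |>
    filter(.data$cog_id %in% truth$null_cogs, .data$indicator)

  amg_found <- res$amg_report$viral_id
  groups <- truth$groups
  amg_cov <- res$scaffold_coverage |>
    filter(.data$entity_id %in% truth$amg_ids) |>
    inner_join(groups, by = "sample_id") |>
    group_by(.data$group) |>
    summarise(mean_cov = mean(.data$norm_cov), .groups = "drop")
  amg_ratio <- amg_cov$mean_cov[amg_cov$group == "deep"] /
    amg_cov$mean_cov[amg_cov$group == "surface"]

  rich_sp <- res$richness |>
    left_join(bundle$samples |> select("sample_id", "core", "depth_cm"),
              by = "sample_id") |>
    group_by(.data$core) |>
    summarise(rho = cor(.data$depth_cm, .data$richness, method = "spearman"),
              .groups = "drop")

  metrics <- list(
    catalogue_size = nrow(acc),
    planted_recall = recall,
    n_false_positive = length(false_pos),
    n_votus = dplyr::n_distinct(res$votus$votu_id),
    votu_ari = ari,
    votu_partition_exact = partition_exact,
    spacer_recall = spacer_recall,
    n_decoy_spacer_links = decoy_hits,
    n_prophage_links = sum(res$host_links$evidence == "prophage"),
    n_shared_links = sum(res$host_links$evidence == "shared_content"),
    indicator_recall = mean(ind_hit),
    n_null_indicator_fp = nrow(null_fp),
    amg_scaffolds_found = length(amg_found),
    amg_deep_surface_ratio = unname(amg_ratio),
    prophage_ph_r = res$tests$prophage_ra_ph$statistic,
    prophage_ph_p = res$tests$prophage_ra_ph$p_value,
    richness_ph_r = res$tests$richness_ph$statistic,
    richness_viral_prok_r = res$tests$richness_viral_prok$statistic,
    richness_depth_spearman = setNames(rich_sp$rho, rich_sp$core),
    anosim_depth_R = res$tests$anosim_depth$statistic,
    permanova_depth_R2 = res$tests$permanova_depth$r_squared,
    mantel_viral_prok_r = res$tests$mantel_viral_prok$statistic,
    mantel_viral_geochem_r = res$tests$mantel_viral_geochem$statistic)

  report <- c(
    sprintf("tailvirkit demo (seed %d)", seed),
    sprintf("curated catalogue: %d viral sequences (recall %.2f, %d false positives)",
            metrics$catalogue_size, metrics$planted_recall,
            metrics$n_false_positive),
    sprintf("vOTUs: %d (ARI vs planted partition: %.3f)",
            metrics$n_votus, metrics$votu_ari),
    sprintf("host links: %d spacer (recall %.2f, %d decoy), %d prophage, %d shared-content",
            sum(res$host_links$evidence == "spacer"), metrics$spacer_recall,
            metrics$n_decoy_spacer_links, metrics$n_prophage_links,
            metrics$n_shared_links),
    sprintf("prophage relative abundance vs pH: Pearson r = %.3f (p = %.3g)",
            metrics$prophage_ph_r, metrics$prophage_ph_p),
    sprintf("vOTU richness vs depth: Spearman rho = %s",
            paste(sprintf("%s %.2f", names(metrics$richness_depth_spearman),
                          metrics$richness_depth_spearman), collapse = ", ")),
    sprintf("viral vs prokaryotic richness: Pearson r = %.3f",
            metrics$richness_viral_prok_r),
    sprintf("indicator COGs: %d called; planted recall %.2f; %d null false positives",
            sum(ind$indicator), metrics$indicator_recall,
            metrics$n_null_indicator_fp),
    sprintf("AMG (COG0175) scaffolds: %d found; deep/surface coverage ratio %.1f",
            metrics$amg_scaffolds_found, metrics$amg_deep_surface_ratio),
    sprintf("depth groups: ANOSIM R = %.3f, PERMANOVA R2 = %.3f",
            metrics$anosim_depth_R, metrics$permanova_depth_R2),
    sprintf("Mantel: viral~prokaryotic r = %.3f; viral~geochemistry r = %.3f",
            metrics$mantel_viral_prok_r, metrics$mantel_viral_geochem_r))

  structure(list(bundle = bundle, results = res, metrics = metrics,
                 report = report), class = "tv_demo")
}

#' @export
print.tv_demo <- function(x, ...) {
  cat(paste(x$report, collapse = "\n"), "\n")
  invisible(x)
}
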