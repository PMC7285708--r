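# Per-COG coverage aggregation, indicator COGs between surface and deep
# groups, and the sulfate-assimilation AMG (COG0175) report.

#' Exact two-sample rank-sum test
#'
#' Two-sided rank-sum (Wilcoxon-Mann-Whitney) test with mid-ranks for
#' ties. The p-value is exact — computed by complete enumeration of all
#' `choose(n1 + n2, n1)` assignments of the pooled mid-ranks — whenever
#' that enumeration is at most `max_enumeration`; otherwise the normal
#' approximation with tie correction is used. With the package's
#' 11-sample design the test is always exact.
#'
#' @param x,y Numeric vectors for the two groups.
#' @param max_enumeration Enumeration budget (number of assignments).
#' @return A list: `statistic` (rank sum of `x`), `p_value`, `exact`
#'   (logical).
#' @examples
#' rank_sum_test(c(1, 2, 3), c(10, 11, 12, 13))$p_value   # 2/35
#' @export
rank_sum_test <- function(x, y, max_enumeration = 2e5) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 == 0 || n2 == 0) abort("both groups must be non-empty")
  rk <- rank(c(x, y))
  w_obs <- sum(rk[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  if (choose(n, n1) <= max_enumeration) {
    idx <- combn(n, n1)
    w_all <- colSums(matrix(rk[idx], nrow = n1))
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
    return(list(statistic = w_obs, p_value = p, exact = TRUE))
  }
  ties <- table(rk)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 == 0) return(list(statistic = w_obs, p_value = 1, exact = FALSE))
  z <- (abs(w_obs - mu) - 0.5) / sqrt(sigma2)   # continuity correction
  list(statistic = w_obs, p_value = min(1, 2 * pnorm(-max(z, 0))),
       exact = FALSE)
}

#' Aggregate gene-level normalized coverage to COGs
#'
#' Sums the normalized coverage of all viral genes annotated with each
#' COG, per library. Genes without a COG assignment are pooled into an
#' `"unassigned"` row so that column sums are conserved.
#'
#' @param genes Gene tibble restricted to the curated viral catalogue,
#'   with `gene_id` and `cog_id`.
#' @param gene_cov Long gene-level normalized coverage (`entity_id` =
#'   gene id, `sample_id`, `norm_cov`).
#' @return Tibble in long form: `cog_id`, `sample_id`, `norm_cov`
#'   (`cog_id = "unassigned"` collects COG-less genes).
#' @export
cog_coverage <- function(genes, gene_cov) {
  ann <- genes |>
    mutate(cog_id = ifelse(is.na(.data$cog_id) | .data$cog_id == "",
                           "unassigned", .data$cog_id)) |>
    select(entity_id = "gene_id", "cog_id")
  gene_cov |>
    inner_join(ann, by = "entity_id") |>
    group_by(.data$cog_id, .data$sample_id) |>
    summarise(norm_cov = sum(.data$norm_cov), .groups = "drop")
}

#' Indicator COGs between surface and deep layer groups
#'
#' For every testable COG, compares normalized coverage between the two
#' depth groups with the exact two-sided rank-sum test, adjusts p-values
#' with Benjamini-Hochberg across all testable COGs in one family, and
#' calls indicators at `q < alpha` with direction given by the group with
#' the larger mean. COGs that are zero in every sample are untestable and
#' skipped (they do not enter the BH family); the `"unassigned"` pool is
#' never tested.
#'
#' @param cog_cov Long COG coverage from [cog_coverage()].
#' @param groups Tibble `sample_id`, `group` with group labels `"surface"`
#'   and `"deep"`.
#' @param alpha Significance level applied to the BH-adjusted q.
#' @param carriers Optional tibble `cog_id`, `viral_id` recording which
#'   catalogue entries carry each COG (attached to the result when given).
#' @return A `tv_indicators` tibble: `cog_id`, `mean_cov_surface`,
#'   `mean_cov_deep`, `p_value`, `q_value`, `direction`, `indicator`
#'   (plus `carrier_viral_ids` when `carriers` is supplied).
#' @export
indicator_cogs <- function(cog_cov, groups, alpha = 0.05, carriers = NULL) {
  stopifnot(all(c("sample_id", "group") %in% names(groups)))
  bad <- setdiff(unique(groups$group), c("surface", "deep"))
  if (length(bad) > 0) {
    abort(sprintf("group labels must be 'surface' or 'deep', got: %s",
                  paste(bad, collapse = ", ")))
  }
  if (length(unique(groups$group)) < 2) abort("both groups must be non-empty")
  wide <- cog_cov |>
    filter(.data$cog_id != "unassigned") |>
    inner_join(groups, by = "sample_id")
  res <- wide |>
    group_by(.data$cog_id) |>
    summarise(
      mean_cov_surface = mean(.data$norm_cov[.data$group == "surface"]),
      mean_cov_deep = mean(.data$norm_cov[.data$group == "deep"]),
      all_zero = all(.data$norm_cov == 0),
      p_value = if (all(.data$norm_cov == 0)) NA_real_ else
        rank_sum_test(.data$norm_cov[.data$group == "surface"],
                      .data$norm_cov[.data$group == "deep"])$p_value,
      .groups = "drop")
  skipped <- res |> filter(.data$all_zero)
  if (nrow(skipped) > 0) {
    inform(sprintf("skipping %d COG(s) with zero coverage in all samples",
                   nrow(skipped)))
  }
  res <- res |>
    filter(!.data$all_zero) |>
    select(-"all_zero") |>
    mutate(q_value = p.adjust(.data$p_value, method = "BH"),
           direction = ifelse(.data$mean_cov_surface >= .data$mean_cov_deep,
                              "surface", "deep"),
           indicator = .data$q_value < alpha) |>
    arrange(.data$q_value, .data$cog_id)
  if (!is.null(carriers)) {
    cl <- carriers |>
      distinct(.data$cog_id, .data$viral_id) |>
      group_by(.data$cog_id) |>
      summarise(carrier_viral_ids = paste(sort(.data$viral_id), collapse = ";"),
                .groups = "drop")
    res <- res |> left_join(cl, by = "cog_id")
  }
  class(res) <- c("tv_indicators", class(res))
  res
}

#' Report sulfate-assimilation AMG carriers (COG0175)
#'
#' One report row per curated viral scaffold carrying at least one gene
#' annotated with the auxiliary-metabolic-gene COG of interest (default
#' COG0175, PAPS/sulfonucleotide reductase of assimilatory sulfate
#' reduction). `flanked_by_hallmark` is `TRUE` when a hallmark
#' (virus-specific or integrase) gene occurs both before and after the
#' AMG on the curated sequence. Per-layer normalized coverage of the
#' carrier and of the AMG gene(s), plus the surface/deep rank-sum p of
#' the carrier, are attached.
#'
#' @param catalogue Curated catalogue ([identify_viruses()], accepted
#'   entries used).
#' @param genes Classified gene tibble.
#' @param scaffold_cov Long normalized coverage of catalogue entries.
#' @param gene_cov Long normalized coverage of genes.
#' @param groups Optional `sample_id`/`group` tibble for the surface-deep
#'   comparison.
#' @param amg_cog COG identifier to report on (default `"COG0175"`).
#' @return A `tv_amg` tibble: `viral_id`, `amg_gene_ids`, `n_amg_genes`,
#'   `length`, `is_prophage`, `flanked_by_hallmark`, `genome_p_value`
#'   (when `groups` given), plus nested per-layer coverage in
#'   `genome_coverage` and `gene_coverage` list-columns.
#' @export
amg_report <- function(catalogue, genes, scaffold_cov, gene_cov,
                       groups = NULL, amg_cog = "COG0175") {
  stopifnot("hallmark" %in% names(genes))
  acc <- catalogue |> filter(.data$accepted)
  out <- list()
  for (r in seq_len(nrow(acc))) {
    g <- genes |>
      filter(.data$scaffold_id == acc$parent_scaffold_id[r],
             .data$start >= acc$region_start[r],
             .data$end <= acc$region_end[r]) |>
      arrange(.data$start)
    amg_idx <- which(!is.na(g$cog_id) & g$cog_id == amg_cog)
    if (length(amg_idx) == 0) next
    flanked <- vapply(amg_idx, function(i) {
      any(g$hallmark[seq_len(nrow(g)) < i]) &&
        any(g$hallmark[seq_len(nrow(g)) > i])
    }, logical(1))
    gcov <- gene_cov |> filter(.data$entity_id %in% g$gene_id[amg_idx])
    scov <- scaffold_cov |> filter(.data$entity_id == acc$viral_id[r])
    p <- NA_real_
    if (!is.null(groups) && nrow(scov) > 0) {
      sg <- scov |> inner_join(groups, by = "sample_id")
      p <- rank_sum_test(sg$norm_cov[sg$group == "surface"],
                         sg$norm_cov[sg$group == "deep"])$p_value
    }
    out[[length(out) + 1]] <- tibble(
      viral_id = acc$viral_id[r],
      amg_gene_ids = paste(g$gene_id[amg_idx], collapse = ";"),
      n_amg_genes = length(amg_idx),
      length = acc$region_end[r] - acc$region_start[r],
      is_prophage = acc$is_prophage[r],
      n_hallmark_genes = sum(g$hallmark),
      flanked_by_hallmark = any(flanked),
      genome_p_value = p,
      genome_coverage = list(scov),
      gene_coverage = list(gcov))
  }
  res <- if (length(out) == 0) {
    tibble(viral_id = character(), amg_gene_ids = character(),
           n_amg_genes = integer(), length = integer(),
           is_prophage = logical(), n_hallmark_genes = integer(),
           flanked_by_hallmark = logical(), genome_p_value = numeric(),
           genome_coverage = list(), gene_coverage = list())
  } else bind_rows(out)
  class(res) <- c("tv_amg", class(res))
  res
}
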