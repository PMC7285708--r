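# Normalized coverage, relative abundance and richness.

#' Library-size normalized coverage
#'
#' For each entity (scaffold, viral region, gene or vOTU) and library,
#' the average coverage (nucleotides mapped to the entity divided by the
#' entity length) is divided by the library read count and multiplied by
#' the mean read count across all libraries in the input:
#' `norm_cov = (mapped_nt / length) / reads * mean(reads)`.
#' The scaling constant is recomputed per run from the libraries present.
#'
#' @param coverage Long tibble with `entity_id`, `sample_id`, `mapped_nt`.
#'   (entity, library) pairs absent from the table count as zero coverage.
#' @param lengths Tibble with `entity_id`, `length` (nt); every entity in
#'   `coverage` must appear with positive length.
#' @param samples Sample tibble with `sample_id`, `reads`.
#' @return Long tibble `entity_id`, `sample_id`, `norm_cov`, complete over
#'   entities x libraries.
#' @examples
#' cov <- tibble::tibble(entity_id = "s1", sample_id = "A1", mapped_nt = 10000)
#' len <- tibble::tibble(entity_id = "s1", length = 1000)
#' smp <- tibble::tibble(sample_id = c("A1", "A2"), reads = c(1e6, 3e6))
#' normalized_coverage(cov, len, smp)   # 10 / 1e6 * 2e6 = 20 in A1
#' @export
normalized_coverage <- function(coverage, lengths, samples) {
  stopifnot(all(c("entity_id", "sample_id", "mapped_nt") %in% names(coverage)),
            all(c("entity_id", "length") %in% names(lengths)),
            all(c("sample_id", "reads") %in% names(samples)))
  if (any(samples$reads <= 0)) abort("library read counts must be positive")
  missing_len <- setdiff(unique(coverage$entity_id), lengths$entity_id)
  if (length(missing_len) > 0) {
    abort(sprintf("no length for entity(ies): %s",
                  paste(head(missing_len, 5), collapse = ", ")))
  }
  if (any(lengths$length <= 0)) abort("entity lengths must be positive")
  mean_reads <- mean(samples$reads)
  grid <- tidyr::expand_grid(entity_id = lengths$entity_id,
                             sample_id = samples$sample_id)
  grid |>
    left_join(coverage, by = c("entity_id", "sample_id")) |>
    mutate(mapped_nt = replace_na(.data$mapped_nt, 0)) |>
    left_join(lengths, by = "entity_id") |>
    left_join(samples |> select("sample_id", "reads"), by = "sample_id") |>
    mutate(norm_cov = (.data$mapped_nt / .data$length) / .data$reads * mean_reads) |>
    select("entity_id", "sample_id", "norm_cov")
}

#' Aggregate scaffold coverage to vOTU level
#'
#' Pools member scaffolds of each vOTU by coverage-weighted pooling:
#' summed mapped nucleotides over summed member lengths, before
#' normalization.
#'
#' @param coverage Long scaffold-level coverage (`entity_id`, `sample_id`,
#'   `mapped_nt`).
#' @param lengths Scaffold lengths (`entity_id`, `length`).
#' @param votus vOTU membership from [cluster_votus()].
#' @return A list with `coverage` and `lengths` tibbles keyed by `votu_id`
#'   (as `entity_id`), ready for [normalized_coverage()].
#' @export
votu_coverage <- function(coverage, lengths, votus) {
  memb <- votus |> select(entity_id = "member_id", "votu_id")
  cov <- coverage |>
    inner_join(memb, by = "entity_id") |>
    group_by(entity_id = .data$votu_id, .data$sample_id) |>
    summarise(mapped_nt = sum(.data$mapped_nt), .groups = "drop")
  len <- lengths |>
    inner_join(memb, by = "entity_id") |>
    group_by(entity_id = .data$votu_id) |>
    summarise(length = sum(.data$length), .groups = "drop")
  list(coverage = cov, lengths = len)
}

#' Relative abundance of a group of viral entities per library
#'
#' The cumulative normalized coverage of the group's members divided by
#' the total normalized coverage of all viral entities in that library.
#' Returns 0 when the group's sum is zero and `NA` when the library total
#' is zero (undefined community).
#'
#' @param norm_cov Long normalized coverage over the viral catalogue
#'   (`entity_id`, `sample_id`, `norm_cov`).
#' @param group_ids Character vector of entity ids; must be a subset of the
#'   catalogue.
#' @return Tibble `sample_id`, `rel_abundance`.
#' @export
relative_abundance <- function(norm_cov, group_ids) {
  outside <- setdiff(group_ids, unique(norm_cov$entity_id))
  if (length(outside) > 0) {
    abort(sprintf("group id(s) outside the catalogue: %s",
                  paste(head(outside, 5), collapse = ", ")))
  }
  norm_cov |>
    group_by(.data$sample_id) |>
    summarise(group_sum = sum(.data$norm_cov[.data$entity_id %in% group_ids]),
              total = sum(.data$norm_cov), .groups = "drop") |>
    mutate(rel_abundance = dplyr::case_when(
      .data$total == 0 ~ NA_real_,
      TRUE ~ .data$group_sum / .data$total)) |>
    select("sample_id", "rel_abundance")
}

#' vOTU richness per library
#'
#' Counts entities whose normalized coverage exceeds the presence
#' threshold (default 0: any mapped signal counts as present).
#'
#' @param norm_cov Long normalized coverage, usually vOTU-aggregated.
#' @param presence_threshold Coverage strictly above this counts as
#'   present.
#' @return Tibble `sample_id`, `richness`.
#' @export
richness <- function(norm_cov, presence_threshold = 0) {
  norm_cov |>
    group_by(.data$sample_id) |>
    summarise(richness = sum(.data$norm_cov > presence_threshold),
              .groups = "drop")
}
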