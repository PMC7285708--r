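#' Greedy species-level vOTU clustering
#'
#' Clusters curated viral sequences into viral operational taxonomic units
#' (vOTUs) with a greedy longest-first centroid rule: sequences are sorted
#' by length descending (ties broken by id); each still-unassigned sequence
#' seeds a vOTU and recruits every remaining unassigned sequence whose ANI
#' against the seed is at least `ani_threshold` with alignment fraction of
#' the shorter sequence at least `af_threshold`. The result is a partition;
#' the representative of each vOTU is its longest member. Sorting makes the
#' outcome invariant to input order.
#'
#' @param scaffolds Tibble with columns `id`, `seq` (and optionally
#'   `length`; recomputed if absent).
#' @param ani_threshold Minimum average nucleotide identity (default 0.95).
#' @param af_threshold Minimum alignment fraction of the shorter sequence
#'   (default 0.85).
#' @param min_shared_kmers Shared 15-mer prefilter; pairs below it are
#'   treated as unrelated without alignment.
#' @return Tibble with one row per input sequence: `member_id`, `votu_id`,
#'   `representative_id`, `ani_to_rep`, `af_to_rep`.
#' @examples
#' \donttest{
#' seqs <- plant_votus(n_votus = 2, members_per_votu = 2, seed = 1)
#' cluster_votus(seqs$scaffolds)
#' }
#' @export
cluster_votus <- function(scaffolds, ani_threshold = 0.95, af_threshold = 0.85,
                          min_shared_kmers = 5) {
  stopifnot(all(c("id", "seq") %in% names(scaffolds)))
  if (nrow(scaffolds) == 0) {
    return(tibble(member_id = character(), votu_id = character(),
                  representative_id = character(), ani_to_rep = numeric(),
                  af_to_rep = numeric()))
  }
  sc <- scaffolds |>
    mutate(length = nchar(.data$seq)) |>
    arrange(desc(.data$length), .data$id)
  n <- nrow(sc)
  assigned <- rep(NA_integer_, n)
  reps <- integer()
  ani_rep <- rep(NA_real_, n)
  af_rep <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!is.na(assigned[i])) next
    cl <- length(reps) + 1L
    reps[cl] <- i
    assigned[i] <- cl
    ani_rep[i] <- 1
    af_rep[i] <- 1
    if (i == n) next
    for (j in (i + 1):n) {
      if (!is.na(assigned[j])) next
      if (shared_kmer_count(sc$seq[i], sc$seq[j]) < min_shared_kmers) next
      st <- ani_pair(sc$seq[i], sc$seq[j])
      if (st$ani >= ani_threshold && st$af_small >= af_threshold) {
        assigned[j] <- cl
        ani_rep[j] <- st$ani
        af_rep[j] <- st$af_small
      }
    }
  }
  tibble(
    member_id = sc$id,
    votu_id = sprintf("vOTU_%04d", assigned),
    representative_id = sc$id[reps[assigned]],
    ani_to_rep = ani_rep,
    af_to_rep = af_rep
  ) |> arrange(.data$votu_id, desc(.data$member_id == .data$representative_id),
               .data$member_id)
}
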