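test_that("default bundle reproduces the 11-sample, 2-core stratified design", {
  b <- test_bundle()
  s <- b$samples
  expect_equal(nrow(s), 11)
  expect_equal(sort(unique(s$core)), c("A", "B"))
  expect_equal(sum(s$core == "A"), 6)
  expect_equal(sum(s$core == "B"), 5)
  # pH increases monotonically with depth within each core, ~2 surface, ~7 deep
  for (core in c("A", "B")) {
    ph <- s$pH[s$core == core][order(s$depth_cm[s$core == core])]
    expect_true(all(diff(ph) >= 0))
    expect_lt(ph[1], 3)
    expect_gt(ph[length(ph)], 6)
  }
  expect_true(all(s$reads >= 8e5 & s$reads <= 1.2e6))
  expect_true(all(b$coverage$mapped_nt >= 0))
})

test_that("bundle generation is deterministic per seed and changes across seeds", {
  b1 <- suppressMessages(simulate_bundle(sim_config(seed = 11)))
  b2 <- suppressMessages(simulate_bundle(sim_config(seed = 11)))
  b3 <- suppressMessages(simulate_bundle(sim_config(seed = 12)))
  expect_identical(b1$scaffolds, b2$scaffolds)
  expect_identical(b1$coverage, b2$coverage)
  expect_identical(b1$truth$planted_viral_ids, b2$truth$planted_viral_ids)
  expect_false(identical(b1$scaffolds$seq, b3$scaffolds$seq))
})

test_that("ground truth has referential integrity against the emitted bundle", {
  b <- test_bundle()
  parents <- sub(":.*$", "", b$truth$planted_viral_ids)
  expect_true(all(parents %in% b$scaffolds$id))
  expect_setequal(b$truth$votu_partition$id, b$truth$planted_viral_ids)
  # every planted entity has coverage rows for all 11 samples
  cov_ids <- unique(b$coverage$entity_id)
  expect_true(all(b$truth$planted_viral_ids %in% cov_ids))
})

test_that("planted community composition follows the depth gradients", {
  b <- test_bundle()
  # archaea dominate the surface, bacteria the deep layers
  frac <- b$otus |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(arch = sum(count[domain == "Archaea"]) / sum(count))
  s <- b$samples
  top <- s$sample_id[s$layer == 1]
  deepest <- s |> dplyr::group_by(core) |>
    dplyr::slice_max(depth_cm, n = 1) |> dplyr::pull(sample_id)
  expect_true(all(frac$arch[frac$sample_id %in% top] > 0.5))
  expect_true(all(frac$arch[frac$sample_id %in% deepest] < 0.2))
  # prokaryotic richness increases with depth
  rich <- b$otus |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(r = sum(count > 0)) |>
    dplyr::left_join(s, by = "sample_id")
  for (core in c("A", "B")) {
    sub <- rich[rich$core == core, ]
    expect_gt(cor(sub$depth_cm, sub$r, method = "spearman"), 0.8)
  }
  # COG0175 carriers >= 4x more covered in deep than surface layers
  amg_cov <- b$coverage |>
    dplyr::filter(entity_id %in% b$truth$amg_ids) |>
    dplyr::left_join(b$truth$groups, by = "sample_id") |>
    dplyr::group_by(group) |>
    dplyr::summarise(m = mean(mapped_nt))
  expect_gt(amg_cov$m[amg_cov$group == "deep"] /
              amg_cov$m[amg_cov$group == "surface"], 4)
})

test_that("planted vOTUs have the advertised identity structure", {
  pv <- plant_votus(n_votus = 3, members_per_votu = 4, seed = 3)
  expect_equal(nrow(pv$scaffolds), 12)
  expect_equal(dplyr::n_distinct(pv$partition$votu_truth), 3)
  # within-cluster pairwise identity by direct mismatch count: 0.98 +- 0.01
  within_ids <- c()
  for (cl in unique(pv$partition$votu_truth)) {
    ids <- pv$partition$id[pv$partition$votu_truth == cl]
    seqs <- pv$scaffolds$seq[match(ids, pv$scaffolds$id)]
    for (i in 1:(length(seqs) - 1)) for (j in (i + 1):length(seqs)) {
      a <- charToRaw(seqs[i]); b <- charToRaw(seqs[j])
      within_ids <- c(within_ids, mean(a == b))
    }
  }
  expect_true(all(abs(within_ids - 0.98) < 0.01))
  # between-cluster identity well below the 0.95 clustering threshold
  reps <- pv$scaffolds$seq[match(unique(pv$partition$votu_truth),
                                 pv$partition$votu_truth)]
  for (i in 1:2) for (j in (i + 1):3) {
    a <- charToRaw(reps[i]); b <- charToRaw(reps[j])
    expect_lt(mean(a == b), 0.85)
  }
  # a half-length member has AF ~ 0.5 against its cluster by construction
  half <- substr(pv$scaffolds$seq[1], 1, nchar(pv$scaffolds$seq[1]) %/% 2)
  st <- ani_pair(pv$scaffolds$seq[2], half)
  expect_equal(st$af_small, 1, tolerance = 0.02)        # af of the smaller
  expect_lt(st$aligned_len / nchar(pv$scaffolds$seq[2]), 0.55)
})

test_that("planted CRISPR arrays are recoverable and decoys are near-misses", {
  set.seed(5)
  hosts <- tibble::tibble(id = paste0("h", 1:4),
                          seq = replicate(4, random_seq(4000)))
  viruses <- tibble::tibble(id = paste0("v", 1:4),
                            seq = replicate(4, random_seq(3000)))
  pc <- plant_crispr(hosts, viruses, n_links = 4, n_decoys = 3, seed = 9)
  expect_equal(nrow(pc$links), 4)
  expect_true(any(pc$links$strand == "-"))   # reverse-complement plants exist
  arrays <- detect_crispr(pc$scaffolds)
  expect_gt(nrow(arrays), 0)
  hits <- match_spacers(
    arrays,
    viruses |> dplyr::rename(viral_id = id) |> dplyr::mutate(accepted = TRUE))
  keys <- unique(paste(hits$virus_id, hits$host_scaffold_id))
  truth_keys <- paste(pc$links$virus_id, pc$links$host_scaffold_id)
  expect_true(all(truth_keys %in% keys))     # recall 1.0
  expect_setequal(keys, truth_keys)          # no decoy and no spurious links
})

test_that("a zero prophage-pH slope yields a near-zero mean correlation", {
  rs <- vapply(1:20, function(i) {
    b <- suppressMessages(
      simulate_bundle(sim_config(seed = 300 + i, prophage_ph_slope = 0)))
    pro <- b$truth$planted_prophages$viral_id
    vir <- b$truth$planted_viral_ids
    lens <- dplyr::bind_rows(
      b$scaffolds |> dplyr::select(entity_id = id, length),
      b$truth$planted_prophages |>
        dplyr::mutate(length = region_end - region_start) |>
        dplyr::select(entity_id = viral_id, length))
    nc <- normalized_coverage(
      b$coverage |> dplyr::filter(entity_id %in% vir), lens, b$samples)
    ra <- relative_abundance(nc, pro)
    cor(ra$rel_abundance,
        b$samples$pH[match(ra$sample_id, b$samples$sample_id)])
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.3)
})

test_that("infeasible simulation configs are rejected", {
  expect_error(sim_config(between_votu_identity = 0.96), "infeasible")
  expect_error(sim_config(within_votu_identity = 0.90), "infeasible")
})
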