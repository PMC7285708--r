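test_that("normalized coverage implements the library-size formula", {
  cov <- tibble::tibble(entity_id = "s1", sample_id = "L1", mapped_nt = 10000)
  len <- tibble::tibble(entity_id = "s1", length = 1000)
  smp <- tibble::tibble(sample_id = c("L1", "L2"), reads = c(1e6, 3e6))
  out <- normalized_coverage(cov, len, smp)
  # (10000/1000) / 1e6 * mean(1e6, 3e6) = 10 / 1e6 * 2e6 = 20
  expect_equal(out$norm_cov[out$sample_id == "L1"], 20)
  expect_equal(out$norm_cov[out$sample_id == "L2"], 0)   # absent pair = 0

  # equal library sizes: normalization cancels, equals raw average coverage
  smp_eq <- tibble::tibble(sample_id = c("L1", "L2"), reads = c(2e6, 2e6))
  out_eq <- normalized_coverage(cov, len, smp_eq)
  expect_equal(out_eq$norm_cov[out_eq$sample_id == "L1"], 10)

  # doubling a library's reads halves its normalized coverage...
  smp2 <- smp; smp2$reads[1] <- 2e6
  out2 <- normalized_coverage(cov, len, smp2)
  ratio_reads <- (mean(smp2$reads) / 2e6) / (mean(smp$reads) / 1e6)
  expect_equal(out2$norm_cov[1] / out$norm_cov[1], ratio_reads)

  # ...and the formula is linear in mapped_nt
  cov3 <- cov; cov3$mapped_nt <- cov$mapped_nt * 3
  out3 <- normalized_coverage(cov3, len, smp)
  expect_equal(out3$norm_cov, out$norm_cov * 3)

  expect_error(normalized_coverage(cov, tibble::tibble(entity_id = "s1",
                                                       length = 0), smp),
               "positive")
  expect_error(normalized_coverage(
    tibble::tibble(entity_id = "zz", sample_id = "L1", mapped_nt = 1),
    len, smp), "no length")
})

test_that("relative abundance normalizes, nests monotonically, and sums to 1", {
  nc <- tibble::tibble(
    entity_id = rep(c("a", "b", "c"), each = 2),
    sample_id = rep(c("L1", "L2"), 3),
    norm_cov = c(2, 0, 3, 0, 5, 0))
  expect_equal(relative_abundance(nc, c("a", "b", "c"))$rel_abundance[1], 1)
  ra_a <- relative_abundance(nc, "a")
  ra_ab <- relative_abundance(nc, c("a", "b"))
  expect_equal(ra_a$rel_abundance[ra_a$sample_id == "L1"], 0.2)
  expect_true(all(ra_a$rel_abundance <= ra_ab$rel_abundance | is.na(ra_a$rel_abundance)))
  # zero-total library is undefined
  expect_true(is.na(ra_a$rel_abundance[ra_a$sample_id == "L2"]))
  # disjoint groups sum to <= 1
  ra_c <- relative_abundance(nc, "c")
  tot <- ra_ab$rel_abundance[1] + ra_c$rel_abundance[1]
  expect_lte(tot, 1 + 1e-12)
  expect_error(relative_abundance(nc, "zz"), "outside the catalogue")
})

test_that("richness counts entities above the presence threshold", {
  nc <- tibble::tibble(entity_id = rep(c("a", "b"), 2),
                       sample_id = rep(c("L1", "L2"), each = 2),
                       norm_cov = c(1.5, 0.2, 0, 0))
  expect_equal(richness(nc)$richness, c(2L, 0L))
  expect_equal(richness(nc, presence_threshold = 1)$richness, c(1L, 0L))
  expect_equal(richness(nc, presence_threshold = 99)$richness, c(0L, 0L))
})

test_that("vOTU aggregation pools members by coverage-weighted lengths", {
  cov <- tibble::tibble(entity_id = c("m1", "m2"), sample_id = "L1",
                        mapped_nt = c(1000, 3000))
  len <- tibble::tibble(entity_id = c("m1", "m2"), length = c(100, 300))
  votus <- tibble::tibble(member_id = c("m1", "m2"), votu_id = "v1",
                          representative_id = "m2")
  agg <- votu_coverage(cov, len, votus)
  expect_equal(agg$coverage$mapped_nt, 4000)
  expect_equal(agg$lengths$length, 400)
})

test_that("family-level fractions recompute the generator's planted values", {
  d <- test_demo()
  got <- d$results$family_ra |>
    dplyr::select(sample_id, family, fraction = rel_abundance)
  want <- d$bundle$truth$family_fractions
  cmp <- dplyr::inner_join(got, want, by = c("sample_id", "family"),
                           suffix = c("_got", "_want"))
  expect_equal(nrow(cmp), nrow(want))
  expect_true(all(abs(cmp$fraction_got - cmp$fraction_want) < 0.02))
})

test_that("planted richness gradients are recovered per core", {
  d <- test_demo()
  rich <- d$results$richness |>
    dplyr::left_join(d$bundle$samples, by = "sample_id")
  for (core in c("A", "B")) {
    sub <- rich[rich$core == core, ]
    expect_gt(cor(sub$depth_cm, sub$richness, method = "spearman"), 0.8)
  }
})
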