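test_that("exact rank-sum p equals complete enumeration", {
  # forced example: surface {1,2,3} vs deep {10,11,12,13} -> p = 2/35
  rs <- rank_sum_test(c(1, 2, 3), c(10, 11, 12, 13))
  expect_true(rs$exact)
  expect_equal(rs$p_value, 2 / 35)
  # identical distributions with full ties -> p = 1
  expect_equal(rank_sum_test(rep(2, 3), rep(2, 4))$p_value, 1)
  # enumeration oracle across all group sizes with n1*n2 <= 50,
  # with and without ties
  set.seed(71)
  sizes <- expand.grid(n1 = 1:7, n2 = 1:10)
  sizes <- sizes[sizes$n1 * sizes$n2 <= 50 & sizes$n1 <= sizes$n2, ]
  for (k in seq_len(nrow(sizes))) {
    n1 <- sizes$n1[k]; n2 <- sizes$n2[k]
    x <- rnorm(n1); y <- rnorm(n2)
    expect_equal(rank_sum_test(x, y)$p_value, oracle_ranksum_p(x, y),
                 info = sprintf("%d vs %d", n1, n2))
    xt <- sample(1:3, n1, replace = TRUE); yt <- sample(1:3, n2, replace = TRUE)
    expect_equal(rank_sum_test(xt, yt)$p_value, oracle_ranksum_p(xt, yt),
                 info = sprintf("ties %d vs %d", n1, n2))
  }
  # tie-free exact p also matches the classical distribution
  x <- c(1.2, 5.3, 2.2, 8.1); y <- c(0.5, 3.3, 9.9, 4.4, 6.6)
  expect_equal(rank_sum_test(x, y)$p_value,
               wilcox.test(x, y, exact = TRUE)$p.value)
})

test_that("COG aggregation is additive, order-invariant, and conserving", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    cog_id = c("COG7", "COG7", ""))
  cov <- tibble::tibble(
    entity_id = rep(c("g1", "g2", "g3"), 2),
    sample_id = rep(c("L1", "L2"), each = 3),
    norm_cov = c(3, 4, 2, 0, 0, 1))
  cc <- cog_coverage(genes, cov)
  expect_equal(cc$norm_cov[cc$cog_id == "COG7" & cc$sample_id == "L1"], 7)
  expect_equal(cc$norm_cov[cc$cog_id == "COG7" & cc$sample_id == "L2"], 0)
  expect_equal(cc$norm_cov[cc$cog_id == "unassigned" & cc$sample_id == "L2"], 1)
  # permuting the gene order changes nothing
  cc2 <- cog_coverage(genes[c(3, 1, 2), ], cov)
  expect_equal(dplyr::arrange(cc, cog_id, sample_id),
               dplyr::arrange(cc2, cog_id, sample_id))
  # conservation: column sums (incl. unassigned) equal gene-level sums
  tot <- cc |> dplyr::group_by(sample_id) |> dplyr::summarise(s = sum(norm_cov))
  gtot <- cov |> dplyr::group_by(sample_id) |> dplyr::summarise(s = sum(norm_cov))
  expect_equal(tot$s, gtot$s)
})

test_that("indicator calling recovers planted COGs with correct direction", {
  d <- test_demo()
  ind <- d$results$indicator_cogs
  planted <- d$bundle$truth$indicator_cogs
  for (cg in names(planted)) {
    row <- ind[ind$cog_id == cg, ]
    expect_equal(nrow(row), 1, info = cg)
    expect_true(row$indicator, info = cg)
    expect_equal(row$direction, unname(planted[[cg]]), info = cg)
  }
  # depth-neutral null COGs stay negative
  expect_false(any(ind$indicator[ind$cog_id %in% d$bundle$truth$null_cogs]))
  # BH is monotone: q is non-decreasing along increasing p
  expect_true(all(diff(ind$q_value[order(ind$p_value)]) >= -1e-12))
  expect_true(all(ind$q_value >= ind$p_value))
  # carriers recorded for every planted indicator
  expect_match(ind$carrier_viral_ids[ind$cog_id == "COG0175"], "vamg")
})

test_that("indicator machinery validates groups and skips untestable COGs", {
  cc <- tibble::tibble(
    cog_id = rep(c("COGA", "COGZ"), each = 4),
    sample_id = rep(paste0("s", 1:4), 2),
    norm_cov = c(5, 6, 0.1, 0.2, 0, 0, 0, 0))
  groups <- tibble::tibble(sample_id = paste0("s", 1:4),
                           group = c("surface", "surface", "deep", "deep"))
  expect_message(out <- indicator_cogs(cc, groups), "zero coverage")
  expect_equal(out$cog_id, "COGA")        # COGZ untestable, not in family
  expect_equal(out$direction, "surface")
  expect_error(indicator_cogs(cc, dplyr::mutate(groups, group = "x")),
               "surface")
})

test_that("the AMG report lists exactly the planted COG0175 carriers", {
  d <- test_demo()
  rep <- d$results$amg_full
  truth <- d$bundle$truth
  expect_setequal(rep$viral_id, truth$amg_ids)
  expect_true(all(rep$length > 10000))
  expect_true(all(rep$n_hallmark_genes >= 1))
  expect_true(all(rep$flanked_by_hallmark))
  # deep enrichment is visible in the per-genome rank-sum p
  expect_true(all(rep$genome_p_value < 0.01))
})

test_that("AMG flanking requires hallmark genes on both sides", {
  genes <- classify_genes(tibble::tibble(
    scaffold_id = "v", gene_id = paste0("g", 1:3),
    start = c(0L, 1200L, 2400L), end = c(1000L, 2200L, 3400L),
    strand = "+",
    cog_id = c("COG0175", "", ""),
    function_text = c("PAPS reductase", "phage capsid protein",
                      "hypothetical protein"),
    source_db = "eggnog"))
  cat <- tibble::tibble(viral_id = "v", parent_scaffold_id = "v",
                        region_start = 0L, region_end = 3400L,
                        is_prophage = FALSE, accepted = TRUE)
  cov <- tibble::tibble(entity_id = character(), sample_id = character(),
                        norm_cov = numeric())
  out <- amg_report(cat, genes, cov, cov)
  expect_equal(out$viral_id, "v")
  expect_false(out$flanked_by_hallmark)   # AMG at gene position 1
  # a scaffold without COG0175 is absent
  genes2 <- genes; genes2$cog_id <- ""
  expect_equal(nrow(amg_report(cat, genes2, cov, cov)), 0)
})
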