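mk_genes <- function(flags, scaffold_id = "s", len = 1200L, gap = 50L) {
  # flags: character vector, one keyword per gene ("unknown" for
  # hypothetical, "metabolic" for an annotated non-viral gene)
  n <- length(flags)
  starts <- (0:(n - 1)) * (len + gap)
  ft <- vapply(flags, function(fl) switch(
    fl,
    unknown = "hypothetical protein",
    metabolic = "ABC transporter ATP-binding protein",
    capsid = "phage capsid protein",
    terminase = "terminase large subunit",
    integrase = "site-specific integrase",
    fl), character(1))
  cog <- ifelse(flags == "metabolic", "COG1131", "")
  tibble::tibble(
    scaffold_id = scaffold_id,
    gene_id = sprintf("%s_g%d", scaffold_id, seq_len(n)),
    start = starts, end = starts + len,
    strand = "+", cog_id = cog, function_text = unname(ft),
    source_db = ifelse(flags == "unknown", "none", "eggnog"))
}

test_that("gene classification follows whole-token keyword matching", {
  g <- tibble::tibble(
    scaffold_id = "s", gene_id = paste0("g", 1:6),
    start = (0:5) * 1000L, end = (0:5) * 1000L + 900L, strand = "+",
    cog_id = c("", "", "", "", "COG0001", ""),
    function_text = c("phage terminase large subunit",
                      "hypothetical protein",
                      "heady metabolism enzyme",      # 'head' must not match
                      "T4SS secretion component",     # 't4' must not match
                      "tape measure protein",
                      "archaeal integrase"),
    source_db = "eggnog")
  cg <- classify_genes(g)
  expect_equal(cg$virus_specific, c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(cg$integrase, c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(cg$unknown, c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_true(all(cg$short))   # all genes are 900 nt < 1 kb
  # hallmark is the union used by trimming and acceptance
  expect_equal(cg$hallmark, cg$virus_specific | cg$integrase)
})

test_that("prophage trimming shrinks to hallmark boundaries and is idempotent", {
  g <- classify_genes(mk_genes(c("unknown", "capsid", "unknown", "terminase",
                                 "metabolic")))
  tr <- trim_prophage(0L, max(g$end), g)
  expect_equal(tr$status, "trimmed")
  expect_equal(tr$start, g$start[2])   # spans capsid..terminase
  expect_equal(tr$end, g$end[4])
  # idempotent and never enlarging
  tr2 <- trim_prophage(tr$start, tr$end, g)
  expect_equal(tr2[c("start", "end")], tr[c("start", "end")])

  g1 <- classify_genes(mk_genes(c("capsid", "unknown", "unknown")))
  tr1 <- trim_prophage(0L, max(g1$end), g1)
  expect_equal(c(tr1$start, tr1$end), c(g1$start[1], g1$end[1]))

  gx <- classify_genes(mk_genes(rep("unknown", 4)))
  expect_equal(trim_prophage(0L, max(gx$end), gx)$status,
               "rejected_no_hallmark")
  expect_equal(trim_prophage(0L, 10L, gx)$status, "rejected_no_genes")
})

test_that("detector merging applies length filters, dedup, and both-tool union", {
  sc <- tibble::tibble(
    id = c("pf_vs", "pf_only1", "pf_only2", "pf_only3", "vs_only1",
           "vs_only2", "pro", "short_pf"),
    seq = NA_character_,
    length = c(8000L, 8000L, 8000L, 8000L, 8000L, 8000L, 20000L, 4000L))
  pro_genes <- classify_genes(
    mk_genes(c("metabolic", "unknown", "capsid", "unknown", "terminase",
               "metabolic"), "pro"))
  other_genes <- classify_genes(
    dplyr::bind_rows(lapply(setdiff(sc$id, "pro"),
                            function(s) mk_genes(c("capsid", "unknown"), s))))
  genes <- dplyr::bind_rows(pro_genes, other_genes)
  calls <- tibble::tibble(
    scaffold_id = c("pf_vs", "pf_vs", "pf_only1", "pf_only2", "pf_only3",
                    "vs_only1", "vs_only2", "pro", "pro", "short_pf"),
    detector = c("protein_family", "virsorter", "protein_family",
                 "protein_family", "protein_family", "virsorter", "virsorter",
                 "protein_family", "virsorter", "protein_family"),
    virsorter_category = c(NA, 1L, NA, NA, NA, 2L, 1L, NA, 4L, NA),
    region_start = c(rep(NA_integer_, 8), pro_genes$start[2], NA),
    region_end = c(rep(NA_integer_, 8), pro_genes$end[6], NA))
  cand <- merge_detector_calls(calls, sc, genes)
  # protein-family whole call on 'pro' superseded by the trimmed prophage
  pro_rows <- cand[cand$parent_scaffold_id == "pro", ]
  expect_equal(nrow(pro_rows), 1)
  expect_true(pro_rows$is_prophage)
  expect_equal(pro_rows$region_start, pro_genes$start[3])  # capsid
  expect_equal(pro_rows$region_end, pro_genes$end[5])      # terminase
  # both-tool whole call collapses to one candidate
  expect_equal(cand$detectors[cand$viral_id == "pf_vs"], "both")
  # 3 pf-only + 2 vs-only + 1 both + 1 prophage; short pf call dropped
  expect_equal(nrow(cand), 7)
  expect_equal(sum(cand$detectors != "both"), 6)
  expect_false("short_pf" %in% cand$parent_scaffold_id)
  # conflicting duplicate call from one detector is malformed input
  expect_error(
    merge_detector_calls(dplyr::bind_rows(calls, calls[3, ]), sc, genes),
    "conflicting")
})

test_that("categories 3 and 6 are discarded with a log message", {
  sc <- tibble::tibble(id = "s", seq = NA_character_, length = 8000L)
  genes <- classify_genes(mk_genes(c("capsid", "unknown"), "s"))
  calls <- tibble::tibble(scaffold_id = "s", detector = "virsorter",
                          virsorter_category = 3L,
                          region_start = NA_integer_, region_end = NA_integer_)
  expect_message(out <- merge_detector_calls(calls, sc, genes), "category-3/6")
  expect_equal(nrow(out), 0)
})

test_that("acceptance requires hallmark genes or >= 80% unknown genes", {
  cases <- list(
    list(flags = c(rep("unknown", 8), "metabolic", "metabolic"),
         accepted = TRUE, reason = "unknown_fraction"),      # 8/10
    list(flags = c(rep("unknown", 7), rep("metabolic", 3)),
         accepted = FALSE, reason = "rejected"),             # 7/10
    list(flags = c("capsid", "metabolic", "metabolic"),
         accepted = TRUE, reason = "virus_specific_gene"),
    # hallmark clause wins the tie when both clauses hold
    list(flags = c("capsid", rep("unknown", 9)),
         accepted = TRUE, reason = "virus_specific_gene"))
  for (cs in cases) {
    g <- classify_genes(mk_genes(cs$flags))
    cand <- tibble::tibble(viral_id = "s", parent_scaffold_id = "s",
                           region_start = 0L, region_end = max(g$end),
                           is_prophage = FALSE, detectors = "protein_family",
                           virsorter_category = NA_integer_,
                           trim_status = "whole")
    out <- accept_viral(cand, g)
    expect_equal(out$accepted, cs$accepted, info = paste(cs$flags, collapse = ","))
    expect_equal(out$reason, cs$reason)
  }
  # zero genes in the region -> rejected
  g <- classify_genes(mk_genes("capsid"))
  cand <- tibble::tibble(viral_id = "s", parent_scaffold_id = "other",
                         region_start = 0L, region_end = 100L,
                         is_prophage = FALSE, detectors = "protein_family",
                         virsorter_category = NA_integer_,
                         trim_status = "whole")
  expect_false(accept_viral(cand, g)$accepted)
})

test_that("on synthetic bundles curation has recall 1 and rejects all decoys", {
  b <- test_bundle()
  cat <- suppressMessages(
    identify_viruses(b$scaffolds, b$genes, b$calls, pipeline_config()))
  acc <- cat[cat$accepted, ]
  expect_true(all(b$truth$planted_viral_ids %in% acc$viral_id))
  expect_length(setdiff(acc$viral_id, b$truth$planted_viral_ids), 0)
  expect_false(any(b$truth$rejected_decoy_ids %in% acc$viral_id))
  # catalogue bookkeeping: both + single = total
  expect_equal(sum(acc$detectors == "both") + sum(acc$detectors != "both"),
               nrow(acc))
})
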