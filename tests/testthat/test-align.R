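test_that("alignment statistics are exact on forced cases", {
  set.seed(1)
  a <- random_seq(5000)
  st <- ani_pair(a, a)
  expect_equal(st$ani, 1)
  expect_equal(st$af_small, 1)
  expect_equal(st$aligned_len, 5000)

  # every 50th base substituted: 2% divergence, full-length alignment
  ch <- strsplit(a, "")[[1]]
  idx <- seq(25, 5000, by = 50)
  for (i in idx) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
  b <- paste(ch, collapse = "")
  st <- ani_pair(a, b)
  expect_equal(st$ani, 0.98, tolerance = 0.005)
  expect_gte(st$af_small, 0.99)

  # containment: the shorter sequence aligns fully
  st <- ani_pair(a, substr(a, 1, 2500))
  expect_equal(st$af_small, 1, tolerance = 0.005)
  expect_gt(st$ani, 0.99)

  # reverse complement orientation is found
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
  st <- ani_pair(a, rc)
  expect_equal(st$orientation, "-")
  expect_equal(st$ani, 0.98, tolerance = 0.005)

  # unrelated sequences
  st <- ani_pair(a, random_seq(5000))
  expect_equal(st$aligned_len, 0)
  expect_equal(st$ani, 0)
})

test_that("Ns never count as matches", {
  set.seed(2)
  a <- random_seq(2000)
  b <- paste0(substr(a, 1, 1000), strrep("N", 100), substr(a, 1101, 2000))
  st <- ani_pair(a, b)
  # at most 1900 identities are available; the N block can only be
  # reported as mismatch columns or excluded from the aligned segments
  expect_lte(round(st$ani * st$aligned_len), 1900)
  expect_gte(st$aligned_len, 1800)
})

test_that("sequences shorter than the anchor size fall back to full DP", {
  st <- ani_pair("ACGTACGTACGT", "ACGTACGTACGT")
  expect_equal(st$ani, 1)
  st <- ani_pair("ACGTACGTACGT", "ACGTACCTACGT")
  expect_equal(st$ani, 11 / 12, tolerance = 1e-9)
})

test_that("seeded ANI tracks the dynamic-programming oracle on random pairs", {
  set.seed(30)
  for (i in 1:15) {
    len <- sample(1000:5000, 1)
    a <- random_seq(len)
    rate <- runif(1, 0, 0.08)
    b <- mutate_at_rate(a, rate)
    if (i %% 3 == 0) b <- substr(b, 1, round(len * runif(1, 0.5, 1)))
    mine <- ani_pair(a, b)$ani
    oracle <- dp_ani(a, b)
    expect_lt(abs(mine - oracle), 0.01)
  }
})

test_that("the k-mer prefilter only skips unrelated pairs", {
  set.seed(4)
  sc <- tibble::tibble(
    id = c("a", "b", "c"),
    seq = c(random_seq(3000), NA, random_seq(3000)))
  sc$seq[2] <- mutate_at_rate(sc$seq[1], 0.02)
  pw <- pairwise_ani(sc)
  expect_equal(nrow(pw), 3)
  ab <- pw[pw$id_a == "a" & pw$id_b == "b", ]
  expect_gt(ab$ani, 0.95)
  ac <- pw[pw$id_a == "a" & pw$id_b == "c", ]
  expect_equal(ac$ani, 0)
})
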