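test_that("Bray-Curtis follows the definition", {
  m <- rbind(s1 = c(1, 2), s2 = c(2, 1), s3 = c(1, 2), s4 = c(0, 5))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["s1", "s2"], 1 / 3)      # (1+1)/(3+3)
  expect_equal(d["s1", "s3"], 0)          # identical samples
  disj <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(as.vector(bray_curtis(disj)), 1)   # disjoint samples
  bad <- rbind(a = c(1, 1), z = c(0, 0))
  expect_error(bray_curtis(bad), "z")
  skip_if_not_installed("vegan")
  set.seed(2)
  mm <- matrix(rpois(50, 10), 5)
  expect_equal(as.vector(bray_curtis(mm)),
               as.vector(vegan::vegdist(mm, "bray")))
})

test_that("standardization gives exact z-scores and drops constants", {
  tb <- tibble::tibble(sample_id = c("a", "b", "c"),
                       x = c(1, 2, 3), y = c(10, 30, 20), k = 5)
  expect_warning(z <- standardize_env(tb), "constant")
  expect_equal(z$x, c(-1, 0, 1))          # sd with n-1 denominator
  expect_equal(mean(z$y), 0, tolerance = 1e-12)
  expect_equal(sd(z$y), 1, tolerance = 1e-12)
  expect_false("k" %in% names(z))
  # affine rescaling of a raw column leaves its z-scores unchanged
  tb2 <- tb; tb2$y <- 100 * tb$y - 7
  expect_warning(z2 <- standardize_env(tb2), "constant")
  expect_equal(z2$y, z$y)
})

test_that("PCoA recovers linear geometry and matches classical scaling", {
  x <- c(0, 1, 3, 7, 12)
  d <- stats::dist(matrix(x, ncol = 1))
  attr(d, "Labels") <- paste0("s", 1:5)
  ord <- pcoa_ord(d)
  expect_equal(abs(cor(ord$coordinates$Axis1, x)), 1)
  expect_true(all(diff(ord$eigenvalues) <= 1e-9))   # sorted decreasing
  expect_true(all(ord$proportion_explained >= 0 &
                    ord$proportion_explained <= 1))
  # PCoA of Euclidean distances of centered data = PCA scores up to sign
  set.seed(7)
  m <- scale(matrix(rnorm(30), 6), scale = FALSE)
  ordp <- pcoa_ord(stats::dist(m))
  pc <- prcomp(m, center = FALSE)
  for (k in 1:2) {
    expect_equal(abs(cor(ordp$coordinates[[paste0("Axis", k)]], pc$x[, k])), 1)
  }
  # two samples: one axis, coordinate difference equals the distance
  d2 <- stats::as.dist(matrix(c(0, 3, 3, 0), 2))
  o2 <- pcoa_ord(d2)
  expect_equal(abs(diff(o2$coordinates$Axis1)), 3)
})

test_that("ANOSIM matches its definition, vegan, and exhaustive enumeration", {
  set.seed(21)
  m <- matrix(rnorm(7 * 5), 7); rownames(m) <- paste0("s", 1:7)
  g <- c("a", "a", "a", "b", "b", "b", "b")
  d <- stats::dist(m)
  a <- anosim_test(d, g, permutations = 99, seed = 1)
  expect_equal(a$statistic, oracle_anosim_R(d, g))
  skip_if_not_installed("vegan")
  expect_equal(a$statistic, vegan::anosim(d, g, permutations = 0)$statistic)

  # perfectly separated groups reach R = 1
  sep <- rbind(matrix(rnorm(6, 0, 0.01), 3), matrix(rnorm(8, 50, 0.01), 4))
  asep <- anosim_test(stats::dist(sep), g, permutations = 49, seed = 1)
  expect_equal(asep$statistic, 1)

  # exhaustive enumeration at n = 4 equals the brute-force p
  set.seed(22)
  m4 <- matrix(rnorm(8), 4)
  g4 <- c("x", "x", "y", "y")
  d4 <- stats::dist(m4)
  perms <- exhaustive_two_group_perms(g4)
  mine <- anosim_test(d4, g4, permutations = perms)
  r_all <- apply(perms, 1, function(ix) oracle_anosim_R(d4, g4[ix]))
  expect_equal(mine$p_value,
               mean(r_all >= oracle_anosim_R(d4, g4) - 1e-12))

  # under random labels the mean statistic is ~0
  set.seed(23)
  rs <- replicate(200, {
    anosim_test(d, sample(g), permutations = 0L + 1, seed = 1)$statistic
  })
  expect_lt(abs(mean(rs)), 0.05)
  expect_error(anosim_test(d, rep("a", 7)), "two groups")
})

test_that("PERMANOVA partitions distances per the definition and vegan", {
  set.seed(31)
  m <- matrix(rpois(8 * 6, 15), 8)
  g <- rep(c("u", "v"), each = 4)
  d <- bray_curtis(m)
  p <- permanova_test(d, g, permutations = 99, seed = 2)
  o <- oracle_permanova(d, g)
  expect_equal(p$statistic, o$F)
  expect_equal(p$r_squared, o$R2)
  skip_if_not_installed("vegan")
  va <- vegan::adonis2(d ~ g, permutations = 2)
  expect_equal(p$statistic, va$F[1])
  expect_equal(p$r_squared, va$R2[1])

  # identical within-group replicates, distinct between: R2 = 1
  rep_m <- rbind(matrix(1:6, 2, 3, byrow = TRUE)[c(1, 1), ],
                 matrix(7:12, 2, 3, byrow = TRUE)[c(1, 1), ])
  dr <- stats::dist(rep_m)
  expect_equal(permanova_test(dr, c("a", "a", "b", "b"),
                              permutations = 9, seed = 1)$r_squared, 1)

  # null expectation of R2 is ~ (g-1)/(n-1)
  set.seed(32)
  r2s <- replicate(300, {
    permanova_test(d, sample(g), permutations = 1, seed = 1)$r_squared
  })
  expect_equal(mean(r2s), (2 - 1) / (8 - 1), tolerance = 0.02)

  # exhaustive enumeration at n = 4
  set.seed(33)
  d4 <- stats::dist(matrix(rnorm(8), 4))
  g4 <- c("x", "x", "y", "y")
  perms <- exhaustive_two_group_perms(g4)
  mine <- permanova_test(d4, g4, permutations = perms)
  f_all <- apply(perms, 1, function(ix) oracle_permanova(d4, g4[ix])$F)
  expect_equal(mine$p_value,
               mean(f_all >= oracle_permanova(d4, g4)$F - 1e-12))
})

test_that("Mantel correlation is affine-invariant and enumeration-exact", {
  set.seed(41)
  m <- matrix(rnorm(5 * 4), 5)
  d1 <- stats::dist(m)
  expect_equal(mantel_test(d1, d1, permutations = 9, seed = 1)$statistic, 1)
  d2 <- 2.5 * d1 + 1
  expect_equal(mantel_test(d1, d2, permutations = 9, seed = 1)$statistic, 1)
  skip_if_not_installed("vegan")
  d3 <- stats::dist(matrix(rnorm(5 * 4), 5))
  expect_equal(mantel_test(d1, d3, permutations = 9, seed = 1)$statistic,
               vegan::mantel(d1, d3, permutations = 2)$statistic)
  # exhaustive p over all 5! joint row/column permutations
  perms <- all_permutations(5)
  mine <- mantel_test(d1, d3, permutations = perms)
  m3 <- as.matrix(d3)
  r_all <- apply(perms, 1, function(ix) {
    cor(as.vector(d1), as.vector(stats::as.dist(m3[ix, ix])))
  })
  obs <- cor(as.vector(d1), as.vector(d3))
  expect_equal(mine$p_value, mean(r_all >= obs - 1e-12))
  expect_error(mantel_test(d1, stats::dist(matrix(rnorm(8), 4))), "size")
})

test_that("permutation p-values use the add-one convention and never hit 0", {
  set.seed(51)
  sep <- rbind(matrix(rnorm(6, 0, 0.01), 3), matrix(rnorm(8, 9, 0.01), 4))
  g <- c(rep("a", 3), rep("b", 4))
  a <- anosim_test(stats::dist(sep), g, permutations = 999, seed = 3)
  # (1 + k) / (1 + 999): strictly positive and on the add-one lattice
  expect_gte(a$p_value, 1 / 1000)
  expect_equal(a$p_value * 1000, round(a$p_value * 1000))
  expect_lt(a$p_value, 0.05)
  p <- permanova_test(stats::dist(sep), g, permutations = 999, seed = 3)
  expect_gt(p$p_value, 0)
  # reproducible given (seed, permutations)
  a2 <- anosim_test(stats::dist(sep), g, permutations = 999, seed = 3)
  expect_identical(a$p_value, a2$p_value)
})

test_that("Pearson correlation matches the closed form and rejects degeneracy", {
  ct <- pearson_cor(c(1, 2, 3), c(1, 2, 2))
  expect_equal(ct$statistic, sqrt(3) / 2, tolerance = 1e-4)   # 0.8660
  expect_equal(pearson_cor(1:10, 2 * (1:10) + 1)$statistic, 1)
  expect_error(pearson_cor(rep(1, 5), 1:5), "variance")
  expect_error(pearson_cor(1:2, 2:3), "3 observations")
})

test_that("tidy and glance methods return broom-shaped tibbles", {
  set.seed(61)
  d <- stats::dist(matrix(rnorm(12), 6))
  g <- rep(c("a", "b"), 3)
  td <- tidy(anosim_test(d, g, permutations = 19, seed = 1))
  expect_true(all(c("statistic", "p.value") %in% names(td)))
  expect_equal(nrow(td), 1)
  ord <- pcoa_ord(d)
  expect_true(all(c("axis", "eigenvalue") %in% names(tidy(ord))))
  expect_equal(glance(ord)$n_samples, 6)
  res <- test_demo()$results
  expect_true(all(c("test", "statistic", "p.value") %in% names(tidy(res))))
  expect_equal(glance(res)$n_amg_scaffolds, 3)
})
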