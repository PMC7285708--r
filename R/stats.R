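# Distance matrices, ordination, and the permutation/correlation statistics
# relating viral communities, prokaryotic communities and geochemistry.

as_sample_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- paste0("sample", seq_len(nrow(x)))
    return(x)
  }
  stopifnot(is.data.frame(x))
  if ("sample_id" %in% names(x)) {
    ids <- x$sample_id
    m <- as.matrix(x[setdiff(names(x), "sample_id")])
    rownames(m) <- ids
    m
  } else {
    as.matrix(x)
  }
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(i, j) = sum|x_ik - x_jk| / sum(x_ik + x_jk)` over taxa `k`.
#'
#' @param x Samples-by-taxa abundance table: a numeric matrix with sample
#'   rownames, or a tibble with a `sample_id` column and one numeric
#'   column per taxon. Abundances must be non-negative and no sample may
#'   be all zero.
#' @return A `dist` object with `metric` attribute `"bray_curtis"`.
#' @examples
#' m <- rbind(a = c(1, 2), b = c(2, 1))
#' bray_curtis(m)   # (1 + 1) / (3 + 3) = 1/3
#' @export
bray_curtis <- function(x) {
  m <- as_sample_matrix(x)
  if (any(m < 0)) abort("abundances must be non-negative")
  zero <- rowSums(m) == 0
  if (any(zero)) {
    abort(sprintf("all-zero sample(s): %s",
                  paste(rownames(m)[zero], collapse = ", ")))
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
    }
  }
  out <- stats::as.dist(d)
  attr(out, "metric") <- "bray_curtis"
  out
}

#' Standardize environmental variables
#'
#' Per-parameter z-scores (mean 0, sd 1, `n - 1` denominator). Constant
#' parameters are dropped with a warning.
#'
#' @param x Samples-by-parameter table (matrix with sample rownames or
#'   tibble with `sample_id`).
#' @return Tibble with `sample_id` and the standardized columns.
#' @export
standardize_env <- function(x) {
  m <- as_sample_matrix(x)
  sds <- apply(m, 2, sd)
  const <- sds == 0 | is.na(sds)
  if (any(const)) {
    warn(sprintf("dropping constant parameter(s): %s",
                 paste(colnames(m)[const], collapse = ", ")))
    m <- m[, !const, drop = FALSE]
  }
  z <- scale(m)
  tibble(sample_id = rownames(m)) |>
    dplyr::bind_cols(as_tibble(as.data.frame(z)))
}

#' Euclidean distance on standardized environmental variables
#'
#' @inheritParams standardize_env
#' @return A `dist` object with `metric` attribute `"euclidean"`.
#' @export
euclidean_env <- function(x) {
  z <- standardize_env(x)
  m <- as_sample_matrix(z)
  out <- stats::dist(m)
  attr(out, "metric") <- "euclidean"
  out
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers `-d^2 / 2`, eigendecomposes, and returns coordinates
#' scaled by the square roots of the positive eigenvalues. Negative
#' eigenvalues (possible for non-Euclidean dissimilarities such as
#' Bray-Curtis) are reported but excluded from the denominator of the
#' proportion of variance explained.
#'
#' @param d A `dist` object.
#' @param k Number of axes to keep (default: all positive-eigenvalue
#'   axes).
#' @return A `tv_ordination` object: list with `coordinates` (tibble,
#'   `sample_id` + `Axis1..k`), `eigenvalues`, `proportion_explained`,
#'   `method = "PCoA"`.
#' @export
pcoa_ord <- function(d, k = NULL) {
  D <- as.matrix(d)
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  pos <- eig$values > sqrt(.Machine$double.eps) * max(abs(eig$values), 1)
  npos <- sum(pos)
  if (is.null(k)) k <- npos else k <- min(k, npos)
  coords <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(eig$values[seq_len(k)]), k, k)
  colnames(coords) <- paste0("Axis", seq_len(k))
  structure(list(
    coordinates = tibble(sample_id = rownames(D) %||%
                           paste0("sample", seq_len(n))) |>
      dplyr::bind_cols(as_tibble(as.data.frame(coords))),
    eigenvalues = eig$values,
    proportion_explained = ifelse(eig$values > 0,
                                  eig$values / sum(eig$values[eig$values > 0]), 0),
    method = "PCoA"), class = "tv_ordination")
}

#' Principal component analysis of standardized variables
#'
#' @inheritParams standardize_env
#' @return A `tv_ordination` object (`method = "PCA"`, coordinates are the
#'   scores).
#' @export
pca_ord <- function(x) {
  z <- standardize_env(x)
  m <- as_sample_matrix(z)
  pc <- prcomp(m, center = FALSE, scale. = FALSE)
  coords <- pc$x
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  ev <- pc$sdev^2
  structure(list(
    coordinates = tibble(sample_id = rownames(m)) |>
      dplyr::bind_cols(as_tibble(as.data.frame(coords))),
    eigenvalues = ev,
    proportion_explained = ev / sum(ev),
    method = "PCA"), class = "tv_ordination")
}

#' @export
print.tv_ordination <- function(x, ...) {
  cat(sprintf("<tv_ordination: %s, %d samples>\n", x$method,
              nrow(x$coordinates)))
  pe <- x$proportion_explained
  cat(sprintf("  axis 1: %.1f%%  axis 2: %.1f%%\n", 100 * pe[1],
              if (length(pe) > 1) 100 * pe[2] else NA))
  invisible(x)
}

check_groups <- function(d, groups) {
  n <- attr(d, "Size")
  groups <- as.factor(groups)
  if (length(groups) != n) abort("groups must have one label per sample")
  if (nlevels(droplevels(groups)) < 2) abort("at least two groups are required")
  droplevels(groups)
}

# Build the permutation index matrix: `permutations` random permutations
# drawn under `seed`, or a user-supplied matrix (rows = permutations),
# e.g. the complete enumeration for exhaustive tests.
perm_matrix <- function(n, permutations, seed) {
  if (is.matrix(permutations)) {
    stopifnot(ncol(permutations) == n)
    return(list(idx = permutations, exhaustive = TRUE))
  }
  draw <- function() t(replicate(permutations, sample.int(n)))
  idx <- if (is.null(seed)) draw() else with_seed(seed, draw())
  list(idx = idx, exhaustive = FALSE)
}

# Add-one permutation p-value for sampled permutations; plain proportion
# for an exhaustive enumeration supplied as a matrix (which includes the
# identity), so that exhaustive p equals the enumeration exactly. p is
# never 0 either way.
perm_pvalue <- function(stat_obs, stat_perm, exhaustive) {
  ge <- sum(stat_perm >= stat_obs - 1e-12)
  if (exhaustive) ge / length(stat_perm)
  else (1 + ge) / (1 + length(stat_perm))
}

anosim_stat <- function(rk, within, M) {
  (mean(rk[!within]) - mean(rk[within])) / (M / 2)
}

#' Analysis of similarity (ANOSIM)
#'
#' Rank-based test of group separation in a distance matrix:
#' `R = (mean between-group rank - mean within-group rank) / (M / 2)` with
#' `M = n(n-1)/2`. Significance by permutation of group labels with the
#' add-one convention `p = (1 + #(R_perm >= R_obs)) / (1 + permutations)`.
#'
#' @param d A `dist` object.
#' @param groups Group labels, one per sample, in the order of `d`.
#' @param permutations Number of random permutations (default 999), or a
#'   matrix of permutation index rows (e.g. the complete enumeration, in
#'   which case `p` is the exact proportion over the supplied rows).
#' @param seed Integer seed for the permutation stream (`NULL`: use the
#'   session RNG).
#' @return A `tv_anosim` object: list with `statistic` (R), `p_value`,
#'   `permutations`, `groups`.
#' @export
anosim_test <- function(d, groups, permutations = 999, seed = NULL) {
  groups <- check_groups(d, groups)
  n <- attr(d, "Size")
  dv <- as.vector(d)
  rk <- rank(dv)
  M <- n * (n - 1) / 2
  pair_i <- unlist(lapply(1:(n - 1), function(i) rep(i, n - i)))
  pair_j <- unlist(lapply(1:(n - 1), function(i) (i + 1):n))
  within <- groups[pair_i] == groups[pair_j]
  obs <- anosim_stat(rk, within, M)
  pm <- perm_matrix(n, permutations, seed)
  perm_stats <- apply(pm$idx, 1, function(ix) {
    g <- groups[ix]
    anosim_stat(rk, g[pair_i] == g[pair_j], M)
  })
  structure(list(statistic = obs,
                 p_value = perm_pvalue(obs, perm_stats, pm$exhaustive),
                 permutations = nrow(pm$idx), groups = groups,
                 method = "ANOSIM"),
            class = "tv_anosim")
}

permanova_ss <- function(d2, groups, pair_i, pair_j, n) {
  ss_total <- sum(d2) / n
  ss_within <- 0
  for (g in levels(groups)) {
    sel <- groups[pair_i] == g & groups[pair_j] == g
    ss_within <- ss_within + sum(d2[sel]) / sum(groups == g)
  }
  c(total = ss_total, within = ss_within)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-factor partition of the sum of squared distances (the
#' distance-based formulation): `SS_total = sum(d^2) / n` over all pairs,
#' `SS_within` summed per group, `R^2 = 1 - SS_within / SS_total`,
#' `pseudo-F = (SS_between / (g - 1)) / (SS_within / (n - g))`.
#' Permutation p-value on pseudo-F as in [anosim_test()].
#'
#' @inheritParams anosim_test
#' @return A `tv_permanova` object: list with `statistic` (pseudo-F),
#'   `r_squared`, `p_value`, `permutations`, `groups`.
#' @export
permanova_test <- function(d, groups, permutations = 999, seed = NULL) {
  groups <- check_groups(d, groups)
  n <- attr(d, "Size")
  g <- nlevels(groups)
  d2 <- as.vector(d)^2
  pair_i <- unlist(lapply(1:(n - 1), function(i) rep(i, n - i)))
  pair_j <- unlist(lapply(1:(n - 1), function(i) (i + 1):n))
  fstat <- function(grp) {
    ss <- permanova_ss(d2, grp, pair_i, pair_j, n)
    ss_b <- ss["total"] - ss["within"]
    unname((ss_b / (g - 1)) / (ss["within"] / (n - g)))
  }
  ss <- permanova_ss(d2, groups, pair_i, pair_j, n)
  obs_f <- fstat(groups)
  r2 <- unname(1 - ss["within"] / ss["total"])
  pm <- perm_matrix(n, permutations, seed)
  perm_stats <- apply(pm$idx, 1, function(ix) fstat(groups[ix]))
  structure(list(statistic = obs_f, r_squared = r2,
                 p_value = perm_pvalue(obs_f, perm_stats, pm$exhaustive),
                 permutations = nrow(pm$idx), groups = groups,
                 method = "PERMANOVA"),
            class = "tv_permanova")
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the `n(n-1)/2` lower-triangle pairs;
#' significance by jointly permuting rows and columns of the second
#' matrix.
#'
#' @param d1,d2 `dist` objects over the same samples in the same order
#'   (checked via labels when present).
#' @inheritParams anosim_test
#' @return A `tv_mantel` object: list with `statistic` (r), `p_value`,
#'   `permutations`.
#' @export
mantel_test <- function(d1, d2, permutations = 999, seed = NULL) {
  n <- attr(d1, "Size")
  if (attr(d2, "Size") != n) abort("distance matrices differ in size")
  l1 <- attr(d1, "Labels"); l2 <- attr(d2, "Labels")
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2)) {
    abort("distance matrices are over different sample sets/orders")
  }
  v1 <- as.vector(d1)
  m2 <- as.matrix(d2)
  obs <- cor(v1, as.vector(stats::as.dist(m2)))
  pm <- perm_matrix(n, permutations, seed)
  perm_stats <- apply(pm$idx, 1, function(ix) {
    cor(v1, as.vector(stats::as.dist(m2[ix, ix])))
  })
  structure(list(statistic = obs,
                 p_value = perm_pvalue(obs, perm_stats, pm$exhaustive),
                 permutations = nrow(pm$idx), method = "Mantel"),
            class = "tv_mantel")
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric vectors (`n >= 3`, finite, non-constant).
#' @return A `tv_pearson` object: list with `statistic` (r), `p_value`,
#'   `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("at least 3 observations are required")
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("non-finite values")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in x or y")
  ct <- cor.test(x, y, method = "pearson")
  structure(list(statistic = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x), method = "Pearson"),
            class = "tv_pearson")
}

#' @export
print.tv_anosim <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$permutations))
  invisible(x)
}

#' @export
print.tv_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, R2 = %.4f, p = %.4g (%d permutations)\n",
              x$statistic, x$r_squared, x$p_value, x$permutations))
  invisible(x)
}

#' @export
print.tv_mantel <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4f, p = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$permutations))
  invisible(x)
}

#' @export
print.tv_pearson <- function(x, ...) {
  cat(sprintf("Pearson: r = %.4f, p = %.4g (n = %d)\n",
              x$statistic, x$p_value, x$n))
  invisible(x)
}

#' Average-linkage clustering of indicator-COG profiles
#'
#' Plotting convenience for heatmaps of indicator COGs: rows are
#' log-transformed (`log10(x + pseudocount)`), z-scored, and clustered by
#' average linkage on Euclidean distance. Clearly non-inferential.
#'
#' @param m COG-by-sample matrix of normalized coverage.
#' @param pseudocount Added before the log transform.
#' @return An `hclust` object over the rows.
#' @export
cluster_cog_profiles <- function(m, pseudocount = 1e-6) {
  lz <- t(scale(t(log10(m + pseudocount))))
  lz[is.nan(lz)] <- 0
  stats::hclust(stats::dist(lz), method = "average")
}
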