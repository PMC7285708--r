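# broom-style tidy()/glance() methods for the fitted statistic objects.

#' Tidy methods for tailvirkit statistic objects
#'
#' One row per fitted statistic, in the broom convention: `statistic`,
#' `p.value` and method-specific columns.
#'
#' @param x A `tv_anosim`, `tv_permanova`, `tv_mantel`, `tv_pearson`,
#'   `tv_ordination` or `tv_results` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tailvirkit-tidiers
NULL

#' @rdname tailvirkit-tidiers
#' @export
tidy.tv_anosim <- function(x, ...) {
  tibble(method = "ANOSIM", statistic = x$statistic, p.value = x$p_value,
         permutations = x$permutations)
}

#' @rdname tailvirkit-tidiers
#' @export
tidy.tv_permanova <- function(x, ...) {
  tibble(method = "PERMANOVA", statistic = x$statistic,
         r.squared = x$r_squared, p.value = x$p_value,
         permutations = x$permutations)
}

#' @rdname tailvirkit-tidiers
#' @export
tidy.tv_mantel <- function(x, ...) {
  tibble(method = "Mantel", statistic = x$statistic, p.value = x$p_value,
         permutations = x$permutations)
}

#' @rdname tailvirkit-tidiers
#' @export
tidy.tv_pearson <- function(x, ...) {
  tibble(method = "Pearson", statistic = x$statistic, p.value = x$p_value,
         n = x$n)
}

#' @rdname tailvirkit-tidiers
#' @export
tidy.tv_ordination <- function(x, ...) {
  k <- sum(grepl("^Axis", names(x$coordinates)))
  tibble(axis = seq_len(k),
         eigenvalue = x$eigenvalues[seq_len(k)],
         proportion_explained = x$proportion_explained[seq_len(k)])
}

#' @rdname tailvirkit-tidiers
#' @export
tidy.tv_results <- function(x, ...) {
  x$stats |> rename(p.value = "p_value", r.squared = "r_squared")
}

#' @rdname tailvirkit-tidiers
#' @export
glance.tv_results <- function(x, ...) {
  m <- x$manifest$counts
  as_tibble(m[c("n_candidates", "n_accepted", "n_votus", "n_links_spacer",
                "n_links_prophage", "n_links_shared", "n_indicator_cogs",
                "n_amg_scaffolds")])
}

#' @rdname tailvirkit-tidiers
#' @export
glance.tv_ordination <- function(x, ...) {
  tibble(method = x$method,
         n_samples = nrow(x$coordinates),
         n_positive_eigenvalues = sum(x$eigenvalues > 0),
         first_axis_prop = x$proportion_explained[1])
}
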